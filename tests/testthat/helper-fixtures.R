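# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures are stored.

# a compact 32x32 spectrogram configuration (k_f = k_t = 1, n = 5) that
# keeps auto-encoder tests fast while exercising the same code paths
tiny_config <- function(compression = "log", layout = "mel") {
  spectrogram_config(fs = 32000, nfft = 256, T = 0.1,
                     n_mels = 32L, n_time = 32L, k_f = 1L, k_t = 1L,
                     layout = layout, compression = compression)
}

# render a small labelled repertoire and return annotations + audio dir
tiny_repertoire <- function(n_types = 2L, n_per_type = 20L, seed = 7L,
                            snr_db = 40, jitter = 0.02) {
  spec <- repertoire_spec(n_types = n_types, snr_db = snr_db,
                          jitter = jitter, seed = seed)
  render_dataset(spec, n_per_type = n_per_type,
                 dir = withr::local_tempdir(.local_envir = parent.frame()),
                 seed = seed)
}

# brute-force mutual-information / entropy evaluation on a contingency
# table, written independently of the package implementation: explicit
# loops over cells, KL form computed cell by cell
nmi_bruteforce <- function(tab) {
  n <- sum(tab)
  hl <- 0
  for (i in seq_len(nrow(tab))) {
    p <- sum(tab[i, ]) / n
    if (p > 0) hl <- hl - p * log(p)
  }
  hc <- 0
  for (j in seq_len(ncol(tab))) {
    p <- sum(tab[, j]) / n
    if (p > 0) hc <- hc - p * log(p)
  }
  kl <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      pij <- tab[i, j] / n
      if (pij > 0) {
        kl <- kl + pij * log(pij / (sum(tab[i, ]) / n * sum(tab[, j]) / n))
      }
    }
  }
  kl * 2 / (hl + hc)
}

# deterministic Gaussian blob matrix: k blobs of n_each points in d dims
make_blobs <- function(k, n_each, d, sep = 10, sd = 0.5, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * d), k, d) * sep
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    matrix(rnorm(n_each * d, sd = sd), n_each, d) +
      matrix(centers[i, ], n_each, d, byrow = TRUE)
  }))
  list(x = x, labels = rep(seq_len(k), each = n_each))
}
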