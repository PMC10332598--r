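#' Synthetic vocal repertoire specification
#'
#' Describes a controllable repertoire of `n_types` unit types, each a
#' harmonic stack following a spectro-temporal contour (constant tone,
#' linear chirp, or sinusoidal FM), with intra-type jitter on frequencies
#' and durations, and background noise at a controlled SNR. Types are
#' spread over distinct base frequencies with 1-3 harmonics, cycling
#' through the three contour families, so that a discrete repertoire is
#' separable by construction; `graded = TRUE` instead draws strongly
#' jittered, overlapping contours emulating a graded repertoire.
#'
#' @param n_types Number of unit types.
#' @param fs Sampling rate (Hz); the default 32 kHz matches a songbird
#'   recording setup.
#' @param snr_db Signal-to-noise ratio per unit in dB (`Inf` = no noise).
#' @param noise `"white"` or `"pink"` background.
#' @param jitter Fractional (log-normal sd) jitter applied to type
#'   frequencies and durations; 3% by default.
#' @param duration_mean,duration_sd Unit duration distribution (s).
#' @param envelope `"hann"` (smooth on/offsets) or `"flat"`.
#' @param graded If `TRUE`, quadruple the jitter and compress the
#'   frequency spacing so types overlap (a graded repertoire).
#' @param seed Master seed; every unit derives its own stream from it,
#'   so any single unit is reproducible in isolation.
#' @return Object of class `"repertoire_spec"` with a `types` data frame
#'   (`label`, `contour`, `f_start`, `f_end`, `n_harmonics`,
#'   `duration_mean`, `duration_sd`, `envelope`).
#' @export
repertoire_spec <- function(n_types = 6L, fs = 32000, snr_db = 20,
                            noise = c("white", "pink"), jitter = 0.03,
                            duration_mean = 0.06, duration_sd = 0.008,
                            envelope = c("hann", "flat"), graded = FALSE,
                            seed = 1L) {
  noise <- match.arg(noise)
  envelope <- match.arg(envelope)
  stopifnot(n_types >= 1, fs > 0, duration_mean > 0)
  if (graded) jitter <- max(jitter * 4, 0.2)
  contours <- rep_len(c("tone", "chirp", "fm"), n_types)
  f_lo <- 800; f_hi <- 3500
  if (graded) { f_lo <- 1500; f_hi <- 2200 }  # overlapping band
  f_start <- if (n_types == 1) (f_lo + f_hi) / 2 else
    seq(f_lo, f_hi, length.out = n_types)
  n_harm <- rep_len(c(3L, 1L, 2L), n_types)
  f_end <- ifelse(contours == "chirp", f_start * 1.3, f_start)
  if (any(pmax(f_start, f_end) * n_harm >= fs / 2)) {
    stop("aliasing: f * n_harmonics reaches Nyquist (", fs / 2, " Hz)")
  }
  types <- data.frame(
    label = sprintf("type%02d", seq_len(n_types)),
    contour = contours, f_start = f_start, f_end = f_end,
    n_harmonics = n_harm,
    duration_mean = duration_mean, duration_sd = duration_sd,
    envelope = envelope, stringsAsFactors = FALSE
  )
  structure(list(n_types = as.integer(n_types), fs = fs, snr_db = snr_db,
                 noise = noise, jitter = jitter, graded = graded,
                 types = types, seed = as.integer(seed)),
            class = "repertoire_spec")
}

# deterministic per-unit seed stream (counter-based, < 2^31)
unit_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 7919) %% 2147483647)
}

#' Synthesise one vocalisation unit
#'
#' Deterministic given the type specification and the jitter draw: a
#' stack of `n_harmonics` partials (amplitude 1/h) following the type's
#' frequency contour, shaped by the amplitude envelope and
#' peak-normalised.
#'
#' @param type_spec One row of `repertoire_spec()$types` (as a list or
#'   one-row data frame).
#' @param jitter_draw List with `f_mult` (frequency multiplier) and
#'   `duration` (s); use `list(f_mult = 1, duration = NULL)` for the
#'   nominal unit.
#' @param fs Sampling rate (Hz).
#' @return Numeric waveform, peak-normalised to 1 (all-zero if the
#'   envelope is identically zero).
#' @export
synth_unit <- function(type_spec, jitter_draw = list(f_mult = 1,
                                                     duration = NULL),
                       fs = 32000) {
  ts <- as.list(type_spec)
  dur <- jitter_draw$duration %||% ts$duration_mean
  f0 <- ts$f_start * jitter_draw$f_mult
  f1 <- ts$f_end * jitter_draw$f_mult
  if (max(f0, f1) * ts$n_harmonics >= fs / 2) {
    stop("aliasing: harmonic ", ts$n_harmonics, " of ", max(f0, f1),
         " Hz reaches Nyquist at fs = ", fs)
  }
  n <- max(as.integer(round(dur * fs)), 2L)
  t <- (seq_len(n) - 1L) / fs
  # instantaneous frequency and its phase integral
  phase1 <- switch(ts$contour,
    tone = f0 * t,
    chirp = f0 * t + (f1 - f0) * t^2 / (2 * dur),
    fm = {
      depth <- 0.08; rate <- 25  # mild vibrato: +-8% at 25 Hz
      f0 * t - f0 * depth / (2 * pi * rate) * (cos(2 * pi * rate * t) - 1)
    },
    stop("unknown contour ", ts$contour)
  )
  x <- numeric(n)
  for (h in seq_len(ts$n_harmonics)) {
    x <- x + sin(2 * pi * h * phase1) / h
  }
  env <- switch(ts$envelope,
    flat = rep(1, n),
    hann = hann_window(n),
    stop("unknown envelope ", ts$envelope)
  )
  x <- x * env
  peak <- max(abs(x))
  if (peak > 0) x <- x / peak
  x
}

#' Render a synthetic dataset to WAV + annotations
#'
#' Places `n_per_type` jittered units of every type on a silence-gapped
#' timeline (type order interleaved), rescales units to a common RMS,
#' adds background noise at the requested SNR, writes one WAV file and
#' returns the matching annotation table with ground-truth labels.
#'
#' @param spec A [repertoire_spec()].
#' @param n_per_type Units per type.
#' @param dir Output directory (created if needed).
#' @param seed Master seed; defaults to `spec$seed`.
#' @param gap_s Silent gap between consecutive units (s).
#' @return A list: `annotations` (an `annotation_table` whose rows carry
#'   exact centres, durations and labels), `wav` (file path),
#'   `csv` (annotation CSV path), `fs`.
#' @export
render_dataset <- function(spec, n_per_type = 40L, dir = tempfile("repertoire"),
                           seed = spec$seed, gap_s = 0.1) {
  stopifnot(n_per_type >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fs <- spec$fs
  n_units <- spec$n_types * n_per_type
  type_idx <- rep_len(seq_len(spec$n_types), n_units)  # interleaved

  units <- vector("list", n_units)
  rms <- numeric(n_units)
  for (i in seq_len(n_units)) {
    set.seed(unit_seed(seed, i))
    ts <- spec$types[type_idx[i], ]
    draw <- list(
      f_mult = exp(stats::rnorm(1, 0, spec$jitter)),
      duration = max(ts$duration_mean +
                       stats::rnorm(1, 0, ts$duration_sd) *
                         (1 + 4 * spec$graded), 0.01)
    )
    units[[i]] <- synth_unit(ts, draw, fs)
    rms[i] <- sqrt(mean(units[[i]]^2))
  }
  # common per-unit RMS so the requested SNR holds for every unit
  target_rms <- 0.1
  units <- lapply(seq_len(n_units), function(i) {
    if (rms[i] > 0) units[[i]] * target_rms / rms[i] else units[[i]]
  })

  gap <- as.integer(round(gap_s * fs))
  lens <- vapply(units, length, 1L)
  starts <- gap + cumsum(c(0L, (lens + gap)[-n_units]))  # 0-based
  total <- starts[n_units] + lens[n_units] + gap
  signal <- numeric(total)
  for (i in seq_len(n_units)) {
    idx <- starts[i] + seq_len(lens[i])
    signal[idx] <- signal[idx] + units[[i]]
  }
  if (is.finite(spec$snr_db)) {
    set.seed(unit_seed(seed, n_units + 1L))
    sigma <- target_rms / 10^(spec$snr_db / 20)
    noise <- if (spec$noise == "white") {
      stats::rnorm(total, 0, sigma)
    } else {
      pink_noise(total, sigma)
    }
    signal <- signal + noise
  }
  peak <- max(abs(signal))
  scale <- if (peak > 0.99) 0.99 / peak else 1
  wav <- file.path(dir, "repertoire.wav")
  write_wav(signal * scale, fs, wav, bits = 32L)

  ann <- data.frame(
    filename = "repertoire.wav",
    center_s = (starts + lens / 2) / fs,
    duration_s = lens / fs,
    label = spec$types$label[type_idx],
    stringsAsFactors = FALSE
  )
  csv <- file.path(dir, "annotations.csv")
  utils::write.csv(ann, csv, row.names = FALSE)
  list(annotations = as_annotation_table(ann, audio_dir = dir),
       wav = wav, csv = csv, fs = fs)
}

# 1/f-shaped Gaussian noise with the requested RMS
pink_noise <- function(n, sigma) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))  # avoid div-by-zero at DC
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x * sigma / sqrt(mean(x^2))
}
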