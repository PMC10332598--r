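test_that("sample duration is the third quartile with linear interpolation", {
  expect_equal(compute_sample_duration(c(1, 1, 1, 1)), 1)
  expect_equal(compute_sample_duration(c(1, 2, 3, 4)), 3.25)
  expect_equal(compute_sample_duration(2), 2)
  expect_error(compute_sample_duration(numeric(0)), "no annotated durations")
  expect_error(compute_sample_duration(c(1, -1)), "positive")
})

test_that("hop formula yields the configured number of time bins", {
  h <- compute_hop(0.1, 32000, 256)
  expect_identical(h$samples, 23L)
  expect_equal(h$ms, 0.7)
  h <- compute_hop(2, 11025, 1024)
  expect_identical(h$samples, 164L)
  expect_equal(h$ms, 14.9)
  h <- compute_hop(2, 96000, 512)
  expect_identical(h$samples, 1496L)
  expect_equal(h$ms, 15.6)
  expect_error(compute_hop(0.001, 32000, 256), "not shorter")
})

test_that("window extraction centres, zero-pads and z-normalises", {
  fs <- 1000
  # constant-zero signal stays zero
  w <- extract_window(numeric(500), 0.25, 0.1, fs)
  expect_equal(w, numeric(100))
  # centre at t = 0: left half is padding
  x <- rep(1, 500)
  w <- extract_window(x, 0, 0.1, fs, znorm = FALSE)
  expect_equal(length(w), 100L)
  expect_true(all(w[1:50] == 0))
  expect_true(all(w[51:100] == 1))
  # unit impulse at the annotation centre lands at index floor(T*fs/2)
  # (0-based), i.e. position 51 in R's 1-based indexing
  x <- numeric(2000); x[1001] <- 1  # impulse at sample 1000 (0-based)
  w <- extract_window(x, 1.0, 0.1, fs, znorm = FALSE)
  expect_equal(which(w != 0), 100 %/% 2 + 1L)
  # out-of-file centre names the row
  expect_error(extract_window(numeric(100), 5, 0.1, fs, id = "row7"), "row7")
})

test_that("z-normalisation gives zero mean, unit sd; constants map to zero", {
  set.seed(1)
  for (i in 1:5) {
    x <- matrix(rexp(128 * 128), 128, 128)
    z <- znormalise(x)
    expect_lt(abs(mean(z)), 1e-5)
    expect_lt(abs(sd(as.vector(z)) - 1), 1e-5)
  }
  expect_equal(znormalise(rep(3.7, 64)), numeric(64))
})

test_that("resampling preserves duration and tone frequency", {
  set.seed(2)
  x <- rnorm(3200)
  expect_identical(resample_audio(x, 32000, 32000), x)
  # pure 100 Hz sine downsampled 32 kHz -> 16 kHz keeps its DFT peak
  t <- (0:31999) / 32000
  s <- sin(2 * pi * 100 * t)
  y <- resample_audio(s, 32000, 16000)
  expect_equal(length(y), 16000L)
  spec <- Mod(fft(y))[1:8000]
  expect_equal(which.max(spec) - 1L, 100L)  # bin k = f * n / fs = 100
  expect_error(resample_audio(c(1, NA), 32000, 16000), "non-finite")
  expect_equal(common_sample_rate(c(32000, 32000, 44100)), 32000)
})

test_that("STFT magnitudes match analytic expectations", {
  cfg <- spectrogram_config(fs = 32000, nfft = 256, T = 0.1)
  expect_equal(stft_mag(numeric(3200), cfg), matrix(0, 129, 128))
  # bin-centre sine: energy confined to one frequency row, constant in time
  f_bin <- 16           # 16 * 32000/256 = 2000 Hz, exactly bin-centred
  t <- (0:3199) / 32000
  s <- sin(2 * pi * 2000 * t)
  m <- stft_mag(s, cfg)
  expect_equal(dim(m), c(129L, 128L))
  peak_rows <- apply(m, 2, which.max)
  expect_true(all(peak_rows == f_bin + 1L))
  # Hann mainlobe: neighbours at half amplitude, beyond-mainlobe ~ 0
  expect_equal(m[f_bin + 2L, ] / m[f_bin + 1L, ], rep(0.5, 128),
               tolerance = 1e-6)
  expect_lt(max(m[-(f_bin + 0:2), ]) / m[f_bin + 1L, 1], 1e-10)
  expect_lt(sd(m[f_bin + 1L, ]), 1e-10)
  expect_error(stft_mag(numeric(100), cfg), "shorter")
})

test_that("all presets yield exactly 128 spectrogram columns", {
  for (p in spectrogram_presets()$preset) {
    cfg <- spectrogram_preset(p)
    set.seed(3)
    w <- rnorm(round(cfg$T * cfg$fs))
    m <- stft_mag(w, cfg)
    expect_identical(ncol(m), 128L)
    expect_identical(nrow(frequency_layout(m, cfg)), 128L)
  }
})

test_that("frequency layout reduces any FFT size to the configured bins", {
  for (nfft in c(256L, 512L, 1024L)) {
    cfg <- spectrogram_config(fs = 32000, nfft = nfft, T = 0.5)
    zero <- matrix(0, nfft %/% 2L + 1L, 4)
    for (lay in c("mel", "linear")) {
      cfg$layout <- lay
      out <- frequency_layout(zero, cfg)
      expect_equal(out, matrix(0, 128, 4))
    }
  }
  # linear layout max-pools contiguous groups: a single hot row lights up
  # exactly the pooled rows covering it
  cfg <- spectrogram_config(fs = 32000, nfft = 512, T = 0.5,
                            layout = "linear")
  n_bins <- 257L
  grp <- as.integer(cut(seq_len(n_bins), breaks = 128L, labels = FALSE))
  for (hot in c(1L, 100L, 257L)) {
    m <- matrix(0, n_bins, 3)
    m[hot, ] <- 2
    out <- frequency_layout(m, cfg)
    expect_equal(which(out[, 1] != 0), grp[hot])
    expect_equal(out[grp[hot], ], rep(2, 3))
  }
  # too few FFT bins for a 128-row linear layout
  cfg_small <- spectrogram_config(fs = 32000, nfft = 128, T = 0.5,
                                  layout = "linear")
  expect_error(frequency_layout(matrix(0, 65, 4), cfg_small),
               "at least 128")
  expect_error(frequency_layout(matrix(0, 100, 4), cfg), "expected 257")
})

test_that("mel filterbank spans 0 to Nyquist with triangular filters", {
  fb <- mel_filterbank(128, 512, 32000)
  expect_equal(dim(fb), c(128L, 257L))
  expect_true(all(fb >= 0))
  # with enough FFT resolution per filter, every band covers some bin and
  # band centres increase monotonically
  fb40 <- mel_filterbank(40, 512, 32000)
  expect_true(all(rowSums(fb40) > 0))
  centres <- apply(fb40, 1, which.max)
  expect_true(all(diff(centres) >= 0))
  # Slaney scale round-trips
  f <- c(0, 500, 1000, 4000, 15999)
  expect_equal(vocclust:::mel_to_hz(vocclust:::hz_to_mel(f)), f)
})

test_that("compression modes behave per contract", {
  set.seed(4)
  m <- matrix(rexp(64), 8, 8)
  expect_identical(compress(m, "none"), m)
  expect_error(compress(-m, "log"), "negative")
  # log of a constant array is constant, so z-normalisation maps it to 0
  const <- matrix(5, 8, 8)
  expect_equal(znormalise(compress(const, "log")), matrix(0, 8, 8))
  # monotone: ordering of any two bins is preserved
  lm <- compress(m, "log")
  pairs <- cbind(sample(64, 50, TRUE), sample(64, 50, TRUE))
  expect_true(all(sign(m[pairs[, 1]] - m[pairs[, 2]]) ==
                    sign(lm[pairs[, 1]] - lm[pairs[, 2]])))
  # all-zero spectrogram passes through log unchanged
  expect_equal(compress(matrix(0, 4, 4), "log"), matrix(0, 4, 4))
  # pcen output is finite and non-negative for positive input
  cfg <- tiny_config()
  pc <- compress(m, "pcen", cfg)
  expect_true(all(is.finite(pc)))
  expect_true(all(pc >= 0))
})

test_that("median denoising removes stationary rows, keeps transients", {
  expect_equal(denoise_median(matrix(3, 6, 10)), matrix(0, 6, 10))
  m <- matrix(0, 4, 11)
  m[2, ] <- 5                      # stationary tone row
  m[3, 6] <- 7                     # one transient
  out <- denoise_median(m)
  expect_equal(out[2, ], rep(0, 11))
  expect_equal(out[3, 6], 7)       # row median is 0
  expect_equal(sum(out != 0), 1L)
  # the subtracted median is order-free over time
  perm <- sample(11)
  expect_equal(denoise_median(m[, perm])[, order(perm)], out)
})

test_that("spectrogram pipeline is deterministic and correctly shaped", {
  cfg <- tiny_config()
  set.seed(5)
  w <- rnorm(3200)
  a <- unit_spectrogram(w, cfg)
  b <- unit_spectrogram(w, cfg)
  expect_identical(a, b)
  expect_equal(dim(a), c(32L, 32L))
  expect_lt(abs(mean(a)), 1e-5)
  expect_lt(abs(sd(as.vector(a)) - 1), 1e-5)
})

test_that("baseline features flatten a pooled 32x32 spectrogram", {
  cfg <- spectrogram_preset("bengalese_finch")
  expect_equal(baseline_spectrogram_features(numeric(3200), cfg),
               numeric(1024))
  set.seed(6)
  w <- rnorm(3200)
  f1 <- baseline_spectrogram_features(w, cfg)
  expect_length(f1, 1024L)
  expect_identical(f1, baseline_spectrogram_features(w, cfg))
})

test_that("config round-trips through YAML and validates its invariants", {
  cfg <- spectrogram_config(fs = 44100, nfft = 512, T = 0.25,
                            compression = "pcen", layout = "linear")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2, cfg)
  expect_error(spectrogram_config(fs = 32000, nfft = 256, T = 0.1,
                                  n_mels = 100L),
               "k_f")
  expect_error(spectrogram_config(fs = 32000, nfft = 6400, T = 0.1),
               "shorter")
})
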