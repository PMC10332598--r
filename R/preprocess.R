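#' Sample duration from annotated unit durations
#'
#' The fixed window duration `T` used for every unit of a dataset is the
#' third quartile of the annotated unit durations: long enough to contain
#' most vocalisations fully while not drowning short ones in context.
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param durations Numeric vector of unit durations in seconds.
#' @return The 75th percentile, in seconds.
#' @examples
#' compute_sample_duration(c(1, 2, 3, 4))  # 3.25
#' @export
compute_sample_duration <- function(durations) {
  durations <- durations[!is.na(durations)]
  if (length(durations) == 0) {
    stop("no annotated durations: cannot derive the sample duration T")
  }
  if (any(durations <= 0)) stop("durations must be positive")
  unname(stats::quantile(durations, 0.75, type = 7))
}

#' STFT hop size yielding a fixed number of time bins
#'
#' For a window of duration `T` seconds at `fs` Hz analysed with an
#' `nfft`-sample FFT window, the hop that yields exactly `n_time`
#' spectrogram columns is `(T*fs - nfft) / n_time`. The hop is rounded to
#' the nearest integer sample; the millisecond value is computed from the
#' unrounded hop and reported at one-decimal precision.
#'
#' @param T Sample duration (s).
#' @param fs Sampling rate (Hz).
#' @param nfft FFT window length (samples).
#' @param n_time Number of time bins (default 128).
#' @return A list with `samples` (integer hop) and `ms` (hop in
#'   milliseconds, rounded to one decimal).
#' @examples
#' compute_hop(0.1, 32000, 256)  # 23 samples, 0.7 ms
#' compute_hop(2, 96000, 512)    # 1496 samples, 15.6 ms
#' @export
compute_hop <- function(T, fs, nfft, n_time = 128L) {
  if (T * fs <= nfft) {
    stop("FFT window (", nfft, ") is not shorter than the sample (",
         round(T * fs), " samples): no room for ", n_time, " frames")
  }
  exact <- (T * fs - nfft) / n_time
  list(samples = as.integer(round(exact)),
       ms = round(exact / fs * 1000, 1))
}

#' Extract a fixed-duration window around an annotation centre
#'
#' Cuts `round(T*fs)` samples centred on `center_time` (0-based sample
#' indexing, half-open window). Regions outside the file — including
#' pre-cut unit files shorter than `T` — are zero-padded. The window is
#' then z-normalised, so units recorded at different gains become
#' comparable before the frequency decomposition; an all-constant window
#' maps to zeros.
#'
#' @param signal Numeric vector of audio samples.
#' @param center_time Annotation centre in seconds.
#' @param T Window duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param znorm Z-normalise the window (default `TRUE`).
#' @param id Optional identifier used in error messages.
#' @return Numeric vector of length `round(T*fs)`.
#' @export
extract_window <- function(signal, center_time, T, fs, znorm = TRUE,
                           id = NULL) {
  n <- length(signal)
  if (n == 0) stop("empty signal")
  dur <- n / fs
  if (center_time < 0 || center_time > dur) {
    stop("annotation centre ", center_time, " s outside file of ",
         signif(dur, 6), " s", if (!is.null(id)) paste0(" (row ", id, ")"))
  }
  len <- as.integer(round(T * fs))
  c0 <- as.integer(round(center_time * fs))   # 0-based centre sample
  start <- c0 - len %/% 2L                    # 0-based, half-open [start, start+len)
  out <- numeric(len)
  src <- pmax(0L, start):pmin(n - 1L, start + len - 1L)
  if (length(src) > 0 && src[1] <= src[length(src)]) {
    out[src - start + 1L] <- signal[src + 1L]
  }
  if (znorm) out <- znormalise(out)
  out
}

#' Z-normalise a vector or matrix
#'
#' Centre to zero mean and scale to unit standard deviation
#' (sample SD, denominator n-1). Constant inputs map to all zeros rather
#' than dividing by zero.
#'
#' @param x Numeric vector, matrix or array.
#' @return Object of the same shape.
#' @export
znormalise <- function(x) {
  mu <- mean(x)
  sdev <- stats::sd(as.vector(x))
  if (!is.finite(sdev) || sdev == 0) {
    x[] <- 0
    return(x)
  }
  (x - mu) / sdev
}

#' Resample audio by a rational factor
#'
#' Polyphase FIR resampling (via \code{signal::resample}) from `fs_in` to
#' `fs_out`. Identity when the rates match. Output length is
#' `round(length(x) * fs_out / fs_in)` within one sample.
#'
#' @param x Numeric vector of samples.
#' @param fs_in,fs_out Input/output sampling rates (Hz).
#' @return Resampled numeric vector.
#' @export
resample_audio <- function(x, fs_in, fs_out) {
  stopifnot(fs_in > 0, fs_out > 0)
  if (any(!is.finite(x))) stop("non-finite samples in input signal")
  if (fs_in == fs_out) return(x)
  # rational approximation of the ratio from integer rates
  p <- as.integer(round(fs_out))
  q <- as.integer(round(fs_in))
  g <- .gcd(p, q)
  y <- as.numeric(signal::resample(x, p / g, q / g))
  target <- as.integer(round(length(x) * fs_out / fs_in))
  if (length(y) >= target) y[seq_len(target)] else c(y, numeric(target - length(y)))
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Most common sampling rate of a dataset
#'
#' The target rate for [resample_audio()] is fixed to the most common
#' rate among the dataset's files (ties broken towards the lower rate).
#'
#' @param rates Integer/numeric vector of per-file sampling rates.
#' @return The modal rate.
#' @export
common_sample_rate <- function(rates) {
  stopifnot(length(rates) > 0)
  tab <- table(rates)
  as.numeric(names(tab)[which.max(tab)])
}

#' Magnitude STFT with unpadded Hann windows
#'
#' Frames the window with `config$nfft`-sample Hann windows advanced by
#' `config$hop` samples; frames are never zero-padded, and trailing frames
#' beyond `config$n_time` are dropped so the output has exactly
#' `config$n_time` columns.
#'
#' @param window Numeric vector of length `round(config$T * config$fs)`.
#' @param config A [spectrogram_config()].
#' @return Magnitude matrix of dimension `(nfft/2 + 1) x n_time`.
#' @export
stft_mag <- function(window, config) {
  nfft <- config$nfft
  hop <- config$hop
  if (length(window) < nfft) {
    stop("window (", length(window), " samples) shorter than the FFT window (",
         nfft, ")")
  }
  n_frames_avail <- (length(window) - nfft) %/% hop + 1L
  if (n_frames_avail < config$n_time) {
    stop("only ", n_frames_avail, " full frames available for ",
         config$n_time, " time bins; check T, fs, nfft")
  }
  starts <- (seq_len(config$n_time) - 1L) * hop
  idx <- outer(seq_len(nfft), starts, `+`)         # nfft x n_time
  frames <- matrix(window[idx], nrow = nfft)
  w <- hann_window(nfft)
  spec <- stats::mvfft(frames * w)
  Mod(spec[seq_len(nfft %/% 2L + 1L), , drop = FALSE])
}

#' Periodic Hann window
#' @param n Window length in samples.
#' @return Numeric vector of length `n`.
#' @export
hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)
}

#' Reduce the frequency axis to the configured number of bins
#'
#' `layout = "mel"` projects the linear-frequency magnitudes onto
#' `config$n_mels` triangular Mel filters spanning 0 to Nyquist
#' (Slaney scale and area normalisation). `layout = "linear"` keeps the
#' linear axis and max-pools contiguous groups of FFT bins down to
#' `config$n_mels` rows, independent of `nfft`.
#'
#' @param mag Magnitude matrix from [stft_mag()], `(nfft/2+1)` rows.
#' @param config A [spectrogram_config()].
#' @return Matrix of dimension `n_mels x n_time`.
#' @export
frequency_layout <- function(mag, config) {
  n_fft_bins <- config$nfft %/% 2L + 1L
  if (nrow(mag) != n_fft_bins) {
    stop("expected ", n_fft_bins, " frequency rows, got ", nrow(mag))
  }
  if (config$layout == "mel") {
    fb <- mel_filterbank(config$n_mels, config$nfft, config$fs)
    fb %*% mag
  } else {
    if (n_fft_bins < config$n_mels) {
      stop("linear layout needs at least ", config$n_mels,
           " FFT bins; nfft=", config$nfft, " gives only ", n_fft_bins)
    }
    # contiguous near-equal groups; max within each group
    grp <- as.integer(cut(seq_len(n_fft_bins), breaks = config$n_mels,
                          labels = FALSE))
    out <- matrix(0, config$n_mels, ncol(mag))
    for (g in seq_len(config$n_mels)) {
      rows <- which(grp == g)
      out[g, ] <- if (length(rows) == 1L) mag[rows, ] else
        apply(mag[rows, , drop = FALSE], 2, max)
    }
    out
  }
}

# Slaney Mel scale: linear below 1 kHz, logarithmic above.
hz_to_mel <- function(f) {
  m <- f / (200 / 3)
  log_region <- f >= 1000
  m[log_region] <- 15 + log(f[log_region] / 1000) / (log(6.4) / 27)
  m
}

mel_to_hz <- function(m) {
  f <- m * (200 / 3)
  log_region <- m >= 15
  f[log_region] <- 1000 * exp((m[log_region] - 15) * log(6.4) / 27)
  f
}

#' Triangular Mel filterbank (Slaney convention)
#'
#' @param n_mels Number of filters.
#' @param nfft FFT length in samples.
#' @param fs Sampling rate (Hz); filters span 0 to `fs/2`.
#' @return Matrix `n_mels x (nfft/2+1)`; rows are area-normalised
#'   triangles (Slaney normalisation: each filter integrates to ~2/bandwidth).
#' @export
mel_filterbank <- function(n_mels, nfft, fs) {
  n_bins <- nfft %/% 2L + 1L
  fft_freqs <- seq(0, fs / 2, length.out = n_bins)
  mel_pts <- seq(hz_to_mel(0), hz_to_mel(fs / 2), length.out = n_mels + 2L)
  hz_pts <- mel_to_hz(mel_pts)
  fb <- matrix(0, n_mels, n_bins)
  for (i in seq_len(n_mels)) {
    lower <- (fft_freqs - hz_pts[i]) / (hz_pts[i + 1] - hz_pts[i])
    upper <- (hz_pts[i + 2] - fft_freqs) / (hz_pts[i + 2] - hz_pts[i + 1])
    fb[i, ] <- pmax(0, pmin(lower, upper))
    # Slaney area normalisation
    fb[i, ] <- fb[i, ] * 2 / (hz_pts[i + 2] - hz_pts[i])
  }
  fb
}

#' Dynamic-range compression of spectrogram magnitudes
#'
#' `"none"` is the identity; `"log"` applies `log(mag/max + eps)` with
#' `eps = 1e-8` relative to the spectrogram's maximum magnitude (an
#' all-zero spectrogram passes through unchanged); `"pcen"` applies
#' per-channel energy normalisation with the standard defaults
#' (gain 0.98, bias 2, power 0.5, eps 1e-6, smoothing coefficient derived
#' from a 400 ms time constant at the configured frame rate).
#'
#' @param mag Non-negative magnitude matrix (frequency x time).
#' @param mode `"none"`, `"log"` or `"pcen"`.
#' @param config A [spectrogram_config()]; required for `"pcen"` (frame
#'   rate) and ignored otherwise.
#' @return Compressed matrix of the same dimension.
#' @export
compress <- function(mag, mode = c("log", "pcen", "none"), config = NULL) {
  mode <- match.arg(mode)
  if (any(mag < 0)) stop("negative magnitudes: compression expects |STFT|")
  switch(mode,
    none = mag,
    log = {
      m <- max(mag)
      if (m == 0) mag else log(mag / m + 1e-8)
    },
    pcen = {
      if (is.null(config)) stop("pcen needs the spectrogram config (frame rate)")
      pcen(mag, fs = config$fs, hop = config$hop)
    }
  )
}

#' Per-channel energy normalisation (PCEN)
#'
#' `PCEN = (E / (eps + M)^gain + bias)^power - bias^power`, with `M` an
#' IIR-smoothed (over time, per frequency channel) version of the
#' magnitudes `E`. The smoothing coefficient follows from the time
#' constant and the frame rate `fs/hop`.
#'
#' @param mag Magnitude matrix (frequency x time).
#' @param fs,hop Sampling rate (Hz) and hop (samples), fixing the frame rate.
#' @param gain,bias,power,eps,time_constant Standard PCEN parameters.
#' @return Matrix of the same dimension.
#' @export
pcen <- function(mag, fs, hop, gain = 0.98, bias = 2, power = 0.5,
                 eps = 1e-6, time_constant = 0.4) {
  t_frames <- time_constant * fs / hop
  b <- (sqrt(1 + 4 * t_frames^2) - 1) / (2 * t_frames^2)
  M <- mag
  for (t in seq_len(ncol(mag))[-1]) {
    M[, t] <- (1 - b) * M[, t - 1] + b * mag[, t]
  }
  (mag / (eps + M)^gain + bias)^power - bias^power
}

#' Stationary-noise suppression by per-row median subtraction
#'
#' Subtracts each frequency row's median over time and clips negative
#' results at zero. Stationary tones and broadband floors vanish while
#' transient vocalisation energy is preserved (minus the row median).
#'
#' @param mag Spectrogram matrix (frequency x time).
#' @return Matrix of the same dimension, non-negative.
#' @export
denoise_median <- function(mag) {
  med <- apply(mag, 1, stats::median)
  pmax(mag - med, 0)
}

#' Full spectrogram for one vocalisation window
#'
#' STFT, optional median denoising, frequency layout, compression and
#' (by default) per-spectrogram z-normalisation, in the order the
#' pipeline applies them.
#'
#' @param window Samples of length `round(T*fs)` (already z-normalised by
#'   [extract_window()]).
#' @param config A [spectrogram_config()].
#' @param znorm Apply the final z-normalisation (set `FALSE` when
#'   normalising per batch).
#' @return `n_mels x n_time` matrix.
#' @export
unit_spectrogram <- function(window, config, znorm = TRUE) {
  mag <- stft_mag(window, config)
  mag <- frequency_layout(mag, config)
  if (isTRUE(config$denoise)) mag <- denoise_median(mag)
  out <- compress(mag, config$compression, config)
  if (znorm) znormalise(out) else out
}

#' Whole-spectrogram baseline features
#'
#' The handcrafted baseline represents each unit by a 32 x 32 spectrogram
#' flattened to 1024 independent features. It reuses the standard
#' pipeline (same `T`, `fs`, `nfft`) and reduces the 128 x 128 compressed
#' spectrogram by 4 x 4 max-pooling.
#'
#' @param window Samples of length `round(T*fs)`.
#' @param config A [spectrogram_config()].
#' @return Numeric vector of length 1024 (column-major flattening of the
#'   32 x 32 array).
#' @export
baseline_spectrogram_features <- function(window, config) {
  sp <- unit_spectrogram(window, config, znorm = FALSE)
  pooled <- pool2x2k(sp, config$n_mels %/% 32L, config$n_time %/% 32L)
  as.vector(znormalise(pooled))
}

# max-pool a matrix by (pf x pt) blocks
pool2x2k <- function(x, pf, pt) {
  nf <- nrow(x) %/% pf
  nt <- ncol(x) %/% pt
  out <- matrix(-Inf, nf, nt)
  for (i in seq_len(pf)) {
    for (j in seq_len(pt)) {
      out <- pmax(out, x[seq(i, by = pf, length.out = nf),
                         seq(j, by = pt, length.out = nt)])
    }
  }
  out
}
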