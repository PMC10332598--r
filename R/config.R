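#' Spectrogram configuration
#'
#' Bundle the signal-level settings that determine how a detected
#' vocalisation is turned into a fixed-size spectrogram: sampling rate,
#' FFT window, sample duration, frequency layout and dynamic-range
#' compression. The output spectrogram has `n_mels` x `n_time` bins, both
#' constrained to the form k * 2^n so that a decoder reconstructing by `n`
#' successive factor-two upsamplings can match the input exactly.
#'
#' The STFT hop is derived, not chosen: `hop = (T * fs - nfft) / n_time`,
#' rounded to the nearest sample, so that the window of duration `T`
#' yields exactly `n_time` spectrogram columns (see [compute_hop()]).
#'
#' @param fs Sampling rate in Hz.
#' @param nfft FFT window length in samples (Hann window, no frame padding).
#' @param T Sample duration in seconds; every unit is represented by a
#'   window of this duration centred on its annotation. Typically set to
#'   the third quartile of unit durations ([compute_sample_duration()]).
#' @param n_mels,n_time Output frequency/time bins. Must equal
#'   `k_f * 2^n_halvings` and `k_t * 2^n_halvings`.
#' @param layout `"mel"` (128-filter Mel bank, 0 to Nyquist) or
#'   `"linear"` (max-pooled linear frequency axis).
#' @param compression `"log"`, `"pcen"` or `"none"`.
#' @param k_f,k_t,n_halvings Integers of the size constraint; defaults
#'   4, 4, 5 give 128 x 128.
#' @param znorm `"per_spectrogram"` (default) or `"per_batch"`: scope of
#'   the final z-normalisation of magnitudes.
#' @param denoise If `TRUE`, subtract each frequency row's median over
#'   time (stationary-noise suppression) before compression.
#'
#' @return An object of class `"spectrogram_config"` (a named list).
#' @examples
#' cfg <- spectrogram_config(fs = 32000, nfft = 256, T = 0.1)
#' cfg$hop  # 23 samples
#' @export
spectrogram_config <- function(fs, nfft, T,
                               n_mels = 128L, n_time = 128L,
                               layout = c("mel", "linear"),
                               compression = c("log", "pcen", "none"),
                               k_f = 4L, k_t = 4L, n_halvings = 5L,
                               znorm = c("per_spectrogram", "per_batch"),
                               denoise = FALSE) {
  layout <- match.arg(layout)
  compression <- match.arg(compression)
  znorm <- match.arg(znorm)
  stopifnot(fs > 0, nfft > 0, T > 0)
  if (n_mels != k_f * 2^n_halvings || n_time != k_t * 2^n_halvings) {
    stop("n_mels and n_time must equal k_f*2^n_halvings and k_t*2^n_halvings ",
         "(got ", n_mels, "x", n_time, " vs ",
         k_f * 2^n_halvings, "x", k_t * 2^n_halvings, ")")
  }
  if (nfft >= T * fs) {
    stop("FFT window (", nfft, " samples) must be shorter than the sample (",
         round(T * fs), " samples)")
  }
  hop <- compute_hop(T, fs, nfft, n_time)
  structure(
    list(fs = fs, nfft = as.integer(nfft), T = T,
         hop = hop$samples, hop_ms = hop$ms,
         n_mels = as.integer(n_mels), n_time = as.integer(n_time),
         layout = layout, compression = compression,
         k_f = as.integer(k_f), k_t = as.integer(k_t),
         n_halvings = as.integer(n_halvings),
         znorm = znorm, denoise = denoise),
    class = "spectrogram_config"
  )
}

#' @export
print.spectrogram_config <- function(x, ...) {
  cat("Spectrogram configuration\n")
  cat(sprintf("  fs %g Hz | NFFT %d | T %g s | hop %d samples (%.1f ms)\n",
              x$fs, x$nfft, x$T, x$hop, x$hop_ms))
  cat(sprintf("  %d x %d bins (k_f=%d, k_t=%d, n=%d) | layout %s | compression %s\n",
              x$n_mels, x$n_time, x$k_f, x$k_t, x$n_halvings,
              x$layout, x$compression))
  invisible(x)
}

# The per-species presets used throughout the study: one row per corpus,
# fs in Hz. Hop is derived from the other fields.
.preset_table <- function() {
  data.frame(
    preset = c("bengalese_finch", "california_thrasher", "cassin_vireo",
               "black_headed_grosbeak", "humpback_whale", "bottlenose_dolphin"),
    fs = c(32000, 44100, 44100, 44100, 11025, 96000),
    nfft = c(256L, 512L, 512L, 512L, 1024L, 512L),
    T = c(0.1, 0.25, 0.5, 0.35, 2, 2),
    stringsAsFactors = FALSE
  )
}

#' Named spectrogram presets
#'
#' Ready-made [spectrogram_config()] objects for the six species
#' configurations evaluated in the benchmark (the two bengalese finch
#' corpora and the two humpback corpora share settings).
#'
#' @param name Preset name; see `spectrogram_presets()` for the list.
#' @param ... Overrides passed on to [spectrogram_config()]
#'   (e.g. `compression = "pcen"`).
#' @return For `spectrogram_preset`, a `spectrogram_config`; for
#'   `spectrogram_presets`, a data frame of available presets.
#' @examples
#' spectrogram_presets()
#' spectrogram_preset("humpback_whale")$hop_ms  # 14.9
#' @export
spectrogram_preset <- function(name, ...) {
  tab <- .preset_table()
  i <- match(name, tab$preset)
  if (is.na(i)) {
    stop("unknown preset '", name, "'; available: ",
         paste(tab$preset, collapse = ", "))
  }
  spectrogram_config(fs = tab$fs[i], nfft = tab$nfft[i], T = tab$T[i], ...)
}

#' @rdname spectrogram_preset
#' @export
spectrogram_presets <- function() .preset_table()

#' Read or write a run configuration file
#'
#' Configurations are stored as flat YAML key/value files so that every
#' pipeline stage (and the command-line tool) can round-trip its settings.
#'
#' @param path File path.
#' @param config For `write_config`, a `spectrogram_config` or plain named
#'   list.
#' @return `read_config` returns a `spectrogram_config` when the file
#'   contains the spectrogram fields, otherwise a named list.
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  needed <- c("fs", "nfft", "T")
  if (all(needed %in% names(x))) {
    args <- x[intersect(names(x),
                        c("fs", "nfft", "T", "n_mels", "n_time", "layout",
                          "compression", "k_f", "k_t", "n_halvings",
                          "znorm", "denoise"))]
    return(do.call(spectrogram_config, args))
  }
  x
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$hop <- NULL  # derived
  x$hop_ms <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}
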