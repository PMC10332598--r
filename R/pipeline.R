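#' Compute the spectrogram batch for an annotation table
#'
#' Reads each source file once, resamples it to `config$fs` when needed,
#' extracts a z-normalised window of duration `config$T` around every
#' annotation centre and converts it to the configured spectrogram.
#'
#' @param annotations An `annotation_table` (see [read_annotations()]).
#' @param config A [spectrogram_config()].
#' @return A list of class `"spectrogram_batch"`: `values` (array
#'   `n_mels x n_time x n_units`), `ids` (aligned with annotation rows),
#'   `config`.
#' @export
make_spectrograms <- function(annotations, config) {
  files <- unique(annotations$filename)
  values <- array(0, c(config$n_mels, config$n_time, nrow(annotations)))
  for (f in files) {
    audio <- read_wav(f)
    x <- resample_audio(audio$samples, audio$fs, config$fs)
    rows <- which(annotations$filename == f)
    for (r in rows) {
      w <- extract_window(x, annotations$center_s[r], config$T, config$fs,
                          id = annotations$id[r])
      values[, , r] <- unit_spectrogram(w, config,
                                        znorm = config$znorm == "per_spectrogram")
    }
  }
  if (config$znorm == "per_batch") values <- znormalise(values)
  structure(list(values = values, ids = annotations$id, config = config),
            class = "spectrogram_batch")
}

#' @export
print.spectrogram_batch <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Spectrogram batch: %d units of %d x %d (%s layout, %s compression)\n",
              d[3], d[1], d[2], x$config$layout, x$config$compression))
  invisible(x)
}

#' Save / load a spectrogram batch archive
#'
#' Batches are archived with their aligned id list and configuration in
#' R's native serialisation format.
#'
#' @param batch A `spectrogram_batch`.
#' @param path Archive path (`.rds`).
#' @return `load_spectrograms` returns the batch.
#' @export
save_spectrograms <- function(batch, path) {
  saveRDS(batch, path)
  invisible(path)
}

#' @rdname save_spectrograms
#' @export
load_spectrograms <- function(path) {
  batch <- readRDS(path)
  stopifnot(inherits(batch, "spectrogram_batch"))
  batch
}

#' Whole-spectrogram baseline features for an annotation table
#'
#' @inheritParams make_spectrograms
#' @return Matrix `n_units x 1024` (32 x 32 spectrogram bins as
#'   independent features), class `"embedding_matrix"`,
#'   `space = "baseline"`; row names are the annotation ids.
#' @export
make_baseline_features <- function(annotations, config) {
  files <- unique(annotations$filename)
  out <- matrix(0, nrow(annotations), 32L * 32L)
  for (f in files) {
    audio <- read_wav(f)
    x <- resample_audio(audio$samples, audio$fs, config$fs)
    for (r in which(annotations$filename == f)) {
      w <- extract_window(x, annotations$center_s[r], config$T, config$fs,
                          id = annotations$id[r])
      out[r, ] <- baseline_spectrogram_features(w, config)
    }
  }
  rownames(out) <- annotations$id
  attr(out, "space") <- "baseline"
  class(out) <- c("embedding_matrix", class(out))
  out
}

#' Run the full repertoire-discovery pipeline
#'
#' Spectrograms, auto-encoder training, bottleneck embedding, UMAP
#' projection, HDBSCAN clustering and evaluation in one call. Every
#' stochastic stage is governed by `seed`.
#'
#' @param annotations An `annotation_table`.
#' @param config A [spectrogram_config()].
#' @param representation `"autoencoder"` (default) or `"baseline"`
#'   (whole-spectrogram features, no training).
#' @param bottleneck_dim,base_channels Auto-encoder size
#'   (see [ae_spec()]).
#' @param loss Reconstruction loss for training.
#' @param train_steps Hard cap on training steps.
#' @param batch_size Training mini-batch size.
#' @param stop_window Window of the median stop rule.
#' @param umap_dims UMAP dimensionality used for clustering.
#' @param min_cluster_size,min_samples,epsilon,selection HDBSCAN
#'   settings (see [cluster_hdbscan()]).
#' @param min_label_count Rare-label threshold applied before
#'   evaluation.
#' @param seed Master seed.
#' @param verbose Progress messages.
#' @return A list of class `"cluster_report"`: `assignment`,
#'   `embeddings` (bottleneck or baseline), `projection` (UMAP),
#'   `projection2d`, `metrics` (from [evaluate_run()]), `model` (the
#'   trained auto-encoder or `NULL`), `annotations`.
#' @export
run_pipeline <- function(annotations, config,
                         representation = c("autoencoder", "baseline"),
                         bottleneck_dim = 256L, base_channels = 32L,
                         loss = c("perceptual", "mse"),
                         train_steps = 2000L, batch_size = 128L,
                         stop_window = 1000L,
                         umap_dims = 8L, min_cluster_size = 10L,
                         min_samples = 3L, epsilon = 0.1,
                         selection = c("leaf", "eom"),
                         min_label_count = 20L, seed = 1L,
                         verbose = FALSE) {
  representation <- match.arg(representation)
  loss <- match.arg(loss)
  selection <- match.arg(selection)
  model <- NULL
  if (representation == "autoencoder") {
    batch <- make_spectrograms(annotations, config)
    spec <- ae_spec(input_shape = c(1L, config$n_mels, config$n_time),
                    bottleneck_dim = bottleneck_dim,
                    base_channels = base_channels)
    model <- autoencoder(spec, seed = seed)
    if (verbose) message("training auto-encoder (", loss, " loss)")
    model <- train_autoencoder(model, batch$values, loss = loss,
                               batch_size = batch_size, window = stop_window,
                               max_steps = train_steps, seed = seed,
                               verbose = verbose)
    emb <- encode(model, batch$values)
    rownames(emb) <- batch$ids
  } else {
    emb <- make_baseline_features(annotations, config)
  }
  if (verbose) message("projecting with UMAP (", umap_dims, "-D)")
  proj <- project_umap(emb, n_dims = umap_dims, seed = seed)
  proj2d <- if (umap_dims == 2L) proj else
    project_umap(emb, n_dims = 2L, seed = seed)
  assignment <- cluster_hdbscan(proj, min_cluster_size = min_cluster_size,
                                min_samples = min_samples, epsilon = epsilon,
                                selection = selection)
  eval_ann <- filter_rare_labels(annotations, min_label_count)
  metrics <- evaluate_run(eval_ann$label, as.integer(assignment),
                          points2d = proj2d,
                          dataset = basename(dirname(annotations$filename[1])),
                          representation = representation, seed = seed)
  structure(list(assignment = assignment, embeddings = emb,
                 projection = proj, projection2d = proj2d,
                 metrics = metrics, model = model,
                 annotations = annotations),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  m <- x$metrics
  cat("Repertoire clustering report\n")
  cat(sprintf("  %d units -> %d clusters (+%d noise)\n",
              m$n, m$n_clusters, m$n_noise))
  cat(sprintf("  NMI %.3f | Hopkins %.3f | %.1f%% discriminant | %.1f%% clustered | %d labels missed\n",
              m$nmi, m$hopkins, m$pct_discriminant, m$pct_clustered,
              m$n_missed))
  invisible(x)
}

#' Write the evaluation record and a human-readable report
#'
#' @param report A `cluster_report` from [run_pipeline()].
#' @param csv_path Path of the flat one-row-per-run CSV (appended to if
#'   it exists).
#' @param txt_path Optional path of a human-readable text report.
#' @return `csv_path`, invisibly.
#' @export
write_report <- function(report, csv_path, txt_path = NULL) {
  m <- report$metrics
  utils::write.table(m, csv_path, sep = ",", row.names = FALSE,
                     col.names = !file.exists(csv_path),
                     append = file.exists(csv_path))
  if (!is.null(txt_path)) {
    lines <- c(
      "Repertoire clustering report",
      sprintf("dataset: %s | representation: %s", m$dataset, m$representation),
      sprintf("units: %d | clusters: %d | noise: %d", m$n, m$n_clusters,
              m$n_noise),
      sprintf("NMI: %.4f", m$nmi),
      sprintf("Hopkins: %.4f", m$hopkins),
      sprintf("discriminant clusters: %.1f%%", m$pct_discriminant),
      sprintf("vocalisations in discriminant clusters: %.1f%%",
              m$pct_clustered),
      sprintf("labels missed: %d", m$n_missed)
    )
    writeLines(lines, txt_path)
  }
  invisible(csv_path)
}
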