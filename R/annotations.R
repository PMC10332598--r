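#' Read an annotation table of detected vocalisations
#'
#' One row per detected unit: `filename`, `center_s` (centre of the unit
#' in seconds; alternatively `onset_s` + `duration_s`, converted to a
#' centre), `duration_s`, and optional `label` and `individual` columns.
#' Empty labels become `NA` (unlabelled).
#'
#' @param path CSV file with a header.
#' @param audio_dir Optional directory prepended to relative `filename`s.
#' @return A data frame of class `"annotation_table"` with columns
#'   `id`, `filename`, `center_s`, `duration_s`, `label`, `individual`.
#' @export
read_annotations <- function(path, audio_dir = NULL) {
  if (!file.exists(path)) stop("annotation CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_annotation_table(df, audio_dir = audio_dir)
}

#' Coerce a data frame to an annotation table
#'
#' @param df Data frame with the columns described in [read_annotations()].
#' @param audio_dir Optional directory prepended to relative `filename`s.
#' @return An `annotation_table` data frame.
#' @export
as_annotation_table <- function(df, audio_dir = NULL) {
  if (!"filename" %in% names(df)) stop("annotation table needs a 'filename' column")
  if (!"center_s" %in% names(df)) {
    if (all(c("onset_s", "duration_s") %in% names(df))) {
      df$center_s <- df$onset_s + df$duration_s / 2
    } else {
      stop("annotation table needs 'center_s' or 'onset_s'+'duration_s'")
    }
  }
  if (!"duration_s" %in% names(df)) df$duration_s <- rep(NA_real_, nrow(df))
  if (!"label" %in% names(df)) df$label <- rep(NA_character_, nrow(df))
  df$label[!is.na(df$label) & df$label == ""] <- NA_character_
  if (!"individual" %in% names(df)) {
    df$individual <- rep(NA_character_, nrow(df))
  }
  if (any(df$center_s < 0, na.rm = TRUE)) stop("center_s must be >= 0")
  if (any(df$duration_s <= 0, na.rm = TRUE)) stop("duration_s must be > 0")
  if (!is.null(audio_dir)) {
    rel <- !grepl("^(/|[A-Za-z]:)", df$filename)
    df$filename[rel] <- file.path(audio_dir, df$filename[rel])
  }
  if (!"id" %in% names(df)) df$id <- seq_len(nrow(df))
  out <- df[, c("id", "filename", "center_s", "duration_s", "label", "individual")]
  class(out) <- c("annotation_table", "data.frame")
  out
}

#' Demote rare labels to unlabelled
#'
#' Unit types observed fewer than `min_count` times are too sparse to
#' evaluate against (and often reflect labelling errors); their rows are
#' kept but marked unlabelled before any evaluation. A label with exactly
#' `min_count` occurrences is kept.
#'
#' @param table An `annotation_table` (or any data frame with a `label`
#'   column).
#' @param min_count Minimum occurrences for a label to survive
#'   (default 20).
#' @return The table with rare labels set to `NA`.
#' @examples
#' df <- data.frame(filename = "a.wav", center_s = 1:25 / 10,
#'                  duration_s = 0.1,
#'                  label = rep(c("A", "B"), c(20, 5)))
#' table(filter_rare_labels(as_annotation_table(df))$label, useNA = "ifany")
#' @export
filter_rare_labels <- function(table, min_count = 20L) {
  if (nrow(table) == 0 || all(is.na(table$label))) return(table)
  counts <- table(table$label)
  rare <- names(counts)[counts < min_count]
  table$label[table$label %in% rare] <- NA_character_
  table
}
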