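# UMAP projection and HDBSCAN clustering. Both stages delegate to the
# reference implementations (umap-learn, scikit-learn) through small
# Python helper scripts shipped with the package; data crosses the
# boundary as CSV. A fixed seed makes the projection deterministic.

find_python <- function() {
  for (cand in c(Sys.getenv("VOCCLUST_PYTHON"), "python", "python3")) {
    if (nzchar(cand) && nzchar(Sys.which(cand))) return(Sys.which(cand))
  }
  stop("no python interpreter found on PATH; UMAP/HDBSCAN stages need ",
       "python with umap-learn and scikit-learn ",
       "(set VOCCLUST_PYTHON to override)")
}

run_py_helper <- function(script, args) {
  py <- find_python()
  path <- system.file("python", script, package = "vocclust")
  if (!nzchar(path)) stop("helper script not found: ", script)
  res <- suppressWarnings(system2(py, c(shQuote(path), shQuote(args)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    stop("python helper ", script, " failed (exit ", status, "):\n",
         paste(utils::tail(res, 15), collapse = "\n"))
  }
  invisible(res)
}

#' Project embeddings with UMAP
#'
#' Reduces per-vocalisation embeddings to `n_dims` dimensions with UMAP.
#' Eight dimensions are the default working space for clustering; two
#' are used for visualisation. Neighbourhood size and minimum distance
#' stay at the reference implementation's defaults.
#'
#' @param embeddings Numeric matrix, one row per vocalisation.
#' @param n_dims Output dimensionality (2, 4, 8, 16 or 32 are typical).
#' @param seed Integer seed; fixing it makes the projection
#'   deterministic (and single-threaded).
#' @param n_neighbors UMAP neighbourhood size (default 15).
#' @param min_dist UMAP minimum embedded distance (default 0.1).
#' @return Matrix `n x n_dims` of class `"embedding_matrix"` with
#'   attribute `space = "umap"`; row names are preserved.
#' @export
project_umap <- function(embeddings, n_dims = 8L, seed = 42L,
                         n_neighbors = 15L, min_dist = 0.1) {
  embeddings <- as.matrix(embeddings)
  if (!all(is.finite(embeddings))) stop("non-finite values in embeddings")
  if (nrow(embeddings) <= n_neighbors) {
    stop("need more than n_neighbors = ", n_neighbors, " points (got ",
         nrow(embeddings), "); reduce n_neighbors")
  }
  fin <- tempfile(fileext = ".csv"); fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  utils::write.table(embeddings, fin, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  run_py_helper("umap_project.py",
                c(fin, fout, n_dims, seed, n_neighbors, min_dist))
  out <- as.matrix(utils::read.table(fout, sep = ","))
  dimnames(out) <- list(rownames(embeddings), NULL)
  attr(out, "space") <- "umap"
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("embedding_matrix", class(out))
  out
}

#' Cluster embeddings with HDBSCAN
#'
#' Density-based clustering of (typically UMAP-projected) embeddings,
#' computed natively: core distances over `min_samples` neighbours,
#' minimum spanning tree of the mutual-reachability graph, condensed
#' tree at `min_cluster_size`, then cluster selection. Points in no
#' dense region are assigned the noise sentinel `-1`; cluster ids are
#' contiguous integers from 0. The generic settings (min_cluster_size
#' 10, min_samples 3, epsilon 0.1, leaf selection) work across
#' repertoires; `selection = "eom"` merges sub-clusters into maximally
#' stable ones, useful for graded repertoires.
#'
#' @param embeddings Numeric matrix, one row per vocalisation.
#' @param min_cluster_size Minimum points for a dense region to count as
#'   a cluster.
#' @param min_samples Neighbourhood size of the core-distance estimate.
#' @param epsilon Cluster-selection epsilon: leaves split below this
#'   distance are merged back.
#' @param selection `"leaf"` (finest-grained leaves, default) or
#'   `"eom"` (excess of mass).
#' @return An object of class `"cluster_assignment"`: integer vector of
#'   cluster ids (`-1` = noise) with the parameters stored as attributes.
#' @export
cluster_hdbscan <- function(embeddings, min_cluster_size = 10L,
                            min_samples = 3L, epsilon = 0.1,
                            selection = c("leaf", "eom")) {
  selection <- match.arg(selection)
  embeddings <- as.matrix(embeddings)
  params <- list(min_cluster_size = as.integer(min_cluster_size),
                 min_samples = as.integer(min_samples),
                 epsilon = epsilon, selection = selection)
  if (nrow(embeddings) < min_cluster_size) {
    warning("fewer points (", nrow(embeddings), ") than min_cluster_size (",
            min_cluster_size, "): everything is noise")
    labels <- rep(-1L, nrow(embeddings))
  } else {
    labels <- hdbscan_labels(embeddings,
                             min_cluster_size = as.integer(min_cluster_size),
                             min_samples = as.integer(min_samples),
                             epsilon = epsilon, selection = selection)
  }
  names(labels) <- rownames(embeddings)
  structure(labels, params = params, class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  p <- attr(x, "params")
  k <- length(unique(x[x >= 0]))
  cat(sprintf(
    "HDBSCAN assignment: %d points, %d clusters, %d noise\n  (min_cluster_size=%d, min_samples=%d, epsilon=%g, selection=%s)\n",
    length(x), k, sum(x < 0), p$min_cluster_size, p$min_samples,
    p$epsilon, p$selection))
  invisible(x)
}

#' Write / read embedding matrices as CSV keyed by vocalisation id
#'
#' @param embeddings Matrix with row names holding vocalisation ids.
#' @param path CSV path.
#' @return `read_embeddings` returns the matrix with ids as row names.
#' @export
write_embeddings <- function(embeddings, path) {
  df <- data.frame(id = rownames(embeddings) %||% seq_len(nrow(embeddings)),
                   as.data.frame(unclass(embeddings)))
  names(df)[-1] <- paste0("d", seq_len(ncol(embeddings)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  df <- utils::read.csv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
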