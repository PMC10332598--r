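#' Normalised mutual information between labels and clusters
#'
#' Agreement between an expert labelling `L` and a clustering `C`,
#' computed as the Kullback-Leibler divergence of the joint distribution
#' from the product of its marginals (i.e. the mutual information),
#' normalised by the arithmetic mean of the two entropies:
#' `NMI = D_KL(P_LC || P_L x P_C) * 2 / (H(L) + H(C))`.
#' A perfect match gives 1, independent partitions give 0. Entropies use
#' the natural log (the base cancels).
#'
#' By default, vocalisations that are unlabelled (`NA` label) or assigned
#' to noise (cluster `-1`) are excluded from the contingency table;
#' `noise = "singletons"` instead keeps noise points, each as its own
#' cluster.
#'
#' @param labels Vector of expert labels (`NA` = unlabelled).
#' @param clusters Integer vector of cluster ids (`-1` = noise), same
#'   length.
#' @param noise `"exclude"` (default) or `"singletons"`.
#' @return NMI in \[0, 1\]. If both partitions are single-category
#'   (entropy sum zero), returns 1 with a warning.
#' @examples
#' nmi(c("a", "a", "b", "b"), c(0, 0, 1, 1))  # 1
#' nmi(c("a", "a", "b", "b"), c(0, 0, 0, 0))  # 0
#' @export
nmi <- function(labels, clusters, noise = c("exclude", "singletons")) {
  noise <- match.arg(noise)
  stopifnot(length(labels) == length(clusters))
  clusters <- as.integer(clusters)
  keep <- !is.na(labels)
  if (noise == "exclude") {
    keep <- keep & clusters >= 0L
  } else {
    idx <- which(keep & clusters < 0L)
    if (length(idx)) {
      clusters[idx] <- max(clusters, 0L) + seq_along(idx)
    }
  }
  if (!any(keep)) {
    stop("no vocalisation is both labelled and clustered: NMI undefined")
  }
  tab <- table(labels[keep], clusters[keep])
  nmi_from_table(tab)
}

#' @rdname nmi
#' @param tab A label x cluster contingency table of counts.
#' @export
nmi_from_table <- function(tab) {
  n <- sum(tab)
  p_joint <- tab / n
  p_l <- rowSums(p_joint)
  p_c <- colSums(p_joint)
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  hl <- h(p_l); hc <- h(p_c)
  if (hl + hc == 0) {
    warning("both partitions are single-category; NMI defined as 1")
    return(1)
  }
  nz <- which(p_joint > 0, arr.ind = TRUE)
  mi <- sum(p_joint[nz] *
              log(p_joint[nz] / (p_l[nz[, 1]] * p_c[nz[, 2]])))
  val <- mi * 2 / (hl + hc)
  min(max(val, 0), 1)  # clip fp noise at the boundaries
}

#' Hopkins statistic of clusterability
#'
#' Compares nearest-neighbour distances of `m` reference points (drawn
#' from a normal distribution matched to the dataset's per-dimension
#' mean and standard deviation) against those of `m` dataset points:
#' `H = sum(u) / (sum(u) + sum(w))`, where `u_i` is the distance from a
#' reference point to its nearest data point, and `w_i` the distance
#' from a sampled data point to its nearest other data point. Values
#' near 0.5 indicate unstructured (normal-like) data; values toward 1
#' indicate a clusterable, discrete repertoire.
#'
#' @param points Numeric matrix (n x d), typically a 2-D UMAP projection.
#' @param m Number of sampled points (default 100).
#' @param seed Integer seed.
#' @param full_cov If `TRUE`, the reference distribution uses the full
#'   covariance of the data rather than per-dimension standard
#'   deviations.
#' @return Hopkins statistic in \[0, 1\].
#' @export
hopkins <- function(points, m = 100L, seed = 1L, full_cov = FALSE) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (m > n - 1) stop("need at least m + 1 = ", m + 1, " points, got ", n)
  set.seed(seed)
  d <- ncol(points)
  if (full_cov) {
    mu <- colMeans(points)
    S <- stats::cov(points)
    E <- eigen(S, symmetric = TRUE)
    A <- E$vectors %*% diag(sqrt(pmax(E$values, 0)), d)
    ref <- matrix(stats::rnorm(m * d), m, d) %*% t(A)
    ref <- sweep(ref, 2, mu, "+")
  } else {
    mu <- colMeans(points)
    sdv <- apply(points, 2, stats::sd)
    ref <- sweep(sweep(matrix(stats::rnorm(m * d), m, d), 2, sdv, "*"),
                 2, mu, "+")
  }
  # u: reference -> nearest data point
  u <- nn_dist(ref, points)
  # w: sampled data point -> nearest *other* data point
  samp <- sample.int(n, m)
  w <- nn_dist(points[samp, , drop = FALSE], points, exclude = samp)
  sum(u) / (sum(u) + sum(w))
}

# rowwise nearest-neighbour distance from a to rows of b; exclude[i]
# gives, per row of a, a row index of b to ignore (the point itself)
nn_dist <- function(a, b, exclude = NULL) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * a %*% t(b)
  if (!is.null(exclude)) {
    d2[cbind(seq_len(nrow(a)), exclude)] <- Inf
  }
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Discriminant-cluster report of annotation effort
#'
#' A cluster is discriminant when at least `purity_threshold` (default
#' 90%) of its labelled members share one type: such clusters can be
#' bulk-annotated by an expert after a quick inspection. Clusters
#' containing no labelled vocalisation cannot be assessed and are
#' excluded from the discriminant percentage. The report gives the
#' cluster count, the share of assessable clusters that are
#' discriminant, the share of all vocalisations (labelled or not,
#' noise excluded from no count — every unit is either clustered or
#' not) sitting in discriminant clusters, and the number of labels
#' never covered by any discriminant cluster.
#'
#' @param clusters Integer cluster ids (`-1` = noise).
#' @param labels Expert labels aligned with `clusters` (`NA` =
#'   unlabelled).
#' @param purity_threshold Majority-label fraction required (boundary
#'   inclusive).
#' @return A list of class `"annotation_report"`: `n_labels`,
#'   `n_clusters`, `pct_discriminant`, `pct_clustered`, `n_missed`,
#'   `purity_threshold`.
#' @export
discriminant_report <- function(clusters, labels, purity_threshold = 0.9) {
  stopifnot(length(clusters) == length(labels))
  clusters <- as.integer(clusters)
  if (all(is.na(labels))) stop("no labelled vocalisations: report undefined")
  ids <- sort(unique(clusters[clusters >= 0L]))
  n_clusters <- length(ids)
  if (n_clusters == 0) stop("no clusters (everything is noise)")
  discriminant <- logical(n_clusters)
  assessable <- logical(n_clusters)
  for (i in seq_along(ids)) {
    lab <- labels[clusters == ids[i]]
    lab <- lab[!is.na(lab)]
    if (length(lab) == 0) next
    assessable[i] <- TRUE
    discriminant[i] <- max(table(lab)) / length(lab) >= purity_threshold
  }
  disc_ids <- ids[discriminant]
  in_disc <- clusters %in% disc_ids
  covered <- unique(labels[in_disc & !is.na(labels)])
  all_labels <- unique(labels[!is.na(labels)])
  structure(list(
    n_labels = length(all_labels),
    n_clusters = n_clusters,
    pct_discriminant = 100 * sum(discriminant) / sum(assessable),
    pct_clustered = 100 * sum(in_disc) / length(clusters),
    n_missed = length(setdiff(all_labels, covered)),
    purity_threshold = purity_threshold
  ), class = "annotation_report")
}

#' @export
print.annotation_report <- function(x, ...) {
  cat("Annotation-effort report\n")
  cat(sprintf("  %d labels | %d clusters | %.1f%% discriminant\n",
              x$n_labels, x$n_clusters, x$pct_discriminant))
  cat(sprintf("  %.1f%% of vocalisations in discriminant clusters | %d labels missed\n",
              x$pct_clustered, x$n_missed))
  invisible(x)
}

#' Flat evaluation record for a pipeline run
#'
#' Combines NMI, Hopkins and the discriminant report into a one-row data
#' frame suitable for appending to a results CSV across runs.
#'
#' @param labels,clusters As in [nmi()].
#' @param points2d 2-D projection used for the Hopkins statistic (may be
#'   `NULL` to skip).
#' @param dataset,representation Free-text identifiers recorded in the
#'   row.
#' @param seed Seed for [hopkins()].
#' @return One-row data frame.
#' @export
evaluate_run <- function(labels, clusters, points2d = NULL,
                         dataset = NA_character_,
                         representation = NA_character_, seed = 1L) {
  rep_ <- discriminant_report(clusters, labels)
  data.frame(
    dataset = dataset,
    representation = representation,
    n = length(clusters),
    n_clusters = rep_$n_clusters,
    n_noise = sum(clusters < 0),
    nmi = nmi(labels, clusters),
    hopkins = if (is.null(points2d)) NA_real_ else
      hopkins(points2d, m = min(100L, nrow(points2d) - 1L), seed = seed),
    pct_discriminant = rep_$pct_discriminant,
    pct_clustered = rep_$pct_clustered,
    n_missed = rep_$n_missed,
    stringsAsFactors = FALSE
  )
}
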