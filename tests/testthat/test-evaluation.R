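test_that("NMI matches its boundary cases and a brute-force oracle", {
  expect_equal(nmi(c("a", "a", "b", "b"), c(0, 0, 1, 1)), 1)
  expect_equal(nmi(c("a", "a", "b", "b"), c(1, 1, 0, 0)), 1)  # relabelled
  expect_equal(nmi(c("a", "a", "b", "b"), c(0, 0, 0, 0)), 0)
  # hand-constructed 2x2 table [[2,0],[1,1]]
  tab <- matrix(c(2, 1, 0, 1), 2, 2)
  expect_equal(nmi_from_table(tab), nmi_bruteforce(tab), tolerance = 1e-12)
  # random contingency tables up to 10x10 against the loop oracle
  set.seed(51)
  for (i in 1:20) {
    r <- sample(2:10, 1); c <- sample(2:10, 1)
    tab <- matrix(rpois(r * c, 3), r, c)
    if (sum(tab) == 0) tab[1, 1] <- 1
    expect_equal(nmi_from_table(tab), nmi_bruteforce(tab),
                 tolerance = 1e-10)
  }
})

test_that("NMI is symmetric and invariant to relabelling", {
  set.seed(52)
  l <- sample(letters[1:4], 200, replace = TRUE)
  c_ <- sample(0:5, 200, replace = TRUE)
  expect_equal(nmi(l, c_), nmi(as.character(c_), match(l, letters)))
  # permuting category names changes nothing
  perm <- sample(0:5)
  expect_equal(nmi(l, perm[c_ + 1]), nmi(l, c_))
})

test_that("NMI handles unlabelled points, noise and degenerate tables", {
  l <- c("a", "a", "b", "b", NA, "a")
  cl <- c(0, 0, 1, 1, 0, -1)
  # unlabelled and noise rows are excluded by default: perfect agreement
  expect_equal(nmi(l, cl), 1)
  # singleton mode turns the noise point into its own cluster
  expect_lt(nmi(l, cl, noise = "singletons"), 1)
  expect_warning(v <- nmi(c("a", "a"), c(0, 0)), "single-category")
  expect_equal(v, 1)
  expect_error(nmi(c(NA, NA), c(0, 1)), "undefined")
})

test_that("Hopkins statistic calibrates on normal data and detects blobs", {
  set.seed(53)
  x <- matrix(rnorm(1000), 500, 2)
  hs <- vapply(1:20, function(s) hopkins(x, m = 100, seed = s), 1.0)
  expect_true(all(abs(hs - 0.5) < 0.1))
  # two far-separated tight blobs
  blobs <- rbind(matrix(rnorm(400, 0, 0.05), 200, 2),
                 matrix(rnorm(400, 10, 0.05), 200, 2))
  expect_gt(hopkins(blobs, m = 100, seed = 1), 0.8)
  # bounded in [0, 1] for arbitrary finite inputs
  set.seed(54)
  weird <- matrix(rcauchy(300), 150, 2)
  h <- hopkins(weird, m = 50, seed = 2)
  expect_gte(h, 0)
  expect_lte(h, 1)
  expect_error(hopkins(matrix(rnorm(20), 10, 2), m = 100), "at least")
  # clusterability rises monotonically (in trend) with blob separation
  seps <- c(0, 2, 5, 10)
  hh <- vapply(seps, function(s) {
    set.seed(55)
    pts <- rbind(matrix(rnorm(300, 0, 1), 150, 2),
                 matrix(rnorm(300, s, 1), 150, 2))
    mean(vapply(1:5, function(sd_) hopkins(pts, m = 100, seed = sd_), 1.0))
  }, 1.0)
  expect_true(all(diff(hh) > 0))
})

test_that("discriminant report applies the 90% rule at the boundary", {
  # cluster 0: 9 A + 1 B labelled -> exactly 0.9, counts as discriminant
  labels <- c(rep("A", 9), "B", rep("B", 10), rep(NA, 5))
  clusters <- c(rep(0, 10), rep(1, 10), rep(2, 5))
  rep_ <- discriminant_report(clusters, labels)
  expect_equal(rep_$n_clusters, 3L)
  # cluster 2 has only unlabelled members: excluded from the denominator
  expect_equal(rep_$pct_discriminant, 100)
  expect_equal(rep_$pct_clustered, 100 * 20 / 25)
  expect_equal(rep_$n_missed, 0L)
  # dropping one A breaks the threshold (8/9 < 0.9)
  rep2 <- discriminant_report(clusters[-1], labels[-1])
  expect_equal(rep2$pct_discriminant, 50)
  # a label whose every occurrence is outside discriminant clusters
  lab3 <- c(rep("A", 10), rep("B", 5), rep("C", 5))
  cl3 <- c(rep(0, 10), rep(1, 10))
  rep3 <- discriminant_report(cl3, lab3)
  expect_equal(rep3$n_missed, 2L)   # B and C share an impure cluster
  expect_error(discriminant_report(c(0, 1), c(NA, NA)), "no labelled")
})

test_that("evaluation record conserves totals", {
  set.seed(56)
  n <- 120
  labels <- sample(c("x", "y", "z"), n, replace = TRUE)
  clusters <- sample(c(-1L, 0L, 1L, 2L), n, replace = TRUE)
  rep_ <- discriminant_report(clusters, labels)
  in_disc <- round(rep_$pct_clustered / 100 * n)
  expect_lte(in_disc, sum(clusters >= 0))
  row <- evaluate_run(labels, clusters,
                      points2d = matrix(rnorm(2 * n), n, 2),
                      dataset = "synthetic", representation = "test")
  expect_equal(row$n, n)
  expect_equal(row$n_noise, sum(clusters < 0))
  expect_true(row$nmi >= 0 && row$nmi <= 1)
  expect_true(row$hopkins >= 0 && row$hopkins <= 1)
})
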