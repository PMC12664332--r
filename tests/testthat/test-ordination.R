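test_that("PCA reproduces a brute-force covariance eigendecomposition", {
  set.seed(3)
  m <- matrix(rnorm(100), 20, 5)
  pc <- jaw_pca(m)
  eg <- eigen(cov(m), symmetric = TRUE)
  expect_lt(max(abs(pc$eigenvalues - eg$values)), 1e-9)
  ## scores agree up to per-axis sign
  centred <- sweep(m, 2, colMeans(m))
  ref <- centred %*% eg$vectors
  for (k in 1:5) {
    agree <- min(max(abs(pc$scores[, k] - ref[, k])),
                 max(abs(pc$scores[, k] + ref[, k])))
    expect_lt(agree, 1e-9)
  }
  ## trace conservation and variance fractions
  expect_equal(sum(pc$eigenvalues), sum(diag(cov(m))), tolerance = 1e-9)
  expect_equal(sum(pc$variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))
  ## deterministic sign convention: dominant loading entry positive
  for (k in 1:5)
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, k])), k], 0)
})

test_that("PCA drops null axes and validates input", {
  two <- matrix(c(0, 1, 0, 2), 2, 2)
  pc <- jaw_pca(two)
  expect_length(pc$eigenvalues, 1L)
  bad <- matrix(c(1, NA, 3, 4, 5, 6), 3, 2)
  expect_error(jaw_pca(bad), "rows: 2")
  expect_error(jaw_pca(matrix(1, 1, 3)), "at least 2")
})

test_that("variance fractions sum over the selected axes", {
  set.seed(8)
  pc <- jaw_pca(matrix(rnorm(80), 16, 5))
  expect_equal(variance_fraction(pc, seq_along(pc$eigenvalues)), 1)
  expect_equal(variance_fraction(pc, 1),
               pc$eigenvalues[1] / sum(pc$eigenvalues))
  expect_equal(variance_fraction(pc, 1:2), sum(pc$variance_fraction[1:2]))
  expect_error(variance_fraction(pc, 99), "out of range")
})

test_that("sum of variances equals the centroid-deviation identity", {
  expect_equal(sum_of_variances(matrix(c(0, 2))), 2)
  one <- sum_of_variances(matrix(c(0, 2)), rows = 1)
  expect_equal(as.numeric(one), 0)
  expect_true(attr(one, "degenerate"))
  expect_error(sum_of_variances(matrix(1), rows = integer()), "empty")
  set.seed(5)
  sc <- matrix(rnorm(60), 15, 4)
  sub <- c(2, 5, 9, 11, 14)
  direct <- {
    x <- sc[sub, ]
    sum(rowSums(sweep(x, 2, colMeans(x))^2)) / (length(sub) - 1)
  }
  expect_equal(as.numeric(sum_of_variances(sc, sub)), direct,
               tolerance = 1e-12)
})

test_that("bootstrap disparity is seeded, consistent and degenerate-safe", {
  same <- matrix(1, 6, 3)
  bs <- bootstrap_disparity(same, n_boot = 50, seed = 2)
  expect_equal(bs$median, 0)
  expect_equal(unname(bs$ci), c(0, 0))
  set.seed(77); sc <- matrix(rnorm(100), 100, 1)
  b1 <- bootstrap_disparity(sc, n_boot = 200, seed = 4)
  b2 <- bootstrap_disparity(sc, n_boot = 200, seed = 4)
  expect_identical(b1, b2)
  b3 <- bootstrap_disparity(sc, n_boot = 10000, seed = 4)
  expect_lt(abs(b3$median - var(sc[, 1])) / var(sc[, 1]), 0.1)
  expect_error(bootstrap_disparity(sc, n_boot = 0), "n_boot")
})

test_that("bootstrap intervals cover the true variance in most replicates", {
  hits <- 0L
  for (i in 1:200) {
    x <- matrix(with_seed(i, rnorm(100)), ncol = 1)
    bs <- bootstrap_disparity(x, n_boot = 400, seed = 1000 + i)
    if (bs$ci[1] <= 1 && 1 <= bs$ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 180L)   # 90% of 200, allowing bootstrap undercoverage
})

test_that("partial disparity partitions total disparity additively", {
  pd <- partial_disparity(matrix(c(0, 2)), c("A", "B"))
  expect_equal(pd$partial_disparity, c(1, 1))
  expect_equal(sum(pd$partial_disparity), 2)
  x <- matrix(rnorm(10))
  single <- partial_disparity(x, rep("A", 10))
  expect_equal(single$fraction, 1)
  expect_equal(single$partial_disparity, as.numeric(sum_of_variances(x)),
               tolerance = 1e-12)
  set.seed(21)
  sc <- matrix(rnorm(200), 40, 5)
  for (g in c(2, 3, 5)) {
    labels <- sample(letters[1:g], 40, replace = TRUE)
    pd <- partial_disparity(sc, labels)
    expect_equal(sum(pd$partial_disparity),
                 as.numeric(sum_of_variances(sc)), tolerance = 1e-9)
    expect_equal(sum(pd$fraction), 1, tolerance = 1e-9)
  }
})

test_that("time-bin tables are named, ordered and contiguous", {
  st <- build_time_bins("stage")
  expect_equal(nrow(st), 15L)
  expect_equal(st$bin[1], "Visean")
  expect_equal(st$bin[15], "Changhsingian")
  expect_true(all(st$older_bound_ma > st$younger_bound_ma))
  expect_equal(st$younger_bound_ma[-15], st$older_bound_ma[-1])
  se <- build_time_bins("series")
  expect_equal(se$bin, c("Mississippian", "Pennsylvanian", "Cisuralian",
                         "Guadalupian", "Lopingian"))
  expect_equal(se$younger_bound_ma[-5], se$older_bound_ma[-1])
  expect_error(build_time_bins("epoch"), "arg")
})

test_that("bin assignment follows the half-open range-overlap convention", {
  bins <- data.frame(bin = c("B1", "B2"),
                     older_bound_ma = c(320, 300),
                     younger_bound_ma = c(300, 280))
  md <- function(fad, lad) data.frame(taxon_id = "t", fad_ma = fad,
                                      lad_ma = lad)
  expect_equal(as.logical(assign_bins(md(310, 290), bins)), c(TRUE, TRUE))
  expect_equal(as.logical(assign_bins(md(305, 305), bins)), c(TRUE, FALSE))
  ## a point range on the shared boundary belongs to the younger bin
  expect_equal(as.logical(assign_bins(md(300, 300), bins)), c(FALSE, TRUE))
  ## touching a boundary without positive overlap does not qualify
  expect_equal(as.logical(assign_bins(md(330, 320), bins)), c(FALSE, FALSE))
  ## a range equal to one bin is in that bin only
  expect_equal(as.logical(assign_bins(md(320, 300), bins)), c(TRUE, FALSE))
  expect_error(assign_bins(md(290, 310), bins), "FAD younger than LAD")
})

test_that("disparity through time composes the per-bin primitives", {
  set.seed(31)
  sc <- matrix(rnorm(36), 12, 3,
               dimnames = list(sprintf("t%02d", 1:12), NULL))
  membership <- cbind(early = c(rep(TRUE, 7), rep(FALSE, 5)),
                      late = c(rep(FALSE, 5), rep(TRUE, 7)),
                      lone = c(TRUE, rep(FALSE, 11)))
  rownames(membership) <- rownames(sc)
  groups <- rep(c("synapsid", "nonamniote"), 6)
  dtt <- disparity_through_time(sc, membership, groups, n_boot = 100,
                                seed = 5)
  for (b in c("early", "late")) {
    idx <- which(membership[, b])
    expect_equal(dtt$sum_of_variances[dtt$bin == b],
                 as.numeric(sum_of_variances(sc, idx)), tolerance = 1e-12)
    pd <- partial_disparity(sc[idx, ], groups[idx])
    for (g in pd$group)
      expect_equal(dtt[[paste0("PD_", g)]][dtt$bin == b],
                   pd$partial_disparity[pd$group == g], tolerance = 1e-12)
    ## additivity inside the bin
    expect_equal(dtt[[paste0("PD_nonamniote")]][dtt$bin == b] +
                   dtt[[paste0("PD_synapsid")]][dtt$bin == b],
                 dtt$sum_of_variances[dtt$bin == b], tolerance = 1e-9)
  }
  lone <- dtt[dtt$bin == "lone", ]
  expect_true(lone$degenerate)
  expect_equal(lone$sum_of_variances, 0)
  expect_equal(lone$n, 1L)
})

test_that("hypothesis relabelling moves exactly the flagged rows", {
  md <- data.frame(
    taxon_id = sprintf("t%d", 1:6),
    clade = c("nonamniote", "nonamniote", "nonamniote",
              "sauropsid", "sauropsid", "synapsid"),
    is_diadectomorph = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    is_captorhinid_araeoscelidian_protorothyridid =
      c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    is_recumbirostran = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  h1 <- apply_hypothesis(md, "H1")
  expect_equal(h1$clade, md$clade)
  expect_equal(h1$amniote, md$clade != "nonamniote")
  expect_identical(apply_hypothesis(h1, "H1")$clade, h1$clade)
  h2 <- apply_hypothesis(md, "H2")
  expect_equal(h2$clade[1:2], c("synapsid", "synapsid"))
  expect_equal(h2$clade[3:6], md$clade[3:6])
  h3 <- apply_hypothesis(md, "H3")
  expect_equal(h3$clade[4], "nonamniote")
  expect_false(h3$amniote[4])
  h4 <- apply_hypothesis(md, "H4")
  expect_equal(h4$clade[3], "sauropsid")
  expect_equal(nrow(h4), 6L)
  expect_error(apply_hypothesis(md, "H9"), "arg")
})

test_that("the unsquared partial-disparity variant uses plain distances", {
  sc <- matrix(c(0, 2, 0, 0), 2, 2)     # centroid (1, 0), distances 1 and 1
  pd <- partial_disparity(sc, c("A", "B"), squared = FALSE)
  expect_equal(pd$partial_disparity, c(1, 1))
  sc2 <- matrix(c(0, 4), 2, 1)          # distances 2; (N - 1) = 1
  pd2 <- partial_disparity(sc2, c("A", "B"), squared = FALSE)
  expect_equal(pd2$partial_disparity, c(2, 2))
})
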