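test_that("a circle is a single pure harmonic", {
  e <- efa_decompose(circle_outline(256), 3)
  hm <- e$harmonics
  expect_equal(unname(hm[1, c("a", "d")]), c(1, 1), tolerance = 1e-3)
  expect_lt(max(abs(hm[1, c("b", "c")])), 1e-3)
  expect_lt(max(abs(hm[2:3, ])), 1e-3)
  expect_lt(max(abs(e$offset)), 1e-9)
  hp <- harmonic_power(e)
  expect_equal(hp$power[1], 1, tolerance = 1e-3)
  expect_equal(hp$cumulative_fraction[1], 1, tolerance = 1e-9)
})

test_that("coefficients match the direct quadrature of the defining integrals", {
  set.seed(7)
  shapes <- list(
    as_outline(cbind(c(0, 4, 5, 2, -1), c(0, -1, 2, 4, 2))),
    ellipse_outline(3, 1, n = 64),
    circle_outline(48, r = 2.5, phase = 0.7),
    as_outline(cbind(runif(9, -1, 1) + 3 * cos(seq(0, 2 * pi,
                                                   length.out = 10)[-10]),
                     runif(9, -1, 1) + 3 * sin(seq(0, 2 * pi,
                                                   length.out = 10)[-10]))))
  for (o in shapes) {
    H <- 6
    mine <- efa_decompose(o, H)$harmonics
    oracle <- efa_quadrature_oracle(o, H)
    expect_lt(max(abs(mine - oracle)), 1e-9)
  }
})

test_that("an eccentric ellipse is harmonic-1 dominated and oracle-consistent", {
  ## under the arc-length parameterisation an eccentric ellipse is not a
  ## single exact harmonic: the first ellipse dominates and odd harmonics
  ## carry the parameter-speed distortion
  e <- efa_decompose(ellipse_outline(3, 1, n = 512), 8)
  expect_equal(unname(e$harmonics[1, "a"]), 3, tolerance = 0.15)
  expect_equal(unname(e$harmonics[1, "d"]), 1, tolerance = 0.15)
  hp <- harmonic_power(e)
  expect_gt(hp$cumulative_fraction[1], 0.97)
  expect_gt(abs(e$harmonics[3, "a"]), abs(e$harmonics[2, "a"]) + 0.01)
  ## higher-harmonic power fraction agrees with the quadrature oracle
  oracle <- efa_quadrature_oracle(ellipse_outline(3, 1, n = 512), 8)
  p_mine <- rowSums(e$harmonics^2) / 2
  p_orac <- rowSums(oracle^2) / 2
  expect_lt(max(abs(p_mine / sum(p_mine) - p_orac / sum(p_orac))), 1e-6)
})

test_that("coefficients are translation-invariant and power is rotation-invariant", {
  o <- make_jaw_outline(shape_params(), 300)
  e0 <- efa_decompose(o, 10)
  shifted <- as_outline(sweep(as.matrix(o), 2, c(-5, 2)))
  e1 <- efa_decompose(shifted, 10)
  expect_lt(max(abs(e0$harmonics - e1$harmonics)), 1e-12)
  expect_equal(unname(e1$offset - e0$offset), c(5, -2), tolerance = 1e-12)

  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rotated <- as_outline(as.matrix(o) %*% t(R))
  e2 <- efa_decompose(rotated, 10)
  expect_equal(rowSums(e0$harmonics^2), rowSums(e2$harmonics^2),
               tolerance = 1e-9)
})

test_that("reconstruction error shrinks monotonically with harmonic count", {
  o <- resample_closed(make_jaw_outline(shape_params(), 300), 256)
  target <- as.matrix(o)
  errs <- vapply(c(1, 2, 4, 8, 16), function(H) {
    rec <- efa_reconstruct(efa_decompose(o, H), k = 256)
    sqrt(mean(rowSums((as.matrix(rec) - target)^2)))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[length(errs)], errs[1] / 5)

  ## one-harmonic circle round trip is near-exact
  rec <- efa_reconstruct(efa_decompose(circle_outline(256), 1), k = 256)
  d <- sqrt(rowSums((as.matrix(rec) - as.matrix(circle_outline(256)))^2))
  expect_lt(max(d), 1e-3)

  ## zero harmonics collapse to k copies of the offset point
  e <- efa_decompose(circle_outline(64), 2)
  e$harmonics[] <- 0
  e$offset <- c(A0 = 4, C0 = -1)
  rec0 <- efa_reconstruct(e, 10)
  expect_equal(unname(rec0), matrix(c(4, -1), 10, 2, byrow = TRUE))
})

test_that("harmonic power is homogeneous of degree two and normalised", {
  o <- make_jaw_outline(shape_params(), 300)
  e <- efa_decompose(o, 12)
  hp <- harmonic_power(e)
  expect_true(all(diff(hp$cumulative_fraction) >= -1e-15))
  expect_equal(hp$cumulative_fraction[12], 1, tolerance = 1e-12)
  es <- e; es$harmonics <- 3 * e$harmonics
  hps <- harmonic_power(es)
  expect_equal(hps$power, 9 * hp$power, tolerance = 1e-12)
  expect_equal(hps$cumulative_fraction, hp$cumulative_fraction,
               tolerance = 1e-12)
})

test_that("harmonic calibration returns the smallest sufficient order", {
  circles <- lapply(1:4, function(i) circle_outline(128, r = i))
  expect_identical(calibrate_harmonics(circles, 0.99), 1L)
  ## threshold 1 forces the full reference order
  poly <- list(as_outline(cbind(c(0, 4, 5, 2, -1), c(0, -1, 2, 4, 2))))
  href <- floor(5 / 2) - 1
  expect_identical(calibrate_harmonics(poly, 1.0), as.integer(href))
  expect_error(calibrate_harmonics(list(), 0.99), "empty")
  ## worst-case aggregation needs at least as many harmonics as mean-case
  set.seed(3)
  mix <- c(lapply(1:3, function(i) circle_outline(128)),
           list(resample_closed(make_jaw_outline(shape_params(), 300), 128)))
  h_worst <- calibrate_harmonics(mix, 0.99, aggregate = "worst")
  h_mean <- calibrate_harmonics(mix, 0.99, aggregate = "mean")
  expect_gte(h_worst, h_mean)
})

test_that("a featureless symmetric jaw is dominated by its first harmonic", {
  p0 <- shape_params(coronoid_height = 0, depth_peak_position = 0.5,
                     articular_offset = 1e-9)
  o0 <- rotate_start(normalize_geometry(make_jaw_outline(p0, 660)))
  cf <- harmonic_power(efa_decompose(o0, 20))$cumulative_fraction
  ## oracle-checked: the flat tooth-row margin keeps a few percent of power
  ## in higher harmonics, but the first ellipse carries nearly all of it
  oracle <- efa_quadrature_oracle(o0, 20)
  p_orac <- rowSums(oracle^2) / 2
  expect_equal(cf[1], (p_orac / sum(p_orac))[1], tolerance = 1e-6)
  expect_gt(cf[1], 0.95)
})

test_that("first-ellipse normalisation removes rotation, scale and start point", {
  o <- make_jaw_outline(shape_params(), 300)
  base <- normalize_first_ellipse(efa_decompose(o, 8))
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- as_outline(2.4 * as.matrix(o) %*% t(R) + 5)
  moved <- rotate_start(moved, start = 77)     # arbitrary new start vertex
  alt <- normalize_first_ellipse(efa_decompose(moved, 8))
  expect_equal(alt$harmonics, base$harmonics, tolerance = 1e-6)
  ## normalised first harmonic has unit semi-major axis along x
  expect_equal(unname(base$harmonics[1, "a"]), 1, tolerance = 1e-9)
  expect_equal(unname(base$harmonics[1, "c"]), 0, tolerance = 1e-9)
})
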