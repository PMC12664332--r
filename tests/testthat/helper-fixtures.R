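# shared fixtures and independent oracles ------------------------------------

## internal helpers exercised directly by the tests
with_seed <- jawspace:::with_seed
validate_sim_config <- jawspace:::validate_sim_config

circle_outline <- function(n = 256, r = 1, phase = 0) {
  th <- phase + seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  as_outline(cbind(r * cos(th), r * sin(th)))
}

ellipse_outline <- function(a = 3, b = 1, n = 512, angle = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  xy <- cbind(a * cos(th), b * sin(th))
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
  as_outline(xy %*% t(R))
}

## symmetric U-shaped jaw arch (occlusal view stand-in), symmetry axis x = 0
arch_outline <- function(outer_r = 10, inner_r = 6, n = 100) {
  th <- seq(0, pi, length.out = n)
  as_outline(rbind(cbind(outer_r * cos(th), outer_r * sin(th)),
                   cbind(inner_r * cos(rev(th)), inner_r * sin(rev(th)))),
             view = "occlusal")
}

## independent oracle: Fourier coefficients of the arc-length parameterised
## polygon by per-segment Gauss-Legendre quadrature of the defining integrals
efa_quadrature_oracle <- function(outline, H, nodes = 24) {
  xy <- as.matrix(outline)
  closed <- rbind(xy, xy[1, ])
  dt <- sqrt(rowSums(diff(closed)^2))
  Tt <- sum(dt)
  t0 <- c(0, cumsum(dt))
  gl <- pracma::gaussLegendre(nodes, 0, 1)
  coef1 <- function(n, fun, coord) {
    tot <- 0
    for (i in seq_along(dt)) {
      tt <- t0[i] + gl$x * dt[i]
      pos <- closed[i, coord] + gl$x * (closed[i + 1, coord] - closed[i, coord])
      tot <- tot + sum(gl$w * dt[i] * pos * fun(2 * pi * n * tt / Tt))
    }
    2 * tot / Tt
  }
  t(vapply(seq_len(H), function(n)
    c(a = coef1(n, cos, 1), b = coef1(n, sin, 1),
      c = coef1(n, cos, 2), d = coef1(n, sin, 2)), numeric(4)))
}

## independent pseudo-F oracle from pairwise distances (Gower decomposition)
permanova_F_oracle <- function(coords, groups) {
  d2 <- as.matrix(dist(coords))^2
  N <- nrow(coords)
  sst <- sum(d2[upper.tri(d2)]) / N
  ssw <- 0
  for (lv in unique(groups)) {
    i <- which(groups == lv)
    ssw <- ssw + sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
  }
  g <- length(unique(groups))
  ((sst - ssw) / (g - 1)) / (ssw / (N - g))
}

## metadata table with two diet groups of fixed size, for generator tests
two_group_metadata <- function(n_per_group) {
  n <- 2L * n_per_group
  data.frame(taxon_id = sprintf("t%04d", seq_len(n)),
             clade = rep("synapsid", n),
             is_diadectomorph = FALSE,
             is_captorhinid_araeoscelidian_protorothyridid = FALSE,
             is_recumbirostran = FALSE,
             diet = rep(c("herbivore", "nonherbivore"), each = n_per_group),
             fad_ma = 300, lad_ma = 290,
             has_lateral = TRUE, has_medial = TRUE, has_occlusal = FALSE,
             stringsAsFactors = FALSE)
}

random_shape_params <- function() {
  sp <- sort(runif(2, 0.2, 0.98))
  fs <- sort(runif(2, 0.03, 0.5))
  shape_params(length = runif(1, 5, 20),
               max_depth = runif(1, 1, 4),
               depth_peak_position = runif(1, 0.25, 0.75),
               coronoid_height = runif(1, 0, 1.5),
               coronoid_position = runif(1, 0.2, 0.5),
               coronoid_width = runif(1, 0.04, 0.1),
               symphysis_length = runif(1, 0.2, 2),
               articular_offset = runif(1, 0, 1),
               insertion_position = runif(1, 0.08, 0.4),
               opening_position = runif(1, 0.03, 0.15),
               toothrow_span = sp, fossa_span = fs)
}
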