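#' Elliptical Fourier decomposition of a closed outline
#'
#' Computes elliptical Fourier descriptors (Kuhl & Giardina form) of the
#' piecewise-linear, arc-length parameterised closed polygon: for harmonic n,
#' the four coefficients (a_n, b_n, c_n, d_n) of
#' x(t) = A0 + sum a_n cos(2 pi n t / T) + b_n sin(2 pi n t / T),
#' y(t) = C0 + sum c_n cos(2 pi n t / T) + d_n sin(2 pi n t / T),
#' where T is the outline perimeter.  The offset (A0, C0) is the arc-length
#' centroid of the curve.  Each harmonic describes an ellipse; a unit circle
#' traversed counter-clockwise from (1, 0) has a1 = d1 = 1 and all other
#' coefficients zero.
#'
#' @param outline an [as_outline()] object (closed polygon).
#' @param H number of harmonics (>= 1); at most `floor(n_vertices / 2) - 1`
#'   is informative.
#' @return an object of class `efa`: list with `harmonics` (H x 4 matrix with
#'   columns a, b, c, d), `offset` (A0, C0), `H`, and the perimeter `T`.
#' @references Kuhl, F.P. & Giardina, C.R. (1982). Elliptic Fourier features
#'   of a closed contour. Computer Graphics and Image Processing 18, 236-258.
#' @export
#' @examples
#' th <- seq(0, 2 * pi, length.out = 257)[-257]
#' circ <- as_outline(cbind(cos(th), sin(th)))
#' efa_decompose(circ, 3)$harmonics
efa_decompose <- function(outline, H) {
  if (H < 1L) stop("H must be at least 1", call. = FALSE)
  xy <- as.matrix(outline)
  n <- nrow(xy)
  closed <- rbind(xy, xy[1L, ])
  dxy <- diff(closed)
  dt <- sqrt(rowSums(dxy^2))
  keep <- dt > 0
  dxy <- dxy[keep, , drop = FALSE]; dt <- dt[keep]
  Tt <- sum(dt)
  t1 <- c(0, cumsum(dt))[seq_along(dt)]   # segment start times
  t2 <- t1 + dt
  ## offsets: arc-length average of the piecewise-linear coordinates
  mid <- (closed[c(keep, FALSE), , drop = FALSE] +
          closed[c(FALSE, keep), , drop = FALSE]) / 2
  offset <- colSums(mid * dt) / Tt
  dxdt <- dxy[, 1] / dt
  dydt <- dxy[, 2] / dt
  w <- 2 * pi * seq_len(H) / Tt           # angular frequency per harmonic
  ## outer products: segments x harmonics
  c2 <- cos(outer(t2, w)); c1 <- cos(outer(t1, w))
  s2 <- sin(outer(t2, w)); s1 <- sin(outer(t1, w))
  const <- Tt / (2 * pi^2 * seq_len(H)^2)
  a <- const * colSums(dxdt * (c2 - c1))
  b <- const * colSums(dxdt * (s2 - s1))
  cc <- const * colSums(dydt * (c2 - c1))
  d <- const * colSums(dydt * (s2 - s1))
  harmonics <- cbind(a = a, b = b, c = cc, d = d)
  rownames(harmonics) <- seq_len(H)
  structure(list(harmonics = harmonics,
                 offset = c(A0 = unname(offset[1]), C0 = unname(offset[2])),
                 H = as.integer(H), T = Tt),
            class = "efa")
}

#' @export
print.efa <- function(x, ...) {
  cat(sprintf("<efa> %d harmonics, offset (%.4g, %.4g)\n",
              x$H, x$offset[1], x$offset[2]))
  print(head(x$harmonics, 4L))
  if (x$H > 4L) cat("...\n")
  invisible(x)
}

#' Reconstruct an outline from elliptical Fourier coefficients
#'
#' Evaluates the truncated Fourier series at `k` equally spaced parameter
#' values in \[0, T).  Used for round-trip validation and for visualising
#' morphospace extremes.
#'
#' @param coeffs an `efa` object from [efa_decompose()].
#' @param k number of points to evaluate.
#' @param H optionally truncate to the first `H` harmonics.
#' @return an [as_outline()] object with `k` vertices.
#' @export
efa_reconstruct <- function(coeffs, k = 256L, H = coeffs$H) {
  H <- min(H, coeffs$H)
  t <- seq(0, 1, length.out = k + 1L)[seq_len(k)]
  ang <- outer(t, 2 * pi * seq_len(H))
  Cn <- cos(ang); Sn <- sin(ang)
  hm <- coeffs$harmonics[seq_len(H), , drop = FALSE]
  x <- coeffs$offset[1] + Cn %*% hm[, "a"] + Sn %*% hm[, "b"]
  y <- coeffs$offset[2] + Cn %*% hm[, "c"] + Sn %*% hm[, "d"]
  pts <- unname(cbind(x, y))
  ## an all-zero series degenerates to k copies of the offset point, which
  ## is not a valid outline; return the bare point matrix in that case
  if (all(abs(sweep(pts, 2, pts[1, ])) < 1e-300)) {
    colnames(pts) <- c("x", "y")
    return(pts)
  }
  as_outline(pts, keep_orientation = TRUE)
}

#' Harmonic power profile of an EFA decomposition
#'
#' The power of harmonic n is P_n = (a_n^2 + b_n^2 + c_n^2 + d_n^2) / 2; the
#' cumulative fraction is the running sum of P_n divided by the total over
#' all computed harmonics.  Used to calibrate how many harmonics are needed
#' to capture a target share of shape variation.
#'
#' @param coeffs an `efa` object.
#' @return a data frame with columns `harmonic`, `power`,
#'   `cumulative_fraction`.
#' @export
harmonic_power <- function(coeffs) {
  p <- rowSums(coeffs$harmonics^2) / 2
  data.frame(harmonic = seq_len(coeffs$H), power = unname(p),
             cumulative_fraction = unname(cumsum(p) / sum(p)))
}

#' Calibrate the number of harmonics for a set of outlines
#'
#' Decomposes every outline at a high reference order
#' `H_ref = floor(k_min / 2) - 1` (k_min = smallest vertex count) and returns
#' the smallest H at which the cumulative power fraction reaches `threshold`.
#' With the default worst-case aggregation every specimen must individually
#' reach the threshold; `aggregate = "mean"` uses the across-specimen mean
#' cumulative fraction instead.
#'
#' @param outlines a list of [as_outline()] objects.
#' @param threshold required cumulative power fraction in (0, 1\]; default
#'   0.99.
#' @param aggregate `"worst"` (default) or `"mean"`.
#' @param H_ref reference decomposition order; defaults to
#'   `floor(k_min / 2) - 1`.
#' @return the calibrated harmonic count (integer).
#' @export
calibrate_harmonics <- function(outlines, threshold = 0.99,
                                aggregate = c("worst", "mean"), H_ref = NULL) {
  aggregate <- match.arg(aggregate)
  if (!length(outlines)) stop("empty outline collection", call. = FALSE)
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]", call. = FALSE)
  if (is.null(H_ref))
    H_ref <- floor(min(vapply(outlines, nrow, 1L)) / 2) - 1L
  cf <- vapply(outlines, function(o)
    harmonic_power(efa_decompose(o, H_ref))$cumulative_fraction,
    numeric(H_ref))
  cf <- matrix(cf, nrow = H_ref)
  prof <- if (aggregate == "worst") apply(cf, 1, min) else rowMeans(cf)
  H <- which(prof >= threshold - 1e-12)[1]
  if (is.na(H)) H <- H_ref
  as.integer(H)
}

#' Normalise EFA coefficients by the first harmonic ellipse
#'
#' The classical alternative to geometric pre-alignment: rotates the
#' starting point and orientation onto the first harmonic's major axis and
#' scales by its semi-major magnitude, making the coefficients invariant to
#' outline rotation, scale and starting point.  Provided as a sensitivity
#' check against the default centre/scale/align route.
#'
#' @param coeffs an `efa` object.
#' @return an `efa` object with normalised harmonics (offset zeroed).
#' @export
normalize_first_ellipse <- function(coeffs) {
  hm <- coeffs$harmonics
  a1 <- hm[1, "a"]; b1 <- hm[1, "b"]; c1 <- hm[1, "c"]; d1 <- hm[1, "d"]
  theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1),
                       a1^2 + c1^2 - b1^2 - d1^2)
  a1s <- a1 * cos(theta) + b1 * sin(theta)
  c1s <- c1 * cos(theta) + d1 * sin(theta)
  scale <- sqrt(a1s^2 + c1s^2)
  psi <- atan2(c1s, a1s)
  Rpsi <- rbind(c(cos(psi), sin(psi)), c(-sin(psi), cos(psi)))
  out <- hm
  for (n in seq_len(coeffs$H)) {
    Sn <- rbind(c(cos(n * theta), -sin(n * theta)),
                c(sin(n * theta), cos(n * theta)))
    M <- rbind(hm[n, c("a", "b")], hm[n, c("c", "d")])
    Mn <- Rpsi %*% M %*% Sn / scale
    out[n, ] <- c(Mn[1, ], Mn[2, ])
  }
  structure(list(harmonics = out, offset = c(A0 = 0, C0 = 0),
                 H = coeffs$H, T = coeffs$T), class = "efa")
}

#' EFA coefficient table for a set of outlines
#'
#' Convenience wrapper: decomposes each outline at `H` harmonics and binds
#' the coefficients into a specimen-by-coefficient matrix with columns
#' a1, b1, c1, d1, ..., dH (offsets excluded), the shape descriptor fed to
#' principal component analysis.
#'
#' @param outlines named list of [as_outline()] objects.
#' @param H harmonic count, e.g. from [calibrate_harmonics()].
#' @param normalization `"none"` (default; outlines are assumed
#'   geometrically pre-normalised) or `"first-ellipse"` (apply
#'   [normalize_first_ellipse()] to every decomposition).
#' @return numeric matrix with one row per outline and `4 * H` columns.
#' @export
efa_coefficient_table <- function(outlines, H,
                                  normalization = c("none", "first-ellipse")) {
  normalization <- match.arg(normalization)
  rows <- t(vapply(outlines, function(o) {
    e <- efa_decompose(o, H)
    if (normalization == "first-ellipse") e <- normalize_first_ellipse(e)
    as.vector(t(e$harmonics))
  }, numeric(4L * H)))
  colnames(rows) <- paste0(rep(c("a", "b", "c", "d"), H),
                           rep(seq_len(H), each = 4L))
  if (!is.null(names(outlines))) rownames(rows) <- names(outlines)
  rows
}
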