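#' Closed outline objects
#'
#' An `outline` is an ordered, closed loop of 2-D vertices describing a jaw
#' silhouette boundary in mathematical (y-up) coordinates.  The closing edge
#' from the last vertex back to the first is implicit; the first vertex is not
#' repeated.  On construction the loop is validated (at least 3 vertices, no
#' two consecutive identical vertices) and, unless `keep_orientation = TRUE`,
#' normalised to counter-clockwise vertex order so that the shoelace signed
#' area is positive.
#'
#' @param xy two-column numeric matrix (or data frame) of vertices.
#' @param view `"lateral"` or `"occlusal"`.
#' @param specimen_id optional identifier.
#' @param anterior optional index of the vertex marking the anterior tip; used
#'   by [normalize_geometry()] to resolve the 180-degree alignment ambiguity.
#' @param keep_orientation if `TRUE` the vertex order is left untouched.
#' @return an object of class `outline`: the vertex matrix with attributes
#'   `view`, `specimen_id` and (optionally) `anterior`.
#' @export
#' @examples
#' sq <- as_outline(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' outline_area(sq)
as_outline <- function(xy, view = c("lateral", "occlusal"), specimen_id = NULL,
                       anterior = NULL, keep_orientation = FALSE) {
  view <- match.arg(view)
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L || !is.numeric(xy))
    stop("outline vertices must be a two-column numeric matrix", call. = FALSE)
  if (anyNA(xy) || any(!is.finite(xy)))
    stop("outline vertices must be finite", call. = FALSE)
  if (nrow(xy) < 3L)
    stop("an outline needs at least 3 vertices", call. = FALSE)
  ## drop consecutive duplicates (incl. a repeated closing vertex)
  d <- rowSums((xy - xy[c(nrow(xy), seq_len(nrow(xy) - 1L)), ])^2)
  if (any(d == 0)) xy <- xy[d > 0, , drop = FALSE]
  if (nrow(xy) < 3L)
    stop("an outline needs at least 3 distinct vertices", call. = FALSE)
  if (!keep_orientation && shoelace_area(xy) < 0) {
    xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
    if (!is.null(anterior)) anterior <- nrow(xy) + 1L - anterior
  }
  dimnames(xy) <- list(NULL, c("x", "y"))
  structure(xy, class = "outline", view = view,
            specimen_id = specimen_id, anterior = anterior)
}

#' @export
print.outline <- function(x, ...) {
  cat(sprintf("<outline> %s, %d vertices, area %.4g%s\n",
              attr(x, "view"), nrow(x), outline_area(x),
              if (is.null(attr(x, "specimen_id"))) ""
              else paste0(", specimen ", attr(x, "specimen_id"))))
  invisible(x)
}

restore_outline <- function(xy, template, anterior = NULL, keep_orientation = TRUE) {
  as_outline(xy, view = attr(template, "view"),
             specimen_id = attr(template, "specimen_id"),
             anterior = anterior, keep_orientation = keep_orientation)
}

shoelace_area <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1L)
  sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]) / 2
}

#' Signed (shoelace) area and perimeter of a closed outline
#'
#' Counter-clockwise outlines have positive area.
#'
#' @param outline an [as_outline()] object (any two-column matrix works).
#' @return a single numeric value.
#' @export
outline_area <- function(outline) shoelace_area(as.matrix(outline))

#' @rdname outline_area
#' @export
outline_perimeter <- function(outline) {
  xy <- as.matrix(outline)
  sum(sqrt(rowSums((xy[c(2:nrow(xy), 1L), ] - xy)^2)))
}

#' Resample a closed outline to equally spaced vertices
#'
#' Places `k` vertices at equal arc-length intervals along the closed
#' piecewise-linear outline, keeping the original start vertex as the first
#' point.  The standard point counts in this package are 660 for jaws in
#' lateral view and 500 for jaw rami in occlusal view.
#'
#' @param outline an [as_outline()] object.
#' @param k number of output vertices (>= 3).
#' @return a resampled `outline`.
#' @export
resample_closed <- function(outline, k) {
  xy <- as.matrix(outline)
  if (k < 3L) stop("k must be at least 3", call. = FALSE)
  closed <- rbind(xy, xy[1L, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  total <- sum(seg)
  if (total <= 0) stop("degenerate outline with zero perimeter", call. = FALSE)
  s <- c(0, cumsum(seg))
  target <- total * (seq_len(k) - 1L) / k
  new <- cbind(approx(s, closed[, 1], xout = target)$y,
               approx(s, closed[, 2], xout = target)$y)
  restore_outline(new, outline, anterior = 1L)
}

#' Centre, scale and align an outline
#'
#' Removes position, size and orientation: the vertex centroid is translated
#' to the origin, the configuration is scaled to unit centroid size (root mean
#' square vertex distance from the centroid), and the major principal axis of
#' the vertex covariance is rotated onto the x-axis.  The remaining
#' 180-degree ambiguity is resolved by the stored anterior-tip hint if
#' present (anterior end towards positive x), otherwise by placing the longer
#' extent from the centroid on the positive x side.  Only proper rotations are
#' used, so counter-clockwise orientation is preserved.
#'
#' @param outline an [as_outline()] object with at least 3 vertices.
#' @return the normalised `outline`.
#' @export
normalize_geometry <- function(outline) {
  xy <- as.matrix(outline)
  if (nrow(xy) < 3L) stop("need at least 3 vertices", call. = FALSE)
  ctr <- colMeans(xy)
  xy <- sweep(xy, 2, ctr)
  size <- sqrt(mean(rowSums(xy^2)))
  if (size <= 0) stop("degenerate outline: all vertices identical", call. = FALSE)
  xy <- xy / size
  eg <- eigen(cov(xy), symmetric = TRUE)
  v <- eg$vectors[, 1]            # major axis
  R <- rbind(c(v[1], v[2]), c(-v[2], v[1]))   # proper rotation sending v -> e1
  xy <- xy %*% t(R)
  ant <- attr(outline, "anterior")
  ext <- max(xy[, 1]) + min(xy[, 1])   # extent imbalance along +x
  flip <- if (!is.null(ant)) xy[ant, 1] < 0
          else if (abs(ext) > 1e-9) ext < 0
          else xy[1, 1] < 0            # symmetric shape: stabilise on vertex 1
  if (flip) xy <- -xy             # 180-degree rotation
  restore_outline(xy, outline, anterior = ant)
}

#' Mirror an outline across the vertical axis
#'
#' Negates x-coordinates and reverses the vertex order, so that
#' counter-clockwise orientation is preserved.  Used to convert right
#' hemimandibles to left-lateral standard view.
#'
#' @param outline an [as_outline()] object.
#' @return the mirrored `outline`.
#' @export
mirror_outline <- function(outline) {
  xy <- as.matrix(outline)
  n <- nrow(xy)
  xy[, 1] <- -xy[, 1]
  rev_i <- rev(seq_len(n))
  xy <- xy[rev_i, , drop = FALSE]
  ant <- attr(outline, "anterior")
  if (!is.null(ant)) ant <- n + 1L - ant
  restore_outline(xy, outline, anterior = ant)
}

#' Rotate the starting vertex of an outline
#'
#' Fixes the elliptical-Fourier starting-point ambiguity by rotating the
#' vertex sequence so that it begins at the vertex with maximal x (the
#' anterior tip once the outline is aligned), or at a supplied index.
#'
#' @param outline an [as_outline()] object.
#' @param start index of the desired first vertex; defaults to the vertex
#'   with the largest x-coordinate.
#' @return the outline with rotated vertex order.
#' @export
rotate_start <- function(outline, start = NULL) {
  xy <- as.matrix(outline)
  n <- nrow(xy)
  if (is.null(start)) start <- which.max(xy[, 1])
  idx <- c(start:n, seq_len(start - 1L))[seq_len(n)]
  ant <- attr(outline, "anterior")
  if (!is.null(ant)) ant <- ((ant - start) %% n) + 1L
  restore_outline(xy[idx, , drop = FALSE], outline, anterior = ant)
}

#' Split an occlusal jaw arch at the symphysis
#'
#' Cuts a closed outline with the vertical line `x = split_axis_x` (the
#' symphysis position, supplied per specimen) and returns the closed
#' sub-outline of one jaw ramus, re-closed along the cut.  The outline must
#' cross the split line exactly twice.
#'
#' @param outline an [as_outline()] object.
#' @param split_axis_x x-position of the cut.
#' @param side which side to keep: `"left"` (x <= split, default) or
#'   `"right"`.
#' @return the ramus `outline`.
#' @export
split_ramus <- function(outline, split_axis_x, side = c("left", "right")) {
  side <- match.arg(side)
  xy <- as.matrix(outline)
  n <- nrow(xy)
  j <- c(2:n, 1L)
  x0 <- xy[, 1] - split_axis_x
  ## a vertex exactly on the line is treated as infinitesimally right of it
  x0[x0 == 0] <- .Machine$double.eps * max(1, abs(split_axis_x))
  x1 <- x0[j]
  crossing <- which(x0 * x1 < 0)   # strict sign change on the edge i -> j(i)
  if (length(crossing) != 2L)
    stop(sprintf("split line x = %g intersects the outline %d times (need exactly 2)",
                 split_axis_x, length(crossing)), call. = FALSE)
  cut_pt <- function(i) {
    t <- x0[i] / (x0[i] - x1[i])
    xy[i, ] + t * (xy[j[i], ] - xy[i, ])
  }
  p1 <- cut_pt(crossing[1]); p2 <- cut_pt(crossing[2])
  ## chains of original vertices between the two crossing edges
  chain_a <- (crossing[1] + 1L):crossing[2]
  chain_b <- c(if (crossing[2] < n) (crossing[2] + 1L):n else integer(),
               1:crossing[1])
  poly_a <- rbind(p1, xy[chain_a, , drop = FALSE], p2)
  poly_b <- rbind(p2, xy[chain_b, , drop = FALSE], p1)
  chain_a_left <- x0[chain_a[1]] < 0
  want_left <- side == "left"
  pick <- if (chain_a_left == want_left) poly_a else poly_b
  restore_outline(pick, outline, keep_orientation = FALSE)
}

#' Read and write outline text files
#'
#' Outline files are plain text with two whitespace-separated columns, x and
#' y, one vertex per line; the first vertex is not repeated at the end.
#'
#' @param path file path.
#' @param outline an [as_outline()] object (for writing).
#' @param ... passed to [as_outline()] (e.g. `view`, `specimen_id`).
#' @return `read_outline()` returns an `outline`; `write_outline()` returns
#'   `path` invisibly.
#' @export
read_outline <- function(path, ...) {
  xy <- as.matrix(read.table(path, col.names = c("x", "y")))
  as_outline(xy, ...)
}

#' @rdname read_outline
#' @export
write_outline <- function(outline, path) {
  xy <- as.matrix(outline)
  write.table(format(xy, trim = TRUE, digits = 12), path,
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
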