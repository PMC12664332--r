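#' Read a binary silhouette image
#'
#' Reads a PNG or TIFF raster and returns a logical foreground mask.  Colour
#' images are converted to luminance (0.2126 R + 0.7152 G + 0.0722 B); pixels
#' darker than the threshold are foreground (black silhouette on white paper)
#' unless `invert = TRUE`.
#'
#' @param path image file (`.png`, `.tif`/`.tiff`).
#' @param threshold luminance threshold in \[0, 1\]; default 0.5.
#' @param invert if `TRUE`, bright pixels are foreground.
#' @return a logical matrix (rows = image rows, top row first).
#' @export
read_silhouette <- function(path, threshold = 0.5, invert = FALSE) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    img <- if (nc >= 3L)
      0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    else img[, , 1]
  }
  fg <- if (invert) img >= threshold else img < threshold
  storage.mode(fg) <- "logical"
  fg
}

#' Trace the outline of a binary silhouette
#'
#' Extracts the boundary of the largest foreground connected component
#' (4-connectivity) as a closed counter-clockwise loop of pixel-corner
#' coordinates in mathematical y-up space: image row r (1-based, top first)
#' maps to y = height - r for the pixel centre, and each pixel occupies a
#' unit square around its centre.  The enclosed shoelace area of the traced
#' loop therefore equals the pixel count of the component.
#'
#' @param image logical or 0/1 numeric matrix, or a file path understood by
#'   [read_silhouette()].
#' @param polarity passed to [read_silhouette()] as `invert` when `image` is
#'   a path; ignored for matrices.
#' @param ... further arguments to [read_silhouette()].
#' @return an [as_outline()] object.
#' @export
extract_outline <- function(image, polarity = FALSE, ...) {
  if (is.character(image))
    image <- read_silhouette(image, invert = polarity, ...)
  mask <- image > 0
  if (!any(mask)) stop("blank image: no foreground pixels", call. = FALSE)
  if (any(mask[1, ]) || any(mask[nrow(mask), ]) ||
      any(mask[, 1]) || any(mask[, ncol(mask)]))
    warning("foreground touches the image border; trace proceeds", call. = FALSE)
  lab <- EBImage::bwlabel(mask * 1L)
  tab <- tabulate(lab[lab > 0])
  mask <- lab == which.max(tab)
  trace_mask(mask)
}

## boundary tracing on the pixel-edge grid. Directed boundary edges carry the
## component interior on their left; chaining them with a left-most-turn rule
## yields one CCW loop per outer boundary (holes give CW loops, discarded by
## taking the largest |area| loop).
trace_mask <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  idx <- which(mask, arr.ind = TRUE)
  r <- idx[, 1]; c <- idx[, 2]
  nbr <- function(dr, dc) !pad[cbind(r + 1L + dr, c + 1L + dc)]
  ## pixel (r, c): x in [c-1, c], y in [H-r, H-r+1]
  xlo <- c - 1; xhi <- c; ylo <- H - r; yhi <- H - r + 1
  edges <- rbind(
    ## bottom neighbour background: edge (xlo,ylo) -> (xhi,ylo)
    cbind(xlo, ylo, xhi, ylo)[nbr(1L, 0L), , drop = FALSE],
    ## top: (xhi,yhi) -> (xlo,yhi)
    cbind(xhi, yhi, xlo, yhi)[nbr(-1L, 0L), , drop = FALSE],
    ## left: (xlo,yhi) -> (xlo,ylo)
    cbind(xlo, yhi, xlo, ylo)[nbr(0L, -1L), , drop = FALSE],
    ## right: (xhi,ylo) -> (xhi,yhi)
    cbind(xhi, ylo, xhi, yhi)[nbr(0L, 1L), , drop = FALSE])
  key <- function(x, y) paste(x, y)
  from <- key(edges[, 1], edges[, 2])
  out_of <- split(seq_len(nrow(edges)), from)
  used <- rep(FALSE, nrow(edges))
  best <- NULL; best_area <- -Inf
  for (start in seq_len(nrow(edges))) {
    if (used[start]) next
    loop <- integer(0)
    e <- start
    repeat {
      used[e] <- TRUE
      loop <- c(loop, e)
      tail_key <- key(edges[e, 3], edges[e, 4])
      cand <- out_of[[tail_key]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      if (length(cand) > 1L) {
        ## left-most turn keeps 4-connected components coherent
        din <- edges[e, 3:4] - edges[e, 1:2]
        cross <- (din[1] * (edges[cand, 4] - edges[cand, 2]) -
                  din[2] * (edges[cand, 3] - edges[cand, 1]))
        cand <- cand[which.max(cross)]
      } else cand <- cand[1]
      e <- cand
    }
    verts <- edges[loop, 1:2, drop = FALSE]
    a <- shoelace_area(verts)
    if (a > best_area) { best_area <- a; best <- verts }
  }
  as_outline(best)
}
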