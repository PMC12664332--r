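#' Jaw landmark sets
#'
#' A `jaw_landmarks` object holds the named 2-D points from which the nine
#' functional traits are computed: `joint` (jaw articulation, the lever
#' fulcrum), `anterior_tip`, `insertion` (adductor in-lever point; optional,
#' defaults to the adductor fossa midpoint), `opening_insertion` (jaw-opening
#' in-lever point, e.g. the retroarticular extremity), `toothrow_anterior`,
#' `toothrow_posterior`, `fossa_anterior`, `fossa_posterior` and
#' `symphysis_posterior`.
#'
#' @param ... named length-2 numeric vectors, or a single named list of them.
#' @return an object of class `jaw_landmarks` (named list of points).
#' @export
jaw_landmarks <- function(...) {
  pts <- list(...)
  if (length(pts) == 1L && is.list(pts[[1]]) && is.null(names(pts)[1]))
    pts <- pts[[1]]
  required <- c("joint", "anterior_tip", "opening_insertion",
                "toothrow_anterior", "toothrow_posterior",
                "fossa_anterior", "fossa_posterior", "symphysis_posterior")
  missing <- setdiff(required, names(pts))
  if (length(missing))
    stop("missing landmarks: ", paste(missing, collapse = ", "), call. = FALSE)
  pts <- lapply(pts, function(p) {
    p <- as.numeric(p)
    if (length(p) != 2L || any(!is.finite(p)))
      stop("each landmark must be a finite 2-D point", call. = FALSE)
    p
  })
  if (identical(pts$joint, pts$anterior_tip))
    stop("joint and anterior_tip must differ", call. = FALSE)
  if (identical(pts$toothrow_anterior, pts$toothrow_posterior))
    stop("tooth-row landmarks must differ", call. = FALSE)
  structure(pts, class = "jaw_landmarks")
}

dist2d <- function(p, q) sqrt(sum((p - q)^2))

#' Lever-arm ratio
#'
#' Mechanical advantage of a simple lever: the ratio of the in-lever
#' (fulcrum to effort-insertion distance) to the out-lever (fulcrum to
#' output-point distance).  For the jaw, the fulcrum is the articulation and
#' the out-point a bite position.
#'
#' @param fulcrum,in_point,out_point 2-D points.
#' @return the ratio |fulcrum-in| / |fulcrum-out|.
#' @export
lever_ratio <- function(fulcrum, in_point, out_point) {
  out <- dist2d(fulcrum, out_point)
  if (out == 0) stop("zero out-lever: out_point equals fulcrum", call. = FALSE)
  dist2d(fulcrum, in_point) / out
}

#' Maximum and average aspect ratio from a depth profile
#'
#' A depth profile gives jaw depth d (perpendicular to the joint to
#' anterior-tip axis) at stations s in \[0, 1\] along that axis.  The maximum
#' aspect ratio is max(d) / jaw length; the average aspect ratio is the
#' trapezoidal mean of d over s divided by jaw length.
#'
#' @param profile two-column matrix or data frame (s, d) with s strictly
#'   increasing and d >= 0.
#' @param jaw_length positive jaw length in the same units as d.
#' @return named numeric vector `c(max_ar, avg_ar)`.
#' @export
aspect_ratios <- function(profile, jaw_length) {
  profile <- as.matrix(profile)
  if (nrow(profile) < 2L) stop("need at least 2 profile samples", call. = FALSE)
  if (jaw_length <= 0) stop("jaw_length must be positive", call. = FALSE)
  s <- profile[, 1]; d <- profile[, 2]
  if (any(diff(s) <= 0)) stop("profile stations must be strictly increasing",
                              call. = FALSE)
  if (any(d < 0)) stop("depths must be non-negative", call. = FALSE)
  mean_d <- sum(diff(s) * (d[-1] + d[-length(d)]) / 2) / (max(s) - min(s))
  c(max_ar = max(d) / jaw_length, avg_ar = mean_d / jaw_length)
}

#' Articular offset ratio
#'
#' Perpendicular distance from the jaw joint to the tooth-row line (through
#' the anterior and posterior tooth-row landmarks), normalised by jaw length.
#'
#' @param landmarks a [jaw_landmarks()] object.
#' @param jaw_length positive jaw length.
#' @return the offset ratio.
#' @export
articular_offset_ratio <- function(landmarks, jaw_length) {
  p <- landmarks$toothrow_anterior; q <- landmarks$toothrow_posterior
  v <- q - p
  len <- sqrt(sum(v^2))
  if (len == 0) stop("degenerate tooth-row line", call. = FALSE)
  w <- landmarks$joint - p
  abs(v[1] * w[2] - v[2] * w[1]) / len / jaw_length
}

#' Relative length of a jaw segment
#'
#' Euclidean distance between two landmarks divided by jaw length; used for
#' the relative tooth-row, adductor-fossa and symphysial lengths.
#'
#' @param p,q 2-D points.
#' @param jaw_length positive jaw length.
#' @return the ratio.
#' @export
relative_length <- function(p, q, jaw_length) {
  if (jaw_length <= 0) stop("jaw_length must be positive", call. = FALSE)
  dist2d(p, q) / jaw_length
}

#' Names of the nine functional traits, in standard order
#' @export
trait_names <- function() c("anterior_ma", "posterior_ma", "opening_ma",
                            "max_ar", "avg_ar", "articular_offset",
                            "rel_toothrow", "rel_fossa", "rel_symphysis")

#' Compute the nine functional jaw traits
#'
#' Evaluates, from a landmark set and a depth profile, the nine dimensionless
#' measurements: anterior, posterior and opening mechanical advantage,
#' maximum and average aspect ratio, articular offset, and relative tooth-row,
#' adductor-fossa and symphysial lengths.  Jaw length is the joint to
#' anterior-tip distance and is the common normaliser.  The closing in-lever
#' point is the explicit `insertion` landmark when present, otherwise the
#' midpoint of the adductor fossa (`insertion_rule = "fossa-midpoint"`).
#'
#' All traits are ratios and hence invariant under rigid motion and uniform
#' scaling of the landmark configuration.
#'
#' @param landmarks a [jaw_landmarks()] object.
#' @param profile depth profile, see [aspect_ratios()].
#' @param insertion_rule `"explicit"` (use the `insertion` landmark, falling
#'   back to the fossa midpoint when absent) or `"fossa-midpoint"`.
#' @return named numeric vector of the nine traits in [trait_names()] order.
#' @export
compute_traits <- function(landmarks, profile,
                           insertion_rule = c("explicit", "fossa-midpoint")) {
  insertion_rule <- match.arg(insertion_rule)
  lm <- landmarks
  jaw_length <- dist2d(lm$joint, lm$anterior_tip)
  insertion <- if (insertion_rule == "explicit" && !is.null(lm$insertion))
    lm$insertion else (lm$fossa_anterior + lm$fossa_posterior) / 2
  wrap <- function(trait, expr) tryCatch(expr, error = function(e)
    stop(sprintf("trait `%s`: %s", trait, conditionMessage(e)), call. = FALSE))
  ar <- wrap("aspect_ratio", aspect_ratios(profile, jaw_length))
  out <- c(
    anterior_ma = wrap("anterior_ma",
      lever_ratio(lm$joint, insertion, lm$anterior_tip)),
    posterior_ma = wrap("posterior_ma",
      lever_ratio(lm$joint, insertion, lm$toothrow_posterior)),
    opening_ma = wrap("opening_ma",
      lever_ratio(lm$joint, lm$opening_insertion, lm$anterior_tip)),
    max_ar = unname(ar["max_ar"]),
    avg_ar = unname(ar["avg_ar"]),
    articular_offset = wrap("articular_offset",
      articular_offset_ratio(lm, jaw_length)),
    rel_toothrow = wrap("rel_toothrow",
      relative_length(lm$toothrow_anterior, lm$toothrow_posterior, jaw_length)),
    rel_fossa = wrap("rel_fossa",
      relative_length(lm$fossa_anterior, lm$fossa_posterior, jaw_length)),
    rel_symphysis = wrap("rel_symphysis",
      relative_length(lm$anterior_tip, lm$symphysis_posterior, jaw_length)))
  out
}

#' Z-standardise a trait matrix
#'
#' Centres every column to mean 0 and scales it to sample standard deviation
#' 1 (n - 1 denominator), giving each trait equal weight in downstream
#' ordination.
#'
#' @param matrix numeric matrix or data frame (specimens x traits).
#' @return the standardised matrix.
#' @export
z_standardize <- function(matrix) {
  m <- as.matrix(matrix)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(m)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant trait column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  z <- sweep(m, 2, colMeans(m))
  sweep(z, 2, sds, "/")
}

#' Read a landmark CSV into jaw_landmarks objects
#'
#' The file must have columns `specimen_id`, `landmark_name`, `x`, `y`.
#'
#' @param path CSV path.
#' @return named list of [jaw_landmarks()] objects, one per specimen.
#' @export
read_landmarks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "landmark_name", "x", "y")
  if (!all(need %in% names(df)))
    stop("landmark file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(split(df, df$specimen_id), function(d)
    jaw_landmarks(setNames(lapply(seq_len(nrow(d)),
                                  function(i) c(d$x[i], d$y[i])),
                           d$landmark_name)))
}

#' @rdname read_landmarks
#' @param landmarks named list of [jaw_landmarks()] objects.
#' @export
write_landmarks <- function(landmarks, path) {
  rows <- do.call(rbind, lapply(names(landmarks), function(id) {
    lm <- landmarks[[id]]
    data.frame(specimen_id = id, landmark_name = names(lm),
               x = vapply(lm, `[`, 1, 1L), y = vapply(lm, `[`, 1, 2L))
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
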