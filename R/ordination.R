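#' Principal component analysis of a trait or coefficient matrix
#'
#' Column-centred PCA of the sample covariance (n - 1 denominator), computed
#' with [stats::prcomp()].  No per-column rescaling is applied: functional
#' trait matrices are expected to arrive Z-standardised (making the analysis
#' correlation-equivalent) and elliptical Fourier coefficient tables are
#' consumed as-is, following the outline-morphometrics convention.  Axes with
#' (numerically) zero variance are dropped, so the number of retained axes is
#' at most `min(n - 1, p)`.  A deterministic sign convention is applied: the
#' largest-magnitude entry of every loading column is positive.
#'
#' @param matrix numeric specimen-by-variable matrix; no missing values.
#' @return an object of class `jaw_pca`: list with `scores`, `eigenvalues`,
#'   `loadings`, `variance_fraction`, `center` and `n`.
#' @export
jaw_pca <- function(matrix) {
  m <- as.matrix(matrix)
  if (nrow(m) < 2L) stop("need at least 2 specimens", call. = FALSE)
  if (anyNA(m)) {
    bad <- which(!complete.cases(m))
    stop("missing values in rows: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  keep <- ev > max(ev) * 1e-12
  ev <- ev[keep]
  scores <- pc$x[, keep, drop = FALSE]
  loadings <- pc$rotation[, keep, drop = FALSE]
  ## sign convention: dominant entry of each loading column positive
  for (k in seq_along(ev)) {
    if (loadings[which.max(abs(loadings[, k])), k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  structure(list(scores = scores, eigenvalues = ev, loadings = loadings,
                 variance_fraction = ev / sum(ev),
                 center = pc$center, n = nrow(m)),
            class = "jaw_pca")
}

#' @export
print.jaw_pca <- function(x, ...) {
  cat(sprintf("<jaw_pca> %d specimens, %d axes; PC1 %.2f%%, PC1-2 %.2f%%\n",
              x$n, length(x$eigenvalues), 100 * x$variance_fraction[1],
              100 * sum(x$variance_fraction[seq_len(min(2, length(x$eigenvalues)))])))
  invisible(x)
}

#' Fraction of variance captured by selected PC axes
#'
#' @param result a [jaw_pca()] object.
#' @param axes integer vector of axis indices.
#' @return the summed variance fraction.
#' @export
variance_fraction <- function(result, axes) {
  k <- length(result$eigenvalues)
  if (any(axes < 1 | axes > k))
    stop("axis index out of range 1..", k, call. = FALSE)
  sum(result$eigenvalues[axes]) / sum(result$eigenvalues)
}

#' Sum of variances disparity metric
#'
#' Disparity of a specimen subset in morphospace: the sum over axes of the
#' sample variance (n - 1 denominator) of the subset's scores.  Equivalently
#' the mean squared Euclidean distance to the subset centroid times
#' n / (n - 1).  A single-specimen subset returns 0 with attribute
#' `degenerate = TRUE`.
#'
#' @param scores numeric score matrix (specimens x axes).
#' @param rows subset of rows (indices, names or logical); defaults to all.
#' @return non-negative numeric value.
#' @export
sum_of_variances <- function(scores, rows = NULL) {
  scores <- as.matrix(scores)
  if (!is.null(rows)) scores <- scores[rows, , drop = FALSE]
  if (nrow(scores) == 0L) stop("empty specimen subset", call. = FALSE)
  if (nrow(scores) == 1L)
    return(structure(0, degenerate = TRUE))
  sum(apply(scores, 2, var))
}

#' Bootstrap distribution of the sum-of-variances metric
#'
#' Resamples the subset's specimens with replacement `n_boot` times,
#' recomputing the sum of variances each time, and summarises the bootstrap
#' distribution by its median and an equal-tailed confidence interval.
#'
#' @param scores score matrix.
#' @param rows specimen subset (default all).
#' @param n_boot number of bootstrap replicates.
#' @param seed RNG seed (the caller's RNG state is untouched).
#' @param ci confidence level, default 0.95.
#' @return list with `observed`, `median`, `ci` (length-2), `level`,
#'   `n_boot` and the replicate vector `boot`.
#' @export
bootstrap_disparity <- function(scores, rows = NULL, n_boot = 1000L,
                                seed = 1L, ci = 0.95) {
  if (n_boot < 1L) stop("n_boot must be at least 1", call. = FALSE)
  scores <- as.matrix(scores)
  if (!is.null(rows)) scores <- scores[rows, , drop = FALSE]
  n <- nrow(scores)
  if (n == 0L) stop("empty specimen subset", call. = FALSE)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i)
      as.numeric(sum_of_variances(scores[sample.int(n, n, replace = TRUE), ,
                                         drop = FALSE])),
      numeric(1))
  })
  alpha <- (1 - ci) / 2
  list(observed = as.numeric(sum_of_variances(scores)),
       median = median(boot),
       ci = unname(quantile(boot, c(alpha, 1 - alpha))),
       level = ci, n_boot = n_boot, boot = boot)
}

#' Foote partial disparity
#'
#' Partitions total disparity across groups: for group g,
#' PD_g = sum over its specimens of the squared Euclidean distance to the
#' grand centroid, divided by (N - 1), N the total specimen count.  The
#' group values sum exactly to the total sum of variances.  With
#' `squared = FALSE` the unsquared distances are used instead (a variant
#' sometimes described verbally in the disparity literature); that form is
#' not additive and is provided for sensitivity checks only.
#'
#' @param scores score matrix.
#' @param labels per-row group labels.
#' @param squared use squared distances (default, the additive Foote form).
#' @return data frame with columns `group`, `n`, `partial_disparity`,
#'   `fraction`.
#' @export
partial_disparity <- function(scores, labels, squared = TRUE) {
  scores <- as.matrix(scores)
  if (nrow(scores) == 0L) stop("empty input", call. = FALSE)
  if (length(labels) != nrow(scores))
    stop("labels must match score rows", call. = FALSE)
  ctr <- colMeans(scores)
  d2 <- rowSums(sweep(scores, 2, ctr)^2)
  if (!squared) d2 <- sqrt(d2)
  N <- nrow(scores)
  pd <- tapply(d2, labels, sum) / max(N - 1, 1)
  total <- sum(pd)
  data.frame(group = names(pd),
             n = as.integer(table(labels)[names(pd)]),
             partial_disparity = as.numeric(pd),
             fraction = if (total > 0) as.numeric(pd) / total
                        else rep(NA_real_, length(pd)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Disparity through time
#'
#' For every time bin, computes the specimen count, the sum of variances of
#' the bin's specimens across all supplied axes, a bootstrap summary, and
#' the per-group Foote partial disparity within the bin (grand centroid =
#' bin centroid).  Bins with fewer than 2 specimens are flagged degenerate
#' and report zero disparity.
#'
#' @param scores score matrix with rownames matching the membership matrix.
#' @param membership logical taxa-by-bins matrix from [assign_bins()].
#' @param groups per-specimen group labels (same order as `scores` rows).
#' @param n_boot bootstrap replicates per bin.
#' @param seed RNG seed.
#' @param ci confidence level.
#' @return a `disparity_series` data frame: one row per bin with columns
#'   `bin`, `n`, `sum_of_variances`, `boot_median`, `ci_low`, `ci_high`,
#'   `degenerate`, one `PD_<group>` and one `n_<group>` column per group;
#'   the bootstrap vectors are attached as attribute `boot`.
#' @export
disparity_through_time <- function(scores, membership, groups,
                                   n_boot = 1000L, seed = 1L, ci = 0.95) {
  scores <- as.matrix(scores)
  if (nrow(scores) != nrow(membership))
    stop("scores and membership must have the same rows", call. = FALSE)
  if (!is.null(rownames(scores)) && !is.null(rownames(membership)) &&
      !identical(rownames(scores), rownames(membership)))
    stop("scores and membership row names disagree", call. = FALSE)
  lv <- sort(unique(groups))
  boots <- list()
  rows <- lapply(seq_len(ncol(membership)), function(b) {
    idx <- which(membership[, b])
    n <- length(idx)
    degen <- n < 2L
    sov <- if (degen) 0 else as.numeric(sum_of_variances(scores, idx))
    bs <- if (degen) list(median = 0, ci = c(0, 0), boot = numeric(0))
      else bootstrap_disparity(scores, idx, n_boot = n_boot,
                               seed = seed + b, ci = ci)
    boots[[b]] <<- bs$boot
    pd <- if (degen) NULL else partial_disparity(scores[idx, , drop = FALSE],
                                                 groups[idx])
    pdv <- setNames(rep(0, length(lv)), lv)
    pdn <- setNames(rep(0L, length(lv)), lv)
    if (!is.null(pd)) {
      pdv[pd$group] <- pd$partial_disparity
      pdn[pd$group] <- pd$n
    } else if (n == 1L) pdn[groups[idx]] <- 1L
    c(list(bin = colnames(membership)[b], n = n, sum_of_variances = sov,
           boot_median = bs$median, ci_low = bs$ci[1], ci_high = bs$ci[2],
           degenerate = degen),
      setNames(as.list(pdv), paste0("PD_", lv)),
      setNames(as.list(pdn), paste0("n_", lv)))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  attr(out, "boot") <- setNames(boots, colnames(membership))
  class(out) <- c("disparity_series", class(out))
  out
}

#' Relabel clades under alternative amniote definitions
#'
#' Implements the four phylogenetic hypotheses as metadata relabelings:
#' H1 leaves the baseline labels unchanged; H2 moves diadectomorphs into
#' Synapsida; H3 moves captorhinids, araeoscelidians and protorothyridids
#' out of Amniota; H4 moves recumbirostran microsaurs into Sauropsida.  A
#' derived logical column `amniote` (`clade != "nonamniote"`) is appended.
#'
#' @param metadata specimen table with `clade` and the subclade flag
#'   columns.
#' @param hypothesis one of `"H1"`, `"H2"`, `"H3"`, `"H4"`.
#' @return the relabelled table (same row count and order).
#' @export
apply_hypothesis <- function(metadata, hypothesis = c("H1", "H2", "H3", "H4")) {
  hypothesis <- match.arg(hypothesis)
  out <- metadata
  out$clade <- switch(hypothesis,
    H1 = out$clade,
    H2 = ifelse(out$is_diadectomorph, "synapsid", out$clade),
    H3 = ifelse(out$is_captorhinid_araeoscelidian_protorothyridid,
                "nonamniote", out$clade),
    H4 = ifelse(out$is_recumbirostran, "sauropsid", out$clade))
  out$amniote <- out$clade != "nonamniote"
  out
}
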