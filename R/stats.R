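#' Pairwise t-tests with Bonferroni correction
#'
#' Two-sided t-tests for every pair of groups.  With the default
#' `pooling = "all-groups"` a common error variance is estimated across all
#' groups (the residual mean square of the one-way layout, df = N - g), the
#' behaviour of the classical pairwise-comparison routine; with
#' `pooling = "pairwise"` each pair uses its own pooled two-sample variance
#' (df = n_i + n_j - 2).  Bonferroni adjustment multiplies each p-value by
#' the number of pairs, capped at 1.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, at least 2 groups with >= 2 observations each.
#' @param adjustment `"bonferroni"` (default) or `"none"`.
#' @param pooling `"all-groups"` (default) or `"pairwise"`.
#' @return data frame with one row per pair: `group1`, `group2`,
#'   `statistic`, `df`, `p_raw`, `p_value` (adjusted), `method`.
#' @export
pairwise_t_tests <- function(values, groups,
                             adjustment = c("bonferroni", "none"),
                             pooling = c("all-groups", "pairwise")) {
  adjustment <- match.arg(adjustment)
  pooling <- match.arg(pooling)
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2L))
    stop("each group needs at least 2 observations: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  lv <- names(sizes)
  means <- tapply(values, groups, mean)
  ss <- tapply(values, groups, function(x) sum((x - mean(x))^2))
  N <- length(values); g <- length(lv)
  mse_all <- sum(ss) / (N - g)
  pairs <- combn(lv, 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    ni <- sizes[[i]]; nj <- sizes[[j]]
    if (pooling == "all-groups") {
      s2 <- mse_all; df <- N - g
    } else {
      s2 <- (ss[[i]] + ss[[j]]) / (ni + nj - 2); df <- ni + nj - 2
    }
    se <- sqrt(s2 * (1 / ni + 1 / nj))
    t <- if (se == 0) 0 else (means[[i]] - means[[j]]) / se
    p <- if (se == 0) 1 else 2 * pt(-abs(t), df)
    c(statistic = t, df = df, p_raw = p)
  })
  n_pairs <- ncol(pairs)
  p_adj <- if (adjustment == "bonferroni")
    pmin(1, res["p_raw", ] * n_pairs) else res["p_raw", ]
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             statistic = res["statistic", ], df = res["df", ],
             p_raw = res["p_raw", ], p_value = p_adj,
             method = paste0("t-test (", pooling, " pooling, ",
                             adjustment, ")"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Levene / Brown--Forsythe test for homogeneity of variance
#'
#' One-way ANOVA F-test on the absolute deviations of each observation from
#' its group centre.  The default centre is the group median (the
#' Brown--Forsythe variant, robust to non-normality); `center = "mean"`
#' gives the classical Levene test.
#'
#' @param values numeric observations.
#' @param groups group labels (>= 2 groups with >= 2 observations).
#' @param center `"median"` (default) or `"mean"`.
#' @return list of class `jaw_test`: `statistic` (F), `p_value`, `df`
#'   (numerator, denominator), `method`.
#' @export
levene_test <- function(values, groups, center = c("median", "mean")) {
  center <- match.arg(center)
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 2L || any(sizes < 2L))
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  fc <- if (center == "median") median else mean
  centres <- tapply(values, groups, fc)
  dev <- abs(values - centres[groups])
  N <- length(dev); g <- length(sizes)
  gm <- mean(dev)
  group_means <- tapply(dev, groups, mean)
  ssb <- sum(sizes * (group_means - gm)^2)
  ssw <- sum((dev - group_means[groups])^2)
  df1 <- g - 1; df2 <- N - g
  f <- if (ssw == 0) {
    if (ssb == 0) 0 else Inf
  } else (ssb / df1) / (ssw / df2)
  p <- if (is.infinite(f)) 0 else pf(f, df1, df2, lower.tail = FALSE)
  structure(list(statistic = unname(f), p_value = unname(p),
                 df = c(df1, df2),
                 method = paste0("Levene (", center, "-centred)")),
            class = "jaw_test")
}

#' @export
print.jaw_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g\n", x$method, x$statistic,
              x$p_value))
  invisible(x)
}

permanova_F <- function(coords, groups) {
  ctr <- colMeans(coords)
  sst <- sum(sweep(coords, 2, ctr)^2)
  ssw <- 0
  for (lv in unique(groups)) {
    sub <- coords[groups == lv, , drop = FALSE]
    ssw <- ssw + sum(sweep(sub, 2, colMeans(sub))^2)
  }
  g <- length(unique(groups)); N <- nrow(coords)
  ssb <- sst - ssw
  (ssb / (g - 1)) / (ssw / (N - g))
}

#' Permutation MANOVA on morphospace coordinates
#'
#' Tests centroid separation between groups on all supplied axes using the
#' Euclidean pseudo-F statistic,
#' F = (SS_between / (g - 1)) / (SS_within / (N - g)), with a permutation
#' p-value obtained by shuffling group labels:
#' p = (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations).  With
#' `exhaustive = TRUE` (only feasible for small N) every distinct label
#' arrangement is enumerated and p is the exact proportion with
#' F >= F_obs, the identity arrangement included.
#'
#' @param coordinates specimen-by-axis matrix.
#' @param groups group labels (all groups non-empty).
#' @param n_permutations number of random permutations (default 999).
#' @param seed RNG seed.
#' @param exhaustive enumerate all label arrangements instead of sampling.
#' @return a `jaw_test` list: `statistic` (pseudo-F), `p_value`, `df`,
#'   `n_permutations`, `method`.
#' @export
permanova <- function(coordinates, groups, n_permutations = 999L, seed = 1L,
                      exhaustive = FALSE) {
  coords <- as.matrix(coordinates)
  groups <- as.character(groups)
  if (any(table(groups) == 0L) || length(unique(groups)) < 2L)
    stop("need at least 2 non-empty groups", call. = FALSE)
  if (nrow(coords) != length(groups))
    stop("coordinates and groups must match", call. = FALSE)
  f_obs <- permanova_F(coords, groups)
  N <- nrow(coords); g <- length(unique(groups))
  if (exhaustive) {
    perms <- all_label_arrangements(groups)
    f_perm <- vapply(perms, function(gp) permanova_F(coords, gp), numeric(1))
    p <- mean(f_perm >= f_obs - 1e-12)
    n_used <- length(perms)
  } else {
    f_perm <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(i)
        permanova_F(coords, sample(groups)), numeric(1))
    })
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_permutations)
    n_used <- n_permutations
  }
  structure(list(statistic = f_obs, p_value = p,
                 df = c(g - 1, N - g), n_permutations = n_used,
                 method = if (exhaustive) "PERMANOVA (exhaustive)"
                          else "PERMANOVA"),
            class = "jaw_test")
}

## all distinct assignments of the multiset of labels to positions
all_label_arrangements <- function(groups) {
  lv <- unique(groups)
  if (length(lv) == 2L) {
    n <- length(groups)
    k <- sum(groups == lv[1])
    combn(n, k, function(idx) {
      g <- rep(lv[2], n); g[idx] <- lv[1]; g
    }, simplify = FALSE)
  } else {
    perms <- unique(perm_all(groups))
    perms
  }
}

perm_all <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(perm_all(x[-i]), function(r) c(x[i], r)))
  out
}

#' Rank-sum comparison of two samples
#'
#' The Wilcoxon--Mann--Whitney statistic W counts the pairs (a, b) with
#' a > b, ties counted one half.  The p-value is exact (enumeration over the
#' null rank distribution) when both samples have at most 10 untied
#' observations, otherwise a normal approximation with tie correction and
#' continuity correction is used.  In this package the typical inputs are
#' two bootstrap disparity distributions, so W is of order n_boot squared.
#'
#' @param sample_a,sample_b numeric vectors.
#' @return a `jaw_test` list: `statistic` (W), `p_value`, `n`, `method`.
#' @export
rank_sum <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b))
    stop("both samples must be non-empty", call. = FALSE)
  m <- length(sample_a); n <- length(sample_b)
  r <- rank(c(sample_a, sample_b))
  W <- sum(r[seq_len(m)]) - m * (m + 1) / 2   # pairs a > b, ties 1/2
  ties <- any(duplicated(c(sample_a, sample_b)))
  if (m <= 10 && n <= 10 && !ties) {
    p <- min(1, 2 * min(pwilcox(W, m, n), 1 - pwilcox(W - 1, m, n)))
    method <- "rank sum (exact)"
  } else {
    mu <- m * n / 2
    tie_tab <- table(r)
    Nt <- m + n
    sigma2 <- m * n / 12 *
      ((Nt + 1) - sum(tie_tab^3 - tie_tab) / (Nt * (Nt - 1)))
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- if (sigma2 == 0) 1 else min(1, 2 * pnorm(-abs(z)))
    method <- "rank sum (normal approximation, tie-corrected)"
  }
  structure(list(statistic = unname(W), p_value = p, n = c(m, n),
                 method = method),
            class = "jaw_test")
}

#' Ordinary least-squares R-squared between two traits
#'
#' Simple linear regression of y on x: returns the coefficient of
#' determination and the two-sided p-value of the slope test.
#'
#' @param x,y numeric vectors of equal length (>= 3, x not constant).
#' @return list with `r_squared` and `p_value`.
#' @export
linear_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need >= 3 paired points", call. = FALSE)
  if (sd(x) == 0) stop("x is constant", call. = FALSE)
  fit <- summary(lm(y ~ x))
  list(r_squared = unname(fit$r.squared),
       p_value = unname(fit$coefficients["x", "Pr(>|t|)"]))
}
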