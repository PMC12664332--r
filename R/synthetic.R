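#' Simulation configuration for the synthetic jaw dataset
#'
#' Bundles and validates the parameters of the synthetic-data generator.  The
#' defaults emulate the composition of the empirical Carboniferous--Permian
#' jaw dataset this package is designed around: 202 taxa, clade proportions
#' 85 : 83 : 34 (non-amniote tetrapods : synapsids : sauropsids), 56/202
#' herbivores, ages spanning the Visean--Changhsingian (346.7--251.9 Ma), and
#' group-structured functional traits in which amniotes show shifted means on
#' opening mechanical advantage, aspect ratios, articular offset and
#' symphysial length, and inflated variance on five of the nine traits.
#'
#' @param n_taxa number of taxa to simulate.
#' @param clade_proportions three non-negative weights (nonamniote, synapsid,
#'   sauropsid) summing to 1.
#' @param herbivore_fraction probability that a taxon is herbivorous.
#' @param age_window ages in Ma as `c(older, younger)`, older > younger.
#' @param trait_group metadata column defining the trait groups:
#'   `"amniote"`, `"diet"` or `"clade"`.
#' @param trait_means group x 9 matrix of trait means (rownames = group
#'   levels, colnames = [trait_names()]).
#' @param trait_sds matrix of positive standard deviations, same shape.
#' @param variance_multipliers matrix of positive per-group, per-trait
#'   variance inflation factors (multiply the variance, i.e. sd is scaled by
#'   their square root), same shape.
#' @param view_probs probabilities that a taxon has a usable lateral, medial
#'   and occlusal figure.
#' @param subclade_probs probabilities of the three hypothesis-relevant
#'   subclade flags (diadectomorph and recumbirostran among non-amniotes;
#'   captorhinid/araeoscelidian/protorothyridid among sauropsids).
#' @param seed integer RNG seed.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 202L,
                       clade_proportions = c(nonamniote = 85, synapsid = 83,
                                             sauropsid = 34) / 202,
                       herbivore_fraction = 56 / 202,
                       age_window = c(older = 346.7, younger = 251.9),
                       trait_group = c("amniote", "diet", "clade"),
                       trait_means = NULL, trait_sds = NULL,
                       variance_multipliers = NULL,
                       view_probs = c(lateral = 198, medial = 111,
                                      occlusal = 73) / 202,
                       subclade_probs = c(diadectomorph = 7 / 85,
                                          captorhinid = 15 / 34,
                                          recumbirostran = 10 / 85),
                       seed = 1L) {
  trait_group <- match.arg(trait_group)
  groups <- switch(trait_group,
                   amniote = c("amniote", "nonamniote"),
                   diet = c("herbivore", "nonherbivore"),
                   clade = c("nonamniote", "synapsid", "sauropsid"))
  if (is.null(trait_means)) trait_means <- default_trait_means(trait_group)
  if (is.null(trait_sds)) trait_sds <- default_trait_sds(trait_means)
  if (is.null(variance_multipliers))
    variance_multipliers <- default_variance_multipliers(trait_means)
  cfg <- list(n_taxa = n_taxa, clade_proportions = clade_proportions,
              herbivore_fraction = herbivore_fraction,
              age_window = age_window, trait_group = trait_group,
              trait_means = as.matrix(trait_means),
              trait_sds = as.matrix(trait_sds),
              variance_multipliers = as.matrix(variance_multipliers),
              view_probs = view_probs, subclade_probs = subclade_probs,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (length(cfg$n_taxa) != 1L || is.na(cfg$n_taxa) || cfg$n_taxa < 1)
    stop_field("n_taxa", "must be a positive integer")
  p <- cfg$clade_proportions
  if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-12)
    stop_field("clade_proportions", "must be 3 non-negative weights summing to 1")
  if (cfg$herbivore_fraction < 0 || cfg$herbivore_fraction > 1)
    stop_field("herbivore_fraction", "must be a probability in [0, 1]")
  aw <- cfg$age_window
  if (length(aw) != 2L || aw[1] <= aw[2])
    stop_field("age_window", "must be c(older, younger) with older > younger")
  for (nm in c("trait_means", "trait_sds", "variance_multipliers")) {
    m <- cfg[[nm]]
    if (ncol(m) != 9L) stop_field(nm, "must have 9 trait columns")
  }
  if (any(cfg$trait_sds <= 0)) stop_field("trait_sds", "must all be positive")
  if (any(cfg$variance_multipliers <= 0))
    stop_field("variance_multipliers", "must all be positive")
  if (!identical(dim(cfg$trait_means), dim(cfg$trait_sds)) ||
      !identical(dim(cfg$trait_means), dim(cfg$variance_multipliers)))
    stop_field("trait_sds", "means, sds and multipliers must share dimensions")
  invisible(cfg)
}

default_trait_means <- function(trait_group) {
  base <- c(anterior_ma = 0.20, posterior_ma = 0.35, opening_ma = 0.06,
            max_ar = 0.22, avg_ar = 0.13, articular_offset = 0.08,
            rel_toothrow = 0.50, rel_fossa = 0.22, rel_symphysis = 0.07)
  hi <- c(anterior_ma = 0.22, posterior_ma = 0.40, opening_ma = 0.10,
          max_ar = 0.28, avg_ar = 0.17, articular_offset = 0.13,
          rel_toothrow = 0.43, rel_fossa = 0.20, rel_symphysis = 0.12)
  m <- switch(trait_group,
    amniote = rbind(amniote = hi, nonamniote = base),
    diet = rbind(herbivore = hi, nonherbivore = base),
    clade = rbind(nonamniote = base, synapsid = hi,
                  sauropsid = (base + hi) / 2))
  m
}

default_trait_sds <- function(trait_means) {
  s <- c(0.04, 0.08, 0.02, 0.05, 0.03, 0.04, 0.08, 0.06, 0.03)
  matrix(s, nrow = nrow(trait_means), ncol = 9L, byrow = TRUE,
         dimnames = dimnames(trait_means))
}

default_variance_multipliers <- function(trait_means) {
  m <- matrix(1, nrow = nrow(trait_means), ncol = 9L,
              dimnames = dimnames(trait_means))
  ## amniotes/herbivores show greater spread on five of the nine traits
  inflate <- c("anterior_ma", "posterior_ma", "articular_offset",
               "rel_fossa", "rel_symphysis")
  first <- rownames(m)[1]
  if (first %in% c("amniote", "herbivore"))
    m[first, inflate] <- 1.8
  m
}

#' Generate a synthetic specimen metadata table
#'
#' Draws taxa with clade and diet labels, hypothesis-relevant subclade flags,
#' stratigraphic ranges (FAD >= LAD, first-appearance uniform in the age
#' window, range duration uniform on \[0, window span / 3\], truncated at the
#' younger window edge) and per-view availability flags.  Deterministic for a
#' given configuration seed.
#'
#' @param config a [sim_config()] object.
#' @return a data frame with one row per taxon and the columns `taxon_id`,
#'   `clade`, `is_diadectomorph`,
#'   `is_captorhinid_araeoscelidian_protorothyridid`, `is_recumbirostran`,
#'   `diet`, `fad_ma`, `lad_ma`, `has_lateral`, `has_medial`, `has_occlusal`.
#' @export
make_specimen_table <- function(config) {
  validate_sim_config(config)
  n <- config$n_taxa
  with_seed(config$seed, {
    clade <- sample(c("nonamniote", "synapsid", "sauropsid"), n,
                    replace = TRUE, prob = config$clade_proportions)
    diet <- ifelse(runif(n) < config$herbivore_fraction,
                   "herbivore", "nonherbivore")
    sp <- config$subclade_probs
    is_diad <- clade == "nonamniote" & runif(n) < sp[["diadectomorph"]]
    is_capt <- clade == "sauropsid" & runif(n) < sp[["captorhinid"]]
    is_rec <- clade == "nonamniote" & !is_diad &
      runif(n) < sp[["recumbirostran"]]
    older <- config$age_window[[1]]; younger <- config$age_window[[2]]
    fad <- runif(n, younger, older)
    dur <- runif(n, 0, (older - younger) / 3)
    lad <- pmax(fad - dur, younger)
    vp <- config$view_probs
    data.frame(
      taxon_id = sprintf("t%03d", seq_len(n)),
      clade = clade,
      is_diadectomorph = is_diad,
      is_captorhinid_araeoscelidian_protorothyridid = is_capt,
      is_recumbirostran = is_rec,
      diet = diet,
      fad_ma = fad, lad_ma = lad,
      has_lateral = runif(n) < vp[["lateral"]],
      has_medial = runif(n) < vp[["medial"]],
      has_occlusal = runif(n) < vp[["occlusal"]],
      stringsAsFactors = FALSE)
  })
}

trait_group_of <- function(metadata, trait_group) {
  switch(trait_group,
         amniote = ifelse(metadata$clade == "nonamniote",
                          "nonamniote", "amniote"),
         diet = metadata$diet,
         clade = metadata$clade)
}

#' Generate a group-structured synthetic trait matrix
#'
#' Draws each taxon's nine functional traits from an independent
#' (diagonal-covariance) normal distribution whose mean and standard
#' deviation are set by the taxon's group; group variances are additionally
#' scaled by the configured variance multipliers.  Deterministic given the
#' configuration seed.
#'
#' @param metadata specimen table, see [make_specimen_table()].
#' @param config a [sim_config()] object.
#' @return numeric matrix (taxa x 9), rownames = `taxon_id`, colnames =
#'   [trait_names()].
#' @export
make_trait_matrix <- function(metadata, config) {
  validate_sim_config(config)
  grp <- trait_group_of(metadata, config$trait_group)
  unknown <- setdiff(unique(grp), rownames(config$trait_means))
  if (length(unknown))
    stop("groups missing from trait_means: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  n <- nrow(metadata)
  with_seed(config$seed + 1L, {
    mu <- config$trait_means[grp, , drop = FALSE]
    sd_eff <- config$trait_sds[grp, , drop = FALSE] *
      sqrt(config$variance_multipliers[grp, , drop = FALSE])
    m <- mu + matrix(rnorm(n * 9L), n, 9L) * sd_eff
    dimnames(m) <- list(metadata$taxon_id, trait_names())
    m
  })
}

#' Parametric jaw shape
#'
#' Defines a family of synthetic lateral jaw silhouettes with closed-form
#' trait values.  The jaw axis runs from the articulation (u = 0) to the
#' anterior tip (u = 1, at x = `length`).  The ventral margin is a smooth
#' unimodal depth profile reaching `max_depth` at `depth_peak_position`; the
#' dorsal margin carries the tooth-row line (y = 0), a Gaussian coronoid bump
#' of height `coronoid_height` at `coronoid_position`, and rises to the
#' articular region, elevated by `articular_offset` above the tooth row.
#'
#' @param length jaw anteroposterior extent (arbitrary units).
#' @param max_depth maximum ventral depth; must be < `length`.
#' @param depth_peak_position fraction in (0, 1) at which depth peaks.
#' @param coronoid_height height of the coronoid bump (>= 0).
#' @param coronoid_position fraction in (0, 1) of the bump centre.
#' @param coronoid_width bump standard deviation as a fraction of length.
#' @param symphysis_length symphysis extent from the anterior tip
#'   (< `length`).
#' @param articular_offset signed dorsal elevation of the joint relative to
#'   the tooth-row line (negative values cannot be rendered as a simple
#'   outline and are rejected by [make_jaw_outline()]).
#' @param insertion_position adductor in-lever point as a fraction of the
#'   joint to anterior-tip distance.
#' @param opening_position jaw-opening in-lever (retroarticular) point as a
#'   fraction of the same axis, extending behind the joint.
#' @param toothrow_span,fossa_span pairs of fractions `c(posterior,
#'   anterior)` along the axis (0 <= first < second <= 1).
#' @return a validated list of class `shape_params`.
#' @export
shape_params <- function(length = 10, max_depth = 2,
                         depth_peak_position = 0.45,
                         coronoid_height = 0.8, coronoid_position = 0.3,
                         coronoid_width = 0.06,
                         symphysis_length = 1, articular_offset = 0.5,
                         insertion_position = 0.2, opening_position = 0.06,
                         toothrow_span = c(0.35, 0.95),
                         fossa_span = c(0.08, 0.3)) {
  p <- list(length = length, max_depth = max_depth,
            depth_peak_position = depth_peak_position,
            coronoid_height = coronoid_height,
            coronoid_position = coronoid_position,
            coronoid_width = coronoid_width,
            symphysis_length = symphysis_length,
            articular_offset = articular_offset,
            insertion_position = insertion_position,
            opening_position = opening_position,
            toothrow_span = toothrow_span, fossa_span = fossa_span)
  validate_shape_params(p)
  structure(p, class = "shape_params")
}

validate_shape_params <- function(p) {
  chk <- function(cond, field, msg) if (!cond) stop_field(field, msg)
  chk(p$length > 0, "length", "must be positive")
  chk(p$max_depth > 0 && p$max_depth < p$length, "max_depth",
      "must be positive and smaller than length")
  chk(p$depth_peak_position > 0 && p$depth_peak_position < 1,
      "depth_peak_position", "must be in (0, 1)")
  chk(p$coronoid_height >= 0, "coronoid_height", "must be non-negative")
  chk(p$coronoid_position > 0 && p$coronoid_position < 1,
      "coronoid_position", "must be in (0, 1)")
  chk(p$coronoid_width > 0, "coronoid_width", "must be positive")
  chk(p$symphysis_length >= 0 && p$symphysis_length < p$length,
      "symphysis_length", "must be in [0, length)")
  chk(p$insertion_position > 0 && p$insertion_position < 1,
      "insertion_position", "must be in (0, 1)")
  chk(p$opening_position > 0, "opening_position", "must be positive")
  sp <- p$toothrow_span
  chk(length(sp) == 2L && sp[1] >= 0 && sp[1] < sp[2] && sp[2] <= 1,
      "toothrow_span", "must satisfy 0 <= s0 < s1 <= 1")
  fs <- p$fossa_span
  chk(length(fs) == 2L && fs[1] >= 0 && fs[1] < fs[2] && fs[2] <= 1,
      "fossa_span", "must satisfy 0 <= f0 < f1 <= 1")
  invisible(p)
}

## dorsal and ventral margin functions at axis fractions u in [0, 1]
margin_functions <- function(p) {
  L <- p$length
  ## ventral depth: unimodal, 0 at both ends, max_depth at the peak station
  pk <- p$depth_peak_position
  ventral <- function(u) {
    v <- rep(0, length(u))
    i <- u > 0 & u < 1
    v[i] <- p$max_depth *
      exp(2 * (pk * log(u[i] / pk) + (1 - pk) * log((1 - u[i]) / (1 - pk))))
    v
  }
  ## coronoid bump: Gaussian minus its chord so it vanishes exactly at the
  ## ends, rescaled to reach exactly coronoid_height at the bump centre
  cp <- p$coronoid_position; cw <- p$coronoid_width
  g <- function(u) exp(-(u - cp)^2 / (2 * cw^2))
  denom <- 1 - g(0) * (1 - cp) - g(1) * cp
  bump <- function(u)
    p$coronoid_height * (g(u) - g(0) * (1 - u) - g(1) * u) / denom
  dorsal <- function(u) p$articular_offset * (1 - u)^3 + bump(u)
  list(ventral = ventral, dorsal = dorsal, L = L)
}

#' Total-depth profile of a parametric jaw
#'
#' Samples the dorsoventral extent (dorsal margin minus ventral margin) of
#' the [shape_params()] jaw at `n` equally spaced axis stations; this is the
#' profile consumed by [aspect_ratios()] and [compute_traits()].
#'
#' @param params a [shape_params()] object.
#' @param n number of stations.
#' @return two-column matrix (s, d).
#' @export
depth_profile_from_params <- function(params, n = 201L) {
  validate_shape_params(params)
  mf <- margin_functions(params)
  u <- seq(0, 1, length.out = n)
  cbind(s = u, d = mf$dorsal(u) - (-mf$ventral(u)))
}

#' Generate a parametric jaw outline
#'
#' Renders the [shape_params()] jaw as a simple closed polygon with
#' counter-clockwise orientation, starting at the anterior tip.  Errors if
#' the requested parameters produce margins that cross (a self-intersecting
#' silhouette).
#'
#' @param params a [shape_params()] object.
#' @param n_points number of polygon vertices.
#' @return an [as_outline()] object with the anterior-tip hint set.
#' @export
make_jaw_outline <- function(params, n_points = 660L) {
  validate_shape_params(params)
  if (n_points < 8L) stop("n_points must be at least 8", call. = FALSE)
  mf <- margin_functions(params)
  L <- mf$L
  m1 <- ceiling(n_points / 2); m2 <- n_points - m1
  u_d <- seq(1, 0, length.out = m1)              # dorsal: tip -> joint
  u_v <- seq(0, 1, length.out = m2 + 1L)[seq_len(m2)]  # ventral: joint -> tip
  ucheck <- seq(1e-3, 1 - 1e-3, length.out = 512)
  if (any(mf$dorsal(ucheck) <= -mf$ventral(ucheck)))
    stop("self-intersecting outline: dorsal and ventral margins cross",
         call. = FALSE)
  xy <- rbind(cbind(L * u_d, mf$dorsal(u_d)),
              cbind(L * u_v, -mf$ventral(u_v)))
  as_outline(xy, view = "lateral", anterior = 1L)
}

#' Landmarks of a parametric jaw
#'
#' Places the nine-trait landmark set consistently with
#' [ground_truth_traits()]: the joint at (0, articular_offset), the anterior
#' tip at (length, 0), tooth-row/fossa/symphysis landmarks on the tooth-row
#' line, and the closing/opening in-lever points on the joint to anterior-tip
#' axis at `insertion_position` (in front of the joint) and
#' `opening_position` (behind it).
#'
#' @param params a [shape_params()] object.
#' @return a [jaw_landmarks()] object.
#' @export
make_landmarks <- function(params) {
  validate_shape_params(params)
  L <- params$length; ao <- params$articular_offset
  joint <- c(0, ao); tip <- c(L, 0)
  axis <- tip - joint
  jaw_landmarks(
    joint = joint,
    anterior_tip = tip,
    insertion = joint + params$insertion_position * axis,
    opening_insertion = joint - params$opening_position * axis,
    toothrow_anterior = c(L * params$toothrow_span[2], 0),
    toothrow_posterior = c(L * params$toothrow_span[1], 0),
    fossa_anterior = c(L * params$fossa_span[2], 0),
    fossa_posterior = c(L * params$fossa_span[1], 0),
    symphysis_posterior = c(L - params$symphysis_length, 0))
}

#' Closed-form trait values of a parametric jaw
#'
#' Evaluates the nine functional traits directly from the shape parameters;
#' [compute_traits()] applied to [make_landmarks()] and
#' [depth_profile_from_params()] reproduces these values to numerical
#' precision.
#'
#' @param params a [shape_params()] object.
#' @param n_profile stations used for the aspect-ratio profile.
#' @return named numeric vector of the nine traits.
#' @export
ground_truth_traits <- function(params, n_profile = 201L) {
  validate_shape_params(params)
  L <- params$length; ao <- params$articular_offset
  jl <- sqrt(L^2 + ao^2)                      # |joint -> anterior tip|
  s <- params$toothrow_span; f <- params$fossa_span
  ar <- aspect_ratios(depth_profile_from_params(params, n_profile), jl)
  c(anterior_ma = params$insertion_position,
    posterior_ma = params$insertion_position * jl /
      sqrt((L * s[1])^2 + ao^2),
    opening_ma = params$opening_position,
    max_ar = unname(ar["max_ar"]),
    avg_ar = unname(ar["avg_ar"]),
    articular_offset = abs(ao) / jl,
    rel_toothrow = L * (s[2] - s[1]) / jl,
    rel_fossa = L * (f[2] - f[1]) / jl,
    rel_symphysis = params$symphysis_length / jl)
}

#' Synthetic shape dataset for a specimen table
#'
#' Draws per-taxon shape parameters with group-structured effects (amniotes
#' and herbivores receive deeper jaws, taller coronoid bumps, larger
#' articular offsets and longer symphyses) plus lognormal individual jitter,
#' then renders outlines, landmarks and depth profiles.  Deterministic given
#' the configuration seed.
#'
#' @param metadata specimen table ([make_specimen_table()]).
#' @param config a [sim_config()] object.
#' @param n_points outline vertices per jaw.
#' @param jitter_sd standard deviation of the multiplicative lognormal
#'   jitter applied to the varied parameters.
#' @return list with named elements `outlines`, `landmarks`, `profiles` and
#'   `params`, each a list keyed by `taxon_id`.
#' @export
make_shape_set <- function(metadata, config, n_points = 660L,
                           jitter_sd = 0.08) {
  validate_sim_config(config)
  amniote <- metadata$clade != "nonamniote"
  herb <- metadata$diet == "herbivore"
  with_seed(config$seed + 2L, {
    out <- lapply(seq_len(nrow(metadata)), function(i) {
      jit <- function(x) x * exp(rnorm(1, 0, jitter_sd))
      p <- shape_params(
        length = 10,
        max_depth = jit(2 * (1 + 0.25 * amniote[i] + 0.2 * herb[i])),
        depth_peak_position = min(0.8, max(0.2, jit(0.45))),
        coronoid_height = jit(0.8 * (1 + 0.5 * amniote[i])),
        coronoid_position = min(0.6, max(0.15, jit(0.3))),
        coronoid_width = 0.06,
        symphysis_length = jit(1 * (1 + 0.5 * herb[i])),
        articular_offset = jit(0.5 * (1 + 0.6 * herb[i])),
        insertion_position = min(0.5, max(0.05, jit(0.2))),
        opening_position = jit(0.06),
        toothrow_span = c(min(0.6, max(0.2, jit(0.35 - 0.05 * herb[i]))),
                          min(0.98, max(0.85, jit(0.95)))),
        fossa_span = c(min(0.15, max(0.03, jit(0.08))),
                       min(0.55, max(0.2, jit(0.3 * (1 - 0.2 * amniote[i]))))))
      list(params = p,
           outline = make_jaw_outline(p, n_points),
           landmarks = make_landmarks(p),
           profile = depth_profile_from_params(p))
    })
    names(out) <- metadata$taxon_id
    list(outlines = lapply(out, `[[`, "outline"),
         landmarks = lapply(out, `[[`, "landmarks"),
         profiles = lapply(out, `[[`, "profile"),
         params = lapply(out, `[[`, "params"))
  })
}

#' Rasterise an outline to a binary silhouette PNG
#'
#' Scanline-fills the closed polygon onto a pixel grid (foreground black on
#' white) and optionally writes it as a PNG.  The outline is scaled to fit
#' the requested width with a margin.
#'
#' @param outline an [as_outline()] object.
#' @param path optional PNG output path.
#' @param width image width in pixels.
#' @param margin border margin in pixels.
#' @return the logical mask, invisibly when `path` is given.
#' @export
write_silhouette <- function(outline, path = NULL, width = 400L, margin = 8L) {
  xy <- as.matrix(outline)
  rng_x <- range(xy[, 1]); rng_y <- range(xy[, 2])
  sc <- (width - 2 * margin) / diff(rng_x)
  px <- (xy[, 1] - rng_x[1]) * sc + margin
  py <- (xy[, 2] - rng_y[1]) * sc + margin
  H <- ceiling(max(py)) + margin
  mask <- matrix(FALSE, H, width)
  n <- length(px); j <- c(2:n, 1L)
  for (r in seq_len(H)) {
    yc <- H - r + 0.5                       # pixel-centre y (y-up)
    cross <- which((py < yc) != (py[j] < yc))
    if (!length(cross)) next
    xs <- sort(px[cross] + (yc - py[cross]) / (py[j[cross]] - py[cross]) *
                 (px[j[cross]] - px[cross]))
    for (k in seq(1, length(xs) - 1, by = 2)) {
      c0 <- max(1L, ceiling(xs[k] + 0.5)); c1 <- min(width, floor(xs[k + 1] + 0.5))
      if (c0 <= c1) mask[r, c0:c1] <- TRUE
    }
  }
  if (!is.null(path)) {
    png::writePNG(1 - mask * 1, path)
    return(invisible(mask))
  }
  mask
}

#' Write a complete synthetic dataset to disk
#'
#' Emits the same formats the analysis pipeline reads: `metadata.csv`,
#' `landmarks.csv`, a `traits.csv` matrix, outline text files
#' (`outlines/<taxon>.txt`, two whitespace-separated columns) and binary
#' silhouette PNGs (`silhouettes/<taxon>.png`).
#'
#' @param config a [sim_config()] object.
#' @param dir output directory (created if needed).
#' @param silhouettes if `TRUE`, also render PNG silhouettes (slower).
#' @return invisibly, a list with the in-memory `metadata`, `traits` and
#'   `shapes`.
#' @export
write_synthetic_dataset <- function(config, dir, silhouettes = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- make_specimen_table(config)
  traits <- make_trait_matrix(meta, config)
  shapes <- make_shape_set(meta, config)
  write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  write.csv(data.frame(taxon_id = rownames(traits), traits),
            file.path(dir, "traits.csv"), row.names = FALSE)
  write_landmarks(shapes$landmarks, file.path(dir, "landmarks.csv"))
  odir <- file.path(dir, "outlines")
  dir.create(odir, showWarnings = FALSE)
  for (id in meta$taxon_id)
    write_outline(shapes$outlines[[id]], file.path(odir, paste0(id, ".txt")))
  if (silhouettes) {
    sdir <- file.path(dir, "silhouettes")
    dir.create(sdir, showWarnings = FALSE)
    for (id in meta$taxon_id)
      write_silhouette(shapes$outlines[[id]],
                       file.path(sdir, paste0(id, ".png")))
  }
  invisible(list(metadata = meta, traits = traits, shapes = shapes))
}
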