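#' Disparity and centroid-separation statistics for a two-group comparison
#'
#' For a binary grouping of morphospace scores: per-group sum of variances
#' with bootstrap summaries, a rank-sum test comparing the two bootstrap
#' disparity distributions (which group occupies more morphospace), and a
#' permutation MANOVA for centroid separation on all axes.
#'
#' @param scores PCA score matrix.
#' @param labels two-level group labels.
#' @param n_boot bootstrap replicates.
#' @param n_perm MANOVA permutations.
#' @param seed RNG seed.
#' @return list with `groups`, per-group `disparity` (bootstrap summaries),
#'   `rank_sum` and `permanova` test results.
#' @export
group_disparity_stats <- function(scores, labels, n_boot = 1000L,
                                  n_perm = 999L, seed = 1L) {
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2L) stop("need exactly 2 groups", call. = FALSE)
  boots <- lapply(seq_along(lv), function(i)
    bootstrap_disparity(scores, labels == lv[i], n_boot = n_boot,
                        seed = seed + i))
  names(boots) <- lv
  rs <- rank_sum(boots[[1]]$boot, boots[[2]]$boot)
  pm <- permanova(scores, labels, n_permutations = n_perm, seed = seed)
  list(groups = lv, disparity = boots, rank_sum = rs, permanova = pm)
}

#' Validate pipeline inputs
#'
#' Structural checks on a specimen metadata table (and optionally a trait
#' matrix): required columns, FAD/LAD ordering, closed label vocabularies,
#' and a warning for any time bin containing fewer than five taxa (sparse
#' bins make per-bin disparity unstable).
#'
#' @param metadata specimen table.
#' @param traits optional trait matrix keyed by `taxon_id`.
#' @param bins_level `"stage"` or `"series"`.
#' @return data frame with columns `level` (`"error"`/`"warning"`) and
#'   `message`; zero rows when fully valid.
#' @export
validate_inputs <- function(metadata, traits = NULL, bins_level = "stage") {
  issues <- list()
  add <- function(level, msg)
    issues[[length(issues) + 1L]] <<- data.frame(level = level, message = msg,
                                                 stringsAsFactors = FALSE)
  need <- c("taxon_id", "clade", "diet", "fad_ma", "lad_ma")
  missing <- setdiff(need, names(metadata))
  if (length(missing)) {
    add("error", paste("metadata missing columns:",
                       paste(missing, collapse = ", ")))
    return(do.call(rbind, issues))
  }
  bad <- which(metadata$fad_ma < metadata$lad_ma)
  for (i in bad)
    add("error", sprintf("taxon %s: FAD (%.3f) younger than LAD (%.3f)",
                         metadata$taxon_id[i], metadata$fad_ma[i],
                         metadata$lad_ma[i]))
  bad_clade <- setdiff(unique(metadata$clade),
                       c("nonamniote", "synapsid", "sauropsid"))
  if (length(bad_clade))
    add("error", paste("unknown clade labels:",
                       paste(bad_clade, collapse = ", ")))
  bad_diet <- setdiff(unique(metadata$diet), c("herbivore", "nonherbivore"))
  if (length(bad_diet))
    add("error", paste("unknown diet labels:",
                       paste(bad_diet, collapse = ", ")))
  if (anyDuplicated(metadata$taxon_id))
    add("error", "duplicated taxon_id values")
  if (!length(bad)) {
    bins <- build_time_bins(bins_level)
    counts <- colSums(assign_bins(metadata, bins))
    for (b in which(counts < 5L))
      add("warning", sprintf("time bin %s contains only %d taxa (< 5)",
                             bins$bin[b], counts[b]))
  }
  if (!is.null(traits)) {
    missing_rows <- setdiff(metadata$taxon_id, rownames(traits))
    if (length(missing_rows))
      add("warning", paste("taxa without trait rows:",
                           paste(head(missing_rows, 5L), collapse = ", ")))
    if (anyNA(traits)) add("error", "trait matrix contains missing values")
  }
  if (!length(issues))
    return(data.frame(level = character(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, issues)
}

#' Run the functional (biomechanical) analysis end to end
#'
#' From metadata, per-specimen landmarks and depth profiles: computes the
#' nine functional traits for every specimen with a usable medial figure,
#' Z-standardises the matrix, ordinates it by PCA, compares disparity and
#' centroid position between amniotes and non-amniotes, synapsids and
#' sauropsids, and herbivores and non-herbivores, runs per-trait Bonferroni
#' pairwise t-tests and Levene variance tests for the amniote and diet
#' contrasts, and resolves disparity (with Foote partial disparity by clade)
#' over stage-level time bins.
#'
#' @param metadata specimen table.
#' @param landmarks named list of [jaw_landmarks()] keyed by `taxon_id`.
#' @param profiles named list of depth profiles keyed by `taxon_id`.
#' @param hypothesis amniote definition, `"H1"`..`"H4"`.
#' @param bins_level `"stage"` (default) or `"series"`.
#' @param n_boot,n_perm,seed,ci analysis parameters.
#' @param insertion_rule passed to [compute_traits()].
#' @param out_dir optional directory; when given, CSV/JSON artefacts and a
#'   manifest are written.
#' @return a `report_bundle` list: `traits`, `z_traits`, `pca`, `metadata`
#'   (analysed rows, relabelled), `group_stats`, `trait_tests`,
#'   `disparity_time`, `counts`, `skipped`, `settings`.
#' @export
run_functional <- function(metadata, landmarks, profiles,
                           hypothesis = "H1", bins_level = "stage",
                           n_boot = 1000L, n_perm = 999L, seed = 1L,
                           ci = 0.95, insertion_rule = "explicit",
                           out_dir = NULL) {
  meta <- apply_hypothesis(metadata, hypothesis)
  sel <- meta[meta$has_medial, , drop = FALSE]
  have <- sel$taxon_id %in% names(landmarks) &
    sel$taxon_id %in% names(profiles)
  skipped <- sel$taxon_id[!have]
  if (length(skipped))
    warning("skipping specimens without landmarks/profiles: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  sel <- sel[have, , drop = FALSE]
  if (nrow(sel) < 3L) stop("too few analysable specimens", call. = FALSE)
  traits <- t(vapply(sel$taxon_id, function(id)
    compute_traits(landmarks[[id]], profiles[[id]],
                   insertion_rule = insertion_rule),
    numeric(9)))
  rownames(traits) <- sel$taxon_id
  z <- z_standardize(traits)
  pca <- jaw_pca(z)
  amn <- ifelse(sel$amniote, "amniote", "nonamniote")
  group_stats <- list(
    amniote = group_disparity_stats(pca$scores, amn, n_boot, n_perm, seed),
    diet = group_disparity_stats(pca$scores, sel$diet, n_boot, n_perm,
                                 seed + 100L))
  if (all(c("synapsid", "sauropsid") %in% sel$clade)) {
    sub <- sel$clade %in% c("synapsid", "sauropsid")
    group_stats$subclade <- group_disparity_stats(
      pca$scores[sub, , drop = FALSE], sel$clade[sub], n_boot, n_perm,
      seed + 200L)
  }
  trait_tests <- lapply(trait_names(), function(tr) {
    list(trait = tr,
         t_amniote = pairwise_t_tests(traits[, tr], amn),
         levene_amniote = levene_test(traits[, tr], amn),
         t_diet = pairwise_t_tests(traits[, tr], sel$diet),
         levene_diet = levene_test(traits[, tr], sel$diet))
  })
  names(trait_tests) <- trait_names()
  bins <- build_time_bins(bins_level)
  membership <- assign_bins(sel, bins)
  dtt <- disparity_through_time(pca$scores, membership, sel$clade,
                                n_boot = n_boot, seed = seed + 300L, ci = ci)
  bundle <- structure(list(
    traits = traits, z_traits = z, pca = pca, metadata = sel,
    group_stats = group_stats, trait_tests = trait_tests,
    disparity_time = dtt,
    counts = list(analysed = nrow(sel), skipped = length(skipped),
                  amniote = sum(sel$amniote),
                  nonamniote = sum(!sel$amniote),
                  herbivore = sum(sel$diet == "herbivore"),
                  per_bin = colSums(membership)),
    skipped = skipped,
    settings = list(analysis = "functional", hypothesis = hypothesis,
                    bins_level = bins_level, n_boot = n_boot,
                    n_perm = n_perm, seed = seed, ci = ci,
                    insertion_rule = insertion_rule)),
    class = "report_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Run the outline shape analysis end to end
#'
#' From metadata and closed outlines: (for occlusal data) splits each jaw
#' arch at its symphysis position and keeps one ramus, resamples every
#' outline to the standard point count (660 lateral, 500 occlusal), centres,
#' scales and aligns it, calibrates the harmonic count so the cumulative
#' harmonic power reaches the threshold (default 99%) for every specimen,
#' computes elliptical Fourier coefficient tables, ordinates them by PCA,
#' and runs the same group comparisons and disparity-through-time series as
#' the functional analysis.
#'
#' @param metadata specimen table.
#' @param outlines named list of [as_outline()] objects keyed by `taxon_id`.
#' @param view `"lateral"` or `"occlusal"`; selects specimens via
#'   `has_lateral`/`has_occlusal` and the default point count and bin level.
#' @param points outline resampling count; defaults to 660 (lateral) or
#'   500 (occlusal).
#' @param power_threshold harmonic-power calibration threshold.
#' @param aggregate calibration aggregation, see [calibrate_harmonics()].
#' @param normalization `"geometric"` (default: centre, scale and align
#'   every outline before decomposition) or `"first-ellipse"` (normalise
#'   the Fourier coefficients by the first harmonic instead), provided as a
#'   sensitivity check.
#' @param split_x named numeric vector of per-specimen symphysis x-positions
#'   (occlusal only).
#' @param hypothesis,bins_level,n_boot,n_perm,seed,ci as in
#'   [run_functional()]; `bins_level` defaults to stages for lateral data
#'   and series for occlusal data.
#' @param out_dir optional artefact directory.
#' @return a `report_bundle` list: `coefficients`, `harmonics` (calibrated
#'   H), `pca`, `metadata`, `group_stats`, `disparity_time`, `counts`,
#'   `skipped`, `settings`.
#' @export
run_shape <- function(metadata, outlines, view = c("lateral", "occlusal"),
                      points = NULL, power_threshold = 0.99,
                      aggregate = "worst",
                      normalization = c("geometric", "first-ellipse"),
                      split_x = NULL,
                      hypothesis = "H1", bins_level = NULL,
                      n_boot = 1000L, n_perm = 999L, seed = 1L, ci = 0.95,
                      out_dir = NULL) {
  view <- match.arg(view)
  normalization <- match.arg(normalization)
  if (is.null(points)) points <- if (view == "lateral") 660L else 500L
  if (is.null(bins_level))
    bins_level <- if (view == "lateral") "stage" else "series"
  meta <- apply_hypothesis(metadata, hypothesis)
  flag <- if (view == "lateral") meta$has_lateral else meta$has_occlusal
  sel <- meta[flag, , drop = FALSE]
  failed <- character()
  prepped <- list()
  for (id in sel$taxon_id) {
    res <- tryCatch({
      o <- outlines[[id]]
      if (is.null(o)) stop("no outline supplied")
      if (view == "occlusal") {
        if (is.null(split_x) || is.na(split_x[id]))
          stop("no symphysis split position supplied")
        o <- split_ramus(o, split_x[[id]])
      }
      o <- resample_closed(o, points)
      if (normalization == "geometric") {
        o <- normalize_geometry(o)
        o <- rotate_start(o)
      }
      o
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failed <- c(failed, sprintf("%s: %s", id, res))
    } else prepped[[id]] <- res
  }
  if (length(failed))
    warning("excluded specimens: ", paste(failed, collapse = "; "),
            call. = FALSE)
  sel <- sel[sel$taxon_id %in% names(prepped), , drop = FALSE]
  if (nrow(sel) < 3L) stop("too few analysable outlines", call. = FALSE)
  H <- calibrate_harmonics(prepped, threshold = power_threshold,
                           aggregate = aggregate)
  coefs <- efa_coefficient_table(
    prepped, H,
    normalization = if (normalization == "first-ellipse") "first-ellipse"
                    else "none")
  pca <- jaw_pca(coefs)
  amn <- ifelse(sel$amniote, "amniote", "nonamniote")
  group_stats <- list(
    amniote = group_disparity_stats(pca$scores, amn, n_boot, n_perm, seed),
    diet = group_disparity_stats(pca$scores, sel$diet, n_boot, n_perm,
                                 seed + 100L))
  bins <- build_time_bins(bins_level)
  membership <- assign_bins(sel, bins)
  dtt <- disparity_through_time(pca$scores, membership, sel$clade,
                                n_boot = n_boot, seed = seed + 300L, ci = ci)
  bundle <- structure(list(
    coefficients = coefs, harmonics = H, pca = pca, metadata = sel,
    group_stats = group_stats, disparity_time = dtt,
    counts = list(analysed = nrow(sel), excluded = length(failed),
                  amniote = sum(sel$amniote),
                  herbivore = sum(sel$diet == "herbivore"),
                  n_axes = length(pca$eigenvalues),
                  per_bin = colSums(membership)),
    skipped = failed,
    settings = list(analysis = paste0("shape_", view), view = view,
                    points = points, power_threshold = power_threshold,
                    aggregate = aggregate, normalization = normalization,
                    hypothesis = hypothesis,
                    bins_level = bins_level, n_boot = n_boot,
                    n_perm = n_perm, seed = seed, ci = ci)),
    class = "report_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  s <- x$settings
  cat(sprintf("<report_bundle> %s analysis: %d specimens, %d PC axes\n",
              s$analysis, x$counts$analysed, length(x$pca$eigenvalues)))
  cat(sprintf("  PC1 %.2f%%, PC1-2 %.2f%%\n",
              100 * x$pca$variance_fraction[1],
              100 * sum(x$pca$variance_fraction[
                seq_len(min(2, length(x$pca$variance_fraction)))])))
  invisible(x)
}

#' Write a report bundle's artefacts to disk
#'
#' Emits scores, eigenvalues/variance fractions, the disparity-through-time
#' series and (where present) the trait matrix as CSV, the test results and
#' run settings as JSON, plus a `manifest.json` listing every artefact with
#' its MD5 content hash.
#'
#' @param bundle a `report_bundle` from [run_functional()] or [run_shape()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data frame.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, name) {
    write.csv(x, file.path(dir, name), row.names = FALSE)
    name
  }
  files <- character()
  files <- c(files, wcsv(data.frame(taxon_id = rownames(bundle$pca$scores),
                                    bundle$pca$scores), "scores.csv"))
  files <- c(files, wcsv(data.frame(
    axis = seq_along(bundle$pca$eigenvalues),
    eigenvalue = bundle$pca$eigenvalues,
    variance_fraction = bundle$pca$variance_fraction), "eigenvalues.csv"))
  dtt <- bundle$disparity_time
  attr(dtt, "boot") <- NULL
  files <- c(files, wcsv(as.data.frame(dtt), "disparity_time.csv"))
  if (!is.null(bundle$traits))
    files <- c(files, wcsv(data.frame(taxon_id = rownames(bundle$traits),
                                      bundle$traits), "traits.csv"))
  strip <- function(x) {
    if (inherits(x, "jaw_test")) unclass(x)
    else if (is.list(x) && !is.data.frame(x)) {
      x$boot <- NULL
      lapply(x, strip)
    } else x
  }
  jsonlite::write_json(strip(bundle$group_stats),
                       file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, "stats.json")
  jsonlite::write_json(bundle$settings, file.path(dir, "settings.json"),
                       auto_unbox = TRUE)
  files <- c(files, "settings.json")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(dir, files))),
    stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"))
  invisible(manifest)
}
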