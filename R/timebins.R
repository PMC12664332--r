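#' Carboniferous--Permian time bins
#'
#' Returns the ordered time-bin table used for disparity-through-time
#' analyses: at `"stage"` level the fifteen sampled geological stages from
#' the Visean to the Changhsingian, at `"series"` level the five series
#' (Mississippian, Pennsylvanian, Cisuralian, Guadalupian, Lopingian) used
#' when per-stage occlusal samples are too sparse.  Boundary ages (Ma) follow
#' the ICS International Chronostratigraphic Chart (2023 edition).  Bins are
#' contiguous and half-open: a bin spans `[older_bound, younger_bound)` in
#' age, with the older bound inclusive.
#'
#' @param level `"stage"` or `"series"`.
#' @return data frame with columns `bin`, `older_bound_ma`,
#'   `younger_bound_ma`.
#' @export
build_time_bins <- function(level = c("stage", "series")) {
  level <- match.arg(level)
  if (level == "stage") {
    data.frame(
      bin = c("Visean", "Serpukhovian", "Bashkirian", "Moscovian",
              "Kasimovian", "Gzhelian", "Asselian", "Sakmarian",
              "Artinskian", "Kungurian", "Roadian", "Wordian",
              "Capitanian", "Wuchiapingian", "Changhsingian"),
      older_bound_ma = c(346.7, 330.9, 323.2, 315.2, 307.0, 303.7, 298.9,
                         293.5, 290.1, 283.5, 273.01, 266.9, 264.28,
                         259.51, 254.14),
      younger_bound_ma = c(330.9, 323.2, 315.2, 307.0, 303.7, 298.9, 293.5,
                           290.1, 283.5, 273.01, 266.9, 264.28, 259.51,
                           254.14, 251.902),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      bin = c("Mississippian", "Pennsylvanian", "Cisuralian",
              "Guadalupian", "Lopingian"),
      older_bound_ma = c(358.9, 323.2, 298.9, 273.01, 259.51),
      younger_bound_ma = c(323.2, 298.9, 273.01, 259.51, 251.902),
      stringsAsFactors = FALSE)
  }
}

#' Assign taxa to time bins by stratigraphic range
#'
#' A taxon is a member of every bin that its closed first-to-last appearance
#' interval `[lad_ma, fad_ma]` overlaps with positive duration; merely
#' touching a bin boundary does not qualify.  Point ranges (FAD = LAD) are
#' assigned to the single bin containing the point under the half-open
#' `[older, younger)` convention (an age exactly on a shared boundary
#' belongs to the younger bin).
#'
#' @param metadata data frame with columns `taxon_id`, `fad_ma`, `lad_ma`.
#' @param bins a [build_time_bins()] table.
#' @return logical membership matrix (taxa x bins) with dimnames.
#' @export
assign_bins <- function(metadata, bins) {
  bad <- metadata$fad_ma < metadata$lad_ma
  if (any(bad))
    stop("FAD younger than LAD for: ",
         paste(metadata$taxon_id[bad], collapse = ", "), call. = FALSE)
  m <- matrix(FALSE, nrow(metadata), nrow(bins),
              dimnames = list(metadata$taxon_id, bins$bin))
  for (b in seq_len(nrow(bins))) {
    older <- bins$older_bound_ma[b]; younger <- bins$younger_bound_ma[b]
    range_overlap <- pmin(metadata$fad_ma, older) >
      pmax(metadata$lad_ma, younger)
    point <- metadata$fad_ma == metadata$lad_ma &
      metadata$fad_ma <= older & metadata$fad_ma > younger
    m[, b] <- range_overlap | point
  }
  m
}
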