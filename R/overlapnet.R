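#' Dice similarity coefficient between two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`; defined as 0 when both masks are empty.
#'
#' @param a,b logical/0-1 arrays on the same grid.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask grid mismatch")
  a <- a != 0; b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(0)
  2 * sum(a & b) / denom
}

#' Overlap between two binary masks with the functional-zero rule
#'
#' Counts overlapping voxels and computes the Dice coefficient; fewer than
#' `zero_below` overlapping voxels (default 10) is considered functionally
#' the same as no overlap.
#'
#' @param a,b logical/0-1 arrays on the same grid.
#' @param zero_below functional-zero cutoff (default 10 voxels).
#' @return list of class `overlap_result`: `n_overlap_voxels`, `dice`,
#'   `functional_zero`.
#' @export
overlap_voxels <- function(a, b, zero_below = 10) {
  if (!identical(dim(a), dim(b))) stop("mask grid mismatch")
  n <- sum((a != 0) & (b != 0))
  structure(list(n_overlap_voxels = n, dice = dice(a, b),
                 functional_zero = n < zero_below),
            class = "overlap_result")
}

#' Normalize a thresholded statistical map to [0, 1]
#'
#' Divides every surviving value by the map's maximum, yielding values in
#' [0, 1] with the peak voxel at exactly 1. Requires the positive-cluster
#' convention (no negative surviving values); an empty map is returned
#' all-zero with a warning and flagged via the `empty` attribute.
#'
#' @param map thresholded `stat_map` (zeros outside surviving clusters).
#' @return `stat_map` with values in [0, 1].
#' @export
normalize_stat_map <- function(map) {
  vals <- map$data
  if (any(vals < 0)) stop("negative surviving values: normalize_stat_map expects positive clusters")
  mx <- max(vals)
  if (mx == 0) {
    warning("empty map: nothing to normalize")
    out <- stat_map(vals, kind = "normalized", df = NA_real_, mask = map$mask,
                    voxel_size = map$voxel_size)
    attr(out, "empty") <- TRUE
    return(out)
  }
  out <- stat_map(vals / mx, kind = "normalized", df = NA_real_,
                  mask = map$mask, voxel_size = map$voxel_size)
  attr(out, "empty") <- FALSE
  out
}

#' Voxelwise product of two normalized maps (statistical overlap map)
#'
#' Multiplies two normalized maps voxelwise; the product is nonzero only
#' where both inputs are nonzero, and larger values indicate a strong
#' response in both conditions.
#'
#' @param a,b normalized `stat_map`s (values in [0, 1]) on the same grid.
#' @return `stat_map` of kind `"overlap"`.
#' @export
statistical_overlap_map <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data))) stop("map grid mismatch")
  stopifnot(all(a$data >= 0 & a$data <= 1), all(b$data >= 0 & b$data <= 1))
  stat_map(a$data * b$data, kind = "overlap", df = NA_real_,
           mask = a$mask, voxel_size = a$voxel_size)
}

#' Group random-effects analysis of subject overlap maps
#'
#' Fits the second-level mixed model of [fit_group_map()] to per-subject
#' normalized statistical overlap maps. Because the inputs are non-negative
#' and frequently zero, testing for values greater than zero is
#' anti-conservative; the returned map carries that caveat in its
#' `note` attribute.
#'
#' @param overlap_maps list of per-subject overlap `stat_map`s.
#' @param design `group_design`.
#' @return `stat_map` (z) with attribute `note`.
#' @export
group_overlap_rfx <- function(overlap_maps, design) {
  out <- fit_group_map(overlap_maps, design)
  attr(out, "note") <- paste(
    "One-sided test of non-negative overlap values against zero.",
    "This is an anti-conservative test."
  )
  out
}

#' Conjunction of named thresholded group maps
#'
#' Labels each voxel with the subset of input maps in which it survives
#' (bit-coded), and flags voxels surviving in every map as the full
#' conjunction.
#'
#' @param maps named list (>= 2) of thresholded `stat_map`s on a common grid.
#' @return list: `labels` (integer array; bit i set = present in map i),
#'   `full_conjunction` (logical array), `legend` (data frame mapping codes
#'   to map-name subsets).
#' @export
conjunction_map <- function(maps) {
  if (length(maps) < 2) stop("need at least 2 maps for a conjunction")
  dims <- dim(maps[[1]]$data)
  for (m in maps) if (!identical(dim(m$data), dims)) stop("map grid mismatch")
  lab <- array(0L, dims)
  for (i in seq_along(maps)) {
    lab <- lab + as.integer(maps[[i]]$data != 0) * bitwShiftL(1L, i - 1L)
  }
  full_code <- bitwShiftL(1L, length(maps)) - 1L
  codes <- sort(unique(as.vector(lab)))
  codes <- codes[codes > 0]
  legend <- data.frame(
    code = codes,
    members = vapply(codes, function(cd) {
      paste(names(maps)[bitwAnd(cd, bitwShiftL(1L, seq_along(maps) - 1L)) > 0],
            collapse = "+")
    }, character(1)),
    n_voxels = vapply(codes, function(cd) sum(lab == cd), numeric(1)),
    stringsAsFactors = FALSE
  )
  list(labels = lab, full_conjunction = lab == full_code, legend = legend)
}

#' Dice report against network masks
#'
#' Long-format table of Dice coefficients between every result mask (subject-
#' and/or group-level) and every network mask, mirroring how thresholded
#' statistical maps are compared with meta-analytically defined networks.
#'
#' @param results named list of binary result masks; for subject-level
#'   results, a named list of lists (`results[[result]][[subject]]`).
#' @param networks named list of binary network masks on the same grid.
#' @return data frame: `level`, `subject`, `result`, `network`, `dice`.
#' @export
network_dice_report <- function(results, networks) {
  rows <- list()
  add <- function(level, subject, result, network, d) {
    rows[[length(rows) + 1]] <<- data.frame(
      level = level, subject = subject, result = result, network = network,
      dice = d, stringsAsFactors = FALSE)
  }
  for (rn in names(results)) {
    r <- results[[rn]]
    if (is.list(r) && !is.array(r) && is.null(dim(r))) {
      for (sn in names(r)) {
        for (nn in names(networks)) {
          add("subject", sn, rn, nn, dice(r[[sn]], networks[[nn]]))
        }
      }
    } else {
      for (nn in names(networks)) {
        add("group", NA_character_, rn, nn, dice(r, networks[[nn]]))
      }
    }
  }
  do.call(rbind, rows)
}
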