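#' Measure the six compartment/tissue volumes of one arm
#'
#' Each volume is 0.001 x a voxel count (1 voxel = 1 mm^3 = 0.001 mL):
#' total arm (inside the external contour), subfascial (inside the fascial
#' contour), epifascial (between the contours), muscle counted only in the
#' subfascial compartment, and fat and fluid counted only in the epifascial
#' compartment. Mixed voxels contribute to the compartment volumes but to no
#' tissue volume. Fluid-labelled voxels found inside the subfascial
#' compartment are counted in the subfascial volume only and reported in the
#' compartment map's diagnostic.
#'
#' @param labels a [segment()] result.
#' @param comp a [build_compartment_map()] result of the same shape.
#' @return An object of class `compartment_volumes`: named numeric of length
#'   6 (mL): `total_arm`, `subfascial`, `epifascial`, `muscle_subfascial`,
#'   `fat_epifascial`, `fluid_epifascial`.
#' @export
measure_volumes <- function(labels, comp) {
  lab <- if (inherits(labels, "tissue_labels")) labels$data else labels
  cp <- if (inherits(comp, "compartment_map")) comp$data else comp
  if (!identical(dim(lab), dim(cp)))
    stopf("label map and compartment map shapes differ")
  v <- c(total_arm = sum(cp != COMP_OUTSIDE),
         subfascial = sum(cp == COMP_SUBFASCIAL),
         epifascial = sum(cp == COMP_EPIFASCIAL),
         muscle_subfascial = sum(lab == GT_MUSCLE & cp == COMP_SUBFASCIAL),
         fat_epifascial = sum(lab == GT_FAT & cp == COMP_EPIFASCIAL),
         fluid_epifascial = sum(lab == GT_FLUID & cp == COMP_EPIFASCIAL)) / 1000
  structure(v, class = "compartment_volumes")
}

#' @export
print.compartment_volumes <- function(x, ...) {
  cat("<compartment_volumes> (mL)\n")
  print(round(unclass(x), 2))
  invisible(x)
}

#' Compare an affected/unaffected volume pair
#'
#' For each of the six volume sets: the excess volume (affected minus
#' unaffected), and the percent change (affected - unaffected)/unaffected x
#' 100 (reported as missing when the unaffected volume is zero). The three
#' relative excess volumes (epifascial, fat, fluid excess each divided by
#' the unaffected arm's epifascial volume) normalize arm size differences
#' across subjects.
#'
#' @param affected,unaffected [measure_volumes()] results over elbow-matched
#'   extents of equal slice count.
#' @return An object of class `arm_comparison`: `table` (data frame with one
#'   row per volume set) and `relative_excess` (named numeric length 3).
#' @export
compare_arms <- function(affected, unaffected) {
  stopifnot(inherits(affected, "compartment_volumes"),
            inherits(unaffected, "compartment_volumes"))
  a <- unclass(affected); u <- unclass(unaffected)
  if (any(a < 0) || any(u < 0)) stopf("volumes must be non-negative")
  tab <- data.frame(metric = names(a), affected_ml = as.numeric(a),
                    unaffected_ml = as.numeric(u),
                    excess_ml = as.numeric(a - u),
                    percent_change = ifelse(u > 0, (a - u) / u * 100, NA_real_))
  denom <- u[["epifascial"]]
  if (denom <= 0) {
    rel <- c(epifascial = NA_real_, fat = NA_real_, fluid = NA_real_)
  } else {
    rel <- c(epifascial = (a[["epifascial"]] - u[["epifascial"]]) / denom,
             fat = (a[["fat_epifascial"]] - u[["fat_epifascial"]]) / denom,
             fluid = (a[["fluid_epifascial"]] - u[["fluid_epifascial"]]) / denom)
  }
  structure(list(table = tab, relative_excess = rel), class = "arm_comparison")
}

#' @export
print.arm_comparison <- function(x, ...) {
  cat("<arm_comparison>\n")
  tab <- x$table
  tab$percent_change <- round(tab$percent_change, 1)
  print(tab, row.names = FALSE)
  cat("relative excess (of unaffected epifascial):",
      paste(sprintf("%s %.3f", names(x$relative_excess), x$relative_excess),
            collapse = ", "), "\n")
  invisible(x)
}

#' Epifascial share of the total excess volume
#'
#' The fraction of the total-arm excess volume that lies in the epifascial
#' compartment (the bulk of lymphoedematous swelling).
#'
#' @param comparison an [compare_arms()] result.
#' @return A single fraction.
#' @export
epifascial_share_of_excess <- function(comparison) {
  stopifnot(inherits(comparison, "arm_comparison"))
  tab <- comparison$table
  total <- tab$excess_ml[tab$metric == "total_arm"]
  if (total == 0) stopf("total excess volume is zero; share undefined")
  tab$excess_ml[tab$metric == "epifascial"] / total
}

#' Write per-arm volumes or a pair comparison as CSV
#'
#' @param x a `compartment_volumes` or `arm_comparison` object.
#' @param path CSV output path.
#' @param metadata optional named list prepended as columns (subject, side,
#'   status, ...).
#' @return Invisibly, the data frame written.
#' @export
write_volumes_csv <- function(x, path, metadata = list()) {
  df <- if (inherits(x, "compartment_volumes"))
    as.data.frame(as.list(unclass(x)))
  else if (inherits(x, "arm_comparison")) x$table
  else stopf("unsupported object")
  if (length(metadata)) df <- cbind(as.data.frame(metadata), df)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
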