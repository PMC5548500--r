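# The compartment codes: 0 outside, 1 subfascial, 2 epifascial.

largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) <= 1L) return(mask)
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

disc_brush <- function(radius_mm) {
  EBImage::makeBrush(2L * as.integer(ceiling(radius_mm)) + 1L, shape = "disc")
}

close_fill <- function(mask, radius_mm) {
  m <- EBImage::fillHull(EBImage::closing(mask, disc_brush(radius_mm)))
  m > 0
}

#' Build the external and subfascial masks of one slice
#'
#' The external mask is the largest connected component of the non-noise
#' voxels, morphologically closed (disc radius `r_close` mm) and hole-filled:
#' the entire cross-section of the arm, noise excluded. The subfascial mask
#' is the largest connected component of the muscle voxels, closed with the
#' larger fascia radius `r_fascia`, hole-filled (so that the muscle and the
#' other subfascial tissue components are contained within the fascial
#' contour) and constrained to the external mask.
#'
#' @param label_slice 2D integer tissue-label matrix (codes as in
#'   [segment()]).
#' @param r_close,r_fascia closing radii in mm for the external and fascial
#'   masks.
#' @return A list of class `slice_masks`: logical matrices `external` and
#'   `subfascial` and flag `muscle_empty` (a slice with no muscle voxels
#'   carries an empty subfascial mask rather than an error).
#' @export
build_slice_masks <- function(label_slice, r_close = 3, r_fascia = 5) {
  stopifnot(is.matrix(label_slice))
  nonnoise <- label_slice != TISSUE_CLASSES[["noise"]]
  if (!any(nonnoise)) stopf("empty slice: no non-noise voxels")
  external <- close_fill(largest_component(nonnoise), r_close)
  muscle <- label_slice == TISSUE_CLASSES[["muscle"]]
  muscle_empty <- !any(muscle)
  subfascial <- if (muscle_empty) matrix(FALSE, nrow(label_slice), ncol(label_slice))
    else close_fill(largest_component(muscle), r_fascia) & external
  structure(list(external = external, subfascial = subfascial,
                 muscle_empty = muscle_empty),
            class = "slice_masks")
}

#' Classify every voxel into outside / subfascial / epifascial
#'
#' Scrolls through each slice, builds the slice masks and assigns: outside =
#' not external; subfascial = the fascial-contour interior; epifascial =
#' external and not subfascial. The partition is exact by construction:
#' subfascial + epifascial voxel counts equal the external (total arm) count
#' on every slice. Slices without non-noise voxels are flagged and counted
#' entirely as outside.
#'
#' @param labels a [segment()] result (or a compatible integer 3D array).
#' @param r_close,r_fascia closing radii in mm, see [build_slice_masks()].
#' @return An object of class `compartment_map`: integer array `data` (0
#'   outside, 1 subfascial, 2 epifascial), per-slice flags `muscle_empty` and
#'   `empty_slice`, and `subfascial_fluid_voxels`, a diagnostic count of
#'   fluid-labelled voxels found inside the subfascial compartment.
#' @export
build_compartment_map <- function(labels, r_close = 3, r_fascia = 5) {
  lab <- if (inherits(labels, "tissue_labels")) labels$data else labels
  stopifnot(length(dim(lab)) == 3L)
  d <- dim(lab)
  comp <- array(COMP_OUTSIDE, d)
  muscle_empty <- logical(d[1]); empty_slice <- logical(d[1])
  for (s in seq_len(d[1])) {
    sl <- lab[s, , ]
    if (!any(sl != TISSUE_CLASSES[["noise"]])) {
      empty_slice[s] <- TRUE
      next
    }
    m <- build_slice_masks(sl, r_close, r_fascia)
    cs <- matrix(COMP_OUTSIDE, d[2], d[3])
    cs[m$external] <- COMP_EPIFASCIAL
    cs[m$subfascial] <- COMP_SUBFASCIAL
    comp[s, , ] <- cs
    muscle_empty[s] <- m$muscle_empty
  }
  if (any(empty_slice))
    warning(sprintf("%d slice(s) contained no non-noise voxels and were marked outside",
                    sum(empty_slice)))
  structure(list(data = comp, muscle_empty = muscle_empty,
                 empty_slice = empty_slice,
                 subfascial_fluid_voxels =
                   sum(lab == TISSUE_CLASSES[["fluid"]] & comp == COMP_SUBFASCIAL),
                 r_close = r_close, r_fascia = r_fascia),
            class = "compartment_map")
}

#' @export
print.compartment_map <- function(x, ...) {
  tab <- tabulate(as.vector(x$data) + 1L, 3L)
  cat(sprintf(paste0("<compartment_map> %s voxels: outside %d, subfascial %d,",
                     " epifascial %d\n"),
              paste(dim(x$data), collapse = "x"), tab[1], tab[2], tab[3]))
  if (x$subfascial_fluid_voxels > 0)
    cat(sprintf("  note: %d fluid-labelled voxel(s) inside the subfascial compartment\n",
                x$subfascial_fluid_voxels))
  invisible(x)
}

#' Export per-slice contours as a CSV vertex list
#'
#' Traces the external and fascial contours of every slice of a compartment
#' map and writes them as `(slice, contour, x_mm, y_mm)` rows.
#'
#' @param comp a [build_compartment_map()] result.
#' @param path CSV output path.
#' @return Invisibly, the data frame written.
#' @export
export_contours <- function(comp, path) {
  stopifnot(inherits(comp, "compartment_map"))
  d <- dim(comp$data)
  rows <- list()
  for (s in seq_len(d[1])) {
    cs <- comp$data[s, , ]
    ext <- cs != COMP_OUTSIDE
    if (!any(ext)) next
    ce <- extract_contour(ext)
    rows[[length(rows) + 1L]] <-
      data.frame(slice = s, contour = "external", x_mm = ce[, 1], y_mm = ce[, 2])
    sub <- cs == COMP_SUBFASCIAL
    if (any(sub)) {
      csub <- extract_contour(sub)
      rows[[length(rows) + 1L]] <-
        data.frame(slice = s, contour = "fascial", x_mm = csub[, 1],
                   y_mm = csub[, 2])
    }
  }
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}
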