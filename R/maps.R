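#' Per-slice tissue volume profile along the arm
#'
#' For every slice of the analysis extent: muscle (subfascial), epifascial
#' fat, epifascial fluid, epifascial and total arm volume in mL/slice (voxel
#' count x 0.001). Summing any column over slices reproduces the
#' corresponding [measure_volumes()] entry exactly.
#'
#' @param labels a [segment()] result.
#' @param comp a [build_compartment_map()] result.
#' @param lm [landmarks()] in the same (cropped) slice coordinates.
#' @return A data frame of class `longitudinal_profile` with attribute
#'   `landmarks`.
#' @export
longitudinal_profile <- function(labels, comp, lm) {
  lab <- labels$data; cp <- comp$data
  stopifnot(identical(dim(lab), dim(cp)), inherits(lm, "landmarks"))
  out <- data.frame(
    slice = seq_len(dim(lab)[1]),
    muscle_ml = slice_counts(lab == GT_MUSCLE & cp == COMP_SUBFASCIAL) / 1000,
    fat_ml = slice_counts(lab == GT_FAT & cp == COMP_EPIFASCIAL) / 1000,
    fluid_ml = slice_counts(lab == GT_FLUID & cp == COMP_EPIFASCIAL) / 1000,
    epifascial_ml = slice_counts(cp == COMP_EPIFASCIAL) / 1000,
    subfascial_ml = slice_counts(cp == COMP_SUBFASCIAL) / 1000,
    total_ml = slice_counts(cp != COMP_OUTSIDE) / 1000)
  attr(out, "landmarks") <- lm
  class(out) <- c("longitudinal_profile", class(out))
  out
}

#' Align an affected/unaffected profile pair at the elbow
#'
#' Shifts the two per-slice profiles so their elbow indices coincide and
#' trims both to the common extent, so both contain the same number of
#' slices with the superior/inferior position matched at the elbow.
#'
#' @param profile_affected,profile_unaffected [longitudinal_profile()]s.
#' @return A list of class `aligned_pair`: `affected`, `unaffected` (trimmed
#'   data frames of equal length) and `elbow_pos` (elbow row index within the
#'   aligned extent).
#' @export
align_pair_at_elbow <- function(profile_affected, profile_unaffected) {
  ea <- attr(profile_affected, "landmarks")$elbow_slice
  eu <- attr(profile_unaffected, "landmarks")$elbow_slice
  na <- nrow(profile_affected); nu <- nrow(profile_unaffected)
  if (ea < 1 || ea > na || eu < 1 || eu > nu)
    stopf("elbow index outside the profile extent")
  left <- min(ea - 1L, eu - 1L)
  right <- min(na - ea, nu - eu)
  if (left + right < 0) stopf("profiles have no overlap after elbow alignment")
  ia <- (ea - left):(ea + right)
  iu <- (eu - left):(eu + right)
  structure(list(affected = profile_affected[ia, , drop = FALSE],
                 unaffected = profile_unaffected[iu, , drop = FALSE],
                 elbow_pos = left + 1L,
                 slices_affected = ia, slices_unaffected = iu),
            class = "aligned_pair")
}

# Contiguous segment id per slice: `n_seg` segments with remainder slices
# given one each starting from the distal end (index 1).
segment_lengths <- function(n_slices, n_seg) {
  base <- n_slices %/% n_seg
  extra <- n_slices %% n_seg
  len <- rep(base, n_seg) + c(rep(1L, extra), rep(0L, n_seg - extra))
  if (any(len == 0)) stopf("fewer slices (%d) than segments (%d)", n_slices, n_seg)
  len
}

#' Longitudinal excess-volume map (6 forearm + 4 upper-arm segments)
#'
#' The forearm (wrist to elbow) and upper arm (elbow to the 65% mark) are
#' divided into 6 and 4 contiguous segments respectively (remainder slices
#' are distributed one per segment from the distal end). Per segment, three
#' measures: fluid excess (mL, affected minus unaffected), fat excess (mL),
#' and the epifascial increase as a percentage of the unaffected epifascial
#' volume. Each measure also carries its peak (largest magnitude) for the
#' per-patient normalization used when rendering; normalized values lie in
#' `[-1, 1]` with at least one value of magnitude 1 when any excess is
#' non-zero.
#'
#' @param aligned an [align_pair_at_elbow()] result.
#' @param forearm_segments,upperarm_segments segment counts.
#' @return A data frame of class `longitudinal_excess_map` with columns
#'   `segment`, `region`, `n_slices`, `fluid_excess_ml`, `fat_excess_ml`,
#'   `epifascial_increase_pct` and their `*_norm` companions; attribute
#'   `peaks` stores the normalization peaks.
#' @export
longitudinal_excess_map <- function(aligned, forearm_segments = 6L,
                                    upperarm_segments = 4L) {
  stopifnot(inherits(aligned, "aligned_pair"))
  fa <- aligned$affected; fu <- aligned$unaffected
  L <- nrow(fa); ep <- aligned$elbow_pos
  len_f <- segment_lengths(ep, forearm_segments)
  len_u <- segment_lengths(L - ep, upperarm_segments)
  seg <- c(rep(seq_len(forearm_segments), len_f),
           rep(forearm_segments + seq_len(upperarm_segments), len_u))
  sum_by <- function(v) as.numeric(tapply(v, seg, sum))
  fluid <- sum_by(fa$fluid_ml - fu$fluid_ml)
  fat <- sum_by(fa$fat_ml - fu$fat_ml)
  epi_a <- sum_by(fa$epifascial_ml); epi_u <- sum_by(fu$epifascial_ml)
  epi_pct <- ifelse(epi_u > 0, (epi_a - epi_u) / epi_u * 100, NA_real_)
  peaks <- c(fluid = max(abs(fluid)), fat = max(abs(fat)),
             epifascial = max(abs(epi_pct), na.rm = TRUE))
  norm <- function(v, p) if (p > 0) v / p else v * 0
  out <- data.frame(
    segment = seq_along(fluid),
    region = rep(c("forearm", "upper_arm"), c(forearm_segments, upperarm_segments)),
    n_slices = c(len_f, len_u),
    fluid_excess_ml = fluid, fat_excess_ml = fat,
    epifascial_increase_pct = epi_pct,
    fluid_norm = norm(fluid, peaks["fluid"]),
    fat_norm = norm(fat, peaks["fat"]),
    epifascial_norm = norm(epi_pct, peaks["epifascial"]))
  attr(out, "peaks") <- peaks
  class(out) <- c("longitudinal_excess_map", class(out))
  out
}

# Boundary ring helpers (8-neighbourhood) used to keep the exact
# nearest-boundary search small.
ring_of <- function(mask) {
  er <- EBImage::erode(mask, EBImage::makeBrush(3, "box")) > 0
  mask & !er
}
outer_ring_of <- function(mask) {
  di <- EBImage::dilate(mask, EBImage::makeBrush(3, "box")) > 0
  di & !mask
}

#' Split the epifascial layer at the midcontour
#'
#' Realizes the midcontour equidistant from the external (skin) and fascial
#' contours by per-voxel distance comparison: an epifascial voxel is
#' `internal` (the layer above the muscle) if its Euclidean distance to the
#' nearest subfascial voxel is no larger than its distance to the nearest
#' voxel outside the arm, otherwise `external` (the layer below the skin);
#' exact ties go to internal. Computed per slice with exact integer-grid
#' distances. On slices with an empty subfascial mask all epifascial voxels
#' are external (infinitely far from the fascia).
#'
#' @param comp a [build_compartment_map()] result.
#' @return Integer 3D array: 0 not epifascial, 1 internal, 2 external.
#' @export
split_epifascial_layers <- function(comp) {
  cp <- if (inherits(comp, "compartment_map")) comp$data else comp
  stopifnot(length(dim(cp)) == 3L)
  if (!any(cp == COMP_EPIFASCIAL)) stopf("empty epifascial region")
  d <- dim(cp)
  layers <- array(0L, d)
  for (s in seq_len(d[1])) {
    cs <- cp[s, , ]
    epi <- which(cs == COMP_EPIFASCIAL)
    if (!length(epi)) next
    qi <- ((epi - 1L) %% d[2]) + 1L
    qj <- ((epi - 1L) %/% d[2]) + 1L
    Q <- cbind(qi, qj)
    sub <- cs == COMP_SUBFASCIAL
    ls <- rep(2L, length(epi))
    if (any(sub)) {
      ext <- cs != COMP_OUTSIDE
      fascia <- which(ring_of(sub))
      outside <- which(outer_ring_of(ext))
      Tf <- cbind(((fascia - 1L) %% d[2]) + 1L, ((fascia - 1L) %/% d[2]) + 1L)
      To <- cbind(((outside - 1L) %% d[2]) + 1L, ((outside - 1L) %/% d[2]) + 1L)
      df <- cpp_min_dist2(Q, Tf)
      do <- cpp_min_dist2(Q, To)
      ls <- ifelse(df <= do, 1L, 2L)
    }
    lsl <- layers[s, , ]
    lsl[epi] <- ls
    layers[s, , ] <- lsl
  }
  layers
}

# Common aligned slice windows of two cropped arms given their landmarks.
align_extents <- function(n_a, elbow_a, n_u, elbow_u) {
  left <- min(elbow_a - 1L, elbow_u - 1L)
  right <- min(n_a - elbow_a, n_u - elbow_u)
  list(idx_a = (elbow_a - left):(elbow_a + right),
       idx_u = (elbow_u - left):(elbow_u + right))
}

# 2 x 8 fluid voxel counts (layers x sectors) for one arm over `slices`.
# Sectors are bounded by the horizontal, vertical and 45-degree lines through
# the per-slice centre of mass of the subfascial mask (external-mask centre
# when the subfascial mask is empty); `mirror` flips the in-plane x axis so
# left arms render with the torso side on the right.
radial_fluid_bins <- function(labels, comp, layers, slices, mirror = FALSE) {
  lab <- labels$data; cp <- comp$data
  bins <- matrix(0, 2, 8, dimnames = list(c("internal", "external"), NULL))
  d <- dim(lab)
  for (s in slices) {
    cs <- cp[s, , ]
    sub <- which(cs == COMP_SUBFASCIAL)
    ref <- if (length(sub)) sub else which(cs != COMP_OUTSIDE)
    if (!length(ref)) next
    ri <- ((ref - 1L) %% d[2]) + 1L
    rj <- ((ref - 1L) %/% d[2]) + 1L
    com_y <- mean(ri); com_x <- mean(rj)
    fl <- which(lab[s, , ] == GT_FLUID & cs == COMP_EPIFASCIAL)
    if (!length(fl)) next
    fy <- ((fl - 1L) %% d[2]) + 1L - com_y
    fx <- ((fl - 1L) %/% d[2]) + 1L - com_x
    if (mirror) fx <- -fx
    ang <- (atan2(fy, fx) * 180 / pi) %% 360
    layer <- layers[s, , ][fl]
    # voxels exactly on a partition line contribute half to each adjacent
    # sector; this keeps the map symmetric under the grid's reflections
    # while preserving the exact partition sum
    res <- ang %% 45
    on_b <- pmin(res, 45 - res) < 1e-7
    sector <- pmin(8L, floor(ang / 45) + 1L)
    for (v in which(!on_b))
      bins[layer[v], sector[v]] <- bins[layer[v], sector[v]] + 1
    for (v in which(on_b)) {
      kb <- round(ang[v] / 45)
      up <- (kb %% 8) + 1L
      dn <- ((kb - 1) %% 8) + 1L
      bins[layer[v], up] <- bins[layer[v], up] + 0.5
      bins[layer[v], dn] <- bins[layer[v], dn] + 0.5
    }
  }
  bins
}

#' @export
print.radial_excess_map <- function(x, ...) {
  cat(sprintf(paste0("<radial_excess_map> fluid excess (mL), torso side",
                     " right (%s arm)\n"), attr(x, "laterality")))
  m <- matrix(x, 2, 8, dimnames = list(c("internal", "external"),
                                       paste0("s", 1:8)))
  print(round(m, 2))
  cat(sprintf("total %.2f mL, peak %.2f mL\n", attr(x, "total_excess_ml"),
              attr(x, "peak")))
  invisible(x)
}

#' Radial fluid-excess map (2 layers x 8 sectors)
#'
#' Partitions the epifascial volume into 16 segments -- 8 external (below
#' the skin) and 8 internal (above the muscle) via the midcontour, with each
#' cross-section divided radially into 8 sectors by the horizontal, vertical
#' and 45-degree lines through the centre of mass of the subfascial volume --
#' and accumulates the fluid excess volume (affected minus unaffected),
#' summed over the elbow-aligned longitudinal extent of the arm pair. The
#' torso-facing side is always represented on the right of the map: left
#' arms are mirrored about the vertical axis.
#'
#' @param affected,unaffected lists with elements `labels` ([segment()]),
#'   `compartments` ([build_compartment_map()]), optional `layers`
#'   ([split_epifascial_layers()], computed when missing), and `landmarks`
#'   (cropped coordinates).
#' @param laterality `"left"` or `"right"` (the imaged side of both arms'
#'   subject; left arms are mirrored).
#' @return A 2 x 8 matrix of class `radial_excess_map` (rows `internal`,
#'   `external`; mL), with attributes `total_excess_ml`, `peak`,
#'   `laterality` and the aligned slice windows.
#' @export
radial_excess_map <- function(affected, unaffected, laterality = "right") {
  laterality <- match.arg(laterality, c("left", "right"))
  mirror <- laterality == "left"
  for (arm in list(affected, unaffected))
    stopifnot(inherits(arm$labels, "tissue_labels"),
              inherits(arm$compartments, "compartment_map"),
              inherits(arm$landmarks, "landmarks"))
  la <- affected$layers %||% split_epifascial_layers(affected$compartments)
  lu <- unaffected$layers %||% split_epifascial_layers(unaffected$compartments)
  ext <- align_extents(dim(affected$labels$data)[1],
                       affected$landmarks$elbow_slice,
                       dim(unaffected$labels$data)[1],
                       unaffected$landmarks$elbow_slice)
  ba <- radial_fluid_bins(affected$labels, affected$compartments, la,
                          ext$idx_a, mirror)
  bu <- radial_fluid_bins(unaffected$labels, unaffected$compartments, lu,
                          ext$idx_u, mirror)
  out <- (ba - bu) / 1000
  structure(out, class = c("radial_excess_map", class(out)),
            total_excess_ml = sum(out), peak = max(abs(out)),
            laterality = laterality, slices_affected = ext$idx_a,
            slices_unaffected = ext$idx_u)
}
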