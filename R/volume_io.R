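#' Scalar MRI volume
#'
#' A 3D intensity grid with per-axis voxel spacing in mm. Axis 1 runs along
#' the arm (wrist towards shoulder with increasing slice index); axes 2 and 3
#' are the in-plane (transaxial) axes. Readers are expected to supply data in
#' this orientation (see the `axes` argument of [read_channel_stack()]).
#'
#' @param data 3D numeric array of intensities.
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, spacing = c(1, 1, 1)) {
  if (length(dim(data)) != 3L) stopf("volume data must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be 3 strictly positive values (mm)")
  structure(list(data = data, spacing = spacing), class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume> %s voxels, spacing %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' Three-channel co-registered arm stack
#'
#' Bundles the Dixon-water, Dixon-fat and STIR volumes of one arm together
#' with acquisition metadata. All three channels must share shape and spacing
#' (they cover the same imaging volume) and intensities must be non-negative.
#'
#' @param water,fat,stir `scalar_volume` objects (or plain 3D arrays at 1 mm).
#' @param laterality `"left"` or `"right"`.
#' @param status `"affected"` or `"unaffected"`.
#' @param subject_id free-text identifier.
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(water, fat, stir, laterality = "right",
                          status = "unaffected", subject_id = "subject") {
  as_vol <- function(v) if (inherits(v, "scalar_volume")) v else scalar_volume(v)
  water <- as_vol(water); fat <- as_vol(fat); stir <- as_vol(stir)
  shapes <- list(dim(water$data), dim(fat$data), dim(stir$data))
  if (!all(vapply(shapes, identical, logical(1), shapes[[1]])))
    stopf("channel shape mismatch: water %s, fat %s, stir %s",
          paste(shapes[[1]], collapse = "x"), paste(shapes[[2]], collapse = "x"),
          paste(shapes[[3]], collapse = "x"))
  sp <- rbind(water$spacing, fat$spacing, stir$spacing)
  if (max(sp) - min(sp) > 1e-6 && any(abs(sweep(sp, 2, sp[1, ])) > 1e-6))
    stopf("channel spacing mismatch beyond tolerance")
  for (nm in c("water", "fat", "stir")) {
    v <- get(nm)
    if (min(v$data) < 0) stopf("%s channel contains negative intensities", nm)
  }
  laterality <- match.arg(laterality, c("left", "right"))
  status <- match.arg(status, c("affected", "unaffected"))
  structure(list(water = water, fat = fat, stir = stir,
                 laterality = laterality, status = status,
                 subject_id = subject_id),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  cat(sprintf("<channel_stack> '%s' (%s, %s): %s voxels at %s mm\n",
              x$subject_id, x$laterality, x$status,
              paste(dim(x$water$data), collapse = "x"),
              paste(format(x$water$spacing), collapse = "x")))
  invisible(x)
}

#' @rdname channel_stack
#' @param x object to test.
#' @export
is.channel_stack <- function(x) inherits(x, "channel_stack")

stack_dim <- function(stack) dim(stack$water$data)

# n_voxels x 3 feature matrix (water, fat, stir) in array order.
stack_features <- function(stack) {
  cbind(water = as.vector(stack$water$data),
        fat = as.vector(stack$fat$data),
        stir = as.vector(stack$stir$data))
}

#' Anatomical landmarks along the arm axis
#'
#' Slice indices (1-based, axis 1) of the wrist (distal radioulnar joint), the
#' elbow, and the shoulder tip. Indices must increase towards the shoulder.
#'
#' @param wrist_slice,elbow_slice,shoulder_tip_slice integer slice indices.
#' @param n_slices optional axis-1 extent used to validate the indices.
#' @return An object of class `landmarks`.
#' @export
landmarks <- function(wrist_slice, elbow_slice, shoulder_tip_slice,
                      n_slices = NULL) {
  for (v in list(wrist_slice, elbow_slice, shoulder_tip_slice))
    if (!is_count(v) || v < 1) stopf("landmark indices must be positive integers")
  if (!(wrist_slice < elbow_slice && elbow_slice < shoulder_tip_slice))
    stopf("landmarks must satisfy wrist < elbow < shoulder tip")
  if (!is.null(n_slices) && shoulder_tip_slice > n_slices)
    stopf("landmarks exceed the volume extent (%d slices)", n_slices)
  structure(list(wrist_slice = as.integer(wrist_slice),
                 elbow_slice = as.integer(elbow_slice),
                 shoulder_tip_slice = as.integer(shoulder_tip_slice)),
            class = "landmarks")
}

#' The 65% upper-arm mark
#'
#' Proximal end of the standardized analysis extent: the slice at 65% of the
#' distance between the elbow and the shoulder tip. The fractional position is
#' rounded half away from zero (a documented choice; the position is invariant
#' to the index origin).
#'
#' @param lm a [landmarks()] object.
#' @return Integer slice index.
#' @export
upper_arm_mark <- function(lm) {
  stopifnot(inherits(lm, "landmarks"))
  as.integer(round_half_away(
    lm$elbow_slice + 0.65 * (lm$shoulder_tip_slice - lm$elbow_slice)))
}

#' Resample a volume to 1 mm isotropic voxels
#'
#' Node-centred resampling onto a 1 mm grid covering the same physical extent
#' (preserved to within one voxel). Linear interpolation by default; use
#' nearest-neighbour for label volumes so values stay categorical. Input that
#' is already 1 mm isotropic is returned unchanged (idempotent).
#'
#' @param volume a [scalar_volume()].
#' @param interpolation `"linear"` or `"nearest"`.
#' @return A `scalar_volume` with spacing `c(1, 1, 1)`.
#' @export
resample_isotropic <- function(volume, interpolation = c("linear", "nearest")) {
  stopifnot(inherits(volume, "scalar_volume"))
  interpolation <- match.arg(interpolation)
  sp <- volume$spacing
  if (all(abs(sp - 1) < 1e-9)) return(volume)
  d <- dim(volume$data)
  n_out <- pmax(2L, as.integer(round((d - 1) * sp)) + 1L)
  # source (1-based, fractional) coordinate of each output node per axis
  src <- lapply(1:3, function(ax) {
    x <- (seq_len(n_out[ax]) - 1) / sp[ax] + 1
    pmin(pmax(x, 1), d[ax])
  })
  if (interpolation == "nearest") {
    idx <- lapply(src, function(x) as.integer(round_half_away(x)))
    out <- volume$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  } else {
    lo <- lapply(seq_along(src), function(ax)
      pmin(pmax(floor(src[[ax]]), 1), d[ax]))
    hi <- lapply(seq_along(src), function(ax) pmin(lo[[ax]] + 1, d[ax]))
    fr <- lapply(seq_along(src), function(ax) src[[ax]] - lo[[ax]])
    out <- array(0, n_out)
    for (c1 in 0:1) for (c2 in 0:1) for (c3 in 0:1) {
      w <- outer(outer(if (c1) fr[[1]] else 1 - fr[[1]],
                       if (c2) fr[[2]] else 1 - fr[[2]]),
                 if (c3) fr[[3]] else 1 - fr[[3]])
      i1 <- if (c1) hi[[1]] else lo[[1]]
      i2 <- if (c2) hi[[2]] else lo[[2]]
      i3 <- if (c3) hi[[3]] else lo[[3]]
      out <- out + w * volume$data[i1, i2, i3, drop = FALSE]
    }
  }
  scalar_volume(out, c(1, 1, 1))
}

#' Read a three-channel NIfTI stack
#'
#' Reads the Dixon-water, Dixon-fat and STIR NIfTI files of one arm, reorders
#' axes to the package convention (axis 1 = along the arm, wrist towards
#' shoulder with increasing index), resamples each channel to 1 mm isotropic
#' voxels, and validates co-registration (equal shapes and spacings).
#'
#' @param water_path,fat_path,stir_path paths to 3D NIfTI files (.nii/.nii.gz).
#' @param metadata list with elements `laterality`, `status`, `subject_id`
#'   (any may be omitted), e.g. as returned by [read_landmark_sidecar()].
#' @param axes permutation mapping file axes to the package convention
#'   (default `c(1, 2, 3)`, i.e. the file is already ordered arm-axis first).
#' @param interpolation interpolation for the isotropic resampling.
#' @return A [channel_stack()].
#' @export
read_channel_stack <- function(water_path, fat_path, stir_path,
                               metadata = list(), axes = c(1, 2, 3),
                               interpolation = "linear") {
  read_one <- function(path, what) {
    if (!file.exists(path)) stopf("%s channel file not found: %s", what, path)
    img <- RNifti::readNifti(path)
    if (length(dim(img)) != 3L)
      stopf("%s channel is not a 3D volume: %s", what, path)
    sp <- RNifti::pixdim(img)[1:3]
    a <- aperm(array(as.numeric(img), dim(img)), axes)
    resample_isotropic(scalar_volume(a, sp[axes]), interpolation)
  }
  channel_stack(read_one(water_path, "water"), read_one(fat_path, "fat"),
                read_one(stir_path, "STIR"),
                laterality = metadata$laterality %||% "right",
                status = metadata$status %||% "unaffected",
                subject_id = metadata$subject_id %||% "subject")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a channel stack to NIfTI files
#'
#' @param stack a [channel_stack()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return Invisibly, the three file paths written.
#' @export
write_channel_stack <- function(stack, dir, prefix = stack$subject_id) {
  stopifnot(is.channel_stack(stack))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_", c("water", "fat", "stir"), ".nii.gz"))
  for (i in seq_along(paths)) {
    ch <- stack[[c("water", "fat", "stir")[i]]]
    RNifti::writeNifti(RNifti::asNifti(ch$data, pixdim = ch$spacing), paths[i])
  }
  invisible(paths)
}

#' Read or write a landmark/metadata sidecar
#'
#' JSON or YAML file (by extension) with fields `wrist_slice`, `elbow_slice`,
#' `shoulder_tip_slice` (1-based slice indices along the arm axis),
#' `laterality`, `status` and `subject_id`.
#'
#' @param path sidecar file path (.json, .yaml or .yml).
#' @return A list with elements `landmarks` (a [landmarks()] object),
#'   `laterality`, `status` and `subject_id`.
#' @export
read_landmark_sidecar <- function(path) {
  if (!file.exists(path)) stopf("sidecar file not found: %s", path)
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  list(landmarks = landmarks(x$wrist_slice, x$elbow_slice, x$shoulder_tip_slice),
       laterality = x$laterality %||% "right",
       status = x$status %||% "unaffected",
       subject_id = x$subject_id %||% "subject")
}

#' @rdname read_landmark_sidecar
#' @param lm a [landmarks()] object.
#' @param laterality,status,subject_id metadata stored alongside the landmarks.
#' @export
write_landmark_sidecar <- function(path, lm, laterality = "right",
                                   status = "unaffected",
                                   subject_id = "subject") {
  stopifnot(inherits(lm, "landmarks"))
  x <- list(wrist_slice = lm$wrist_slice, elbow_slice = lm$elbow_slice,
            shoulder_tip_slice = lm$shoulder_tip_slice,
            laterality = laterality, status = status, subject_id = subject_id)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Crop a stack to the standardized analysis extent
#'
#' Keeps all slices between the wrist and the 65% upper-arm mark, inclusive at
#' both ends, on all three channels identically. Landmarks are re-expressed in
#' the cropped coordinates (wrist becomes slice 1).
#'
#' @param stack a [channel_stack()].
#' @param lm a [landmarks()] object in the stack's slice coordinates.
#' @return A list with elements `stack` (cropped) and `landmarks` (shifted).
#' @export
crop_to_analysis_extent <- function(stack, lm) {
  stopifnot(is.channel_stack(stack), inherits(lm, "landmarks"))
  n <- stack_dim(stack)[1]
  mark <- upper_arm_mark(lm)
  if (mark > n || lm$wrist_slice > n)
    stopf("landmarks exceed the stack extent (%d slices)", n)
  idx <- lm$wrist_slice:mark
  crop <- function(ch) scalar_volume(ch$data[idx, , , drop = FALSE], ch$spacing)
  cropped <- channel_stack(crop(stack$water), crop(stack$fat), crop(stack$stir),
                           laterality = stack$laterality, status = stack$status,
                           subject_id = stack$subject_id)
  shift <- lm$wrist_slice - 1L
  list(stack = cropped,
       landmarks = landmarks(1L, lm$elbow_slice - shift,
                             lm$shoulder_tip_slice - shift))
}
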