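#' Default phantom tissue intensity table
#'
#' Mean channel intensities (Dixon water, Dixon fat, STIR; arbitrary units)
#' for the five phantom classes. The table encodes the contrast structure the
#' segmentation assumes: fat is bright on the Dixon fat image, muscle on the
#' Dixon water image, fluid on STIR (with moderate water signal), background
#' is dark everywhere, and interstitial (vessel-like, mixed-signal) tissue is
#' intermediate on all channels.
#'
#' @return A 5 x 3 numeric matrix with row names `background`, `muscle`,
#'   `fat`, `fluid`, `interstitial` and column names `water`, `fat`, `stir`.
#' @export
default_tissue_means <- function() {
  m <- rbind(background   = c(0, 0, 0),
             muscle       = c(100, 10, 20),
             fat          = c(20, 100, 10),
             fluid        = c(60, 10, 100),
             interstitial = c(50, 50, 50))
  colnames(m) <- c("water", "fat", "stir")
  m
}

#' Minimum inter-tissue contrast of an intensity table
#'
#' The smallest pairwise Euclidean distance between class mean triples in
#' feature space. Used as the reference scale when expressing noise levels
#' (e.g. "noise at 10% of the minimum inter-tissue contrast").
#'
#' @param means an intensity table as in [default_tissue_means()].
#' @return A single number (intensity units).
#' @export
min_intertissue_contrast <- function(means = default_tissue_means()) {
  min(stats::dist(means))
}

# Ground-truth label codes: 0 background, 1 muscle, 2 fat, 3 fluid,
# 4 interstitial (mixed-signal tissue). Tissue label codes from segmentation
# use the same integers with 0 = noise and 4 = mixed.
GT_BACKGROUND <- 0L; GT_MUSCLE <- 1L; GT_FAT <- 2L; GT_FLUID <- 3L
GT_INTERSTITIAL <- 4L
COMP_OUTSIDE <- 0L; COMP_SUBFASCIAL <- 1L; COMP_EPIFASCIAL <- 2L

#' Synthetic arm phantom specification
#'
#' Describes a tapered (optionally elliptical) cylindrical arm with a
#' concentric muscle core bounded by the fascia, an epifascial layer of fat
#' containing fluid pockets, vessel-like interstitial structures, and imaging
#' parameters (per-channel tissue means, additive Gaussian noise clipped at
#' zero, optional smooth multiplicative bias field).
#'
#' Pocket `layer` is `"internal"` (epifascial, above the muscle),
#' `"external"` (epifascial, below the skin) or `"subfascial"` (inside the
#' muscle; off the normal anatomy, for misclassification experiments).
#' Pocket `shape` is `"blob"` (sphere, diameter `extent_mm`) or
#' `"annulus_sector"` (a 90-degree sector of the layer's radial band spanning
#' `extent_mm` slices). Angles are degrees counter-clockwise from the torso
#' direction. For left-laterality phantoms the built volume is mirrored
#' in-plane, so anatomical angles keep their meaning.
#'
#' @param n_slices axis-1 extent (slices, 1 mm each).
#' @param in_plane in-plane grid size (voxels, 1 mm each).
#' @param arm_radius,muscle_radius radii in mm at (wrist-end, shoulder-end),
#'   linearly interpolated per slice; `muscle_radius < arm_radius` everywhere.
#' @param ellipticity ratio of the anterior-posterior to the torso-axis
#'   semi-axis (1 = circular).
#' @param lm [landmarks()] for the phantom (defaults scale with `n_slices`).
#' @param fluid_pockets data frame with columns `slice`, `angle_deg`,
#'   `layer`, `extent_mm`, `shape`; `NULL` for the default two blobs plus an
#'   elbow annulus sector, `"none"` or a zero-row data frame for no fluid.
#' @param interstitial data frame of vessel-like tubes with columns
#'   `angle_deg`, `pos` (radial position as a fraction of the compartment) and
#'   `radius_mm`, plus `compartment` (`"subfascial"` or `"epifascial"`).
#' @param tissue_means intensity table, see [default_tissue_means()].
#' @param noise_sd per-channel additive Gaussian noise SD (length 1 or 3).
#' @param bias_amplitude amplitude of the smooth multiplicative bias field as
#'   a fraction of the mean (0 disables it).
#' @param honeycomb if `TRUE`, fluid pockets are interleaved with fat on a
#'   2-voxel lattice, mimicking the trabecular "honeycomb" fluid pattern.
#' @param laterality,status,subject_id arm metadata.
#' @param seed integer seed making the phantom deterministic.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 200L, in_plane = 120L,
                         arm_radius = c(36, 50), muscle_radius = c(24, 32),
                         ellipticity = 1, lm = NULL, fluid_pockets = NULL,
                         interstitial = NULL,
                         tissue_means = default_tissue_means(),
                         noise_sd = 0, bias_amplitude = 0, honeycomb = FALSE,
                         laterality = "right", status = "unaffected",
                         subject_id = "phantom", seed = 1L) {
  stopifnot(is_count(n_slices), n_slices >= 10, is_count(in_plane),
            in_plane >= 24)
  expand <- function(r) if (length(r) == 2L)
    seq(r[1], r[2], length.out = n_slices) else rep_len(as.numeric(r), n_slices)
  arm_r <- expand(arm_radius); muscle_r <- expand(muscle_radius)
  if (any(muscle_r >= arm_r))
    stopf("muscle radius must be strictly below the arm radius at every slice")
  if (max(arm_r) * max(1, ellipticity) > in_plane / 2 - 2)
    stopf("arm radius exceeds the in-plane grid")
  if (is.null(lm))
    lm <- landmarks(max(1L, round(0.03 * n_slices)), round(0.525 * n_slices),
                    min(n_slices, round(0.975 * n_slices)), n_slices)
  if (is.null(fluid_pockets)) {
    fluid_pockets <- data.frame(
      slice = round(c(0.30, 0.62, 0.48) * n_slices),
      angle_deg = c(300, 210, 260),
      layer = c("external", "internal", "external"),
      extent_mm = c(14, 12, round(0.2 * n_slices)),
      shape = c("blob", "blob", "annulus_sector"))
  } else if (identical(fluid_pockets, "none")) {
    fluid_pockets <- data.frame(slice = integer(), angle_deg = numeric(),
                                layer = character(), extent_mm = numeric(),
                                shape = character())
  }
  stopifnot(all(c("slice", "angle_deg", "layer", "extent_mm", "shape") %in%
                  names(fluid_pockets)),
            all(fluid_pockets$layer %in% c("internal", "external", "subfascial")),
            all(fluid_pockets$shape %in% c("blob", "annulus_sector")))
  if (is.null(interstitial))
    interstitial <- data.frame(
      angle_deg = c(20, 140, 250, 90),
      pos = c(0.45, 0.5, 0.4, 0.55),
      radius_mm = c(4, 4, 3.5, 3),
      compartment = c("subfascial", "subfascial", "subfascial", "epifascial"))
  stopifnot(is.matrix(tissue_means), nrow(tissue_means) == 5L,
            ncol(tissue_means) == 3L)
  # contrast assumption: each tissue's dominant channel exceeds that channel
  # in every other class
  dom <- c(muscle = "water", fat = "fat", fluid = "stir")
  for (tis in names(dom)) {
    ch <- dom[[tis]]
    if (any(tissue_means[setdiff(rownames(tissue_means), tis), ch] >=
            tissue_means[tis, ch]))
      stopf("intensity table violates the contrast assumption for %s", tis)
  }
  noise_sd <- rep_len(as.numeric(noise_sd), 3L)
  stopifnot(all(noise_sd >= 0), bias_amplitude >= 0)
  structure(list(n_slices = as.integer(n_slices),
                 in_plane = as.integer(in_plane), arm_r = arm_r,
                 muscle_r = muscle_r, ellipticity = ellipticity, lm = lm,
                 fluid_pockets = fluid_pockets, interstitial = interstitial,
                 tissue_means = tissue_means, noise_sd = noise_sd,
                 bias_amplitude = bias_amplitude, honeycomb = honeycomb,
                 laterality = match.arg(laterality, c("left", "right")),
                 status = match.arg(status, c("affected", "unaffected")),
                 subject_id = subject_id, seed = as.integer(seed)),
            class = "phantom_spec")
}

# In-plane geometry helpers: voxel centre offsets from the grid centre, and
# the normalized elliptical radius for a circular radius r.
plane_grid <- function(in_plane, ellipticity) {
  c0 <- (in_plane + 1) / 2
  dx <- matrix(rep(seq_len(in_plane) - c0, each = in_plane), in_plane)  # cols
  dy <- matrix(rep(seq_len(in_plane) - c0, times = in_plane), in_plane) # rows
  list(dx = dx, dy = dy, r2 = dx^2 + (dy / ellipticity)^2,
       angle = (atan2(dy, dx) * 180 / pi) %% 360, c0 = c0)
}

# Build geometric label and compartment arrays (right-handed anatomy; the
# laterality mirror is applied at render time).
phantom_labels <- function(spec) {
  g <- plane_grid(spec$in_plane, spec$ellipticity)
  n <- spec$n_slices; np <- spec$in_plane
  labels <- array(GT_BACKGROUND, c(n, np, np))
  comp <- array(COMP_OUTSIDE, c(n, np, np))
  for (s in seq_len(n)) {
    arm <- g$r2 <= spec$arm_r[s]^2
    mus <- g$r2 <= spec$muscle_r[s]^2
    sl <- matrix(GT_BACKGROUND, np, np)
    sl[arm] <- GT_FAT
    sl[mus] <- GT_MUSCLE
    labels[s, , ] <- sl
    cp <- matrix(COMP_OUTSIDE, np, np)
    cp[arm] <- COMP_EPIFASCIAL
    cp[mus] <- COMP_SUBFASCIAL
    comp[s, , ] <- cp
  }
  # vessel-like interstitial tubes running the length of the arm
  it <- spec$interstitial
  if (nrow(it)) for (s in seq_len(n)) {
    sl <- labels[s, , ]
    for (i in seq_len(nrow(it))) {
      th <- it$angle_deg[i] * pi / 180
      rc <- if (it$compartment[i] == "subfascial") it$pos[i] * spec$muscle_r[s]
            else spec$muscle_r[s] + it$pos[i] * (spec$arm_r[s] - spec$muscle_r[s])
      d2 <- (g$dx - rc * cos(th))^2 + (g$dy - rc * sin(th))^2
      tube <- d2 <= it$radius_mm[i]^2
      target <- if (it$compartment[i] == "subfascial") GT_MUSCLE else GT_FAT
      sl[tube & sl == target] <- GT_INTERSTITIAL
    }
    labels[s, , ] <- sl
  }
  list(labels = labels, comp = comp, grid = g)
}

# Carve fluid pockets into a label array (in place semantics via return).
# Fluid replaces fat within the epifascial layer (or muscle for the
# explicitly subfascial option), so fluid stays inside its compartment.
apply_fluid_pockets <- function(labels, spec, grid) {
  pk <- spec$fluid_pockets
  n <- spec$n_slices
  for (i in seq_len(nrow(pk))) {
    layer <- pk$layer[i]
    target <- if (layer == "subfascial") GT_MUSCLE else GT_FAT
    th <- pk$angle_deg[i] * pi / 180
    if (pk$shape[i] == "blob") {
      R <- pk$extent_mm[i] / 2
      s0 <- pk$slice[i]
      for (s in max(1, ceiling(s0 - R)):min(n, floor(s0 + R))) {
        rr2 <- R^2 - (s - s0)^2
        if (rr2 <= 0) next
        t <- switch(layer, internal = 0.3, external = 0.7, subfascial = 0.5)
        rc <- if (layer == "subfascial") t * spec$muscle_r[s]
              else spec$muscle_r[s] + t * (spec$arm_r[s] - spec$muscle_r[s])
        d2 <- (grid$dx - rc * cos(th))^2 + (grid$dy - rc * sin(th))^2
        sl <- labels[s, , ]
        sl[d2 <= rr2 & sl == target] <- GT_FLUID
        labels[s, , ] <- sl
      }
    } else {  # annulus_sector: 90-degree sector of the layer's radial band
      half <- pk$extent_mm[i] / 2
      s0 <- pk$slice[i]
      dang <- abs((grid$angle - pk$angle_deg[i] + 180) %% 360 - 180)
      for (s in max(1, ceiling(s0 - half)):min(n, floor(s0 + half))) {
        mid <- (spec$muscle_r[s] + spec$arm_r[s]) / 2
        band <- if (layer == "internal")
          grid$r2 > spec$muscle_r[s]^2 & grid$r2 <= mid^2
        else grid$r2 > mid^2 & grid$r2 <= spec$arm_r[s]^2
        sl <- labels[s, , ]
        sl[band & dang <= 45 & sl == target] <- GT_FLUID
        labels[s, , ] <- sl
      }
    }
  }
  if (spec$honeycomb && any(labels == GT_FLUID)) {
    # re-interleave fluid with fat on a 2-voxel lattice
    d <- dim(labels)
    lattice <- array((slice.index(labels, 1) + slice.index(labels, 2) +
                        slice.index(labels, 3)) %% 2L == 0L, d)
    labels[labels == GT_FLUID & !lattice] <- GT_FAT
  }
  labels
}

# Render intensity channels from a label array: tissue mean x bias field +
# clipped Gaussian noise. Advances the RNG (caller seeds).
phantom_render <- function(labels, spec) {
  d <- dim(labels)
  idx <- as.vector(labels) + 1L
  bias <- 1
  if (spec$bias_amplitude > 0) {
    co <- runif(9, -1, 1)
    ax <- lapply(d, function(k) seq(-1, 1, length.out = k))
    P <- outer(outer(co[1] * ax[[1]] + co[4] * ax[[1]]^2,
                     co[2] * ax[[2]] + co[5] * ax[[2]]^2, `+`),
               co[3] * ax[[3]] + co[6] * ax[[3]]^2, `+`) +
      co[7] * outer(outer(ax[[1]], ax[[2]]), rep(1, d[3])) +
      co[8] * outer(outer(ax[[1]], rep(1, d[2])), ax[[3]]) +
      co[9] * outer(outer(rep(1, d[1]), ax[[2]]), ax[[3]])
    bias <- 1 + spec$bias_amplitude * P / max(abs(P))
  }
  make_channel <- function(ch) {
    v <- array(spec$tissue_means[idx, ch], d) * bias
    if (spec$noise_sd[ch] > 0)
      v <- v + array(rnorm(prod(d), 0, spec$noise_sd[ch]), d)
    v[v < 0] <- 0
    scalar_volume(v, c(1, 1, 1))
  }
  list(water = make_channel(1), fat = make_channel(2), stir = make_channel(3))
}

mirror_lr <- function(a) a[, , dim(a)[3]:1, drop = FALSE]

# Exact ground-truth volumes (mL) over the analysis extent.
gt_volumes <- function(labels, comp, lm) {
  idx <- lm$wrist_slice:upper_arm_mark(lm)
  L <- labels[idx, , , drop = FALSE]; C <- comp[idx, , , drop = FALSE]
  c(total_arm = sum(C != COMP_OUTSIDE),
    subfascial = sum(C == COMP_SUBFASCIAL),
    epifascial = sum(C == COMP_EPIFASCIAL),
    muscle_subfascial = sum(L == GT_MUSCLE & C == COMP_SUBFASCIAL),
    fat_epifascial = sum(L == GT_FAT & C == COMP_EPIFASCIAL),
    fluid_epifascial = sum(L == GT_FLUID & C == COMP_EPIFASCIAL)) / 1000
}

finish_ground_truth <- function(labels, comp, spec) {
  if (spec$laterality == "left") {
    labels <- mirror_lr(labels); comp <- mirror_lr(comp)
  }
  structure(list(labels = labels, compartments = comp, landmarks = spec$lm,
                 true_volumes = gt_volumes(labels, comp, spec$lm),
                 laterality = spec$laterality),
            class = "ground_truth")
}

#' Generate a synthetic arm
#'
#' Builds the three-channel stack and its voxel-exact ground truth from a
#' [phantom_spec()]. Deterministic given the spec's seed. In the noise-free,
#' bias-free case every voxel's channel triple equals its class mean triple
#' exactly, so the feature space is perfectly separable.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `stack` (a [channel_stack()]) and
#'   `ground_truth` (labels, compartments, landmarks, true volumes in mL over
#'   the analysis extent).
#' @export
generate_arm <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- phantom_labels(spec)
  labels <- apply_fluid_pockets(geo$labels, spec, geo$grid)
  chans <- with_seed(spec$seed, phantom_render(labels, spec))
  if (spec$laterality == "left")
    chans <- lapply(chans, function(v) scalar_volume(mirror_lr(v$data), v$spacing))
  stack <- channel_stack(chans$water, chans$fat, chans$stir,
                         laterality = spec$laterality, status = spec$status,
                         subject_id = spec$subject_id)
  list(stack = stack, ground_truth = finish_ground_truth(labels, geo$comp, spec))
}

#' Excess-volume specification for an affected arm
#'
#' Target epifascial fat and fluid excess volumes (mL) injected into the
#' affected arm of a pair, with their longitudinal placement. Fat excess is
#' realized as an outward thickening of the epifascial layer; fluid excess as
#' conversion of epifascial fat voxels around `fluid_angle`. Both are steered
#' by exact voxel counting, so the realized ground-truth excesses match the
#' targets to within voxelization error (well under 1% relative).
#'
#' @param fat_ml,fluid_ml target excess volumes in mL (>= 0).
#' @param fat_slices,fluid_slices slice windows (integer vectors) receiving
#'   the excess; defaults: whole analysis extent for fat, a window around the
#'   elbow for fluid (fluid accumulates prevalently around the elbow).
#' @param fluid_angle angular placement of the fluid, degrees from the torso
#'   direction.
#' @return An object of class `excess_spec`.
#' @export
excess_spec <- function(fat_ml = 100, fluid_ml = 50, fat_slices = NULL,
                        fluid_slices = NULL, fluid_angle = 280) {
  stopifnot(fat_ml >= 0, fluid_ml >= 0)
  structure(list(fat_ml = fat_ml, fluid_ml = fluid_ml,
                 fat_slices = fat_slices, fluid_slices = fluid_slices,
                 fluid_angle = fluid_angle),
            class = "excess_spec")
}

#' Generate an elbow-matched affected/unaffected phantom pair
#'
#' The unaffected arm follows `spec` exactly. The affected arm shares its
#' base geometry and landmarks (elbow-aligned by construction) and receives
#' the requested fat and fluid excess; muscle is identical between arms.
#'
#' @param spec a [phantom_spec()] describing the unaffected arm.
#' @param excess an [excess_spec()].
#' @return A list with elements `affected` and `unaffected`, each a list of
#'   `stack` and `ground_truth` as in [generate_arm()].
#' @export
generate_pair <- function(spec, excess = excess_spec()) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(excess, "excess_spec"))
  geo <- phantom_labels(spec)
  lab_u <- apply_fluid_pockets(geo$labels, spec, geo$grid)
  mark <- upper_arm_mark(spec$lm)
  fat_sl <- excess$fat_slices %||% (spec$lm$wrist_slice:mark)
  half <- max(3L, round(0.15 * spec$n_slices))
  fluid_sl <- excess$fluid_slices %||%
    (max(spec$lm$wrist_slice, spec$lm$elbow_slice - half):
       min(mark, spec$lm$elbow_slice + half))
  stopifnot(all(fat_sl >= 1 & fat_sl <= spec$n_slices),
            all(fluid_sl >= 1 & fluid_sl <= spec$n_slices))

  lab_a <- lab_u
  comp_a <- geo$comp
  arm_r_a <- spec$arm_r
  cap <- spec$in_plane / 2 - 2

  # 1) thicken the epifascial layer outwards: fat target + fluid target
  remaining <- round((excess$fat_ml + excess$fluid_ml) * 1000)
  fat_sl <- sort(fat_sl)
  for (i in seq_along(fat_sl)) {
    if (remaining <= 0) break
    s <- fat_sl[i]
    a_target <- remaining / (length(fat_sl) - i + 1)
    r_old <- arm_r_a[s]
    r_new <- sqrt(r_old^2 + a_target / (pi * spec$ellipticity))
    if (r_new * max(1, spec$ellipticity) > cap)
      stopf("excess targets exceed the geometric capacity of the phantom grid")
    ring <- geo$grid$r2 > r_old^2 & geo$grid$r2 <= r_new^2
    sl <- lab_a[s, , ]
    added <- ring & sl == GT_BACKGROUND
    sl[added] <- GT_FAT
    lab_a[s, , ] <- sl
    cs <- comp_a[s, , ]
    cs[added] <- COMP_EPIFASCIAL
    comp_a[s, , ] <- cs
    arm_r_a[s] <- r_new
    remaining <- remaining - sum(added)
  }

  # 2) convert epifascial fat voxels to fluid around the requested angle
  remaining <- round(excess$fluid_ml * 1000)
  fluid_sl <- sort(fluid_sl)
  dang <- abs((geo$grid$angle - excess$fluid_angle + 180) %% 360 - 180)
  carry <- 0
  for (i in seq_along(fluid_sl)) {
    if (remaining <= 0) break
    s <- fluid_sl[i]
    w <- min(remaining, round(remaining / (length(fluid_sl) - i + 1)) + carry)
    sl <- lab_a[s, , ]
    cand <- which(sl == GT_FAT & comp_a[s, , ] == COMP_EPIFASCIAL)
    if (!length(cand)) next
    take <- cand[order(dang[cand], -geo$grid$r2[cand])][seq_len(min(w, length(cand)))]
    sl[take] <- GT_FLUID
    lab_a[s, , ] <- sl
    remaining <- remaining - length(take)
    carry <- max(0, w - length(take))
  }
  if (remaining > 0)
    stopf("fluid excess target exceeds the epifascial fat available in the window")

  # 3) render both arms under one seeded RNG stream
  chans <- with_seed(spec$seed, list(u = phantom_render(lab_u, spec),
                                     a = phantom_render(lab_a, spec)))
  build <- function(ch, status) {
    if (spec$laterality == "left")
      ch <- lapply(ch, function(v) scalar_volume(mirror_lr(v$data), v$spacing))
    channel_stack(ch$water, ch$fat, ch$stir, laterality = spec$laterality,
                  status = status, subject_id = spec$subject_id)
  }
  spec_a <- spec; spec_a$status <- "affected"
  list(affected = list(stack = build(chans$a, "affected"),
                       ground_truth = finish_ground_truth(lab_a, comp_a, spec_a)),
       unaffected = list(stack = build(chans$u, "unaffected"),
                         ground_truth = finish_ground_truth(lab_u, geo$comp, spec)))
}

#' Generate a synthetic cohort of affected/unaffected pairs
#'
#' Per-subject excess targets are drawn from a truncated-normal fat excess
#' distribution with the fluid excess linearly coupled to it
#' (`fluid = fluid_coef * fat + noise`, clipped to `[fluid_min,
#' fluid_frac_max * fat]`), and arm size varied by a multiplicative factor.
#' Reproducible given `seed`.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param params list overriding any of: `template` (a [phantom_spec()] for
#'   the unaffected arms), `fat_mean`, `fat_sd`, `fat_range`, `fluid_coef`,
#'   `fluid_sd`, `fluid_min`, `fluid_frac_max`, `size_sd`.
#' @param seed integer seed.
#' @param images if `FALSE`, phantoms are not voxelised; only the sampled
#'   per-subject excess table is returned (the generating truth).
#' @return A list with `truth` (data frame: subject, laterality, fat and
#'   fluid excess in mL, size factor; attribute `population_r` gives the
#'   Pearson correlation implied by the generating coupling) and `pairs`
#'   (list of [generate_pair()] results, or `NULL` when `images = FALSE`).
#' @export
generate_cohort <- function(n_subjects = 13, params = list(), seed = 1L,
                            images = TRUE) {
  stopifnot(is_count(n_subjects), n_subjects >= 2)
  p <- utils::modifyList(list(
    template = phantom_spec(n_slices = 80L, in_plane = 104L,
                            arm_radius = c(24, 32), muscle_radius = c(15, 20)),
    fat_mean = 90, fat_sd = 30, fat_range = c(20, 150),
    fluid_coef = 0.5, fluid_sd = 15, fluid_min = 2, fluid_frac_max = 0.8,
    size_sd = 0.04), params)
  if (p$fat_sd <= 0)
    stopf("fat excess distribution is degenerate (zero variance); no correlation can be generated")
  truth <- with_seed(seed, {
    fat <- pmin(pmax(rnorm(n_subjects, p$fat_mean, p$fat_sd), p$fat_range[1]),
                p$fat_range[2])
    fluid <- pmin(pmax(p$fluid_coef * fat + rnorm(n_subjects, 0, p$fluid_sd),
                       p$fluid_min), p$fluid_frac_max * fat)
    data.frame(subject = sprintf("S%02d", seq_len(n_subjects)),
               laterality = rep_len(c("right", "left"), n_subjects),
               fat_excess_ml = fat, fluid_excess_ml = fluid,
               size_factor = pmax(0.8, rnorm(n_subjects, 1, p$size_sd)))
  })
  attr(truth, "population_r") <-
    p$fluid_coef * p$fat_sd / sqrt((p$fluid_coef * p$fat_sd)^2 + p$fluid_sd^2)
  pairs <- NULL
  if (images) {
    pairs <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      tp <- p$template
      sp <- phantom_spec(n_slices = tp$n_slices, in_plane = tp$in_plane,
                         arm_radius = range(tp$arm_r) * truth$size_factor[i],
                         muscle_radius = range(tp$muscle_r) * truth$size_factor[i],
                         ellipticity = tp$ellipticity,
                         fluid_pockets = tp$fluid_pockets,
                         tissue_means = tp$tissue_means,
                         noise_sd = tp$noise_sd,
                         bias_amplitude = tp$bias_amplitude,
                         laterality = truth$laterality[i],
                         subject_id = truth$subject[i],
                         seed = seed + i)
      pairs[[i]] <- generate_pair(sp, excess_spec(truth$fat_excess_ml[i],
                                                  truth$fluid_excess_ml[i]))
    }
  }
  list(truth = truth, pairs = pairs)
}
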