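# Helpers building label/compartment pairs straight from ground truth.
gt_as_labels <- function(arm, idx = NULL) {
  lm <- arm$ground_truth$landmarks
  if (is.null(idx)) idx <- lm$wrist_slice:upper_arm_mark(lm)
  lab <- arm$ground_truth$labels[idx, , , drop = FALSE]
  shift <- idx[1] - 1L
  list(labels = structure(list(data = lab, model = NULL),
                          class = "tissue_labels"),
       comp = build_compartment_map(lab),
       landmarks = landmarks(1L, lm$elbow_slice - shift,
                             lm$shoulder_tip_slice - shift))
}

test_that("uniform cylinders give flat profiles equal to the cross-section", {
  arm <- generate_arm(uniform_spec())
  g <- gt_as_labels(arm)
  pr <- longitudinal_profile(g$labels, g$comp, g$landmarks)
  area <- sum(g$comp$data[1, , ] != 0L)
  expect_true(all(pr$total_ml == area / 1000))
  expect_equal(sd(pr$muscle_ml), 0)
  # per-slice total within 2% of the analytic disc area
  expect_lt(max(abs(pr$total_ml * 1000 - pi * 24^2)) / (pi * 24^2), 0.02)
})

test_that("profile sums equal the measured volumes exactly", {
  arm <- generate_arm(small_spec())
  g <- gt_as_labels(arm)
  pr <- longitudinal_profile(g$labels, g$comp, g$landmarks)
  v <- measure_volumes(g$labels, g$comp)
  expect_equal(sum(pr$muscle_ml), v[["muscle_subfascial"]])
  expect_equal(sum(pr$fat_ml), v[["fat_epifascial"]])
  expect_equal(sum(pr$fluid_ml), v[["fluid_epifascial"]])
  expect_equal(sum(pr$total_ml), v[["total_arm"]])
  # mixed voxels account for the gap between total and the tissue sum
  expect_true(all(pr$total_ml >=
                    pr$muscle_ml + pr$fat_ml + pr$fluid_ml - 1e-12))
})

test_that("tapered phantoms track the analytic disc area per slice", {
  arm <- generate_arm(uniform_spec(arm_r = NULL, n_slices = 60,
                                   arm_radius = c(18, 30),
                                   muscle_radius = c(10, 16)))
  g <- gt_as_labels(arm)
  pr <- longitudinal_profile(g$labels, g$comp, g$landmarks)
  lm <- arm$ground_truth$landmarks
  idx <- lm$wrist_slice:upper_arm_mark(lm)
  radii <- seq(18, 30, length.out = 60)[idx]
  rel <- abs(pr$total_ml * 1000 - pi * radii^2) / (pi * radii^2)
  expect_lt(max(rel), 0.02)
})

test_that("elbow alignment trims to the common extent", {
  mk_prof <- function(n, elbow) {
    df <- data.frame(slice = 1:n, muscle_ml = 0, fat_ml = 0, fluid_ml = 0,
                     epifascial_ml = 1, subfascial_ml = 1, total_ml = 2)
    attr(df, "landmarks") <- landmarks(1, elbow, n)
    class(df) <- c("longitudinal_profile", class(df))
    df
  }
  # identical arms: identity alignment
  al0 <- align_pair_at_elbow(mk_prof(100, 40), mk_prof(100, 40))
  expect_equal(nrow(al0$affected), 100)
  expect_equal(al0$elbow_pos, 40)
  # elbows at 80 and 90, lengths 200: common extent 190
  al <- align_pair_at_elbow(mk_prof(200, 80), mk_prof(200, 90))
  expect_equal(nrow(al$affected), 190)
  expect_equal(nrow(al$unaffected), 190)
  expect_equal(al$affected$slice[al$elbow_pos], 80)
  expect_equal(al$unaffected$slice[al$elbow_pos], 90)
})

test_that("aligned length equals min left spans + min right spans + 1", {
  set.seed(5)
  mk_prof <- function(n, elbow) {
    df <- data.frame(slice = 1:n, fluid_ml = 0)
    attr(df, "landmarks") <- landmarks(1, elbow, n)
    class(df) <- c("longitudinal_profile", class(df))
    df
  }
  for (i in 1:100) {
    na <- sample(50:200, 1); nu <- sample(50:200, 1)
    ea <- sample(2:(na - 1), 1); eu <- sample(2:(nu - 1), 1)
    al <- align_pair_at_elbow(mk_prof(na, ea), mk_prof(nu, eu))
    expect_equal(nrow(al$affected),
                 min(ea - 1, eu - 1) + min(na - ea, nu - eu) + 1)
    expect_equal(nrow(al$affected), nrow(al$unaffected))
  }
})

test_that("segment lengths follow the distal-first remainder rule", {
  expect_equal(lymphmap:::segment_lengths(62, 6), c(11, 11, 10, 10, 10, 10))
  expect_equal(lymphmap:::segment_lengths(60, 6), rep(10, 6))
  expect_equal(lymphmap:::segment_lengths(43, 4), c(11, 11, 11, 10))
  expect_error(lymphmap:::segment_lengths(3, 6), "fewer slices")
})

test_that("identical arms give an all-zero longitudinal excess map", {
  arm <- generate_arm(small_spec())
  g <- gt_as_labels(arm)
  pr <- longitudinal_profile(g$labels, g$comp, g$landmarks)
  lmap <- longitudinal_excess_map(align_pair_at_elbow(pr, pr))
  expect_true(all(lmap$fluid_excess_ml == 0))
  expect_true(all(lmap$fat_excess_ml == 0))
  expect_true(all(lmap$epifascial_increase_pct == 0))
  expect_true(all(lmap$fluid_norm == 0))
})

test_that("longitudinal map sums equal the global excesses exactly", {
  pair <- generate_pair(small_spec(seed = 4, in_plane = 96L),
                        excess_spec(fat_ml = 60, fluid_ml = 30))
  ga <- gt_as_labels(pair$affected); gu <- gt_as_labels(pair$unaffected)
  pa <- longitudinal_profile(ga$labels, ga$comp, ga$landmarks)
  pu <- longitudinal_profile(gu$labels, gu$comp, gu$landmarks)
  al <- align_pair_at_elbow(pa, pu)
  lmap <- longitudinal_excess_map(al)
  expect_equal(nrow(lmap), 10)
  expect_equal(sum(lmap$n_slices), nrow(al$affected))
  expect_equal(sum(lmap$fluid_excess_ml),
               sum(al$affected$fluid_ml - al$unaffected$fluid_ml))
  expect_equal(sum(lmap$fat_excess_ml),
               sum(al$affected$fat_ml - al$unaffected$fat_ml))
  # normalization: peak magnitude 1 when any excess is non-zero
  expect_equal(max(abs(lmap$fluid_norm)), 1)
  expect_true(all(abs(lmap$fat_norm) <= 1))
})

test_that("excess confined to one forearm segment lands only there", {
  spec <- small_spec(seed = 13, in_plane = 96L)
  # fluid window inside the first sixth of the forearm (wrist side)
  pair <- generate_pair(spec, excess_spec(fat_ml = 0, fluid_ml = 3,
                                          fluid_slices = 4:8))
  ga <- gt_as_labels(pair$affected); gu <- gt_as_labels(pair$unaffected)
  pa <- longitudinal_profile(ga$labels, ga$comp, ga$landmarks)
  pu <- longitudinal_profile(gu$labels, gu$comp, gu$landmarks)
  lmap <- longitudinal_excess_map(align_pair_at_elbow(pa, pu))
  expect_equal(sum(lmap$fluid_excess_ml), 3, tolerance = 1e-6)
  expect_equal(lmap$fluid_excess_ml[1], 3, tolerance = 1e-6)
  expect_true(all(lmap$fluid_excess_ml[-1] == 0))
})

test_that("the midcontour split matches brute force on random annuli", {
  set.seed(23)
  for (i in 1:20) {
    n <- 48
    c0 <- (n + 1) / 2 + runif(2, -3, 3)
    rm_ <- runif(1, 5, 10)
    ra <- rm_ + runif(1, 3, 10)
    ell <- runif(1, 0.8, 1.25)
    d2 <- outer(seq_len(n), seq_len(n), function(i_, j_)
      ((j_ - c0[1]))^2 + ((i_ - c0[2]) / ell)^2)
    cs <- matrix(0L, n, n)
    cs[d2 <= ra^2] <- 2L
    cs[d2 <= rm_^2] <- 1L
    comp3 <- array(cs, c(1, n, n)); comp3[1, , ] <- cs
    layers <- split_epifascial_layers(comp3)
    bf <- brute_force_layers(cs)
    expect_identical(layers[1, , ][bf$epi], bf$layer)
  }
})

test_that("concentric discs split at the analytic mid-radius", {
  n <- 96
  sl <- matrix(0L, n, n)
  c0 <- (n + 1) / 2
  d2 <- outer(seq_len(n), seq_len(n),
              function(i, j) (i - c0)^2 + (j - c0)^2)
  sl[d2 <= 40^2] <- 2L
  sl[d2 <= 20^2] <- 1L
  comp3 <- array(sl, c(1, n, n)); comp3[1, , ] <- sl
  layers <- split_epifascial_layers(comp3)
  r <- sqrt(d2)
  internal <- layers[1, , ] == 1L
  external <- layers[1, , ] == 2L
  expect_lt(max(r[internal]), 31)   # boundary at radius 30 +- 1 voxel
  expect_gt(min(r[external]), 29)
})

test_that("a one-voxel epifascial shell ties to internal", {
  n <- 20
  sl <- matrix(0L, n, n)
  sl[8:13, 8:13] <- 2L
  sl[9:12, 9:12] <- 1L   # epifascial = 1-voxel frame around the muscle
  comp3 <- array(sl, c(1, n, n)); comp3[1, , ] <- sl
  layers <- split_epifascial_layers(comp3)
  edge <- matrix(FALSE, n, n)
  edge[8:13, 8:13] <- TRUE
  corners <- rbind(c(8, 8), c(8, 13), c(13, 8), c(13, 13))
  # edge voxels are equidistant from fascia and skin: the tie goes internal;
  # the four frame corners are diagonal to the muscle but adjacent to the
  # outside, hence genuinely external
  ls <- layers[1, , ]
  edge_ids <- which(edge & sl == 2L, arr.ind = TRUE)
  is_corner <- paste(edge_ids[, 1], edge_ids[, 2]) %in%
    paste(corners[, 1], corners[, 2])
  expect_true(all(ls[edge_ids[!is_corner, , drop = FALSE]] == 1L))
  expect_true(all(ls[edge_ids[is_corner, , drop = FALSE]] == 2L))
})

test_that("rotationally uniform fluid fills all 8 sectors equally", {
  spec <- uniform_spec(fluid_pockets = "none")
  arm <- generate_arm(spec)
  lab <- arm$ground_truth$labels
  # make the whole external epifascial half-band fluid: rotationally uniform
  comp <- build_compartment_map(lab)
  layers <- split_epifascial_layers(comp)
  lab[layers == 2L & lab == 2L] <- 3L
  g <- list(labels = structure(list(data = lab, model = NULL),
                               class = "tissue_labels"),
            comp = comp,
            landmarks = arm$ground_truth$landmarks)
  arm0 <- gt_as_labels(arm)
  rmap <- radial_excess_map(
    list(labels = g$labels, compartments = g$comp, layers = layers,
         landmarks = landmarks(1, 30, 60)),
    list(labels = arm0$labels, compartments = arm0$comp,
         landmarks = arm0$landmarks),
    laterality = "right")
  ext <- unclass(rmap)["external", ]
  expect_lt((max(ext) - min(ext)) / mean(ext), 0.02)
})

test_that("the 16-bin radial sum equals the total fluid excess exactly", {
  pair <- generate_pair(small_spec(seed = 19, in_plane = 96L),
                        excess_spec(fat_ml = 40, fluid_ml = 30))
  ga <- gt_as_labels(pair$affected); gu <- gt_as_labels(pair$unaffected)
  rmap <- radial_excess_map(
    list(labels = ga$labels, compartments = ga$comp, landmarks = ga$landmarks),
    list(labels = gu$labels, compartments = gu$comp, landmarks = gu$landmarks))
  va <- measure_volumes(ga$labels, ga$comp)
  vu <- measure_volumes(gu$labels, gu$comp)
  expect_equal(sum(unclass(rmap)),
               va[["fluid_epifascial"]] - vu[["fluid_epifascial"]])
  expect_equal(attr(rmap, "total_excess_ml"), sum(unclass(rmap)))
})

test_that("mirrored left/right phantoms give identical radial maps", {
  mk_pair <- function(side) {
    spec <- small_spec(seed = 27, in_plane = 96L, laterality = side)
    generate_pair(spec, excess_spec(fat_ml = 30, fluid_ml = 20,
                                    fluid_angle = 300))
  }
  rmap_of <- function(pair) {
    ga <- gt_as_labels(pair$affected); gu <- gt_as_labels(pair$unaffected)
    radial_excess_map(
      list(labels = ga$labels, compartments = ga$comp, landmarks = ga$landmarks),
      list(labels = gu$labels, compartments = gu$comp, landmarks = gu$landmarks),
      laterality = pair$affected$stack$laterality)
  }
  mr <- rmap_of(mk_pair("right"))
  ml <- rmap_of(mk_pair("left"))
  expect_equal(matrix(mr, 2, 8), matrix(ml, 2, 8))
})

test_that("rendering produces PNG files with embedded peak captions", {
  pair <- generate_pair(small_spec(seed = 2, in_plane = 96L),
                        excess_spec(fat_ml = 30, fluid_ml = 15))
  ga <- gt_as_labels(pair$affected); gu <- gt_as_labels(pair$unaffected)
  pa <- longitudinal_profile(ga$labels, ga$comp, ga$landmarks)
  pu <- longitudinal_profile(gu$labels, gu$comp, gu$landmarks)
  al <- align_pair_at_elbow(pa, pu)
  lmap <- longitudinal_excess_map(al)
  rmap <- radial_excess_map(
    list(labels = ga$labels, compartments = ga$comp, landmarks = ga$landmarks),
    list(labels = gu$labels, compartments = gu$comp, landmarks = gu$landmarks))
  dir <- withr::local_tempdir()
  f1 <- save_figure(render_longitudinal_profile(al), file.path(dir, "p.png"))
  f2 <- save_figure(render_longitudinal_excess_map(lmap),
                    file.path(dir, "l.png"))
  f3 <- save_figure(render_radial_excess_map(rmap), file.path(dir, "r.png"))
  expect_true(all(file.exists(c(f1, f2, f3))))
  expect_true(all(file.size(c(f1, f2, f3)) > 1000))
  # the darkest longitudinal fluid cell is the segment holding the peak
  expect_equal(which.max(lmap$fluid_norm), which.max(lmap$fluid_excess_ml))
})
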