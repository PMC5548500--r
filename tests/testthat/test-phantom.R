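test_that("noise-free phantoms are piecewise-constant at the tissue means", {
  arm <- generate_arm(small_spec())
  gt <- arm$ground_truth
  means <- default_tissue_means()
  feats <- cbind(as.vector(arm$stack$water$data), as.vector(arm$stack$fat$data),
                 as.vector(arm$stack$stir$data))
  lab <- as.vector(gt$labels)
  for (cls in 0:4) {
    rows <- feats[lab == cls, , drop = FALSE]
    expect_true(all(sweep(rows, 2, means[cls + 1, ]) == 0),
                label = sprintf("class %d exactly at its mean triple", cls))
  }
  # perfectly separable: exactly five distinct feature triples
  expect_equal(nrow(unique(feats)), 5L)
})

test_that("phantom generation is deterministic given the seed", {
  s <- small_spec(seed = 9, noise_sd = 5, bias_amplitude = 0.1)
  a1 <- generate_arm(s); a2 <- generate_arm(s)
  expect_identical(a1$stack$water$data, a2$stack$water$data)
  expect_identical(a1$stack$stir$data, a2$stack$stir$data)
  a3 <- generate_arm(small_spec(seed = 10, noise_sd = 5, bias_amplitude = 0.1))
  expect_false(identical(a1$stack$water$data, a3$stack$water$data))
})

test_that("ground-truth volumes are exact voxel counts and conserve the grid", {
  arm <- generate_arm(small_spec())
  gt <- arm$ground_truth
  # conservation over the whole grid: the five classes partition it
  expect_equal(sum(tabulate(as.vector(gt$labels) + 1L, 5L)),
               prod(dim(gt$labels)))
  # compartment partition: subfascial + epifascial = total arm
  tv <- gt$true_volumes
  expect_equal(tv[["subfascial"]] + tv[["epifascial"]], tv[["total_arm"]])
  # fluid and fat lie only epifascially, muscle only subfascially
  expect_equal(sum(gt$labels == 3 & gt$compartments != 2), 0)
  expect_equal(sum(gt$labels == 2 & gt$compartments != 2), 0)
  expect_equal(sum(gt$labels == 1 & gt$compartments != 1), 0)
})

test_that("a single spherical fluid blob voxelises to the brute-force sphere count", {
  R <- 5  # 10 mm blob
  s0 <- 30
  spec <- uniform_spec(fluid_pockets = data.frame(
    slice = s0, angle_deg = 0, layer = "external", extent_mm = 2 * R,
    shape = "blob"))
  arm <- generate_arm(spec)
  gt <- arm$ground_truth
  # brute-force: count grid points inside the sphere around the blob centre,
  # intersected with the fat annulus (the blob is carved out of fat)
  thickness <- 24 - 14
  rc <- 14 + 0.7 * thickness
  c0 <- (72 + 1) / 2
  cx <- c0 + rc; cy <- c0
  cnt <- 0L
  for (s in 1:60) for (y in 1:72) for (x in 1:72) {
    if ((s - s0)^2 + (x - cx)^2 + (y - cy)^2 <= R^2 &&
        (x - c0)^2 + (y - c0)^2 > 14^2 && (x - c0)^2 + (y - c0)^2 <= 24^2)
      cnt <- cnt + 1L
  }
  expect_equal(sum(gt$labels == 3), cnt)
  expect_equal(unname(gt$true_volumes["fluid_epifascial"]) * 1000, cnt)
})

test_that("generated pairs realize the requested excess within voxelization error", {
  spec <- small_spec(seed = 5, in_plane = 96L)
  pair <- generate_pair(spec, excess_spec(fat_ml = 100, fluid_ml = 50))
  ga <- pair$affected$ground_truth$true_volumes
  gu <- pair$unaffected$ground_truth$true_volumes
  expect_lt(abs((ga[["fat_epifascial"]] - gu[["fat_epifascial"]]) - 100), 1)
  expect_lt(abs((ga[["fluid_epifascial"]] - gu[["fluid_epifascial"]]) - 50), 0.5)
  # muscle identical unless specified
  expect_identical(ga[["muscle_subfascial"]], gu[["muscle_subfascial"]])

  # zero-excess pair: identical ground truths (and identical noise-free stacks)
  p0 <- generate_pair(spec, excess_spec(0, 0))
  expect_identical(p0$affected$ground_truth$true_volumes,
                   p0$unaffected$ground_truth$true_volumes)
  expect_identical(p0$affected$stack$water$data, p0$unaffected$stack$water$data)
})

test_that("a fat:fluid excess ratio of 2.1 is reproduced in the ground truth", {
  pair <- generate_pair(small_spec(seed = 2, in_plane = 96L),
                        excess_spec(fat_ml = 105, fluid_ml = 50))
  ga <- pair$affected$ground_truth$true_volumes
  gu <- pair$unaffected$ground_truth$true_volumes
  ratio <- (ga[["fat_epifascial"]] - gu[["fat_epifascial"]]) /
    (ga[["fluid_epifascial"]] - gu[["fluid_epifascial"]])
  expect_lt(abs(ratio - 2.1) / 2.1, 0.02)
})

test_that("excess targets beyond the grid capacity are rejected", {
  expect_error(generate_pair(small_spec(), excess_spec(fat_ml = 5000)),
               "capacity")
})

test_that("cohort excesses carry the generating correlation sign", {
  pos <- 0L
  for (seed in 1:100) {
    tr <- generate_cohort(13, seed = seed, images = FALSE)$truth
    if (cor(tr$fat_excess_ml, tr$fluid_excess_ml) > 0) pos <- pos + 1L
  }
  expect_gte(pos, 95L)
})

test_that("cohort truth respects its clamps and degeneracy contract", {
  tr <- generate_cohort(50, seed = 4, images = FALSE)$truth
  expect_true(all(tr$fluid_excess_ml <= 0.8 * tr$fat_excess_ml + 1e-9))
  expect_true(all(tr$fat_excess_ml >= 20 & tr$fat_excess_ml <= 150))
  expect_error(generate_cohort(5, params = list(fat_sd = 0), images = FALSE),
               "degenerate")
  expect_error(generate_cohort(1, images = FALSE))
})

test_that("built cohort pairs match their truth-table targets", {
  res <- generate_cohort(2, seed = 8, images = TRUE)
  for (i in 1:2) {
    ga <- res$pairs[[i]]$affected$ground_truth$true_volumes
    gu <- res$pairs[[i]]$unaffected$ground_truth$true_volumes
    expect_lt(abs((ga[["fat_epifascial"]] - gu[["fat_epifascial"]]) -
                    res$truth$fat_excess_ml[i]) /
                res$truth$fat_excess_ml[i], 0.01)
    expect_lt(abs((ga[["fluid_epifascial"]] - gu[["fluid_epifascial"]]) -
                    res$truth$fluid_excess_ml[i]) /
                res$truth$fluid_excess_ml[i], 0.01)
  }
})

test_that("honeycomb fluid interleaves with fat on the lattice", {
  spec <- uniform_spec(honeycomb = TRUE, fluid_pockets = data.frame(
    slice = 30, angle_deg = 0, layer = "external", extent_mm = 40,
    shape = "annulus_sector"))
  arm <- generate_arm(spec)
  lab <- arm$ground_truth$labels
  idx <- which(lab == 3, arr.ind = TRUE)
  expect_gt(nrow(idx), 100)
  expect_true(all((idx[, 1] + idx[, 2] + idx[, 3]) %% 2 == 0))
})

test_that("phantom specs validate geometry and contrast", {
  expect_error(phantom_spec(arm_radius = c(20, 20), muscle_radius = c(20, 25)),
               "strictly below")
  bad <- default_tissue_means()
  bad["fluid", "stir"] <- 40  # interstitial (50) now beats fluid on STIR
  expect_error(small_spec(tissue_means = bad), "contrast")
})
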