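make_maps <- function() {
  arm <- generate_arm(small_spec())
  lm <- arm$ground_truth$landmarks
  idx <- lm$wrist_slice:upper_arm_mark(lm)  # true volumes span this extent
  lab <- arm$ground_truth$labels[idx, , , drop = FALSE]
  labels <- structure(list(data = lab, model = NULL), class = "tissue_labels")
  comp <- build_compartment_map(lab)
  list(arm = arm, labels = labels, comp = comp, n = length(idx))
}

test_that("volumes are voxel counts at 0.001 mL per voxel", {
  lab <- array(0L, c(10, 20, 20))
  cp <- array(0L, c(10, 20, 20))
  lab[1:5, 1:10, 1:20] <- 2L  # 1000 fat voxels
  cp[1:5, 1:10, 1:20] <- 2L   # all epifascial
  v <- measure_volumes(lab, cp)
  expect_equal(v[["fat_epifascial"]], 1.0)
  expect_equal(v[["fluid_epifascial"]], 0)
  expect_equal(v[["total_arm"]], 1.0)
  expect_error(measure_volumes(lab, array(0L, c(9, 20, 20))), "shape")
})

test_that("tissue volumes are restricted to their compartment", {
  lab <- array(0L, c(4, 10, 10))
  cp <- array(0L, c(4, 10, 10))
  lab[1, 1, 1] <- 3L; cp[1, 1, 1] <- 1L   # fluid voxel inside subfascial
  lab[1, 1, 2] <- 1L; cp[1, 1, 2] <- 2L   # muscle voxel inside epifascial
  lab[1, 1, 3] <- 4L; cp[1, 1, 3] <- 2L   # mixed voxel: compartment only
  v <- measure_volumes(lab, cp)
  expect_equal(v[["fluid_epifascial"]], 0)
  expect_equal(v[["muscle_subfascial"]], 0)
  expect_equal(v[["subfascial"]], 0.001)
  expect_equal(v[["epifascial"]], 0.002)
})

test_that("phantom volumes match ground truth and satisfy the invariants", {
  mm <- make_maps()
  v <- measure_volumes(mm$labels, mm$comp)
  expect_rel_error(unclass(v), mm$arm$ground_truth$true_volumes, 0.02)
  expect_equal(v[["subfascial"]] + v[["epifascial"]], v[["total_arm"]])
  expect_lte(v[["muscle_subfascial"]], v[["subfascial"]])
  expect_lte(v[["fat_epifascial"]] + v[["fluid_epifascial"]],
             v[["epifascial"]])
})

test_that("volumes are additive over disjoint slice partitions", {
  mm <- make_maps()
  v_all <- measure_volumes(mm$labels, mm$comp)
  cuts <- list(1:20, 21:47, 48:mm$n)
  parts <- lapply(cuts, function(idx)
    measure_volumes(mm$labels$data[idx, , , drop = FALSE],
                    mm$comp$data[idx, , , drop = FALSE]))
  expect_equal(Reduce(`+`, lapply(parts, unclass)), unclass(v_all))
})

test_that("arm comparison implements the excess and percent-change formulas", {
  mk <- function(...) structure(c(...), class = "compartment_volumes")
  nm <- c("total_arm", "subfascial", "epifascial", "muscle_subfascial",
          "fat_epifascial", "fluid_epifascial")
  a <- mk(stats::setNames(c(150, 50, 100, 45, 70, 20), nm))
  u <- mk(stats::setNames(c(100, 48, 52, 44, 40, 5), nm))
  cmp <- compare_arms(a, u)
  tab <- cmp$table
  expect_equal(tab$excess_ml[tab$metric == "total_arm"], 50)
  expect_equal(tab$percent_change[tab$metric == "total_arm"], 50)
  # fat affected = 1.96 x fat unaffected -> +96%
  a2 <- mk(stats::setNames(c(150, 50, 100, 45, 1.96 * 40, 20), nm))
  cmp2 <- compare_arms(a2, u)
  expect_equal(cmp2$table$percent_change[cmp2$table$metric == "fat_epifascial"],
               96)
  # relative excess uses the unaffected epifascial volume as denominator
  expect_equal(cmp$relative_excess[["epifascial"]], (100 - 52) / 52)
  expect_equal(cmp$relative_excess[["fat"]], (70 - 40) / 52)

  # equal arms: all zero excesses and 0% changes
  cmp0 <- compare_arms(u, u)
  expect_true(all(cmp0$table$excess_ml == 0))
  expect_true(all(cmp0$table$percent_change == 0))

  # zero unaffected volume: percent change missing, not infinite
  u0 <- mk(stats::setNames(c(100, 48, 52, 44, 40, 0), nm))
  cmp3 <- compare_arms(a, u0)
  expect_true(is.na(
    cmp3$table$percent_change[cmp3$table$metric == "fluid_epifascial"]))
})

test_that("excesses are antisymmetric under swapping the arms", {
  mm <- make_maps()
  v1 <- measure_volumes(mm$labels, mm$comp)
  v2 <- structure(unclass(v1) * c(1.3, 1.05, 1.45, 1.02, 1.5, 2),
                  class = "compartment_volumes")
  e12 <- compare_arms(v1, v2)$table$excess_ml
  e21 <- compare_arms(v2, v1)$table$excess_ml
  expect_equal(e12, -e21)
})

test_that("the epifascial share of excess follows its definition", {
  mk <- function(v) structure(stats::setNames(v, c(
    "total_arm", "subfascial", "epifascial", "muscle_subfascial",
    "fat_epifascial", "fluid_epifascial")), class = "compartment_volumes")
  u <- mk(c(100, 40, 60, 38, 30, 5))
  a <- mk(c(200, 46, 154, 40, 80, 30))
  cmp <- compare_arms(a, u)
  expect_equal(epifascial_share_of_excess(cmp), 94 / 100)
  a2 <- mk(c(160, 40, 120, 38, 60, 20))  # subfascial excess 0 -> share 1
  expect_equal(epifascial_share_of_excess(compare_arms(a2, u)), 1.0)
  expect_error(epifascial_share_of_excess(compare_arms(u, u)), "zero")
})

test_that("injected pair excesses give the ground-truth epifascial share", {
  pair <- generate_pair(small_spec(seed = 6, in_plane = 96L),
                        excess_spec(fat_ml = 80, fluid_ml = 40))
  ga <- pair$affected$ground_truth$true_volumes
  gu <- pair$unaffected$ground_truth$true_volumes
  mk <- function(v) structure(v, class = "compartment_volumes")
  share <- epifascial_share_of_excess(compare_arms(mk(ga), mk(gu)))
  # all injected excess is epifascial by construction
  expect_lt(abs(share - 1.0), 0.03)
})

test_that("volume CSV export round-trips", {
  mm <- make_maps()
  v <- measure_volumes(mm$labels, mm$comp)
  p <- withr::local_tempfile(fileext = ".csv")
  write_volumes_csv(v, p, metadata = list(subject = "S1", status = "affected"))
  df <- read.csv(p)
  expect_equal(df$fat_epifascial, v[["fat_epifascial"]])
  expect_equal(df$subject, "S1")
})
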