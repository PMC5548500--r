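# Shared fixtures: small phantoms keep the unit tests fast; the acceptance
# suite uses the full-size default spec.

small_spec <- function(seed = 3, ...) {
  args <- list(n_slices = 80L, in_plane = 72L, arm_radius = c(20, 28),
               muscle_radius = c(12, 17), seed = seed)
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

# A uniform (untapered, circular) cylinder with no fluid and no vessels:
# analytically tractable geometry.
uniform_spec <- function(seed = 1, arm_r = 24, muscle_r = 14, ...) {
  args <- list(n_slices = 60L, in_plane = 72L, arm_radius = c(arm_r, arm_r),
               muscle_radius = c(muscle_r, muscle_r), fluid_pockets = "none",
               interstitial = data.frame(angle_deg = numeric(),
                                         pos = numeric(), radius_mm = numeric(),
                                         compartment = character()),
               seed = seed)
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

# Brute-force within-cluster sum of squares optimum over all 2-partitions.
brute_force_wcss_k2 <- function(X) {
  n <- nrow(X)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {   # point 1 fixed in group A; both non-empty
    grp <- as.logical(bitwAnd(code, 2^(seq_len(n - 1) - 1)))
    g <- c(FALSE, grp)
    w <- 0
    for (side in list(X[g, , drop = FALSE], X[!g, , drop = FALSE]))
      w <- w + sum(sweep(side, 2, colMeans(side))^2)
    best <- min(best, w)
  }
  best
}

# Exhaustive nearest-boundary layer split for one slice (full target sets,
# no boundary-ring reduction): the independent oracle for the midcontour.
brute_force_layers <- function(comp_slice) {
  epi <- which(comp_slice == 2L)
  sub <- which(comp_slice == 1L)
  out <- which(comp_slice == 0L)
  ny <- nrow(comp_slice)
  xy <- function(idx) cbind(((idx - 1L) %% ny) + 1L, ((idx - 1L) %/% ny) + 1L)
  qe <- xy(epi); qs <- xy(sub); qo <- xy(out)
  res <- integer(length(epi))
  for (i in seq_along(epi)) {
    df <- min((qe[i, 1] - qs[, 1])^2 + (qe[i, 2] - qs[, 2])^2)
    do <- min((qe[i, 1] - qo[, 1])^2 + (qe[i, 2] - qo[, 2])^2)
    res[i] <- if (df <= do) 1L else 2L
  }
  list(epi = epi, layer = res)
}

expect_rel_error <- function(measured, truth, tol) {
  expect_lt(max(abs(measured - truth) / pmax(abs(truth), 1e-12)), tol)
}
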