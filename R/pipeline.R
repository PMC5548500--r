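#' Pipeline configuration
#'
#' Collects the tunable parameters of the whole workflow. A run's config and
#' seed reproduce its outputs exactly.
#'
#' @param k number of k-means clusters.
#' @param seed master seed; every stochastic step derives from it.
#' @param nstart,max_iter,tol,fit_sample,standardize see [fit_kmeans()].
#' @param r_close,r_fascia closing radii (mm), see [build_slice_masks()].
#' @param forearm_segments,upperarm_segments longitudinal map segments.
#' @param verbose if `TRUE`, per-stage progress messages are emitted.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(k = 5L, seed = 42L, nstart = 60L, max_iter = 300L,
                            tol = 1e-4, fit_sample = 30000L,
                            standardize = FALSE, r_close = 3, r_fascia = 5,
                            forearm_segments = 6L, upperarm_segments = 4L,
                            verbose = FALSE) {
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 nstart = as.integer(nstart), max_iter = as.integer(max_iter),
                 tol = tol, fit_sample = fit_sample, standardize = standardize,
                 r_close = r_close, r_fascia = r_fascia,
                 forearm_segments = as.integer(forearm_segments),
                 upperarm_segments = as.integer(upperarm_segments),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

say <- function(config, ...) if (config$verbose) message(sprintf(...))

#' Process one arm: crop, segment, contour, measure
#'
#' Runs the three workflow steps on one arm: (1) crop to the analysis extent
#' between the wrist and the 65% upper-arm mark (input is expected at 1 mm
#' isotropic resolution, as produced by [read_channel_stack()] or the
#' phantom generator); (2) k-means segmentation of the three-channel feature
#' space with cluster-to-tissue assignment; (3) per-slice external/fascial
#' contouring into compartments. Logs per-stage voxel accounting and QC
#' flags (empty muscle masks, subfascial fluid) when `config$verbose`.
#'
#' @param stack a [channel_stack()] at 1 mm isotropic resolution.
#' @param lm [landmarks()] in the stack's slice coordinates.
#' @param config a [pipeline_config()].
#' @param outdir if non-`NULL`, label/compartment NIfTIs, the volumes CSV,
#'   the profile CSV and the cluster model JSON are written there.
#' @return A list of class `arm_result`: `labels`, `compartments`, `layers`,
#'   `volumes`, `profile`, `landmarks` (cropped coordinates), `model`,
#'   `stack` metadata.
#' @export
run_arm <- function(stack, lm, config = pipeline_config(), outdir = NULL) {
  stopifnot(is.channel_stack(stack), inherits(lm, "landmarks"),
            inherits(config, "pipeline_config"))
  cropped <- crop_to_analysis_extent(stack, lm)
  say(config, "[%s/%s] cropped to %d slices", stack$subject_id, stack$status,
      stack_dim(cropped$stack)[1])
  model <- fit_kmeans(cropped$stack, k = config$k, seed = config$seed,
                      nstart = config$nstart, max_iter = config$max_iter,
                      tol = config$tol, fit_sample = config$fit_sample,
                      standardize = config$standardize)
  model <- assign_tissue_classes(model)
  labels <- segment(cropped$stack, model)
  counts <- tabulate(as.vector(labels$data) + 1L, 5L)
  say(config, "  label counts noise/muscle/fat/fluid/mixed: %s",
      paste(counts, collapse = "/"))
  comp <- build_compartment_map(labels, config$r_close, config$r_fascia)
  if (any(comp$muscle_empty))
    say(config, "  QC: %d slice(s) with empty muscle mask", sum(comp$muscle_empty))
  if (comp$subfascial_fluid_voxels > 0)
    say(config, "  QC: %d fluid voxel(s) in the subfascial compartment",
        comp$subfascial_fluid_voxels)
  layers <- split_epifascial_layers(comp)
  volumes <- measure_volumes(labels, comp)
  profile <- longitudinal_profile(labels, comp, cropped$landmarks)
  res <- structure(list(labels = labels, compartments = comp, layers = layers,
                        volumes = volumes, profile = profile,
                        landmarks = cropped$landmarks, model = model,
                        subject_id = stack$subject_id, status = stack$status,
                        laterality = stack$laterality),
                   class = "arm_result")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    tag <- paste0(stack$subject_id, "_", stack$status)
    write_label_map(labels, file.path(outdir, paste0(tag, "_labels.nii.gz")))
    write_label_map(comp, file.path(outdir, paste0(tag, "_compartments.nii.gz")))
    write_cluster_model(model, file.path(outdir, paste0(tag, "_model.json")))
    write_volumes_csv(volumes, file.path(outdir, paste0(tag, "_volumes.csv")),
                      metadata = list(subject = stack$subject_id,
                                      status = stack$status,
                                      laterality = stack$laterality))
    write.csv(profile, file.path(outdir, paste0(tag, "_profile.csv")),
              row.names = FALSE)
  }
  res
}

#' Process an affected/unaffected pair
#'
#' Runs [run_arm()] on both arms, aligns the profiles at the elbow, and
#' produces the pair comparison, the 10-segment longitudinal excess map and
#' the 16-segment radial fluid-excess map, plus rendered figures when
#' requested.
#'
#' @param stack_affected,stack_unaffected [channel_stack()]s at 1 mm.
#' @param lm_affected,lm_unaffected corresponding [landmarks()].
#' @param config a [pipeline_config()].
#' @param outdir if non-`NULL`, per-arm outputs, the comparison CSV, the map
#'   CSVs/JSON and PNG figures are written there.
#' @param render if `TRUE` (and `outdir` given), PNG figures are written.
#' @return A list of class `pair_result`: both `arm_result`s, `comparison`,
#'   `longitudinal_map`, `radial_map`, `aligned`.
#' @export
run_pair <- function(stack_affected, lm_affected, stack_unaffected,
                     lm_unaffected, config = pipeline_config(), outdir = NULL,
                     render = !is.null(outdir)) {
  if (stack_affected$status != "affected" ||
      stack_unaffected$status != "unaffected")
    stopf("stacks must carry status 'affected' and 'unaffected'")
  arm_a <- run_arm(stack_affected, lm_affected, config, outdir)
  arm_u <- run_arm(stack_unaffected, lm_unaffected, config, outdir)
  aligned <- align_pair_at_elbow(arm_a$profile, arm_u$profile)
  comparison <- compare_arms(arm_a$volumes, arm_u$volumes)
  lmap <- longitudinal_excess_map(aligned, config$forearm_segments,
                                  config$upperarm_segments)
  rmap <- radial_excess_map(
    list(labels = arm_a$labels, compartments = arm_a$compartments,
         layers = arm_a$layers, landmarks = arm_a$landmarks),
    list(labels = arm_u$labels, compartments = arm_u$compartments,
         layers = arm_u$layers, landmarks = arm_u$landmarks),
    laterality = stack_affected$laterality)
  res <- structure(list(affected = arm_a, unaffected = arm_u,
                        comparison = comparison, longitudinal_map = lmap,
                        radial_map = rmap, aligned = aligned,
                        subject_id = stack_affected$subject_id),
                   class = "pair_result")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    tag <- stack_affected$subject_id
    write_volumes_csv(comparison,
                      file.path(outdir, paste0(tag, "_comparison.csv")),
                      metadata = list(subject = tag))
    write.csv(as.data.frame(lmap),
              file.path(outdir, paste0(tag, "_longitudinal_map.csv")),
              row.names = FALSE)
    write.csv(as.data.frame(unclass(rmap)),
              file.path(outdir, paste0(tag, "_radial_map.csv")),
              row.names = FALSE)
    jsonlite::write_json(
      list(subject = tag, laterality = stack_affected$laterality,
           torso_side = "right",
           longitudinal_peaks = as.list(attr(lmap, "peaks")),
           radial_peak_ml = attr(rmap, "peak"),
           radial_total_excess_ml = attr(rmap, "total_excess_ml")),
      file.path(outdir, paste0(tag, "_maps.json")), auto_unbox = TRUE,
      digits = NA)
    if (render) {
      save_figure(render_longitudinal_profile(aligned),
                  file.path(outdir, paste0(tag, "_profile.png")), 8, 4)
      save_figure(render_longitudinal_excess_map(lmap),
                  file.path(outdir, paste0(tag, "_longitudinal_map.png")), 7, 3)
      save_figure(render_radial_excess_map(rmap),
                  file.path(outdir, paste0(tag, "_radial_map.png")), 5, 5)
    }
  }
  res
}

#' Process a cohort of pairs
#'
#' Runs [run_pair()] on every pair, assembles the per-subject cohort table
#' (six volumes per arm, excesses, relative excesses) and the statistics
#' report, and optionally writes the cohort CSV, report and a map-array
#' figure (one row per subject).
#'
#' @param pairs list of pairs; each element is a list with `affected` and
#'   `unaffected`, each carrying `stack` and `landmarks` (or a
#'   [generate_pair()] result, whose ground-truth landmarks are used).
#' @param config a [pipeline_config()].
#' @param outdir if non-`NULL`, outputs are written there.
#' @return A list of class `cohort_result`: `table` (per-subject data
#'   frame), `report` (a [cohort_report()]), `pair_results`.
#' @export
run_cohort <- function(pairs, config = pipeline_config(), outdir = NULL) {
  if (length(pairs) < 3) stopf("a cohort needs at least 3 pairs")
  get_lm <- function(arm) arm$landmarks %||% arm$ground_truth$landmarks
  results <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    say(config, "cohort subject %d/%d", i, length(pairs))
    run_pair(p$affected$stack, get_lm(p$affected), p$unaffected$stack,
             get_lm(p$unaffected), config, outdir = NULL, render = FALSE)
  })
  rows <- lapply(results, function(r) {
    a <- unclass(r$affected$volumes); u <- unclass(r$unaffected$volumes)
    row <- data.frame(subject = r$subject_id,
                      laterality = r$affected$laterality)
    for (m in names(a)) {
      row[[paste0(m, "_affected_ml")]] <- a[[m]]
      row[[paste0(m, "_unaffected_ml")]] <- u[[m]]
    }
    row$total_excess_ml <- a[["total_arm"]] - u[["total_arm"]]
    row$epifascial_excess_ml <- a[["epifascial"]] - u[["epifascial"]]
    row$fat_excess_ml <- a[["fat_epifascial"]] - u[["fat_epifascial"]]
    row$fluid_excess_ml <- a[["fluid_epifascial"]] - u[["fluid_epifascial"]]
    row$epifascial_unaffected_ml <- u[["epifascial"]]
    row
  })
  tab <- relative_excess_table(do.call(rbind, rows))
  report <- cohort_report(tab)
  res <- structure(list(table = tab, report = report, pair_results = results),
                   class = "cohort_result")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write.csv(tab, file.path(outdir, "cohort.csv"), row.names = FALSE)
    write_cohort_report(report, file.path(outdir, "cohort_report.json"),
                        file.path(outdir, "cohort_report.txt"))
    save_figure(render_cohort_array(results),
                file.path(outdir, "cohort_maps.png"), 9,
                1.4 * length(results) + 1)
  }
  res
}
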