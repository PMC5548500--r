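# Figure rendering. Colour coding follows the longitudinal-plot convention:
# muscle red, epifascial fat yellow, epifascial fluid blue, total arm as a
# green line; darker map colours indicate greater values, normalized to the
# per-patient peak of each measure (peaks are embedded in the captions so
# absolute values stay recoverable).

tissue_fill <- c(muscle = "#c0392b", fat = "#f1c40f", fluid = "#2980b9")

#' Render an aligned pair of longitudinal tissue-volume plots
#'
#' @param aligned an [align_pair_at_elbow()] result (a single
#'   [longitudinal_profile()] also works).
#' @return A ggplot object.
#' @export
render_longitudinal_profile <- function(aligned) {
  frames <- if (inherits(aligned, "aligned_pair"))
    list(affected = aligned$affected, unaffected = aligned$unaffected)
  else list(arm = aligned)
  elbow <- if (inherits(aligned, "aligned_pair")) aligned$elbow_pos
  else attr(aligned, "landmarks")$elbow_slice
  long <- do.call(rbind, lapply(names(frames), function(nm) {
    f <- frames[[nm]]
    pos <- seq_len(nrow(f))
    rbind(data.frame(arm = nm, pos = pos, tissue = "muscle", ml = f$muscle_ml),
          data.frame(arm = nm, pos = pos, tissue = "fat", ml = f$fat_ml),
          data.frame(arm = nm, pos = pos, tissue = "fluid", ml = f$fluid_ml))
  }))
  totals <- do.call(rbind, lapply(names(frames), function(nm)
    data.frame(arm = nm, pos = seq_len(nrow(frames[[nm]])),
               ml = frames[[nm]]$total_ml)))
  ggplot2::ggplot(long, ggplot2::aes(x = pos, y = ml)) +
    ggplot2::geom_area(ggplot2::aes(fill = tissue), alpha = 0.85,
                       position = "identity") +
    ggplot2::geom_line(data = totals, colour = "#1e8449", linewidth = 0.7) +
    ggplot2::geom_vline(xintercept = elbow, colour = "black",
                        linetype = "solid") +
    ggplot2::scale_fill_manual(values = tissue_fill) +
    ggplot2::facet_wrap(~arm, ncol = 2) +
    ggplot2::labs(x = "slice (wrist → shoulder, elbow marked)",
                  y = "volume (mL/slice)",
                  title = "Longitudinal tissue volumes") +
    ggplot2::theme_minimal()
}

#' Render a longitudinal excess-volume intensity map
#'
#' One row per measure (fluid blue, fat orange, epifascial increase green),
#' darker colour for greater values; intensities are normalized to the peak
#' of each measure, which is reported in the caption.
#'
#' @param lmap a [longitudinal_excess_map()] result.
#' @return A ggplot object.
#' @export
render_longitudinal_excess_map <- function(lmap) {
  peaks <- attr(lmap, "peaks")
  df <- rbind(
    data.frame(measure = "fluid", segment = lmap$segment, v = lmap$fluid_norm),
    data.frame(measure = "fat", segment = lmap$segment, v = lmap$fat_norm),
    data.frame(measure = "epifascial", segment = lmap$segment,
               v = lmap$epifascial_norm))
  df$measure <- factor(df$measure, c("epifascial", "fat", "fluid"))
  pal <- c(fluid = "#2166ac", fat = "#e08214", epifascial = "#1b7837")
  df$col <- unname(pal[as.character(df$measure)])
  ggplot2::ggplot(df, ggplot2::aes(x = segment, y = measure)) +
    ggplot2::geom_tile(ggplot2::aes(fill = col, alpha = pmax(v, 0)),
                       colour = "grey30") +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_alpha_identity() +
    ggplot2::scale_x_continuous(breaks = lmap$segment) +
    ggplot2::labs(
      x = "segment (1-6 forearm, 7-10 upper arm)", y = NULL,
      title = "Longitudinal excess-volume map",
      caption = sprintf("peaks: fluid %.1f mL, fat %.1f mL, epifascial %.1f%%",
                        peaks["fluid"], peaks["fat"], peaks["epifascial"])) +
    ggplot2::theme_minimal()
}

#' Render a radial fluid-excess intensity map
#'
#' Wedge plot of the 16 segments (8 external below the skin, 8 internal
#' above the muscle); the torso-facing side is on the right. Darker blue
#' indicates greater fluid excess; the peak is reported in the caption.
#'
#' @param rmap a [radial_excess_map()] result.
#' @return A ggplot object.
#' @export
render_radial_excess_map <- function(rmap) {
  peak <- attr(rmap, "peak")
  m <- unclass(rmap)
  df <- expand.grid(layer = c("internal", "external"), sector = 1:8)
  df$v <- mapply(function(l, s) m[l, s], as.character(df$layer), df$sector)
  df$vnorm <- if (peak > 0) df$v / peak else 0
  df$r0 <- ifelse(df$layer == "internal", 1, 2)
  df$a0 <- (df$sector - 1) * 45
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = a0, xmax = a0 + 45,
                                    ymin = r0, ymax = r0 + 1,
                                    alpha = pmax(vnorm, 0)),
                       fill = "#2166ac", colour = "grey30") +
    ggplot2::scale_alpha_identity() +
    ggplot2::coord_polar(theta = "x", start = pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360)) +
    ggplot2::scale_y_continuous(limits = c(0, 3)) +
    ggplot2::labs(title = "Radial fluid-excess map",
                  caption = sprintf("torso side right; peak %.2f mL", peak)) +
    ggplot2::theme_void() +
    ggplot2::theme(plot.title = ggplot2::element_text(hjust = 0.5))
}

#' Render the cohort map array (one row per subject)
#'
#' @param pair_results list of [run_pair()] results.
#' @return A ggplot object combining the longitudinal maps of all subjects.
#' @export
render_cohort_array <- function(pair_results) {
  df <- do.call(rbind, lapply(pair_results, function(r) {
    lm <- r$longitudinal_map
    rbind(data.frame(subject = r$subject_id, measure = "fluid",
                     segment = lm$segment, v = lm$fluid_norm),
          data.frame(subject = r$subject_id, measure = "fat",
                     segment = lm$segment, v = lm$fat_norm),
          data.frame(subject = r$subject_id, measure = "epifascial",
                     segment = lm$segment, v = lm$epifascial_norm))
  }))
  pal <- c(fluid = "#2166ac", fat = "#e08214", epifascial = "#1b7837")
  df$col <- unname(pal[df$measure])
  ggplot2::ggplot(df, ggplot2::aes(x = segment, y = subject)) +
    ggplot2::geom_tile(ggplot2::aes(fill = col, alpha = pmax(v, 0)),
                       colour = "grey40") +
    ggplot2::scale_fill_identity() + ggplot2::scale_alpha_identity() +
    ggplot2::facet_wrap(~measure, ncol = 3) +
    ggplot2::labs(x = "segment", y = NULL,
                  title = "Cohort excess-volume maps (per-subject peak normalization)") +
    ggplot2::theme_minimal()
}

#' Save a ggplot figure as PNG
#'
#' @param plot ggplot object.
#' @param path output path.
#' @param width,height size in inches.
#' @return Invisibly, `path`.
#' @export
save_figure <- function(plot, path, width = 7, height = 5) {
  grDevices::png(path, width = width * 100, height = height * 100, res = 100)
  print(plot)
  grDevices::dev.off()
  invisible(path)
}

utils::globalVariables(c("pos", "ml", "tissue", "measure", "v", "col",
                         "vnorm", "a0", "r0", "segment", "subject"))
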