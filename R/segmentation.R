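# Tissue label codes shared with the phantom ground truth:
# 0 noise/background, 1 muscle, 2 fat, 3 fluid, 4 mixed/interstitial.
TISSUE_CLASSES <- c(noise = 0L, muscle = 1L, fat = 2L, fluid = 3L, mixed = 4L)

#' Fit a k-means cluster model in the three-channel feature space
#'
#' Voxel intensities of the Dixon-water, Dixon-fat and STIR channels form a
#' 3D feature space that is partitioned into `k` clusters (default 5: muscle,
#' fat and fluid, plus image noise and mixed-composition voxels at tissue
#' interfaces). Lloyd's algorithm is run to convergence (largest centroid
#' shift below `tol`, expressed relative to the data range, or `max_iter`
#' sweeps) from k-means++ seedings; with `nstart > 1` the restart with the
#' lowest within-cluster sum of squares is kept. Deterministic given `seed`;
#' nearest-centroid ties go to the lowest cluster index.
#'
#' For very large volumes the centroids are fitted on a deterministic random
#' subsample of `fit_sample` voxels (full-volume assignment still happens in
#' [segment()]); set `fit_sample = Inf` to always fit on every voxel.
#'
#' @param stack a [channel_stack()] (or an n x 3 feature matrix).
#' @param k number of clusters (>= 2; the workflow uses 5).
#' @param seed integer seed for initialization.
#' @param nstart number of k-means++ restarts.
#' @param max_iter maximum Lloyd sweeps.
#' @param tol convergence tolerance in normalized intensity units (scaled by
#'   the feature range).
#' @param fit_sample voxel budget for the fitting subsample.
#' @param standardize if `TRUE`, channels are standardized (z-scored) before
#'   clustering; the default operates on raw intensities.
#' @return An object of class `cluster_model`: centroids (k x 3), WCSS, the
#'   seed, and (once [assign_tissue_classes()] has run) the cluster-to-tissue
#'   assignment.
#' @export
fit_kmeans <- function(stack, k = 5L, seed = 1L, nstart = 60L, max_iter = 300L,
                       tol = 1e-4, fit_sample = 30000L, standardize = FALSE) {
  X <- if (is.channel_stack(stack)) stack_features(stack) else {
    stopifnot(is.matrix(stack), ncol(stack) == 3L)
    colnames(stack) <- c("water", "fat", "stir")
    stack
  }
  stopifnot(is_count(k), k >= 2)
  scale_center <- c(0, 0, 0); scale_sd <- c(1, 1, 1)
  if (standardize) {
    scale_center <- colMeans(X)
    scale_sd <- pmax(apply(X, 2, sd), .Machine$double.eps)
    X <- sweep(sweep(X, 2, scale_center), 2, scale_sd, `/`)
  }
  if (nrow(X) < k) stopf("fewer points (%d) than clusters (%d)", nrow(X), k)
  fit <- with_seed(seed, {
    Xfit <- X
    subsampled <- nrow(X) > fit_sample
    if (subsampled)
      Xfit <- X[sample.int(nrow(X), fit_sample), , drop = FALSE]
    tol_abs <- tol * max(diff(range(Xfit)), .Machine$double.eps)
    best <- NULL
    for (r in seq_len(nstart)) {
      init <- cpp_kmeanspp_init(Xfit, k)
      if (isTRUE(attr(init, "degenerate")))
        stopf("fewer than k = %d distinct feature vectors", k)
      res <- cpp_lloyd(Xfit, init, max_iter, tol_abs)
      if (is.null(best) || res$wcss < best$wcss) best <- res
    }
    # when fitted on a subsample, polish the winning centroids with Lloyd
    # sweeps over the full feature space
    if (subsampled) best <- cpp_lloyd(X, best$centers, max_iter, tol_abs)
    # on tiny problems, additionally sweep every k-subset of the points as
    # an initialization: deterministic and, in practice, globally optimal
    if (nrow(Xfit) <= 50 && choose(nrow(Xfit), k) <= 500) {
      cmb <- utils::combn(nrow(Xfit), k)
      for (j in seq_len(ncol(cmb))) {
        res <- cpp_lloyd(Xfit, Xfit[cmb[, j], , drop = FALSE], max_iter,
                         tol_abs)
        if (res$wcss < best$wcss) best <- res
      }
    }
    best
  })
  centroids <- fit$centers
  attr(centroids, "degenerate") <- NULL
  dimnames(centroids) <- list(paste0("cluster", seq_len(k)),
                              c("water", "fat", "stir"))
  structure(list(k = as.integer(k), centroids = centroids, wcss = fit$wcss,
                 iter = fit$iter, seed = as.integer(seed),
                 standardize = standardize, scale_center = scale_center,
                 scale_sd = scale_sd, assignment = NULL),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d, WCSS = %.4g, seed = %d\n",
              x$k, x$wcss, x$seed))
  tab <- as.data.frame(round(x$centroids, 2))
  if (!is.null(x$assignment)) tab$tissue <- x$assignment
  print(tab)
  invisible(x)
}

#' Map clusters to tissue classes
#'
#' Labels the five clusters by centroid dominance, in fixed priority order:
#' noise is the centroid with the smallest channel sum (voxels contributing
#' no signal); among the remainder, fat has the largest Dixon-fat value,
#' fluid the largest STIR value, muscle the largest Dixon-water value; the
#' last centroid is the mixed-composition cluster. Ties at any step are
#' broken deterministically by the lower cluster index. The assignment is a
#' bijection onto \{noise, muscle, fat, fluid, mixed\}.
#'
#' @param model a fitted [fit_kmeans()] model with `k = 5`.
#' @return The model with its `assignment` field set (character vector of
#'   length 5, tissue class per cluster index).
#' @export
assign_tissue_classes <- function(model) {
  stopifnot(inherits(model, "cluster_model"))
  if (model$k != 5L)
    stopf("tissue assignment is defined for k = 5 (got k = %d)", model$k)
  C <- model$centroids
  remaining <- 1:5
  assignment <- character(5)
  pick <- function(score) {
    i <- remaining[which.max(score[remaining])]  # which.max: lowest index wins
    i
  }
  i <- remaining[which.min(rowSums(C)[remaining])]
  assignment[i] <- "noise"; remaining <- setdiff(remaining, i)
  i <- pick(C[, "fat"]); assignment[i] <- "fat"; remaining <- setdiff(remaining, i)
  i <- pick(C[, "stir"]); assignment[i] <- "fluid"; remaining <- setdiff(remaining, i)
  i <- pick(C[, "water"]); assignment[i] <- "muscle"; remaining <- setdiff(remaining, i)
  assignment[remaining] <- "mixed"
  model$assignment <- assignment
  model
}

#' Segment a stack into tissue classes
#'
#' Labels every voxel with the tissue class of its nearest centroid
#' (Euclidean distance; ties to the lowest cluster index). The five labels
#' partition the volume.
#'
#' @param stack a [channel_stack()].
#' @param model a [fit_kmeans()] model; if its tissue assignment is missing,
#'   [assign_tissue_classes()] is applied first.
#' @return An object of class `tissue_labels`: integer 3D array `data` with
#'   codes 0 noise, 1 muscle, 2 fat, 3 fluid, 4 mixed, plus the model as
#'   provenance.
#' @export
segment <- function(stack, model) {
  stopifnot(is.channel_stack(stack), inherits(model, "cluster_model"))
  if (is.null(model$assignment)) model <- assign_tissue_classes(model)
  X <- stack_features(stack)
  if (model$standardize)
    X <- sweep(sweep(X, 2, model$scale_center), 2, model$scale_sd, `/`)
  cl <- cpp_assign(X, model$centroids)
  codes <- TISSUE_CLASSES[model$assignment]
  structure(list(data = array(codes[cl], stack_dim(stack)), model = model),
            class = "tissue_labels")
}

#' @export
print.tissue_labels <- function(x, ...) {
  cat(sprintf("<tissue_labels> %s voxels\n", paste(dim(x$data), collapse = "x")))
  tab <- tabulate(as.vector(x$data) + 1L, 5L)
  names(tab) <- names(TISSUE_CLASSES)
  print(tab)
  invisible(x)
}

#' Write a tissue label map as NIfTI plus a JSON legend
#'
#' @param labels a [segment()] result.
#' @param path output NIfTI path (a `.json` legend is written alongside).
#' @return Invisibly, `path`.
#' @export
write_label_map <- function(labels, path) {
  stopifnot(inherits(labels, "tissue_labels") ||
              inherits(labels, "compartment_map"))
  RNifti::writeNifti(RNifti::asNifti(labels$data, pixdim = c(1, 1, 1)), path)
  legend <- if (inherits(labels, "tissue_labels"))
    as.list(TISSUE_CLASSES) else list(outside = 0, subfascial = 1, epifascial = 2)
  jsonlite::write_json(legend, sub("\\.nii(\\.gz)?$", ".json", path),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Serialize / restore a cluster model as JSON
#'
#' @param model a [fit_kmeans()] model.
#' @param path JSON file path.
#' @return `write_cluster_model` invisibly returns `path`;
#'   `read_cluster_model` returns the restored `cluster_model`.
#' @export
write_cluster_model <- function(model, path) {
  stopifnot(inherits(model, "cluster_model"))
  jsonlite::write_json(
    list(k = model$k, centroids = model$centroids, wcss = model$wcss,
         seed = model$seed, standardize = model$standardize,
         scale_center = model$scale_center, scale_sd = model$scale_sd,
         assignment = model$assignment),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  centroids <- matrix(unlist(x$centroids), ncol = 3, byrow = FALSE)
  if (is.matrix(x$centroids)) centroids <- x$centroids
  dimnames(centroids) <- list(paste0("cluster", seq_len(x$k)),
                              c("water", "fat", "stir"))
  structure(list(k = as.integer(x$k), centroids = centroids, wcss = x$wcss,
                 iter = NA_integer_, seed = as.integer(x$seed),
                 standardize = isTRUE(x$standardize),
                 scale_center = x$scale_center, scale_sd = x$scale_sd,
                 assignment = x$assignment),
            class = "cluster_model")
}
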