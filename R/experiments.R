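#' Synthetic recovery experiment
#'
#' End-to-end validation against known ground truth: generates a synthetic
#' landscape, samples transect surveys, derives the decision tree from the
#' calibration half of the points, classifies the scene with
#' homestead/depression/urban overlays burned in, and scores the map
#' against the groundtruth half with the buffered relative accuracy at
#' several radii.
#'
#' Classes that the survey cannot calibrate (fewer than two calibration
#' points, typically the rare forest patches) cannot enter the tree and
#' are excluded from the assessment, exactly as uncalibratable categories
#' are excluded from mapping in practice; their count is reported.
#'
#' @param seed integer seed.
#' @param nrow,ncol grid size in pixels (30 m pixels).
#' @param noise_sd spectral noise standard deviation (0 = noise-free).
#' @param gps_noise_m GPS jitter on survey points.
#' @param buffers buffer radii (m) at which relative accuracy is reported.
#' @param n_transects,length_m,spacing_m survey design.
#' @return list: `accuracy_pct` named by buffer radius,
#'   `point_accuracy_pct`, `min_pairwise_m` (smallest best-layer
#'   separability among tree classes), `tree`, `report` (15 m
#'   [accuracy_report()]), `n_points`, `n_excluded`, `elapsed_s`.
#' @export
recovery_experiment <- function(seed = 1, nrow = 300, ncol = 300,
                                noise_sd = 0.01, gps_noise_m = 5,
                                buffers = c(0, 15, 30),
                                n_transects = 27, length_m = 3000,
                                spacing_m = 100) {
  t0 <- proc.time()[["elapsed"]]
  layout <- landscape_layout(nrow = nrow, ncol = ncol)
  land <- generate_landscape(spectral_signature_model(noise_sd = noise_sd),
                             layout, seed = seed)
  pts <- withCallingHandlers(
    sample_transects(land$truth, n_transects = n_transects,
                     length_m = length_m, spacing_m = spacing_m,
                     gps_noise_m = gps_noise_m, seed = seed + 1L),
    warning = function(w) invokeRestart("muffleWarning"))
  layers <- compute_indices(land$scene, dem = land$dem)
  sig <- withCallingHandlers(class_signatures(layers, pts),
                             warning = function(w)
                               invokeRestart("muffleWarning"))
  tree <- derive_tree(sig, class_order = c("water", "forest", "shrubland",
                                           "field", "bare_soil"))
  spec <- classifier_spec(tree, overlays = land$truth$overlays)
  pm <- classify(layers, spec)

  tree_classes <- unique(c(
    unlist(rapply(unclass(tree), function(x) x, how = "unlist"))))
  tree_classes <- intersect(unique(sig$class), patch_classes())
  mappable <- c(tree_classes, "homestead", "depression", "urban")
  gt <- pts[pts$role == "groundtruth", , drop = FALSE]
  n_excluded <- sum(!gt$true_class %in% mappable)
  assessed <- gt[gt$true_class %in% mappable, , drop = FALSE]

  acc <- vapply(buffers, function(b)
    relative_accuracy(pm, assessed, buffer_m = b)$overall_pct, numeric(1))
  names(acc) <- paste0("buffer_", buffers, "m")

  # smallest best-layer pairwise separability among the tree's classes
  sep <- separability_matrix(sig[sig$class %in% tree_classes, ])
  best <- NULL
  for (m in sep) {
    mm <- m[tree_classes, tree_classes, drop = FALSE]
    best <- if (is.null(best)) mm else pmax(best, mm)
  }
  min_m <- min(best[upper.tri(best)])

  list(accuracy_pct = acc,
       point_accuracy_pct =
         relative_accuracy(pm, assessed, buffer_m = 0)$overall_pct,
       min_pairwise_m = min_m,
       tree = tree, patch_map = pm, truth = land$truth, points = pts,
       report = accuracy_report(pm, assessed, buffer_m = 15),
       n_points = nrow(assessed), n_excluded = n_excluded,
       elapsed_s = proc.time()[["elapsed"]] - t0)
}
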