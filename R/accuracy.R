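#' Buffered relative accuracy
#'
#' A groundtruthing point counts as correct if the disk of radius
#' `buffer_m` around it overlaps (with positive area) at least one pixel
#' of the point's true class. "Overlap" is the open disk intersecting the
#' open pixel cell with positive area, i.e. the distance from the point to
#' the (closed) cell is strictly less than `buffer_m`; touching at a
#' single point or along an edge does not count. At `buffer_m = 0` this
#' reduces exactly to plain point-in-pixel accuracy. The buffer absorbs
#' small GPS and co-registration offsets, which is why this relative
#' accuracy is at least as high as pixel-to-pixel accuracy.
#'
#' @param patch_map integer patch-map [sep_raster()] on a metric grid.
#' @param points survey data frame (`x`, `y`, `true_class`, optionally
#'   `role`); rows with `role == "groundtruth"` are used when the column
#'   is present.
#' @param buffer_m buffer radius in meters (`>= 0`, default 15).
#' @param exclude_classes classes whose groundtruth points are excluded
#'   from accuracy (urban by default: a land cover mapped from overlays,
#'   not assessed).
#' @return list with `per_class` (class, n, n_correct, accuracy_pct),
#'   `overall_pct` (point-pooled, the primary summary),
#'   `mean_class_pct` (mean of per-class accuracies, secondary),
#'   `buffer_m`, and `notes` for classes without groundtruth points.
#' @export
relative_accuracy <- function(patch_map, points, buffer_m = 15,
                              exclude_classes = "urban") {
  if (buffer_m < 0) stop("buffer_m must be >= 0")
  assert_metric(patch_map)
  if ("role" %in% names(points)) {
    points <- points[points$role == "groundtruth", , drop = FALSE]
  }
  points <- points[!points$true_class %in% exclude_classes, , drop = FALSE]
  if (!nrow(points)) stop("no groundtruth points to assess")
  pv <- patch_map$values
  nr <- nrow(pv); nc <- ncol(pv); px <- patch_map$pixel

  correct <- logical(nrow(points))
  rc <- xy_to_rc(patch_map, points$x, points$y)
  true_code <- patch_code(points$true_class)
  for (i in seq_len(nrow(points))) {
    row <- rc[i, 1]; col <- rc[i, 2]
    if (!is.na(row) && !is.na(pv[row, col]) && pv[row, col] == true_code[i]) {
      correct[i] <- TRUE
      next
    }
    if (buffer_m == 0) next
    # candidate cells within the buffer's bounding box
    reach <- ceiling(buffer_m / px) + 1L
    r0 <- max(1L, (if (is.na(row)) 1L else row) - reach)
    r1 <- min(nr, (if (is.na(row)) nr else row) + reach)
    c0 <- max(1L, (if (is.na(col)) 1L else col) - reach)
    c1 <- min(nc, (if (is.na(col)) nc else col) + reach)
    hit <- FALSE
    for (rr in r0:r1) {
      yb0 <- patch_map$ymin + (nr - rr) * px; yb1 <- yb0 + px
      dy <- max(yb0 - points$y[i], 0, points$y[i] - yb1)
      if (dy >= buffer_m) next
      for (cc in c0:c1) {
        if (is.na(pv[rr, cc]) || pv[rr, cc] != true_code[i]) next
        xb0 <- patch_map$xmin + (cc - 1) * px; xb1 <- xb0 + px
        dx <- max(xb0 - points$x[i], 0, points$x[i] - xb1)
        if (sqrt(dx^2 + dy^2) < buffer_m) { hit <- TRUE; break }
      }
      if (hit) break
    }
    correct[i] <- hit
  }

  cls <- sort(unique(points$true_class))
  per <- do.call(rbind, lapply(cls, function(cl) {
    sel <- points$true_class == cl
    data.frame(class = cl, n = sum(sel), n_correct = sum(correct[sel]),
               accuracy_pct = 100 * mean(correct[sel]))
  }))
  absent <- setdiff(setdiff(patch_classes(), exclude_classes), cls)
  notes <- if (length(absent)) {
    paste0("no groundtruth points for: ", paste(absent, collapse = ", "))
  } else character(0)
  list(per_class = per,
       overall_pct = 100 * mean(correct),
       mean_class_pct = mean(per$accuracy_pct),
       buffer_m = buffer_m, n_points = nrow(points), notes = notes)
}

#' Confusion matrix with producer's and user's accuracies
#'
#' Standard point-in-pixel cross-tabulation of mapped class (rows) against
#' groundtruth class (columns). Producer's accuracy (per-class recall) is
#' the diagonal over column sums; user's accuracy (per-class precision)
#' the diagonal over row sums.
#'
#' @inheritParams relative_accuracy
#' @return list with `matrix` (predicted x true counts), `producers_pct`,
#'   `users_pct`, `overall_pct`, `n_points`.
#' @export
confusion_matrix <- function(patch_map, points) {
  if ("role" %in% names(points)) {
    points <- points[points$role == "groundtruth", , drop = FALSE]
  }
  if (!nrow(points)) stop("no groundtruth points to assess")
  pred_code <- rast_lookup(patch_map, points$x, points$y)
  if (anyNA(pred_code) &&
      any(is.na(xy_to_rc(patch_map, points$x, points$y)[, 1]))) {
    stop("groundtruth points fall outside the map extent")
  }
  keep <- !is.na(pred_code)
  if (!all(keep)) {
    warning(sum(!keep), " point(s) on nodata pixels dropped")
    points <- points[keep, , drop = FALSE]
    pred_code <- pred_code[keep]
  }
  pred <- factor(patch_label(pred_code), levels = patch_classes())
  true <- factor(points$true_class, levels = patch_classes())
  m <- table(predicted = pred, true = true)
  used <- rowSums(m) > 0 | colSums(m) > 0
  m <- m[used, used, drop = FALSE]
  diagv <- diag(m)
  producers <- 100 * diagv / colSums(m)
  users <- 100 * diagv / rowSums(m)
  list(matrix = unclass(m),
       producers_pct = producers, users_pct = users,
       overall_pct = 100 * sum(diagv) / sum(m),
       n_points = sum(m))
}

#' Landcover composition of a patch map
#'
#' Percentage of non-nodata pixels in each class, over all mapped classes
#' including the water and urban land covers. Percentages sum to 100.
#'
#' @param patch_map integer patch-map [sep_raster()].
#' @return data frame with `class`, `n_pixels`, `pct`.
#' @export
landcover_composition <- function(patch_map) {
  pv <- patch_map$values
  total <- sum(!is.na(pv))
  if (total == 0) stop("patch map is entirely nodata")
  counts <- tabulate(pv[!is.na(pv)], nbins = length(patch_classes()))
  data.frame(class = patch_classes(), n_pixels = counts,
             pct = 100 * counts / total)
}

#' Full accuracy report
#'
#' Bundles landcover composition, buffered relative accuracy (per class
#' and overall), plain point accuracy, and the confusion matrix into one
#' report mirroring the standard class / landcover % / relative accuracy %
#' table layout.
#'
#' @inheritParams relative_accuracy
#' @return object of class `sep_accuracy_report`.
#' @export
accuracy_report <- function(patch_map, points, buffer_m = 15,
                            exclude_classes = "urban") {
  comp <- landcover_composition(patch_map)
  rel <- relative_accuracy(patch_map, points, buffer_m, exclude_classes)
  pt <- relative_accuracy(patch_map, points, 0, exclude_classes)
  conf <- confusion_matrix(patch_map, points)
  tab <- merge(comp, rel$per_class[, c("class", "n", "accuracy_pct")],
               by = "class", all.x = TRUE)
  names(tab)[names(tab) == "accuracy_pct"] <- "relative_accuracy_pct"
  names(tab)[names(tab) == "n"] <- "n_groundtruth"
  tab <- tab[match(patch_classes(), tab$class), ]
  rownames(tab) <- NULL
  structure(list(
    table = tab,
    overall_relative_accuracy_pct = rel$overall_pct,
    mean_class_relative_accuracy_pct = rel$mean_class_pct,
    overall_point_accuracy_pct = pt$overall_pct,
    confusion = conf, buffer_m = buffer_m, notes = rel$notes
  ), class = "sep_accuracy_report")
}

#' @export
print.sep_accuracy_report <- function(x, ...) {
  cat(sprintf("Accuracy report (buffer %g m, %d groundtruth points)\n",
              x$buffer_m, x$confusion$n_points))
  print(x$table, digits = 3)
  cat(sprintf("Overall relative accuracy: %.1f%% (point accuracy %.1f%%)\n",
              x$overall_relative_accuracy_pct,
              x$overall_point_accuracy_pct))
  if (length(x$notes)) cat("Note:", x$notes, "\n")
  invisible(x)
}

#' Write an accuracy report as JSON and delimited text
#'
#' @param report a [accuracy_report()] result.
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
write_accuracy_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "accuracy_report.tsv")
  utils::write.table(report$table, tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  js <- file.path(dir, "accuracy_report.json")
  jsonlite::write_json(list(
    table = report$table,
    overall_relative_accuracy_pct = report$overall_relative_accuracy_pct,
    mean_class_relative_accuracy_pct =
      report$mean_class_relative_accuracy_pct,
    overall_point_accuracy_pct = report$overall_point_accuracy_pct,
    buffer_m = report$buffer_m,
    confusion_matrix = report$confusion$matrix,
    producers_pct = as.list(report$confusion$producers_pct),
    users_pct = as.list(report$confusion$users_pct),
    overall_confusion_pct = report$confusion$overall_pct,
    notes = report$notes
  ), js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv, js))
}
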