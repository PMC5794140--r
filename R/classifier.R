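#' Decision tree nodes
#'
#' A binary threshold tree over named data layers. Each internal node tests
#' one layer against a threshold with one of `<`, `<=`, `>`, `>=`; the
#' `yes` branch is taken when the test holds (ties on `>=`/`<=` route to
#' the branch the operator includes). Leaves are patch class labels, or
#' `NA` for an explicit nodata leaf.
#'
#' @param layer layer name the node tests.
#' @param op comparison operator, one of `"<", "<=", ">", ">="`.
#' @param threshold numeric split value.
#' @param yes,no branch taken when the test is true/false: either another
#'   `decision_node()` or a patch class label (character scalar).
#' @return an object of class `sep_node`.
#' @examples
#' tree <- decision_node("ndvi_rainy", ">=", 0.4, "forest", "field")
#' classify_pixel(tree, c(ndvi_rainy = 0.5))
#' @export
decision_node <- function(layer, op, threshold, yes, no) {
  if (!op %in% c("<", "<=", ">", ">=")) stop("invalid operator: ", op)
  if (!is.numeric(threshold) || !is.finite(threshold)) {
    stop("threshold must be a finite number")
  }
  chk <- function(b) {
    if (inherits(b, "sep_node")) return(b)
    if (is.character(b) && length(b) == 1) {
      if (!is.na(b) && !b %in% patch_classes()) {
        stop("unknown leaf class: ", b)
      }
      return(b)
    }
    if (length(b) == 1 && is.na(b)) return(NA_character_)
    stop("branches must be decision nodes or class labels")
  }
  structure(list(layer = layer, op = op, threshold = as.numeric(threshold),
                 yes = chk(yes), no = chk(no)),
            class = "sep_node")
}

#' @rdname decision_node
#' @param node a `sep_node` or leaf.
#' @return `tree_layers()`: character vector of layer names the tree uses;
#'   `tree_depth()`: number of internal nodes.
#' @export
tree_layers <- function(node) {
  if (!inherits(node, "sep_node")) return(character(0))
  unique(c(node$layer, tree_layers(node$yes), tree_layers(node$no)))
}

#' @rdname decision_node
#' @export
tree_size <- function(node) {
  if (!inherits(node, "sep_node")) return(0L)
  1L + tree_size(node$yes) + tree_size(node$no)
}

#' @export
print.sep_node <- function(x, ...) {
  show <- function(n, ind) {
    pad <- strrep("  ", ind)
    if (!inherits(n, "sep_node")) {
      cat(pad, "-> ", if (is.na(n)) "<nodata>" else n, "\n", sep = "")
    } else {
      cat(sprintf("%s[%s %s %g]\n", pad, n$layer, n$op, n$threshold))
      show(n$yes, ind + 1)
      show(n$no, ind + 1)
    }
  }
  show(x, 0)
  invisible(x)
}

#' Route one pixel's layer values through a tree
#'
#' Reference per-pixel evaluator; [classify()] uses a vectorized
#' equivalent, and the two are held equal by tests.
#'
#' @param node a [decision_node()] or leaf label.
#' @param values named numeric vector of layer values.
#' @return class label, or `NA` if any tested layer value is missing.
#' @export
classify_pixel <- function(node, values) {
  while (inherits(node, "sep_node")) {
    v <- values[[node$layer]]
    if (is.null(v) || is.na(v)) return(NA_character_)
    hit <- switch(node$op,
                  "<" = v < node$threshold, "<=" = v <= node$threshold,
                  ">" = v > node$threshold, ">=" = v >= node$threshold)
    node <- if (hit) node$yes else node$no
  }
  node
}

#' Classifier specification
#'
#' Bundles the preparatory overlay list with the decision tree. Overlays
#' are burned in first, in order (later overlays override earlier ones);
#' the tree then classifies every remaining pixel.
#'
#' @param tree a [decision_node()] (or single class label for a trivial map).
#' @param overlays ordered list of overlay polygons (each
#'   `list(x=, y=, class=)`), e.g. from digitized vector files or
#'   [detect_built_patches()].
#' @param m_threshold minimum separability used when the tree was derived
#'   (recorded for provenance; must be > 0).
#' @return object of class `sep_classifier_spec`.
#' @export
classifier_spec <- function(tree, overlays = list(), m_threshold = 1) {
  if (m_threshold <= 0) stop("m_threshold must be positive")
  structure(list(tree = tree, overlays = overlays,
                 m_threshold = m_threshold),
            class = "sep_classifier_spec")
}

#' Burn vector overlays into a partial patch map
#'
#' Assigns every pixel whose center falls inside an overlay polygon that
#' overlay's class; later overlays override earlier ones; all other pixels
#' stay unassigned (`NA`). An empty overlay list yields a fully unassigned
#' map.
#'
#' @param template a [sep_raster()] defining the grid.
#' @param overlays ordered list of `list(x=, y=, class=)` polygons.
#' @return integer [sep_raster()] of class codes with `NA` where unassigned.
#' @export
burn_overlays <- function(template, overlays = list()) {
  nr <- nrow(template$values); nc <- ncol(template$values)
  out <- matrix(NA_integer_, nr, nc)
  if (!length(overlays)) return(rast_like(template, out))
  cx <- template$xmin + (seq_len(nc) - 0.5) * template$pixel
  cy <- template$ymin + (nr - seq_len(nr) + 0.5) * template$pixel
  X <- matrix(cx, nr, nc, byrow = TRUE)
  Y <- matrix(cy, nr, nc)
  for (ov in overlays) {
    code <- patch_code(ov$class)
    # bounding-box prefilter keeps the point-in-polygon test cheap
    inbb <- X >= min(ov$x) & X <= max(ov$x) & Y >= min(ov$y) & Y <= max(ov$y)
    idx <- which(inbb)
    if (!length(idx)) next
    hit <- points_in_polygon(ov, X[idx], Y[idx])
    out[idx[hit]] <- code
  }
  rast_like(template, out)
}

#' Detect built-up patches from a brightness layer
#'
#' Simplified object-based stand-in for manual interpretation of built
#' areas: thresholds high-brightness pixels (strictly above `threshold`),
#' extracts 8-connected components, and keeps components by size.
#' Components within `size_limits` become homestead candidates; larger
#' components become urban candidates when they overlap a village point's
#' neighborhood, and are dropped otherwise. Components are returned as
#' polygons on pixel boundaries, ready for [burn_overlays()].
#'
#' @param brightness a [sep_raster()] (e.g. tasseled cap brightness).
#' @param threshold brightness cut; pixels must exceed it strictly.
#' @param size_limits `c(min_px, max_px)` component size window for
#'   homesteads.
#' @param village_points data frame with `x`, `y` village locations.
#' @param village_radius_m neighborhood radius for the urban rule.
#' @return list of overlay polygons (`x`, `y`, `class`, `id`, `n_pixels`);
#'   empty list if nothing qualifies.
#' @export
detect_built_patches <- function(brightness, threshold,
                                 size_limits = c(2, 100),
                                 village_points = NULL,
                                 village_radius_m = 500) {
  assert_metric(brightness)
  mask <- !is.na(brightness$values) & brightness$values > threshold
  if (!any(mask)) return(list())
  lab <- label_components(mask)
  out <- list()
  for (k in seq_len(max(lab))) {
    comp <- lab == k
    n_px <- sum(comp)
    if (n_px < size_limits[1]) next
    cls <- NULL
    if (n_px <= size_limits[2]) {
      cls <- "homestead"
    } else if (!is.null(village_points) && nrow(village_points) > 0) {
      idx <- which(comp, arr.ind = TRUE)
      xy <- rc_to_xy(brightness, idx[, 1], idx[, 2])
      for (v in seq_len(nrow(village_points))) {
        dd <- sqrt((xy[, 1] - village_points$x[v])^2 +
                     (xy[, 2] - village_points$y[v])^2)
        if (any(dd <= village_radius_m)) { cls <- "urban"; break }
      }
    }
    if (is.null(cls)) next
    rings <- trace_component(comp, brightness)
    for (rg in rings) {
      out[[length(out) + 1]] <- list(x = rg$x, y = rg$y, class = cls,
                                     id = length(out) + 1, n_pixels = n_px)
    }
  }
  out
}

#' Derive a decision tree from calibration signatures
#'
#' Sequential class peeling: for each class in `class_order`, the
#' candidate layers are those on which the class mean is extremal with
#' respect to every remaining class (a single binary threshold can only
#' peel off an extremal class). Among candidates, the layer maximizing the
#' minimum pairwise M statistic against the remaining pool is chosen; if
#' that M falls below `m_threshold` a calibration error names the
#' hardest class pair. The split threshold is the midpoint between the
#' class mean and the nearest remaining-class mean, with `>=` on the true
#' branch; the last remaining class becomes the default leaf. `k` classes
#' yield `k - 1` internal nodes.
#'
#' @param signatures output of [class_signatures()].
#' @param class_order peeling order; default water, forest, depression,
#'   shrubland, field, bare_soil restricted to classes present (biomass
#'   logic: spectrally extreme classes first, confusable sparse classes
#'   last).
#' @param m_threshold minimum acceptable separability (default 1, a
#'   conventional good-separability cut).
#' @param layers optional subset of layer names to consider.
#' @return a [decision_node()] tree (or a single leaf label if only one
#'   class is present).
#' @export
derive_tree <- function(signatures,
                        class_order = c("water", "forest", "depression",
                                        "shrubland", "field", "bare_soil"),
                        m_threshold = 1, layers = NULL) {
  class_order <- intersect(class_order, unique(signatures$class))
  if (length(class_order) < 1) stop("no classes to build a tree for")
  missing <- setdiff(class_order, unique(signatures$class))
  if (length(missing)) stop("signatures missing for: ",
                            paste(missing, collapse = ", "))
  if (is.null(layers)) layers <- unique(signatures$layer)
  if (length(class_order) == 1) return(class_order)

  sig <- function(cl, ly) {
    s <- signatures[signatures$class == cl & signatures$layer == ly, ]
    if (!nrow(s)) stop("no signature for class ", cl, " on layer ", ly)
    s[1, ]
  }
  splits <- list()
  for (i in seq_len(length(class_order) - 1)) {
    cl <- class_order[i]
    pool <- class_order[(i + 1):length(class_order)]
    best <- NULL
    for (ly in layers) {
      mu_c <- sig(cl, ly)$mean
      mus <- vapply(pool, function(p) sig(p, ly)$mean, numeric(1))
      sds <- vapply(pool, function(p) sig(p, ly)$sd, numeric(1))
      if (!all(is.finite(c(mu_c, sig(cl, ly)$sd, mus, sds)))) next
      if (!(all(mus > mu_c) || all(mus < mu_c))) next  # not extremal
      ms <- vapply(pool, function(p) m_statistic(sig(cl, ly), sig(p, ly)),
                   numeric(1))
      score <- min(ms)
      if (is.null(best) || score > best$score) {
        nearest <- pool[which.min(abs(mus - mu_c))]
        best <- list(layer = ly, score = score, mu_c = mu_c,
                     mu_near = mus[[nearest]], nearest = nearest)
      }
    }
    if (is.null(best) || best$score < m_threshold) {
      hard <- if (is.null(best)) pool[1] else best$nearest
      stop("calibration error: classes '", cl, "' and '", hard,
           "' are not separable at M >= ", m_threshold,
           " on any layer")
    }
    splits[[i]] <- list(class = cl, layer = best$layer,
                        threshold = (best$mu_c + best$mu_near) / 2,
                        class_high = best$mu_c > best$mu_near)
  }
  # assemble from the default leaf upward
  node <- class_order[length(class_order)]
  for (i in rev(seq_along(splits))) {
    s <- splits[[i]]
    if (s$class_high) {
      node <- decision_node(s$layer, ">=", s$threshold, s$class, node)
    } else {
      node <- decision_node(s$layer, ">=", s$threshold, node, s$class)
    }
  }
  node
}

#' Classify a scene into a social-ecological patch map
#'
#' The hybrid workflow: overlays are burned in first (those pixels are
#' never overwritten), then every remaining pixel is routed through the
#' decision tree. Output is total: every non-nodata pixel receives exactly
#' one class; pixels with nodata in any tree-referenced layer are nodata.
#' Layers referenced by the tree but absent from `layers` raise an error
#' before any pixel is processed.
#'
#' @param layers named list of aligned [sep_raster()] layers (e.g. from
#'   [compute_indices()]).
#' @param spec a [classifier_spec()].
#' @param dem optional elevation raster, exposed to the tree as layer
#'   `dem` if not already present.
#' @return integer patch-map [sep_raster()].
#' @export
classify <- function(layers, spec, dem = NULL) {
  stopifnot(inherits(spec, "sep_classifier_spec"))
  if (!is.null(dem) && !"dem" %in% names(layers)) layers$dem <- dem
  need <- tree_layers(spec$tree)
  missing <- setdiff(need, names(layers))
  if (length(missing)) {
    stop("tree references missing layer(s): ", paste(missing, collapse = ", "))
  }
  if (length(layers) > 1) do.call(assert_aligned, unname(layers))
  tmpl <- layers[[1]]
  base <- burn_overlays(tmpl, spec$overlays)
  out <- base$values
  todo <- which(is.na(out))
  if (length(todo)) {
    mats <- lapply(layers, rast_values)
    assign_branch <- function(node, idx) {
      if (!length(idx)) return(invisible(NULL))
      if (!inherits(node, "sep_node")) {
        out[idx] <<- if (is.na(node)) NA_integer_ else patch_code(node)
        return(invisible(NULL))
      }
      v <- mats[[node$layer]][idx]
      hit <- switch(node$op,
                    "<" = v < node$threshold, "<=" = v <= node$threshold,
                    ">" = v > node$threshold, ">=" = v >= node$threshold)
      nod <- is.na(hit)
      out[idx[nod]] <<- NA_integer_
      assign_branch(node$yes, idx[!nod & hit])
      assign_branch(node$no, idx[!nod & !hit])
    }
    assign_branch(spec$tree, todo)
  }
  rast_like(tmpl, out)
}

# ---- tree serialization -----------------------------------------------------

node_to_list <- function(node) {
  if (!inherits(node, "sep_node")) {
    return(if (is.na(node)) list(leaf = "nodata") else list(leaf = node))
  }
  list(layer = node$layer, op = node$op, threshold = node$threshold,
       yes = node_to_list(node$yes), no = node_to_list(node$no))
}

list_to_node <- function(x) {
  if (!is.null(x$leaf)) {
    return(if (identical(x$leaf, "nodata")) NA_character_ else x$leaf)
  }
  decision_node(x$layer, x$op, x$threshold,
                list_to_node(x$yes), list_to_node(x$no))
}

#' Read and write decision trees as structured text
#'
#' Trees serialize to a small YAML schema: internal nodes are maps with
#' keys `layer`, `op`, `threshold`, `yes`, `no`; leaves are maps with the
#' single key `leaf` (a class label, or `nodata`). The files are
#' hand-editable, so a tree derived from calibration data can be inspected
#' and adjusted.
#'
#' @param tree a [decision_node()] or leaf label.
#' @param path YAML file path.
#' @return `read_tree()` returns the tree.
#' @export
write_tree <- function(tree, path) {
  yaml::write_yaml(node_to_list(tree), path)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  list_to_node(yaml::read_yaml(path))
}
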