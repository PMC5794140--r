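#' Benefit score table
#'
#' Per-patch, per-benefit scores (per unit area) plus the two weighting
#' applicability sets. Scores are dimensionless relative contributions;
#' water and urban land are land covers, not social-ecological patches,
#' and must score 0 everywhere. The distance-weighting set defaults to
#' fields and shrubland for every benefit except saving/insurance (benefit
#' value falls off with distance from homesteads because of transport
#' effort); the area-weighting set defaults to shrubland for nutritional
#' diversity/medicinal uses, material assets/energy and saving/insurance
#' (those benefits depend on how much shrubland a village has).
#'
#' @param scores 8 x 5 numeric matrix (classes x benefits), nonnegative.
#' @param distance_weighted,area_weighted logical 8 x 5 matrices flagging
#'   which (class, benefit) cells each weight raster applies to.
#' @return object of class `sep_score_table`.
#' @export
benefit_score_table <- function(scores, distance_weighted, area_weighted) {
  cls <- patch_classes(); ben <- benefit_labels()
  chk <- function(m, what, logical_ok = FALSE) {
    if (!is.matrix(m) || !identical(rownames(m), cls) ||
        !identical(colnames(m), ben)) {
      stop(what, " must be a matrix with rows ",
           paste(cls, collapse = ","), " and columns ",
           paste(ben, collapse = ","))
    }
    m
  }
  chk(scores, "scores"); chk(distance_weighted, "distance_weighted")
  chk(area_weighted, "area_weighted")
  if (any(scores < 0)) stop("scores must be nonnegative")
  if (any(scores[c("water", "urban"), ] != 0)) {
    stop("water and urban are land covers, not patches: scores must be 0")
  }
  structure(list(scores = scores,
                 distance_weighted = distance_weighted,
                 area_weighted = area_weighted),
            class = "sep_score_table")
}

#' @rdname benefit_score_table
#' @details
#' `default_score_table()` encodes the qualitative patch-benefit relations
#' on an integer 0-5 scale: fields are the main source of annual crops;
#' depressions are arable and well watered; homesteads carry gardens and
#' useful trees; shrubland and forest supply wild foods, medicine, wood
#' and pasture but no annual crops (so annual crops score 0 for bare soil,
#' shrubland and forest); and every patch feeds livestock, so
#' saving/insurance is positive for all six patches. The numbers are a
#' documented default meant to be swapped for study-specific scores.
#' @export
default_score_table <- function() {
  ben <- benefit_labels()
  scores <- rbind(
    bare_soil  = c(0, 1, 1, 1, 1),
    depression = c(4, 3, 2, 2, 3),
    field      = c(5, 3, 2, 3, 3),
    forest     = c(0, 4, 3, 2, 2),
    homestead  = c(3, 4, 3, 3, 2),
    shrubland  = c(0, 4, 4, 3, 3),
    water      = c(0, 0, 0, 0, 0),
    urban      = c(0, 0, 0, 0, 0)
  )
  colnames(scores) <- ben
  dw <- matrix(FALSE, 8, 5, dimnames = dimnames(scores))
  dw[c("field", "shrubland"), setdiff(ben, "saving_insurance")] <- TRUE
  aw <- matrix(FALSE, 8, 5, dimnames = dimnames(scores))
  aw["shrubland", c("nutritional_diversity_medicinal",
                    "material_assets_energy", "saving_insurance")] <- TRUE
  benefit_score_table(scores, dw, aw)
}

#' Thiessen (Voronoi) village territories
#'
#' Approximates village boundaries as Voronoi cells of the village points,
#' clipped to the study extent: each territory is the region closer to its
#' village than to any other. Cells are computed exactly by clipping the
#' extent rectangle with the perpendicular-bisector half-planes, so the
#' territories partition the extent (areas sum to the extent area).
#'
#' @param villages data frame with `x`, `y`, `village_id`; points must be
#'   distinct and inside the extent.
#' @param template a [sep_raster()] supplying extent and CRS.
#' @return object of class `sep_territories`: `villages`, `polygons`
#'   (one per village), `areas` (squared CRS units).
#' @export
voronoi_territories <- function(villages, template) {
  stopifnot(is.data.frame(villages), nrow(villages) >= 1)
  if (anyDuplicated(villages[, c("x", "y")])) {
    stop("duplicate village points are not allowed")
  }
  ext <- rast_extent(template)
  rect <- list(x = c(ext["xmin"], ext["xmax"], ext["xmax"], ext["xmin"]),
               y = c(ext["ymin"], ext["ymin"], ext["ymax"], ext["ymax"]))
  n <- nrow(villages)
  polys <- vector("list", n)
  for (i in seq_len(n)) {
    poly <- rect
    for (j in seq_len(n)) {
      if (i == j) next
      # keep || p - v_i ||^2 <= || p - v_j ||^2  <=>  a x + b y <= c
      a <- 2 * (villages$x[j] - villages$x[i])
      b <- 2 * (villages$y[j] - villages$y[i])
      c <- (villages$x[j]^2 + villages$y[j]^2) -
        (villages$x[i]^2 + villages$y[i]^2)
      poly <- clip_halfplane(poly, a, b, c)
      if (!length(poly$x)) break
    }
    polys[[i]] <- poly
  }
  names(polys) <- as.character(villages$village_id)
  structure(list(villages = villages, polygons = polys,
                 areas = vapply(polys, polygon_area, numeric(1))),
            class = "sep_territories")
}

#' Rasterize territories: nearest-village pixel assignment
#'
#' @param territories a [voronoi_territories()] result.
#' @param template grid-defining [sep_raster()].
#' @return integer [sep_raster()] of village indices (1..n, row order of
#'   `territories$villages`).
#' @export
territory_raster <- function(territories, template) {
  nr <- nrow(template$values); nc <- ncol(template$values)
  cx <- template$xmin + (seq_len(nc) - 0.5) * template$pixel
  cy <- template$ymin + (nr - seq_len(nr) + 0.5) * template$pixel
  X <- matrix(cx, nr, nc, byrow = TRUE)
  Y <- matrix(cy, nr, nc)
  v <- territories$villages
  best <- matrix(1L, nr, nc)
  bestd <- (X - v$x[1])^2 + (Y - v$y[1])^2
  for (i in seq_len(nrow(v))[-1]) {
    d <- (X - v$x[i])^2 + (Y - v$y[i])^2
    upd <- d < bestd
    best[upd] <- i
    bestd[upd] <- d[upd]
  }
  rast_like(template, best)
}

#' Distance-decay weight raster around homesteads
#'
#' Per-pixel Euclidean distance to the nearest homestead pixel, binned
#' into `n_zones` annuli of width `zone_width_m`; zone weights are
#' linearly interpolated from `w_near` (closest zone, default 1.2) to
#' `w_far` (outermost, default 0.8), and distances beyond the last zone
#' keep `w_far`. Zone bins are left-closed (`[0, w)` is zone 1), so a
#' pixel inside a homestead gets exactly `w_near`.
#'
#' @param homestead_mask [sep_raster()] that is 1/TRUE on homestead pixels
#'   (must be nonempty; distances need an anchor) on a metric grid.
#' @param n_zones number of buffer zones (default 5).
#' @param w_near,w_far weights of the closest and furthest zone.
#' @param zone_width_m zone width in meters (> 0; default 500).
#' @return [sep_raster()] of weights with attribute `kind = "distance"`.
#' @export
homestead_distance_weights <- function(homestead_mask, n_zones = 5,
                                       w_near = 1.2, w_far = 0.8,
                                       zone_width_m = 500) {
  assert_metric(homestead_mask)
  if (zone_width_m <= 0) stop("zone_width_m must be positive")
  if (n_zones < 2) stop("need at least 2 zones")
  m <- homestead_mask$values
  m[is.na(m)] <- 0
  if (!any(m != 0)) stop("homestead mask is empty: no anchor for distances")
  dist_px <- EBImage::distmap(matrix(as.numeric(m == 0),
                                     nrow(m), ncol(m)))
  dist_m <- as.matrix(dist_px) * homestead_mask$pixel
  zone <- pmin(floor(dist_m / zone_width_m) + 1, n_zones)
  wts <- w_near + (seq_len(n_zones) - 1) * (w_far - w_near) / (n_zones - 1)
  out <- rast_like(homestead_mask, matrix(wts[zone], nrow(m), ncol(m)))
  attr(out, "kind") <- "distance"
  attr(out, "zones") <- rast_like(homestead_mask, zone)
  out
}

#' Shrubland-area weight raster per village territory
#'
#' For each village, the shrubland fraction of its territory is computed
#' from the patch map and binned by `breakpoints` into one of five
#' categories; every pixel of the territory receives that category's
#' weight. The default schedule is hump-shaped: villages with barely any
#' shrubland get the low weight (shrubland too small/scattered to deliver
#' its benefits), mid-range shrubland cover gets the maximum 1.2, and
#' above an upper limit the added value declines again.
#'
#' @param patch_map integer patch-map [sep_raster()].
#' @param territories a [voronoi_territories()] result.
#' @param breakpoints 4 strictly increasing fraction thresholds
#'   (default 0.02, 0.10, 0.25, 0.40); category k covers
#'   `[breakpoints[k-1], breakpoints[k])`.
#' @param weights 5 category weights, each in `[0.8, 1.2]`
#'   (default 0.8, 1.0, 1.2, 1.1, 0.9).
#' @return [sep_raster()] of weights with attributes `kind =
#'   "shrubland_area"` and `village_stats` (per-village fraction,
#'   category, weight).
#' @export
shrubland_area_weights <- function(patch_map, territories,
                                   breakpoints = c(0.02, 0.10, 0.25, 0.40),
                                   weights = c(0.8, 1.0, 1.2, 1.1, 0.9)) {
  if (length(breakpoints) != 4 || any(diff(breakpoints) <= 0)) {
    stop("breakpoints must be 4 strictly increasing values")
  }
  if (length(weights) != 5 || any(weights < 0.8 | weights > 1.2)) {
    stop("weights must be 5 values in [0.8, 1.2]")
  }
  terr <- territory_raster(territories, patch_map)
  pv <- patch_map$values
  out <- matrix(NA_real_, nrow(pv), ncol(pv))
  stats_rows <- list()
  for (i in seq_len(nrow(territories$villages))) {
    sel <- terr$values == i & !is.na(pv)
    n_pix <- sum(sel)
    if (n_pix == 0) {
      warning("territory of village ",
              territories$villages$village_id[i],
              " contains no mapped pixels; weight set to 1.0")
      frac <- NA_real_; cat_i <- NA_integer_; w <- 1.0
    } else {
      frac <- sum(pv[sel] == .CODE[["shrubland"]]) / n_pix
      cat_i <- findInterval(frac, breakpoints) + 1L
      w <- weights[cat_i]
    }
    out[terr$values == i] <- w
    stats_rows[[i]] <- data.frame(
      village_id = territories$villages$village_id[i],
      n_pixels = n_pix, shrubland_fraction = frac,
      category = cat_i, weight = w)
  }
  res <- rast_like(patch_map, out)
  attr(res, "kind") <- "shrubland_area"
  attr(res, "village_stats") <- do.call(rbind, stats_rows)
  res
}

#' Compute one livelihood-benefit raster
#'
#' Per pixel: the patch's score for the benefit, multiplied by the
#' distance weight where (class, benefit) is distance-weighted and by the
#' shrubland-area weight where it is area-weighted (both can apply).
#' Water/urban pixels score 0; nodata stays nodata.
#'
#' @param patch_map integer patch-map [sep_raster()].
#' @param table a [benefit_score_table()].
#' @param dist_w,area_w aligned weight rasters (from
#'   [homestead_distance_weights()] / [shrubland_area_weights()]).
#' @param benefit one of [benefit_labels()].
#' @return numeric benefit [sep_raster()].
#' @export
compute_benefit_map <- function(patch_map, table, dist_w, area_w, benefit) {
  stopifnot(inherits(table, "sep_score_table"))
  if (!benefit %in% benefit_labels()) stop("unknown benefit: ", benefit)
  assert_aligned(patch_map, dist_w, area_w)
  pv <- patch_map$values
  present <- unique(pv[!is.na(pv)])
  if (any(!present %in% seq_along(patch_classes()))) {
    stop("patch map contains codes without score entries")
  }
  sc <- table$scores[, benefit]
  dwf <- table$distance_weighted[, benefit]
  awf <- table$area_weighted[, benefit]
  out <- matrix(NA_real_, nrow(pv), ncol(pv))
  ok <- !is.na(pv)
  base <- sc[pv[ok]]
  d <- ifelse(dwf[pv[ok]], dist_w$values[ok], 1)
  a <- ifelse(awf[pv[ok]], area_w$values[ok], 1)
  out[ok] <- base * d * a
  rast_like(patch_map, out)
}

#' All five benefit maps
#'
#' @inheritParams compute_benefit_map
#' @return named list of five benefit rasters in [benefit_labels()] order.
#' @export
benefit_maps <- function(patch_map, table, dist_w, area_w) {
  stats::setNames(lapply(benefit_labels(), function(b)
    compute_benefit_map(patch_map, table, dist_w, area_w, b)),
    benefit_labels())
}

#' Composite heat map
#'
#' Adds the five separate livelihood benefit maps into one composite map;
#' high values flag multifunctional parts of the landscape. Nodata in any
#' input propagates.
#'
#' @param maps list of exactly five aligned benefit rasters.
#' @return numeric [sep_raster()].
#' @export
heat_map <- function(maps) {
  if (length(maps) != 5) {
    stop("heat map needs exactly 5 benefit maps, got ", length(maps))
  }
  do.call(assert_aligned, unname(maps))
  acc <- maps[[1]]$values
  for (m in maps[-1]) acc <- acc + m$values
  rast_like(maps[[1]], acc)
}
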