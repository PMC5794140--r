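#' Per-class spectral signature model for synthetic scenes
#'
#' Defines, for each patch class, mean reflectance and noise standard
#' deviation in each season/band (dry/rainy x red/NIR/MIR), plus parameters
#' of the synthetic elevation model. The defaults sketch a semi-arid
#' savanna-mosaic landscape: fields are bright bare soil in the dry season
#' and green in the rainy season, shrubland keeps moderate biomass in both,
#' depressions are wet and green after the rains, water is dark in all
#' bands, and built surfaces are bright with high mid-infrared response.
#' Reported per-class spectra are free model parameters (no radiometric
#' calibration is claimed); what matters downstream is that classes are
#' separable on the layers the decision tree uses.
#'
#' @param noise_sd per-band Gaussian noise standard deviation (reflectance
#'   units), a single value or a full class x band matrix.
#' @return an object of class `sep_signature_model` with elements `means`,
#'   `sds` (8 classes x 6 season-bands) and `dem` parameters (meters).
#' @examples
#' m <- spectral_signature_model()
#' m$means["field", "rainy_nir"]
#' @export
spectral_signature_model <- function(noise_sd = 0.01) {
  sb <- c("dry_red", "dry_nir", "dry_mir", "rainy_red", "rainy_nir",
          "rainy_mir")
  means <- rbind(
    bare_soil  = c(0.30, 0.32, 0.38, 0.26, 0.29, 0.34),
    depression = c(0.15, 0.25, 0.18, 0.08, 0.40, 0.10),
    field      = c(0.25, 0.30, 0.35, 0.12, 0.35, 0.20),
    forest     = c(0.08, 0.35, 0.15, 0.06, 0.45, 0.12),
    homestead  = c(0.28, 0.30, 0.40, 0.24, 0.28, 0.36),
    shrubland  = c(0.18, 0.28, 0.25, 0.14, 0.30, 0.22),
    water      = c(0.05, 0.03, 0.02, 0.06, 0.04, 0.03),
    urban      = c(0.32, 0.30, 0.45, 0.30, 0.29, 0.44)
  )
  colnames(means) <- sb
  if (is.matrix(noise_sd)) {
    sds <- noise_sd
    if (!identical(dim(sds), dim(means))) stop("noise_sd matrix must be 8 x 6")
    dimnames(sds) <- dimnames(means)
  } else {
    if (length(noise_sd) != 1L || noise_sd < 0) {
      stop("noise_sd must be a single nonnegative number or an 8 x 6 matrix")
    }
    sds <- matrix(noise_sd, nrow(means), ncol(means),
                  dimnames = dimnames(means))
  }
  if (any(means < 0 | means > 1)) stop("reflectance means must lie in [0, 1]")
  structure(list(
    means = means, sds = sds,
    dem = list(base_elevation = 320, relief_amplitude = 15,
               depression_drop = 8, n_bumps = 12)
  ), class = "sep_signature_model")
}

#' Layout configuration for synthetic landscapes
#'
#' Target class fractions follow the landscape composition the method was
#' developed for: a field-dominated mosaic with substantial shrubland,
#' scattered depressions and water bodies, rare forest, small built
#' fractions, and bare soil as the remainder.
#'
#' @param nrow,ncol grid dimensions in pixels.
#' @param pixel pixel size in meters (30 m nominal).
#' @param n_villages number of village points.
#' @param fractions named target class fractions (must be `>= 0`, sum
#'   `<= 1`); the remainder of the grid becomes bare soil.
#' @param tolerance acceptable absolute deviation of realized from target
#'   fractions for the freely grown classes.
#' @return a list of validated layout parameters.
#' @export
landscape_layout <- function(nrow = 200, ncol = 200, pixel = 30,
                             n_villages = 6,
                             fractions = c(field = 0.50, shrubland = 0.20,
                                           depression = 0.06,
                                           homestead = 0.03, water = 0.02,
                                           forest = 0.01, urban = 0.01),
                             tolerance = 0.05) {
  if (any(fractions < 0)) stop("class fractions must be nonnegative")
  if (sum(fractions) > 1 + 1e-12) stop("class fractions must sum to <= 1")
  bad <- setdiff(names(fractions), patch_classes())
  if (length(bad)) stop("unknown classes in fractions: ",
                        paste(bad, collapse = ", "))
  if (nrow < 20 || ncol < 20) stop("grid too small (need >= 20 x 20)")
  if (pixel <= 0) stop("pixel size must be positive")
  list(nrow = as.integer(nrow), ncol = as.integer(ncol), pixel = pixel,
       n_villages = as.integer(n_villages), fractions = fractions,
       tolerance = tolerance)
}

# ---- internal landscape construction helpers --------------------------------

# linear-index 4-neighbors on an nr x nc grid (column-major)
.neighbors4 <- function(idx, nr, nc) {
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  c(idx[row > 1L] - 1L, idx[row < nr] + 1L,
    idx[col > 1L] - nr, idx[col < nc] + nr)
}

# place a class rectangle; returns NULL if it cannot avoid assigned cells
.place_rect <- function(assign_m, nr, nc, h, w, center = NULL, tries = 25) {
  for (t in seq_len(tries)) {
    if (is.null(center)) {
      r0 <- sample.int(nr - h + 1L, 1L)
      c0 <- sample.int(nc - w + 1L, 1L)
    } else {
      r0 <- min(max(1L, center[1] - h %/% 2L + sample(-2:2, 1)), nr - h + 1L)
      c0 <- min(max(1L, center[2] - w %/% 2L + sample(-2:2, 1)), nc - w + 1L)
    }
    rows <- r0:(r0 + h - 1L); cols <- c0:(c0 + w - 1L)
    if (all(assign_m[rows, cols] == 0L)) {
      return(list(rows = rows, cols = cols))
    }
  }
  NULL
}

# rectangle (pixel index ranges) -> polygon on pixel boundaries
.rect_polygon <- function(rows, cols, nr, xmin, ymin, px) {
  x0 <- xmin + (min(cols) - 1) * px
  x1 <- xmin + max(cols) * px
  y0 <- ymin + (nr - max(rows)) * px
  y1 <- ymin + (nr - min(rows) + 1) * px
  list(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

#' Generate a synthetic study area with known ground truth
#'
#' Builds a patch mosaic (seeded region growing for the open-land classes;
#' homesteads as small blocks around village points; urban land as a
#' contiguous block around one designated town; depressions as elongated
#' blocks), a two-season three-band scene drawn from the signature model's
#' class Gaussians, and a smooth synthetic elevation model with carved
#' depressions, all on one 30 m grid. Overlay polygons (homestead,
#' depression, urban) rasterize exactly to the corresponding patch labels.
#' Deterministic given `seed`; no global random state is left behind.
#'
#' @param model a [spectral_signature_model()].
#' @param layout a [landscape_layout()].
#' @param seed integer seed driving all randomness.
#' @param crs CRS tag; must be metric.
#' @return a list with class `sep_landscape`:
#'   * `truth`: patch raster (integer codes), `villages` data frame
#'     (`x`, `y`, `village_id`), overlay polygon list, and the layout;
#'   * `scene`: [sep_scene()] of six season-band rasters;
#'   * `dem`: elevation raster (m).
#' @export
generate_landscape <- function(model = spectral_signature_model(),
                               layout = landscape_layout(),
                               seed = 1L, crs = metric_crs()) {
  stopifnot(inherits(model, "sep_signature_model"))
  assert_metric(crs)
  withr::with_seed(as.integer(seed), {
    nr <- layout$nrow; nc <- layout$ncol; px <- layout$pixel
    N <- nr * nc
    frac <- layout$fractions
    quota <- round(frac * N)
    assign_m <- matrix(0L, nr, nc)

    # --- villages: spread points with a minimum separation ---
    n_vill <- layout$n_villages
    min_d <- 0.25 * min(nr, nc) / sqrt(n_vill)
    vr <- integer(0); vc <- integer(0)
    guard <- 0L
    while (length(vr) < n_vill && guard < 5000L) {
      guard <- guard + 1L
      r <- sample(seq(5L, nr - 5L), 1L)
      c <- sample(seq(5L, nc - 5L), 1L)
      if (!length(vr) || min(sqrt((vr - r)^2 + (vc - c)^2)) >= min_d) {
        vr <- c(vr, r); vc <- c(vc, c)
      }
    }
    if (length(vr) < n_vill) stop("could not place villages; grid too small")

    overlays <- list()
    add_overlay <- function(rows, cols, cls) {
      overlays[[length(overlays) + 1]] <<- c(
        .rect_polygon(rows, cols, nr, 0, 0, px),
        list(class = cls, id = length(overlays) + 1))
    }

    # --- urban: one contiguous block around the designated town ---
    if (!is.na(quota["urban"]) && quota["urban"] > 0) {
      side <- max(2L, round(sqrt(quota["urban"])))
      rect <- .place_rect(assign_m, nr, nc, side, side,
                          center = c(vr[1], vc[1]))
      if (is.null(rect)) rect <- .place_rect(assign_m, nr, nc, side, side)
      assign_m[rect$rows, rect$cols] <- .CODE[["urban"]]
      add_overlay(rect$rows, rect$cols, "urban")
    }

    # --- homesteads: 1-3 small blocks near each village point ---
    if (!is.na(quota["homestead"]) && quota["homestead"] > 0) {
      per_v <- quota["homestead"] / n_vill
      for (v in seq_len(n_vill)) {
        k <- sample(1:3, 1)
        target <- max(1, round(per_v / k))
        for (b in seq_len(k)) {
          h <- max(1L, round(sqrt(target)))
          w <- max(1L, round(target / h))
          rect <- .place_rect(assign_m, nr, nc, h, w,
                              center = c(vr[v], vc[v]), tries = 40)
          if (is.null(rect)) next
          assign_m[rect$rows, rect$cols] <- .CODE[["homestead"]]
          add_overlay(rect$rows, rect$cols, "homestead")
        }
      }
    }

    # --- depressions: elongated blocks scattered over the grid ---
    if (!is.na(quota["depression"]) && quota["depression"] > 0) {
      placed <- 0
      guard <- 0L
      while (placed < quota["depression"] && guard < 200L) {
        guard <- guard + 1L
        area <- min(quota["depression"] - placed,
                    max(20, round(quota["depression"] / 6)))
        if (area < 4) break
        if (stats::runif(1) < 0.5) {
          h <- max(2L, round(sqrt(area / 3))); w <- max(2L, round(area / h))
        } else {
          w <- max(2L, round(sqrt(area / 3))); h <- max(2L, round(area / w))
        }
        if (h > nr - 2L || w > nc - 2L) next
        rect <- .place_rect(assign_m, nr, nc, h, w)
        if (is.null(rect)) next
        assign_m[rect$rows, rect$cols] <- .CODE[["depression"]]
        add_overlay(rect$rows, rect$cols, "depression")
        placed <- placed + h * w
      }
    }

    # --- freely grown classes: seeded region growing with quotas ---
    grow_classes <- intersect(c("water", "forest", "shrubland", "field"),
                              names(quota)[quota > 0])
    grown <- stats::setNames(numeric(length(grow_classes)), grow_classes)
    frontier <- list()
    for (cl in grow_classes) {
      n_nuc <- max(1L, ceiling(quota[[cl]] / 1500))
      free <- which(assign_m == 0L)
      nuc <- sample(free, min(n_nuc, length(free)))
      assign_m[nuc] <- .CODE[[cl]]
      grown[cl] <- length(nuc)
      frontier[[cl]] <- nuc
    }
    active <- grow_classes[grown < quota[grow_classes]]
    while (length(active)) {
      for (cl in sample(active)) {
        need <- quota[[cl]] - grown[cl]
        if (need <= 0) next
        cand <- unique(.neighbors4(frontier[[cl]], nr, nc))
        cand <- cand[assign_m[cand] == 0L]
        if (!length(cand)) {
          # frontier exhausted: retry from all class cells once
          cand <- unique(.neighbors4(which(assign_m == .CODE[[cl]]), nr, nc))
          cand <- cand[assign_m[cand] == 0L]
          if (!length(cand)) { grown[cl] <- quota[[cl]]; next }  # enclosed
        }
        take <- if (length(cand) > need) sample(cand, need) else cand
        assign_m[take] <- .CODE[[cl]]
        grown[cl] <- grown[cl] + length(take)
        frontier[[cl]] <- take
      }
      active <- grow_classes[grown < quota[grow_classes]]
    }
    assign_m[assign_m == 0L] <- .CODE[["bare_soil"]]

    patch <- sep_raster(assign_m, xmin = 0, ymin = 0, pixel = px, crs = crs)
    vxy <- rc_to_xy(patch, vr, vc)
    villages <- data.frame(x = vxy[, 1], y = vxy[, 2],
                           village_id = seq_len(n_vill))

    # --- DEM: smooth bump field, then carve depressions and water ---
    dp <- model$dem
    rowg <- matrix(seq_len(nr), nr, nc)
    colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    dem_v <- matrix(dp$base_elevation, nr, nc)
    for (b in seq_len(dp$n_bumps)) {
      amp <- stats::runif(1, -dp$relief_amplitude, dp$relief_amplitude)
      cr <- stats::runif(1, 1, nr); cc <- stats::runif(1, 1, nc)
      sg <- stats::runif(1, 0.08, 0.25) * min(nr, nc)
      dem_v <- dem_v + amp * exp(-((rowg - cr)^2 + (colg - cc)^2) / (2 * sg^2))
    }
    low <- assign_m == .CODE[["depression"]] | assign_m == .CODE[["water"]]
    dem_v[low] <- dem_v[low] - dp$depression_drop
    dem <- sep_raster(dem_v, 0, 0, px, crs)

    # --- scene: class Gaussians per season-band, clamped to [0, 1] ---
    bands <- list()
    for (sb in colnames(model$means)) {
      mu <- model$means[, sb][assign_m]
      sd <- model$sds[, sb][assign_m]
      v <- matrix(mu + stats::rnorm(N) * sd, nr, nc)
      v[v < 0] <- 0; v[v > 1] <- 1
      bands[[sb]] <- sep_raster(v, 0, 0, px, crs)
    }

    truth <- structure(list(patch = patch, villages = villages,
                            overlays = overlays, layout = layout),
                       class = "sep_truth")
    structure(list(truth = truth, scene = sep_scene(bands), dem = dem),
              class = "sep_landscape")
  })
}

#' Bundle season-band rasters into a scene
#'
#' @param bands named list of aligned [sep_raster()] layers; names follow
#'   `<season>_<band>` with season in dry/rainy and band in red/nir/mir.
#' @return object of class `sep_scene`.
#' @export
sep_scene <- function(bands) {
  stopifnot(is.list(bands), length(bands) >= 1, !is.null(names(bands)))
  do.call(assert_aligned, unname(bands))
  structure(list(bands = bands), class = "sep_scene")
}

#' Sample survey points along village transect walks
#'
#' Emulates participatory transect walks: straight transects start at
#' village points with random headings, stops are recorded at a fixed
#' spacing (inclusive of both endpoints, so a 3 km walk at 100 m spacing
#' yields 31 stops), each stop is labeled with the true patch class at the
#' undisturbed location, and the recorded coordinates are then jittered by
#' isotropic GPS noise. Stops falling outside the study extent are dropped
#' with a warning (the transect is truncated); jittered coordinates are
#' clamped to the extent so every returned point is mappable. Points are
#' split into calibration and groundtruthing roles, stratified by class.
#'
#' @param truth the `truth` element of [generate_landscape()] output.
#' @param n_transects number of walks.
#' @param length_m walk length (m).
#' @param spacing_m stop spacing (m, > 0; `length_m >= spacing_m`).
#' @param gps_noise_m GPS jitter scale (m); 0 keeps exact stop locations.
#' @param seed integer seed.
#' @param calibration_fraction fraction of each class assigned the
#'   calibration role (default an even split).
#' @return data frame with columns `x`, `y`, `true_class`, `role`
#'   (calibration/groundtruth), `transect_id`, `point_id`.
#' @export
sample_transects <- function(truth, n_transects = 27, length_m = 3000,
                             spacing_m = 100, gps_noise_m = 5, seed = 1L,
                             calibration_fraction = 0.5) {
  stopifnot(inherits(truth, "sep_truth"))
  if (spacing_m <= 0) stop("spacing_m must be positive")
  if (length_m < spacing_m) stop("length_m must be >= spacing_m")
  patch <- truth$patch
  ext <- rast_extent(patch)
  withr::with_seed(as.integer(seed), {
    nv <- nrow(truth$villages)
    d <- seq(0, by = spacing_m, length.out = floor(length_m / spacing_m) + 1)
    pts <- vector("list", n_transects)
    truncated <- 0L
    for (t in seq_len(n_transects)) {
      v <- ((t - 1L) %% nv) + 1L
      ang <- stats::runif(1, 0, 2 * pi)
      x <- truth$villages$x[v] + d * cos(ang)
      y <- truth$villages$y[v] + d * sin(ang)
      keep <- x >= ext["xmin"] & x < ext["xmax"] &
        y >= ext["ymin"] & y < ext["ymax"]
      if (!all(keep)) truncated <- truncated + 1L
      pts[[t]] <- data.frame(x = x[keep], y = y[keep], transect_id = t)
    }
    if (truncated > 0) {
      warning(truncated, " transect(s) extended outside the study extent ",
              "and were truncated")
    }
    out <- do.call(rbind, pts)
    out$true_class <- patch_label(rast_lookup(patch, out$x, out$y))
    out <- out[!is.na(out$true_class), , drop = FALSE]
    if (gps_noise_m > 0) {
      out$x <- out$x + stats::rnorm(nrow(out), 0, gps_noise_m)
      out$y <- out$y + stats::rnorm(nrow(out), 0, gps_noise_m)
      eps <- 1e-9 * patch$pixel
      out$x <- pmin(pmax(out$x, ext["xmin"]), ext["xmax"] - eps)
      out$y <- pmin(pmax(out$y, ext["ymin"]), ext["ymax"] - eps)
    }
    out$role <- "groundtruth"
    for (cl in unique(out$true_class)) {
      i <- which(out$true_class == cl)
      ncal <- round(calibration_fraction * length(i))
      if (ncal > 0) out$role[sample(i, ncal)] <- "calibration"
    }
    out$point_id <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
  })
}
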