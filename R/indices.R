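#' Normalized difference vegetation index
#'
#' Per-pixel `(nir - red) / (nir + red)`. Pixels where `nir + red == 0`
#' (and any input nodata) become nodata. On nonnegative reflectance inputs
#' the result is bounded in `[-1, 1]`.
#'
#' @param red,nir aligned [sep_raster()] layers.
#' @return a [sep_raster()] on the same grid.
#' @examples
#' r <- sep_raster(matrix(0.1, 2, 2)); n <- sep_raster(matrix(0.5, 2, 2))
#' rast_values(ndvi(r, n))[1, 1]  # 0.666...
#' @export
ndvi <- function(red, nir) {
  assert_aligned(red, nir)
  s <- nir$values + red$values
  v <- (nir$values - red$values) / s
  v[!is.na(s) & s == 0] <- NA
  rast_like(red, v)
}

#' Tasseled cap coefficient tables
#'
#' The shipped default is the published Landsat 8 at-satellite reflectance
#' coefficient set restricted to the three bands modeled here (red, NIR,
#' MIR = SWIR2); `full = TRUE` returns the six-band table for use with
#' complete scenes. Any named coefficient matrix with one column per
#' available band can be substituted.
#'
#' @param full return the six-band table instead of the red/nir/mir subset.
#' @return numeric matrix, rows brightness/greenness/wetness, columns bands.
#' @export
tct_coefficients_l8 <- function(full = FALSE) {
  tab <- rbind(
    brightness = c(0.3029, 0.2786, 0.4733, 0.5599, 0.5080, 0.1872),
    greenness  = c(-0.2941, -0.2430, -0.5424, 0.7276, 0.0713, -0.1608),
    wetness    = c(0.1511, 0.1973, 0.3283, 0.3407, -0.7117, -0.4559)
  )
  colnames(tab) <- c("blue", "green", "red", "nir", "swir1", "swir2")
  if (full) return(tab)
  out <- tab[, c("red", "nir", "swir2")]
  colnames(out) <- c("red", "nir", "mir")
  out
}

#' Tasseled cap transformation
#'
#' Compresses a multispectral band set into brightness, greenness and
#' wetness as per-pixel linear combinations with the chosen coefficients.
#'
#' @param bands named list of aligned [sep_raster()] layers (e.g. `red`,
#'   `nir`, `mir`); every band must have a matching coefficient column.
#' @param coefficients coefficient matrix (components x bands); default
#'   [tct_coefficients_l8()].
#' @return named list of rasters `brightness`, `greenness`, `wetness`.
#' @export
tasseled_cap <- function(bands, coefficients = tct_coefficients_l8()) {
  stopifnot(is.list(bands), !is.null(names(bands)))
  do.call(assert_aligned, unname(bands))
  missing <- setdiff(names(bands), colnames(coefficients))
  if (length(missing)) {
    stop("no tasseled cap coefficient for band(s): ",
         paste(missing, collapse = ", "))
  }
  tmpl <- bands[[1]]
  out <- list()
  for (comp in rownames(coefficients)) {
    acc <- matrix(0, nrow(tmpl$values), ncol(tmpl$values))
    for (b in names(bands)) {
      acc <- acc + coefficients[comp, b] * bands[[b]]$values
    }
    out[[comp]] <- rast_like(tmpl, acc)
  }
  out
}

#' Compute all derived layers for a two-season scene
#'
#' Returns the full named layer set the classifier draws on: the six
#' season-band rasters, per-season NDVI, and per-season tasseled cap
#' brightness/greenness/wetness (layer names like `ndvi_dry`,
#' `tct_wetness_rainy`). An elevation model, when given, is included as
#' layer `dem`.
#'
#' @param scene a [sep_scene()] with bands named `<season>_<band>`.
#' @param dem optional elevation [sep_raster()].
#' @param coefficients tasseled cap coefficient matrix.
#' @return named list of aligned [sep_raster()] layers.
#' @export
compute_indices <- function(scene, dem = NULL,
                            coefficients = tct_coefficients_l8()) {
  stopifnot(inherits(scene, "sep_scene"))
  layers <- scene$bands
  for (season in c("dry", "rainy")) {
    bn <- function(b) paste0(season, "_", b)
    have <- intersect(paste0(season, "_", c("red", "nir", "mir")),
                      names(scene$bands))
    if (!length(have)) next
    if (all(c(bn("red"), bn("nir")) %in% names(scene$bands))) {
      layers[[paste0("ndvi_", season)]] <-
        ndvi(scene$bands[[bn("red")]], scene$bands[[bn("nir")]])
    }
    sb <- scene$bands[have]
    names(sb) <- sub(paste0("^", season, "_"), "", have)
    tc <- tasseled_cap(sb, coefficients)
    for (comp in names(tc)) {
      layers[[paste0("tct_", comp, "_", season)]] <- tc[[comp]]
    }
  }
  if (!is.null(dem)) {
    assert_aligned(scene$bands[[1]], dem)
    layers[["dem"]] <- dem
  }
  layers
}

#' Per-class, per-layer calibration signatures
#'
#' Samples every layer at the calibration points (nearest-pixel lookup,
#' half-open cell convention) and reports per class x layer the sample size,
#' mean and sample (n-1) standard deviation. Classes with fewer than two
#' usable calibration points are skipped with a warning.
#'
#' @param layers named list of aligned [sep_raster()] layers.
#' @param points survey point data frame (`x`, `y`, `true_class`, `role`);
#'   only rows with `role == "calibration"` are used.
#' @return data frame with columns `class`, `layer`, `n`, `mean`, `sd`.
#' @export
class_signatures <- function(layers, points) {
  stopifnot(is.list(layers), !is.null(names(layers)))
  if ("role" %in% names(points)) {
    points <- points[points$role == "calibration", , drop = FALSE]
  }
  if (!nrow(points)) stop("no calibration points supplied")
  out <- list()
  for (cl in sort(unique(points$true_class))) {
    p <- points[points$true_class == cl, , drop = FALSE]
    vals0 <- rast_lookup(layers[[1]], p$x, p$y)
    usable <- sum(!is.na(vals0))
    if (usable < 2) {
      warning("class '", cl, "' has fewer than 2 calibration points in ",
              "extent; skipped")
      next
    }
    for (ly in names(layers)) {
      v <- rast_lookup(layers[[ly]], p$x, p$y)
      v <- v[!is.na(v)]
      out[[length(out) + 1]] <- data.frame(
        class = cl, layer = ly, n = length(v),
        mean = mean(v), sd = stats::sd(v))
    }
  }
  if (!length(out)) stop("no class had enough calibration points")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a signature table as delimited text
#'
#' @param signatures output of [class_signatures()].
#' @param path TSV path.
#' @export
write_signatures <- function(signatures, path) {
  utils::write.table(signatures, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' M statistic: spectral separability between two class signatures
#'
#' `M = |mean_a - mean_b| / (sd_a + sd_b)`. Values above about 1 indicate
#' classes that a single threshold on that layer can split well. When both
#' standard deviations are zero the statistic is 0 for equal means and
#' `Inf` (perfect separability) otherwise.
#'
#' @param a,b class signatures: one-row data frames or lists with `mean`
#'   and `sd` (and optionally `layer`, checked for agreement).
#' @return a nonnegative number (possibly `Inf`).
#' @examples
#' m_statistic(list(mean = 10, sd = 2), list(mean = 4, sd = 1))  # 2
#' @export
m_statistic <- function(a, b) {
  if (!is.null(a$layer) && !is.null(b$layer) &&
      !identical(as.character(a$layer), as.character(b$layer))) {
    stop("signatures are from different layers: ", a$layer, " vs ", b$layer)
  }
  num <- abs(a$mean - b$mean)
  den <- a$sd + b$sd
  if (den == 0) return(if (num == 0) 0 else Inf)
  num / den
}

#' Pairwise separability matrices per layer
#'
#' @param signatures output of [class_signatures()].
#' @return named list (one symmetric class x class matrix per layer).
#' @export
separability_matrix <- function(signatures) {
  out <- list()
  for (ly in unique(signatures$layer)) {
    s <- signatures[signatures$layer == ly, , drop = FALSE]
    cls <- s$class
    m <- matrix(0, length(cls), length(cls), dimnames = list(cls, cls))
    if (length(cls) > 1) {
      for (i in seq_along(cls)) for (j in seq_along(cls)) {
        if (i < j) {
          v <- m_statistic(s[i, ], s[j, ])
          m[i, j] <- v; m[j, i] <- v
        }
      }
    }
    out[[ly]] <- m
  }
  out
}
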