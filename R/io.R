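#' Read and write rasters as Esri ASCII grid
#'
#' Plain-text raster exchange in the standard ASCII grid layout (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `nodata_value` header, then
#' rows north to south). CRS units are stored in a `<path>.prj` sidecar text
#' file. Values are written at full double precision, so integer rasters
#' round-trip bit-identically and float rasters round-trip exactly in
#' practice (the format guarantees at least float tolerance).
#'
#' @param r a [sep_raster()].
#' @param path output `.asc` file path.
#' @param nodata value written for `NA` cells (default -9999).
#' @return `read_ascii_grid()` returns a [sep_raster()].
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  v <- r$values
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.17g", r$xmin),
    sprintf("yllcorner %.17g", r$ymin),
    sprintf("cellsize %.17g", r$pixel),
    sprintf("nodata_value %.17g", nodata)
  )
  v[is.na(v)] <- nodata
  rows <- apply(v, 1L, function(row) paste(sprintf("%.17g", row),
                                           collapse = " "))
  writeLines(c(hdr, rows), path)
  writeLines(c(paste0("name: ", r$crs$name), paste0("units: ", r$crs$units)),
             paste0(path, ".prj"))
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path)
  }
  body <- lines[i:length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != hdr$nrows) stop("row count mismatch in ", path)
  v <- t(vapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]),
                numeric(hdr$ncols), USE.NAMES = FALSE))
  if (!is.null(hdr$nodata_value)) v[v == hdr$nodata_value] <- NA
  crs <- metric_crs()
  prj <- paste0(path, ".prj")
  if (file.exists(prj)) {
    pl <- readLines(prj)
    get <- function(key) sub(paste0("^", key, ":\\s*"), "",
                             grep(paste0("^", key, ":"), pl, value = TRUE)[1])
    crs <- list(name = get("name"), units = get("units"))
  }
  sep_raster(v, xmin = hdr$xllcorner, ymin = hdr$yllcorner,
             pixel = hdr$cellsize, crs = crs)
}

#' Read and write point sets as GeoJSON
#'
#' Points are a data frame with `x`, `y` plus arbitrary attribute columns;
#' each row becomes a GeoJSON Point feature. CRS units travel in a
#' `crs_units` foreign member (GeoJSON proper is CRS-agnostic).
#'
#' @param points data frame with columns `x`, `y` and attributes.
#' @param path `.geojson` file path.
#' @param crs CRS tag ([metric_crs()] by default).
#' @return `read_points_geojson()` returns the data frame with the CRS tag
#'   in `attr(, "crs")`.
#' @export
write_points_geojson <- function(points, path, crs = metric_crs()) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  props <- setdiff(names(points), c("x", "y"))
  feats <- lapply(seq_len(nrow(points)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(points$x[i], points$y[i])),
         properties = as.list(points[i, props, drop = FALSE]))
  })
  obj <- list(type = "FeatureCollection",
              crs_name = crs$name, crs_units = crs$units,
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_points_geojson
#' @export
read_points_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  feats <- obj$features
  coords <- t(vapply(feats, function(f)
    as.numeric(unlist(f$geometry$coordinates)), numeric(2)))
  props <- lapply(feats, function(f) f$properties)
  df <- data.frame(x = coords[, 1], y = coords[, 2])
  if (length(props) && length(props[[1]])) {
    for (nm in names(props[[1]])) {
      df[[nm]] <- unlist(lapply(props, function(p)
        if (is.null(p[[nm]])) NA else p[[nm]]))
    }
  }
  attr(df, "crs") <- list(name = obj$crs_name %||% "unknown",
                          units = obj$crs_units %||% "m")
  df
}

#' Read and write polygon overlays as GeoJSON
#'
#' An overlay polygon is a list with numeric `x`, `y` ring coordinates (open
#' ring; closed on write) and optional `class`/`id` fields. A set of
#' overlays is a list of such polygons.
#'
#' @param polys list of polygons (each `list(x=, y=, class=, id=)`).
#' @param path `.geojson` file path.
#' @param crs CRS tag.
#' @return `read_polygons_geojson()` returns the list of polygons with the
#'   CRS tag in `attr(, "crs")`.
#' @export
write_polygons_geojson <- function(polys, path, crs = metric_crs()) {
  feats <- lapply(seq_along(polys), function(i) {
    p <- polys[[i]]
    ring <- cbind(p$x, p$y)
    if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(k) ring[k, ]))),
         properties = list(class = p$class %||% NA,
                           id = p$id %||% i))
  })
  obj <- list(type = "FeatureCollection",
              crs_name = crs$name, crs_units = crs$units,
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_polygons_geojson
#' @export
read_polygons_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  polys <- lapply(obj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(c2) as.numeric(unlist(c2))))
    # drop the closing vertex back off
    n <- nrow(ring)
    if (n > 1 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
    cls <- f$properties$class
    list(x = ring[, 1], y = ring[, 2],
         class = if (is.null(cls) || is.na(cls)) NULL else cls,
         id = f$properties$id)
  })
  attr(polys, "crs") <- list(name = obj$crs_name %||% "unknown",
                             units = obj$crs_units %||% "m")
  polys
}

#' Write the patch-code legend
#'
#' @param path output TSV path.
#' @return the legend data frame, invisibly.
#' @export
write_legend <- function(path) {
  leg <- data.frame(code = c(0L, seq_along(patch_classes())),
                    label = c("nodata", patch_classes()),
                    is_social_patch = c(FALSE,
                                        patch_classes() %in% social_patches()))
  utils::write.table(leg, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(leg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
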