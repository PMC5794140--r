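# Independent brute-force oracles. These re-derive expected results with
# explicit per-pixel loops and must stay independent of the package's
# vectorized code paths.

# per-pixel tree evaluation through the reference single-pixel router
oracle_classify <- function(layers, tree) {
  tmpl <- layers[[1]]
  v <- rast_values(tmpl)
  out <- matrix(NA_integer_, nrow(v), ncol(v))
  for (r in seq_len(nrow(v))) {
    for (c in seq_len(ncol(v))) {
      vals <- vapply(layers, function(l) rast_values(l)[r, c], numeric(1))
      lab <- classify_pixel(tree, vals)
      out[r, c] <- if (is.na(lab)) NA_integer_ else patch_code(lab)
    }
  }
  out
}

oracle_composition <- function(patch_map) {
  v <- rast_values(patch_map)
  counts <- numeric(length(patch_classes()))
  total <- 0
  for (val in v) {
    if (!is.na(val)) { counts[val] <- counts[val] + 1; total <- total + 1 }
  }
  100 * counts / total
}

oracle_confusion <- function(patch_map, points) {
  k <- length(patch_classes())
  m <- matrix(0L, k, k)
  for (i in seq_len(nrow(points))) {
    pred <- rast_lookup(patch_map, points$x[i], points$y[i])
    if (is.na(pred)) next
    true <- patch_code(points$true_class[i])
    m[pred, true] <- m[pred, true] + 1L
  }
  dimnames(m) <- list(patch_classes(), patch_classes())
  m
}

oracle_heat <- function(maps) {
  v1 <- rast_values(maps[[1]])
  out <- matrix(0, nrow(v1), ncol(v1))
  for (r in seq_len(nrow(v1))) for (c in seq_len(ncol(v1))) {
    s <- 0
    for (m in maps) s <- s + rast_values(m)[r, c]
    out[r, c] <- s
  }
  out
}

# exact Euclidean distance (in meters) to the nearest TRUE cell, by
# exhaustive pairwise search over pixel centers
oracle_edt <- function(mask, pixel) {
  seeds <- which(mask, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    out[r, c] <- sqrt(min((seeds[, 1] - r)^2 + (seeds[, 2] - c)^2)) * pixel
  }
  out
}

# even-odd point-in-polygon by explicit edge crossing count
oracle_pip <- function(poly, px, py) {
  x <- poly$x; y <- poly$y; n <- length(x)
  inside <- logical(length(px))
  for (p in seq_along(px)) {
    cnt <- 0L
    j <- n
    for (i in seq_len(n)) {
      if ((y[i] > py[p]) != (y[j] > py[p])) {
        xint <- x[i] + (py[p] - y[i]) / (y[j] - y[i]) * (x[j] - x[i])
        if (px[p] < xint) cnt <- cnt + 1L
      }
      j <- i
    }
    inside[p] <- (cnt %% 2L) == 1L
  }
  inside
}
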