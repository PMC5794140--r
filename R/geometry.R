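# Planar geometry helpers shared by the classifier and benefit stages.

#' Test points against a polygon ring
#'
#' Thin wrapper over `mgcv::in.out` (even-odd rule). Points exactly on the
#' boundary are not guaranteed in or out; callers keep test geometry off
#' pixel centers (the synthetic generator places overlay edges on pixel
#' boundaries for this reason).
#'
#' @param poly list with numeric `x`, `y` ring coordinates.
#' @param x,y point coordinate vectors.
#' @return logical vector, `TRUE` for inside.
#' @export
points_in_polygon <- function(poly, x, y) {
  ring <- cbind(poly$x, poly$y)
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  mgcv::in.out(ring, cbind(x, y))
}

#' Polygon area (shoelace formula)
#'
#' @param poly list with `x`, `y` ring coordinates (open or closed ring).
#' @return unsigned area in squared CRS units.
#' @export
polygon_area <- function(poly) {
  x <- poly$x; y <- poly$y
  n <- length(x)
  if (n > 1 && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]; n <- n - 1
  }
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Sutherland-Hodgman clip of a convex polygon by the half-plane
# a*x + b*y <= c. Returns list(x, y); empty vectors if nothing remains.
clip_halfplane <- function(poly, a, b, c) {
  x <- poly$x; y <- poly$y
  n <- length(x)
  if (n == 0) return(list(x = numeric(0), y = numeric(0)))
  f <- a * x + b * y - c            # <= 0 means inside
  ox <- numeric(0); oy <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ini <- f[i] <= 0; inj <- f[j] <= 0
    if (ini) { ox <- c(ox, x[i]); oy <- c(oy, y[i]) }
    if (xor(ini, inj)) {
      t <- f[i] / (f[i] - f[j])
      ox <- c(ox, x[i] + t * (x[j] - x[i]))
      oy <- c(oy, y[i] + t * (y[j] - y[i]))
    }
  }
  list(x = ox, y = oy)
}

# 8-connectivity labelling of a logical matrix by iterative minimum
# propagation (components here are compact blobs, so few sweeps converge).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- which(mask)
  shift <- function(m, dr, dc) {
    out <- matrix(Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  cur <- matrix(Inf, nr, nc)
  cur[mask] <- lab[mask]
  repeat {
    nxt <- cur
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nxt <- pmin(nxt, shift(cur, dr, dc))
    }
    nxt[!mask] <- Inf
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  out <- matrix(0L, nr, nc)
  out[mask] <- match(cur[mask], sort(unique(cur[mask])))
  out
}

# Trace the outer ring(s) of a set of pixels given by a logical matrix on a
# raster grid. Boundary edges are oriented counter-clockwise around the
# interior and chained into loops; rings with positive signed area are
# returned (holes are dropped). Coordinates lie on pixel boundaries, so
# re-rasterizing by pixel-center containment reproduces the pixel set.
trace_component <- function(mask, r) {
  nr <- nrow(mask); nc <- ncol(mask)
  px <- r$pixel
  cellx <- function(col) r$xmin + (col - 1) * px
  celly <- function(row) r$ymin + (nr - row) * px   # lower edge of cell
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list())
  inset <- function(row, col) {
    ok <- row >= 1 & row <= nr & col >= 1 & col <= nc
    out <- logical(length(row))
    out[ok] <- mask[cbind(row[ok], col[ok])]
    out
  }
  # directed edges (x1,y1)->(x2,y2), CCW around interior
  e <- list()
  for (k in seq_len(nrow(idx))) {
    row <- idx[k, 1]; col <- idx[k, 2]
    x0 <- cellx(col); x1 <- x0 + px
    y0 <- celly(row); y1 <- y0 + px
    if (!inset(row + 1, col)) e[[length(e) + 1]] <- c(x0, y0, x1, y0)  # S
    if (!inset(row, col + 1)) e[[length(e) + 1]] <- c(x1, y0, x1, y1)  # E
    if (!inset(row - 1, col)) e[[length(e) + 1]] <- c(x1, y1, x0, y1)  # N
    if (!inset(row, col - 1)) e[[length(e) + 1]] <- c(x0, y1, x0, y0)  # W
  }
  em <- do.call(rbind, e)
  keyfun <- function(x, y) paste(round(x / px * 2), round(y / px * 2))
  starts <- keyfun(em[, 1], em[, 2])
  used <- rep(FALSE, nrow(em))
  lookup <- split(seq_len(nrow(em)), starts)
  rings <- list()
  for (s in seq_len(nrow(em))) {
    if (used[s]) next
    ring_x <- em[s, 1]; ring_y <- em[s, 2]
    cur <- s
    repeat {
      used[cur] <- TRUE
      nx <- em[cur, 3]; ny <- em[cur, 4]
      ring_x <- c(ring_x, nx); ring_y <- c(ring_y, ny)
      cand <- lookup[[keyfun(nx, ny)]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      cur <- cand[1]
    }
    # closed loop: drop duplicate closing vertex
    n <- length(ring_x)
    if (n > 3 && ring_x[1] == ring_x[n] && ring_y[1] == ring_y[n]) {
      ring_x <- ring_x[-n]; ring_y <- ring_y[-n]
      # signed area: keep CCW (outer) rings only
      j <- c(length(ring_x), seq_len(length(ring_x) - 1))
      signed <- sum(ring_x[j] * ring_y - ring_x * ring_y[j]) / 2
      if (signed > 0) {
        rings[[length(rings) + 1]] <- list(x = ring_x, y = ring_y)
      }
    }
  }
  rings
}
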