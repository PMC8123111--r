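#' @title Bottom detection and the seafloor TIN
#'
#' @description
#' Per-beam bottom picks are triangulated into a triangulated irregular
#' network (TIN) which is resampled onto a 2 m x 2 m grid (maximum
#' triangulation distance 20 m) and used to exclude bottom-adjacent samples
#' from target detection.
#'
#' @name seafloor_tin
NULL

#' Detect the bottom in every beam of a ping
#'
#' The per-beam pick is the maximum-Sv sample beyond the near field; beams
#' without an echo above `min_sv` are skipped. Slant range and beam angle
#' convert the pick to a horizontal position and depth.
#'
#' @param fan a `ping_fan`.
#' @param min_sv minimum Sv (dB) for a valid bottom echo.
#' @param near_field ranges shallower than this (m) are ignored.
#' @return data.frame with columns `x`, `y`, `depth` (one row per detected
#'   beam), possibly empty.
#' @export
detect_bottom_per_beam <- function(fan, min_sv = -40, near_field = 4) {
  g <- fan$geom
  sv <- fan$sv
  sv[, g$range_axis < near_field] <- NA_real_
  pick <- integer(g$n_beams); val <- numeric(g$n_beams)
  for (b in seq_len(g$n_beams)) {
    v <- sv[b, ]
    if (all(is.na(v))) { pick[b] <- NA_integer_; next }
    i <- which.max(v)
    pick[b] <- i; val[b] <- v[i]
  }
  ok <- !is.na(pick) & val >= min_sv
  if (!any(ok)) return(data.frame(x = numeric(0), y = numeric(0), depth = numeric(0)))
  b <- which(ok)
  r <- g$range_axis[pick[b]]
  acr_y <- r * g$sin_a[b]
  depth <- r * g$cos_a[b]
  phi <- deg2rad(fan$nav[3])
  acr <- c(sin(phi), -cos(phi))
  data.frame(x = fan$nav[1] + acr_y * acr[1],
             y = fan$nav[2] + acr_y * acr[2],
             depth = depth)
}

# ---- Bowyer-Watson incremental Delaunay triangulation -----------------------
# No Delaunay provider is installed, so the classic incremental algorithm is
# implemented directly: points are inserted one at a time, triangles whose
# circumcircle contains the point are removed, and the resulting cavity is
# re-triangulated against the point. A tiny deterministic jitter breaks the
# co-circularity of gridded soundings.

circumcircle <- function(px, py, tri) {
  ax <- px[tri[, 1]]; ay <- py[tri[, 1]]
  bx <- px[tri[, 2]]; by <- py[tri[, 2]]
  cx <- px[tri[, 3]]; cy <- py[tri[, 3]]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  d[abs(d) < 1e-12] <- NA_real_
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  r2 <- (ax - ux)^2 + (ay - uy)^2
  r2[is.na(d)] <- Inf
  cbind(ux, uy, r2)
}

delaunay_triangulate <- function(x, y) {
  n <- length(x)
  if (n < 3) stop("need at least 3 points to triangulate")
  # deterministic jitter to break ties from gridded input
  scale <- max(diff(range(x)), diff(range(y)), 1)
  jit <- scale * 1e-7
  px <- x + jit * sin(seq_len(n) * 12.9898)
  py <- y + jit * sin(seq_len(n) * 78.233)
  # collinearity check
  cxm <- px - mean(px); cym <- py - mean(py)
  if (max(abs(cxm * cym[1] - cym * cxm[1])) < 1e-9 * scale^2 &&
      stats::sd(cxm) * stats::sd(cym) >= 0)
    if (abs(stats::cor(px, py)) > 1 - 1e-12 || stats::sd(px) == 0 || stats::sd(py) == 0)
      stop("collinear soundings cannot be triangulated")
  big <- 10 * scale
  mx <- mean(px); my <- mean(py)
  px <- c(px, mx - 3 * big, mx + 3 * big, mx)
  py <- c(py, my - big, my - big, my + 3 * big)
  sup <- n + 1:3
  tri <- matrix(sup, 1, 3)
  cc <- circumcircle(px, py, tri)
  for (i in seq_len(n)) {
    bad <- (px[i] - cc[, 1])^2 + (py[i] - cc[, 2])^2 <= cc[, 3] * (1 + 1e-12)
    if (!any(bad)) next  # degenerate; point skipped (cannot happen inside hull)
    badtri <- tri[bad, , drop = FALSE]
    tri <- tri[!bad, , drop = FALSE]
    cc <- cc[!bad, , drop = FALSE]
    edges <- rbind(badtri[, c(1, 2)], badtri[, c(2, 3)], badtri[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    keep <- !(key %in% key[duplicated(key)])
    edges <- edges[keep, , drop = FALSE]
    newtri <- cbind(edges, i)
    tri <- rbind(tri, newtri)
    cc <- rbind(cc, circumcircle(px, py, newtri))
  }
  keep <- !(tri[, 1] %in% sup | tri[, 2] %in% sup | tri[, 3] %in% sup)
  tri[keep, , drop = FALSE]
}

#' Build and resample the seafloor TIN
#'
#' Triangulates the soundings (Delaunay) and resamples the surface onto a
#' regular grid by planar interpolation on the containing triangle. Grid
#' nodes farther than `max_triangulation_distance` from any sounding, or
#' outside the convex hull, are undefined.
#'
#' @param soundings data.frame with columns `x`, `y`, `depth`.
#' @param res grid resolution (m).
#' @param max_triangulation_distance nodes farther than this (m) from any
#'   sounding are undefined.
#' @param max_points soundings are decimated to at most this many before
#'   triangulation.
#' @return an object of class `seafloor_tin`.
#' @export
build_and_resample_tin <- function(soundings, res = 2,
                                   max_triangulation_distance = 20,
                                   max_points = 1500) {
  stopifnot(all(c("x", "y", "depth") %in% names(soundings)))
  s <- soundings[stats::complete.cases(soundings[c("x", "y", "depth")]), ]
  if (nrow(s) < 3) stop("need at least 3 soundings")
  if (nrow(s) > max_points) {
    idx <- unique(as.integer(round(seq(1, nrow(s), length.out = max_points))))
    s <- s[idx, ]
  }
  tri <- delaunay_triangulate(s$x, s$y)
  if (nrow(tri) == 0) stop("collinear soundings cannot be triangulated")

  xs <- seq(floor(min(s$x)), ceiling(max(s$x)), by = res)
  ys <- seq(floor(min(s$y)), ceiling(max(s$y)), by = res)
  z <- matrix(NA_real_, length(xs), length(ys))
  for (t in seq_len(nrow(tri))) {
    i1 <- tri[t, 1]; i2 <- tri[t, 2]; i3 <- tri[t, 3]
    x1 <- s$x[i1]; y1 <- s$y[i1]; x2 <- s$x[i2]; y2 <- s$y[i2]
    x3 <- s$x[i3]; y3 <- s$y[i3]
    det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    if (abs(det) < 1e-12) next
    ix <- which(xs >= min(x1, x2, x3) - res & xs <= max(x1, x2, x3) + res)
    iy <- which(ys >= min(y1, y2, y3) - res & ys <= max(y1, y2, y3) + res)
    if (!length(ix) || !length(iy)) next
    gx <- rep(xs[ix], times = length(iy))
    gy <- rep(ys[iy], each = length(ix))
    l1 <- ((y2 - y3) * (gx - x3) + (x3 - x2) * (gy - y3)) / det
    l2 <- ((y3 - y1) * (gx - x3) + (x1 - x3) * (gy - y3)) / det
    l3 <- 1 - l1 - l2
    inb <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    if (!any(inb)) next
    zz <- l1 * s$depth[i1] + l2 * s$depth[i2] + l3 * s$depth[i3]
    sub <- cbind(rep(ix, times = length(iy))[inb], rep(iy, each = length(ix))[inb])
    z[sub] <- zz[inb]
  }
  # undefined beyond the maximum triangulation distance from any sounding
  near <- matrix(FALSE, length(xs), length(ys))
  rad <- ceiling(max_triangulation_distance / res)
  for (k in seq_len(nrow(s))) {
    ci <- round((s$x[k] - xs[1]) / res) + 1
    cj <- round((s$y[k] - ys[1]) / res) + 1
    ix <- max(1, ci - rad):min(length(xs), ci + rad)
    iy <- max(1, cj - rad):min(length(ys), cj + rad)
    dd <- outer((xs[ix] - s$x[k])^2, (ys[iy] - s$y[k])^2, `+`)
    near[ix, iy] <- near[ix, iy] | dd <= max_triangulation_distance^2
  }
  z[!near] <- NA_real_

  tin <- list(vertices = s, triangles = tri,
              grid = list(xs = xs, ys = ys, z = z),
              res = res, max_triangulation_distance = max_triangulation_distance)
  class(tin) <- "seafloor_tin"
  tin
}

#' @export
print.seafloor_tin <- function(x, ...) {
  cat(sprintf("Seafloor TIN: %d soundings, %d triangles, %d x %d grid @ %g m\n",
              nrow(x$vertices), nrow(x$triangles),
              length(x$grid$xs), length(x$grid$ys), x$res))
  zr <- range(x$grid$z, na.rm = TRUE)
  cat(sprintf("  depth %.2f-%.2f m; undefined nodes: %d\n", zr[1], zr[2],
              sum(is.na(x$grid$z))))
  invisible(x)
}

#' Look up seafloor depth on the resampled TIN grid
#'
#' Bilinear interpolation on the 2 m grid; undefined (or out-of-grid)
#' positions return `NA`.
#'
#' @param tin a `seafloor_tin`.
#' @param x,y query coordinates (m), vectorized.
#' @return numeric vector of depths (m), `NA` where undefined.
#' @export
tin_depth_at <- function(tin, x, y) {
  xs <- tin$grid$xs; ys <- tin$grid$ys; z <- tin$grid$z
  fx <- (x - xs[1]) / tin$res + 1
  fy <- (y - ys[1]) / tin$res + 1
  i0 <- floor(fx); j0 <- floor(fy)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(fx) & !is.na(fy) &
    i0 >= 1 & i0 <= length(xs) - 1 & j0 >= 1 & j0 <= length(ys) - 1
  # exact node hits on the grid edge
  edge <- !ok & !is.na(fx) & !is.na(fy) &
    abs(fx - round(fx)) < 1e-9 & abs(fy - round(fy)) < 1e-9 &
    round(fx) >= 1 & round(fx) <= length(xs) & round(fy) >= 1 & round(fy) <= length(ys)
  if (any(edge))
    out[edge] <- z[cbind(round(fx[edge]), round(fy[edge]))]
  if (any(ok)) {
    i0k <- i0[ok]; j0k <- j0[ok]
    tx <- fx[ok] - i0k; ty <- fy[ok] - j0k
    z00 <- z[cbind(i0k, j0k)];     z10 <- z[cbind(i0k + 1, j0k)]
    z01 <- z[cbind(i0k, j0k + 1)]; z11 <- z[cbind(i0k + 1, j0k + 1)]
    out[ok] <- z00 * (1 - tx) * (1 - ty) + z10 * tx * (1 - ty) +
      z01 * (1 - tx) * ty + z11 * tx * ty
  }
  out
}

#' Write the resampled TIN grid as an ESRI ASCII raster
#'
#' @param tin a `seafloor_tin`.
#' @param path output file.
#' @param nodata value written for undefined cells.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(tin, path, nodata = -9999) {
  z <- tin$grid$z
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", length(tin$grid$xs)),
    sprintf("nrows %d", length(tin$grid$ys)),
    sprintf("xllcorner %.3f", tin$grid$xs[1] - tin$res / 2),
    sprintf("yllcorner %.3f", tin$grid$ys[1] - tin$res / 2),
    sprintf("cellsize %g", tin$res),
    sprintf("NODATA_value %g", nodata)), con)
  for (j in rev(seq_along(tin$grid$ys))) {  # north to south
    row <- z[, j]
    row[is.na(row)] <- nodata
    writeLines(paste(format(row, trim = TRUE), collapse = " "), con)
  }
  invisible(path)
}
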