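#' @title Per-ping slice detection, extrusion and region tracking
#'
#' @description
#' "School detection": 8-connected components of above-threshold samples in
#' the beam x range-bin lattice of each ping, mapped to the across-track /
#' depth plane as polygon "slices", extruded to 0.8 m polyhedra, and grouped
#' across pings into multi-ping objects by centroid proximity.
#'
#' @name extraction
NULL

# 8-connected component labelling of a set of lattice cells. `cells` is an
# integer matrix (row = cell, columns beam, bin). Returns a component id per
# cell (consecutive from 1).
label_components8 <- function(cells, n_beams) {
  n <- nrow(cells)
  if (n == 0) return(integer(0))
  key <- cells[, 1] + (cells[, 2] - 1) * n_beams
  ord <- order(key)
  skey <- key[ord]
  comp <- integer(n)
  cur <- 0L
  offs <- as.vector(outer(c(-1L, 0L, 1L), c(-1L, 0L, 1L) * n_beams, `+`))
  offs <- offs[offs != 0L]
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    stack <- i
    comp[i] <- cur
    while (length(stack)) {
      c0 <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nk <- key[c0] + offs
      # guard against wrap-around across the beam axis
      b0 <- cells[c0, 1]
      nk <- nk[abs(((nk - 1) %% n_beams + 1) - b0) <= 1]
      j <- ord[findInterval(nk, skey)]
      j <- j[!is.na(j) & j > 0]
      j <- j[key[j] %in% nk & comp[j] == 0L]
      if (length(j)) {
        comp[j] <- cur
        stack <- c(stack, j)
      }
    }
  }
  comp
}

# Trace the outer boundary polygon of a union of lattice cells. Works in the
# corner lattice (beam boundary i, range boundary j): interior shared edges
# cancel, the remaining directed edges chain into loops, and the loop with
# the largest absolute area is the outer ring. Collinear lattice vertices are
# collapsed.
trace_cell_boundary <- function(cells) {
  b <- cells[, 1]; r <- cells[, 2]
  # directed edges per cell, CCW in (i, j) corner space
  e_from <- rbind(cbind(b, r), cbind(b + 1L, r), cbind(b + 1L, r + 1L), cbind(b, r + 1L))
  e_to   <- rbind(cbind(b + 1L, r), cbind(b + 1L, r + 1L), cbind(b, r + 1L), cbind(b, r))
  M <- 2L^20L
  ek <- function(a, d) (a[, 1] * M + a[, 2]) * 4 + d
  und <- paste(pmin(e_from[, 1] * M + e_from[, 2], e_to[, 1] * M + e_to[, 2]),
               pmax(e_from[, 1] * M + e_from[, 2], e_to[, 1] * M + e_to[, 2]))
  keep <- !(und %in% und[duplicated(und)])
  e_from <- e_from[keep, , drop = FALSE]
  e_to <- e_to[keep, , drop = FALSE]
  n_e <- nrow(e_from)
  from_key <- e_from[, 1] * M + e_from[, 2]
  used <- logical(n_e)
  loops <- list()
  for (start in seq_len(n_e)) {
    if (used[start]) next
    loop <- matrix(0L, 0, 2)
    cur <- start
    repeat {
      used[cur] <- TRUE
      loop <- rbind(loop, e_from[cur, , drop = FALSE])
      nxt <- which(!used & from_key == e_to[cur, 1] * M + e_to[cur, 2])
      if (!length(nxt)) break
      cur <- nxt[1]
    }
    loops[[length(loops) + 1L]] <- loop
  }
  areas <- vapply(loops, function(L) {
    xs <- L[, 1]; ys <- L[, 2]
    abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  }, 0)
  L <- loops[[which.max(areas)]]
  # collapse collinear runs (lattice edges share a direction)
  n <- nrow(L)
  if (n > 2) {
    dirs <- diff(rbind(L, L[1, , drop = FALSE]))
    prev <- rbind(dirs[n, , drop = FALSE], dirs[-n, , drop = FALSE])
    corner <- dirs[, 1] != prev[, 1] | dirs[, 2] != prev[, 2]
    L <- L[corner, , drop = FALSE]
  }
  L
}

shoelace_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

shoelace_centroid <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

# Beam-boundary angles (degrees) for a fan geometry: midpoints between
# adjacent merged beams, extrapolated by half a step at the fan edges.
beam_boundaries <- function(geom) {
  a <- geom$angles
  n <- length(a)
  c(a[1] - (a[2] - a[1]) / 2, (a[-n] + a[-1]) / 2, a[n] + (a[n] - a[n - 1]) / 2)
}

#' Detect target slices in one ping
#'
#' Thresholds the (smoothed, masked) fan and extracts 8-connected components
#' of above-threshold samples in the beam x range-bin lattice. Components
#' are mapped to the across-track/depth plane, sized, and kept when they
#' meet the minimum height and width; each surviving component becomes a
#' `slice_region` carrying its boundary polygon, member samples and
#' centroids.
#'
#' @param fan a `ping_fan` (typically smoothed).
#' @param sv_threshold detection threshold (dB).
#' @param min_height,min_width minimum vertical/across-track extent (m).
#' @param mask optional logical matrix from [exclusion_mask()]; `TRUE` cells
#'   are ignored.
#' @return list of `slice_region` objects (possibly empty).
#' @export
detect_slices <- function(fan, sv_threshold = -65, min_height = 1,
                          min_width = 1, mask = NULL) {
  g <- fan$geom
  active <- !is.na(fan$sv) & fan$sv >= sv_threshold
  if (!is.null(mask)) active <- active & !mask
  cells <- which(active, arr.ind = TRUE)
  if (nrow(cells) == 0) return(list())
  comp <- label_components8(cells, g$n_beams)
  thb <- deg2rad(beam_boundaries(g))
  phi <- deg2rad(fan$nav[3])
  acr <- c(sin(phi), -cos(phi))
  out <- list()
  for (cid in seq_len(max(comp))) {
    cc <- cells[comp == cid, , drop = FALSE]
    b <- cc[, 1]; r <- cc[, 2]
    # exact cell corners in the across/depth plane
    r_lo <- (r - 1) * g$cfg$range_bin; r_hi <- r * g$cfg$range_bin
    t_lo <- thb[b]; t_hi <- thb[b + 1]
    d_corners <- cbind(r_lo * cos(t_lo), r_lo * cos(t_hi),
                       r_hi * cos(t_lo), r_hi * cos(t_hi))
    y_corners <- cbind(r_lo * sin(t_lo), r_lo * sin(t_hi),
                       r_hi * sin(t_lo), r_hi * sin(t_hi))
    height <- max(d_corners) - min(d_corners)
    width <- max(y_corners) - min(y_corners)
    if (height < min_height || width < min_width) next
    # exact quad areas (corners ordered lo-lo, lo-hi, hi-hi, hi-lo)
    qx <- cbind(y_corners[, 1], y_corners[, 2], y_corners[, 4], y_corners[, 3])
    qy <- cbind(d_corners[, 1], d_corners[, 2], d_corners[, 4], d_corners[, 3])
    cell_area <- abs(qx[, 1] * qy[, 2] - qx[, 2] * qy[, 1] +
                     qx[, 2] * qy[, 3] - qx[, 3] * qy[, 2] +
                     qx[, 3] * qy[, 4] - qx[, 4] * qy[, 3] +
                     qx[, 4] * qy[, 1] - qx[, 1] * qy[, 4]) / 2
    ring <- trace_cell_boundary(cc)
    rr <- (ring[, 2] - 1) * g$cfg$range_bin
    tt <- thb[ring[, 1]]
    poly <- cbind(across = rr * sin(tt), depth = rr * cos(tt))
    area <- abs(shoelace_area(poly))
    cen <- shoelace_centroid(poly)
    sv <- fan$sv[cc]
    s <- list(ping_id = fan$ping_id, time = fan$time, nav = fan$nav,
              cells = cc, sv = sv, cell_area = cell_area,
              sample_across = g$Y[cc], sample_depth = g$D[cc],
              polygon = poly, area = area,
              perimeter = sum(sqrt(rowSums(diff(rbind(poly, poly[1, ]))^2))),
              centroid = c(across = cen[1], depth = cen[2]),
              world_centroid = c(x = fan$nav[1] + cen[1] * acr[1],
                                 y = fan$nav[2] + cen[1] * acr[2],
                                 depth = cen[2]),
              beams = sort(unique(b)), n_beams_fan = g$n_beams,
              height = height, width = width)
    class(s) <- "slice_region"
    out[[length(out) + 1L]] <- s
  }
  out
}

#' @export
print.slice_region <- function(x, ...) {
  cat(sprintf("slice (ping %d): %d cells, %.1f x %.1f m, area %.2f m2, centroid %.1f m depth\n",
              x$ping_id, nrow(x$cells), x$width, x$height, x$area,
              x$centroid["depth"]))
  invisible(x)
}

# Ear-clipping triangulation of a simple polygon; returns (n-2) x 3 indices.
ear_clip <- function(p) {
  n <- nrow(p)
  if (n < 3) stop("degenerate polygon")
  if (shoelace_area(p) < 0) p <- p[n:1, , drop = FALSE]
  idx <- seq_len(n)
  tris <- matrix(0L, 0, 3)
  guard <- 0L
  while (length(idx) > 3 && guard < n * n) {
    guard <- guard + 1L
    m <- length(idx)
    clipped <- FALSE
    for (k in seq_len(m)) {
      a <- idx[(k - 2) %% m + 1]; b <- idx[(k - 1) %% m + 1]; c <- idx[k %% m + 1]
      cr <- (p[b, 1] - p[a, 1]) * (p[c, 2] - p[a, 2]) -
            (p[b, 2] - p[a, 2]) * (p[c, 1] - p[a, 1])
      if (cr <= 1e-12) next
      others <- setdiff(idx, c(a, b, c))
      if (length(others)) {
        d1 <- (p[b, 1] - p[a, 1]) * (p[others, 2] - p[a, 2]) -
              (p[b, 2] - p[a, 2]) * (p[others, 1] - p[a, 1])
        d2 <- (p[c, 1] - p[b, 1]) * (p[others, 2] - p[b, 2]) -
              (p[c, 2] - p[b, 2]) * (p[others, 1] - p[b, 1])
        d3 <- (p[a, 1] - p[c, 1]) * (p[others, 2] - p[c, 2]) -
              (p[a, 2] - p[c, 2]) * (p[others, 1] - p[c, 1])
        if (any(d1 > 0 & d2 > 0 & d3 > 0)) next
      }
      tris <- rbind(tris, c(a, b, c))
      idx <- idx[idx != b]
      clipped <- TRUE
      break
    }
    if (!clipped) {  # numerically stuck: fan out the remainder
      for (k in 2:(length(idx) - 1))
        tris <- rbind(tris, c(idx[1], idx[k], idx[k + 1]))
      idx <- idx[1:3]
      tris <- tris[seq_len(n - 2), , drop = FALSE]
      return(tris)
    }
  }
  rbind(tris, idx)
}

#' Extrude a slice polygon to a 0.8 m polyhedron
#'
#' The cross-section polygon is copied 0.4 m fore and aft along-track and
#' closed with triangulated caps and side walls: a prism with `2n` vertices
#' and `2(n-2) + 2n` triangles for an `n`-vertex polygon.
#'
#' @param s a `slice_region`.
#' @param thickness along-track thickness (m).
#' @return list with `vertices` (2n x 3: along, across, depth), `triangles`
#'   (index matrix), `surface_area` (m2), `volume` (m3), `thickness`.
#' @export
extrude_slice <- function(s, thickness = 0.8) {
  p <- s$polygon
  n <- nrow(p)
  if (n < 3 || abs(shoelace_area(p)) < 1e-9) stop("degenerate polygon")
  h <- thickness / 2
  v1 <- cbind(along = -h, across = p[, 1], depth = p[, 2])
  v2 <- cbind(along = +h, across = p[, 1], depth = p[, 2])
  verts <- rbind(v1, v2)
  cap <- ear_clip(p)
  tris <- rbind(cap,                                  # near cap
                cap[, c(1, 3, 2), drop = FALSE] + n,  # far cap (flipped)
                do.call(rbind, lapply(seq_len(n), function(i) {
                  j <- i %% n + 1
                  rbind(c(i, j, i + n), c(j, j + n, i + n))
                })))
  area <- abs(shoelace_area(p))
  list(vertices = verts, triangles = tris,
       surface_area = 2 * area + s$perimeter * thickness,
       volume = area * thickness, thickness = thickness)
}

#' Group slices across pings into multi-ping objects
#'
#' Slices in pings at most `max_ping_gap` apart whose 3D world centroids lie
#' within `max_distance` are linked; multi-ping objects are the connected
#' components of the link graph (singletons allowed).
#'
#' @param slices list of `slice_region`s from all pings.
#' @param max_distance centroid linking distance (m).
#' @param max_ping_gap maximum ping-id gap for a link.
#' @return list of `multi_ping_object`s, each with `object_id`, `slice_idx`
#'   (indices into `slices`, ordered by ping) and `ping_ids`.
#' @export
track_regions <- function(slices, max_distance = 5, max_ping_gap = 1) {
  n <- length(slices)
  if (n == 0) return(list())
  pid <- vapply(slices, function(s) s$ping_id, 0L)
  cen <- t(vapply(slices, function(s) s$world_centroid, numeric(3)))
  from <- integer(0); to <- integer(0)
  for (gap in seq_len(max_ping_gap)) {
    for (p in sort(unique(pid))) {
      i <- which(pid == p); j <- which(pid == p + gap)
      if (!length(i) || !length(j)) next
      d2 <- outer(cen[i, 1], cen[j, 1], `-`)^2 +
        outer(cen[i, 2], cen[j, 2], `-`)^2 +
        outer(cen[i, 3], cen[j, 3], `-`)^2
      hit <- which(d2 <= max_distance^2, arr.ind = TRUE)
      if (nrow(hit)) {
        from <- c(from, i[hit[, 1]])
        to <- c(to, j[hit[, 2]])
      }
    }
  }
  gr <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0L, n - igraph::vcount(gr)))
  comp <- igraph::components(gr)$membership[seq_len(n)]
  objs <- lapply(sort(unique(comp)), function(k) {
    idx <- which(comp == k)
    idx <- idx[order(pid[idx])]
    o <- list(object_id = 0L, slice_idx = idx, ping_ids = pid[idx])
    class(o) <- "multi_ping_object"
    o
  })
  # stable object ids ordered by first ping then first slice index
  ord <- order(vapply(objs, function(o) min(o$ping_ids), 0L),
               vapply(objs, function(o) min(o$slice_idx), 0L))
  objs <- objs[ord]
  for (k in seq_along(objs)) objs[[k]]$object_id <- k
  objs
}

#' @export
print.multi_ping_object <- function(x, ...) {
  cat(sprintf("multi-ping object %d: %d slices over pings %d-%d\n",
              x$object_id, length(x$slice_idx), min(x$ping_ids), max(x$ping_ids)))
  invisible(x)
}

# slice index -> object id lookup for a tracked slice set
slice_object_map <- function(objects, n_slices) {
  m <- integer(n_slices)
  for (o in objects) m[o$slice_idx] <- o$object_id
  m
}
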