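#' @title The 24-metric slice classification schema
#'
#' @description
#' Per-slice metrics used for target classification: position (geometric and
#' mass centres, flattened coordinates), shape (height, surface area, base,
#' bounding-box lengths, vertex/triangle counts), backscatter (linear-domain
#' sample mean, max-minus-mean difference), swath intersection, the
#' per-object vertical velocity (relative depth in time) and the k-means
#' cluster feature.
#'
#' @name slice_metrics
NULL

#' The 24 feature column names
#' @return character vector of the schema column names, in order.
#' @export
feature_schema <- function() c(
  "x", "y",
  "Geometric center latitude", "Geometric center longitude",
  "Mass center latitude", "Mass center longitude",
  "Geometric center depth", "Mass center depth", "Depth ratio",
  "Vertices", "Triangles", "Height", "Surface area", "Base", "Cluster",
  "Length 1", "Length 2", "Length ratio", "Relative depth in time",
  "Sv_UNCAL diff", "Sample mean", "Beams",
  "Intersection area first beam", "Intersection area last beam")

#' Coordinate columns excluded from normalization and ensemble training
#' @return character vector of the six raw-coordinate column names.
#' @export
coordinate_columns <- function() c(
  "x", "y",
  "Geometric center latitude", "Geometric center longitude",
  "Mass center latitude", "Mass center longitude")

#' Local equirectangular projection about a survey origin
#'
#' `flatten_coords()` converts latitude/longitude to zero-centred metres
#' (x = northing from latitude, y = easting from longitude, following the
#' schema's "flattened latitude"/"flattened longitude" convention);
#' `unflatten_coords()` is its exact inverse.
#'
#' @param lat,lon decimal degrees.
#' @param origin c(lat, lon) of the projection centre.
#' @return two-column matrix (`x`, `y`) in metres.
#' @export
flatten_coords <- function(lat, lon, origin) {
  cbind(x = (lat - origin[1]) * .M_PER_DEG,
        y = (lon - origin[2]) * .M_PER_DEG * cos(deg2rad(origin[1])))
}

#' @rdname flatten_coords
#' @param x,y flattened metres (northing, easting).
#' @export
unflatten_coords <- function(x, y, origin) {
  cbind(lat = origin[1] + x / .M_PER_DEG,
        lon = origin[2] + y / (.M_PER_DEG * cos(deg2rad(origin[1]))))
}

# survey-frame (east, north) metres -> (lat, lon)
survey_to_latlon <- function(ex, ny, cfg) {
  cbind(lat = cfg$origin_lat + ny / .M_PER_DEG,
        lon = cfg$origin_lon + ex / (.M_PER_DEG * cos(deg2rad(cfg$origin_lat))))
}

#' Geometric centre of a slice polyhedron
#'
#' Unweighted centroid of the extruded prism: the polygon area centroid in
#' the across-track/depth plane at the ping's along-track position.
#'
#' @param s a `slice_region`.
#' @param cfg the `survey_config` (for the geographic origin).
#' @return named vector (lat, lon, depth).
#' @export
geometric_center <- function(s, cfg) {
  ll <- survey_to_latlon(s$world_centroid["x"], s$world_centroid["y"], cfg)
  c(lat = unname(ll[1, "lat"]), lon = unname(ll[1, "lon"]),
    depth = unname(s$world_centroid["depth"]))
}

#' Mass centre of a slice
#'
#' Member-sample centroid weighted by linear-domain backscatter power.
#'
#' @inheritParams geometric_center
#' @return named vector (lat, lon, depth).
#' @export
mass_center <- function(s, cfg) {
  w <- db_to_linear(s$sv)
  acr <- sum(w * s$sample_across) / sum(w)
  dep <- sum(w * s$sample_depth) / sum(w)
  phi <- deg2rad(s$nav[3])
  av <- c(sin(phi), -cos(phi))
  wx <- s$nav[1] + acr * av[1]
  wy <- s$nav[2] + acr * av[2]
  ll <- survey_to_latlon(wx, wy, cfg)
  c(lat = unname(ll[1, "lat"]), lon = unname(ll[1, "lon"]), depth = dep)
}

#' Shape metrics of a slice
#'
#' Height (max minus min depth), polyhedron surface area, vertex and
#' triangle counts of the extruded prism, base (surface area / height), and
#' the two longest dimensions of the transect-aligned bounding box
#' (along-track thickness x across-track width x height).
#'
#' @param s a `slice_region`.
#' @param thickness along-track extrusion thickness (m).
#' @return named list.
#' @export
shape_metrics <- function(s, thickness = 0.8) {
  poly <- extrude_slice(s, thickness)
  n <- nrow(s$polygon)
  dims <- sort(c(thickness, s$width, s$height), decreasing = TRUE)
  list(height = s$height, surface_area = poly$surface_area,
       vertices = 2L * n, triangles = nrow(poly$triangles),
       base = poly$surface_area / s$height,
       length1 = dims[1], length2 = dims[2],
       length_ratio = dims[2] / dims[1], volume = poly$volume)
}

#' Depth ratio of a slice
#'
#' Ratio between the geometric-centre and mass-centre depths; below 1 when
#' the backscatter mass sits deeper than the geometric centre (typical of
#' platform legs).
#'
#' @inheritParams geometric_center
#' @return scalar.
#' @export
depth_ratio <- function(s, cfg) {
  g <- geometric_center(s, cfg)["depth"]
  m <- mass_center(s, cfg)["depth"]
  unname(g / m)
}

#' Backscatter metrics of a slice
#'
#' Sample mean computed in the linear power domain and reported in dB, and
#' the (non-negative) difference between maximum and mean in dB.
#'
#' @param s a `slice_region`.
#' @return named vector (`sample_mean`, `sv_diff`), both dB.
#' @export
sv_metrics <- function(s) {
  mn <- linear_to_db(mean(db_to_linear(s$sv)))
  c(sample_mean = mn, sv_diff = max(s$sv) - mn)
}

#' Vertical velocity of slices within a multi-ping object
#'
#' For consecutive slices, `(depth_i - depth_{i+1}) / dt`, so a rising
#' target is positive; the last slice inherits the previous value and
#' singleton objects get 0.
#'
#' @param depth per-slice depths (m), ordered by ping.
#' @param time per-slice times (s), same order.
#' @return numeric vector of m/s, one value per slice.
#' @export
relative_depth_in_time <- function(depth, time) {
  n <- length(depth)
  if (n < 2) return(rep(0, n))
  v <- (depth[-n] - depth[-1]) / (time[-1] - time[-n])
  c(v, v[n - 1])
}

#' Beam intersection metrics of a slice
#'
#' Number of beams intersecting the slice, and the member-cell area falling
#' in the fan's first and last beams (non-zero only when the slice is
#' clipped by the swath edge).
#'
#' @param s a `slice_region`.
#' @return named list (`beams`, `first_area`, `last_area`).
#' @export
beam_metrics <- function(s) {
  b <- s$cells[, 1]
  list(beams = length(unique(b)),
       first_area = sum(s$cell_area[b == 1L]),
       last_area = sum(s$cell_area[b == s$n_beams_fan]))
}

#' K-means cluster feature
#'
#' K-means (k = 4) on standardized Vertices, Mass center latitude and Mass
#' center longitude; codes 0-3 are relabelled by ascending cluster-centre
#' vertex count so refits with the same seed are stable.
#'
#' @param table a feature data.frame containing the three input columns.
#' @param k number of clusters.
#' @param seed RNG seed for the k-means initialisation.
#' @return integer vector of cluster codes in `0:(k-1)`.
#' @export
cluster_feature <- function(table, k = 4, seed = 1L) {
  cols <- c("Vertices", "Mass center latitude", "Mass center longitude")
  miss <- setdiff(cols, names(table))
  if (length(miss)) stop("missing cluster input columns: ", paste(miss, collapse = ", "))
  X <- as.matrix(table[cols])
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0 | is.na(sds)] <- 1
  X <- scale(X, center = colMeans(X), scale = sds)
  if (nrow(unique(X)) < k) {
    # degenerate input: fewer distinct points than clusters
    codes <- as.integer(factor(apply(X, 1, paste, collapse = "/"))) - 1L
    return(pmin(codes, k - 1L))
  }
  set.seed(derive_seed(seed, "kmeans"))
  km <- stats::kmeans(X, centers = k, nstart = 10, iter.max = 50)
  relabel <- order(km$centers[, 1])
  match(km$cluster, relabel) - 1L
}

#' Compute the 24-metric feature table for tracked slices
#'
#' One row per slice with the full classification schema plus `slice_id`,
#' `ping_id` and `object_id` bookkeeping columns and an empty `label`
#' column. The flattened x/y are the mass-centre coordinates projected
#' about the survey origin.
#'
#' @param slices list of `slice_region`s.
#' @param objects list of `multi_ping_object`s from [track_regions()].
#' @param cfg the `survey_config`.
#' @param thickness extrusion thickness (m).
#' @param cluster_seed seed for the k-means cluster feature.
#' @return data.frame with 24 metric columns (exact schema names) plus
#'   `slice_id`, `ping_id`, `object_id`, `label`.
#' @export
compute_slice_metrics <- function(slices, objects, cfg, thickness = 0.8,
                                  cluster_seed = cfg$seed) {
  n <- length(slices)
  if (n == 0) stop("no slices to characterize")
  obj_of <- slice_object_map(objects, n)
  gc <- t(vapply(slices, geometric_center, numeric(3), cfg = cfg))
  mc <- t(vapply(slices, mass_center, numeric(3), cfg = cfg))
  sm <- lapply(slices, shape_metrics, thickness = thickness)
  sv <- t(vapply(slices, sv_metrics, numeric(2)))
  bm <- lapply(slices, beam_metrics)
  flat <- flatten_coords(mc[, "lat"], mc[, "lon"],
                         c(cfg$origin_lat, cfg$origin_lon))

  rdit <- numeric(n)
  times <- vapply(slices, function(s) s$time, 0)
  for (o in objects) {
    idx <- o$slice_idx
    # an object may hold several slices of one ping: aggregate per ping
    # time before differencing so dt is never zero
    tu <- sort(unique(times[idx]))
    du <- vapply(tu, function(t) mean(gc[idx, "depth"][times[idx] == t]), 0)
    vu <- relative_depth_in_time(du, tu)
    rdit[idx] <- vu[match(times[idx], tu)]
  }

  df <- data.frame(check.names = FALSE,
    `x` = flat[, "x"], `y` = flat[, "y"],
    `Geometric center latitude` = gc[, "lat"],
    `Geometric center longitude` = gc[, "lon"],
    `Mass center latitude` = mc[, "lat"],
    `Mass center longitude` = mc[, "lon"],
    `Geometric center depth` = gc[, "depth"],
    `Mass center depth` = mc[, "depth"],
    `Depth ratio` = gc[, "depth"] / mc[, "depth"],
    `Vertices` = vapply(sm, function(m) m$vertices, 0L),
    `Triangles` = vapply(sm, function(m) m$triangles, 0L),
    `Height` = vapply(sm, function(m) m$height, 0),
    `Surface area` = vapply(sm, function(m) m$surface_area, 0),
    `Base` = vapply(sm, function(m) m$base, 0),
    `Cluster` = 0L,
    `Length 1` = vapply(sm, function(m) m$length1, 0),
    `Length 2` = vapply(sm, function(m) m$length2, 0),
    `Length ratio` = vapply(sm, function(m) m$length_ratio, 0),
    `Relative depth in time` = rdit,
    `Sv_UNCAL diff` = sv[, "sv_diff"],
    `Sample mean` = sv[, "sample_mean"],
    `Beams` = vapply(bm, function(m) m$beams, 0L),
    `Intersection area first beam` = vapply(bm, function(m) m$first_area, 0),
    `Intersection area last beam` = vapply(bm, function(m) m$last_area, 0))
  df$Cluster <- cluster_feature(df, k = 4, seed = cluster_seed)
  df$slice_id <- seq_len(n)
  df$ping_id <- vapply(slices, function(s) s$ping_id, 0L)
  df$object_id <- obj_of
  df$label <- NA_character_
  df
}
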