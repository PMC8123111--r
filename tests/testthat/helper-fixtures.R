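# Shared fixtures: small, fast survey configurations and hand-built fans.

# A shallow single-transect survey with a reduced beam count: fast enough for
# unit tests while keeping the full two-transducer geometry.
tiny_config <- function(seed = 1L, ...) {
  args <- list(water_depth = 30, area_side = 40, n_transects = 1,
               transect_spacing = 40, n_beams_per_transducer = 64L,
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(survey_config, args)
}

# Wrap a plain matrix as a stacked echogram (ping x range), 0.64 m bins.
echogram_from_matrix <- function(m, range_bin = 0.64) {
  e <- list(mat = m, ping_ids = seq_len(nrow(m)),
            range_axis = (seq_len(ncol(m)) - 0.5) * range_bin)
  class(e) <- "stacked_echogram"
  e
}

# A minimal hand-built ping fan with a vertical fan geometry; `sv` is a
# beam x range matrix. Used where tests need full control of the samples.
manual_fan <- function(sv, truth = NULL, ping_id = 1L, time = 0,
                       nav = c(0, 0, 0), fan_width = 60, range_bin = 0.64) {
  nb <- nrow(sv); nr <- ncol(sv)
  cfg <- list(range_bin = range_bin, along_beamwidth = 1,
              background_sv = -75, water_depth = nr * range_bin)
  angles <- seq(-fan_width / 2, fan_width / 2, length.out = nb)
  g <- new.env(parent = emptyenv())
  g$angles <- angles
  g$transducer <- rep(1:2, length.out = nb)
  g$range_axis <- (seq_len(nr) - 0.5) * range_bin
  g$n_beams <- nb; g$n_bins <- nr
  g$R <- matrix(g$range_axis, nb, nr, byrow = TRUE)
  g$sin_a <- sin(angles * pi / 180); g$cos_a <- cos(angles * pi / 180)
  g$D <- g$R * g$cos_a; g$Y <- g$R * g$sin_a
  g$Ahalf <- g$R * tan(0.5 * pi / 180)
  g$cfg <- cfg
  if (is.null(truth)) truth <- matrix(0L, nb, nr)
  f <- list(ping_id = ping_id, time = time, nav = nav, sv = sv, truth = truth,
            floor_range = rep(Inf, nb), geom = g)
  class(f) <- "ping_fan"
  f
}

# Brute-force 3x3 sliding-window oracle with replicate padding.
oracle_window3 <- function(m, fun, exclude_centre = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- c()
    for (di in -1:1) for (dj in -1:1) {
      if (exclude_centre && di == 0 && dj == 0) next
      vals <- c(vals, m[min(max(i + di, 1), nr), min(max(j + dj, 1), nc)])
    }
    out[i, j] <- switch(fun, median = stats::median(vals, na.rm = TRUE),
                        min = suppressWarnings(min(vals, na.rm = TRUE)),
                        max = suppressWarnings(max(vals, na.rm = TRUE)))
  }
  out[!is.finite(out)] <- NA_real_
  out
}

# A feature table with the full 24-column schema where a few features carry
# the class signal; used by the ML-stage tests.
synth_feature_table <- function(n_per_class = 40, seed = 1L,
                                classes = c("FISH", "GAS", "NOISE", "PLATFORM")) {
  set.seed(seed)
  n <- n_per_class * length(classes)
  lab <- rep(classes, each = n_per_class)
  cls <- as.integer(factor(lab, levels = classes))
  tab <- data.frame(check.names = FALSE, matrix(stats::rnorm(n * 24), n, 24))
  names(tab) <- feature_schema()
  # every non-coordinate feature separates the classes cleanly (the classes
  # are meant to be genuinely well-separated Gaussians in feature space)
  tab$Height <- cls * 8 + stats::rnorm(n, sd = 0.5)
  tab$Base <- (5 - cls) * 4 + stats::rnorm(n, sd = 0.5)
  tab$`Depth ratio` <- 1 - 0.08 * cls + stats::rnorm(n, sd = 0.01)
  tab$`Relative depth in time` <- c(0, 2, 0, 0)[cls] + stats::rnorm(n, sd = 0.1)
  tab$`Sample mean` <- -70 + 5 * cls + stats::rnorm(n, sd = 0.5)
  tab$Vertices <- 2 * (10 + 4 * cls + sample(0:1, n, TRUE))
  tab$Triangles <- 6 * (10 + 4 * cls) - 8 + sample(0:2, n, TRUE)
  tab$`Surface area` <- 30 * cls + stats::rnorm(n, sd = 2)
  tab$`Length 1` <- 5 * cls + stats::rnorm(n, sd = 0.4)
  tab$`Length 2` <- 2 * cls + stats::rnorm(n, sd = 0.2)
  tab$`Length ratio` <- pmin(1, 0.2 * cls + stats::rnorm(n, sd = 0.02))
  tab$`Sv_UNCAL diff` <- 2 * cls + stats::rnorm(n, sd = 0.2)
  tab$`Mass center depth` <- 15 * cls + stats::rnorm(n, sd = 0.5)
  tab$`Geometric center depth` <- tab$`Mass center depth` + stats::rnorm(n, sd = 0.3)
  tab$Beams <- 6 * cls + sample(0:1, n, TRUE)
  tab$`Intersection area first beam` <- ifelse(cls <= 2, 0, cls) +
    stats::rnorm(n, sd = 0.05)
  tab$`Intersection area last beam` <- ifelse(cls >= 3, 0, cls) +
    stats::rnorm(n, sd = 0.05)
  tab$Cluster <- cls - 1L
  tab$x <- stats::rnorm(n, sd = 200); tab$y <- stats::rnorm(n, sd = 200)
  tab$`Mass center latitude` <- 43 + tab$x / 111320
  tab$`Mass center longitude` <- 14.5 + tab$y / 111320
  tab$`Geometric center latitude` <- tab$`Mass center latitude`
  tab$`Geometric center longitude` <- tab$`Mass center longitude`
  tab$slice_id <- seq_len(n)
  tab$ping_id <- seq_len(n)
  tab$object_id <- rep(seq_len(n / 2), each = 2)[seq_len(n)]
  tab$truth <- lab
  tab$label <- NA_character_
  tab
}

# independent union-find over pairwise 8-adjacency, used as the
# connected-component oracle
oracle_components8 <- function(cells) {
  n <- nrow(cells)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && abs(cells[i, 1] - cells[j, 1]) <= 1 &&
        abs(cells[i, 2] - cells[j, 2]) <= 1) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, 0L)
}

same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}


# transitive-closure oracle via boolean matrix powers
oracle_tracking <- function(centroids, pings, max_distance, max_gap) {
  n <- nrow(centroids)
  A <- diag(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dg <- abs(pings[i] - pings[j])
    if (i != j && dg >= 1 && dg <= max_gap &&
        sqrt(sum((centroids[i, ] - centroids[j, ])^2)) <= max_distance)
      A[i, j] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A > 0)) break
    A <- A2
  }
  comp <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) { k <- k + 1L; comp[which(A[i, ] > 0)] <- k }
  }
  comp
}

fake_slice <- function(ping, x, y, depth) {
  s <- list(ping_id = as.integer(ping), time = (ping - 1) / 2.6,
            world_centroid = c(x = x, y = y, depth = depth))
  class(s) <- "slice_region"
  s
}

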