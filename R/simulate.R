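#' @title Synthetic multibeam water-column survey generator
#'
#' @description
#' Generates labelled synthetic surveys with the acquisition geometry of a
#' dual-head multibeam system: two 75.1 degree fans of 256 equiangular beams
#' tilted so their union is a 130.1 degree swath of 512 beams, 2.6 Hz ping
#' rate, 0.64 m range bins. Each ping carries an uncalibrated Sv sample
#' matrix (beam x range bin) and a same-shape ground-truth matrix of class
#' codes, so every downstream stage can be tested against known truth.
#'
#' @name synthetic_scene
NULL

# Shared per-survey fan geometry, kept in an environment so the (large)
# coordinate matrices are stored once and referenced by every ping.
build_fan_geometry <- function(cfg) {
  nb <- cfg$n_beams_per_transducer
  delta <- cfg$fan_width / nb
  half <- cfg$combined_swath / 2
  lo1 <- -half                      # fan 1: port edge of the combined swath
  lo2 <- half - cfg$fan_width      # fan 2: tilted so the union is exact
  ang1 <- lo1 + (seq_len(nb) - 0.5) * delta
  ang2 <- lo2 + (seq_len(nb) - 0.5) * delta
  angles <- c(ang1, ang2)
  transducer <- rep(1:2, each = nb)
  ord <- order(angles)
  angles <- angles[ord]
  transducer <- transducer[ord]

  max_slant <- cfg$water_depth / cos(deg2rad(max(abs(angles)))) + 12
  nr <- as.integer(ceiling(max_slant / cfg$range_bin))
  range_axis <- (seq_len(nr) - 0.5) * cfg$range_bin

  n_beams <- length(angles)
  R <- matrix(range_axis, nrow = n_beams, ncol = nr, byrow = TRUE)
  sin_a <- sin(deg2rad(angles))
  cos_a <- cos(deg2rad(angles))
  D <- R * cos_a          # depth of each sample (m, positive down)
  Y <- R * sin_a          # across-track offset (m, starboard positive)
  # along-track half-width of the insonified volume at each sample
  Ahalf <- R * tan(deg2rad(cfg$along_beamwidth / 2))

  g <- new.env(parent = emptyenv())
  g$angles <- angles; g$transducer <- transducer
  g$beam_order <- ord                     # merged index -> original (td,beam)
  g$range_axis <- range_axis; g$n_beams <- n_beams; g$n_bins <- nr
  g$R <- R; g$D <- D; g$Y <- Y; g$Ahalf <- Ahalf
  g$cos_a <- cos_a; g$sin_a <- sin_a
  g$cfg <- cfg
  g
}

# Smooth seeded seafloor roughness about the nominal depth ("muddy sand",
# no microtopography). Draws its phases from the current RNG stream.
make_floor_fun <- function(cfg, roughness_amp = 0.25) {
  ph <- stats::runif(6, 0, 2 * pi)
  wl <- c(61, 37, 23)  # m, incommensurate wavelengths
  force(cfg)
  function(x, y) {
    cfg$water_depth +
      roughness_amp * (sin(2 * pi * x / wl[1] + ph[1]) * cos(2 * pi * y / wl[2] + ph[2]) +
                       0.6 * sin(2 * pi * x / wl[2] + ph[3]) * cos(2 * pi * y / wl[3] + ph[4]) +
                       0.4 * sin(2 * pi * x / wl[3] + ph[5]) * cos(2 * pi * y / wl[1] + ph[6]))
  }
}

# Transect layout: parallel lines along +/- x, spaced in y, centred on the
# survey area, run in alternating directions. Ping positions advance by
# vessel_speed / ping_rate.
transect_layout <- function(cfg) {
  step <- cfg$vessel_speed / cfg$ping_rate
  n_per <- max(2L, as.integer(floor(cfg$area_side / step)) + 1L)
  y0 <- -(cfg$n_transects - 1) * cfg$transect_spacing / 2
  half <- (n_per - 1) * step / 2
  pings <- vector("list", cfg$n_transects * n_per)
  k <- 0L
  for (tr in seq_len(cfg$n_transects)) {
    east <- (tr %% 2L) == 1L
    xs <- seq(-half, half, by = step)[seq_len(n_per)]
    if (!east) xs <- rev(xs)
    for (i in seq_len(n_per)) {
      k <- k + 1L
      pings[[k]] <- list(x = xs[i], y = y0 + (tr - 1) * cfg$transect_spacing,
                         heading = if (east) 0 else 180, transect = tr)
    }
  }
  pings
}

new_ping_fan <- function(ping_id, time, nav, geom, sv, truth, floor_range) {
  f <- list(ping_id = ping_id, time = time, nav = nav, sv = sv, truth = truth,
            floor_range = floor_range, geom = geom)
  class(f) <- "ping_fan"
  f
}

#' @export
print.ping_fan <- function(x, ...) {
  cat(sprintf("ping %d  t=%.2fs  nav=(%.1f, %.1f) hdg %g  [%d beams x %d bins]\n",
              x$ping_id, x$time, x$nav[1], x$nav[2], x$nav[3],
              x$geom$n_beams, x$geom$n_bins))
  invisible(x)
}

# Build one background ping: speckled water column, seafloor echo, no-data
# beyond 10 m past the per-beam seafloor range.
make_background_fan <- function(ping_id, time, nav, geom, floor_fun) {
  cfg <- geom$cfg
  phi <- deg2rad(nav[3])
  acr <- c(sin(phi + pi / 2) * 0, 0)  # placeholder, computed below
  # across-track unit vector (starboard) for heading phi measured from +x
  acr <- c(sin(phi), -cos(phi))
  # one fixed-point iteration for the per-beam seafloor slant range
  d0 <- cfg$water_depth
  rsf <- d0 / geom$cos_a
  bx <- nav[1] + rsf * geom$sin_a * acr[1]
  by <- nav[2] + rsf * geom$sin_a * acr[2]
  dfl <- floor_fun(bx, by)
  rsf <- dfl / geom$cos_a

  sv <- matrix(cfg$background_sv, geom$n_beams, geom$n_bins) +
    stats::rnorm(geom$n_beams * geom$n_bins, sd = cfg$speckle_sd)
  # seafloor echo: strong smear around the per-beam seafloor range
  sv <- sv + cfg$seafloor_sv_offset * exp(-0.5 * ((geom$R - rsf) / 0.8)^2)
  sv[geom$R > rsf + 10] <- NA_real_
  truth <- matrix(0L, geom$n_beams, geom$n_bins)
  f <- new_ping_fan(ping_id, time, nav, geom, sv, truth, rsf)
  f$across <- acr
  f$floor_depth <- dfl
  f
}

#' Inject one target into a ping fan
#'
#' Raises the samples inside the target's instantaneous footprint by its
#' `sv_offset` (with a Gaussian taper for fish schools and noise patches)
#' and marks the ground truth with the class code. The footprint advances
#' with the target's velocity between pings; targets outside the ping's
#' swath are silently absent.
#'
#' @param fan a `ping_fan`.
#' @param t a [target_spec()].
#' @return the modified `ping_fan`.
#' @export
inject_target <- function(fan, t) {
  g <- fan$geom; cfg <- g$cfg
  time <- fan$time
  if (time > t$persistence) return(fan)
  phi <- deg2rad(fan$nav[3])
  alg <- c(cos(phi), sin(phi))
  acr <- c(sin(phi), -cos(phi))
  pos <- t$anchor[1:2] + t$velocity[1:2] * time
  dvec <- pos - fan$nav[1:2]
  t_along <- dvec[1] * alg[1] + dvec[2] * alg[2]
  t_across <- dvec[1] * acr[1] + dvec[2] * acr[2]
  # quick cull: beyond any possible along-track insonification
  max_reach <- max(g$Ahalf) + max(t$dims) + 1
  if (abs(t_along) > max_reach) return(fan)

  code <- .CLASS_CODES[[t$klass]]
  amp <- NULL; inside <- NULL
  if (t$klass %in% c("FISH", "NOISE")) {
    zc <- t$anchor[3] - t$velocity[3] * time
    ax <- t$dims[1] / 2; ay <- t$dims[2] / 2; az <- t$dims[3] / 2
    q <- ((g$Y - t_across) / ax)^2 + ((g$D - zc) / az)^2 +
      (t_along / (ay + g$Ahalf))^2
    inside <- q <= 1
    if (!any(inside, na.rm = TRUE)) return(fan)
    amp <- t$sv_offset * exp(-1.5 * q)
  } else if (t$klass == "PLATFORM") {
    hx <- t$dims[1] / 2; hy <- t$dims[2] / 2
    inside <- abs(g$Y - t_across) <= hx &
      abs(t_along) <= hy + g$Ahalf &
      g$D >= t$anchor[3] & g$R <= fan$floor_range - 0.5 / g$cos_a
    if (!any(inside, na.rm = TRUE)) return(fan)
    # echo strength grows with depth: incidence angle + sidelobe pile-up,
    # which pushes the mass centre of platform slices deeper
    amp <- t$sv_offset * (0.55 + 0.45 * g$D / cfg$water_depth)
  } else { # GAS: train of bubble packets rising through a narrow column
    span <- t$anchor[3]                 # seabed origin -> surface
    spacing <- 2.5 * t$dims[3]
    npack <- as.integer(ceiling(span / spacing)) + 1L
    vz <- t$velocity[3]
    rr <- t$dims[1] / 2; hz <- t$dims[3] / 2
    phase <- (t$anchor[1] * 13.7 + t$anchor[2] * 7.3) %% (2 * pi)
    r_eff <- rr * (1 + 0.25 * sin(2 * pi * g$D / 7 + phase))  # radius jitter
    inside <- matrix(FALSE, g$n_beams, g$n_bins)
    for (k in seq_len(npack) - 1L) {
      zk <- span - ((vz * time + k * spacing) %% span)
      pk <- abs(g$D - zk) <= hz &
        ((g$Y - t_across) / r_eff)^2 + (t_along / (r_eff + g$Ahalf))^2 <= 1
      inside <- inside | pk
    }
    if (!any(inside, na.rm = TRUE)) return(fan)
    amp <- matrix(t$sv_offset, g$n_beams, g$n_bins)
  }
  inside[is.na(inside)] <- FALSE
  inside <- inside & !is.na(fan$sv)
  fan$sv[inside] <- fan$sv[inside] + amp[inside]
  tr <- fan$truth
  set <- inside & tr == 0L
  tr[set] <- code
  fan$truth <- tr
  fan
}

#' Inject acquisition noise into a ping fan
#'
#' Adds (i) sidelobe arcs: constant-range elevated samples in the beams
#' neighbouring any strong target sample, (ii) a near-surface entrained-air
#' layer, and (iii) optional extra speckle. Ground truth for (i) and (ii) is
#' coded NOISE where not already claimed by a target.
#'
#' @param fan a `ping_fan`.
#' @param noise_cfg a [noise_config()].
#' @return the modified `ping_fan`.
#' @export
inject_noise <- function(fan, noise_cfg = noise_config()) {
  g <- fan$geom; cfg <- g$cfg
  nb <- g$n_beams
  code <- .CLASS_CODES[["NOISE"]]
  if (noise_cfg$sidelobe) {
    trigger <- cfg$background_sv + noise_cfg$sidelobe_trigger
    strong <- !is.na(fan$sv) & fan$sv >= trigger & fan$truth > 0L &
      g$R < fan$floor_range - 1
    if (any(strong)) {
      src <- ifelse(strong, fan$sv, -Inf)
      for (s in c(-(noise_cfg$sidelobe_beams:1), 1:noise_cfg$sidelobe_beams)) {
        idx <- seq_len(nb) - s
        ok <- idx >= 1L & idx <= nb
        arc <- matrix(-Inf, nb, g$n_bins)
        arc[ok, ] <- src[idx[ok], ]
        arc <- arc - noise_cfg$sidelobe_drop - noise_cfg$sidelobe_decay * abs(s)
        raise <- !is.na(fan$sv) & arc > fan$sv
        if (any(raise)) {
          fan$sv[raise] <- arc[raise]
          mark <- raise & fan$truth == 0L & arc > cfg$background_sv + 6
          fan$truth[mark] <- code
        }
      }
    }
  }
  if (noise_cfg$surface_layer_depth > 0) {
    lay <- g$D < noise_cfg$surface_layer_depth & !is.na(fan$sv)
    fan$sv[lay] <- fan$sv[lay] + noise_cfg$surface_layer_sv
    mark <- lay & fan$truth == 0L
    fan$truth[mark] <- code
  }
  if (noise_cfg$speckle_sd > 0) {
    set.seed(derive_seed(noise_cfg$seed, sprintf("speckle%d", fan$ping_id)))
    ok <- !is.na(fan$sv)
    fan$sv[ok] <- fan$sv[ok] + stats::rnorm(sum(ok), sd = noise_cfg$speckle_sd)
  }
  fan
}

#' Generate a labelled synthetic survey
#'
#' Runs the vessel along the configured transects and emits one `ping_fan`
#' per ping: background speckle, seafloor echo with seeded roughness,
#' injected targets and injected noise, plus a ground-truth class-code
#' matrix. Deterministic for a fixed `config$seed`.
#'
#' @param config a [survey_config()].
#' @param targets list of [target_spec()] objects; all anchors must lie
#'   inside the survey area.
#' @param noise a [noise_config()], or `NULL` to disable noise injection.
#' @return an object of class `wc_survey`: list with `config`, `geom`,
#'   `fans` (list of `ping_fan`) and `floor_fun`.
#' @export
generate_survey <- function(config, targets = list(),
                            noise = noise_config(seed = config$seed)) {
  validate_survey_config(config)
  half <- config$area_side / 2 + 1e-9
  for (i in seq_along(targets)) {
    t <- targets[[i]]
    stopifnot(inherits(t, "target_spec"))
    if (abs(t$anchor[1]) > half || abs(t$anchor[2]) > half)
      stop(sprintf("target %d (%s) lies outside the survey area", i, t$klass))
    if (t$anchor[3] < 0 || t$anchor[3] > config$water_depth + 2)
      stop(sprintf("target %d (%s) anchor depth outside the water column", i, t$klass))
  }
  geom <- build_fan_geometry(config)
  layout <- transect_layout(config)
  set.seed(derive_seed(config$seed, "survey"))
  floor_fun <- make_floor_fun(config)
  fans <- vector("list", length(layout))
  for (p in seq_along(layout)) {
    lp <- layout[[p]]
    nav <- c(lp$x, lp$y, lp$heading)
    time <- (p - 1) / config$ping_rate
    fan <- make_background_fan(p, time, nav, geom, floor_fun)
    fan$transect <- lp$transect
    for (t in targets) fan <- inject_target(fan, t)
    if (!is.null(noise)) fan <- inject_noise(fan, noise)
    fans[[p]] <- fan
  }
  s <- list(config = config, geom = geom, fans = fans, floor_fun = floor_fun,
            targets = targets)
  class(s) <- "wc_survey"
  s
}

#' @export
print.wc_survey <- function(x, ...) {
  cat(sprintf("Synthetic water-column survey: %d pings, %d beams x %d bins\n",
              length(x$fans), x$geom$n_beams, x$geom$n_bins))
  cat(sprintf("  %d targets (%s)\n", length(x$targets),
              paste(vapply(x$targets, function(t) t$klass, ""), collapse = ", ")))
  print(x$config)
  invisible(x)
}

# World (x, y) coordinates of every sample of a fan, as two matrices.
fan_world_coords <- function(fan) {
  phi <- deg2rad(fan$nav[3])
  acr <- c(sin(phi), -cos(phi))
  list(x = fan$nav[1] + fan$geom$Y * acr[1],
       y = fan$nav[2] + fan$geom$Y * acr[2])
}
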