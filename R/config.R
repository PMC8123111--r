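#' Survey acquisition configuration
#'
#' Describes the acquisition geometry of a simulated multibeam water-column
#' survey: a dual-transducer system forming two 75.1 degree fans of 256
#' equiangular beams each, combined into a 130.1 degree across-track swath of
#' 512 beams, pinging at 2.6 Hz with 0.64 m range bins. Transects are
#' parallel lines run in alternating directions.
#'
#' @param water_depth nominal water depth (m, positive down).
#' @param area_side side of the square survey area (m).
#' @param n_transects number of parallel transects.
#' @param transect_spacing spacing between adjacent transects (m).
#' @param vessel_speed vessel speed along transects (m/s).
#' @param ping_rate ping repetition rate (Hz).
#' @param n_beams_per_transducer beams formed per transducer.
#' @param fan_width across-track swath width of one transducer fan (degrees).
#' @param combined_swath union of the two fans (degrees); the fans are tilted
#'   so their union is exactly this wide (the overlap is
#'   `2 * fan_width - combined_swath`).
#' @param range_bin range extent of one sample (m).
#' @param background_sv background (water) volume backscattering strength,
#'   uncalibrated dB.
#' @param speckle_sd standard deviation of additive Gaussian speckle in dB.
#' @param seafloor_sv_offset seafloor echo strength above background (dB).
#' @param along_beamwidth along-track beam width (degrees).
#' @param origin_lat,origin_lon geographic anchor of the local survey frame
#'   (decimal degrees); survey x/y metres are converted to latitude/longitude
#'   about this point.
#' @param seed integer seed driving every random component of the survey.
#' @return an object of class `survey_config`.
#' @export
survey_config <- function(water_depth = 85,
                          area_side = 220,
                          n_transects = 2,
                          transect_spacing = 100,
                          vessel_speed = 2.3,
                          ping_rate = 2.6,
                          n_beams_per_transducer = 256L,
                          fan_width = 75.1,
                          combined_swath = 130.1,
                          range_bin = 0.64,
                          background_sv = -75,
                          speckle_sd = 2,
                          seafloor_sv_offset = 45,
                          along_beamwidth = 1,
                          origin_lat = 43.0,
                          origin_lon = 14.5,
                          seed = 1L) {
  cfg <- list(
    water_depth = water_depth, area_side = area_side,
    n_transects = as.integer(n_transects), transect_spacing = transect_spacing,
    vessel_speed = vessel_speed, ping_rate = ping_rate,
    n_beams_per_transducer = as.integer(n_beams_per_transducer),
    fan_width = fan_width, combined_swath = combined_swath,
    range_bin = range_bin, background_sv = background_sv,
    speckle_sd = speckle_sd, seafloor_sv_offset = seafloor_sv_offset,
    along_beamwidth = along_beamwidth,
    origin_lat = origin_lat, origin_lon = origin_lon,
    seed = as.integer(seed)
  )
  class(cfg) <- "survey_config"
  validate_survey_config(cfg)
  cfg
}

validate_survey_config <- function(cfg) {
  if (cfg$ping_rate <= 0) stop("config error: ping_rate must be > 0")
  if (cfg$vessel_speed <= 0) stop("config error: vessel_speed must be > 0")
  if (cfg$range_bin <= 0) stop("config error: range_bin must be > 0")
  if (cfg$water_depth <= 0) stop("config error: water_depth must be > 0")
  if (cfg$combined_swath > 2 * cfg$fan_width)
    stop("config error: combined_swath cannot exceed twice fan_width")
  if (cfg$n_transects > 1 &&
      cfg$area_side < (cfg$n_transects - 1) * cfg$transect_spacing)
    stop("config error: area_side too small for the requested transect layout")
  invisible(cfg)
}

#' @export
print.survey_config <- function(x, ...) {
  cat("Multibeam survey configuration\n")
  cat(sprintf("  swath: %g deg over %d beams (2 x %d @ %g deg), %g Hz, %g m bins\n",
              x$combined_swath, 2L * x$n_beams_per_transducer,
              x$n_beams_per_transducer, x$fan_width, x$ping_rate, x$range_bin))
  cat(sprintf("  area: %g m square, %d transects spaced %g m, %g m/s\n",
              x$area_side, x$n_transects, x$transect_spacing, x$vessel_speed))
  cat(sprintf("  depth: %g m; background %g dB; seed %d\n",
              x$water_depth, x$background_sv, x$seed))
  invisible(x)
}

#' Specify a water-column target for the simulator
#'
#' The four target classes have the shape and kinematics expected of real
#' water-column scatterers: compact fish schools moving slowly
#' (horizontal speed below 5 m/s), narrow gas-seep bubble columns whose
#' bubble packets rise quickly (can exceed 10 m/s) between the seabed and
#' the surface, static vertical platform legs spanning the water column, and
#' diffuse noise patches (entrained air).
#'
#' @param klass one of `"FISH"`, `"GAS"`, `"NOISE"`, `"PLATFORM"`.
#' @param anchor numeric (x, y, depth) anchor in survey metres. For GAS the
#'   anchor depth is the seabed origin of the seep; for PLATFORM the anchor
#'   depth is the top of the leg.
#' @param dims numeric (dx, dy, dz) extents in m. For FISH/NOISE these are
#'   full ellipsoid axes; for GAS, dx is the column diameter and dz the
#'   bubble-packet height; for PLATFORM dx/dy are the leg footprint.
#' @param sv_offset echo strength above background (dB).
#' @param velocity numeric (vx, vy, vz) in m/s; vz is positive upward
#'   (rising). GAS rises; PLATFORM must be static.
#' @param persistence time the target exists (s); `Inf` for permanent.
#' @return an object of class `target_spec`.
#' @export
target_spec <- function(klass, anchor, dims, sv_offset,
                        velocity = c(0, 0, 0), persistence = Inf) {
  klass <- match.arg(klass, c("FISH", "GAS", "NOISE", "PLATFORM"))
  stopifnot(length(anchor) == 3, length(dims) == 3, length(velocity) == 3)
  if (any(dims <= 0)) stop("target dims must all be > 0")
  hspeed <- sqrt(velocity[1]^2 + velocity[2]^2)
  if (klass == "FISH" && hspeed >= 5)
    stop("FISH horizontal speed must be < 5 m/s")
  if (klass == "GAS" && velocity[3] < 0)
    stop("GAS vertical velocity must be rising (vz >= 0)")
  if (klass == "PLATFORM" && any(velocity != 0))
    stop("PLATFORM targets must be static")
  t <- list(klass = klass, anchor = as.numeric(anchor),
            dims = as.numeric(dims), sv_offset = sv_offset,
            velocity = as.numeric(velocity), persistence = persistence)
  class(t) <- "target_spec"
  t
}

#' Noise injection configuration
#'
#' @param sidelobe `TRUE` to add constant-range sidelobe arcs across beams
#'   neighbouring strong targets.
#' @param sidelobe_trigger samples this many dB above background trigger arcs.
#' @param sidelobe_beams number of neighbouring beams affected on each side.
#' @param sidelobe_drop dB lost by the arc relative to the triggering sample
#'   (the first-sidelobe suppression of the array; ~20 dB is typical).
#' @param sidelobe_decay extra dB lost per beam of separation.
#' @param surface_layer_depth depth of the near-surface entrained-air layer
#'   (m); 0 disables it.
#' @param surface_layer_sv layer strength above background (dB).
#' @param speckle_sd extra speckle added at injection time (dB); the survey
#'   generator already adds its own speckle, so this defaults to 0.
#' @param seed seed for the injection randomness.
#' @return an object of class `noise_config`.
#' @export
noise_config <- function(sidelobe = TRUE, sidelobe_trigger = 28,
                         sidelobe_beams = 6L, sidelobe_drop = 20,
                         sidelobe_decay = 2, surface_layer_depth = 5,
                         surface_layer_sv = 15, speckle_sd = 0, seed = 1L) {
  n <- list(sidelobe = sidelobe, sidelobe_trigger = sidelobe_trigger,
            sidelobe_beams = as.integer(sidelobe_beams),
            sidelobe_drop = sidelobe_drop, sidelobe_decay = sidelobe_decay,
            surface_layer_depth = surface_layer_depth,
            surface_layer_sv = surface_layer_sv,
            speckle_sd = speckle_sd, seed = as.integer(seed))
  class(n) <- "noise_config"
  n
}

# integer ground-truth codes; 0 is background
.CLASS_CODES <- c(FISH = 1L, GAS = 2L, NOISE = 3L, PLATFORM = 4L)
.CLASS_NAMES <- names(.CLASS_CODES)

#' @export
class_codes <- function() .CLASS_CODES
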