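#' @title End-to-end pipeline
#'
#' @description
#' Ties the stages into one workflow: simulate (or accept) a survey, clean
#' the stacked echogram, detect the seafloor and build the TIN, smooth and
#' segment the retained pings into slices, track them into multi-ping
#' objects, compute the 24-metric table, and run the semi-supervised
#' classification. Every run emits a manifest of counts and seeds from
#' which each reported number is recomputable.
#'
#' @name pipeline
NULL

#' Default demonstration scene
#'
#' A compact scene with all four target classes placed under the transects
#' of the given configuration: four platform legs, fish schools with slow
#' horizontal drift, seabed-to-surface gas seeps with fast-rising bubble
#' packets, and diffuse entrained-air noise patches.
#'
#' @param cfg a [survey_config()].
#' @return list of [target_spec()]s.
#' @export
demo_targets <- function(cfg) {
  y0 <- -(cfg$n_transects - 1) * cfg$transect_spacing / 2
  yy <- function(tr, off) y0 + (tr - 1) * cfg$transect_spacing + off
  zb <- cfg$water_depth
  c(
    # four-legged platform straddling transect 1
    lapply(list(c(-8, -8), c(-8, 8), c(8, -8), c(8, 8)), function(d)
      target_spec("PLATFORM", c(30 + d[1], yy(1, d[2]), 1),
                  c(2.5, 2.5, zb), sv_offset = 35)),
    list(
      target_spec("FISH", c(-80, yy(1, -10), 0.62 * zb), c(14, 12, 7), 25,
                  velocity = c(0.4, 0.2, 0)),
      target_spec("FISH", c(-40, yy(1, 10), 0.42 * zb), c(12, 10, 6), 25,
                  velocity = c(-0.3, 0.3, 0)),
      target_spec("FISH", c(0, yy(1, -14), 0.75 * zb), c(16, 12, 8), 24,
                  velocity = c(0.5, 0, 0)),
      target_spec("FISH", c(65, yy(min(2, cfg$n_transects), 8), 0.5 * zb),
                  c(13, 11, 7), 26, velocity = c(0.2, -0.4, 0)),
      target_spec("FISH", c(-70, yy(min(2, cfg$n_transects), 5), 0.68 * zb),
                  c(15, 13, 8), 25, velocity = c(0.3, 0.2, 0)),
      target_spec("GAS", c(-60, yy(1, 6), zb), c(2.4, 2.4, 6), 30,
                  velocity = c(0, 0, 1.5)),
      target_spec("GAS", c(90, yy(1, -5), zb), c(2.2, 2.2, 6), 30,
                  velocity = c(0, 0, 2)),
      target_spec("GAS", c(-20, yy(min(2, cfg$n_transects), -6), zb),
                  c(2.6, 2.6, 7), 29, velocity = c(0, 0, 1.8)),
      target_spec("GAS", c(50, yy(min(2, cfg$n_transects), 7), zb),
                  c(2.4, 2.4, 6), 31, velocity = c(0, 0, 1.6)),
      target_spec("NOISE", c(-30, yy(1, 2), 14), c(10, 8, 4), 18),
      target_spec("NOISE", c(75, yy(min(2, cfg$n_transects), -3), 16),
                  c(8, 8, 3), 18),
      target_spec("NOISE", c(-85, yy(min(2, cfg$n_transects), 0), 18),
                  c(9, 7, 4), 18)
    )
  )
}

#' Ground-truth class labels for detected slices
#'
#' Each slice is labelled with the ground-truth class carrying the most
#' linear-domain backscatter power among its member samples (so a target is
#' not out-voted by the weaker sidelobe-arc cells it drags along). Because
#' detection runs on fans smoothed over a 5-ping window, the vote covers
#' the member cells across that same window: a slice produced by temporal
#' smear of a neighbouring ping's target inherits that target's class.
#' Slices whose members are background everywhere (residual artefacts that
#' survived cleaning) are labelled NOISE.
#'
#' @param slices list of `slice_region`s.
#' @param fans the survey's list of `ping_fan`s (indexed by ping id).
#' @param window ping half-window of the provenance vote (2 matches the
#'   45-cell smoother).
#' @return character vector of class labels, one per slice.
#' @export
slice_truth_labels <- function(slices, fans, window = 2L) {
  np <- length(fans)
  vapply(slices, function(s) {
    pw <- numeric(length(.CLASS_NAMES))
    for (p in max(1L, s$ping_id - window):min(np, s$ping_id + window)) {
      f <- fans[[p]]
      codes <- f$truth[s$cells]
      w <- db_to_linear(f$sv[s$cells])
      ok <- codes > 0L & !is.na(w)
      if (!any(ok)) next
      for (k in unique(codes[ok])) pw[k] <- pw[k] + sum(w[ok][codes[ok] == k])
    }
    if (all(pw == 0)) return("NOISE")
    .CLASS_NAMES[which.max(pw)]
  }, "")
}

#' Simulate operator labelling of a slice fraction
#'
#' Marks a stratified fraction of slices as operator-labelled with their
#' ground-truth class (at least `min_per_class` per class where available),
#' emulating manual review of a subset of slices.
#'
#' @param truth character vector of ground-truth labels.
#' @param fraction fraction of slices labelled.
#' @param seed RNG seed.
#' @param min_per_class minimum labelled slices per class.
#' @return character vector with labels for the selected slices, `NA`
#'   elsewhere.
#' @export
operator_labels <- function(truth, fraction = 0.08, seed = 1L,
                            min_per_class = 3L) {
  set.seed(derive_seed(seed, "operator"))
  out <- rep(NA_character_, length(truth))
  for (cl in unique(truth)) {
    idx <- which(truth == cl)
    n <- min(length(idx), max(min_per_class, round(fraction * length(idx))))
    pick <- if (length(idx) == 1) idx else sample(idx, n)
    out[pick] <- cl
  }
  out
}

subset_echogram <- function(e, ping_ids) {
  keep <- e$ping_ids %in% ping_ids
  new_stacked_echogram(e$mat[keep, , drop = FALSE], e$ping_ids[keep], e$range_axis)
}

# group sorted integer ids into runs of consecutive values
consecutive_runs <- function(ids) {
  ids <- sort(ids)
  split(ids, cumsum(c(1L, diff(ids) != 1L)))
}

#' Run the full water-column pipeline on a survey
#'
#' Executes the complete chain on a (simulated) survey and returns the
#' fitted classifier, per-slice predictions, ground-truth comparison and a
#' run manifest. Deterministic for a fixed seed.
#'
#' @param config a [survey_config()].
#' @param targets list of [target_spec()]s (defaults to [demo_targets()]).
#' @param noise a [noise_config()] or `NULL`.
#' @param survey optionally, an existing `wc_survey` (the config/targets
#'   arguments are then ignored for simulation).
#' @param seed seed for labelling and the ML stage (defaults to the survey
#'   seed).
#' @param label_fraction fraction of slices given operator labels.
#' @param sv_threshold slice detection threshold (dB); default background
#'   + 10.
#' @param min_height,min_width slice size conditions (m).
#' @param track_distance,track_gap region-tracking linkage parameters.
#' @param tin_offset vertical exclusion offset above the TIN (m); the
#'   default covers the above-threshold shoulder of the simulated seafloor
#'   echo after smoothing.
#' @param run_ml set `FALSE` to stop after the feature table.
#' @return an object of class `wc_run`.
#' @export
run_pipeline <- function(config = survey_config(), targets = NULL,
                         noise = NULL, survey = NULL, seed = NULL,
                         label_fraction = 0.08,
                         sv_threshold = NULL, min_height = 1, min_width = 1,
                         track_distance = 5, track_gap = 1, tin_offset = 3,
                         run_ml = TRUE) {
  t0 <- Sys.time()
  if (is.null(survey)) {
    if (is.null(targets)) targets <- demo_targets(config)
    if (is.null(noise)) noise <- noise_config(seed = config$seed)
    survey <- generate_survey(config, targets, noise)
  }
  cfg <- survey$config
  if (is.null(seed)) seed <- cfg$seed
  bg <- cfg$background_sv
  if (is.null(sv_threshold)) sv_threshold <- bg + 10

  # --- stacked echogram cleaning chain ---------------------------------
  stacked <- stack_max_intensity(survey$fans)
  # interference pings exceed the threshold over essentially the whole range
  # extent; a platform-spanning ping plus the outer-beam seafloor smear
  # already reaches ~0.93, so the cut sits above that
  retained <- reject_bad_pings(stacked, frac_threshold = 0.98,
                               sv_threshold = bg + 15)
  e <- subset_echogram(stacked, retained)
  em <- median_3x3(e)
  ee <- erosion_3x3(em)
  surface <- threshold_offset_line(em, reference = 0, sv_threshold = bg + 12,
                                   offset = 1, consensus_window = 61)
  bottom <- best_bottom_candidate(em, window_pings = 5, min_peak_sv = bg + 38,
                                  near_field = surface)
  poi <- select_pings_of_interest(ee, surface_line = surface,
                                  bottom_line = bottom,
                                  sv_threshold = sv_threshold)

  # --- seafloor TIN from decimated per-beam bottom picks ----------------
  surf_of <- stats::setNames(surface$range, surface$ping_ids)
  sub_pings <- retained[seq(1, length(retained), by = 3)]
  soundings <- do.call(rbind, lapply(sub_pings, function(p) {
    f <- survey$fans[[p]]
    nf <- max(4, surf_of[as.character(p)], na.rm = TRUE)
    s <- detect_bottom_per_beam(f, min_sv = bg + 38, near_field = nf)
    s[seq(1, nrow(s), by = 4), , drop = FALSE]
  }))
  tin <- build_and_resample_tin(soundings)

  # --- fan smoothing, masking, slice detection --------------------------
  slices <- list()
  for (run in consecutive_runs(poi)) {
    fans <- smooth_fan_45(survey$fans[run])
    for (f in fans) {
      g <- f$geom
      sr <- surf_of[as.character(f$ping_id)]
      mask <- g$R < 4 | is.na(f$sv)
      if (is.finite(sr)) mask <- mask | g$R < sr
      cand <- which(!mask & f$sv >= sv_threshold)
      if (length(cand)) {  # seafloor test only where it can matter
        w <- fan_world_coords(f)
        fd <- tin_depth_at(tin, w$x[cand], w$y[cand])
        bad <- is.na(fd) | g$D[cand] > fd - tin_offset
        mask[cand[bad]] <- TRUE
      }
      sl <- detect_slices(f, sv_threshold = sv_threshold,
                          min_height = min_height, min_width = min_width,
                          mask = mask)
      slices <- c(slices, sl)
    }
  }
  objects <- track_regions(slices, max_distance = track_distance,
                           max_ping_gap = track_gap)

  truth <- NULL; metrics <- NULL; ml <- NULL; pred <- NULL; acc <- NA_real_
  if (length(slices)) {
    metrics <- compute_slice_metrics(slices, objects, cfg, cluster_seed = seed)
    truth <- slice_truth_labels(slices, survey$fans)
    metrics$label <- operator_labels(truth, fraction = label_fraction,
                                     seed = seed)
    if (run_ml) {
      ml <- train_wc_classifier(metrics, seed = seed)
      pred <- as.character(predict(ml$model, metrics))
      acc <- mean(pred == truth)
    }
  }

  manifest <- list(
    config = unclass(cfg), seed = seed,
    counts = list(
      pings = length(survey$fans), pings_retained = length(retained),
      pings_of_interest = length(poi), soundings = nrow(soundings),
      slices = length(slices), objects = length(objects),
      operator_labelled = if (!is.null(metrics)) sum(!is.na(operator_labels(truth, label_fraction, seed))) else 0L,
      labelled_after_extension = if (!is.null(ml)) sum(ml$table$label_source == "labelled", na.rm = TRUE) else 0L),
    thresholds = list(sv_threshold = sv_threshold, min_height = min_height,
                      min_width = min_width, track_distance = track_distance,
                      track_gap = track_gap, tin_offset = tin_offset,
                      label_fraction = label_fraction),
    accuracy_vs_truth = acc,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  run <- list(survey_config = cfg, stacked = stacked, retained = retained,
              bottom_line = bottom, surface_line = surface, poi = poi,
              tin = tin, slices = slices, objects = objects,
              metrics = metrics, truth = truth, ml = ml,
              predictions = pred, accuracy = acc, manifest = manifest)
  class(run) <- "wc_run"
  run
}

#' @export
print.wc_run <- function(x, ...) {
  cat("Water-column pipeline run\n")
  m <- x$manifest$counts
  cat(sprintf("  pings %d -> retained %d -> of interest %d\n",
              m$pings, m$pings_retained, m$pings_of_interest))
  cat(sprintf("  slices %d in %d multi-ping objects\n", m$slices, m$objects))
  if (!is.null(x$ml)) {
    cat(sprintf("  ensemble held-out accuracy: %.3f\n",
                x$ml$eval_report$accuracy))
    cat(sprintf("  slice accuracy vs simulator truth: %.3f\n", x$accuracy))
  }
  invisible(x)
}
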