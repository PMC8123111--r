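#' @title Stacked-beam echogram cleaning
#'
#' @description
#' The 2D cleaning chain applied to the ping x range "stacked beams" view:
#' per-range maxima over all beams, bad-ping rejection, 3x3 median/erosion/
#' dilation convolution filters, bottom and surface virtual lines, selection
#' of pings of interest, the 45-cell fan smoother and the sample exclusion
#' mask. Order statistics are computed in dB (order-preserving); means are
#' computed in the linear power domain.
#'
#' @name echogram_ops
NULL

new_stacked_echogram <- function(mat, ping_ids, range_axis) {
  stopifnot(nrow(mat) == length(ping_ids), ncol(mat) == length(range_axis))
  e <- list(mat = mat, ping_ids = as.integer(ping_ids), range_axis = range_axis)
  class(e) <- "stacked_echogram"
  e
}

#' @export
print.stacked_echogram <- function(x, ...) {
  cat(sprintf("Stacked echogram: %d pings x %d range bins (%.2f m bins, max %.1f m)\n",
              nrow(x$mat), ncol(x$mat), diff(x$range_axis[1:2]),
              max(x$range_axis)))
  invisible(x)
}

#' @export
plot.stacked_echogram <- function(x, ...) {
  graphics::image(x$ping_ids, x$range_axis, x$mat, ylim = rev(range(x$range_axis)),
                  xlab = "ping", ylab = "range (m)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Stack a ping sequence with the Maximum Intensity operator
#'
#' Each output sample at range R holds the maximum over all beams (both
#' transducers) of the corresponding samples at range R, ignoring no-data.
#' A range bin with no valid sample in any beam stays no-data.
#'
#' @param pings list of `ping_fan` objects sharing one range axis.
#' @return a `stacked_echogram` (ping x range matrix, dB).
#' @export
stack_max_intensity <- function(pings) {
  if (length(pings) == 0) stop("empty ping set")
  ra <- pings[[1]]$geom$range_axis
  mat <- matrix(NA_real_, length(pings), length(ra))
  for (i in seq_along(pings)) {
    v <- suppressWarnings(apply(pings[[i]]$sv, 2, max, na.rm = TRUE))
    v[!is.finite(v)] <- NA_real_
    mat[i, ] <- v
  }
  new_stacked_echogram(mat, vapply(pings, function(f) f$ping_id, 0L), ra)
}

#' Reject pings with unusually high backscatter through the water column
#'
#' A ping is removed when the fraction of its valid range bins whose Sv
#' exceeds `sv_threshold` is at least `frac_threshold`.
#'
#' @param e a `stacked_echogram`.
#' @param frac_threshold fraction of above-threshold bins that flags a ping.
#' @param sv_threshold Sv level (dB) defining "unusually high".
#' @return integer vector of retained ping ids.
#' @export
reject_bad_pings <- function(e, frac_threshold = 0.9, sv_threshold = -60) {
  stopifnot(is.finite(frac_threshold), is.finite(sv_threshold))
  frac <- apply(e$mat, 1, function(v) {
    ok <- !is.na(v)
    if (!any(ok)) return(1)  # a ping with no data carries nothing of use
    mean(v[ok] > sv_threshold)
  })
  e$ping_ids[frac < frac_threshold]
}

# Generic 3x3 sliding-window statistic with replicate padding. `fun` is one
# of "median", "min", "max"; `exclude_centre` drops the central cell (used by
# dilation, which replaces a sample by the max of the eight surrounding ones).
window3 <- function(m, fun, exclude_centre = FALSE) {
  if (nrow(m) < 3 || ncol(m) < 3) stop("matrix must be at least 3 x 3")
  p <- pad_replicate(m, 1L)
  nr <- nrow(m); nc <- ncol(m)
  shifts <- list()
  for (di in -1:1) for (dj in -1:1) {
    if (exclude_centre && di == 0 && dj == 0) next
    shifts[[length(shifts) + 1L]] <-
      p[(1 + 1 + di):(nr + 1 + di), (1 + 1 + dj):(nc + 1 + dj), drop = FALSE]
  }
  if (fun == "min") {
    out <- Reduce(function(a, b) pmin(a, b, na.rm = TRUE), shifts)
  } else if (fun == "max") {
    out <- Reduce(function(a, b) pmax(a, b, na.rm = TRUE), shifts)
  } else {
    stk <- vapply(shifts, as.vector, numeric(nr * nc))
    out <- matrix(apply(stk, 1, stats::median, na.rm = TRUE), nr, nc)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' 3x3 convolution filters on a stacked echogram
#'
#' `median_3x3()` and `erosion_3x3()` replace each cell by the median /
#' minimum of the 3x3 window centred on it (stochastic-noise and
#' reverberation removal); `dilate_3x3()` replaces each cell by the maximum
#' of the eight surrounding cells. Edges use replicate padding; no-data
#' cells are ignored within each window.
#'
#' @param e a `stacked_echogram`.
#' @return a filtered `stacked_echogram`.
#' @export
median_3x3 <- function(e) { e$mat <- window3(e$mat, "median"); e }

#' @rdname median_3x3
#' @export
erosion_3x3 <- function(e) { e$mat <- window3(e$mat, "min"); e }

#' @rdname median_3x3
#' @export
dilate_3x3 <- function(e) { e$mat <- window3(e$mat, "max", exclude_centre = TRUE); e }

new_virtual_line <- function(range, ping_ids, kind) {
  l <- list(range = range, ping_ids = as.integer(ping_ids),
            kind = match.arg(kind, c("surface-exclusion", "bottom")))
  class(l) <- "virtual_line"
  l
}

#' @export
print.virtual_line <- function(x, ...) {
  cat(sprintf("Virtual line (%s): %d pings, range %.1f-%.1f m (%d undefined)\n",
              x$kind, length(x$range),
              suppressWarnings(min(x$range, na.rm = TRUE)),
              suppressWarnings(max(x$range, na.rm = TRUE)), sum(is.na(x$range))))
  invisible(x)
}

#' Pick the bottom line from a stacked echogram
#'
#' Per-ping candidate: the shallowest range whose Sv exceeds `min_peak_sv`
#' (the minimum range of the seafloor echo); candidates are then smoothed by
#' a median consensus over a window of pings. Pings whose window holds no
#' candidate are left undefined.
#'
#' @param e a `stacked_echogram` (usually median-filtered first).
#' @param window_pings consensus window width in pings (odd).
#' @param min_peak_sv minimum Sv (dB) for a seafloor candidate.
#' @param near_field ranges shallower than this (m) are never candidates; a
#'   scalar, a per-ping vector, or a `virtual_line` (e.g. the
#'   surface-exclusion line, so strong near-surface scatterers are never
#'   mistaken for the seafloor).
#' @return a `virtual_line` of kind `"bottom"`.
#' @export
best_bottom_candidate <- function(e, window_pings = 5, min_peak_sv = -37,
                                  near_field = 4) {
  np <- nrow(e$mat)
  nf <- if (inherits(near_field, "virtual_line")) near_field$range
        else rep_len(as.numeric(near_field), np)
  nf[is.na(nf)] <- min(nf, na.rm = TRUE)
  cand <- rep(NA_real_, np)
  for (p in seq_len(np)) {
    ok_rng <- e$range_axis >= nf[p]
    hit <- which(ok_rng & !is.na(e$mat[p, ]) & e$mat[p, ] >= min_peak_sv)
    if (length(hit)) cand[p] <- e$range_axis[hit[1]]
  }
  half <- floor(window_pings / 2)
  line <- rep(NA_real_, np)
  for (p in seq_len(np)) {
    w <- cand[max(1, p - half):min(np, p + half)]
    w <- w[!is.na(w)]
    if (length(w)) line[p] <- stats::median(w)
  }
  new_virtual_line(line, e$ping_ids, "bottom")
}

#' Surface-exclusion line by threshold offset
#'
#' For each ping, finds the range nearest to the reference line where Sv
#' first crosses below `sv_threshold` (the bottom of any near-surface
#' entrained-air layer) and offsets it; where the reference side is already
#' below threshold the line sits at reference + offset.
#'
#' @param e a `stacked_echogram`.
#' @param reference a `virtual_line`, or a single range (m) recycled to all
#'   pings (default 0, the transducer face).
#' @param sv_threshold Sv level (dB) delimiting the layer.
#' @param offset extra range (m) added beyond the crossing.
#' @param consensus_window odd number of pings for a median consensus over
#'   the per-ping crossings (1 disables it). The entrained-air layer varies
#'   slowly, so the consensus stops strong mid-water targets (and their
#'   sidelobe arcs) from dragging the line down locally.
#' @return a `virtual_line` of kind `"surface-exclusion"`.
#' @export
threshold_offset_line <- function(e, reference = 0, sv_threshold = -63,
                                  offset = 1, consensus_window = 1) {
  np <- nrow(e$mat)
  ref <- if (inherits(reference, "virtual_line")) reference$range
         else rep(as.numeric(reference), np)
  stopifnot(length(ref) == np)
  line <- rep(NA_real_, np)
  for (p in seq_len(np)) {
    if (is.na(ref[p])) next
    i0 <- max(1L, findInterval(ref[p], e$range_axis))
    v <- e$mat[p, i0:ncol(e$mat)]
    below <- which(is.na(v) | v < sv_threshold)
    line[p] <- if (length(below)) e$range_axis[i0 + below[1] - 1L] + offset
               else ref[p] + offset
  }
  if (consensus_window > 1) {
    half <- floor(consensus_window / 2)
    sm <- line
    for (p in seq_len(np)) {
      w <- line[max(1, p - half):min(np, p + half)]
      w <- w[!is.na(w)]
      if (length(w)) sm[p] <- stats::median(w)
    }
    line <- sm
  }
  new_virtual_line(line, e$ping_ids, "surface-exclusion")
}

#' Select pings of interest
#'
#' After dilation, a ping is retained when at least one above-threshold
#' sample survives strictly between the surface-exclusion and bottom lines.
#'
#' @param e a cleaned `stacked_echogram`.
#' @param surface_line,bottom_line `virtual_line`s (or scalars, recycled).
#' @param sv_threshold detection threshold (dB).
#' @param bottom_margin samples within this range (m) above the bottom line
#'   are not counted (seafloor echo shoulder).
#' @param dilate apply `dilate_3x3()` before thresholding.
#' @return integer vector of retained ping ids.
#' @export
select_pings_of_interest <- function(e, surface_line = 4, bottom_line = Inf,
                                     sv_threshold = -65, bottom_margin = 2,
                                     dilate = TRUE) {
  if (dilate) e <- dilate_3x3(e)
  np <- nrow(e$mat)
  sl <- if (inherits(surface_line, "virtual_line")) surface_line$range
        else rep(as.numeric(surface_line), np)
  bl <- if (inherits(bottom_line, "virtual_line")) bottom_line$range
        else rep(as.numeric(bottom_line), np)
  keep <- logical(np)
  for (p in seq_len(np)) {
    lo <- if (is.na(sl[p])) 0 else sl[p]
    hi <- if (is.na(bl[p])) Inf else bl[p] - bottom_margin
    in_band <- e$range_axis > lo & e$range_axis < hi
    keep[p] <- any(!is.na(e$mat[p, in_band]) & e$mat[p, in_band] >= sv_threshold)
  }
  e$ping_ids[keep]
}

# Sum of 3 shifted rows/cols with replicate padding (separable box filter).
box3_dim <- function(m, dim) {
  n <- dim(m)[dim]
  idx_lo <- pmax(seq_len(n) - 1L, 1L)
  idx_hi <- pmin(seq_len(n) + 1L, n)
  if (dim == 1L) m[idx_lo, , drop = FALSE] + m + m[idx_hi, , drop = FALSE]
  else m[, idx_lo, drop = FALSE] + m + m[, idx_hi, drop = FALSE]
}

#' Smooth ping fans with the 45-cell mean kernel
#'
#' Each sample is replaced by the mean over a 3 (beams) x 5 (pings) x 3
#' (range bins) neighbourhood of 45 cells. The mean is computed in the
#' linear power domain and converted back to dB; no-data cells are ignored
#' (a cell whose whole neighbourhood is no-data stays no-data). Runs
#' shorter than the kernel use replicate padding along pings.
#'
#' @param fans list of consecutive `ping_fan`s (one retained run).
#' @return the list of fans with smoothed `sv`.
#' @export
smooth_fan_45 <- function(fans) {
  np <- length(fans)
  if (np == 0) return(fans)
  # per-ping 2D pass (3 beams x 3 range bins) on linear sums and counts
  S <- vector("list", np); C <- vector("list", np)
  for (i in seq_len(np)) {
    lin <- db_to_linear(fans[[i]]$sv)
    cnt <- !is.na(lin) + 0
    lin[is.na(lin)] <- 0
    S[[i]] <- box3_dim(box3_dim(lin, 1L), 2L)
    C[[i]] <- box3_dim(box3_dim(cnt, 1L), 2L)
  }
  # ping pass: sum of 5 with index clamping (replicate padding)
  for (i in seq_len(np)) {
    js <- pmin(pmax(i + (-2:2), 1L), np)
    Ssum <- Reduce(`+`, S[js])
    Csum <- Reduce(`+`, C[js])
    out <- linear_to_db(Ssum / Csum)
    out[Csum == 0] <- NA_real_
    fans[[i]]$sv <- out
  }
  fans
}

#' Sample exclusion mask for a ping fan
#'
#' Marks samples excluded from target detection: within `near_field` metres
#' of the transducer face, deeper than the resampled seafloor TIN minus
#' `tin_offset` at the sample's horizontal position (conservatively
#' excluded where the TIN is undefined), shallower than the
#' surface-exclusion line, or no-data.
#'
#' @param fan a `ping_fan`.
#' @param near_field near-field blanking range (m).
#' @param tin a `seafloor_tin`, or `NULL` to skip the seafloor test.
#' @param tin_offset vertical offset above the TIN (m).
#' @param surface_range per-ping surface-exclusion range (m), or `NULL`.
#' @return logical matrix, `TRUE` = excluded.
#' @export
exclusion_mask <- function(fan, near_field = 4, tin = NULL, tin_offset = 1,
                           surface_range = NULL) {
  g <- fan$geom
  mask <- g$R < near_field | is.na(fan$sv)
  if (!is.null(surface_range) && is.finite(surface_range))
    mask <- mask | g$D < surface_range
  if (!is.null(tin)) {
    w <- fan_world_coords(fan)
    fd <- tin_depth_at(tin, as.vector(w$x), as.vector(w$y))
    fdm <- matrix(fd, g$n_beams, g$n_bins)
    mask <- mask | is.na(fdm) | g$D > fdm - tin_offset
  } else {
    # fall back to the per-beam detected seafloor range
    mask <- mask | g$R > fan$floor_range - tin_offset / g$cos_a
  }
  mask
}
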