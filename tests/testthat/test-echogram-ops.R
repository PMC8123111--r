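test_that("3x3 filters equal their brute-force window oracles", {
  for (seed in 1:3) {
    set.seed(seed)
    m <- matrix(rnorm(400, -70, 5), 20, 20)
    e <- echogram_from_matrix(m)
    expect_equal(median_3x3(e)$mat, oracle_window3(m, "median"))
    expect_equal(erosion_3x3(e)$mat, oracle_window3(m, "min"))
    expect_equal(dilate_3x3(e)$mat, oracle_window3(m, "max", exclude_centre = TRUE))
  }
})

test_that("filters: constants pass through, impulses behave, ordering holds", {
  const <- echogram_from_matrix(matrix(-70, 10, 10))
  expect_equal(median_3x3(const)$mat, const$mat)
  expect_equal(erosion_3x3(const)$mat, const$mat)
  expect_equal(dilate_3x3(const)$mat, const$mat)

  m <- matrix(-80, 11, 11); m[6, 6] <- -30
  e <- echogram_from_matrix(m)
  expect_true(all(median_3x3(e)$mat == -80))   # impulse erased
  expect_true(all(erosion_3x3(e)$mat == -80))
  d <- dilate_3x3(e)$mat
  hot <- which(d == -30, arr.ind = TRUE)       # exactly the 8 neighbours
  expect_equal(nrow(hot), 8L)
  expect_true(all(abs(hot[, 1] - 6) <= 1 & abs(hot[, 2] - 6) <= 1))
  expect_equal(d[6, 6], -80)                   # centre excluded

  set.seed(7)
  m <- matrix(rnorm(100), 10, 10)
  e <- echogram_from_matrix(m)
  expect_true(all(erosion_3x3(e)$mat <= m))    # pointwise ordering
  expect_true(all(dilate_3x3(e)$mat >= erosion_3x3(e)$mat))
})

test_that("maximum-intensity stacking equals the per-range max and is beam-order invariant", {
  set.seed(3)
  sv1 <- matrix(rnorm(4 * 12, -70, 5), 4, 12)
  sv1[2, 5] <- NA; sv1[, 9] <- NA  # one no-data cell and one no-data column
  f1 <- manual_fan(sv1, ping_id = 1L)
  f2 <- manual_fan(sv1[c(3, 1, 4, 2), ], ping_id = 2L)  # beams permuted
  st <- stack_max_intensity(list(f1, f2))
  oracle <- apply(sv1, 2, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  expect_equal(st$mat[1, ], oracle)
  expect_equal(st$mat[2, ], st$mat[1, ])       # permutation invariance
  expect_true(is.na(st$mat[1, 9]))             # no-data propagated
  # single-beam fan: output equals that beam's profile
  fb <- manual_fan(matrix(sv1[1, ], 1))
  expect_error(stack_max_intensity(list()), "empty")
  expect_equal(stack_max_intensity(list(fb))$mat[1, ], sv1[1, ])
})

test_that("bad-ping rejection agrees with a per-ping counting oracle", {
  set.seed(11)
  m <- matrix(rnorm(30 * 40, -70, 8), 30, 40)
  m[4, ] <- -20                                 # saturated ping
  e <- echogram_from_matrix(m)
  kept <- reject_bad_pings(e, frac_threshold = 0.5, sv_threshold = -65)
  frac <- rowMeans(m > -65)
  expect_equal(kept, which(frac < 0.5))
  expect_false(4 %in% kept)
  # all-background ping retained, fully saturated removed
  expect_true(1 %in% reject_bad_pings(echogram_from_matrix(matrix(-75, 3, 10)), 0.9, -60))
  expect_length(reject_bad_pings(echogram_from_matrix(matrix(0, 3, 10)), 0.9, -60), 0)
})

test_that("bottom line recovers the minimum seafloor range of a simulated seabed", {
  cfg <- tiny_config(seed = 21, speckle_sd = 0.5)
  sv <- generate_survey(cfg, list(), noise = NULL)
  st <- stack_max_intensity(sv$fans)
  em <- median_3x3(st)
  bl <- best_bottom_candidate(em, window_pings = 5,
                              min_peak_sv = cfg$background_sv + 42)
  truth <- vapply(sv$fans, function(f) min(f$floor_range), 0)
  expect_true(all(!is.na(bl$range)))
  expect_lt(max(abs(bl$range - truth)), cfg$range_bin + 1e-9)
  # a mid-water school does not capture the line
  sv2 <- generate_survey(cfg, list(target_spec("FISH", c(0, 2, 15),
                                               c(10, 10, 5), 25)), noise = NULL)
  bl2 <- best_bottom_candidate(median_3x3(stack_max_intensity(sv2$fans)),
                               window_pings = 5,
                               min_peak_sv = cfg$background_sv + 42)
  expect_lt(max(abs(bl2$range - truth)), cfg$range_bin + 1e-9)
  # no seafloor echo at all: line undefined
  empty <- echogram_from_matrix(matrix(-75, 8, 40))
  bl3 <- best_bottom_candidate(empty, min_peak_sv = -37)
  expect_true(all(is.na(bl3$range)))
})

test_that("threshold-offset line finds the layer bottom and falls back cleanly", {
  # hot near-surface layer down to 3 m, then background
  ra <- (1:60 - 0.5) * 0.64
  m <- matrix(rep(ifelse(ra < 3, -55, -75), each = 9), 9, 60)
  e <- echogram_from_matrix(m)
  l <- threshold_offset_line(e, reference = 0, sv_threshold = -65, offset = 1)
  expect_equal(unique(l$range), 3 + 1, tolerance = 0.64)
  # no layer: line at reference + offset
  e0 <- echogram_from_matrix(matrix(-75, 5, 30))
  l0 <- threshold_offset_line(e0, reference = 2, sv_threshold = -65, offset = 1.5)
  expect_true(all(abs(l0$range - (2 + 1.5)) <= 0.64))
  # monotone decreasing profile: crossing matches a scan oracle
  prof <- seq(-50, -90, length.out = 50)
  em <- echogram_from_matrix(matrix(prof, 1, 50, byrow = TRUE))
  lm <- threshold_offset_line(em, 0, -70, 0)
  oracle <- em$range_axis[which(prof < -70)[1]]
  expect_equal(lm$range, oracle)
})

test_that("ping-of-interest selection: empty scenes give none, targets their pings", {
  cfg <- tiny_config(seed = 31)
  bg <- cfg$background_sv
  pipeline_poi <- function(survey) {
    st <- stack_max_intensity(survey$fans)
    em <- median_3x3(st)
    ee <- erosion_3x3(em)
    sl <- threshold_offset_line(em, 0, bg + 12, 1, consensus_window = 61)
    bl <- best_bottom_candidate(em, 5, bg + 38, near_field = sl)
    select_pings_of_interest(ee, sl, bl, bg + 10)
  }
  empty <- generate_survey(cfg, list(), noise = NULL)
  expect_length(pipeline_poi(empty), 0)

  tg <- target_spec("FISH", c(0, 2, 15), c(8, 8, 5), 25)
  one <- generate_survey(cfg, list(tg), noise = NULL)
  poi <- pipeline_poi(one)
  true_pings <- which(vapply(one$fans, function(f) any(f$truth == 1L), TRUE))
  expect_gt(length(poi), 0)
  # retained pings sit on the school (within the dilation margin)
  expect_true(all(poi >= min(true_pings) - 2 & poi <= max(true_pings) + 2))
  # superset monotonicity: adding a second target never removes pings
  two <- generate_survey(cfg, list(tg, target_spec("NOISE", c(-12, -3, 12),
                                                   c(6, 6, 3), 20)), noise = NULL)
  expect_true(all(poi %in% pipeline_poi(two)))
})

test_that("45-cell smoother: mean over 3 beams x 5 pings x 3 bins in linear power", {
  # constant field is unchanged
  fans <- lapply(1:5, function(p) manual_fan(matrix(-70, 12, 20), ping_id = p))
  sm <- smooth_fan_45(fans)
  for (f in sm) expect_equal(f$sv, matrix(-70, 12, 20))
  # an impulse spreads over exactly 45 cells with equal linear weight
  fans[[3]]$sv[6, 10] <- -40
  sm <- smooth_fan_45(fans)
  base <- db_to_linear(-70)
  delta <- (db_to_linear(-40) - base) / 45
  hits <- 0L
  for (p in 1:5) for (b in 1:12) for (r in 1:20) {
    got <- db_to_linear(sm[[p]]$sv[b, r])
    if (abs(b - 6) <= 1 && abs(r - 10) <= 1) {
      hits <- hits + 1L
      expect_equal(got, base + delta, tolerance = 1e-9)
    } else {
      expect_equal(got, base, tolerance = 1e-12)
    }
  }
  expect_equal(hits, 45L)  # 3 x 5 x 3 kernel
})

test_that("exclusion mask: near field, seafloor offset, undefined TIN", {
  cfg <- tiny_config(seed = 41)
  sv <- generate_survey(cfg, list(), noise = NULL)
  f <- sv$fans[[3]]
  # flat synthetic TIN at the nominal depth, covering the whole swath
  s <- expand.grid(x = seq(-80, 80, by = 10), y = seq(-80, 80, by = 10))
  s$depth <- cfg$water_depth
  tin <- build_and_resample_tin(s, max_points = 400)
  mask <- exclusion_mask(f, near_field = 4, tin = tin, tin_offset = 2)
  g <- f$geom
  expect_true(all(mask[g$R < 4]))                        # 2 m range excluded
  mid <- g$R > 6 & g$D < cfg$water_depth - 8 & !is.na(f$sv)
  expect_false(any(mask[mid & g$R >= 4]))                # mid-water retained
  near_bottom <- g$D > cfg$water_depth - 1 & g$D < cfg$water_depth & !is.na(f$sv)
  expect_true(all(mask[near_bottom]))                    # 1 m above floor, 2 m offset
  # undefined TIN: everything except nothing is conservatively excluded
  tin_far <- build_and_resample_tin(data.frame(x = c(500, 510, 505),
                                               y = c(500, 510, 490),
                                               depth = 30))
  mask2 <- exclusion_mask(f, near_field = 4, tin = tin_far, tin_offset = 2)
  expect_true(all(mask2[!is.na(f$sv)]))
})
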