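# Synthetic generator: optics helper, step patterns, walk simulation,
# fTIR renderer.

test_that("critical_angle matches Snell's law and rejects bad indices", {
  expect_equal(critical_angle(2, 1), 30)
  expect_equal(round(critical_angle(1.471, 1)), 43)
  expect_equal(critical_angle(1.471, 1), asin(1 / 1.471) * 180 / pi)
  expect_error(critical_angle(1, 1), "no total internal reflection")
  expect_error(critical_angle(1, 1.5), "no total internal reflection")
  expect_error(critical_angle(-1, -2), "> 0")
})

test_that("tripod pattern: antiphase triplets, exact timing", {
  spec <- gait_spec("tripod", period_ms = 100, duty_factor = 0.5,
                    n_cycles = 10)
  pat <- make_step_pattern(spec)
  # every leg stance lasts 50 ms
  for (l in LEG_LABELS) {
    df <- pat$legs[[l]]
    expect_true(all(abs(df$liftoff_ms - df$touchdown_ms - 50) < 1e-9))
  }
  # LF onset = RF onset + 50 (RF leads by half a period here)
  lf <- pat$legs$LF$touchdown_ms[!pat$legs$LF$edge_touchdown]
  rf <- pat$legs$RF$touchdown_ms[!pat$legs$RF$edge_touchdown]
  expect_equal(sort(abs(outer(lf, rf, `-`)) %% 100)[1], 50)
  # contralateral same-segment phase exactly 0.5
  for (pair in list(c("LF", "RF"), c("LM", "RM"), c("LH", "RH")))
    expect_equal(unique(phases(pat, pair[1], pair[2])), 0.5)
  # hind-to-fore metachronal lag equals the period
  expect_equal(unique(metachronal_lags(pat, "L")$lag_ms), 100)
  expect_equal(unique(metachronal_lags(pat, "R")$lag_ms), 100)
})

test_that("duty factor 1 keeps all legs in stance for the whole record", {
  pat <- make_step_pattern(gait_spec("tripod", duty_factor = 1,
                                     n_cycles = 2, fps = 100))
  codes <- frame_codes(pat, 20, fps = 100)
  expect_true(all(codes == "111111"))
})

test_that("tetrapod patterns produce exactly the canonical codes", {
  for (g in c("tetrapod_right", "tetrapod_left")) {
    pat <- make_step_pattern(gait_spec(g, period_ms = 120, n_cycles = 8,
                                       fps = 250))
    gm <- gait_map(pat, 250 * 8 * 120 / 1000 / 2, fps = 250)
    codes <- unique(gm$code[gm$in_range])
    expect_length(codes, 3)
    expect_true(all(codes %in% TETRAPOD_CODES))
  }
  # the two handednesses use disjoint code triples
  cr <- unique(frame_codes(make_step_pattern(
    gait_spec("tetrapod_right", n_cycles = 3, fps = 250)), 100,
    fps = 250))
  cl <- unique(frame_codes(make_step_pattern(
    gait_spec("tetrapod_left", n_cycles = 3, fps = 250)), 100,
    fps = 250))
  expect_length(intersect(setdiff(cr, "000000"), setdiff(cl, "000000")),
                0)
  expect_error(make_step_pattern(gait_spec("tetrapod_right",
                                           duty_factor = 0.5)),
               "duty factor < 2/3")
})

test_that("wave gait swings one leg at a time, back to front", {
  pat <- make_step_pattern(gait_spec("wave", period_ms = 120,
                                     n_cycles = 6, fps = 250))
  gm <- gait_map(pat, 200, fps = 250)
  expect_true(all(gm$stance_count[gm$in_range] %in% c(5L, 6L)))
  expect_true(any(gm$pentapod[gm$in_range]))
  # ipsilateral swing order is hind, mid, fore (within the cycle)
  lo <- vapply(c("LH", "LM", "LF"),
               function(l) pat$legs[[l]]$liftoff_ms[
                 !pat$legs[[l]]$edge_liftoff][1] %% 120, 0)
  expect_true(lo["LH"] < lo["LM"] && lo["LM"] < lo["LF"])
})

test_that("metachronal override reproduces the requested lag", {
  P <- 120
  lag <- 0.505 * P + 27.627
  spec <- gait_spec("tetrapod_right", period_ms = P,
                    metachronal_lag_ms = lag, n_cycles = 10)
  pat <- quantize_step_pattern(make_step_pattern(spec), 1000)
  got <- metachronal_lags(pat, "L")$lag_ms
  expect_close(got, 88.227, tol = 0.5)   # 1000 fps grid -> 1 ms steps
})

test_that("simulate_walk: displacement, zero speed, workspace guard", {
  plan <- body_plan()
  tr <- simulate_walk(gait_spec(speed_mm_s = 20, period_ms = 100), plan)
  # body advances speed * period = 2000 um per cycle
  expect_equal(diff(body_xy_at(tr, c(0, 100))[, 1]), 2000)
  fp0 <- truth_footprints(simulate_walk(gait_spec(speed_mm_s = 0), plan))
  expect_true(all(abs(fp0$aep_x_bl - fp0$pep_x_bl) < 1e-12))
  expect_true(all(abs(fp0$aep_y_bl - fp0$pep_y_bl) < 1e-12))
  expect_error(simulate_walk(gait_spec(speed_mm_s = 60), plan),
               "kinematically impossible")
})

test_that("per-step jitter spreads PEPs more than AEPs by design", {
  plan <- body_plan()
  tr <- simulate_walk(gait_spec(n_cycles = 15), plan, seed = 5,
                      aep_jitter_bl = 0.01, pep_jitter_bl = 0.03)
  fp <- truth_footprints(tr)
  fp <- fp[!fp$edge_touchdown & !fp$edge_liftoff, ]
  for (l in LEG_LABELS) {
    a <- fp[fp$leg == l, ]
    expect_gt(footprint_clustering(a[, c("pep_x_bl", "pep_y_bl")]),
              footprint_clustering(a[, c("aep_x_bl", "aep_y_bl")]))
  }
})

test_that("renderer is deterministic and honors pre-entry dust", {
  spec <- gait_spec(n_cycles = 1, fps = 50)
  tr <- simulate_walk(spec, body_plan())
  cfg <- render_config(noise_sd = 0)
  a <- render_ftir_frames(tr, cfg, seed = 9)
  b <- render_ftir_frames(tr, cfg, seed = 9)
  expect_identical(a$stack$frames, b$stack$frames)
  # explicit dust spot is present in pre-entry frames
  cfg2 <- render_config(noise_sd = 0, dust = data.frame(
    x_px = 10, y_px = 10, amplitude = 0.3, sigma_px = 1))
  rr <- render_ftir_frames(tr, cfg2, seed = 1)
  pre <- rr$stack$frames[[1]]          # a pre-entry frame
  expect_gt(pre[11, 11], 0.3)          # dust + background offset
  expect_lt(max(pre[40:60, 40:60]), 0.1)  # elsewhere only background
  # invariants of the config
  expect_error(render_config(spot_amplitude = 0.1, body_amplitude = 0.2),
               "spot_amplitude > body_amplitude")
})

test_that("rendered spots sit at the true footprints (conservation)", {
  rr <- small_render()
  st <- rr$stack; tru <- rr$truth
  fp <- pattern_events(tru$pattern_rendered)
  upp <- st$calibration$um_per_px
  # threshold above body glow, background offset, dust and noise, but
  # well below the footprint-spot peak (0.5 + background)
  glow <- 0.45
  for (f in c(15, 20, 26)) {                # 0-based probe frames
    t <- f * 1000 / st$calibration$fps
    active <- fp[fp$touchdown_ms <= t + 1e-9 &
                   t < fp$liftoff_ms - 1e-9, ]
    m <- st$frames[[f + 1]]
    # one local maximum above the body glow within 1 px of each truth spot
    for (k in seq_len(nrow(active))) {
      cx <- active$x_um[k] / upp; cy <- active$y_um[k] / upp
      win <- m[round(cy) + 1 + (-1:1), round(cx) + 1 + (-1:1)]
      expect_gt(max(win), glow)
    }
    # and no more bright spots than legs in stance
    bright <- label_components(m > glow)
    expect_equal(max(bright), nrow(active))
  }
})

test_that("frame-quantized onsets deviate from truth by < 1 frame", {
  spec <- gait_spec("tetrapod_right", period_ms = 110, n_cycles = 4,
                    fps = 250)
  pat <- make_step_pattern(spec)
  q <- quantize_step_pattern(pat, 250)
  for (l in LEG_LABELS) {
    expect_true(all(abs(q$legs[[l]]$touchdown_ms -
                          pat$legs[[l]]$touchdown_ms) < 1000 / 250))
    expect_true(all(abs(q$legs[[l]]$liftoff_ms -
                          pat$legs[[l]]$liftoff_ms) < 1000 / 250))
  }
})

test_that("truth sidecar round-trips through JSON", {
  rr <- small_render()
  f <- withr::local_tempfile(fileext = ".json")
  write_truth(rr$truth, f)
  tr2 <- read_truth(f)
  expect_equal(tr2$pattern$legs, rr$truth$pattern$legs)
  expect_equal(tr2$pattern_rendered$legs, rr$truth$pattern_rendered$legs)
  expect_equal(tr2$spec$period_ms, rr$truth$spec$period_ms)
  expect_equal(tr2$origin_um, rr$truth$origin_um)
  expect_equal(tr2$plan$aep, rr$truth$plan$aep)
})
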