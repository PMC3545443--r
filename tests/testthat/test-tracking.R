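# Tracking: background subtraction, blob detection, body tracking,
# leg labeling, edits, stance extraction.

test_that("pre-entry background removes static dust downstream", {
  tk <- small_tracked()
  # the renderer placed random dust spots; none may survive detection
  dust <- tk$truth$render$dust
  for (i in seq_len(nrow(tk$detections))) {
    d2 <- (dust$x_px - tk$detections$x_px[i])^2 +
      (dust$y_px - tk$detections$y_px[i])^2
    expect_gt(min(d2), 3^2)
  }
  # subtracting a pre-entry frame's own background zeroes the statics
  st <- tk$stack
  resid <- subtract_background(st$frames[[1]], tk$background)
  expect_lt(max(resid), 8 * tk$noise)
})

test_that("estimate_background handles degenerate inputs", {
  st <- frame_stack(rep(list(matrix(0, 4, 4)), 5), calibration(100, 10))
  expect_warning(bg0 <- estimate_background(st, 0), "zero background")
  expect_true(all(bg0 == 0))
  expect_equal(estimate_background(st, 3), matrix(0, 4, 4))
  expect_error(estimate_background(st, 5), "must be <")
  # median method on constant frames
  expect_equal(estimate_background(st, 3, method = "median"),
               matrix(0, 4, 4))
})

test_that("label_components finds 8-connected blobs", {
  m <- matrix(FALSE, 6, 8)
  m[2:3, 2:3] <- TRUE          # blob A
  m[5, 5] <- TRUE              # blob B, diagonal neighbour below
  m[6, 6] <- TRUE
  m[1, 8] <- TRUE              # blob C, isolated pixel
  lab <- label_components(m)
  expect_equal(max(lab), 3)
  expect_equal(length(unique(lab[m])), 3)
  expect_equal(lab[5, 5], lab[6, 6])   # diagonal connectivity
  expect_true(all(lab[!m] == 0))
  expect_equal(max(label_components(matrix(FALSE, 3, 3))), 0)
})

test_that("detect_footprints: blanks, area filter, centroid accuracy", {
  bg <- matrix(0, 40, 40)
  blank <- frame_stack(list(bg), calibration(100, 10))
  expect_equal(nrow(detect_footprints(blank, bg, 0.1)), 0)
  # one 2-px spot is rejected by min_area = 3, a larger one kept
  m <- matrix(0, 40, 40)
  m[5, 5] <- m[5, 6] <- 0.9
  m[20:22, 20:22] <- 0.9
  st <- frame_stack(list(m), calibration(100, 10))
  det <- detect_footprints(st, bg, 0.5, min_area = 3)
  expect_equal(nrow(det), 1)
  expect_equal(det$area, 9L)
  expect_equal(det$x_px, 20)  # 0-based centroid of cols 20:22
  expect_equal(det$y_px, 20)
  expect_error(detect_footprints(st, bg, 0), "> 0")
})

test_that("rendered spots are recovered within 1 px of truth", {
  tk <- small_tracked()
  fp <- pattern_events(tk$truth$pattern_rendered)
  upp <- tk$stack$calibration$um_per_px
  dt <- 1000 / tk$stack$calibration$fps
  det <- tk$detections
  count_ok <- dist_max <- numeric(0)
  for (f in unique(det$frame)) {
    t <- f * dt
    active <- fp[fp$touchdown_ms <= t + 1e-9 & t < fp$liftoff_ms - 1e-9, ]
    rows <- det[det$frame == f, ]
    count_ok <- c(count_ok, nrow(rows) == nrow(active))
    dist_max <- c(dist_max, vapply(seq_len(nrow(rows)), function(i)
      sqrt(min((active$x_um / upp - rows$x_px[i])^2 +
                 (active$y_um / upp - rows$y_px[i])^2)), 0))
  }
  expect_true(all(count_ok == 1))
  expect_lt(max(dist_max), 1)
})

test_that("track_body recovers pose; stationary body falls back", {
  tk <- small_tracked()
  bt <- tk$body_track
  tbt <- truth_body_track(tk$truth,
                          um_per_px = tk$stack$calibration$um_per_px)
  v <- bt$valid & tbt$valid
  # heading within 2 degrees of the true +x heading
  expect_true(all(abs(atan2(bt$uy[v], bt$ux[v])) * 180 / pi < 2))
  # body length within 10% of the rendered major axis
  expect_close(median(bt$length_px[v]) /
                 median(tbt$length_px[v]), 1, tol = 0.1)
  # centroid within 1 px
  expect_true(all(sqrt((bt$cx_px[v] - tbt$cx_px[v])^2 +
                         (bt$cy_px[v] - tbt$cy_px[v])^2) < 1))
  # stationary body: displacement axis falls back to ellipse orientation
  m <- matrix(0, 30, 60)
  m[13:17, 20:40] <- 0.2                     # horizontal bar "body"
  st <- frame_stack(rep(list(m), 8), calibration(100, 10))
  bts <- track_body(st, matrix(0, 30, 60), 0.1)
  expect_true(all(abs(abs(bts$ux) - 1) < 0.01))
  # a stack with no body errors out
  blank <- frame_stack(rep(list(matrix(0, 10, 10)), 4),
                       calibration(100, 10))
  expect_error(track_body(blank, matrix(0, 10, 10), 0.1), "fly not found")
})

test_that("leg labels match ground truth on the synthetic walk", {
  tk <- small_tracked()
  fp <- pattern_events(tk$truth$pattern_rendered)
  upp <- tk$stack$calibration$um_per_px
  expect_length(attr(tk$contacts, "conflicts"), 0)
  expect_false(any(is.na(tk$contacts$leg)))
  hits <- 0L
  for (i in seq_len(nrow(tk$contacts))) {
    d2 <- (fp$x_um / upp - tk$contacts$x_px[i])^2 +
      (fp$y_um / upp - tk$contacts$y_px[i])^2
    hits <- hits + (fp$leg[which.min(d2)] == tk$contacts$leg[i])
  }
  expect_equal(hits, nrow(tk$contacts))    # 100% of contact frames
})

test_that("single prints are labeled by side and zone convention", {
  # straight track moving +x, body at (50, 20) px, length 10 px
  bt <- data.frame(frame = 0:9, valid = TRUE, cx_px = 41:50 + 0,
                   cy_px = 20, ux = 1, uy = 0, length_px = 10)
  class(bt) <- c("fw_body_track", "data.frame")
  # left of the displacement axis (fly's left = +y image), mid-body
  det <- data.frame(frame = 5L, x_px = 48, y_px = 24, area = 5L,
                    peak = 1)
  lab <- assign_leg_identities(det, bt)
  expect_equal(lab$leg, "LM")
  # two new ipsilateral prints: the anterior one gets the more
  # anterior unclaimed label
  det2 <- data.frame(frame = c(5L, 5L), x_px = c(52, 48),
                     y_px = c(24, 24), area = 5L, peak = 1)
  lab2 <- assign_leg_identities(det2, bt)
  expect_equal(lab2$leg[order(-lab2$x_px)], c("LF", "LM"))
  # right side mirror
  det3 <- data.frame(frame = 5L, x_px = 48, y_px = 16, area = 5L,
                     peak = 1)
  expect_equal(assign_leg_identities(det3, bt)$leg, "RM")
})

test_that("apply_edits: add/remove/relabel semantics and errors", {
  tk <- small_tracked()
  contacts <- tk$contacts
  # identity on empty log
  expect_equal(apply_edits(contacts, NULL), contacts)
  expect_equal(apply_edits(contacts, contacts[0, c("frame", "leg")]),
               contacts)
  # add an LF contact at a frame where LF is absent
  f_abs <- setdiff(0:(tk$stack$n - 1),
                   contacts$frame[contacts$leg == "LF"])[1]
  ed <- data.frame(frame = f_abs, action = "add", leg = "LF",
                   to = NA, x_px = 100, y_px = 50)
  out <- apply_edits(contacts, ed)
  expect_true(any(out$frame == f_abs & out$leg == "LF"))
  # remove it again
  ed2 <- rbind(ed, data.frame(frame = f_abs, action = "remove",
                              leg = "LF", to = NA, x_px = NA, y_px = NA))
  expect_equal(nrow(apply_edits(contacts, ed2)), nrow(contacts))
  # relabel onto an occupied leg errors with the record index
  # (RF and RH stance together in the same tripod triplet)
  f_both <- intersect(contacts$frame[contacts$leg == "RF"],
                      contacts$frame[contacts$leg == "RH"])[1]
  bad <- data.frame(frame = f_both, action = "relabel", leg = "RF",
                    to = "RH", x_px = NA, y_px = NA)
  expect_error(apply_edits(contacts, bad), "edit 1.*two contacts")
  # remove of a non-existent detection errors
  expect_error(apply_edits(contacts, data.frame(
    frame = f_abs, action = "remove", leg = "LF", to = NA,
    x_px = NA, y_px = NA)), "no LF contact")
  # a remove edit deletes a dust transient for good
  fake <- rbind(contacts, transform(contacts[1, ], frame = 0L,
                                    leg = "RH"))
  cleaned <- apply_edits(fake, data.frame(
    frame = 0L, action = "remove", leg = "RH", to = NA,
    x_px = NA, y_px = NA))
  expect_false(any(cleaned$frame == 0 & cleaned$leg == "RH"))
})

test_that("edit log JSON round trip", {
  ed <- data.frame(frame = c(3L, 4L), action = c("add", "relabel"),
                   leg = c("LF", "RM"), to = c(NA, "RH"),
                   x_px = c(10, NA), y_px = c(20, NA))
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(ed, f, dataframe = "rows", na = "null")
  ed2 <- read_edit_log(f)
  expect_equal(ed2$action, ed$action)
  expect_equal(ed2$frame, ed$frame)
})

test_that("extract_step_pattern: half-open runs, merging, dropping", {
  cal <- calibration(250, 10)
  mk <- function(frames) data.frame(
    frame = as.integer(frames), x_px = 5, y_px = 5, area = 5L,
    peak = 1, track_id = 1L, leg = "LF")
  # contact at frames 10..19 -> stance [10, 20)
  pat <- extract_step_pattern(mk(10:19), cal, n_frames = 100)
  expect_equal(pat$legs$LF$touchdown_frame, 10L)
  expect_equal(pat$legs$LF$liftoff_frame, 20L)
  expect_equal(pat$legs$LF$touchdown_ms, 40)
  expect_equal(pat$legs$LF$liftoff_ms, 80)
  # runs 10..13 and 15..19 merge across a 1-frame gap
  pat2 <- extract_step_pattern(mk(c(10:13, 15:19)), cal,
                               max_gap_frames = 1, n_frames = 100)
  expect_equal(nrow(pat2$legs$LF), 1)
  expect_equal(pat2$legs$LF$liftoff_frame, 20L)
  # but not across a larger gap than allowed
  pat3 <- extract_step_pattern(mk(c(10:13, 16:19)), cal,
                               max_gap_frames = 1, n_frames = 100)
  expect_equal(nrow(pat3$legs$LF), 2)
  # a 1-frame run is dropped with min_stance_frames = 2
  pat4 <- extract_step_pattern(mk(c(10:19, 40)), cal,
                               min_stance_frames = 2, n_frames = 100)
  expect_equal(nrow(pat4$legs$LF), 1)
})

test_that("end-to-end stance recovery is within one frame of truth", {
  tk <- small_tracked()
  dt <- 1000 / tk$stack$calibration$fps
  fp <- tk$truth$pattern_rendered
  for (l in LEG_LABELS) {
    rec <- tk$pattern$legs[[l]]
    tru <- fp$legs[[l]]
    expect_gt(nrow(rec), 0)
    m <- match_truth_events(rec, tru)
    expect_true(all(abs(rec$touchdown_ms - tru$touchdown_ms[m]) <=
                      dt + 1e-9))
    ok <- !rec$edge_liftoff & !tru$edge_liftoff[m]
    expect_true(all(abs(rec$liftoff_ms[ok] - tru$liftoff_ms[m][ok]) <=
                      dt + 1e-9))
  }
})
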