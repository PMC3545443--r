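# Shared synthetic fixtures, built in code and memoized per test run.

.fw_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fw_cache[[key]])) .fw_cache[[key]] <- force(expr)
  .fw_cache[[key]]
}

# small, quick render for unit tests: 3 cycles at 100 fps
small_render <- function() {
  cached("small_render", {
    spec <- gait_spec(n_cycles = 3, fps = 100)
    render_ftir_frames(simulate_walk(spec, body_plan(), seed = 3),
                       render_config(), seed = 3)
  })
}

# tracking products of the small render
small_tracked <- function() {
  cached("small_tracked", {
    rr <- small_render()
    st <- rr$stack
    noise <- estimate_noise_mad(st, 10)
    bg <- estimate_background(st, 10)
    bt <- track_body(st, bg, 2 * noise)
    det <- detect_footprints(st, bg, 8 * noise, body_track = bt)
    contacts <- assign_leg_identities(det, bt)
    pattern <- extract_step_pattern(contacts, st$calibration,
                                    n_frames = st$n)
    list(stack = st, truth = rr$truth, noise = noise, background = bg,
         body_track = bt, detections = det, contacts = contacts,
         pattern = pattern)
  })
}

# match each recovered stance interval to the closest true one
match_truth_events <- function(recovered_leg_df, truth_leg_df) {
  vapply(recovered_leg_df$touchdown_ms, function(t)
    which.min(abs(truth_leg_df$touchdown_ms - t)), 0L)
}

expect_close <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol),
              label = sprintf("max |err| = %g (tol %g)",
                              max(abs(object - expected)), tol))
}

empty_interval_df_for_test <- function() {
  data.frame(touchdown_ms = numeric(0), liftoff_ms = numeric(0))
}
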