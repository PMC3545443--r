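# Temporal step parameters.  All times ms, distances um, speeds mm/s
# (1 um/ms == 1 mm/s).  Duration-based parameters only use complete
# cycles: stances flagged as edge-truncated are skipped.

#' Instantaneous and average body speed
#'
#' Instantaneous speed at frame `t` is the centroid displacement over
#' a centered window of `integration_ms` divided by the window span;
#' at the edges the window is truncated (and the sample flagged).
#' Average speed is the total path length over the total duration of
#' the valid track.
#'
#' @param body_track a `fw_body_track`.
#' @param calibration a [calibration()] object.
#' @param integration_ms centered integration window (must cover at
#'   least 2 frame intervals and fit inside the video).
#' @return list with `inst` (data.frame: frame, t_ms, speed_mm_s,
#'   truncated) and `average_mm_s`.
#' @export
speeds <- function(body_track, calibration, integration_ms = 25) {
  dt <- 1000 / calibration$fps
  upp <- calibration$um_per_px
  vi <- which(body_track$valid)
  if (length(vi) < 2) stop_fg("need at least 2 valid body frames")
  if (integration_ms < 2 * dt)
    stop_fg("integration_ms must cover at least 2 frame intervals")
  span_ms <- (max(vi) - min(vi)) * dt
  if (integration_ms > span_ms)
    stop_fg("integration window (%g ms) longer than the video (%g ms)",
            integration_ms, span_ms)
  k <- max(1L, as.integer(round(integration_ms / 2 / dt)))
  lo <- min(vi); hi <- max(vi)
  cx <- body_track$cx_px * upp
  cy <- body_track$cy_px * upp
  inst <- do.call(rbind, lapply(vi, function(f) {
    a <- max(lo, f - k); b <- min(hi, f + k)
    # shrink onto valid frames (straight walks have contiguous validity)
    while (!body_track$valid[a] && a < f) a <- a + 1L
    while (!body_track$valid[b] && b > f) b <- b - 1L
    if (b == a) return(NULL)
    data.frame(frame = f - 1L, t_ms = (f - 1L) * dt,
               speed_mm_s = sqrt((cx[b] - cx[a])^2 +
                                   (cy[b] - cy[a])^2) / ((b - a) * dt),
               truncated = (a != f - k) || (b != f + k))
  }))
  steps <- sqrt(diff(cx[vi])^2 + diff(cy[vi])^2)
  avg <- sum(steps) / ((length(vi) - 1) * dt)
  list(inst = inst, average_mm_s = avg)
}

#' Per-cycle step periods and stance/swing durations
#'
#' A complete cycle runs touchdown to touchdown: period is the time
#' between consecutive stance onsets of the leg, stance is liftoff
#' minus touchdown, swing is the next touchdown minus liftoff; the
#' three satisfy period = stance + swing exactly.  Edge-truncated
#' stances never contribute.
#'
#' @param pattern a `fw_step_pattern`.
#' @return data.frame: leg, cycle, touchdown_ms, period_ms, stance_ms,
#'   swing_ms (zero rows for legs with fewer than 2 onsets).
#' @export
step_timings <- function(pattern) {
  out <- do.call(rbind, lapply(LEG_LABELS, function(l) {
    df <- pattern$legs[[l]]
    if (nrow(df) < 2) return(NULL)
    i <- seq_len(nrow(df) - 1L)
    keep <- !df$edge_touchdown[i] & !df$edge_liftoff[i] &
      !df$edge_touchdown[i + 1L]
    i <- i[keep]
    if (!length(i)) return(NULL)
    data.frame(leg = l, cycle = i,
               touchdown_ms = df$touchdown_ms[i],
               period_ms = df$touchdown_ms[i + 1L] - df$touchdown_ms[i],
               stance_ms = df$liftoff_ms[i] - df$touchdown_ms[i],
               swing_ms = df$touchdown_ms[i + 1L] - df$liftoff_ms[i])
  }))
  if (is.null(out))
    out <- data.frame(leg = character(0), cycle = integer(0),
                      touchdown_ms = numeric(0), period_ms = numeric(0),
                      stance_ms = numeric(0), swing_ms = numeric(0))
  out
}

#' Per-cycle step lengths and swing speeds
#'
#' Step length is the Euclidean world-frame distance between two
#' successive footprints of the same leg (no normalization to the
#' direction of travel).  Swing speed is the step length divided by
#' the intervening swing duration: during the swing the tarsus travels
#' between the consecutive footprint positions.
#'
#' @param pattern a `fw_step_pattern` with world positions.
#' @return data.frame: leg, cycle, step_length_um, swing_ms,
#'   swing_speed_mm_s.
#' @export
step_lengths <- function(pattern) {
  out <- do.call(rbind, lapply(LEG_LABELS, function(l) {
    df <- pattern$legs[[l]]
    if (nrow(df) < 2 || all(is.na(df$x_um))) return(NULL)
    i <- seq_len(nrow(df) - 1L)
    keep <- !is.na(df$x_um[i]) & !is.na(df$x_um[i + 1L]) &
      !df$edge_liftoff[i] & !df$edge_touchdown[i + 1L]
    i <- i[keep]
    if (!length(i)) return(NULL)
    len <- sqrt((df$x_um[i + 1L] - df$x_um[i])^2 +
                  (df$y_um[i + 1L] - df$y_um[i])^2)
    sw <- df$touchdown_ms[i + 1L] - df$liftoff_ms[i]
    data.frame(leg = l, cycle = i, step_length_um = len,
               swing_ms = sw, swing_speed_mm_s = len / sw)
  }))
  if (is.null(out))
    out <- data.frame(leg = character(0), cycle = integer(0),
                      step_length_um = numeric(0), swing_ms = numeric(0),
                      swing_speed_mm_s = numeric(0))
  out
}

#' Metachronal lags of one body side
#'
#' For every hindleg swing onset, the lag to the first ipsilateral
#' foreleg swing onset strictly after it (simultaneous onsets are
#' skipped, so an ideal tripod -- where hind and fore lift off
#' together -- yields a lag of one period).  Waves with no subsequent
#' foreleg onset are dropped.
#'
#' @param pattern a `fw_step_pattern`.
#' @param side `"L"` or `"R"`.
#' @return data.frame: side, hind_liftoff_ms, lag_ms.
#' @export
metachronal_lags <- function(pattern, side = c("L", "R")) {
  side <- match.arg(side)
  hind <- pattern$legs[[paste0(side, "H")]]
  fore <- pattern$legs[[paste0(side, "F")]]
  t_h <- hind$liftoff_ms[!hind$edge_liftoff]
  t_f <- fore$liftoff_ms[!fore$edge_liftoff]
  eps <- 1e-9
  out <- do.call(rbind, lapply(t_h, function(t0) {
    nxt <- t_f[t_f > t0 + eps]
    if (!length(nxt)) return(NULL)
    data.frame(side = side, hind_liftoff_ms = t0,
               lag_ms = min(nxt) - t0)
  }))
  if (is.null(out))
    out <- data.frame(side = character(0), hind_liftoff_ms = numeric(0),
                      lag_ms = numeric(0))
  out
}

#' Per-cycle phase of one leg relative to another
#'
#' For each complete cycle of `leg_x` (onset `t`, period `P`), the
#' phase is the time from `t` to the first onset of `leg_y` at or
#' after `t`, divided by `P` and reduced modulo 1.  A leg against
#' itself gives 0 for every cycle.
#'
#' @param pattern a `fw_step_pattern`.
#' @param leg_x reference leg (defines the cycles).
#' @param leg_y compared leg.
#' @return numeric vector of phases in `[0, 1)`.
#' @export
phases <- function(pattern, leg_x, leg_y) {
  if (!leg_x %in% LEG_LABELS || !leg_y %in% LEG_LABELS)
    stop_fg("legs must be one of: %s", paste(LEG_LABELS, collapse = ", "))
  dfx <- pattern$legs[[leg_x]]
  if (nrow(dfx) < 2) return(numeric(0))
  t_y <- pattern$legs[[leg_y]]$touchdown_ms
  eps <- 1e-9
  out <- numeric(0)
  for (i in seq_len(nrow(dfx) - 1L)) {
    if (dfx$edge_touchdown[i] || dfx$edge_touchdown[i + 1L]) next
    t0 <- dfx$touchdown_ms[i]
    P <- dfx$touchdown_ms[i + 1L] - t0
    cand <- t_y[t_y >= t0 - eps]
    if (!length(cand)) next
    out <- c(out, ((min(cand) - t0) / P) %% 1)
  }
  out
}
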