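# Body-frame spatial parameters: stance traces, AEP/PEP, stance
# linearity, footprint clustering, footprint alignment.  Body-frame
# coordinates put the body center at (0, 0), +x anterior along the
# displacement axis and +y to the fly's left, normalized by the median
# body length.

#' Transform world points to normalized body-frame coordinates
#'
#' Translate by minus the body centroid, rotate so the displacement
#' axis maps to +x (left to +y), and divide by the body length
#' (median over valid frames unless given).
#'
#' @param points_um n x 2 matrix of world positions, um.
#' @param body_track a `fw_body_track`.
#' @param frame 0-based frame index at which to take the body pose.
#' @param calibration a [calibration()] object.
#' @param body_length_um body length used for normalization; default
#'   is the median tracked length.
#' @return n x 2 matrix of body-frame coordinates in body lengths.
#' @export
to_body_frame <- function(points_um, body_track, frame, calibration,
                          body_length_um = NULL) {
  row <- body_track[body_track$frame == frame, ]
  if (!nrow(row) || !row$valid)
    stop_fg("body track is not valid at frame %d", frame)
  upp <- calibration$um_per_px
  if (is.null(body_length_um))
    body_length_um <-
      median(body_track$length_px[body_track$valid]) * upp
  p <- matrix(as.numeric(points_um), ncol = 2)
  dx <- p[, 1] - row$cx_px * upp
  dy <- p[, 2] - row$cy_px * upp
  cbind(x = (dx * row$ux + dy * row$uy) / body_length_um,
        y = (-dx * row$uy + dy * row$ux) / body_length_um)
}

#' Stance traces with AEP and PEP
#'
#' For every stance interval, the (stationary) world footprint mapped
#' into the body frame at each frame from touchdown through liftoff.
#' Because the body moves forward over the fixed footprint, each trace
#' sweeps from anterior to posterior; its first point is the anterior
#' extreme position (AEP, at the touchdown timestamp) and its last the
#' posterior extreme position (PEP, at the liftoff timestamp).  The
#' liftoff sample is included deliberately: under the half-open stance
#' convention the last *contact* frame precedes the liftoff instant by
#' one frame, and sampling the PEP there would displace it posteriorly
#' by a full frame of body travel.
#'
#' @param pattern a frame-quantized `fw_step_pattern` with positions.
#' @param body_track a `fw_body_track`.
#' @param calibration a [calibration()] object.
#' @param body_length_um optional body length for normalization.
#' @return a `fw_stance_traces` data.frame: leg, cycle, frame, t_ms,
#'   x_norm, y_norm; attribute `body_length_um`.
#' @export
stance_traces <- function(pattern, body_track, calibration,
                          body_length_um = NULL) {
  dt <- 1000 / calibration$fps
  upp <- calibration$um_per_px
  if (is.null(body_length_um))
    body_length_um <-
      median(body_track$length_px[body_track$valid]) * upp
  ev <- pattern_events(pattern)
  ev <- ev[!is.na(ev$x_um), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(ev)), function(k) {
    f0 <- ev$touchdown_frame[k]; f1 <- ev$liftoff_frame[k]
    if (is.na(f0) || is.na(f1)) {
      f0 <- as.integer(ceiling(ev$touchdown_ms[k] / dt - 1e-9))
      f1 <- as.integer(ceiling(ev$liftoff_ms[k] / dt - 1e-9))
    }
    frames <- f0:f1
    frames <- frames[frames + 1L <= nrow(body_track) &
                       body_track$valid[frames + 1L]]
    if (!length(frames)) return(NULL)
    bf <- t(vapply(frames, function(f)
      to_body_frame(c(ev$x_um[k], ev$y_um[k]), body_track, f,
                    calibration, body_length_um)[1, ],
      c(x = 0, y = 0)))
    data.frame(leg = ev$leg[k], cycle = ev$cycle[k], frame = frames,
               t_ms = frames * dt, x_norm = bf[, 1], y_norm = bf[, 2])
  }))
  if (is.null(out))
    out <- data.frame(leg = character(0), cycle = integer(0),
                      frame = integer(0), t_ms = numeric(0),
                      x_norm = numeric(0), y_norm = numeric(0))
  attr(out, "body_length_um") <- body_length_um
  class(out) <- c("fw_stance_traces", "data.frame")
  out
}

#' AEP and PEP of every stance trace
#'
#' @param traces a `fw_stance_traces` data.frame.
#' @return data.frame: leg, cycle, aep_x, aep_y, pep_x, pep_y
#'   (body lengths).
#' @export
aep_pep <- function(traces) {
  sp <- split(as.data.frame(traces),
              list(traces$leg, traces$cycle), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(tr) {
    tr <- tr[order(tr$frame), ]
    data.frame(leg = tr$leg[1], cycle = tr$cycle[1],
               aep_x = tr$x_norm[1], aep_y = tr$y_norm[1],
               pep_x = tr$x_norm[nrow(tr)], pep_y = tr$y_norm[nrow(tr)])
  }))
  out <- out[order(out$leg, out$cycle), ]
  rownames(out) <- NULL
  out
}

#' Stance linearity index of one trace
#'
#' A smoothed trace is built from every 5th sample (first and last
#' always included) and linearly interpolated back to per-frame
#' resolution; the index is the mean Euclidean distance between the
#' original and smoothed traces.  Perfectly straight, evenly swept
#' traces score 0; body wobble raises the score.  Traces shorter than
#' 6 frames are not scored (NA).
#'
#' @param xy two-column matrix (or data.frame) of trace coordinates in
#'   order.
#' @param every knot spacing in samples (default 5).
#' @return the index, in the units of `xy`.
#' @export
stance_linearity <- function(xy, every = 5) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 6) return(NA_real_)
  knots <- unique(c(seq(1L, n, by = every), n))
  sx <- stats::approx(knots, xy[knots, 1], xout = seq_len(n))$y
  sy <- stats::approx(knots, xy[knots, 2], xout = seq_len(n))$y
  mean(sqrt((xy[, 1] - sx)^2 + (xy[, 2] - sy)^2))
}

#' Per-video stance linearity
#'
#' Mean of [stance_linearity()] over all traces of all six legs;
#' short traces are skipped and counted.
#'
#' @param traces a `fw_stance_traces` data.frame.
#' @return list: `index_norm` (body lengths), `index_um`, `n_traces`,
#'   `n_skipped`.
#' @export
stance_linearity_video <- function(traces) {
  BL <- attr(traces, "body_length_um")
  sp <- split(as.data.frame(traces),
              list(traces$leg, traces$cycle), drop = TRUE)
  vals <- vapply(sp, function(tr) {
    tr <- tr[order(tr$frame), ]
    stance_linearity(cbind(tr$x_norm, tr$y_norm))
  }, 0)
  list(index_norm = if (all(is.na(vals))) NA_real_
       else mean(vals, na.rm = TRUE),
       index_um = if (all(is.na(vals))) NA_real_
       else mean(vals, na.rm = TRUE) * (BL %||% NA_real_),
       n_traces = sum(!is.na(vals)), n_skipped = sum(is.na(vals)))
}

#' Footprint clustering of one leg
#'
#' Spread of a leg's AEPs (or PEPs): the vector sum
#' `sqrt(sd_x^2 + sd_y^2)` of the sample standard deviations of the
#' two coordinates.
#'
#' @param positions n x 2 matrix of positions (any consistent units;
#'   normalized body-frame coordinates in the standard pipeline).
#' @return the clustering value; NA when fewer than 2 positions.
#' @export
footprint_clustering <- function(positions) {
  p <- as.matrix(positions)
  if (nrow(p) < 2) return(NA_real_)
  sqrt(sd(p[, 1])^2 + sd(p[, 2])^2)
}

#' Footprint alignment (follow-the-leader precision)
#'
#' Fore/mid/hind touchdown triplets are formed per side
#' follow-the-leader style: each foreleg touchdown is matched to the
#' nearest-in-world-space ipsilateral midleg touchdown occurring at or
#' after it (within `match_radius_bl` body lengths), and that midleg
#' touchdown to the nearest subsequent hindleg touchdown.  The three
#' world positions are projected onto the mean displacement axis; the
#' per-triplet value is the sample SD of the three projections and the
#' video value their mean.
#'
#' @param pattern a `fw_step_pattern` with world positions.
#' @param body_track a `fw_body_track`.
#' @param calibration a [calibration()] object.
#' @param match_radius_bl matching radius, body lengths.
#' @param body_length_um optional body length override.
#' @return list: `triplets` (data.frame side, fore cycle, sd_um) and
#'   `mean_um` (NA when no complete triplet exists).
#' @export
footprint_alignment <- function(pattern, body_track, calibration,
                                match_radius_bl = 0.3,
                                body_length_um = NULL) {
  upp <- calibration$um_per_px
  if (is.null(body_length_um))
    body_length_um <-
      median(body_track$length_px[body_track$valid]) * upp
  r_um <- match_radius_bl * body_length_um
  v <- body_track[body_track$valid, ]
  u <- c(mean(v$ux), mean(v$uy))
  u <- u / sqrt(sum(u^2))
  pick <- function(df, t0, p0) {
    ok <- which(df$touchdown_ms >= t0 - 1e-9 & !is.na(df$x_um))
    if (!length(ok)) return(NULL)
    d2 <- (df$x_um[ok] - p0[1])^2 + (df$y_um[ok] - p0[2])^2
    k <- ok[which.min(d2)]
    if (min(d2) > r_um^2) return(NULL)
    k
  }
  trips <- do.call(rbind, lapply(c("L", "R"), function(side) {
    fore <- pattern$legs[[paste0(side, "F")]]
    mid <- pattern$legs[[paste0(side, "M")]]
    hind <- pattern$legs[[paste0(side, "H")]]
    do.call(rbind, lapply(seq_len(nrow(fore)), function(i) {
      if (is.na(fore$x_um[i])) return(NULL)
      pf <- c(fore$x_um[i], fore$y_um[i])
      j <- pick(mid, fore$touchdown_ms[i], pf)
      if (is.null(j)) return(NULL)
      pm <- c(mid$x_um[j], mid$y_um[j])
      k <- pick(hind, mid$touchdown_ms[j], pm)
      if (is.null(k)) return(NULL)
      ph <- c(hind$x_um[k], hind$y_um[k])
      proj <- c(sum(pf * u), sum(pm * u), sum(ph * u))
      data.frame(side = side, fore_cycle = i, sd_um = sd(proj))
    }))
  }))
  if (is.null(trips))
    trips <- data.frame(side = character(0), fore_cycle = integer(0),
                        sd_um = numeric(0))
  list(triplets = trips,
       mean_um = if (nrow(trips)) mean(trips$sd_um) else NA_real_)
}
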