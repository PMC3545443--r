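# From calibrated frames to a labeled step pattern: pre-entry
# background subtraction, blob detection, body tracking, leg-identity
# assignment, manual-edit application and stance-event extraction.
#
# Conventions: image origin top-left, x right (columns), y down
# (rows), 0-based pixel coordinates.  Body frame: +x anterior along
# the displacement axis, +y to the fly's left.  The fTIR camera views
# the glass from below, so for a fly walking toward +x its left side
# is at +y in image coordinates: the left-leg normal is (-uy, ux) and
# left-leg lateral coordinates come out positive.

#' Label connected components of a binary mask
#'
#' 8-connected components, computed by building the pixel adjacency
#' graph of the mask and taking its connected components.
#'
#' @param mask logical matrix.
#' @return integer matrix of the same shape; 0 = background,
#'   components numbered from 1.
#' @export
label_components <- function(mask) {
  nr <- nrow(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, ncol(mask))
  if (!length(idx)) return(lab)
  row <- (idx - 1L) %% nr + 1L
  edges <- integer(0)
  for (off in c(1L, nr, nr + 1L, nr - 1L)) {
    ok <- if (off == 1L || off == nr + 1L) row < nr
          else if (off == nr - 1L) row > 1L
          else rep(TRUE, length(idx))
    cand <- idx[ok] + off
    m <- match(cand, idx)
    hit <- !is.na(m)
    if (any(hit))
      edges <- c(edges, rbind(which(ok)[hit], m[hit]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  lab[idx] <- as.integer(igraph::components(g)$membership)
  lab
}

#' Estimate the static background from pre-entry frames
#'
#' Any fTIR signal already present before the fly enters the arena
#' (dust, scratches) is static, so the pixelwise maximum (default) or
#' median of the first `n_pre_entry` frames captures it; subtracting
#' this background from all frames removes such false-positive
#' sources.
#'
#' @param stack a `fw_frame_stack`.
#' @param n_pre_entry number of fly-free frames at the start of the
#'   video; 0 yields a zero background with a warning.
#' @param method `"max"` (conservative for static artifacts) or
#'   `"median"`.
#' @return background intensity matrix.
#' @export
estimate_background <- function(stack, n_pre_entry,
                                method = c("max", "median")) {
  method <- match.arg(method)
  if (n_pre_entry == 0) {
    warning("n_pre_entry = 0: using a zero background")
    return(matrix(0, stack$dim[1], stack$dim[2]))
  }
  if (n_pre_entry >= stack$n)
    stop_fg("n_pre_entry (%d) must be < number of frames (%d)",
            n_pre_entry, stack$n)
  pre <- stack$frames[seq_len(n_pre_entry)]
  if (method == "max") {
    bg <- pre[[1]]
    for (m in pre[-1]) bg <- pmax(bg, m)
    bg
  } else {
    a <- array(unlist(pre), dim = c(stack$dim, n_pre_entry))
    apply(a, c(1, 2), median)
  }
}

#' Background-subtract a frame (clipped at zero)
#' @param frame,background intensity matrices.
#' @return the subtracted frame.
#' @export
subtract_background <- function(frame, background) {
  pmax(frame - background, 0)
}

#' Robust noise scale of the pre-entry frames
#'
#' Raw (not normal-consistent) median absolute deviation of the sensor
#' noise, estimated from consecutive pre-entry frame differences: the
#' static scene cancels in the difference, whose absolute median is
#' sqrt(2) times the raw MAD of the per-frame noise.  Used to express
#' detection thresholds in exposure-independent units.
#'
#' @param stack a `fw_frame_stack`.
#' @param n_pre_entry number of fly-free frames.
#' @return the MAD (raw, not normal-consistent).
#' @export
estimate_noise_mad <- function(stack, n_pre_entry) {
  if (n_pre_entry < 2) stop_fg("need at least 2 pre-entry frames")
  d <- unlist(lapply(seq_len(n_pre_entry - 1L), function(i)
    abs(stack$frames[[i + 1L]] - stack$frames[[i]])))
  median(d) / sqrt(2)
}

component_stats <- function(d, lab) {
  idx <- which(lab > 0L)
  if (!length(idx))
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      area = integer(0), peak = numeric(0)))
  l <- lab[idx]
  w <- d[idx]
  nr <- nrow(d)
  y0 <- (idx - 1L) %% nr          # 0-based row
  x0 <- (idx - 1L) %/% nr         # 0-based col
  sw <- rowsum(w, l)
  data.frame(x_px = rowsum(w * x0, l) / sw,
             y_px = rowsum(w * y0, l) / sw,
             area = as.integer(rowsum(rep(1L, length(idx)), l)),
             peak = vapply(split(w, l), max, 0))
}

#' Track the fly body through a stack
#'
#' The dim body glow is segmented as the largest connected component
#' above `body_threshold` in each background-subtracted frame.  The
#' body center is its intensity-weighted centroid; body length is the
#' major-axis extent `4 * sqrt(lambda_1)` of the binary component (the
#' standard moment-based ellipse fit).  The displacement axis is the
#' unit vector of the centroid displacement over a centered window
#' (default 5 frames); where the displacement is too small to be
#' directional the axis falls back to the component's major-axis
#' orientation (sign carried over from the previous frame).
#'
#' @param stack a `fw_frame_stack`.
#' @param background from [estimate_background()].
#' @param body_threshold intensity threshold for the body glow (must
#'   be below the footprint-spot threshold).
#' @param window centered smoothing window for the displacement axis,
#'   frames.
#' @param min_area smallest component accepted as a body, px.
#' @param min_disp_px displacement below which the axis is taken from
#'   the ellipse orientation instead.
#' @return a `fw_body_track` data.frame: frame (0-based), valid,
#'   centroid (px), displacement-axis unit vector, body length (px).
#'   The per-frame body pixel sets are attached as attribute
#'   `body_px` for downstream masking.
#' @export
track_body <- function(stack, background, body_threshold, window = 5,
                       min_area = 20, min_disp_px = 0.5) {
  n <- stack$n
  cx <- cy <- len <- orient <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  body_px <- vector("list", n)
  for (f in seq_len(n)) {
    d <- subtract_background(stack$frames[[f]], background)
    mask <- d > body_threshold
    if (!any(mask)) next
    lab <- label_components(mask)
    sizes <- tabulate(lab[lab > 0L])
    big <- which.max(sizes)
    if (sizes[big] < min_area) next
    idx <- which(lab == big)
    body_px[[f]] <- idx
    nr <- nrow(d)
    y0 <- (idx - 1L) %% nr
    x0 <- (idx - 1L) %/% nr
    w <- d[idx]
    cx[f] <- sum(w * x0) / sum(w)
    cy[f] <- sum(w * y0) / sum(w)
    # binary second moments -> ellipse axes/orientation
    mx <- mean(x0); my <- mean(y0)
    cxx <- mean((x0 - mx)^2) + 1 / 12    # finite-pixel correction
    cyy <- mean((y0 - my)^2) + 1 / 12
    cxy <- mean((x0 - mx) * (y0 - my))
    tr <- cxx + cyy
    det_ <- cxx * cyy - cxy^2
    l1 <- tr / 2 + sqrt(pmax(tr^2 / 4 - det_, 0))
    len[f] <- 4 * sqrt(l1)
    orient[f] <- atan2(l1 - cxx, cxy)    # angle of major axis (y-down)
    valid[f] <- TRUE
  }
  if (mean(valid) <= 0.5)
    stop_fg("fly not found: no valid body in %d of %d frames",
            sum(!valid), n)
  k <- max(1L, floor(window / 2))
  vi <- which(valid)
  # de-noise the centroid series before differencing: the axis is a
  # direction estimate and per-frame centroid noise dominates it
  scx <- cx; scy <- cy
  if (length(vi) >= window) {
    f5 <- as.numeric(stats::filter(cx[vi], rep(1 / window, window)))
    g5 <- as.numeric(stats::filter(cy[vi], rep(1 / window, window)))
    keep <- !is.na(f5)
    scx[vi[keep]] <- f5[keep]; scy[vi[keep]] <- g5[keep]
  }
  ux <- uy <- rep(NA_real_, n)
  prev_u <- c(1, 0)
  for (f in vi) {
    a <- max(min(vi), f - k); b <- min(max(vi), f + k)
    while (!valid[a] && a < f) a <- a + 1L
    while (!valid[b] && b > f) b <- b - 1L
    dx <- scx[b] - scx[a]; dy <- scy[b] - scy[a]
    nrm <- sqrt(dx^2 + dy^2)
    if (is.finite(nrm) && nrm >= min_disp_px) {
      u <- c(dx, dy) / nrm
    } else {
      u <- c(cos(orient[f]), sin(orient[f]))
      if (sum(u * prev_u) < 0) u <- -u     # keep heading continuous
    }
    ux[f] <- u[1]; uy[f] <- u[2]
    prev_u <- u
  }
  bt <- data.frame(frame = seq_len(n) - 1L, valid = valid,
                   cx_px = cx, cy_px = cy, ux = ux, uy = uy,
                   length_px = len)
  attr(bt, "body_px") <- body_px
  class(bt) <- c("fw_body_track", "data.frame")
  bt
}

#' Detect candidate footprints in every frame
#'
#' Connected components of `(frame - background) > spot_threshold`,
#' filtered by area, with intensity-weighted centroids.  Components
#' whose centroid falls on (or within `body_clearance_px` of) the body
#' mask from [track_body()] are excluded, so the dim body glow is
#' never called a footprint.
#'
#' @param stack a `fw_frame_stack`.
#' @param background from [estimate_background()].
#' @param spot_threshold intensity threshold for footprint spots.
#' @param min_area,max_area accepted component area range, px.
#' @param body_track optional `fw_body_track` supplying the body mask.
#' @param body_clearance_px exclusion distance around body pixels.
#' @return data.frame of raw detections: frame (0-based), centroid
#'   (px, 0-based), area, peak intensity.
#' @export
detect_footprints <- function(stack, background, spot_threshold,
                              min_area = 3, max_area = 400,
                              body_track = NULL,
                              body_clearance_px = 2) {
  if (spot_threshold <= 0 || min_area <= 0)
    stop_fg("thresholds must be > 0")
  body_px <- if (!is.null(body_track)) attr(body_track, "body_px")
  nr <- stack$dim[1]
  out <- vector("list", stack$n)
  for (f in seq_len(stack$n)) {
    d <- subtract_background(stack$frames[[f]], background)
    mask <- d > spot_threshold
    if (!any(mask)) next
    st <- component_stats(d, label_components(mask))
    st <- st[st$area >= min_area & st$area <= max_area, , drop = FALSE]
    if (!nrow(st)) next
    if (!is.null(body_px) && length(body_px) >= f &&
        !is.null(body_px[[f]]) && length(body_px[[f]])) {
      idx <- body_px[[f]]
      by <- (idx - 1L) %% nr
      bx <- (idx - 1L) %/% nr
      keep <- vapply(seq_len(nrow(st)), function(i) {
        min((bx - st$x_px[i])^2 + (by - st$y_px[i])^2) >
          body_clearance_px^2
      }, TRUE)
      st <- st[keep, , drop = FALSE]
    }
    if (nrow(st)) out[[f]] <- cbind(frame = f - 1L, st)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(frame = integer(0), x_px = numeric(0),
                      y_px = numeric(0), area = integer(0),
                      peak = numeric(0))
  rownames(res) <- NULL
  res
}

body_frame_xy <- function(x_px, y_px, bt_row, norm = 1) {
  dx <- x_px - bt_row$cx_px
  dy <- y_px - bt_row$cy_px
  cbind(x = (dx * bt_row$ux + dy * bt_row$uy) / norm,
        y = (-dx * bt_row$uy + dy * bt_row$ux) / norm)
}

#' Link detections into tracks and assign leg identities
#'
#' Detections are linked across frames into contact tracks (same
#' track when within `link_radius_px` of the previous position, with
#' up to `max_link_gap` missed frames).  A persisting track keeps its
#' label.  A new track is labeled by the side of its body-frame
#' lateral coordinate (left = positive) and, within the side, by a
#' longitudinal-order rule: only labels are considered that keep all
#' ipsilateral tracks detected in the same frame in
#' anterior-to-posterior order (fore > mid > hind along the
#' displacement axis); among those, the label whose typical touchdown
#' zone (`zone_centers`, body-frame AEP longitudinal positions) is
#' nearest is picked.  Tracks that cannot be labeled consistently are
#' flagged for the edit log (attribute `"conflicts"`).
#'
#' @param detections data.frame from [detect_footprints()].
#' @param body_track a `fw_body_track` (must be valid at detection
#'   frames; detections at invalid frames are dropped with a warning).
#' @param link_radius_px linking radius between consecutive frames.
#' @param max_link_gap missed frames a track may bridge.
#' @param zone_centers named vector of typical touchdown (AEP)
#'   longitudinal positions of fore/mid/hind contacts, body lengths.
#' @return data.frame of labeled contacts: frame, x_px, y_px, area,
#'   peak, track_id, leg (NA when flagged).
#' @export
assign_leg_identities <- function(detections, body_track,
                                  link_radius_px = 5, max_link_gap = 1,
                                  zone_centers = c(F = 0.60, M = 0.25,
                                                   H = -0.18)) {
  det <- detections
  if (!nrow(det)) {
    det$track_id <- integer(0); det$leg <- character(0)
    return(det)
  }
  ok <- body_track$valid[det$frame + 1L]
  if (any(!ok)) {
    warning(sprintf("%d detections at frames without a valid body dropped",
                    sum(!ok)))
    det <- det[ok, , drop = FALSE]
  }
  med_len <- median(body_track$length_px[body_track$valid])
  det <- det[order(det$frame), , drop = FALSE]
  det$track_id <- NA_integer_
  det$leg <- NA_character_
  tracks <- data.frame(id = integer(0), leg = character(0),
                       last_frame = integer(0), x_px = numeric(0),
                       y_px = numeric(0))
  conflicts <- integer(0)
  next_id <- 1L
  seg_rank <- c(F = 3, M = 2, H = 1)
  for (f in sort(unique(det$frame))) {
    rows <- which(det$frame == f)
    bt_row <- body_track[f + 1L, ]
    active <- tracks$last_frame >= f - 1L - max_link_gap
    # greedy nearest-neighbor linking, one-to-one
    if (any(active) && length(rows)) {
      ai <- which(active)
      dmat <- outer(det$x_px[rows], tracks$x_px[ai], `-`)^2 +
              outer(det$y_px[rows], tracks$y_px[ai], `-`)^2
      repeat {
        m <- which.min(dmat)
        if (!length(m) || dmat[m] > link_radius_px^2) break
        i <- (m - 1) %% length(rows) + 1
        j <- (m - 1) %/% length(rows) + 1
        r <- rows[i]; tj <- ai[j]
        det$track_id[r] <- tracks$id[tj]
        det$leg[r] <- tracks$leg[tj]
        tracks$last_frame[tj] <- f
        tracks$x_px[tj] <- det$x_px[r]
        tracks$y_px[tj] <- det$y_px[r]
        dmat[i, ] <- Inf; dmat[, j] <- Inf
      }
    }
    # new tracks for unmatched detections
    for (r in rows[is.na(det$track_id[rows])]) {
      bf <- body_frame_xy(det$x_px[r], det$y_px[r], bt_row, med_len)
      side <- if (bf[2] > 0) "L" else "R"
      # only tracks detected in this very frame claim a label: a leg
      # that just lifted off must not block its neighbour's touchdown
      act <- tracks[which(tracks$last_frame == f &
                            !is.na(tracks$leg) &
                            leg_side(tracks$leg) == side), ,
                    drop = FALSE]
      cands <- setdiff(paste0(side, c("F", "M", "H")), act$leg)
      if (nrow(act)) {
        act_bf <- body_frame_xy(act$x_px, act$y_px, bt_row, med_len)
        consistent <- vapply(cands, function(l) {
          rl <- seg_rank[leg_segment(l)]
          all((seg_rank[leg_segment(act$leg)] < rl) ==
                (act_bf[, 1] < bf[1]))
        }, TRUE)
        cands <- cands[consistent]
      }
      if (!length(cands)) {
        conflicts <- c(conflicts, r)
        det$track_id[r] <- next_id
        tracks <- rbind(tracks, data.frame(
          id = next_id, leg = NA_character_, last_frame = f,
          x_px = det$x_px[r], y_px = det$y_px[r]))
        next_id <- next_id + 1L
        next
      }
      leg <- cands[which.min(abs(zone_centers[leg_segment(cands)] -
                                   bf[1]))]
      det$track_id[r] <- next_id
      det$leg[r] <- leg
      tracks <- rbind(tracks, data.frame(
        id = next_id, leg = leg, last_frame = f,
        x_px = det$x_px[r], y_px = det$y_px[r]))
      next_id <- next_id + 1L
    }
    n_active <- sum(tracks$last_frame == f)
    if (n_active > 6L)
      stop_fg("%d simultaneous contact tracks at frame %d (max 6)",
              n_active, f)
  }
  attr(det, "conflicts") <- conflicts
  det
}

#' Read a manual-edit log from JSON
#'
#' The edit log is the declarative replacement for on-screen editing:
#' an ordered array of records
#' `{"frame": int, "action": "add"|"remove"|"relabel", "leg": str,
#'   "to": str (relabel), "x_px": num, "y_px": num (add)}`.
#'
#' @param path JSON file.
#' @return data.frame of edit records.
#' @export
read_edit_log <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(x)) x else as.data.frame(x)
}

#' Apply a manual-edit log to labeled contacts
#'
#' Records are applied in order: `add` creates a single-frame contact
#' for a leg at a position; `remove` deletes a leg's contact at a
#' frame; `relabel` renames it.  Invalid references or relabels that
#' would give one leg two contacts in one frame raise an error citing
#' the record index.
#'
#' @param contacts labeled contacts from [assign_leg_identities()].
#' @param edits data.frame of edit records (see [read_edit_log()]);
#'   NULL or empty is the identity.
#' @return edited contacts.
#' @export
apply_edits <- function(contacts, edits) {
  if (is.null(edits) || !nrow(edits)) return(contacts)
  for (i in seq_len(nrow(edits))) {
    e <- edits[i, ]
    if (!e$action %in% c("add", "remove", "relabel"))
      stop_fg("edit %d: unknown action '%s'", i, e$action)
    if (!e$leg %in% LEG_LABELS)
      stop_fg("edit %d: unknown leg '%s'", i, e$leg)
    at <- which(contacts$frame == e$frame &
                  !is.na(contacts$leg) & contacts$leg == e$leg)
    if (e$action == "add") {
      if (length(at))
        stop_fg("edit %d: %s already has a contact at frame %d",
                i, e$leg, e$frame)
      row <- contacts[0, ]
      row[1, c("frame", "x_px", "y_px")] <-
        list(as.integer(e$frame), e$x_px, e$y_px)
      row$leg <- e$leg
      contacts <- rbind(contacts, row)
    } else if (e$action == "remove") {
      if (!length(at))
        stop_fg("edit %d: no %s contact at frame %d to remove",
                i, e$leg, e$frame)
      contacts <- contacts[-at, , drop = FALSE]
    } else {
      if (!length(at))
        stop_fg("edit %d: no %s contact at frame %d to relabel",
                i, e$leg, e$frame)
      if (!e$to %in% LEG_LABELS)
        stop_fg("edit %d: unknown target leg '%s'", i, e$to)
      clash <- which(contacts$frame == e$frame &
                       !is.na(contacts$leg) & contacts$leg == e$to)
      if (length(clash))
        stop_fg("edit %d: relabel %s->%s would give %s two contacts at frame %d",
                i, e$leg, e$to, e$to, e$frame)
      contacts$leg[at] <- e$to
    }
  }
  contacts <- contacts[order(contacts$frame), , drop = FALSE]
  rownames(contacts) <- NULL
  contacts
}

#' Extract a step pattern from labeled contacts
#'
#' Per leg, contiguous runs of contact frames become stance intervals
#' (half-open `[touchdown, liftoff)`; the touchdown frame owns the
#' AEP).  Gaps of up to `max_gap_frames` missed frames are bridged;
#' runs shorter than `min_stance_frames` are dropped.  Stances that
#' touch the first or last contact frame of the video are flagged as
#' edge-truncated so duration-based parameters skip them.
#'
#' @param contacts labeled contacts.
#' @param calibration a [calibration()] object.
#' @param min_stance_frames minimum accepted stance length, frames.
#' @param max_gap_frames largest bridged dropout, frames.
#' @param n_frames total frames in the video (for edge flagging).
#' @return a frame-quantized `fw_step_pattern` with world footprint
#'   positions in um.
#' @export
extract_step_pattern <- function(contacts, calibration,
                                 min_stance_frames = 2,
                                 max_gap_frames = 2, n_frames = NULL) {
  dt <- 1000 / calibration$fps
  upp <- calibration$um_per_px
  lo_frame <- if (!is.null(contacts$frame) && nrow(contacts))
    min(contacts$frame) else 0L
  hi_frame <- if (!is.null(contacts$frame) && nrow(contacts))
    max(contacts$frame) else 0L
  legs <- lapply(LEG_LABELS, function(l) {
    rows <- contacts[!is.na(contacts$leg) & contacts$leg == l, ,
                     drop = FALSE]
    if (!nrow(rows)) return(empty_interval_df())
    rows <- rows[order(rows$frame), ]
    gap <- c(Inf, diff(rows$frame))
    run <- cumsum(gap > max_gap_frames + 1L)
    out <- do.call(rbind, lapply(split(rows, run), function(rr) {
      td <- min(rr$frame); lo <- max(rr$frame) + 1L
      if (lo - td < min_stance_frames) return(NULL)
      data.frame(touchdown_ms = td * dt, liftoff_ms = lo * dt,
                 x_um = mean(rr$x_px) * upp, y_um = mean(rr$y_px) * upp,
                 touchdown_frame = as.integer(td),
                 liftoff_frame = as.integer(lo),
                 edge_touchdown = td <= lo_frame,
                 edge_liftoff = (lo >= hi_frame + 1L) ||
                   (!is.null(n_frames) && lo >= n_frames))
    }))
    if (is.null(out)) empty_interval_df() else out
  })
  names(legs) <- LEG_LABELS
  step_pattern(legs, fps = calibration$fps)
}
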