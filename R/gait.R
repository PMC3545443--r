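# Per-frame leg-combination coding, tripod/tetrapod classification,
# gait map, gait index and combination frequency table.
#
# Combination codes are 6-character strings over {0,1} in leg order
# LF LM LH RF RM RH; "1" means the footprint is present (stance).

#' Canonical tripod combination codes
#' @format character vector of 2 codes.
#' @export
TRIPOD_CODES <- c("101010", "010101")

#' Canonical tetrapod combination codes
#'
#' The six codes arise from the two-leg swing pairs of the right- and
#' left-handed tetrapod cycles (contralateral, one segment apart):
#' right-handed (RH,LM) -> (RM,LF) -> (RF,LH) and its mirror.
#' @format character vector of 6 codes.
#' @export
TETRAPOD_CODES <- c("101110", "011101", "110011",
                    "110101", "101011", "011110")

#' Per-frame combination codes of a step pattern
#'
#' Digit = 1 iff the leg has a stance interval covering the frame
#' timestamp (half-open `[touchdown, liftoff)`).
#'
#' @param pattern a `fw_step_pattern`.
#' @param n_frames number of frames to code.
#' @param fps frame rate; defaults to the pattern's own.
#' @return character vector of `n_frames` codes.
#' @export
frame_codes <- function(pattern, n_frames, fps = pattern$fps) {
  if (is.na(fps)) stop_fg("'fps' is required for a continuous pattern")
  t_f <- (seq_len(n_frames) - 1) * 1000 / fps
  digits <- vapply(LEG_LABELS, function(l) {
    df <- pattern$legs[[l]]
    if (!nrow(df)) return(rep(0L, n_frames))
    on <- vapply(t_f, function(t)
      any(df$touchdown_ms <= t + 1e-9 & t < df$liftoff_ms - 1e-9),
      TRUE)
    as.integer(on)
  }, integer(n_frames))
  if (n_frames == 1L) digits <- matrix(digits, nrow = 1)
  apply(digits, 1, paste, collapse = "")
}

#' Classify combination codes
#'
#' Tripod for the two canonical alternating-triplet codes, tetrapod
#' for the six canonical two-swing-pair codes, noncanonical otherwise.
#'
#' @param code character vector of 6-digit codes.
#' @return character vector over
#'   `{"tripod", "tetrapod", "noncanonical"}`.
#' @export
classify_code <- function(code) {
  if (!all(grepl("^[01]{6}$", code)))
    stop_fg("combination codes must be 6 characters over {0,1}")
  ifelse(code %in% TRIPOD_CODES, "tripod",
         ifelse(code %in% TETRAPOD_CODES, "tetrapod", "noncanonical"))
}

#' Per-frame gait map
#'
#' Codes, classes and stance counts per frame, with pentapod (exactly
#' one leg swinging) and all-stance flags.  Frames before the first
#' and after the last tracked contact are marked out of range and are
#' excluded from all indexes.
#'
#' @param pattern a `fw_step_pattern`.
#' @param n_frames number of frames.
#' @param fps frame rate; defaults to the pattern's own.
#' @return a `fw_gait_map` data.frame: frame, t_ms, code, class,
#'   stance_count, pentapod, all_stance, in_range.
#' @export
gait_map <- function(pattern, n_frames, fps = pattern$fps) {
  if (is.na(fps)) stop_fg("'fps' is required for a continuous pattern")
  code <- frame_codes(pattern, n_frames, fps)
  cnt <- nchar(gsub("0", "", code))
  ev <- pattern_events(pattern)
  t_f <- (seq_len(n_frames) - 1) * 1000 / fps
  in_range <- if (nrow(ev))
    t_f >= min(ev$touchdown_ms) - 1e-9 & t_f < max(ev$liftoff_ms) - 1e-9
  else rep(FALSE, n_frames)
  gm <- data.frame(frame = seq_len(n_frames) - 1L, t_ms = t_f,
                   code = code, class = classify_code(code),
                   stance_count = cnt, pentapod = cnt == 5L,
                   all_stance = cnt == 6L, in_range = in_range)
  class(gm) <- c("fw_gait_map", "data.frame")
  gm
}

#' Sliding gait index and average gait index
#'
#' Each in-range frame scores +1 (tripod), -1 (tetrapod) or 0
#' (noncanonical).  The sliding index is the mean score over a
#' trailing window of `window` frames (the first `window - 1` frames
#' use the partial window and are flagged); the average gait index is
#' the mean of the raw per-frame scores.
#'
#' @param gait_map a `fw_gait_map`.
#' @param window trailing window length, frames (the classic choice
#'   is 8).
#' @return list: `series` (data.frame frame, score, gait_index,
#'   partial) over in-range frames, and `average`.
#' @export
gait_index <- function(gait_map, window = 8) {
  if (window < 1) stop_fg("'window' must be >= 1")
  gm <- gait_map[gait_map$in_range, , drop = FALSE]
  if (!nrow(gm))
    return(list(series = data.frame(frame = integer(0),
                                    score = numeric(0),
                                    gait_index = numeric(0),
                                    partial = logical(0)),
                average = NA_real_))
  score <- c(tripod = 1, tetrapod = -1, noncanonical = 0)[gm$class]
  n <- length(score)
  cs <- cumsum(score)
  w <- pmin(seq_len(n), window)
  idx <- (cs - c(rep(0, min(window, n)),
                 head(cs, max(0, n - window)))) / w
  list(series = data.frame(frame = gm$frame, score = unname(score),
                           gait_index = idx,
                           partial = seq_len(n) < window),
       average = mean(score))
}

#' Gait summary: indexes and combination frequency table
#'
#' Tripod and tetrapod indexes are the percentage of in-range frames
#' whose combination is canonical tripod / tetrapod.  The frequency
#' table lists every observed code with its percentage (sorted by
#' frequency), plus aggregate percentages for the tripod, tetrapod and
#' pentapod groups.
#'
#' @param gait_map a `fw_gait_map`.
#' @return list: `tripod_index`, `tetrapod_index`, `pentapod_pct`,
#'   `n_frames`, `table` (data.frame code, class, pentapod, percent).
#' @export
gait_summary <- function(gait_map) {
  gm <- gait_map[gait_map$in_range, , drop = FALSE]
  if (!nrow(gm)) stop_fg("gait map has no in-range frames")
  n <- nrow(gm)
  tab <- sort(table(gm$code), decreasing = TRUE)
  tbl <- data.frame(code = names(tab),
                    class = classify_code(names(tab)),
                    pentapod = nchar(gsub("0", "", names(tab))) == 5L,
                    percent = 100 * as.numeric(tab) / n)
  list(tripod_index = 100 * mean(gm$class == "tripod"),
       tetrapod_index = 100 * mean(gm$class == "tetrapod"),
       pentapod_pct = 100 * mean(gm$pentapod),
       n_frames = n, table = tbl)
}
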