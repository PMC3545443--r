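# Per-leg stance-interval container shared by the generator and the
# tracker.  Times are in ms; intervals are half-open
# [touchdown, liftoff).  World footprint positions (um) are NA for
# purely temporal patterns.  Interval rows carry edge flags marking
# stances truncated by the start or end of the record, so that
# duration-based parameters can skip incomplete cycles.

#' Construct a step pattern
#'
#' @param legs named list over the six labels in [LEG_LABELS]; each
#'   element a data.frame with columns `touchdown_ms`, `liftoff_ms`
#'   and optionally `x_um`, `y_um`, `touchdown_frame`,
#'   `liftoff_frame`, `edge_touchdown`, `edge_liftoff`.
#' @param fps frames per second if the pattern is frame-quantized,
#'   `NA` for a continuous-time pattern.
#' @return a `fw_step_pattern` object.
#' @export
step_pattern <- function(legs, fps = NA_real_) {
  if (!all(LEG_LABELS %in% names(legs)))
    stop_fg("'legs' must contain entries for all of: %s",
            paste(LEG_LABELS, collapse = ", "))
  legs <- lapply(legs[LEG_LABELS], function(df) {
    df <- as.data.frame(df)
    tmpl <- empty_interval_df()
    for (col in names(tmpl)) {
      if (is.null(df[[col]]))
        df[[col]] <- rep(tmpl[[col]][NA_integer_], length.out = nrow(df))
      mode_fn <- switch(class(tmpl[[col]]), integer = as.integer,
                        numeric = as.numeric, logical = as.logical)
      df[[col]] <- mode_fn(df[[col]])
    }
    df$edge_touchdown[is.na(df$edge_touchdown)] <- FALSE
    df$edge_liftoff[is.na(df$edge_liftoff)] <- FALSE
    df <- df[order(df$touchdown_ms), names(tmpl)]
    if (nrow(df)) {
      if (any(df$liftoff_ms <= df$touchdown_ms))
        stop_fg("liftoff must be after touchdown")
      if (nrow(df) > 1L &&
          any(df$touchdown_ms[-1L] < df$liftoff_ms[-nrow(df)]))
        stop_fg("stance intervals of one leg must be disjoint")
    }
    rownames(df) <- NULL
    df
  })
  structure(list(legs = legs, fps = fps), class = "fw_step_pattern")
}

#' @export
print.fw_step_pattern <- function(x, ...) {
  n <- vapply(x$legs, nrow, 0L)
  cat(sprintf("<step pattern> %s; stances per leg: %s\n",
              if (is.na(x$fps)) "continuous time"
              else sprintf("%g fps", x$fps),
              paste(sprintf("%s=%d", names(n), n), collapse = " ")))
  invisible(x)
}

#' All stance events of a pattern as one data.frame
#' @param pattern a `fw_step_pattern`.
#' @return data.frame with a `leg` column plus the interval columns.
#' @export
pattern_events <- function(pattern) {
  out <- do.call(rbind, lapply(LEG_LABELS, function(l) {
    df <- pattern$legs[[l]]
    if (!nrow(df)) return(NULL)
    cbind(leg = l, cycle = seq_len(nrow(df)), df)
  }))
  if (is.null(out)) cbind(leg = character(0), cycle = integer(0),
                          empty_interval_df())
  else out
}

#' Quantize a continuous-time pattern to a frame grid
#'
#' With `rule = "nearest"`, touchdown and liftoff times are snapped to
#' the nearest frame timestamp of an `fps` grid (frame `i` at
#' `i * 1000 / fps` ms).  With `rule = "ceiling"`, times move to the
#' first frame timestamp at or after them, which reproduces what a
#' renderer or camera sampling the half-open stance interval
#' `[onset, offset)` actually records: the first frame showing the
#' footprint and the first frame without it.  Degenerate intervals
#' created by the rounding are dropped.
#'
#' @param pattern a `fw_step_pattern`.
#' @param fps target acquisition rate.
#' @param rule `"nearest"` or `"ceiling"`.
#' @return a frame-quantized `fw_step_pattern`.
#' @export
quantize_step_pattern <- function(pattern, fps,
                                  rule = c("nearest", "ceiling")) {
  check_num(fps, "fps", positive = TRUE)
  rule <- match.arg(rule)
  dt <- 1000 / fps
  snap <- function(t) {
    if (rule == "nearest") round(t / dt) else ceiling(t / dt - 1e-9)
  }
  legs <- lapply(pattern$legs, function(df) {
    df$touchdown_frame <- as.integer(snap(df$touchdown_ms))
    df$liftoff_frame <- as.integer(snap(df$liftoff_ms))
    df$touchdown_ms <- df$touchdown_frame * dt
    df$liftoff_ms <- df$liftoff_frame * dt
    df[df$liftoff_ms > df$touchdown_ms, , drop = FALSE]
  })
  step_pattern(legs, fps = fps)
}
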