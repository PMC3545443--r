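# Circular statistics for inter-leg phases and the ordinary least
# squares fit used by the parameter plots.  Phases live on [0, 1)
# (fraction of a cycle) and are converted to radians only internally.

#' Circular mean and resultant length of phases
#'
#' Phases are mapped to angles `2 * pi * phase`; `r` is the length of
#' the mean unit vector and the mean phase its direction mapped back
#' to `[0, 1)`.
#'
#' @param phases numeric vector of phases in `[0, 1)`.
#' @return list: `mean_phase`, `r`, `n` (class `fw_circular`).
#' @export
circular_mean <- function(phases) {
  if (!length(phases)) stop_fg("'phases' must be non-empty")
  th <- 2 * pi * phases
  C <- mean(cos(th)); S <- mean(sin(th))
  r <- sqrt(C^2 + S^2)
  mu <- (atan2(S, C) / (2 * pi)) %% 1
  if (1 - mu < 1e-12) mu <- 0              # wrap-around guard
  structure(list(mean_phase = mu, r = r, n = length(phases)),
            class = "fw_circular")
}

#' Rayleigh test p-value for circular uniformity
#'
#' Standard series approximation: with `Z = n * r^2`,
#' `p = exp(-Z) * (1 + (2Z - Z^2) / (4n)
#'                   - (24Z - 132Z^2 + 76Z^3 - 9Z^4) / (288n^2))`,
#' clipped to (0, 1].
#'
#' @param n sample size (>= 2).
#' @param r mean resultant length in `[0, 1]`.
#' @return the p-value.
#' @export
rayleigh_p <- function(n, r) {
  if (n < 2) stop_fg("Rayleigh test needs n >= 2")
  if (r < 0 || r > 1) stop_fg("'r' must be in [0, 1]")
  Z <- n * r^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) /
                    (288 * n^2))
  min(max(p, .Machine$double.xmin), 1)
}

#' Circular summary of phases with Rayleigh p
#'
#' @param phases numeric vector of phases in `[0, 1)`.
#' @return list: `mean_phase`, `r`, `n`, `p` (class `fw_circular`).
#' @export
circular_summary <- function(phases) {
  cm <- circular_mean(phases)
  cm$p <- if (cm$n >= 2) rayleigh_p(cm$n, cm$r) else NA_real_
  cm
}

#' @export
print.fw_circular <- function(x, ...) {
  cat(sprintf("<circular> mean phase %.4f, r = %.4f, n = %d%s\n",
              x$mean_phase, x$r, x$n,
              if (!is.null(x$p) && !is.na(x$p))
                sprintf(", Rayleigh p = %.3g", x$p) else ""))
  invisible(x)
}

#' Ordinary least squares fit with Pearson correlation
#'
#' @param x,y numeric vectors of equal length (n >= 2, `x` not
#'   constant).
#' @return list: `slope`, `intercept`, `r`, `n` (class
#'   `fw_linear_fit`).
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop_fg("'x' and 'y' must have equal length >= 2")
  if (sd(x) == 0) stop_fg("'x' is constant; no regression line")
  fit <- lm(y ~ x)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = cor(x, y), n = length(x)),
            class = "fw_linear_fit")
}

#' @export
print.fw_linear_fit <- function(x, ...) {
  cat(sprintf("<fit> y = %.4g x + %.4g, R = %.4f, n = %d\n",
              x$slope, x$intercept, x$r, x$n))
  invisible(x)
}

#' The 7 standard leg pairings for phase reporting
#'
#' Contralateral same-segment pairs and adjacent ipsilateral pairs:
#' LH:RH, LM:RM, LF:RF, LH:LM, LM:LF, RH:RM, RM:RF.
#' @format 7 x 2 character matrix (reference leg, compared leg).
#' @export
PHASE_PAIRINGS <- matrix(c("LH", "RH", "LM", "RM", "LF", "RF",
                           "LH", "LM", "LM", "LF", "RH", "RM",
                           "RM", "RF"),
                         ncol = 2, byrow = TRUE,
                         dimnames = list(NULL, c("x", "y")))
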