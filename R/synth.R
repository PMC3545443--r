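# Synthetic walking-fly generator: parametric hexapod step patterns,
# straight-walk kinematics with ground truth, and an fTIR-style
# renderer.  Everything is generated in continuous time and only
# quantized when rendered, so analysis-level tests can consume the
# exact pattern directly.

#' Critical angle of total internal reflection
#'
#' The fTIR arena works because light inside the glass plate hits the
#' glass-air interface above the critical angle
#' `asin(n_rare / n_dense)` and is totally reflected until a tarsus
#' frustrates the reflection.  For borosilicate glass against air
#' (n = 1.471 vs 1.000) the angle is approximately 43 degrees.
#'
#' @param n_dense refractive index of the dense medium (the glass).
#' @param n_rare refractive index of the rare medium (air).
#' @return the critical angle in degrees.
#' @export
critical_angle <- function(n_dense, n_rare) {
  check_num(n_dense, "n_dense", positive = TRUE)
  check_num(n_rare, "n_rare", positive = TRUE)
  if (n_rare >= n_dense)
    stop_fg("no total internal reflection from rarer to denser medium")
  asin(n_rare / n_dense) * 180 / pi
}

#' Gait specification for the synthetic walker
#'
#' @param gait one of `"tripod"`, `"tetrapod_right"`,
#'   `"tetrapod_left"`, `"wave"`.
#' @param period_ms step period, ms per leg cycle.
#' @param duty_factor fraction of the period spent in stance, in
#'   (0, 1].  Defaults: 0.5 (tripod), 2/3 (tetrapod), 5/6 (wave, one
#'   leg swinging at a time).
#' @param metachronal_lag_ms optional override of the ipsilateral
#'   hind-to-fore swing-onset lag.  When given, the pattern is built
#'   as a metachronal wave: per side, hindleg first, midleg at half
#'   the lag, foreleg at the full lag, with the right side offset by
#'   half a period.
#' @param n_cycles number of full cycles to generate.
#' @param fps frame rate the rendered video will use.
#' @param speed_mm_s average body speed.
#' @param speed_mod_amplitude relative amplitude of the within-cycle
#'   speed modulation (0 = constant speed).  The modulation period is
#'   half the step period with peaks at tripod mid-stance, emulating
#'   the speed maxima real flies show halfway through stance.
#' @return a `fw_gait_spec` object.
#' @export
gait_spec <- function(gait = c("tripod", "tetrapod_right",
                               "tetrapod_left", "wave"),
                      period_ms = 100, duty_factor = NULL,
                      metachronal_lag_ms = NULL, n_cycles = 10,
                      fps = 250, speed_mm_s = 20,
                      speed_mod_amplitude = 0) {
  gait <- match.arg(gait)
  if (is.null(duty_factor))
    duty_factor <- switch(gait, tripod = 0.5, wave = 5 / 6, 2 / 3)
  check_num(period_ms, "period_ms", positive = TRUE)
  check_num(duty_factor, "duty_factor", positive = TRUE)
  if (duty_factor > 1) stop_fg("'duty_factor' must be in (0, 1]")
  check_num(n_cycles, "n_cycles", positive = TRUE)
  if (n_cycles < 1) stop_fg("'n_cycles' must be >= 1")
  check_num(fps, "fps", positive = TRUE)
  check_num(speed_mm_s, "speed_mm_s", nonneg = TRUE)
  check_num(speed_mod_amplitude, "speed_mod_amplitude", nonneg = TRUE)
  if (speed_mod_amplitude >= 1)
    stop_fg("'speed_mod_amplitude' must be < 1 (speed stays positive)")
  if (!is.null(metachronal_lag_ms))
    check_num(metachronal_lag_ms, "metachronal_lag_ms", positive = TRUE)
  structure(list(gait = gait, period_ms = period_ms,
                 duty_factor = duty_factor,
                 metachronal_lag_ms = metachronal_lag_ms,
                 n_cycles = as.integer(n_cycles), fps = fps,
                 speed_mm_s = speed_mm_s,
                 speed_mod_amplitude = speed_mod_amplitude),
            class = "fw_gait_spec")
}

#' Hexapod body plan for the synthetic walker
#'
#' Leg geometry in body-frame coordinates (+x anterior, +y to the
#' fly's left, normalized by body length; body center at the origin).
#' `aep` gives each leg's touchdown position (anterior extreme
#' position); `pep_x` the longitudinal coordinate of the neutral
#' liftoff position (posterior extreme position).  For straight
#' walking the lateral PEP coordinate equals the AEP one, since the
#' footprint does not move in the world while the body advances.
#' Defaults approximate an adult Drosophila (body length 2.5 mm).
#'
#' @param body_length_um body length in micrometers.
#' @param aep 6 x 2 matrix of touchdown positions, rows in
#'   [LEG_LABELS] order, units of body length.
#' @param pep_x length-6 vector of neutral liftoff longitudinal
#'   coordinates; must be anterior-smaller than `aep[, 1]`.
#' @return a `fw_body_plan` object.
#' @export
body_plan <- function(body_length_um = 2500,
                      aep = NULL, pep_x = NULL) {
  check_num(body_length_um, "body_length_um", positive = TRUE)
  if (is.null(aep))
    aep <- rbind(LF = c(0.62, 0.32), LM = c(0.25, 0.52),
                 LH = c(-0.18, 0.36), RF = c(0.62, -0.32),
                 RM = c(0.25, -0.52), RH = c(-0.18, -0.36))
  if (is.null(pep_x))
    pep_x <- c(LF = 0.17, LM = -0.20, LH = -0.63,
               RF = 0.17, RM = -0.20, RH = -0.63)
  aep <- as.matrix(aep)
  if (!all(dim(aep) == c(6, 2)) || length(pep_x) != 6)
    stop_fg("'aep' must be 6 x 2 and 'pep_x' length 6")
  rownames(aep) <- LEG_LABELS
  names(pep_x) <- LEG_LABELS
  if (any(aep[, 1] <= pep_x))
    stop_fg("every AEP must be anterior to (greater x than) its PEP")
  structure(list(body_length_um = body_length_um, aep = aep,
                 pep_x = pep_x), class = "fw_body_plan")
}

# touchdown phases (fraction of period) per leg for each gait; the
# touchdown of a leg with swing-onset phase phi is at phi + 1 - duty.
gait_touchdown_phases <- function(spec) {
  d <- spec$duty_factor
  if (!is.null(spec$metachronal_lag_ms)) {
    lag <- spec$metachronal_lag_ms / spec$period_ms
    psi <- c(LH = 0, LM = lag / 2, LF = lag,
             RH = 0.5, RM = 0.5 + lag / 2, RF = 0.5 + lag)
    return(psi[LEG_LABELS] %% 1)
  }
  psi <- switch(spec$gait,
    tripod = c(LF = 0, LH = 0, RM = 0, RF = 0.5, RH = 0.5, LM = 0.5),
    tetrapod_right = {
      if (d < 2 / 3)
        stop_fg(paste("tetrapod gait with duty factor < 2/3 forces more",
                      "than two legs to swing simultaneously"))
      # swing-pair cycle (RH,LM) -> (RM,LF) -> (RF,LH)
      phi <- c(RH = 0, LM = 0, RM = 1 / 3, LF = 1 / 3,
               RF = 2 / 3, LH = 2 / 3)
      phi + 1 - d
    },
    tetrapod_left = {
      if (d < 2 / 3)
        stop_fg(paste("tetrapod gait with duty factor < 2/3 forces more",
                      "than two legs to swing simultaneously"))
      phi <- c(LH = 0, RM = 0, LM = 1 / 3, RF = 1 / 3,
               LF = 2 / 3, RH = 2 / 3)
      phi + 1 - d
    },
    wave = {
      # single-leg swings, back-to-front on each side
      phi <- c(LH = 0, LM = 1 / 6, LF = 2 / 6,
               RH = 3 / 6, RM = 4 / 6, RF = 5 / 6)
      phi + 1 - d
    })
  psi[LEG_LABELS] %% 1
}

#' Generate a continuous-time step pattern for a gait
#'
#' Stance onsets and offsets are exact reals (no frame quantization).
#' Stances truncated by the start or end of the record carry edge
#' flags.  Canonical timings: tripod legs split into `{LF, LH, RM}`
#' and `{RF, RH, LM}` in antiphase (contralateral same-segment phase
#' exactly 0.5); tetrapod swing pairs cycle at period/3 offsets,
#' right-handed `(RH,LM) -> (RM,LF) -> (RF,LH)` or the left-right
#' mirror; wave gait swings one leg at a time, back to front on each
#' side.
#'
#' @param spec a [gait_spec()].
#' @return a continuous-time `fw_step_pattern` covering
#'   `n_cycles * period_ms` ms.
#' @export
make_step_pattern <- function(spec) {
  if (!inherits(spec, "fw_gait_spec"))
    stop_fg("'spec' must be a gait_spec() object")
  P <- spec$period_ms
  d <- spec$duty_factor
  T_ms <- spec$n_cycles * P
  psi <- gait_touchdown_phases(spec)
  legs <- lapply(LEG_LABELS, function(leg) {
    td <- (seq(-1, spec$n_cycles) + psi[[leg]]) * P
    lo <- td + d * P
    keep <- lo > 0 & td < T_ms
    td <- td[keep]; lo <- lo[keep]
    edge_td <- td < 0
    edge_lo <- lo > T_ms
    data.frame(touchdown_ms = pmax(td, 0), liftoff_ms = pmin(lo, T_ms),
               edge_touchdown = edge_td, edge_liftoff = edge_lo)
  })
  names(legs) <- LEG_LABELS
  pat <- step_pattern(legs)
  attr(pat, "duration_ms") <- T_ms
  pat
}

#' Simulate a straight walk and return ground truth
#'
#' The body advances along +x at the specified average speed
#' (optionally modulated within the cycle); each leg touches down at
#' its AEP (body-frame position de-normalized by body length, rotated
#' to world and added to the instantaneous body position) and the
#' footprint stays fixed in the world for the whole stance, so in the
#' body frame it sweeps backward from the AEP to the PEP.
#'
#' Optional per-step Gaussian jitter supports footprint-clustering
#' tests: `aep_jitter_bl` perturbs each touchdown position in x and y;
#' `pep_jitter_bl` perturbs the liftoff *time* so that the liftoff
#' position acquires extra spread along the travel axis (a stationary
#' footprint cannot be moved at liftoff, only released earlier or
#' later).
#'
#' @param spec a [gait_spec()].
#' @param plan a [body_plan()].
#' @param seed integer seed for the jitter RNG.
#' @param aep_jitter_bl per-axis SD of touchdown-position jitter, in
#'   body lengths.
#' @param pep_jitter_bl additional SD of liftoff-position spread along
#'   the travel axis, in body lengths (requires speed > 0).
#' @return a `fw_ground_truth` object: the gait spec, body plan,
#'   continuous-time pattern with world footprint positions, and the
#'   trajectory parameters (start at the origin, heading +x).
#' @export
simulate_walk <- function(spec, plan, seed = NULL,
                          aep_jitter_bl = 0, pep_jitter_bl = 0) {
  if (!inherits(plan, "fw_body_plan"))
    stop_fg("'plan' must be a body_plan() object")
  check_num(aep_jitter_bl, "aep_jitter_bl", nonneg = TRUE)
  check_num(pep_jitter_bl, "pep_jitter_bl", nonneg = TRUE)
  pat <- make_step_pattern(spec)
  BL <- plan$body_length_um
  v <- spec$speed_mm_s                    # um/ms == mm/s
  P <- spec$period_ms
  stance_ms <- spec$duty_factor * P
  sweep_bl <- v * stance_ms / BL
  room_bl <- plan$aep[, 1] - plan$pep_x
  if (any(sweep_bl > 1.5 * room_bl))
    stop_fg(paste("kinematically impossible: stance sweep of %.2f body",
                  "lengths exceeds the leg workspace (max %.2f); lower",
                  "speed, duty factor or period"),
            sweep_bl, 1.5 * min(room_bl))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  traj <- list(speed_um_ms = v, mod = spec$speed_mod_amplitude,
               mod_period_ms = P / 2,
               mod_peak_ms = spec$duty_factor * P / 2,
               start_x_um = 0, start_y_um = 0, heading_rad = 0)
  legs <- lapply(LEG_LABELS, function(leg) {
    df <- pat$legs[[leg]]
    if (!nrow(df)) return(df)
    n <- nrow(df)
    jx <- if (aep_jitter_bl > 0) rnorm(n, 0, aep_jitter_bl * BL) else 0
    jy <- if (aep_jitter_bl > 0) rnorm(n, 0, aep_jitter_bl * BL) else 0
    if (pep_jitter_bl > 0 && v > 0) {
      jt <- rnorm(n, 0, pep_jitter_bl * BL / v)
      lo <- df$liftoff_ms + jt
      lo <- pmax(lo, df$touchdown_ms + 0.05 * stance_ms)
      if (n > 1L) lo[-n] <- pmin(lo[-n], df$touchdown_ms[-1L] - 1e-9)
      df$liftoff_ms <- lo
    }
    bp_td <- body_xy_at(traj, df$touchdown_ms)
    df$x_um <- bp_td[, 1] + plan$aep[leg, 1] * BL + jx
    df$y_um <- bp_td[, 2] + plan$aep[leg, 2] * BL + jy
    df
  })
  names(legs) <- LEG_LABELS
  pat2 <- step_pattern(legs)
  attr(pat2, "duration_ms") <- attr(pat, "duration_ms")
  structure(list(spec = spec, plan = plan, pattern = pat2,
                 traj = traj, seed = seed,
                 aep_jitter_bl = aep_jitter_bl,
                 pep_jitter_bl = pep_jitter_bl,
                 duration_ms = attr(pat, "duration_ms"),
                 time_offset_ms = 0, origin_um = c(0, 0)),
            class = "fw_ground_truth")
}

#' Body position at given times
#'
#' @param traj trajectory component of a ground-truth object (or the
#'   object itself).
#' @param t_ms times in ms (walk time; the pre-entry offset of a
#'   rendered video is handled by the caller via `time_offset_ms`).
#' @return n x 2 matrix of world positions, um.
#' @export
body_xy_at <- function(traj, t_ms) {
  if (inherits(traj, "fw_ground_truth")) traj <- traj$traj
  v <- traj$speed_um_ms
  x <- v * t_ms
  if (traj$mod > 0) {
    w <- 2 * pi / traj$mod_period_ms
    x <- x + v * traj$mod / w *
      (sin(w * (t_ms - traj$mod_peak_ms)) - sin(-w * traj$mod_peak_ms))
  }
  cbind(x_um = traj$start_x_um + x,
        y_um = rep(traj$start_y_um, length(t_ms)))
}

#' True per-step AEP/PEP positions in the body frame
#'
#' Derived from the ground truth: the AEP is the footprint position
#' relative to the body at touchdown, the PEP the same footprint
#' relative to the body at liftoff; both normalized by body length.
#'
#' @param truth a `fw_ground_truth`.
#' @param quantized use the as-rendered (frame-quantized) onsets of a
#'   rendered truth rather than the continuous ones; this is the right
#'   reference when comparing against quantities recovered from the
#'   video, which cannot carry sub-frame timing.
#' @return data.frame: leg, cycle, touchdown/liftoff ms, world
#'   footprint position (um) and AEP/PEP body-frame coordinates
#'   (body lengths).
#' @export
truth_footprints <- function(truth, quantized = FALSE) {
  pat <- if (quantized && !is.null(truth$pattern_rendered))
    truth$pattern_rendered else truth$pattern
  ev <- pattern_events(pat)
  if (!nrow(ev)) return(ev)
  BL <- truth$plan$body_length_um
  t0 <- truth$time_offset_ms
  bp_td <- body_xy_at(truth$traj, ev$touchdown_ms - t0)
  bp_lo <- body_xy_at(truth$traj, ev$liftoff_ms - t0)
  # positions already carry the rendering origin shift; undo for body math
  org <- truth$origin_um
  data.frame(leg = ev$leg, cycle = ev$cycle,
             touchdown_ms = ev$touchdown_ms, liftoff_ms = ev$liftoff_ms,
             x_um = ev$x_um, y_um = ev$y_um,
             aep_x_bl = (ev$x_um + org[1] - bp_td[, 1]) / BL,
             aep_y_bl = (ev$y_um + org[2] - bp_td[, 2]) / BL,
             pep_x_bl = (ev$x_um + org[1] - bp_lo[, 1]) / BL,
             pep_y_bl = (ev$y_um + org[2] - bp_lo[, 2]) / BL,
             edge_touchdown = ev$edge_touchdown,
             edge_liftoff = ev$edge_liftoff)
}

#' Rendering configuration for the fTIR-style renderer
#'
#' The rendered signal mimics the optics of an fTIR arena: bright,
#' compact Gaussian footprint spots that are stationary in the world
#' frame during stance; a dim uniform body ellipse (background light
#' partially illuminating the body); static dust spots present in
#' every frame including the pre-entry ones; a constant background
#' offset; and additive Gaussian sensor noise.
#'
#' @param um_per_px spatial calibration of the virtual camera.
#' @param spot_amplitude peak intensity of a footprint spot (fraction
#'   of full scale).
#' @param spot_sigma_px Gaussian radius of a footprint spot, px.
#' @param body_amplitude intensity of the body glow; must be dimmer
#'   than the spots.
#' @param body_axes_bl semi-axes of the body ellipse (along/across the
#'   heading), body lengths; the default `c(0.5, 0.15)` makes the
#'   major axis extent equal to the body length.
#' @param background constant background offset.
#' @param noise_sd SD of the additive Gaussian sensor noise; must be
#'   below `body_amplitude`.
#' @param dust data.frame with columns `x_px`, `y_px`, `amplitude`,
#'   `sigma_px`, or NULL to scatter `n_dust` random dust spots.
#' @param n_dust number of random dust spots when `dust` is NULL.
#' @param dust_amplitude peak intensity of random dust spots.
#' @param n_pre_entry frames rendered before the fly appears (used by
#'   the tracker's background estimator).
#' @param shape optional c(rows, cols) image shape in px; when NULL
#'   the frame is sized to fit the trajectory plus `margin_px`.
#' @param margin_px margin kept around the scene when auto-sizing.
#' @return a `fw_render_config` object.
#' @export
render_config <- function(um_per_px = 25, spot_amplitude = 0.5,
                          spot_sigma_px = 2, body_amplitude = 0.12,
                          body_axes_bl = c(0.5, 0.15),
                          background = 0.05, noise_sd = 0.025,
                          dust = NULL, n_dust = 8, dust_amplitude = 0.3,
                          n_pre_entry = 10, shape = NULL,
                          margin_px = 20) {
  check_num(um_per_px, "um_per_px", positive = TRUE)
  check_num(spot_amplitude, "spot_amplitude", positive = TRUE)
  check_num(spot_sigma_px, "spot_sigma_px", positive = TRUE)
  check_num(body_amplitude, "body_amplitude", positive = TRUE)
  check_num(noise_sd, "noise_sd", nonneg = TRUE)
  check_num(n_pre_entry, "n_pre_entry", nonneg = TRUE)
  if (!(spot_amplitude > body_amplitude && body_amplitude > noise_sd))
    stop_fg("need spot_amplitude > body_amplitude > noise_sd >= 0")
  structure(list(um_per_px = um_per_px, spot_amplitude = spot_amplitude,
                 spot_sigma_px = spot_sigma_px,
                 body_amplitude = body_amplitude,
                 body_axes_bl = body_axes_bl, background = background,
                 noise_sd = noise_sd, dust = dust, n_dust = n_dust,
                 dust_amplitude = dust_amplitude,
                 n_pre_entry = as.integer(n_pre_entry), shape = shape,
                 margin_px = margin_px),
            class = "fw_render_config")
}

add_gaussian_spot <- function(m, cx, cy, amplitude, sigma) {
  # cx, cy are 0-based pixel coordinates (x = column, y = row)
  r <- ceiling(4 * sigma)
  rows <- max(1L, floor(cy + 1 - r)):min(nrow(m), ceiling(cy + 1 + r))
  cols <- max(1L, floor(cx + 1 - r)):min(ncol(m), ceiling(cx + 1 + r))
  if (!length(rows) || !length(cols)) return(m)
  dy <- (rows - 1) - cy
  dx <- (cols - 1) - cx
  g <- exp(-outer(dy^2, dx^2, `+`) / (2 * sigma^2))
  m[rows, cols] <- m[rows, cols] + amplitude * g
  m
}

add_body_ellipse <- function(m, cx, cy, a_px, b_px, heading,
                             amplitude) {
  r <- ceiling(max(a_px, b_px)) + 1L
  rows <- max(1L, floor(cy + 1 - r)):min(nrow(m), ceiling(cy + 1 + r))
  cols <- max(1L, floor(cx + 1 - r)):min(ncol(m), ceiling(cx + 1 + r))
  if (!length(rows) || !length(cols)) return(m)
  dy <- (rows - 1) - cy
  dx <- (cols - 1) - cx
  ca <- cos(heading); sa <- sin(heading)
  # rotate pixel offsets into the body frame (y is the image row axis)
  u <- outer(dy * sa, dx * ca, `+`)      # along heading
  w <- outer(dy * ca, -dx * sa, `+`)     # across heading
  inside <- (u / a_px)^2 + (w / b_px)^2 <= 1
  m[rows, cols] <- m[rows, cols] + amplitude * inside
  m
}

#' Render a ground-truth walk as an fTIR-like frame stack
#'
#' Per frame: background offset plus dust spots (all frames, including
#' the pre-entry ones), then -- once the fly has entered -- a dim body
#' ellipse at the instantaneous body position and one Gaussian spot
#' for every leg currently in stance at its fixed world footprint
#' position.  Stance membership tests the half-open interval
#' `[onset, offset)` against the frame timestamp.  Gaussian sensor
#' noise is added with the given seed, so equal seeds give
#' bit-identical stacks.
#'
#' @param truth a `fw_ground_truth` from [simulate_walk()].
#' @param cfg a [render_config()].
#' @param seed integer seed for the noise (and random dust placement).
#' @return list with elements `stack` (a `fw_frame_stack`) and `truth`
#'   (the input shifted into video coordinates: times offset by the
#'   pre-entry frames, positions in image-frame um).
#' @export
render_ftir_frames <- function(truth, cfg = render_config(),
                               seed = NULL) {
  if (!inherits(truth, "fw_ground_truth"))
    stop_fg("'truth' must come from simulate_walk()")
  if (!inherits(cfg, "fw_render_config"))
    stop_fg("'cfg' must be a render_config() object")
  fps <- truth$spec$fps
  dt <- 1000 / fps
  upp <- cfg$um_per_px
  BL <- truth$plan$body_length_um
  n_walk <- max(1L, as.integer(round(truth$duration_ms / dt)))
  n_frames <- cfg$n_pre_entry + n_walk
  tw <- (seq_len(n_walk) - 1) * dt        # walk-time stamps

  ev <- pattern_events(truth$pattern)
  body <- body_xy_at(truth$traj, tw)
  a_um <- cfg$body_axes_bl[1] * BL
  b_um <- cfg$body_axes_bl[2] * BL
  pad <- 4 * cfg$spot_sigma_px * upp
  xmin <- min(body[, 1] - a_um, ev$x_um - pad)
  xmax <- max(body[, 1] + a_um, ev$x_um + pad)
  ymin <- min(body[, 2] - a_um, ev$y_um - pad)
  ymax <- max(body[, 2] + a_um, ev$y_um + pad)
  if (is.null(cfg$shape)) {
    origin <- c(xmin - cfg$margin_px * upp, ymin - cfg$margin_px * upp)
    shape <- c(ceiling((ymax - ymin) / upp) + 2 * cfg$margin_px + 1,
               ceiling((xmax - xmin) / upp) + 2 * cfg$margin_px + 1)
  } else {
    shape <- cfg$shape
    origin <- c(xmin - cfg$margin_px * upp, ymin - cfg$margin_px * upp)
    lim <- origin + c(shape[2], shape[1]) * upp
    bad <- which(body[, 1] + a_um > lim[1] | body[, 2] + a_um > lim[2])
    if (length(bad))
      stop_fg("trajectory exits the %d x %d frame at frame %d",
              shape[1], shape[2], cfg$n_pre_entry + bad[1] - 1L)
  }

  if (!is.null(seed)) set.seed(seed)
  dust <- cfg$dust
  if (is.null(dust)) {
    dust <- data.frame(
      x_px = runif(cfg$n_dust, 2, shape[2] - 3),
      y_px = runif(cfg$n_dust, 2, shape[1] - 3),
      amplitude = cfg$dust_amplitude * runif(cfg$n_dust, 0.5, 1),
      sigma_px = runif(cfg$n_dust, 0.8, 1.6))
  }

  base <- matrix(cfg$background, shape[1], shape[2])
  for (k in seq_len(nrow(dust)))
    base <- add_gaussian_spot(base, dust$x_px[k], dust$y_px[k],
                              dust$amplitude[k], dust$sigma_px[k])

  to_px <- function(x_um, y_um)
    cbind((x_um - origin[1]) / upp, (y_um - origin[2]) / upp)
  spot_px <- to_px(ev$x_um, ev$y_um)
  body_px <- to_px(body[, 1], body[, 2])

  frames <- vector("list", n_frames)
  npx <- shape[1] * shape[2]
  for (f in seq_len(n_frames)) {
    m <- base
    if (f > cfg$n_pre_entry) {
      i <- f - cfg$n_pre_entry
      m <- add_body_ellipse(m, body_px[i, 1], body_px[i, 2],
                            a_um / upp, b_um / upp,
                            truth$traj$heading_rad, cfg$body_amplitude)
      active <- which(ev$touchdown_ms <= tw[i] & tw[i] < ev$liftoff_ms)
      for (k in active)
        m <- add_gaussian_spot(m, spot_px[k, 1], spot_px[k, 2],
                               cfg$spot_amplitude, cfg$spot_sigma_px)
    }
    if (cfg$noise_sd > 0) m <- m + rnorm(npx, 0, cfg$noise_sd)
    frames[[f]] <- pmin(pmax(m, 0), 1)
  }
  stack <- frame_stack(frames, calibration(fps, upp))

  # shift the truth into video coordinates
  t0 <- cfg$n_pre_entry * dt
  truth2 <- truth
  truth2$time_offset_ms <- t0
  truth2$origin_um <- origin
  legs <- lapply(truth$pattern$legs, function(df) {
    df$touchdown_ms <- df$touchdown_ms + t0
    df$liftoff_ms <- df$liftoff_ms + t0
    df$x_um <- df$x_um - origin[1]
    df$y_um <- df$y_um - origin[2]
    df
  })
  truth2$pattern <- step_pattern(legs)
  # what the video can actually show: onsets snapped forward onto the
  # frame grid (a spot is rendered at frame f iff onset <= t_f < offset)
  truth2$pattern_rendered <-
    quantize_step_pattern(truth2$pattern, fps, rule = "ceiling")
  truth2$n_frames <- n_frames
  truth2$render <- list(um_per_px = upp, shape = shape,
                        n_pre_entry = cfg$n_pre_entry, dust = dust,
                        spot_amplitude = cfg$spot_amplitude,
                        body_amplitude = cfg$body_amplitude,
                        noise_sd = cfg$noise_sd, seed = seed)
  list(stack = stack, truth = truth2)
}

#' Synthetic body track from ground truth
#'
#' Builds the per-frame body track a perfect tracker would recover,
#' for exercising the analysis modules without rendering or tracking.
#'
#' @param truth a `fw_ground_truth` (raw from [simulate_walk()] or
#'   video-aligned from [render_ftir_frames()]).
#' @param um_per_px pixel size of the virtual track (1 = work in um).
#' @return a `fw_body_track` data.frame.
#' @export
truth_body_track <- function(truth, um_per_px = 1) {
  fps <- truth$spec$fps
  dt <- 1000 / fps
  n_walk <- max(1L, as.integer(round(truth$duration_ms / dt)))
  n_pre <- as.integer(round(truth$time_offset_ms / dt))
  tw <- (seq_len(n_walk) - 1) * dt
  body <- body_xy_at(truth$traj, tw)
  body[, 1] <- body[, 1] - truth$origin_um[1]
  body[, 2] <- body[, 2] - truth$origin_um[2]
  h <- truth$traj$heading_rad
  bt <- data.frame(
    frame = c(seq_len(n_pre) - 1L, n_pre + seq_len(n_walk) - 1L),
    valid = c(rep(FALSE, n_pre), rep(TRUE, n_walk)),
    cx_px = c(rep(NA_real_, n_pre), body[, 1] / um_per_px),
    cy_px = c(rep(NA_real_, n_pre), body[, 2] / um_per_px),
    ux = c(rep(NA_real_, n_pre), rep(cos(h), n_walk)),
    uy = c(rep(NA_real_, n_pre), rep(sin(h), n_walk)),
    length_px = c(rep(NA_real_, n_pre),
                  rep(truth$plan$body_length_um / um_per_px, n_walk)))
  class(bt) <- c("fw_body_track", "data.frame")
  bt
}

#' Write / read a ground-truth sidecar file
#'
#' @param truth a `fw_ground_truth`.
#' @param path JSON file path.
#' @return `path` (write) / a `fw_ground_truth` (read).
#' @export
write_truth <- function(truth, path) {
  x <- list(
    spec = unclass(truth$spec), seed = truth$seed,
    plan = list(body_length_um = truth$plan$body_length_um,
                aep = truth$plan$aep, pep_x = truth$plan$pep_x),
    traj = truth$traj, duration_ms = truth$duration_ms,
    time_offset_ms = truth$time_offset_ms, origin_um = truth$origin_um,
    aep_jitter_bl = truth$aep_jitter_bl,
    pep_jitter_bl = truth$pep_jitter_bl,
    n_frames = truth$n_frames, render = truth$render,
    pattern = truth$pattern$legs,
    pattern_rendered = if (!is.null(truth$pattern_rendered))
      truth$pattern_rendered$legs,
    fps_rendered = if (!is.null(truth$pattern_rendered))
      truth$pattern_rendered$fps)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(gait_spec, c(
    list(gait = x$spec$gait, period_ms = x$spec$period_ms,
         duty_factor = x$spec$duty_factor,
         n_cycles = x$spec$n_cycles, fps = x$spec$fps,
         speed_mm_s = x$spec$speed_mm_s,
         speed_mod_amplitude = x$spec$speed_mod_amplitude),
    if (!is.null(x$spec$metachronal_lag_ms))
      list(metachronal_lag_ms = x$spec$metachronal_lag_ms)))
  plan <- body_plan(x$plan$body_length_um, as.matrix(x$plan$aep),
                    unlist(x$plan$pep_x))
  legs <- lapply(x$pattern, as.data.frame)
  pat <- step_pattern(legs)
  pat_r <- if (!is.null(x$pattern_rendered))
    step_pattern(lapply(x$pattern_rendered, as.data.frame),
                 fps = x$fps_rendered %||% NA_real_)
  structure(list(spec = spec, plan = plan, pattern = pat,
                 pattern_rendered = pat_r,
                 traj = x$traj, seed = x$seed,
                 aep_jitter_bl = x$aep_jitter_bl %||% 0,
                 pep_jitter_bl = x$pep_jitter_bl %||% 0,
                 duration_ms = x$duration_ms,
                 time_offset_ms = x$time_offset_ms %||% 0,
                 origin_um = unlist(x$origin_um) %||% c(0, 0),
                 n_frames = x$n_frames, render = x$render),
            class = "fw_ground_truth")
}
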