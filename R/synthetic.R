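# Synthetic VFSS cohort generator. Produces landmark pixel time series for
# two prognosis groups with the structure the pipeline assumes: a smooth
# backward -> forward-upward -> return hyoid path in the anatomical frame,
# rendered into image pixels with a slow rigid whole-neck drift, landmark
# jitter, and a coin calibration. Group moment defaults are calibrated to the
# reference good/poor cohort statistics (amplitudes, durations). Every draw is
# deterministic under the config seed.

#' Smooth unimodal bump vanishing at both ends of the percentile axis
#'
#' A Gaussian bump multiplied by a C2 polynomial taper that brings it to
#' exactly zero at 0 and 100 (ramp length `min(10, center, 100 - center)`),
#' renormalized so `g(center) = 1`. Unlike chord subtraction, the taper never
#' produces negative lobes, so amplitudes calibrate cleanly.
#'
#' @param t percentile points.
#' @param center bump center in (0, 100).
#' @param width Gaussian width (SD) in percentiles.
#' @return bump values at `t`, in `[0, 1]`.
#' @export
bump <- function(t, center, width) {
  if (center <= 0 || center >= 100) stop("bump center outside (0, 100)")
  smoother <- function(u) {                        # C2 smoothstep on [0, 1]
    u <- pmin(pmax(u, 0), 1)
    u^3 * (6 * u^2 - 15 * u + 10)
  }
  ramp <- min(10, center, 100 - center)
  g <- function(u) {
    exp(-(u - center)^2 / (2 * width^2)) *
      smoother(u / ramp) * smoother((100 - u) / ramp)
  }
  g(t) / g(center)
}

#' Template hyoid trajectory on the percentile axis
#'
#' Three-bump minimal family reproducing the loop shape of a swallow:
#' `x(t) = -B g(t; t_b, w_b) + F g(t; t_f, w_f)` (backward then forward) and
#' `y(t) = U g(t; t_u, w_u)` (upward), all in mm, vanishing at 0 and 100.
#'
#' @param t percentile points in `[0, 100]`.
#' @param F,B,U forward, backward, upward amplitudes (mm, nonnegative).
#' @param timings named list of bump centers/widths `t_b, w_b, t_f, w_f,
#'   t_u, w_u` (percentiles).
#' @return list with `x` and `y` (mm).
#' @export
template_trajectory <- function(t, F, B, U, timings = default_timings()) {
  stopifnot(F >= 0, B >= 0, U >= 0)
  list(
    x = -B * bump(t, timings$t_b, timings$w_b) +
         F * bump(t, timings$t_f, timings$w_f),
    y =  U * bump(t, timings$t_u, timings$w_u)
  )
}

#' Default template phase timings
#'
#' Bump centers sit at the reference cohort's group-mean times to maximal backward,
#' forward and upward displacement; widths were fixed once so that the
#' noise-free group templates reproduce the reference early-phase direction
#' angles (about 119 degrees good, 96 degrees poor).
#'
#' @return named list `t_b, w_b, t_f, w_f, t_u, w_u`.
#' @export
default_timings <- function() {
  list(t_b = 16, w_b = 6, t_f = 49, w_f = 16, t_u = 34, w_u = 8)
}

#' Synthetic cohort configuration
#'
#' Defaults are calibrated to the reference clinical cohort: group-specific forward /
#' backward / upward amplitude moments, swallow durations, 30 frames/s, and
#' a 23.5 mm coin imaged at `coin_mm / mm_per_px` pixels. Amplitude and
#' duration draws are truncated below (amplitudes at 0, durations at
#' `min_duration_s`). The poor-group backward amplitude is the one
#' deliberately uncalibrated moment: it is scaled down (mean 1.02 mm, same
#' coefficient of variation) so that the noise-free poor template reproduces
#' the reference early-phase direction angle of about 96 degrees — the
#' direction-angle group effect is induced through the backward-to-vertical
#' ratio, at the cost of the poor group's backward displacement moment.
#'
#' @param n_good,n_poor subjects per group (each >= 2).
#' @param fps frame rate, images/s.
#' @param duration_mean,duration_sd per-group swallow duration moments (s),
#'   named vectors `c(good = , poor = )`.
#' @param forward_mean,forward_sd,backward_mean,backward_sd,upward_mean,upward_sd
#'   per-group amplitude moments (mm).
#' @param timings template phase timings, see [default_timings()].
#' @param pixel_noise_sd iid Gaussian landmark jitter, px.
#' @param drift_rot_sd,drift_trans_sd per-frame random-walk increments of the
#'   rigid neck drift (degrees, px).
#' @param mm_per_px image scale; `coin_px` is derived from it.
#' @param coin_mm coin diameter, mm.
#' @param lead_s,tail_s quiescent lead-in and tail, s.
#' @param min_duration_s lower truncation for duration draws.
#' @param seed RNG seed making the cohort reproducible.
#' @return object of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(
    n_good = 18L, n_poor = 18L, fps = 30,
    duration_mean = c(good = 1.76, poor = 1.89),
    duration_sd = c(good = 0.45, poor = 0.47),
    forward_mean = c(good = 12.43, poor = 9.22),
    forward_sd = c(good = 4.81, poor = 3.95),
    backward_mean = c(good = 3.49, poor = 1.02),
    backward_sd = c(good = 2.59, poor = 1.14),
    upward_mean = c(good = 15.37, poor = 16.81),
    upward_sd = c(good = 7.14, poor = 7.10),
    timings = default_timings(),
    pixel_noise_sd = 0.5,
    drift_rot_sd = 0.05, drift_trans_sd = 0.2,
    mm_per_px = 0.5, coin_mm = 23.5,
    lead_s = 0.3, tail_s = 0.3, min_duration_s = 0.8,
    seed = 1L) {
  if (n_good < 2L || n_poor < 2L) stop("need at least 2 subjects per group")
  if (fps <= 0) stop("fps must be positive")
  for (m in list(forward_mean, backward_mean, upward_mean, duration_mean)) {
    if (any(m < 0)) stop("amplitude/duration means must be nonnegative")
  }
  structure(as.list(environment()), class = "synthetic_cohort_config")
}

rtrunc_norm <- function(n, mean, sd, lower = 0) {
  u <- stats::runif(n)                             # always consume the stream
  if (sd <= 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(plo + u * (1 - plo), mean, sd)
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

#' Generate a synthetic two-group VFSS cohort
#'
#' For each subject: amplitudes and duration are drawn from the group
#' distributions, the template trajectory is rendered at `fps` between a
#' quiescent lead-in and tail, C2/C4 sit at fixed anatomical offsets, a slow
#' rigid neck drift (rotation + translation random walk) is applied to all
#' three landmarks jointly, coordinates are converted to image pixels
#' (y down) and iid pixel noise is added.
#'
#' @param config a [synthetic_cohort_config()].
#' @return list with `subjects` (list of [landmark_series()]), `truth`
#'   (per-subject ground truth: drawn amplitudes/duration, true window
#'   frames, true grid displacement curves), `labels`, `calibration`
#'   (a [scale_calibration()]), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  set.seed(config$seed)
  n <- config$n_good + config$n_poor
  labels <- rep(c("good", "poor"), c(config$n_good, config$n_poor))
  coin_px <- config$coin_mm / config$mm_per_px
  cal <- scale_calibration(coin_px, config$coin_mm)
  # fixed anatomy (mm, anatomical frame): C4 origin, C2 35 mm superior,
  # hyoid resting anterior between the two
  c2_mm <- c(0, 35); c4_mm <- c(0, 0); hyoid_rest <- c(35, 5)
  img_center <- c(256, 256)
  grid <- seq(0, 100, length.out = 101L)
  subjects <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    g <- labels[i]
    fa <- rtrunc_norm(1L, config$forward_mean[[g]], config$forward_sd[[g]])
    ba <- rtrunc_norm(1L, config$backward_mean[[g]], config$backward_sd[[g]])
    ua <- rtrunc_norm(1L, config$upward_mean[[g]], config$upward_sd[[g]])
    dur <- rtrunc_norm(1L, config$duration_mean[[g]],
                       config$duration_sd[[g]], lower = config$min_duration_s)
    n_sw <- max(4L, round(dur * config$fps))
    dur_q <- n_sw / config$fps                     # frame-quantized duration
    n_lead <- round(config$lead_s * config$fps)
    n_tail <- round(config$tail_s * config$fps)
    nf <- n_lead + n_sw + n_tail + 1L
    time <- (seq_len(nf) - 1L) / config$fps
    t0 <- n_lead / config$fps
    pct <- pmin(pmax((time - t0) / dur_q, 0), 1) * 100
    tem <- template_trajectory(pct, fa, ba, ua, config$timings)
    hy <- cbind(hyoid_rest[1] + tem$x, hyoid_rest[2] + tem$y)
    c2 <- matrix(c2_mm, nf, 2L, byrow = TRUE)
    c4 <- matrix(c4_mm, nf, 2L, byrow = TRUE)
    # rigid neck drift shared by all landmarks; standard normals are always
    # drawn and scaled so the RNG stream is identical across noise settings
    theta <- cumsum(stats::rnorm(nf)) * config$drift_rot_sd * pi / 180
    tau_x <- cumsum(stats::rnorm(nf)) * config$drift_trans_sd *
      config$mm_per_px
    tau_y <- cumsum(stats::rnorm(nf)) * config$drift_trans_sd *
      config$mm_per_px
    drift <- function(p) {
      t(vapply(seq_len(nf), function(j) {
        rot2(theta[j]) %*% p[j, ] + c(tau_x[j], tau_y[j])
      }, numeric(2L)))
    }
    to_px <- function(p) {
      cbind(img_center[1] + p[, 1] / config$mm_per_px,
            img_center[2] - p[, 2] / config$mm_per_px) +
        matrix(stats::rnorm(2L * nf), nf, 2L) * config$pixel_noise_sd
    }
    subjects[[i]] <- landmark_series(
      time, to_px(drift(hy)), to_px(drift(c2)), to_px(drift(c4)),
      y_axis_convention = "image-down"
    )
    tg <- template_trajectory(grid, fa, ba, ua, config$timings)
    truth[[i]] <- list(
      F = fa, B = ba, U = ua, duration_s = dur_q,
      window = c(n_lead + 1L, n_lead + n_sw + 1L),
      grid = grid, disp_x = tg$x, disp_y = tg$y,
      hyoid_mm = hy                                # noise/drift-free, mm
    )
  }
  list(subjects = subjects, truth = truth, labels = labels,
       calibration = cal, config = config)
}
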