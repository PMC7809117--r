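# Temporal normalization and per-subject kinematic profiles: displacement on
# the 0-100 percentile grid, symmetric-difference-quotient velocity, direction
# angles, and the discrete summary parameters (maximal displacements and
# velocities, times to maxima, early-phase mean direction angle).

#' Detect the swallow window in an anatomical trajectory
#'
#' The start is taken where the hyoid leaves its lowest pre-peak position and
#' begins to move: the last minimum-height frame before the vertical peak,
#' advanced to the first frame whose (lightly smoothed) frame-to-frame speed
#' exceeds `speed_threshold`. The end is the last moving frame before speed
#' stays below the threshold for `dwell` consecutive frames through to the
#' end of the recording. An explicit `manual` window always wins.
#'
#' @param traj an `anatomical_trajectory` (mm).
#' @param speed_threshold minimum speed counted as motion, mm/s.
#' @param dwell number of consecutive sub-threshold frames ending the swallow.
#' @param manual optional `c(start_frame, end_frame)` override.
#' @return integer `c(start_frame, end_frame)`.
#' @export
detect_swallow_window <- function(traj, speed_threshold = 10, dwell = 3L,
                                  manual = NULL) {
  stopifnot(inherits(traj, "anatomical_trajectory"))
  n <- nrow(traj$position_mm)
  if (!is.null(manual)) {
    manual <- as.integer(manual)
    if (length(manual) != 2L || manual[1] < 1L || manual[2] > n ||
        manual[1] >= manual[2]) {
      stop("manual window must be c(start, end) within the recording")
    }
    return(manual)
  }
  if (n < 4L) stop("trajectory too short for window detection")
  # 3-point moving average tames landmark jitter before differencing
  ma3 <- function(v) {
    f <- as.numeric(stats::filter(v, rep(1 / 3, 3), sides = 2))
    f[1] <- v[1]; f[n] <- v[n]
    f
  }
  sm <- cbind(ma3(traj$position_mm[, 1]), ma3(traj$position_mm[, 2]))
  dt <- diff(traj$time)
  speed <- sqrt(rowSums(diff(sm)^2)) / dt          # speed on frame i -> i+1
  moving <- speed > speed_threshold
  if (!any(moving)) {
    stop("no motion above threshold detected; annotate the window manually")
  }
  dwell <- max(1L, as.integer(dwell))
  # start: the hyoid leaves its lowest pre-peak resting position. Measured as
  # displacement from that resting point, since near the onset speeds are of
  # the order of the landmark jitter while displacement accumulates.
  peak <- which.max(sm[, 2])
  low <- max(which(sm[seq_len(peak), 2] <= min(sm[seq_len(peak), 2]) + 1e-12))
  r0 <- sqrt(rowSums(sweep(sm, 2L, sm[low, ])^2))
  rmax <- max(r0)
  cross <- which(r0 >= 0.3 * rmax)[1]              # unambiguously in motion
  jitter <- 1.4826 * stats::median(abs(diff(r0[seq_len(max(cross, 2L))])))
  start <- max(which(r0[seq_len(cross)] <= max(jitter, 1e-9)), 1L)
  # end: displacement from the final resting position (median of the last
  # dwell frames) decays back under the jitter floor after the last crossing
  rest <- apply(sm[max(1L, n - dwell + 1L):n, , drop = FALSE], 2L,
                stats::median)
  r1 <- sqrt(rowSums(sweep(sm, 2L, rest)^2))
  crossb <- max(which(r1 >= 0.3 * max(r1)))
  post <- which(r1 <= max(jitter, 1e-9) & seq_len(n) > crossb)
  end <- if (length(post)) post[1] else n
  if (end <= start + 3L) end <- min(n, start + 4L) # degenerate guard
  c(as.integer(start), as.integer(end))
}

#' Normalize a swallow onto the 0-100 percentile grid
#'
#' Linearly interpolates the rebased trajectory from its frame timestamps
#' onto a uniform grid of `n_grid` points covering the window, so that
#' subjects with different swallow durations become pointwise comparable.
#'
#' @param traj a rebased `anatomical_trajectory`.
#' @param window `c(start_frame, end_frame)`; must span at least 4 frames.
#' @param n_grid grid size (default 101: percentiles 0,1,...,100).
#' @return Object of class `kinematic_profile` with `grid`, `disp_x`,
#'   `disp_y` (mm) and `duration_s`; velocity/angle slots filled by
#'   [compute_velocity()] and [compute_direction_angles()].
#' @export
normalize_time <- function(traj, window, n_grid = 101L) {
  stopifnot(inherits(traj, "anatomical_trajectory"))
  s <- window[1]; e <- window[2]
  if (e - s + 1L < 4L) stop("window too short: need at least 4 frames")
  idx <- s:e
  tt <- traj$time[idx]
  if (any(diff(tt) <= 0)) stop("non-monotone time in window")
  if (!isTRUE(traj$rebased)) traj <- rebase_to_start(traj, s)
  grid <- seq(0, 100, length.out = n_grid)
  tq <- tt[1] + (tt[length(tt)] - tt[1]) * grid / 100
  tq[1] <- tt[1]; tq[n_grid] <- tt[length(tt)]     # guard fp round-off
  dx <- stats::approx(tt, traj$position_mm[idx, 1], xout = tq)$y
  dy <- stats::approx(tt, traj$position_mm[idx, 2], xout = tq)$y
  structure(
    list(grid = grid, disp_x = dx, disp_y = dy,
         vel_x = NULL, vel_y = NULL, angle = NULL,
         duration_s = tt[length(tt)] - tt[1]),
    class = "kinematic_profile"
  )
}

#' Velocity by the symmetric difference quotient
#'
#' Interior grid points use `(d[i+1] - d[i-1]) / (2h)`; the endpoints use
#' one-sided differences. On the percentile grid `h = 1`, so units are
#' mm per percentile of normalized swallow time.
#'
#' @param profile a `kinematic_profile` with displacement filled.
#' @return the profile with `vel_x` and `vel_y` filled.
#' @export
compute_velocity <- function(profile) {
  stopifnot(inherits(profile, "kinematic_profile"))
  h <- diff(profile$grid)
  if (any(abs(h - h[1]) > 1e-9)) stop("grid must be uniform")
  sdq <- function(d) {
    n <- length(d)
    v <- numeric(n)
    v[1] <- (d[2] - d[1]) / h[1]
    v[n] <- (d[n] - d[n - 1]) / h[1]
    if (n > 2L) v[2:(n - 1)] <- (d[3:n] - d[1:(n - 2)]) / (2 * h[1])
    v
  }
  profile$vel_x <- sdq(profile$disp_x)
  profile$vel_y <- sdq(profile$disp_y)
  profile
}

#' Direction angle of the instantaneous hyoid motion vector
#'
#' The angle of `(vel_x, vel_y)` measured from the positive horizontal
#' (anterior) axis, in degrees mapped to `[0, 360)`. Where the speed is below
#' `floor` the direction is undefined and stored as `NA` (and excluded from
#' any averaging).
#'
#' @param profile a `kinematic_profile` with velocities filled.
#' @param floor minimum speed (mm/percentile) for a defined angle.
#' @return the profile with `angle` filled.
#' @export
compute_direction_angles <- function(profile, floor = 1e-6) {
  stopifnot(inherits(profile, "kinematic_profile"))
  if (is.null(profile$vel_x)) stop("compute velocities first")
  ang <- atan2(profile$vel_y, profile$vel_x) * 180 / pi
  ang <- ang %% 360
  ang[sqrt(profile$vel_x^2 + profile$vel_y^2) < floor] <- NA_real_
  profile$angle <- ang
  profile
}

#' Mean direction angle over the early swallow phase
#'
#' The early phase is the 5th-20th percentile of normalized swallow time
#' (hyoid motion before the 5th percentile is too variable to average). By
#' default the arithmetic mean of the defined angles is returned; set
#' `circular = TRUE` for the circular mean, which agrees with the arithmetic
#' mean when early-phase motion stays in the backward-upward quadrant.
#'
#' @param profile a `kinematic_profile` with angles filled.
#' @param lo,hi percentile bounds of the window (inclusive).
#' @param circular use the circular mean instead of the arithmetic mean.
#' @return mean angle in degrees.
#' @export
mean_early_phase_angle <- function(profile, lo = 5, hi = 20,
                                   circular = FALSE) {
  stopifnot(inherits(profile, "kinematic_profile"))
  if (is.null(profile$angle)) stop("compute direction angles first")
  sel <- profile$grid >= lo & profile$grid <= hi
  a <- profile$angle[sel]
  a <- a[!is.na(a)]
  if (!length(a)) stop("all direction angles undefined in the early window")
  if (circular) {
    r <- a * pi / 180
    (atan2(mean(sin(r)), mean(cos(r))) * 180 / pi) %% 360
  } else {
    mean(a)
  }
}

#' Discrete summary parameters of one swallow
#'
#' Signed extrema of the displacement and velocity profiles and the grid
#' times at which they occur (ties broken toward the earliest time), the
#' early-phase mean direction angle, and the swallow duration. Backward
#' values are negative by convention, forward/upward positive.
#'
#' @param profile a complete `kinematic_profile`.
#' @param early_lo,early_hi early-phase window passed to
#'   [mean_early_phase_angle()].
#' @return a one-row data.frame of class `summary_parameters`.
#' @export
summarize_profile <- function(profile, early_lo = 5, early_hi = 20) {
  stopifnot(inherits(profile, "kinematic_profile"))
  if (is.null(profile$angle)) stop("profile incomplete: need angles")
  g <- profile$grid
  ext <- function(v, f) {
    i <- which(v == f(v))[1]                       # earliest tie
    c(v[i], g[i])
  }
  fb <- ext(profile$disp_x, min); ff <- ext(profile$disp_x, max)
  fu <- ext(profile$disp_y, max)
  vb <- ext(profile$vel_x, min); vf <- ext(profile$vel_x, max)
  vu <- ext(profile$vel_y, max)
  ang <- tryCatch(mean_early_phase_angle(profile, early_lo, early_hi),
                  error = function(e) NA_real_)
  out <- data.frame(
    max_backward_x = fb[1], t_max_backward_x = fb[2],
    max_forward_x = ff[1], t_max_forward_x = ff[2],
    max_upward_y = fu[1], t_max_upward_y = fu[2],
    max_backward_vx = vb[1], t_max_backward_vx = vb[2],
    max_forward_vx = vf[1], t_max_forward_vx = vf[2],
    max_upward_vy = vu[1], t_max_upward_vy = vu[2],
    mean_early_angle = ang, duration_s = profile$duration_s
  )
  class(out) <- c("summary_parameters", class(out))
  out
}

#' Full kinematic profile from an anatomical trajectory
#'
#' Convenience chain: window detection (or manual window), rebasing at the
#' start frame, temporal normalization, velocity, direction angles.
#'
#' @inheritParams detect_swallow_window
#' @inheritParams normalize_time
#' @param angle_floor passed to [compute_direction_angles()].
#' @return a complete `kinematic_profile`.
#' @export
kinematic_profile <- function(traj, manual = NULL, n_grid = 101L,
                              speed_threshold = 10, dwell = 3L,
                              angle_floor = 1e-6) {
  win <- detect_swallow_window(traj, speed_threshold, dwell, manual)
  traj <- rebase_to_start(traj, win[1])
  profile <- normalize_time(traj, win, n_grid)
  profile <- compute_velocity(profile)
  compute_direction_angles(profile, floor = angle_floor)
}
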