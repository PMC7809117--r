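test_that("temporal normalization maps a window onto the percentile grid", {
  # 54 frames at 30 fps: duration (54-1)/30 ~ 1.767 s
  n <- 54
  tr <- dash_trajectory(n_lead = 0, n_move = n, n_tail = 0)
  pr <- normalize_time(tr, c(1, n))
  expect_length(pr$grid, 101)
  expect_equal(pr$duration_s, (n - 1) / 30, tolerance = 1e-12)
  expect_equal(pr$disp_x[1], 0)
  expect_equal(pr$disp_x[101], 10)
  # a path linear in time stays exactly linear in percentile, even when
  # sampled at irregular times
  t_irr <- sort(stats::runif(20, 0, 2))
  tr2 <- structure(list(time = t_irr,
                        position_mm = cbind(3 * t_irr, -2 * t_irr),
                        rebased = FALSE),
                   class = "anatomical_trajectory")
  pr2 <- normalize_time(rebase_to_start(tr2, 1), c(1, 20))
  span <- t_irr[20] - t_irr[1]
  expect_equal(pr2$disp_x, 3 * span * pr2$grid / 100, tolerance = 1e-9)
  expect_error(normalize_time(tr, c(1, 3)), "window too short")
})

test_that("normalizing an already-gridded profile is the identity", {
  g <- seq(0, 100, 1)
  tr <- structure(list(time = g, position_mm = cbind(sin(g / 9), cos(g / 7) - 1),
                       rebased = TRUE),
                  class = "anatomical_trajectory")
  tr <- rebase_to_start(tr, 1)
  pr <- normalize_time(tr, c(1, 101))
  expect_equal(pr$disp_x, tr$position_mm[, 1], tolerance = 1e-12)
  expect_equal(pr$disp_y, tr$position_mm[, 2], tolerance = 1e-12)
})

test_that("symmetric difference quotient is exact on lines and quadratics", {
  g <- seq(0, 100, 1)
  pr <- compute_velocity(profile_from_disp(0.1 * g, rep(2, 101)))
  expect_equal(pr$vel_x, rep(0.1, 101), tolerance = 1e-12)   # incl. endpoints
  expect_equal(pr$vel_y, rep(0, 101))
  pr2 <- compute_velocity(profile_from_disp(g^2, g))
  expect_equal(pr2$vel_x[2:100], 2 * g[2:100], tolerance = 1e-9)
})

test_that("velocity of a cumulative sum recovers the increments", {
  set.seed(1)
  v <- stats::rnorm(101)
  d <- cumsum(v)
  pr <- compute_velocity(profile_from_disp(d, d))
  # symmetric quotient of a cumsum averages adjacent increments
  expect_equal(pr$vel_x[2:100], (v[3:101] + v[2:100]) / 2, tolerance = 1e-9)
})

test_that("direction angles follow atan2 in degrees on [0, 360)", {
  pr <- profile_from_disp(c(0, 1, 1, 0, 1), c(0, 0, 1, 1, 0))
  pr$vel_x <- c(1, 0, -1, 1, 0)
  pr$vel_y <- c(0, 1, 1, -1, 0)
  pr <- compute_direction_angles(pr)
  expect_equal(pr$angle[1:4], c(0, 90, 135, 315))
  expect_true(is.na(pr$angle[5]))                  # below the speed floor
})

test_that("angles are rotation-equivariant", {
  set.seed(2)
  pr <- profile_from_disp(stats::rnorm(30), stats::rnorm(30))
  pr <- compute_direction_angles(compute_velocity(pr))
  th <- 73.3
  rot <- pr
  rad <- th * pi / 180
  vx <- pr$vel_x * cos(rad) - pr$vel_y * sin(rad)
  rot$vel_y <- pr$vel_x * sin(rad) + pr$vel_y * cos(rad)
  rot$vel_x <- vx
  rot <- compute_direction_angles(rot)
  d <- (rot$angle - pr$angle) %% 360
  expect_equal(d[!is.na(d)], rep(th, sum(!is.na(d))), tolerance = 1e-9)
})

test_that("early-phase mean angle averages defined angles on percentiles 5-20", {
  pr <- profile_from_disp(seq(0, 10, length.out = 101), rep(0, 101))
  pr$vel_x <- rep(1, 101); pr$vel_y <- rep(0, 101)
  pr$angle <- rep(119.18, 101)
  expect_equal(mean_early_phase_angle(pr), 119.18)
  pr$angle[seq(6, 21, 2)] <- 90
  pr$angle[seq(7, 21, 2)] <- 180
  expect_equal(mean_early_phase_angle(pr), 135)
  pr$angle[6:21] <- NA
  expect_error(mean_early_phase_angle(pr), "undefined")
})

test_that("profile summary extrema match a brute-force scan", {
  set.seed(3)
  for (rep in 1:20) {
    dx <- cumsum(stats::rnorm(101)); dy <- cumsum(stats::rnorm(101))
    pr <- profile_from_disp(dx - dx[1], dy - dy[1])
    pr <- compute_direction_angles(compute_velocity(pr))
    s <- summarize_profile(pr)
    expect_equal(s$max_forward_x, max(pr$disp_x))
    expect_equal(s$max_backward_x, min(pr$disp_x))
    expect_equal(s$max_upward_y, max(pr$disp_y))
    expect_equal(s$t_max_forward_x, pr$grid[which.max(pr$disp_x)])
    expect_equal(s$max_forward_vx, max(pr$vel_x))
    expect_equal(s$t_max_upward_vy, pr$grid[which.max(pr$vel_y)])
    expect_gte(s$max_forward_x, 0)
    expect_lte(s$max_backward_x, 0)
  }
})

test_that("summary picks the earliest time among ties", {
  d <- rep(0, 101); d[c(21, 61)] <- 5
  pr <- profile_from_disp(d, rep(0, 101))
  pr <- compute_direction_angles(compute_velocity(pr))
  expect_equal(summarize_profile(pr)$t_max_forward_x, 20)
})

test_that("window detection finds a crisp onset and honours overrides", {
  tr <- dash_trajectory(n_lead = 5, n_move = 30, n_tail = 10)
  w <- detect_swallow_window(tr)
  expect_lte(abs(w[1] - 6), 1)                     # motion starts at frame 6
  expect_lte(abs(w[2] - 35), 2)
  expect_equal(detect_swallow_window(tr, manual = c(3, 40)), c(3L, 40L))
  still <- structure(list(time = 0:19 / 30,
                          position_mm = matrix(1, 20, 2), rebased = FALSE),
                     class = "anatomical_trajectory")
  expect_error(detect_swallow_window(still), "no motion")
})
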