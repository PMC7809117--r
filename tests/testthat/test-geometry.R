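test_that("coin calibration gives mm per pixel and rejects degenerate input", {
  expect_equal(compute_scale_factor(scale_calibration(47)), 0.5)
  expect_equal(compute_scale_factor(scale_calibration(23.5)), 1)
  expect_error(scale_calibration(0), "calibration")
  expect_error(scale_calibration(-3), "calibration")
})

test_that("frame transform maps C4 to origin and C2 onto the superior axis", {
  # axis-aligned, math-up: identity
  tf <- build_frame_transform(c(0, 30), c(0, 0), c(10, 5), "math-up")
  expect_equal(apply_frame_transform(tf, c(0, 30)), c(0, 30))
  expect_equal(apply_frame_transform(tf, c(10, 5)), c(10, 5))
  # image-down: pure flip
  tf <- build_frame_transform(c(100, 40), c(100, 100), c(150, 90),
                              "image-down")
  expect_equal(apply_frame_transform(tf, c(100, 40)), c(0, 60))
  expect_equal(apply_frame_transform(tf, c(150, 90)), c(50, 10))
  # vertebral axis along pixel x: quarter-turn, anterior resolved from hint
  tf <- build_frame_transform(c(30, 0), c(0, 0), c(0, -10), "math-up")
  expect_equal(apply_frame_transform(tf, c(30, 0)), c(0, 30))
  expect_equal(apply_frame_transform(tf, c(0, -10)), c(10, 0))
})

test_that("degenerate axis and on-axis hints are rejected", {
  expect_error(build_frame_transform(c(5, 5), c(5, 5), c(1, 1)), "degenerate")
  expect_error(build_frame_transform(c(0, 30), c(0, 0), c(0, 15), "math-up"),
               "ambiguous")
})

test_that("transform preserves pairwise distances and frame invariants", {
  set.seed(42)
  for (rep in 1:20) {
    c2 <- stats::runif(2, 0, 200)
    c4 <- c2 + stats::runif(2, 5, 40) * sample(c(-1, 1), 2, replace = TRUE)
    hint <- c4 + c(30, 2)
    tf <- tryCatch(build_frame_transform(c2, c4, hint, "image-down"),
                   error = function(e) NULL)
    if (is.null(tf)) next
    expect_equal(apply_frame_transform(tf, c4), c(0, 0), tolerance = 1e-12)
    c2i <- apply_frame_transform(tf, c2)
    expect_lt(abs(c2i[1]), 1e-9)
    expect_equal(c2i[2], sqrt(sum((c2 - c4)^2)), tolerance = 1e-9)
    p <- matrix(stats::runif(8, 0, 300), 4, 2)
    q <- apply_frame_transform(tf, p)
    expect_equal(as.numeric(dist(q)), as.numeric(dist(p)), tolerance = 1e-9)
  }
})

test_that("anatomical trajectories are invariant to rigid motion and scale", {
  set.seed(7)
  cal <- scale_calibration(47)
  for (rep in 1:100) {
    n <- 12
    hy <- cbind(150 + cumsum(stats::rnorm(n)), 90 + cumsum(stats::rnorm(n)))
    c2 <- matrix(c(100, 40), n, 2, byrow = TRUE)
    c4 <- matrix(c(100, 100), n, 2, byrow = TRUE)
    base <- landmark_series((seq_len(n) - 1) / 30, hy, c2, c4, "image-down")
    ref <- to_anatomical(base, cal)
    # a different rigid motion of the whole image on every frame
    moved <- base
    for (i in seq_len(n)) {
      rt <- random_rigid()
      moved$hyoid_px[i, ] <- rt(matrix(hy[i, ], 1))
      moved$c2_px[i, ] <- rt(matrix(c2[i, ], 1))
      moved$c4_px[i, ] <- rt(matrix(c4[i, ], 1))
    }
    got <- to_anatomical(moved, cal)
    expect_lt(max(abs(got$position_mm - ref$position_mm)), 1e-9)
    # uniform pixel scaling with matching coin measurement
    s <- stats::runif(1, 0.5, 3)
    scaled <- landmark_series(base$time, hy * s, c2 * s, c4 * s, "image-down")
    got2 <- to_anatomical(scaled, scale_calibration(47 * s))
    expect_lt(max(abs(got2$position_mm - ref$position_mm)), 1e-9)
  }
})

test_that("stationary landmarks give a constant anatomical position", {
  tr <- to_anatomical(static_series(), scale_calibration(47))
  expect_lt(max(abs(sweep(tr$position_mm, 2, tr$position_mm[1, ]))), 1e-12)
})

test_that("rebasing zeroes the start frame and is idempotent", {
  tr <- structure(list(time = 0:3 / 30,
                       position_mm = rbind(c(1, 1), c(3, 2), c(4, 0), c(5, 7)),
                       rebased = FALSE),
                  class = "anatomical_trajectory")
  rb <- rebase_to_start(tr, 1)
  expect_equal(rb$position_mm[1, ], c(0, 0))
  expect_equal(rb$position_mm[2, ], c(2, 1))
  expect_true(rb$rebased)
  expect_equal(rebase_to_start(rb, 1), rb)
  expect_error(rebase_to_start(tr, 9), "out of range")
  # constant trajectory rebases to all zeros
  ct <- structure(list(time = 0:3 / 30,
                       position_mm = matrix(c(5, 7), 4, 2, byrow = TRUE),
                       rebased = FALSE),
                  class = "anatomical_trajectory")
  expect_true(all(rebase_to_start(ct, 2)$position_mm == 0))
})

test_that("per-frame errors carry the offending frame index", {
  s <- static_series(n = 5)
  s$c2_px[3, ] <- s$c4_px[3, ]
  expect_error(to_anatomical(s, scale_calibration(47)), "frame 3")
})
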