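test_that("design matrix uses reference coding with the good group first", {
  d <- build_design(rep(c("good", "poor"), each = 18))
  expect_equal(dim(d$Z), c(36L, 2L))
  expect_equal(colSums(d$Z), c(intercept = 36, group = 18))
  expect_equal(d$reference, "good")
  expect_error(build_design(c("good", "good", "poor")), "at least 2")
  expect_error(build_design(rep("good", 6)), "two groups")
})

test_that("constant group curves give exact coefficients and zero SE", {
  g <- seq(0, 100, 1)
  curves <- rbind(matrix(2, 5, 101), matrix(5, 4, 101))
  d <- build_design(rep(c("good", "poor"), c(5, 4)))
  fit <- fit_pointwise_flr(curves, d, g)
  expect_equal(fit$beta_ref, rep(2, 101))
  expect_equal(fit$beta_diff, rep(3, 101))
  expect_equal(fit$se, rep(0, 101))
  expect_equal(fit$significant, cbind(lo = 0, hi = 100))
})

test_that("difference coefficient equals the pointwise group-mean difference", {
  set.seed(20)
  for (rep in 1:50) {
    ng <- sample(2:10, 1); np <- sample(2:10, 1)
    curves <- matrix(stats::rnorm((ng + np) * 101), ng + np, 101)
    labs <- rep(c("good", "poor"), c(ng, np))
    fit <- fit_pointwise_flr(curves, build_design(labs))
    oracle <- colMeans(curves[labs == "poor", , drop = FALSE]) -
      colMeans(curves[labs == "good", , drop = FALSE])
    expect_equal(fit$beta_diff, oracle, tolerance = 1e-10)
    expect_equal(fit$beta_ref,
                 colMeans(curves[labs == "good", , drop = FALSE]),
                 tolerance = 1e-10)
  }
})

test_that("a known bump difference is recovered from a noisy cohort", {
  set.seed(21)
  g <- seq(0, 100, 1)
  delta <- 3 * bump(g, 55, 15)
  base <- 10 * sin(2 * pi * g / 100)
  curves <- rbind(
    t(replicate(40, base + stats::rnorm(101))),
    t(replicate(40, base + delta + stats::rnorm(101)))
  )
  fit <- fit_pointwise_flr(curves, build_design(rep(c("good", "poor"),
                                                    each = 40)))
  expect_lt(max(abs(fit$beta_diff - delta)), 0.5)
})

test_that("significant intervals are the maximal runs excluding zero", {
  g <- seq(0, 100, 1)
  fit <- structure(list(grid = g, beta_diff = rep(0, 101),
                        lower = rep(-1, 101), upper = rep(1, 101)),
                   class = "flr_fit")
  expect_equal(nrow(significant_intervals(fit)), 0L)
  fit$lower[36:79] <- 0.2                          # CI above zero on 35..78
  expect_equal(significant_intervals(fit), cbind(lo = 35, hi = 78))
  # a separate two-point negative excursion is reported as its own interval
  fit$lower[36:79] <- -1
  fit$upper[45:46] <- -0.1
  expect_equal(significant_intervals(fit), cbind(lo = 44, hi = 45))
})

test_that("swapping group coding negates the difference, intervals unchanged", {
  set.seed(22)
  curves <- matrix(stats::rnorm(12 * 101), 12, 101) +
    outer(rep(c(0, 2), each = 6), bump(seq(0, 100, 1), 40, 10))
  labs <- rep(c("good", "poor"), each = 6)
  f1 <- fit_pointwise_flr(curves, build_design(labs, reference = "good"))
  f2 <- fit_pointwise_flr(curves, build_design(labs, reference = "poor"))
  expect_equal(f1$beta_diff, -f2$beta_diff, tolerance = 1e-10)
  expect_equal(f1$significant, f2$significant, tolerance = 1e-10)
})

test_that("null coverage of the pointwise band stays near nominal", {
  # both groups share one smooth mean + iid noise; fraction of grid points
  # flagged significant should hover at the pointwise rate, not far above
  set.seed(23)
  g <- seq(0, 100, 1)
  base <- 8 * sin(2 * pi * g / 100) + 3 * bump(g, 30, 10)
  sel <- select_smoothing(
    t(replicate(36, base + stats::rnorm(101))))
  basis <- make_bspline_basis(sel$K)
  B <- eval_basis(basis, g)
  S <- B %*% solve(crossprod(B) + sel$lambda * penalty_matrix(basis),
                   t(B))
  d <- build_design(rep(c("good", "poor"), each = 18))
  frac <- vapply(seq_len(500), function(i) {
    curves <- t(replicate(36, base + stats::rnorm(101))) %*% t(S)
    fit <- fit_pointwise_flr(curves, d, g)
    mean(fit$lower > 0 | fit$upper < 0)
  }, numeric(1))
  expect_lte(mean(frac), 0.07)
})

test_that("a strong localized difference is detected over its support", {
  # bump amplitude 4x the noise SD at n = 18 per group
  set.seed(24)
  g <- seq(0, 100, 1)
  delta <- 4 * bump(g, 50, 12)
  half <- g[delta >= 2][c(1, sum(delta >= 2))]     # half-maximum support
  d <- build_design(rep(c("good", "poor"), each = 18))
  hits <- vapply(seq_len(200), function(i) {
    curves <- rbind(matrix(stats::rnorm(18 * 101), 18),
                    t(replicate(18, delta + stats::rnorm(101))))
    iv <- fit_pointwise_flr(curves, d, g)$significant
    nrow(iv) > 0 && any(iv[, 1] <= half[2] & iv[, 2] >= half[1])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
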