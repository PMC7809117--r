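# Function-on-scalar regression: y_i(t) = Z_i1 beta_ref(t) + Z_i2 beta_diff(t)
# + eps_i(t), fitted by ordinary least squares at each point of the percentile
# grid. With reference coding (good prognosis = reference), beta_diff(t) is
# the time-varying poor-minus-good group difference; a pointwise 95%
# confidence band that excludes zero marks a significant percentile interval.

#' Design matrix for the two-group functional regression
#'
#' Reference coding: column 1 is the intercept (reference = good prognosis),
#' column 2 indicates poor prognosis, so the second coefficient function
#' estimates poor minus good.
#'
#' @param labels character/factor group label per subject; must contain
#'   exactly two distinct labels.
#' @param reference label used as the reference (default `"good"`, or the
#'   first level if absent).
#' @return list with matrix `Z` (n x 2), `labels`, `reference`, `other`.
#' @export
build_design <- function(labels, reference = "good") {
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2L) stop("need exactly two groups, got ", length(lv))
  if (!reference %in% lv) reference <- lv[1]
  other <- setdiff(lv, reference)
  if (min(table(labels)) < 2L) stop("each group needs at least 2 subjects")
  Z <- cbind(intercept = 1, group = as.numeric(labels == other))
  list(Z = Z, labels = labels, reference = reference, other = other)
}

#' Pointwise function-on-scalar regression with 95% bands
#'
#' At every grid point the subject curve values are regressed on the group
#' design by OLS. The residual variance function is
#' `sigma2(t) = RSS(t) / (n - p)` and the standard error of the difference
#' coefficient comes from the (2,2) element of `sigma2(t) (Z'Z)^-1`. The 95%
#' band is `beta_diff(t) +/- crit * SE(t)` with a normal critical value by
#' default (`use_t = TRUE` switches to the t(n-p) quantile).
#'
#' @param curves numeric matrix (subjects x grid points) of curve values —
#'   typically smoothed profiles evaluated on the grid — or a list of
#'   `functional_sample`s sharing one basis.
#' @param design from [build_design()].
#' @param grid grid points (default 0..100 over the columns).
#' @param conf confidence level of the pointwise band.
#' @param use_t use Student-t instead of normal critical values.
#' @return object of class `flr_fit` with `beta_ref`, `beta_diff`, `se`,
#'   `lower`, `upper`, `sigma2`, `grid`, `significant` (list of intervals).
#' @export
fit_pointwise_flr <- function(curves, design, grid = NULL, conf = 0.95,
                              use_t = FALSE) {
  if (is.list(curves) && inherits(curves[[1]], "functional_sample")) {
    ng <- if (is.null(grid)) 101L else length(grid)
    if (is.null(grid)) {
      grid <- seq(curves[[1]]$basis$domain[1], curves[[1]]$basis$domain[2],
                  length.out = ng)
    }
    curves <- t(vapply(curves, eval_function, numeric(length(grid)), t = grid))
  } else {
    curves <- as.matrix(curves)
    if (is.null(grid)) grid <- seq(0, 100, length.out = ncol(curves))
  }
  Z <- design$Z
  n <- nrow(Z); p <- ncol(Z)
  if (nrow(curves) != n) stop("curves and design disagree on subject count")
  if (qr(Z)$rank < p) stop("design matrix is rank deficient")
  ZtZinv <- solve(crossprod(Z))
  beta <- ZtZinv %*% crossprod(Z, curves)          # p x ngrid
  res <- curves - Z %*% beta
  sigma2 <- colSums(res^2) / (n - p)
  se <- sqrt(sigma2 * ZtZinv[2, 2])
  crit <- if (use_t) stats::qt(1 - (1 - conf) / 2, df = n - p)
          else stats::qnorm(1 - (1 - conf) / 2)
  lower <- beta[2, ] - crit * se
  upper <- beta[2, ] + crit * se
  fit <- structure(
    list(grid = grid, beta_ref = beta[1, ], beta_diff = beta[2, ],
         se = se, lower = lower, upper = upper, sigma2 = sigma2,
         conf = conf, crit = crit, n = n,
         reference = design$reference, other = design$other),
    class = "flr_fit"
  )
  fit$significant <- significant_intervals(fit)
  fit
}

#' Significant percentile intervals of the group difference
#'
#' Maximal runs of consecutive grid points at which the pointwise confidence
#' band excludes zero, reported as closed percentile ranges. Single-point
#' runs are reported too.
#'
#' @param fit an `flr_fit`.
#' @return a two-column matrix `cbind(lo, hi)` in grid units (possibly with
#'   zero rows).
#' @export
significant_intervals <- function(fit) {
  stopifnot(inherits(fit, "flr_fit"))
  sig <- fit$lower > 0 | fit$upper < 0
  sig[is.na(sig)] <- FALSE
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- cbind(lo = fit$grid[starts[keep]], hi = fit$grid[ends[keep]])
  out
}

#' @export
print.flr_fit <- function(x, ...) {
  cat("Function-on-scalar regression (", x$other, " - ", x$reference,
      "), n = ", x$n, "\n", sep = "")
  cat(sprintf("  pointwise %d%% band, critical value %.3f\n",
              round(100 * x$conf), x$crit))
  if (nrow(x$significant)) {
    iv <- apply(x$significant, 1L,
                function(r) sprintf("[%g, %g]", r[1], r[2]))
    cat("  significant intervals:", paste(iv, collapse = ", "), "\n")
  } else {
    cat("  no significant intervals\n")
  }
  invisible(x)
}
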