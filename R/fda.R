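# Penalized B-spline representation of gridded profiles. A profile observed
# with noise on the percentile grid, W(t_j) = X(t_j) + e_j, is represented as
# X(t) = sum_k c_k phi_k(t) over a B-spline basis, with coefficients chosen
# to minimize  sum_j [W(t_j) - X(t_j)]^2 + lambda * int X''(t)^2 dt.
# Generalized cross-validation picks lambda and the basis dimension.

#' B-spline basis system
#'
#' Order-`order` B-splines with `K - order` equally spaced interior knots on
#' `domain` (so `K` basis functions in total). The basis is a partition of
#' unity on the domain.
#'
#' @param K number of basis functions (`K >= order`).
#' @param order spline order (degree + 1); 4 = cubic, the default.
#' @param domain numeric length-2 interval, default `c(0, 100)`.
#' @return object of class `bspline_basis`.
#' @export
make_bspline_basis <- function(K, order = 4L, domain = c(0, 100)) {
  K <- as.integer(K); order <- as.integer(order)
  if (order < 2L) stop("order must be at least 2")
  if (K < order) stop("K must be at least the spline order")
  if (length(domain) != 2L || diff(domain) <= 0) stop("bad domain")
  interior <- if (K > order) {
    seq(domain[1], domain[2], length.out = K - order + 2L)[-c(1L, K - order + 2L)]
  } else {
    numeric(0)
  }
  knots <- c(rep(domain[1], order), interior, rep(domain[2], order))
  structure(list(K = K, order = order, domain = domain, knots = knots),
            class = "bspline_basis")
}

#' Evaluate the basis (or a derivative) at points
#'
#' @param basis a `bspline_basis`.
#' @param t evaluation points inside the domain.
#' @param deriv derivative order (0 = function values).
#' @return length(t) x K matrix of basis values.
#' @export
eval_basis <- function(basis, t, deriv = 0L) {
  stopifnot(inherits(basis, "bspline_basis"))
  if (any(t < basis$domain[1] - 1e-12 | t > basis$domain[2] + 1e-12)) {
    stop("evaluation points outside the basis domain")
  }
  t <- pmin(pmax(t, basis$domain[1]), basis$domain[2])
  splines::splineDesign(basis$knots, t, ord = basis$order,
                        derivs = rep(as.integer(deriv), length(t)),
                        outer.ok = FALSE)
}

#' Roughness penalty matrix (integrated squared second derivative)
#'
#' `P[k, l] = int phi_k''(t) phi_l''(t) dt`, computed exactly by
#' Gauss-Legendre quadrature on each knot span (the integrand is a piecewise
#' polynomial of degree `2 * (order - 3)`).
#'
#' @param basis a `bspline_basis`.
#' @return K x K positive semi-definite matrix with nullspace spanned by
#'   degree-1 polynomials (for order >= 3).
#' @export
penalty_matrix <- function(basis) {
  stopifnot(inherits(basis, "bspline_basis"))
  spans <- unique(basis$knots)
  nq <- max(2L, basis$order)                       # exact for the degree needed
  P <- matrix(0, basis$K, basis$K)
  for (i in seq_len(length(spans) - 1L)) {
    gl <- pracma::gaussLegendre(nq, spans[i], spans[i + 1L])
    B2 <- eval_basis(basis, gl$x, deriv = 2L)
    P <- P + t(B2) %*% (gl$w * B2)
  }
  (P + t(P)) / 2
}

smoother_internals <- function(observations, basis, lambda, t = NULL) {
  y <- as.numeric(observations)
  n <- length(y)
  if (any(!is.finite(y))) stop("observations must be finite")
  if (!is.finite(lambda) || lambda < 0) stop("lambda must be >= 0")
  if (is.null(t)) t <- seq(basis$domain[1], basis$domain[2], length.out = n)
  B <- eval_basis(basis, t)
  P <- penalty_matrix(basis)
  # coefficients by QR on the penalty-augmented least-squares system, which
  # avoids squaring the condition number of B (critical for saturated bases)
  if (lambda > 0) {
    ep <- eigen(P, symmetric = TRUE)
    keep <- ep$values > max(ep$values, 0) * 1e-12
    Rp <- sqrt(pmax(ep$values[keep], 0)) * t(ep$vectors[, keep, drop = FALSE])
    A <- rbind(B, sqrt(lambda) * Rp)
    yy <- c(y, numeric(nrow(Rp)))
  } else {
    A <- B
    yy <- y
  }
  qa <- qr(A)
  if (qa$rank < basis$K) {
    stop("singular penalized least-squares system (rank ", qa$rank,
         " < K = ", basis$K, "); increase lambda or reduce K")
  }
  coef <- qr.coef(qa, yy)
  fitted <- as.numeric(B %*% coef)
  # df = tr(B (B'B + lambda P)^-1 B'); at lambda = 0 the hat matrix is an
  # orthogonal projection, so the trace is exactly the basis rank
  df <- if (lambda == 0) {
    min(basis$K, n)
  } else {
    M <- crossprod(B) + lambda * P
    sum(B * t(solve(M, t(B))))
  }
  list(coef = coef, fitted = fitted, rss = sum((y - fitted)^2), df = df,
       t = t, B = B)
}

#' Penalized least-squares smooth of one gridded profile
#'
#' @param observations numeric profile values, by default on an equally
#'   spaced grid spanning the basis domain.
#' @param basis a `bspline_basis`.
#' @param lambda roughness penalty weight (>= 0).
#' @param t optional observation points (defaults to a uniform grid).
#' @return object of class `functional_sample`: basis, `coefficients`,
#'   `lambda`, `rss`, `df`, `fitted`.
#' @export
penalized_smooth <- function(observations, basis, lambda, t = NULL) {
  s <- smoother_internals(observations, basis, lambda, t)
  structure(list(basis = basis, coefficients = s$coef, lambda = lambda,
                 rss = s$rss, df = s$df, fitted = s$fitted, t = s$t),
            class = "functional_sample")
}

#' Generalized cross-validation score of a smooth
#'
#' `GCV = n * RSS / (n - df)^2` with `df` the trace of the smoothing hat
#' matrix. A saturated fit (`df >= n`) returns `Inf`.
#'
#' @inheritParams penalized_smooth
#' @return scalar GCV score.
#' @export
gcv_score <- function(observations, basis, lambda, t = NULL) {
  s <- smoother_internals(observations, basis, lambda, t)
  n <- length(s$fitted)
  if (s$df >= n - 1e-8) return(Inf)
  n * s$rss / (n - s$df)^2
}

#' Select basis dimension and penalty by cohort-mean GCV
#'
#' Scores every `(K, lambda)` pair on every curve and returns the pair
#' minimizing the mean GCV across curves; ties break toward larger lambda,
#' then smaller K (prefer the smoother model).
#'
#' @param curves numeric matrix, one row per curve, columns = grid points.
#' @param K_grid candidate basis dimensions.
#' @param lambda_grid candidate penalty weights.
#' @param order spline order.
#' @param domain basis domain.
#' @return list with `K`, `lambda`, `gcv` (the achieved mean score) and the
#'   full `score` matrix (K x lambda).
#' @export
select_smoothing <- function(curves, K_grid = c(8L, 12L, 16L, 20L),
                             lambda_grid = 10^seq(-4, 6, length.out = 11),
                             order = 4L, domain = c(0, 100)) {
  curves <- as.matrix(curves)
  if (!length(K_grid) || !length(lambda_grid)) stop("empty selection grid")
  n <- ncol(curves)
  tg <- seq(domain[1], domain[2], length.out = n)
  score <- matrix(NA_real_, length(K_grid), length(lambda_grid),
                  dimnames = list(K_grid, signif(lambda_grid, 3)))
  for (a in seq_along(K_grid)) {
    basis <- make_bspline_basis(K_grid[a], order, domain)
    B <- eval_basis(basis, tg)
    P <- penalty_matrix(basis)
    BtB <- crossprod(B)
    for (b in seq_along(lambda_grid)) {
      M <- BtB + lambda_grid[b] * P
      ch <- tryCatch(chol(M), error = function(e) NULL)
      if (is.null(ch)) { score[a, b] <- Inf; next }
      Minv_Bt <- backsolve(ch, forwardsolve(t(ch), t(B)))
      S <- B %*% Minv_Bt
      df <- sum(diag(S))
      if (df >= n - 1e-8) { score[a, b] <- Inf; next }
      res <- curves - curves %*% t(S)
      score[a, b] <- mean(n * rowSums(res^2) / (n - df)^2)
    }
  }
  if (all(!is.finite(score))) stop("all GCV scores are infinite")
  best <- min(score[is.finite(score)])
  hit <- which(score <= best + 1e-12, arr.ind = TRUE)
  # prefer smoother: largest lambda, then smallest K
  hit <- hit[order(-hit[, 2], hit[, 1]), , drop = FALSE]
  pick <- hit[1, ]
  list(K = K_grid[pick[1]], lambda = lambda_grid[pick[2]],
       gcv = score[pick[1], pick[2]], score = score)
}

#' Evaluate a functional sample
#'
#' @param fs a `functional_sample`.
#' @param t evaluation points within the basis domain.
#' @return function values at `t`.
#' @export
eval_function <- function(fs, t) {
  stopifnot(inherits(fs, "functional_sample"))
  as.numeric(eval_basis(fs$basis, t) %*% fs$coefficients)
}

#' Evaluate the derivative of a functional sample
#'
#' @inheritParams eval_function
#' @param deriv derivative order (default 1).
#' @return derivative values at `t`.
#' @export
eval_derivative <- function(fs, t, deriv = 1L) {
  stopifnot(inherits(fs, "functional_sample"))
  as.numeric(eval_basis(fs$basis, t, deriv = deriv) %*% fs$coefficients)
}
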