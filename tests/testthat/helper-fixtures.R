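# Shared fixture builders; everything is generated in code.

# a landmark series whose three landmarks are all static (plus optional noise)
static_series <- function(n = 20, hyoid = c(150, 90), c2 = c(100, 40),
                          c4 = c(100, 100), fps = 30) {
  one <- function(p) matrix(p, n, 2, byrow = TRUE)
  landmark_series((seq_len(n) - 1) / fps, one(hyoid), one(c2), one(c4),
                  y_axis_convention = "image-down")
}

# random rigid 2-D transform (rotation + translation) applied to pixel points
random_rigid <- function() {
  th <- stats::runif(1, -pi, pi)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  tr <- stats::runif(2, -50, 50)
  function(p) sweep(p %*% t(R), 2, -tr)
}

# a bare kinematic profile from displacement vectors on the 0..100 grid
profile_from_disp <- function(dx, dy, duration_s = 1.76) {
  stopifnot(length(dx) == length(dy))
  structure(
    list(grid = seq(0, 100, length.out = length(dx)), disp_x = dx,
         disp_y = dy, vel_x = NULL, vel_y = NULL, angle = NULL,
         duration_s = duration_s),
    class = "kinematic_profile"
  )
}

# trajectory with a crisp onset/offset: still, then a linear dash, then still
dash_trajectory <- function(n_lead = 5, n_move = 30, n_tail = 10, fps = 30,
                            reach = c(10, 15)) {
  n <- n_lead + n_move + n_tail
  frac <- c(rep(0, n_lead), seq(0, 1, length.out = n_move), rep(1, n_tail))
  pos <- cbind(frac * reach[1], frac * reach[2])
  structure(list(time = (seq_len(n) - 1) / fps, position_mm = pos,
                 rebased = FALSE),
            class = "anatomical_trajectory")
}
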