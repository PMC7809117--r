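# Anatomical-frame geometry: pixel landmarks -> mm trajectories in the C2-C4
# frame. The local frame has its origin at the C4 anteroinferior vertex and
# its vertical (+y, superior) axis through the C2 anteroinferior vertex; +x
# points anteriorly. Built per frame so that rigid neck motion cancels.

#' Landmark frame series
#'
#' Container for raw per-frame pixel coordinates of the three tracked
#' landmarks in a lateral VFSS recording: the hyoid bone and the
#' anteroinferior vertices of the C2 and C4 vertebrae.
#'
#' @param time numeric vector of frame timestamps in seconds, strictly
#'   increasing.
#' @param hyoid_px,c2_px,c4_px numeric matrices (n x 2) of pixel coordinates.
#' @param y_axis_convention `"image-down"` (pixel y grows downwards, the usual
#'   image convention) or `"math-up"`.
#' @return An object of class `landmark_series`.
#' @export
landmark_series <- function(time, hyoid_px, c2_px, c4_px,
                            y_axis_convention = c("image-down", "math-up")) {
  y_axis_convention <- match.arg(y_axis_convention)
  hyoid_px <- as_xy_matrix(hyoid_px, "hyoid_px")
  c2_px <- as_xy_matrix(c2_px, "c2_px")
  c4_px <- as_xy_matrix(c4_px, "c4_px")
  n <- length(time)
  if (n < 1L) stop("empty landmark series")
  if (nrow(hyoid_px) != n || nrow(c2_px) != n || nrow(c4_px) != n) {
    stop("landmark coordinate sequences must all have length(time) rows")
  }
  if (any(!is.finite(time)) || any(diff(time) <= 0)) {
    stop("time must be finite and strictly increasing")
  }
  if (any(!is.finite(hyoid_px)) || any(!is.finite(c2_px)) ||
      any(!is.finite(c4_px))) {
    stop("landmark coordinates must be finite (no missing frames)")
  }
  structure(
    list(time = as.numeric(time), hyoid_px = hyoid_px, c2_px = c2_px,
         c4_px = c4_px, y_axis_convention = y_axis_convention),
    class = "landmark_series"
  )
}

as_xy_matrix <- function(p, what) {
  p <- as.matrix(p)
  if (ncol(p) != 2L) stop(what, " must have two columns (x, y)")
  storage.mode(p) <- "double"
  unname(p)
}

#' Scale calibration from a reference coin
#'
#' @param coin_px measured pixel diameter of the reference coin.
#' @param coin_mm physical diameter in mm; defaults to 23.5 (Korean 100-won
#'   coin used as the in-image reference object).
#' @return Object of class `scale_calibration`.
#' @export
scale_calibration <- function(coin_px, coin_mm = 23.5) {
  if (!is.finite(coin_px) || coin_px <= 0) {
    stop("calibration error: coin_px must be a positive finite pixel length")
  }
  if (!is.finite(coin_mm) || coin_mm <= 0) stop("coin_mm must be positive")
  structure(list(coin_px = coin_px, coin_mm = coin_mm),
            class = "scale_calibration")
}

#' Millimetres per pixel from a coin calibration
#'
#' @param cal a [scale_calibration()].
#' @return mm-per-pixel scalar (`coin_mm / coin_px`).
#' @export
compute_scale_factor <- function(cal) {
  stopifnot(inherits(cal, "scale_calibration"))
  cal$coin_mm / cal$coin_px
}

#' Rigid transform from image pixels to the C2-C4 anatomical frame
#'
#' Maps C4 to the origin and C2 onto the positive vertical axis (superior
#' = +y), preserving distances. The anterior (+x) direction is the
#' perpendicular on the side of `anterior_hint` — typically the hyoid, which
#' lies anterior to the vertebral column in a lateral view.
#'
#' @param c2,c4 length-2 pixel coordinates of the vertebral landmarks.
#' @param anterior_hint length-2 pixel point known to lie anteriorly.
#' @param y_axis_convention pixel y-axis convention, see [landmark_series()].
#' @param handedness optional +1/-1 overriding the hint-based orientation
#'   (used internally to keep one chirality across frames).
#' @return A list with rotation matrix `R` (rows are the anatomical axes),
#'   origin `origin` (C4 after y-convention resolution), and `handedness`.
#'   Apply with [apply_frame_transform()].
#' @export
build_frame_transform <- function(c2, c4, anterior_hint = NULL,
                                  y_axis_convention = "image-down",
                                  handedness = NULL) {
  flip <- identical(y_axis_convention, "image-down")
  fy <- function(p) if (flip) c(p[1], -p[2]) else as.numeric(p)
  c2 <- fy(c2); c4 <- fy(c4)
  axis <- c2 - c4
  d <- sqrt(sum(axis^2))
  if (d < .Machine$double.eps^0.5) {
    stop("degenerate axis: C2 and C4 coincide")
  }
  ey <- axis / d
  # rotating ey by -90 deg gives one perpendicular; handedness picks the side
  ex0 <- c(ey[2], -ey[1])
  if (is.null(handedness)) {
    if (is.null(anterior_hint)) stop("need anterior_hint or handedness")
    h <- fy(anterior_hint) - c4
    s <- sum(ex0 * h)
    if (abs(s) < .Machine$double.eps^0.5 * max(1, d)) {
      stop("ambiguous orientation: anterior_hint lies on the C2-C4 axis")
    }
    handedness <- sign(s)
  }
  R <- rbind(handedness * ex0, ey)
  list(R = R, origin = c4, handedness = handedness, flip_y = flip)
}

#' Apply an anatomical frame transform to pixel points
#'
#' @param tf transform from [build_frame_transform()].
#' @param p length-2 point or n x 2 matrix of pixel coordinates (original
#'   convention; the transform resolves the y flip itself).
#' @return transformed coordinates, same shape as `p`.
#' @export
apply_frame_transform <- function(tf, p) {
  one <- is.null(dim(p))
  p <- if (one) matrix(as.numeric(p), 1L) else as.matrix(p)
  if (tf$flip_y) p[, 2] <- -p[, 2]
  out <- sweep(p, 2L, tf$origin) %*% t(tf$R)
  if (one) as.numeric(out) else out
}

#' Convert a landmark series to an anatomical-frame trajectory in mm
#'
#' A fresh C2-C4 transform is built for every frame (so rigid neck motion is
#' removed image by image) and the hyoid position is expressed in mm through
#' the coin scale factor. The anterior sign is resolved once, from the first
#' frame's hyoid, and that chirality is kept for all frames.
#'
#' @param series a [landmark_series()].
#' @param cal a [scale_calibration()].
#' @param reference_frame optional frame index; when given, a single transform
#'   built from that frame's C2/C4 is applied to every frame instead of the
#'   default per-frame adjustment.
#' @return Object of class `anatomical_trajectory`: `time` (s),
#'   `position_mm` (n x 2; x anterior+, y superior+), `rebased` flag.
#' @export
to_anatomical <- function(series, cal, reference_frame = NULL) {
  stopifnot(inherits(series, "landmark_series"))
  mmpp <- compute_scale_factor(cal)
  n <- length(series$time)
  tf1 <- tryCatch(
    build_frame_transform(series$c2_px[1, ], series$c4_px[1, ],
                          anterior_hint = series$hyoid_px[1, ],
                          y_axis_convention = series$y_axis_convention),
    error = function(e) stop("frame 1: ", conditionMessage(e))
  )
  pos <- matrix(NA_real_, n, 2L)
  if (!is.null(reference_frame)) {
    if (reference_frame < 1L || reference_frame > n) {
      stop("reference_frame out of range")
    }
    tf <- tryCatch(
      build_frame_transform(series$c2_px[reference_frame, ],
                            series$c4_px[reference_frame, ],
                            y_axis_convention = series$y_axis_convention,
                            handedness = tf1$handedness),
      error = function(e) {
        stop("frame ", reference_frame, ": ", conditionMessage(e))
      })
    pos <- apply_frame_transform(tf, series$hyoid_px)
  } else {
    for (i in seq_len(n)) {
      tf <- tryCatch(
        build_frame_transform(series$c2_px[i, ], series$c4_px[i, ],
                              y_axis_convention = series$y_axis_convention,
                              handedness = tf1$handedness),
        error = function(e) stop("frame ", i, ": ", conditionMessage(e))
      )
      pos[i, ] <- apply_frame_transform(tf, series$hyoid_px[i, ])
    }
  }
  structure(
    list(time = series$time, position_mm = pos * mmpp, rebased = FALSE),
    class = "anatomical_trajectory"
  )
}

#' Rebase a trajectory so the swallow start point is the origin
#'
#' @param traj an `anatomical_trajectory`.
#' @param start_frame frame index taken as the start of the swallow.
#' @return the trajectory shifted so `position_mm[start_frame, ] == c(0, 0)`,
#'   with `rebased = TRUE`. Idempotent for a fixed `start_frame`.
#' @export
rebase_to_start <- function(traj, start_frame) {
  stopifnot(inherits(traj, "anatomical_trajectory"))
  n <- nrow(traj$position_mm)
  if (start_frame < 1L || start_frame > n) stop("start_frame out of range")
  traj$position_mm <- sweep(traj$position_mm, 2L,
                            traj$position_mm[start_frame, ])
  traj$rebased <- TRUE
  traj
}
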