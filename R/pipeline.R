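# End-to-end pipeline plumbing: landmark CSV dialect, cohort manifest,
# and the three workflow stages (simulate -> extract -> analyze) used by the
# numbered scripts under analysis/. All stages are plain functions so tests
# can drive them in memory or on disk.

#' Write a landmark series to CSV
#'
#' Columns: `frame, t_sec, hx, hy, c2x, c2y, c4x, c4y` (pixel coordinates in
#' the series' own y-axis convention).
#'
#' @param series a [landmark_series()].
#' @param path output file.
#' @export
write_landmarks <- function(series, path) {
  df <- data.frame(
    frame = seq_along(series$time), t_sec = series$time,
    hx = series$hyoid_px[, 1], hy = series$hyoid_px[, 2],
    c2x = series$c2_px[, 1], c2y = series$c2_px[, 2],
    c4x = series$c4_px[, 1], c4y = series$c4_px[, 2]
  )
  utils::write.csv(df, path, row.names = FALSE)
}

#' Read a landmark series from CSV
#'
#' @param path CSV written by [write_landmarks()] (or any file with the same
#'   columns).
#' @param y_axis_convention pixel y-axis convention of the file.
#' @return a [landmark_series()].
#' @export
read_landmarks <- function(path, y_axis_convention = "image-down") {
  df <- utils::read.csv(path)
  need <- c("t_sec", "hx", "hy", "c2x", "c2y", "c4x", "c4y")
  if (!all(need %in% names(df))) {
    stop("landmark file ", path, " lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  landmark_series(df$t_sec, cbind(df$hx, df$hy), cbind(df$c2x, df$c2y),
                  cbind(df$c4x, df$c4y), y_axis_convention)
}

#' Simulate a synthetic cohort to disk
#'
#' Writes one landmark CSV per subject, a cohort manifest
#' (`subject_id, landmark_file, group, coin_px, fps`), the per-subject ground
#' truth, and the full config echoed as YAML (re-ingestable to reproduce the
#' run).
#'
#' @param config a [synthetic_cohort_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the in-memory cohort from [generate_cohort()] plus the
#'   manifest path.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config)
  n <- length(cohort$subjects)
  ids <- sprintf("S%03d", seq_len(n))
  files <- file.path(out_dir, paste0(ids, "_landmarks.csv"))
  for (i in seq_len(n)) write_landmarks(cohort$subjects[[i]], files[i])
  manifest <- data.frame(
    subject_id = ids, landmark_file = basename(files),
    group = cohort$labels, coin_px = cohort$calibration$coin_px,
    fps = config$fps
  )
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  truth <- do.call(rbind, lapply(seq_len(n), function(i) {
    tr <- cohort$truth[[i]]
    data.frame(subject_id = ids[i], F = tr$F, B = tr$B, U = tr$U,
               duration_s = tr$duration_s,
               window_start = tr$window[1], window_end = tr$window[2])
  }))
  utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  cfg <- cohort$config
  cfg$timings <- unclass(cfg$timings)
  yaml::write_yaml(lapply(unclass(cfg), function(v)
    if (is.numeric(v)) as.numeric(v) else v),
    file.path(out_dir, "config.yaml"))
  invisible(c(cohort, list(manifest = manifest_path)))
}

extract_one <- function(series, cal, manual = NULL, n_grid = 101L,
                        speed_threshold = 10, dwell = 3L) {
  traj <- to_anatomical(series, cal)
  kinematic_profile(traj, manual = manual, n_grid = n_grid,
                    speed_threshold = speed_threshold, dwell = dwell)
}

#' Extract kinematic profiles for a whole cohort
#'
#' Runs geometry -> window detection -> rebasing -> temporal normalization ->
#' velocity -> direction angle -> summary for every subject. Per-subject
#' failures are collected (not fatal) and reported in the result.
#'
#' @param cohort either the list returned by [generate_cohort()] /
#'   [run_simulate()] or a manifest CSV path.
#' @param dir directory holding the landmark files when `cohort` is a
#'   manifest path.
#' @param out_dir optional; when given, per-subject kinematics CSVs
#'   (`grid, disp_x, disp_y, vel_x, vel_y, angle`) and the cohort summary
#'   CSV are written there.
#' @param windows optional list of manual `c(start, end)` windows keyed by
#'   subject index.
#' @param ... tuning arguments passed to [kinematic_profile()].
#' @return list with `profiles` (per subject), `summaries` (one row each),
#'   `labels`, `errors` (named list of failure messages).
#' @export
run_extract <- function(cohort, dir = NULL, out_dir = NULL, windows = NULL,
                        ...) {
  if (is.character(cohort)) {
    manifest <- utils::read.csv(cohort)
    if (is.null(dir)) dir <- dirname(cohort)
    # defer reading so one bad file cannot sink the whole cohort
    subjects <- lapply(file.path(dir, manifest$landmark_file), function(f) {
      function() {
        if (!file.exists(f)) stop("missing landmark file: ", basename(f))
        read_landmarks(f)
      }
    })
    labels <- manifest$group
    cal <- scale_calibration(manifest$coin_px[1])
    ids <- manifest$subject_id
  } else {
    subjects <- cohort$subjects
    labels <- cohort$labels
    cal <- cohort$calibration
    ids <- sprintf("S%03d", seq_along(subjects))
  }
  profiles <- vector("list", length(subjects))
  errors <- list()
  for (i in seq_along(subjects)) {
    manual <- if (!is.null(windows)) windows[[i]] else NULL
    profiles[[i]] <- tryCatch({
      s <- if (is.function(subjects[[i]])) subjects[[i]]() else subjects[[i]]
      extract_one(s, cal, manual = manual, ...)
    }, error = function(e) {
      errors[[ids[i]]] <<- conditionMessage(e)
      NULL
    })
  }
  ok <- !vapply(profiles, is.null, logical(1))
  summaries <- do.call(rbind, lapply(which(ok), function(i) {
    cbind(data.frame(subject_id = ids[i], group = labels[i]),
          summarize_profile(profiles[[i]]))
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in which(ok)) {
      pr <- profiles[[i]]
      utils::write.csv(
        data.frame(grid = pr$grid, disp_x = pr$disp_x, disp_y = pr$disp_y,
                   vel_x = pr$vel_x, vel_y = pr$vel_y, angle = pr$angle),
        file.path(out_dir, paste0(ids[i], "_kinematics.csv")),
        row.names = FALSE)
    }
    utils::write.csv(summaries, file.path(out_dir, "cohort_summaries.csv"),
                     row.names = FALSE)
  }
  list(profiles = profiles, summaries = summaries, labels = labels,
       ids = ids, errors = errors)
}

profile_signal <- function(profile, signal) {
  switch(signal,
         disp_x = profile$disp_x, disp_y = profile$disp_y,
         vel_x = profile$vel_x, vel_y = profile$vel_y,
         angle = profile$angle,
         stop("unknown signal ", signal))
}

#' Functional regression analysis of an extracted cohort
#'
#' For each kinematic signal (`disp_x, disp_y, vel_x, vel_y, angle`): one
#' cohort-wide `(K, lambda)` is selected by mean GCV, every subject profile
#' is smoothed with it, and the two-group function-on-scalar regression is
#' fitted with pointwise 95% bands and significant percentile intervals.
#' Also produces the discrete cohort summary table.
#'
#' @param extract result of [run_extract()] (failed subjects are dropped).
#' @param signals kinematic signals to analyze.
#' @param K_grid,lambda_grid smoothing selection grids, see
#'   [select_smoothing()].
#' @param method two-sample test policy for the summary table.
#' @param out_dir optional; when given, per-signal FLR CSVs
#'   (`grid, beta_ref, beta_diff, se, lo95, hi95, significant`), a
#'   significant-interval report, the summary table, and a smoothing log are
#'   written there.
#' @return list with `flr` (per-signal `flr_fit`s), `smoothing` (per-signal
#'   selected K/lambda/df), `summary_table`, `labels`.
#' @export
run_analyze <- function(extract,
                        signals = c("disp_x", "disp_y", "vel_x", "vel_y",
                                    "angle"),
                        K_grid = c(8L, 12L, 16L, 20L),
                        lambda_grid = 10^seq(-4, 6, length.out = 11),
                        method = "auto", out_dir = NULL) {
  ok <- !vapply(extract$profiles, is.null, logical(1))
  profiles <- extract$profiles[ok]
  labels <- extract$labels[ok]
  if (length(unique(labels)) != 2L || min(table(labels)) < 2L) {
    stop("functional regression needs two groups with >= 2 subjects each")
  }
  design <- build_design(labels)
  grid <- profiles[[1]]$grid
  flr <- list(); smoothing <- list()
  for (sg in signals) {
    curves <- t(vapply(profiles, profile_signal, numeric(length(grid)),
                       signal = sg))
    if (anyNA(curves)) {
      # undefined angles (speed under the floor) are bridged by linear
      # interpolation before smoothing
      curves <- t(apply(curves, 1L, function(v) {
        if (anyNA(v)) v <- stats::approx(grid[!is.na(v)], v[!is.na(v)],
                                         xout = grid, rule = 2)$y
        v
      }))
    }
    sel <- select_smoothing(curves, K_grid, lambda_grid)
    basis <- make_bspline_basis(sel$K)
    smooth_curves <- t(apply(curves, 1L, function(v) {
      penalized_smooth(v, basis, sel$lambda)$fitted
    }))
    fit <- fit_pointwise_flr(smooth_curves, design, grid)
    flr[[sg]] <- fit
    smoothing[[sg]] <- list(K = sel$K, lambda = sel$lambda, gcv = sel$gcv)
  }
  # extract$summaries already holds only successfully processed subjects
  summary_table <- summarize_cohort(
    extract$summaries[, !(names(extract$summaries) %in%
                            c("subject_id", "group")), drop = FALSE],
    extract$summaries$group, method = method)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    iv_rows <- list()
    for (sg in signals) {
      fit <- flr[[sg]]
      sig <- fit$lower > 0 | fit$upper < 0
      utils::write.csv(
        data.frame(grid = fit$grid, beta_ref = fit$beta_ref,
                   beta_diff = fit$beta_diff, se = fit$se,
                   lo95 = fit$lower, hi95 = fit$upper, significant = sig),
        file.path(out_dir, paste0("flr_", sg, ".csv")), row.names = FALSE)
      if (nrow(fit$significant)) {
        iv_rows[[sg]] <- data.frame(signal = sg,
                                    lo = fit$significant[, 1],
                                    hi = fit$significant[, 2])
      }
    }
    iv <- if (length(iv_rows)) do.call(rbind, iv_rows) else
      data.frame(signal = character(), lo = numeric(), hi = numeric())
    utils::write.csv(iv, file.path(out_dir, "significant_intervals.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_table, file.path(out_dir, "summary_table.csv"),
                     row.names = FALSE)
    sm_log <- do.call(rbind, lapply(names(smoothing), function(sg) {
      data.frame(signal = sg, K = smoothing[[sg]]$K,
                 lambda = smoothing[[sg]]$lambda, gcv = smoothing[[sg]]$gcv)
    }))
    utils::write.csv(sm_log, file.path(out_dir, "smoothing_log.csv"),
                     row.names = FALSE)
  }
  list(flr = flr, smoothing = smoothing, summary_table = summary_table,
       labels = labels)
}
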