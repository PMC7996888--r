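pipeline_defaults <- function() list(
  input = NULL,                 # path to a frame directory/file
  synthetic_spec = NULL,        # a synthetic_wound_spec (alternative input)
  method = "texture",           # "texture" | "otsu" | "imagej"
  front_dir = NULL,             # imagej method: directory of <side>_%03d.txt
  out_dir = NULL,               # optional output directory
  sides = c("L", "R"),
  frame_interval = 0.25,
  pixel_size = 1.0,
  frame_range = NULL,
  clahe_tile_size = c(50L, 50L),
  clahe_clip_limit = 40,
  lbp_tile_height = 12L,
  lbp_tile_width = 16L,
  pca_n_components = 5L,
  gmm_seed = 0L,
  labeling = "auto",
  fit_on = "each",              # classifier per frame, or "first"
  otsu_blur_sigma = 2,
  otsu_morph_radius = 5L,
  n_particles = 103L,
  drift_window = NULL,          # c(t_low, t_high) hours; NULL = auto-detect
  write_masks = FALSE)

#' Validate a pipeline configuration
#'
#' Merges user settings over the documented defaults; unknown keys are
#' rejected with the offending key named.
#'
#' @param config named list of settings (possibly empty).
#' @return validated full configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (!cfg$method %in% c("texture", "otsu", "imagej"))
    stop("method must be texture, otsu or imagej", call. = FALSE)
  if (!all(cfg$sides %in% c("L", "R")))
    stop("sides must be a subset of c('L', 'R')", call. = FALSE)
  structure(cfg, class = c("pipeline_config", "list"))
}

read_front_dir <- function(front_dir, side, n_frames) {
  lapply(seq_len(n_frames) - 1L, function(k) {
    path <- file.path(front_dir, sprintf("%s_%03d.txt", side, k))
    if (!file.exists(path))
      stop("missing hand-traced front file: ", path, call. = FALSE)
    read_imagej_front(path, side, frame_index = k)
  })
}

#' Run the full wound-tracking pipeline
#'
#' Executes, per frame: contrast equalization, binarization (texture
#' classifier or Otsu baseline) or reading of hand-traced fronts, wound-edge
#' extraction, then pseudo-particle tracking, SPT statistics and model fits.
#' Frames after the fronts merge (wound closed) are dropped with a recorded
#' warning, truncating M for the downstream statistics. When `out_dir` is
#' set, fronts, trajectories, statistics, fit tables, the area series and a
#' machine-readable JSON run report are written there.
#'
#' @param config a [pipeline_config()] or plain named list of settings.
#' @return object of class `pipeline_run`: per-side `fronts`,
#'   `trajectories` (centred, right side mirrored), `statistics` (tidy data
#'   frame), `area`, `fits`, plus `config`, `warnings` and `report`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  warnings <- character(0)
  note <- function(msg) warnings <<- c(warnings, msg)
  stages <- character(0)

  # ---- input ---------------------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$synthetic_spec)) {
    spec <- cfg$synthetic_spec
    stopifnot(inherits(spec, "synthetic_wound_spec"))
    truth <- generate_ground_truth_fronts(spec)
    stack <- render_frames(truth, spec)
    cfg$frame_interval <- spec$frame_interval
  } else if (!is.null(cfg$input)) {
    stack <- load_time_lapse(cfg$input, frame_interval = cfg$frame_interval,
                             pixel_size = cfg$pixel_size,
                             frame_range = cfg$frame_range)
  } else if (cfg$method != "imagej") {
    stop("config needs `input` or `synthetic_spec`", call. = FALSE)
  } else stack <- NULL
  if (cfg$pixel_size == 1)
    note("pixel_size defaulted to 1: positions in px, velocities in px/frame")
  stages <- c(stages, "load")

  # ---- segmentation + front extraction ------------------------------------
  fronts <- list(L = list(), R = list())
  masks <- list()
  if (cfg$method == "imagej") {
    if (is.null(cfg$front_dir))
      stop("method 'imagej' needs `front_dir`", call. = FALSE)
    n_frames <- if (!is.null(stack)) length(stack$frames) else
      length(list.files(cfg$front_dir, pattern = "^L_\\d+\\.txt$"))
    for (s in cfg$sides)
      fronts[[s]] <- read_front_dir(cfg$front_dir, s, n_frames)
    stages <- c(stages, "read_fronts")
  } else {
    eq <- equalize_stack(stack, tile_size = cfg$clahe_tile_size,
                         clip_limit = cfg$clahe_clip_limit)
    stages <- c(stages, "equalize")
    grid <- tessellate(c(stack$height, stack$width),
                       tile_height = cfg$lbp_tile_height,
                       tile_width = cfg$lbp_tile_width)
    classifier <- NULL
    for (k in seq_along(eq$frames)) {
      fr <- eq$frames[[k]]
      if (cfg$method == "texture") {
        if (is.null(classifier) || cfg$fit_on == "each") {
          feats <- extract_features(lbp_image(fr), grid)
          classifier <- fit_texture_classifier(
            feats, n_pca = cfg$pca_n_components, seed = cfg$gmm_seed,
            labeling = cfg$labeling)
        }
        mask <- binarize_frame(fr, classifier, grid, frame_index = k - 1L)
      } else {
        mask <- otsu_segment(fr, blur_sigma = cfg$otsu_blur_sigma,
                             morph_radius = cfg$otsu_morph_radius,
                             frame_index = k - 1L)
      }
      masks[[k]] <- mask
      sp <- tryCatch(split_fronts(extract_wound_contour(mask),
                                  frame_index = k - 1L),
                     error = function(e) e)
      if (inherits(sp, "error")) {
        note(sprintf("frame %d: %s; truncating analysis at M = %d frames",
                     k - 1L, conditionMessage(sp), k - 1L))
        break
      }
      fronts$L[[k]] <- sp$L
      fronts$R[[k]] <- sp$R
    }
    stages <- c(stages, "binarize", "extract_fronts")
  }
  M <- min(vapply(cfg$sides, function(s) length(fronts[[s]]), integer(1)))
  if (M < 3L) stop("fewer than 3 analyzable frames; cannot track",
                   call. = FALSE)
  frame_width <- if (!is.null(stack)) stack$width else
    max(vapply(fronts[[cfg$sides[length(cfg$sides)]]][seq_len(M)],
               function(f) max(f$points[, 1L]), numeric(1)))

  # ---- tracking + statistics + fits ----------------------------------------
  dt <- cfg$frame_interval
  trajectories <- list(); statistics <- list(); fits <- list()
  for (s in cfg$sides) {
    traj <- build_trajectories(fronts[[s]][seq_len(M)], n = cfg$n_particles,
                               frame_interval = dt,
                               pixel_size = cfg$pixel_size)
    if (s == "R") traj <- mirror_right_front(traj, frame_width)
    traj <- center_initial_position(traj)
    trajectories[[s]] <- traj
    t_pos <- trajectory_times(traj)
    vel <- velocity(traj); acc <- acceleration(vel)
    t_vel <- t_pos[-1L] - dt / 2
    t_acc <- t_pos[-(1:2)] - dt
    mean_x <- ensemble_mean(traj)
    mean_v <- ensemble_mean(vel)
    window <- if (is.null(cfg$drift_window))
      detect_drift_window(mean_x, t_pos) else cfg$drift_window
    drift <- fit_drift(mean_x, t_pos, window)
    in_win <- t_acc > window[1L] & t_acc < window[2L]
    abs_dv <- abs(as.vector(acc[, in_win, drop = FALSE]))
    tails <- tryCatch(fit_increment_tails(abs_dv), error = function(e) {
      note(sprintf("side %s: increment-tail fit failed: %s", s,
                   conditionMessage(e)))
      NULL
    })
    fits[[s]] <- list(drift = drift, tails = tails, window = window)
    tidy <- function(q, lag, t, val)
      data.frame(quantity = q, side = s, lag_or_frame = lag, time_h = t,
                 value = val)
    statistics[[s]] <- rbind(
      tidy("mean_x", seq_along(mean_x) - 1L, t_pos, mean_x),
      tidy("mean_v", seq_along(mean_v) - 1L, t_vel, mean_v),
      tidy("mean_a", seq_len(ncol(acc)) - 1L, t_acc, ensemble_mean(acc)),
      tidy("std_a", seq_len(ncol(acc)) - 1L, t_acc, ensemble_std_series(acc)),
      tidy("acf_x", seq_along(mean_x) - 1L, t_pos, ensemble_acf(traj)),
      tidy("acf_v", seq_along(mean_v) - 1L, t_vel, ensemble_acf(vel)),
      tidy("msd_x", seq_along(mean_x) - 1L, t_pos,
           mean_squared_displacement(traj)),
      tidy("msd_v", seq_along(mean_v) - 1L, t_vel,
           mean_squared_displacement(vel)))
  }
  area <- if (all(c("L", "R") %in% cfg$sides))
    wound_area_series(fronts$L[seq_len(M)], fronts$R[seq_len(M)],
                      frame_interval = dt) else NULL
  stages <- c(stages, "track", "statistics", "fit")

  run <- structure(list(
    config = cfg, fronts = fronts, masks = masks, truth = truth,
    trajectories = trajectories, statistics = do.call(rbind, statistics),
    area = area, fits = fits, n_frames = M, frame_width = frame_width,
    warnings = warnings,
    report = list(stages = stages, n_frames = M,
                  n_particles = cfg$n_particles, method = cfg$method,
                  sides = cfg$sides, warnings = warnings)),
    class = "pipeline_run")
  if (!is.null(cfg$out_dir)) write_run(run, cfg$out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("pipeline_run [%s]: %d frames, %d particles, sides %s\n",
              x$config$method, x$n_frames, x$config$n_particles,
              paste(x$config$sides, collapse = "/")))
  for (s in names(x$fits)) {
    f <- x$fits[[s]]$drift
    cat(sprintf("  %s: vd = %.3g +/- %.2g /h, tau1 = %.3g +/- %.2g h, adj R^2 = %.3f\n",
                s, f$params["vd"], f$std_errors["vd"], f$params["tau1"],
                f$std_errors["tau1"], f$adj_r_squared))
  }
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

trajectories_long <- function(run) {
  do.call(rbind, lapply(names(run$trajectories), function(s) {
    tr <- run$trajectories[[s]]
    data.frame(side = s,
               particle = rep(seq_len(tr$n_particles), tr$n_frames),
               frame = rep(seq_len(tr$n_frames) - 1L, each = tr$n_particles),
               x = as.vector(tr$x), y = as.vector(tr$y))
  }))
}

fits_table <- function(run) {
  rows <- list()
  for (s in names(run$fits)) {
    f <- run$fits[[s]]
    add <- function(fr) if (!is.null(fr))
      data.frame(side = s, model = fr$model,
                 parameter = names(fr$params), estimate = unname(fr$params),
                 std_error = unname(fr$std_errors),
                 adj_r_squared = fr$adj_r_squared,
                 window_low = fr$window[1L], window_high = fr$window[2L],
                 n_points = fr$n_points)
    rows <- c(rows, list(add(f$drift)),
              if (!is.null(f$tails)) list(add(f$tails$half_gaussian),
                                          add(f$tails$exponential)))
  }
  do.call(rbind, rows)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fdir <- file.path(out_dir, "fronts")
  dir.create(fdir, showWarnings = FALSE)
  for (s in names(run$fronts)) {
    for (fr in run$fronts[[s]]) {
      if (is.null(fr)) next
      write_front(fr, file.path(fdir, sprintf("%s_%03d.txt", s,
                                              fr$frame_index)))
    }
  }
  utils::write.csv(trajectories_long(run),
                   file.path(out_dir, "trajectories.csv"), row.names = FALSE)
  utils::write.csv(run$statistics, file.path(out_dir, "statistics.csv"),
                   row.names = FALSE)
  utils::write.csv(fits_table(run), file.path(out_dir, "fits.csv"),
                   row.names = FALSE)
  if (!is.null(run$area))
    utils::write.csv(run$area, file.path(out_dir, "area.csv"),
                     row.names = FALSE)
  if (isTRUE(run$config$write_masks) && length(run$masks)) {
    mdir <- file.path(out_dir, "masks")
    dir.create(mdir, showWarnings = FALSE)
    for (m in run$masks)
      write_pgm(m$mask * 255L,
                file.path(mdir, sprintf("mask_%03d.pgm", m$frame_index)))
  }
  report <- run$report
  report$config <- run$config[!vapply(run$config, is.object, logical(1))]
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Cross-method agreement table for two pipeline runs
#'
#' Pearson correlations, per side, of the pooled pseudo-particle x and y
#' coordinate collections and of the ensemble mean position, velocity and
#' velocity-increment series of two runs over the same data (e.g. texture
#' analysis versus hand-traced fronts).
#'
#' @param run_a,run_b `pipeline_run` objects or output directories written by
#'   [run_pipeline()] (their `trajectories.csv` is read back).
#' @return data.frame with columns `side`, `variable`, `pearson_r`,
#'   `p_value`, `n`.
#' @export
compare_runs <- function(run_a, run_b) {
  get_traj <- function(r) {
    if (inherits(r, "pipeline_run")) return(trajectories_long(r))
    f <- file.path(r, "trajectories.csv")
    if (!file.exists(f)) stop("no trajectories.csv under ", r, call. = FALSE)
    utils::read.csv(f)
  }
  ta <- get_traj(run_a); tb <- get_traj(run_b)
  rows <- list()
  for (s in intersect(unique(ta$side), unique(tb$side))) {
    a <- ta[ta$side == s, ]; b <- tb[tb$side == s, ]
    a <- a[order(a$frame, a$particle), ]; b <- b[order(b$frame, b$particle), ]
    if (nrow(a) != nrow(b))
      stop("runs have mismatched N x M for side ", s, call. = FALSE)
    xa <- matrix(a$x, nrow = max(a$particle)); xb <- matrix(b$x, nrow = max(b$particle))
    ya <- matrix(a$y, nrow = max(a$particle)); yb <- matrix(b$y, nrow = max(b$particle))
    pairs <- list(
      x_coords = list(xa, xb),
      y_coords = list(ya, yb),
      mean_X = list(colMeans(xa), colMeans(xb)),
      mean_V = list(colMeans(velocity(xa)), colMeans(velocity(xb))),
      mean_A = list(colMeans(acceleration(velocity(xa))),
                    colMeans(acceleration(velocity(xb)))))
    for (v in names(pairs)) {
      cr <- compare_methods(pairs[[v]][[1L]], pairs[[v]][[2L]], variable = v)
      rows <- c(rows, list(data.frame(side = s, variable = v,
                                      pearson_r = cr$pearson_r,
                                      p_value = cr$p_value, n = cr$n)))
    }
  }
  do.call(rbind, rows)
}
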