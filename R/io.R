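#' Write / read EIT voltage frame series
#'
#' Frames travel as plain CSV with a single header line: column `t` (seconds,
#' time-sorted) followed by one column per pattern entry (`v1`..`v208` for
#' the 16-electrode band). Round-trips are lossless to full double precision.
#'
#' @param frames Matrix of frames, one per row.
#' @param t Timestamps in seconds, non-decreasing, one per frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_frames <- function(frames, t, path) {
  stopifnot(is.matrix(frames), length(t) == nrow(frames))
  df <- data.frame(t = t, frames)
  names(df) <- c("t", paste0("v", seq_len(ncol(frames))))
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_frames
#' @param pattern Optional `eit_pattern`; when given, the column count is
#'   validated against [frame_length()].
#' @return For `read_frames`: list with `t` (numeric) and `frames` (matrix),
#'   rows sorted by time. An empty file yields an empty series.
#' @export
read_frames <- function(path, pattern = NULL) {
  if (file.size(path) == 0) {
    nv <- if (is.null(pattern)) 0L else frame_length(pattern)
    return(list(t = numeric(0), frames = matrix(numeric(0), 0, nv)))
  }
  dt <- data.table::fread(path, header = TRUE)
  if (nrow(dt) == 0 && ncol(dt) <= 1) {
    nv <- if (is.null(pattern)) 0L else frame_length(pattern)
    return(list(t = numeric(0), frames = matrix(numeric(0), 0, nv)))
  }
  if (!"t" %in% names(dt)) stop("format error: missing 't' column", call. = FALSE)
  nv <- ncol(dt) - 1L
  if (!is.null(pattern) && nv != frame_length(pattern)) {
    stop(sprintf("format error: %d value columns, expected %d for this pattern",
                 nv, frame_length(pattern)), call. = FALSE)
  }
  tt <- dt[["t"]]
  if (is.unsorted(tt)) {
    stop("format error: timestamps are not monotone non-decreasing", call. = FALSE)
  }
  list(t = as.numeric(tt),
       frames = as.matrix(dt[, -1, with = FALSE]))
}

#' Write / read reference wrist-angle series
#'
#' Angle tables are CSV with columns `t`, `fe`, `rdud`, `ps` (degrees).
#' `read_angles()` optionally decimates a faster stream (e.g. a 100 Hz
#' inertial sensor) onto a 10 Hz frame clock by nearest timestamp.
#'
#' @param angles n x 3 matrix of angles.
#' @param t Timestamps (seconds).
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_angles <- function(angles, t, path) {
  stopifnot(is.matrix(angles), ncol(angles) == 3, length(t) == nrow(angles))
  df <- data.frame(t = t, fe = angles[, 1], rdud = angles[, 2], ps = angles[, 3])
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_angles
#' @param mapping Optional named character vector renaming input columns to
#'   `c(fe=, rdud=, ps=)` when the source uses other axis labels
#'   (e.g. `c(fe = "pitch", rdud = "roll", ps = "yaw")`).
#' @param clock Optional target timestamps (the frame clock); when given,
#'   angles are aligned by nearest timestamp. Without it, streams faster than
#'   `rate` are decimated to a uniform `rate` grid.
#' @param rate Nominal target rate in Hz (default 10).
#' @return For `read_angles`: list with `t` and `angles` (n x 3 matrix).
#' @export
read_angles <- function(path, mapping = NULL, clock = NULL, rate = 10) {
  dt <- data.table::fread(path, header = TRUE)
  if (!is.null(mapping)) {
    for (k in names(mapping)) {
      if (!mapping[[k]] %in% names(dt)) {
        stop(sprintf("format error: mapped column '%s' not found", mapping[[k]]),
             call. = FALSE)
      }
      data.table::setnames(dt, mapping[[k]], k)
    }
  }
  need <- c("t", "fe", "rdud", "ps")
  if (!all(need %in% names(dt))) {
    stop("format error: need columns t, fe, rdud, ps (or a column mapping)",
         call. = FALSE)
  }
  tt <- as.numeric(dt[["t"]])
  A <- as.matrix(dt[, c("fe", "rdud", "ps"), with = FALSE])
  if (is.null(clock)) {
    if (length(tt) >= 2) {
      in_rate <- 1 / stats::median(diff(tt))
      if (in_rate > rate * 1.5) {
        clock <- seq(tt[1], tt[length(tt)], by = 1 / rate)
      }
    }
  }
  if (!is.null(clock)) {
    idx <- align_to_clock(tt, clock)
    tt <- clock
    A <- A[idx, , drop = FALSE]
  }
  list(t = tt, angles = A)
}

#' Nearest-timestamp alignment of a source stream onto a target clock
#'
#' @param t_src Source timestamps (sorted).
#' @param clock Target timestamps.
#' @return Integer indices into `t_src`, one per clock tick (nearest sample).
#' @export
align_to_clock <- function(t_src, clock) {
  stopifnot(length(t_src) >= 1)
  iv <- findInterval(clock, t_src, all.inside = TRUE)
  lo <- pmax(iv, 1L)
  hi <- pmin(iv + 1L, length(t_src))
  ifelse(abs(t_src[lo] - clock) <= abs(t_src[hi] - clock), lo, hi)
}

#' Run the full estimation pipeline on the synthetic phantom
#'
#' Chains the stages end to end: simulate the configured sessions, build the
#' Tikhonov reconstructor, reconstruct every frame, extract region (and
#' optionally augmented) features, train per-DoF models with CV-selected
#' hyperparameters, and evaluate by session-wise cross-validation. All
#' artifacts are written as delimited text under `out_dir` together with a
#' JSON provenance sidecar (config, seed, package version); identical
#' config + seed reproduce identical outputs.
#'
#' @param config Named list of settings; see [pipeline_config()] for the
#'   defaults that any entry overrides. `center_features` (default TRUE)
#'   re-centers each session's region features to their session means before
#'   any augmentation: time-difference images are only defined relative to
#'   the estimated baseline, whose residual error is a per-session constant
#'   that outer-product features amplify.
#' @param out_dir Output directory, or NULL to skip writing artifacts.
#' @return List with `report` (an `eit_metrics_report`), `selection` (an
#'   `eit_selection_summary` for augmented Lasso, else NULL), `grid`,
#'   `model`, and the effective `config`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- utils::modifyList(pipeline_config(), config)
  phantom <- phantom_config(noise_sd = cfg$noise_sd,
                            cycles_per_dof = cfg$cycles_per_dof,
                            cadence = cfg$cadence, sessions = cfg$sessions,
                            seed = cfg$seed)
  mesh <- build_forearm_mesh(forearm_boundary(), density = cfg$mesh_density,
                             n_electrodes = cfg$n_electrodes)
  pat <- build_pattern(electrode_layout(cfg$n_electrodes))
  fm <- forward_model(mesh, pat)
  rec <- build_reconstructor(fm, lam = cfg$lam)
  rgrid <- build_region_grid(mesh, target_M = cfg$target_M)

  sessions <- lapply(seq_len(cfg$sessions), function(s) {
    sim <- simulate_session(phantom, fm, session = s)
    imgs <- reconstruct_series(rec, sim$frames,
                               baseline = baseline_frame(sim$frames, cfg$baseline_frames))
    S <- region_features(imgs, rgrid)
    # per-session re-centering absorbs residual baseline error, to which
    # product features are quadratically sensitive (unsupervised, no labels)
    if (cfg$center_features) S <- sweep(S, 2, colMeans(S))
    X <- if (cfg$feature_mode == "augmented") augment(S) else S
    list(sim = sim, data = session_data(X, sim$angles, sim$segment))
  })

  report <- session_cv(lapply(sessions, `[[`, "data"), kind = cfg$model,
                       feature_mode = cfg$feature_mode,
                       cv_folds = cfg$cv_folds,
                       cross_table = cfg$cross_table)

  selection <- NULL
  if (cfg$model == "lasso" && cfg$feature_mode == "augmented") {
    d1 <- sessions[[1]]$data
    hyper <- report$hyper[[1]]
    final <- fit_multidof(d1$features, d1$angles, kind = "lasso",
                          hyper = hyper, feature_mode = "augmented")
    selection <- selection_summary(final, rgrid)
  } else {
    final <- NULL
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pattern(pat, file.path(out_dir, "pattern.csv"))
    write_mesh(mesh, file.path(out_dir, "mesh"))
    for (s in seq_along(sessions)) {
      sim <- sessions[[s]]$sim
      write_frames(sim$frames, sim$t, file.path(out_dir, sprintf("frames_s%d.csv", s)))
      write_angles(sim$angles, sim$t, file.path(out_dir, sprintf("angles_s%d.csv", s)))
    }
    data.table::fwrite(report$per_dof, file.path(out_dir, "metrics_per_dof.csv"))
    if (!is.null(report$cross_table)) {
      ctl <- do.call(rbind, lapply(names(report$cross_table), function(m) {
        d <- as.data.frame(as.table(report$cross_table[[m]]))
        names(d) <- c("train_dof", "test_segment", "value")
        d$metric <- m
        d
      }))
      data.table::fwrite(ctl, file.path(out_dir, "cross_table.csv"))
    }
    if (!is.null(selection)) {
      data.table::fwrite(selection$per_dof, file.path(out_dir, "selection_per_dof.csv"))
      data.table::fwrite(data.frame(region = seq_len(selection$M), selection$region_heat),
                         file.path(out_dir, "region_heat.csv"))
    }
    prov <- list(package = "eitwrist",
                 version = as.character(utils::packageVersion("eitwrist")),
                 config = cfg, timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(report = report, selection = selection, grid = rgrid, model = final,
       config = cfg)
}

#' Default pipeline configuration
#'
#' @return Named list of defaults consumed by [run_pipeline()]: mesh density,
#'   electrode count, regularization, region target, feature mode, model
#'   kind, phantom protocol settings and seed.
#' @export
pipeline_config <- function() {
  list(mesh_density = 800, n_electrodes = 16, lam = 1e-2, target_M = 100,
       feature_mode = "augmented", model = "lasso", noise_sd = 1e-3,
       cycles_per_dof = 20, cadence = 4, sessions = 2, baseline_frames = 10,
       center_features = TRUE, cv_folds = 3, cross_table = TRUE, seed = 1)
}
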