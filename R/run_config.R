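#' Simulation run configuration
#'
#' A serializable description of a complete simulation: the trajectory
#' specification, HD-ring and grid-module parameters, warmup and seed. Every
#' default is either a printed model constant or a calibrated value (see the
#' methods vignette); regime switches (theta off, adaptation strengths) are
#' plain parameter overrides.
#'
#' @param trajectory List describing the trajectory: field `kind`
#'   (`straight`, `rotation`, `segments`, `random_walk`) plus the arguments of
#'   the corresponding `make_*` generator.
#' @param hd An [hd_params] object.
#' @param grid A [grid_params] object or list of them.
#' @param warmup Warmup, seconds.
#' @param seed Integer seed (used for stochastic trajectory kinds and spike
#'   generation).
#' @return An object of class `run_config`.
#' @export
run_config <- function(trajectory = list(kind = "straight", speed = 0.5,
                                         heading = pi / 4, duration = 4,
                                         dt = 1e-3),
                       hd = hd_params(), grid = grid_params(),
                       warmup = 0.5, seed = 1L) {
  if (inherits(grid, "grid_params")) grid <- list(grid)
  structure(list(trajectory = trajectory, hd = hd, grid = grid,
                 warmup = warmup, seed = as.integer(seed)),
            class = "run_config")
}

#' Build the trajectory described by a config
#' @param config A [run_config].
#' @return A [trajectory].
#' @export
config_trajectory <- function(config) {
  sp <- config$trajectory
  kind <- sp$kind
  a <- sp[setdiff(names(sp), "kind")]
  traj_fun <- switch(kind,
                     straight = make_straight_run,
                     rotation = make_rotation,
                     segments = make_segments,
                     random_walk = make_random_walk,
                     stop("unknown trajectory kind: ", kind))
  if (kind == "random_walk" && is.null(a$seed)) a$seed <- config$seed
  do.call(traj_fun, a)
}

#' Read/write run configurations as YAML
#'
#' @param config A [run_config].
#' @param file Path to a YAML file.
#' @return `write_run_config` returns `file` invisibly; `read_run_config`
#'   returns a [run_config] (round-trip stable).
#' @export
write_run_config <- function(config, file) {
  plain <- list(trajectory = config$trajectory,
                hd = unclass(config$hd),
                grid = lapply(config$grid, unclass),
                warmup = config$warmup, seed = config$seed)
  yaml::write_yaml(plain, file, precision = 15)
  invisible(file)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(file) {
  plain <- yaml::read_yaml(file)
  need <- c("trajectory", "hd", "grid", "warmup", "seed")
  miss <- setdiff(need, names(plain))
  if (length(miss)) {
    stop("invalid config: missing fields ", paste(miss, collapse = ", "))
  }
  run_config(trajectory = plain$trajectory,
             hd = do.call(hd_params, plain$hd),
             grid = lapply(plain$grid, function(g) do.call(grid_params, g)),
             warmup = plain$warmup, seed = plain$seed)
}

#' Run a configured simulation and write its outputs
#'
#' Simulates the coupled model, decodes every module, computes per-module
#' sweep statistics and writes everything to a run directory: `config.yaml`,
#' `trajectory.csv`, `hd_center.csv`, `module<k>_track.csv`,
#' `module<k>_sweeps.csv`, `summary.csv` and `log.txt` (with the config MD5
#' and wall time). Deterministic given config and seed.
#'
#' @param config A [run_config].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list with the run, tracks, records and summary.
#' @export
simulate_run <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(outdir, "config.yaml")
  write_run_config(config, cfg_path)
  traj <- config_trajectory(config)
  run <- run_coupled(traj, config$hd, config$grid, warmup = config$warmup)
  write_trajectory(traj, file.path(outdir, "trajectory.csv"))
  utils::write.csv(data.frame(t = run$t, center = run$hd$center,
                              pop_rate = run$hd$pop_rate,
                              theta_phase = run$theta_phase),
                   file.path(outdir, "hd_center.csv"), row.names = FALSE)
  tracks <- list(); records <- list(); sumrows <- list()
  for (k in seq_along(run$modules)) {
    track <- decode_track(run, module = k)
    recs <- segment_sweeps(track, traj, run$theta_phase,
                           hd_pop_rate = run$hd$pop_rate)
    st <- tryCatch(sweep_stats(recs), error = function(e) NULL)
    write_decoded_track(track, file.path(outdir, sprintf("module%d_track.csv", k)))
    utils::write.csv(recs, file.path(outdir, sprintf("module%d_sweeps.csv", k)),
                     row.names = FALSE)
    tracks[[k]] <- track; records[[k]] <- recs
    sumrows[[k]] <- data.frame(
      module = k, lambda = run$modules[[k]]$params$lambda,
      m_adapt = run$modules[[k]]$params$m,
      n_sweeps = if (is.null(st)) 0L else st$n,
      mean_abs_alpha_deg = if (is.null(st)) NA else st$mean_abs_alpha_deg,
      var_alpha = if (is.null(st)) NA else st$var_alpha,
      mean_length_m = if (is.null(st)) NA else st$mean_length_m,
      mean_abs_peak_dir_offset_deg = if (is.null(st)) NA
                                     else st$mean_abs_peak_dir_offset_deg,
      alternation = if (is.null(st)) NA else st$alternation)
  }
  summary <- do.call(rbind, sumrows)
  utils::write.csv(summary, file.path(outdir, "summary.csv"), row.names = FALSE)
  log <- c(sprintf("config_md5: %s", unname(tools::md5sum(cfg_path))),
           sprintf("wall_time_s: %.2f",
                   as.numeric(difftime(Sys.time(), t0, units = "secs"))),
           sprintf("r_version: %s", R.version.string),
           sprintf("steps: %d", length(run$t)),
           sprintf("modules: %d", length(run$modules)))
  writeLines(log, file.path(outdir, "log.txt"))
  message(paste(log, collapse = " | "))
  invisible(list(run = run, tracks = tracks, records = records,
                 summary = summary))
}

#' Recompute sweep metrics from a run directory
#'
#' Reads the decoded tracks and trajectory written by [simulate_run] and
#' recomputes the sweep statistics, writing `metrics.csv`. Idempotent.
#'
#' @param outdir A run directory produced by [simulate_run].
#' @return The metrics data frame, invisibly.
#' @export
run_metrics <- function(outdir) {
  cfg_path <- file.path(outdir, "config.yaml")
  if (!file.exists(cfg_path)) {
    stop("not a run directory (missing config.yaml): ", outdir)
  }
  config <- read_run_config(cfg_path)
  traj <- read_trajectory(file.path(outdir, "trajectory.csv"))
  hdc <- utils::read.csv(file.path(outdir, "hd_center.csv"))
  rows <- list()
  k <- 1
  repeat {
    f <- file.path(outdir, sprintf("module%d_track.csv", k))
    if (!file.exists(f)) break
    track <- utils::read.csv(f)
    attr(track, "lambda") <- config$grid[[k]]$lambda
    class(track) <- c("decoded_track", "data.frame")
    recs <- segment_sweeps(track, traj, hdc$theta_phase,
                           hd_pop_rate = hdc$pop_rate)
    st <- sweep_stats(recs)
    rows[[k]] <- data.frame(module = k, lambda = config$grid[[k]]$lambda,
                            n_sweeps = st$n,
                            mean_abs_alpha_deg = st$mean_abs_alpha_deg,
                            var_alpha = st$var_alpha,
                            mean_length_m = st$mean_length_m,
                            mean_abs_peak_dir_offset_deg =
                              st$mean_abs_peak_dir_offset_deg,
                            alternation = st$alternation)
    k <- k + 1
  }
  if (!length(rows)) stop("no module tracks found in ", outdir)
  out <- do.call(rbind, rows)
  utils::write.csv(out, file.path(outdir, "metrics.csv"), row.names = FALSE)
  invisible(out)
}

#' Parameter sensitivity analysis of the alternation score
#'
#' Varies one parameter at a time over a multiplicative grid (the published
#' analysis uses 10%-200% of the default), reruns a straight-run simulation,
#' and records the location-sweep alternation score; parameters are ranked by
#' the range (max - min) of the score. The eight analysed parameters are the
#' adaptation strengths and theta amplitudes of both networks, the recurrent
#' connection-noise levels of both networks, the conjunctive-cell offset and
#' the running speed.
#'
#' Connection noise defaults to 0 in the model; the analysis scales a
#' reference noise SD (`noise_ref`) instead, since a multiple of zero would
#' not vary.
#'
#' @param config Base [run_config] (its trajectory should be a straight run).
#' @param params Character vector of parameter names to vary, among
#'   `"m_h"`, `"m_g"`, `"abar_h"`, `"abar_g"`, `"conn_noise_h"`,
#'   `"conn_noise_g"`, `"w0"`, `"speed"`.
#' @param grid Multiplicative factors applied to each default
#'   (default `seq(0.1, 2, length.out = 5)`).
#' @param noise_ref Reference connection-noise SD treated as the 100% level.
#' @return A data frame of class `sensitivity_table`: one row per parameter
#'   with the score at each factor, the range, and the rank; attribute
#'   `"scores"` holds the full grid.
#' @export
sensitivity_analysis <- function(config,
                                 params = c("m_h", "m_g", "abar_h", "abar_g",
                                            "conn_noise_h", "conn_noise_g",
                                            "w0", "speed"),
                                 grid = seq(0.1, 2, length.out = 5),
                                 noise_ref = 0.05) {
  known <- c("m_h", "m_g", "abar_h", "abar_g", "conn_noise_h",
             "conn_noise_g", "w0", "speed")
  bad <- setdiff(params, known)
  if (length(bad)) stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
  score_of <- function(cfg) {
    traj <- config_trajectory(cfg)
    run <- run_coupled(traj, cfg$hd, cfg$grid, warmup = cfg$warmup)
    track <- decode_track(run, module = 1)
    recs <- segment_sweeps(track, traj, run$theta_phase,
                           hd_pop_rate = run$hd$pop_rate)
    if (sum(recs$valid) < 3) return(NA_real_)
    alternation_score(recs$alpha[recs$valid])
  }
  rows <- list(); all_scores <- list()
  for (pn in params) {
    sc <- vapply(grid, function(f) {
      cfg <- config
      if (pn == "m_h") cfg$hd$m <- cfg$hd$m * f
      if (pn == "abar_h") cfg$hd$abar <- cfg$hd$abar * f
      if (pn == "conn_noise_h") cfg$hd$conn_noise <- noise_ref * f
      if (pn == "m_g") cfg$grid <- lapply(cfg$grid, function(g) { g$m <- g$m * f; g })
      if (pn == "abar_g") cfg$grid <- lapply(cfg$grid, function(g) { g$abar <- g$abar * f; g })
      if (pn == "conn_noise_g") cfg$grid <- lapply(cfg$grid, function(g) { g$conn_noise <- noise_ref * f; g })
      if (pn == "w0") cfg$grid <- lapply(cfg$grid, function(g) { g$w0 <- g$w0 * f; g })
      if (pn == "speed") {
        if (!is.null(cfg$trajectory$speed)) {
          cfg$trajectory$speed <- cfg$trajectory$speed * f
        } else cfg$trajectory$linear_speed <- cfg$trajectory$linear_speed * f
      }
      tryCatch(score_of(cfg), error = function(e) NA_real_)
    }, numeric(1))
    all_scores[[pn]] <- sc
    rows[[pn]] <- data.frame(param = pn,
                             min_score = min(sc, na.rm = TRUE),
                             max_score = max(sc, na.rm = TRUE),
                             range = diff(range(sc, na.rm = TRUE)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$range), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "scores") <- do.call(rbind, all_scores)
  attr(out, "grid") <- grid
  class(out) <- c("sensitivity_table", "data.frame")
  out
}
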