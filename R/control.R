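#' Feedback controller configuration
#'
#' The dispensing loop regulates droplet volume by adjusting the pin's
#' dipping depth at fixed downward velocity, the actuation direction the
#' instrument itself uses. The control law is model-inversion feedforward
#' plus integral correction: the calibrated dispense law supplies the depth
#' that should yield the setpoint, and an integral accumulator on depth
#' trims the residual error each step.
#'
#' The integral gain sets how fast a ramp disturbance is tracked: a
#' reservoir level falling `d` mm per dispense leaves a steady-state volume
#' error of `d / ki` nL, so the default `ki = 0.02` mm/nL holds the default
#' drift (0.02 mm/step) to about 1 nL while keeping the loop gain
#' `ki * df/dh` comfortably inside the stable range.
#'
#' @param setpoint_nl Volume setpoint (nL), positive.
#' @param velocity_mm_s Fixed downward velocity (mm/s).
#' @param ki Integral gain (mm of depth per nL of error per step).
#' @param max_step_mm Largest commanded depth change per step (mm).
#' @param depth_bounds Allowed commanded depth range `c(lo, hi)` (mm); must
#'   lie within the calibration grid's depth envelope.
#' @param saturation_steps Consecutive steps pinned at a depth bound before
#'   a saturation warning is raised.
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(setpoint_nl = 100, velocity_mm_s = 1000,
                              ki = 0.02, max_step_mm = 0.2,
                              depth_bounds = c(2, 5),
                              saturation_steps = 5L) {
  if (setpoint_nl <= 0) stop("`setpoint_nl` must be positive", call. = FALSE)
  if (max_step_mm <= 0) stop("`max_step_mm` must be positive", call. = FALSE)
  if (length(depth_bounds) != 2 || depth_bounds[1] >= depth_bounds[2]) {
    stop("`depth_bounds` must be c(lo, hi) with lo < hi", call. = FALSE)
  }
  if (ki < 0) stop("`ki` must be >= 0", call. = FALSE)
  structure(list(setpoint_nl = setpoint_nl, velocity_mm_s = velocity_mm_s,
                 ki = ki, max_step_mm = max_step_mm,
                 depth_bounds = depth_bounds,
                 saturation_steps = as.integer(saturation_steps)),
            class = "controller_config")
}

#' Initial controller/process state
#'
#' Seeds the loop at the feedforward depth: the model-inverted depth for the
#' setpoint at the configured velocity.
#'
#' @param cfg A [controller_config()].
#' @param grid The controller's belief of the dispense law, a
#'   [calibration_grid()].
#' @return An object of class `dispense_state`: commanded depth, integral
#'   accumulator, and (growing) histories of commanded depths, measured
#'   volumes and errors.
#' @export
new_dispense_state <- function(cfg, grid) {
  ff <- invert_for_depth(grid, cfg$velocity_mm_s, cfg$setpoint_nl)
  if (ff < cfg$depth_bounds[1] || ff > cfg$depth_bounds[2]) {
    stop("feedforward depth lies outside `depth_bounds`", call. = FALSE)
  }
  structure(list(step = 0L, depth_mm = ff, feedforward_mm = ff,
                 integrator_mm = 0, saturated_run = 0L,
                 depths_mm = numeric(0), volumes_nl = numeric(0),
                 errors_nl = numeric(0)),
            class = "dispense_state")
}

#' @export
print.dispense_state <- function(x, ...) {
  cat(sprintf("<dispense_state> step %d, commanded depth %.3f mm\n",
              x$step, x$depth_mm))
  if (x$step > 0) {
    cat(sprintf("  last volume %.2f nL, last error %+.2f nL\n",
                x$volumes_nl[x$step], x$errors_nl[x$step]))
  }
  invisible(x)
}

#' One feedback update from a volume measurement
#'
#' Computes the error `e = setpoint - measurement`, moves the integral
#' accumulator by `clamp(ki * e, +/- max_step_mm)`, and commands
#' `feedforward + integrator`, clipped to `depth_bounds`. Anti-windup: when
#' the command saturates at a bound the accumulator is frozen, and a
#' warning is raised after `saturation_steps` consecutive saturated steps.
#' A zero error leaves the commanded depth unchanged; a measurement below
#' the setpoint deepens the dip (volume grows with depth).
#'
#' @param cfg A [controller_config()].
#' @param state A `dispense_state`.
#' @param measurement_nl Measured volume of the last dispense (nL, >= 0).
#' @return The updated `dispense_state`; its `depth_mm` is the commanded
#'   depth for the next dispense.
#' @export
feedback_step <- function(cfg, state, measurement_nl) {
  stopifnot(inherits(cfg, "controller_config"),
            inherits(state, "dispense_state"))
  if (!is.numeric(measurement_nl) || measurement_nl < 0) {
    stop("`measurement_nl` must be >= 0", call. = FALSE)
  }
  e <- cfg$setpoint_nl - measurement_nl
  delta <- clamp(cfg$ki * e, -cfg$max_step_mm, cfg$max_step_mm)
  proposed <- state$integrator_mm + delta
  raw_depth <- state$feedforward_mm + proposed
  depth <- clamp(raw_depth, cfg$depth_bounds[1], cfg$depth_bounds[2])
  if (depth != raw_depth) {
    # saturated: freeze the accumulator so it cannot wind up off the rail
    state$saturated_run <- state$saturated_run + 1L
    if (state$saturated_run == cfg$saturation_steps) {
      warning(sprintf(paste0("commanded depth saturated at %.3f mm for %d ",
                             "consecutive steps"),
                      depth, state$saturated_run), call. = FALSE)
    }
  } else {
    state$integrator_mm <- proposed
    state$saturated_run <- 0L
  }
  state$step <- state$step + 1L
  state$depths_mm <- c(state$depths_mm, state$depth_mm)
  state$volumes_nl <- c(state$volumes_nl, measurement_nl)
  state$errors_nl <- c(state$errors_nl, e)
  state$depth_mm <- depth
  state
}

#' Run the closed loop against a simulated process
#'
#' Dispense, measure, correct: each step dispenses at the currently
#' commanded depth, observes the (noisy, drifting) volume, and updates the
#' command through [feedback_step()].
#'
#' @param cfg A [controller_config()].
#' @param proc A [process_spec()].
#' @param grid The controller's belief grid; defaults to the process's own
#'   (a perfectly identified model).
#' @param n_steps Number of dispenses.
#' @param seed Integer seed (defaults to the process seed). Identical seeds
#'   and configurations give bit-identical trajectories.
#' @return The final `dispense_state` with full histories.
#' @export
closed_loop_run <- function(cfg, proc, grid = proc$grid, n_steps = 50L,
                            seed = proc$seed) {
  stopifnot(inherits(proc, "process_spec"), n_steps >= 1)
  state <- new_dispense_state(cfg, grid)
  set.seed(seed)
  for (step in seq_len(n_steps)) {
    vol <- simulate_dispense(proc, cfg$velocity_mm_s, state$depth_mm, step)
    state <- feedback_step(cfg, state, vol)
  }
  state
}

#' Run the open-loop baseline
#'
#' Commanded parameters stay constant, as in passive droplet generation:
#' under reservoir drift the effective depth shrinks and the dispensed
#' volume decays with it.
#'
#' @param velocity_mm_s,depth_mm Constant commanded parameters.
#' @param proc A [process_spec()].
#' @param n_steps Number of dispenses (>= 1).
#' @param seed Integer seed (defaults to the process seed).
#' @param setpoint_nl Optional setpoint used only to fill the error history.
#' @return A `dispense_state` with histories; the commanded depth never
#'   moves.
#' @export
open_loop_run <- function(velocity_mm_s, depth_mm, proc, n_steps = 50L,
                          seed = proc$seed, setpoint_nl = NA_real_) {
  stopifnot(inherits(proc, "process_spec"), n_steps >= 1)
  set.seed(seed)
  vols <- vapply(seq_len(n_steps), function(step) {
    simulate_dispense(proc, velocity_mm_s, depth_mm, step)
  }, numeric(1))
  structure(list(step = as.integer(n_steps), depth_mm = depth_mm,
                 feedforward_mm = depth_mm, integrator_mm = 0,
                 saturated_run = 0L,
                 depths_mm = rep(depth_mm, n_steps), volumes_nl = vols,
                 errors_nl = if (is.na(setpoint_nl)) rep(NA_real_, n_steps)
                             else setpoint_nl - vols),
            class = "dispense_state")
}

# First step after which the error stays inside the band for good.
settling_step <- function(errors_nl, setpoint_nl, band = 0.05) {
  inside <- abs(errors_nl) < band * setpoint_nl
  ok <- rev(cumprod(rev(inside))) > 0  # inside from here to the end
  if (!any(ok)) return(NA_integer_)
  which(ok)[1]
}

#' Compare closed-loop and open-loop dispensing
#'
#' Runs paired replicates of the feedback loop and the fixed-depth baseline
#' against the same process realizations (matched seeds), and reports per
#' strategy the settling step (first step after which the error stays
#' within 5% of the setpoint), the steady-state mean absolute error over
#' the last `steady_window` steps, and the mean/SD of the measured volumes
#' in that window. The open loop starts from the same model-inverted depth
#' as the closed loop.
#'
#' @param cfg A [controller_config()].
#' @param proc A [process_spec()].
#' @param grid The controller's belief grid (default: the process grid).
#' @param n_steps Steps per run.
#' @param n_replicates Paired replicates (>= 1).
#' @param seed Base seed; replicate `r` uses `seed + r - 1`.
#' @param steady_window Trailing steps used for steady-state statistics.
#' @return An object of class `strategy_comparison`: a data frame
#'   `replicates` (per-replicate metrics for both strategies) and a
#'   `summary` list, including the fraction of replicates in which the
#'   closed loop's steady-state MAE beats the open loop's.
#' @export
compare_strategies <- function(cfg, proc, grid = proc$grid, n_steps = 50L,
                               n_replicates = 20L, seed = proc$seed,
                               steady_window = 20L) {
  stopifnot(n_replicates >= 1)
  steady_window <- min(steady_window, n_steps)
  ff <- invert_for_depth(grid, cfg$velocity_mm_s, cfg$setpoint_nl)
  rows <- lapply(seq_len(n_replicates), function(r) {
    s <- seed + r - 1L
    cl <- closed_loop_run(cfg, proc, grid, n_steps, seed = s)
    op <- open_loop_run(cfg$velocity_mm_s, ff, proc, n_steps, seed = s,
                        setpoint_nl = cfg$setpoint_nl)
    tail_idx <- (n_steps - steady_window + 1):n_steps
    metrics <- function(st) {
      v <- st$volumes_nl[tail_idx]
      e <- st$errors_nl[tail_idx]
      c(settle = settling_step(st$errors_nl, cfg$setpoint_nl),
        mae = mean(abs(e)), mean = mean(v), sd = sd(v))
    }
    data.frame(replicate = r, seed = s,
               t(c(closed = metrics(cl), open = metrics(op))))
  })
  reps <- do.call(rbind, rows)
  comparison <- structure(list(
    replicates = reps,
    summary = list(
      setpoint_nl = cfg$setpoint_nl,
      n_steps = n_steps, steady_window = steady_window,
      closed = list(mae = mean(reps$closed.mae), mean = mean(reps$closed.mean),
                    sd = mean(reps$closed.sd),
                    settling_step = mean(reps$closed.settle)),
      open = list(mae = mean(reps$open.mae), mean = mean(reps$open.mean),
                  sd = mean(reps$open.sd),
                  settling_step = mean(reps$open.settle)),
      closed_wins_fraction = mean(reps$closed.mae < reps$open.mae))),
    class = "strategy_comparison")
  comparison
}

#' @export
print.strategy_comparison <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<strategy_comparison> setpoint %.4g nL, %d steps x %d replicates\n",
              s$setpoint_nl, s$n_steps, nrow(x$replicates)))
  cat(sprintf("  closed loop: steady-state MAE %.2f nL, mean %.2f nL (SD %.2f)\n",
              s$closed$mae, s$closed$mean, s$closed$sd))
  cat(sprintf("  open loop:   steady-state MAE %.2f nL, mean %.2f nL (SD %.2f)\n",
              s$open$mae, s$open$mean, s$open$sd))
  cat(sprintf("  closed loop wins on MAE in %.0f%% of paired replicates\n",
              100 * s$closed_wins_fraction))
  invisible(x)
}

#' Read a simulation run configuration from YAML
#'
#' Recognised keys: `setpoint_nl`, `velocity_mm_s`, `ki`, `max_step_mm`,
#' `depth_bounds`, `drift_mm_per_step`, `noise_cv`, `n_steps`, `seed`.
#' Missing keys fall back to the package defaults.
#'
#' @param path YAML file path.
#' @return A list with elements `cfg` ([controller_config()]),
#'   `proc` ([process_spec()]) and `n_steps`.
#' @export
read_control_config <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(key, default) if (is.null(y[[key]])) default else y[[key]]
  cfg <- controller_config(
    setpoint_nl = take("setpoint_nl", 100),
    velocity_mm_s = take("velocity_mm_s", 1000),
    ki = take("ki", 0.02),
    max_step_mm = take("max_step_mm", 0.2),
    depth_bounds = unlist(take("depth_bounds", c(2, 5))))
  proc <- process_spec(
    noise_cv = take("noise_cv", 0.01),
    drift_mm_per_step = take("drift_mm_per_step", 0.02),
    seed = take("seed", 1L))
  list(cfg = cfg, proc = proc, n_steps = as.integer(take("n_steps", 50L)))
}

#' Write a run record CSV
#'
#' One row per dispense: step, chip index, commanded depth and measured
#' volume — the tabular record an operator would keep per chip.
#'
#' @param state A `dispense_state` with histories.
#' @param path Output CSV path.
#' @param chip_index Chip position index per step (recycled).
#' @return The record data frame, invisibly.
#' @export
write_run_record <- function(state, path, chip_index = seq_len(state$step)) {
  rec <- data.frame(step = seq_len(state$step),
                    chip_index = rep_len(chip_index, state$step),
                    commanded_depth_mm = state$depths_mm,
                    measured_volume_nl = state$volumes_nl)
  write.csv(rec, path, row.names = FALSE)
  invisible(rec)
}
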