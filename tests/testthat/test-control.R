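default_grid <- function() extend_calibration(table1_grid(), 5)

test_that("a zero error leaves the commanded depth unchanged", {
  cfg <- controller_config()
  st <- new_dispense_state(cfg, default_grid())
  d0 <- st$depth_mm
  st <- feedback_step(cfg, st, cfg$setpoint_nl)
  expect_identical(st$depth_mm, d0)
})

test_that("a low measurement deepens the dip, a high one raises it", {
  cfg <- controller_config()
  st <- new_dispense_state(cfg, default_grid())
  d0 <- st$depth_mm
  low <- feedback_step(cfg, st, cfg$setpoint_nl - 10)
  expect_gt(low$depth_mm, d0)
  high <- feedback_step(cfg, st, cfg$setpoint_nl + 10)
  expect_lt(high$depth_mm, d0)
})

test_that("zero gain reduces the closed loop exactly to the open loop", {
  grid <- default_grid()
  cfg <- controller_config(ki = 0)
  proc <- process_spec()
  ff <- invert_for_depth(grid, cfg$velocity_mm_s, cfg$setpoint_nl)
  cl <- closed_loop_run(cfg, proc, grid, n_steps = 30, seed = 77)
  op <- open_loop_run(cfg$velocity_mm_s, ff, proc, n_steps = 30, seed = 77)
  expect_identical(cl$volumes_nl, op$volumes_nl)
  expect_identical(cl$depths_mm, op$depths_mm)
})

test_that("identical seeds give bit-identical trajectories", {
  cfg <- controller_config()
  proc <- process_spec()
  a <- closed_loop_run(cfg, proc, n_steps = 25, seed = 123)
  b <- closed_loop_run(cfg, proc, n_steps = 25, seed = 123)
  expect_identical(a, b)
  c <- closed_loop_run(cfg, proc, n_steps = 25, seed = 124)
  expect_false(identical(a$volumes_nl, c$volumes_nl))
})

test_that("with a perfect model and no disturbance the loop is at its fixed point", {
  grid <- default_grid()
  cfg <- controller_config()
  proc <- process_spec(grid = grid, noise_cv = 0, drift_mm_per_step = 0)
  st <- closed_loop_run(cfg, proc, grid, n_steps = 6, seed = 1)
  expect_lt(max(abs(st$errors_nl[3:6])), 0.01)
  expect_lt(max(abs(st$errors_nl)), 0.01)  # exact inversion: from step 1
})

test_that("actuation stays within bounds and step limits", {
  grid <- default_grid()
  cfg <- controller_config(ki = 0.2, max_step_mm = 0.05,
                           depth_bounds = c(3, 4.2))
  proc <- process_spec(drift_mm_per_step = 0.05)
  st <- suppressWarnings(closed_loop_run(cfg, proc, grid, n_steps = 40,
                                         seed = 9))
  expect_true(all(st$depths_mm >= 3 & st$depths_mm <= 4.2))
  expect_true(all(abs(diff(st$depths_mm)) <= 0.05 + 1e-12))
})

test_that("persistent saturation raises a warning and freezes the integrator", {
  grid <- default_grid()
  cfg <- controller_config(depth_bounds = c(3.2, 3.6), saturation_steps = 3)
  proc <- process_spec(drift_mm_per_step = 0.05)
  expect_warning(
    st <- closed_loop_run(cfg, proc, grid, n_steps = 30, seed = 4),
    "saturated")
  expect_true(all(st$depths_mm <= 3.6))
})

test_that("open loop decays under drift but is flat without it", {
  grid <- default_grid()
  quiet <- process_spec(grid = grid, noise_cv = 0, drift_mm_per_step = 0)
  flat <- open_loop_run(1000, 3.4, quiet, n_steps = 10, seed = 1)
  expect_equal(length(unique(flat$volumes_nl)), 1L)
  single <- open_loop_run(1000, 3.4, quiet, n_steps = 1, seed = 1)
  expect_length(single$volumes_nl, 1L)

  drifty <- process_spec(grid = grid)
  st <- open_loop_run(1000, 3.4, drifty, n_steps = 50, seed = 2)
  expect_lt(mean(tail(st$volumes_nl, 10)), mean(head(st$volumes_nl, 10)))
})

test_that("strategy comparison is ideal without disturbances and paired under them", {
  grid <- default_grid()
  ideal <- process_spec(grid = grid, noise_cv = 0, drift_mm_per_step = 0)
  cfg <- controller_config()
  cmp0 <- compare_strategies(cfg, ideal, grid, n_steps = 10,
                             n_replicates = 2, seed = 1)
  expect_true(all(cmp0$replicates$closed.settle == 1))
  expect_true(all(cmp0$replicates$open.settle == 1))
  expect_lt(cmp0$summary$closed$mae, 1e-9)

  cmp <- compare_strategies(cfg, process_spec(grid = grid), grid,
                            n_steps = 50, n_replicates = 5, seed = 11)
  expect_true(all(cmp$replicates$closed.mae < cmp$replicates$open.mae))
  expect_identical(cmp$summary$closed_wins_fraction, 1)
})

test_that("YAML run configuration round-trips into config objects", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("setpoint_nl: 80", "velocity_mm_s: 400", "ki: 0.01",
               "max_step_mm: 0.1", "depth_bounds: [2.5, 4.5]",
               "drift_mm_per_step: 0.01", "noise_cv: 0.02",
               "n_steps: 12", "seed: 99"), path)
  run <- read_control_config(path)
  expect_equal(run$cfg$setpoint_nl, 80)
  expect_equal(run$cfg$depth_bounds, c(2.5, 4.5))
  expect_equal(run$proc$noise_cv, 0.02)
  expect_identical(run$n_steps, 12L)
  expect_identical(run$proc$seed, 99L)
})

test_that("run records mirror the dispensing log layout", {
  grid <- default_grid()
  st <- closed_loop_run(controller_config(), process_spec(grid = grid),
                        grid, n_steps = 5, seed = 3)
  path <- tempfile(fileext = ".csv")
  rec <- write_run_record(st, path)
  expect_true(file.exists(path))
  back <- read.csv(path)
  expect_identical(names(back), c("step", "chip_index",
                                  "commanded_depth_mm",
                                  "measured_volume_nl"))
  expect_equal(back$measured_volume_nl, st$volumes_nl)
})
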