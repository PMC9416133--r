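test_that("PID holds its commands when both setpoints are met", {
  cfg <- controller_config(mode = "single_pass")
  st <- pid_init(cfg)
  u1 <- pid_update(st, cfg, 29, 50, 0.1)
  u2 <- pid_update(u1$state, cfg, 29, 50, 0.1)
  expect_equal(u1$commands, c(50 + 14.5, 50 - 14.5), tolerance = 1e-12)
  expect_equal(u2$commands, u1$commands, tolerance = 1e-12)
})

test_that("raising the back-pressure setpoint lifts both commands equally", {
  cfg1 <- controller_config(p_ooc_setpoint = 50, mode = "single_pass")
  cfg2 <- controller_config(p_ooc_setpoint = 60, mode = "single_pass")
  c1 <- pid_update(pid_init(cfg1), cfg1, 29, 50, 0.1)$commands
  c2 <- pid_update(pid_init(cfg2), cfg2, 29, 50, 0.1)$commands
  shift <- c2 - c1
  expect_equal(shift[1], shift[2], tolerance = 1e-9)
  expect_gt(shift[1], 0)
  # the commanded difference, hence the flow, is unchanged
  expect_equal(c2[1] - c2[2], c1[1] - c1[2], tolerance = 1e-9)
})

test_that("anti-windup freezes the integral while commands saturate", {
  cfg <- controller_config(mode = "single_pass")
  st <- pid_init(cfg)
  i0 <- st$integral
  # a wildly low dP reading drives the command into the 345 mbar limit
  out <- pid_update(st, cfg, -3000, 50, 0.1)
  expect_true(out$state$anti_windup_active)
  expect_equal(out$state$integral, i0)
  expect_lte(max(out$commands), 345)
  expect_gte(min(out$commands), 0)
})

test_that("non-finite measurements hold the last command", {
  cfg <- controller_config(mode = "single_pass")
  st <- pid_init(cfg)
  good <- pid_update(st, cfg, 28, 50, 0.1)
  held <- pid_update(good$state, cfg, NaN, 50, 0.1)
  expect_true(held$state$nan_hold)
  expect_equal(held$commands, good$commands)
})

test_that("switch decisions respect threshold, hysteresis and lockout", {
  cfg <- controller_config(switch_low_volume = 3, hysteresis = 0.25,
                           lockout_s = 30, mode = "graetz")
  # donor at threshold minus hysteresis: switch
  expect_true(should_switch(c(2.75, 7), cfg, 1, time = 100,
                            last_switch_time = 0))
  # just above the threshold: hold
  expect_false(should_switch(c(3.05, 7), cfg, 1, time = 100,
                             last_switch_time = 0))
  # direction -1 watches reservoir 2
  expect_true(should_switch(c(7, 2.7), cfg, -1, time = 100,
                            last_switch_time = 0))
  # inside the lockout window: hold regardless of level
  expect_false(should_switch(c(1.5, 7), cfg, 1, time = 10,
                             last_switch_time = 0))
  expect_warning(res <- should_switch(c(NA, 7), cfg, 1, 100, 0), "stale")
  expect_false(res)
})

test_that("noisy levels at the threshold cannot chatter faster than the lockout", {
  cfg <- controller_config(switch_low_volume = 3, hysteresis = 0.1,
                           lockout_s = 30, mode = "graetz")
  set.seed(99)
  last <- -Inf
  fires <- c()
  for (t in seq(0, 300, by = 0.1)) {
    lvl <- c(2.9 + rnorm(1, 0, 0.05), 7)
    if (should_switch(lvl, cfg, 1, t, last)) {
      fires <- c(fires, t)
      last <- t
    }
  }
  expect_true(all(diff(fires) >= 30))
})

test_that("a direction switch is an involution on commands and direction", {
  s1 <- execute_switch("graetz", 1, c(64.5, 35.5))
  expect_equal(s1$direction, -1)
  expect_equal(s1$commands, c(35.5, 64.5))
  s2 <- execute_switch("graetz", s1$direction, s1$commands)
  expect_equal(s2$direction, 1)
  expect_equal(s2$commands, c(64.5, 35.5))
  # active_valve also toggles the 3/2 valves
  sv <- execute_switch("active_valve", 1, c(64.5, 35.5),
                       valve_positions = 1)
  expect_equal(sv$valve_positions, -1)
})

test_that("swapping reservoir pressures leaves the rectified sample flow unchanged", {
  gb <- fixture_circuit("graetz_bridge")
  hi <- mbar_to_pa(64.5); lo <- mbar_to_pa(35.5)
  a <- solve_network(gb, terminals = c(res1 = hi, res2 = lo))
  b <- solve_network(gb, terminals = c(res1 = lo, res2 = hi))
  expect_equal(unname(b$element_flows[["sample"]]),
               unname(a$element_flows[["sample"]]), tolerance = 1e-9)
})

test_that("zero-duration runs return empty telemetry without error", {
  net <- fixture_circuit("tubing_loop_48h")
  cfg <- controller_config(mode = "single_pass")
  run <- run_experiment(plant_state(), net, sensor_suite(), cfg, 0, 1)
  expect_equal(nrow(run$telemetry), 0)
  expect_equal(length(run$summaries), 0)
})

test_that("telemetry is bit-identical for identical seeds", {
  net <- fixture_circuit("tubing_loop_48h")
  cfg <- controller_config(mode = "single_pass")
  r1 <- run_experiment(plant_state(), net, sensor_suite(), cfg, 20, 7)
  r2 <- run_experiment(plant_state(), net, sensor_suite(), cfg, 20, 7)
  r3 <- run_experiment(plant_state(), net, sensor_suite(), cfg, 20, 8)
  expect_identical(r1$telemetry, r2$telemetry)
  expect_false(identical(r1$telemetry, r3$telemetry))
})

test_that("closed-loop dP tracking settles on the long-term circuit", {
  net <- fixture_circuit("tubing_loop_48h")
  cfg <- controller_config(mode = "single_pass")
  run <- run_experiment(plant_state(), net, sensor_suite(), cfg, 120, 1)
  post <- run$telemetry[run$telemetry$time_s > 60, ]
  expect_gt(mean(abs(post$dp_mbar - 29) < 0.02 * 29), 0.95)
  expect_equal(mean(post$q_true_ulmin), 208.5, tolerance = 0.05)
})

test_that("steady flow is decoupled from the back-pressure setpoint", {
  net <- fixture_circuit("tubing_loop_48h")
  mk <- function(pooc) controller_config(p_ooc_setpoint = pooc,
                                         mode = "single_pass")
  r50 <- run_experiment(plant_state(), net, sensor_suite(), mk(50), 90, 4)
  r70 <- run_experiment(plant_state(), net, sensor_suite(), mk(70), 90, 4)
  q50 <- mean(r50$telemetry$q_true_ulmin[r50$telemetry$time_s > 60])
  q70 <- mean(r70$telemetry$q_true_ulmin[r70$telemetry$time_s > 60])
  expect_lt(abs(q70 - q50) / q50, 0.005)
})

test_that("graetz recirculation switches on level and keeps flow unidirectional", {
  net <- fixture_circuit("graetz_bridge")
  cfg <- controller_config(dp_setpoint = 10, p_ooc_setpoint = 30,
                           mode = "graetz", switch_low_volume = 4,
                           lockout_s = 3)
  run <- run_experiment(plant_state(), net, sensor_suite(), cfg, 60, 2)
  expect_gte(run$switch_count, 2)
  tel <- run$telemetry
  # the bridge keeps the sample flow strictly forward
  expect_gte(min(tel$q_true_ulmin), 0)
  expect_equal(run$backflow_events, 0L)
  # per-sequence summaries account for the whole run
  expect_equal(length(run$summaries), run$switch_count + 1L)
  expect_equal(sum(vapply(run$summaries, `[[`, 0, "duration_s")),
               max(tel$time_s), tolerance = 1e-9)
  # displaced volume integrates the flow
  s1 <- run$summaries[[1]]
  expect_equal(s1$displaced_ml,
               s1$flow_mean_ulmin / 60 * 1e-3 * s1$duration_s,
               tolerance = 0.01)
})

test_that("desynchronised 3/2 valves cause reverse sample flow; synchronised do not", {
  net <- fixture_circuit("single_chip")
  mk <- function(lag) controller_config(
    dp_setpoint = 10, p_ooc_setpoint = 30, mode = "active_valve",
    switch_low_volume = 4, lockout_s = 3, valve_lag_ticks = lag)
  sync <- run_experiment(plant_state(), net, sensor_suite(), mk(0), 30, 3)
  lag <- run_experiment(plant_state(), net, sensor_suite(), mk(20), 30, 3)
  expect_gte(sync$switch_count, 1)
  expect_equal(sync$backflow_events, 0L)
  expect_gt(lag$backflow_events, 0L)
  expect_lt(min(lag$telemetry$q_true_ulmin), 0)
})

test_that("running a reservoir dry aborts with a diagnostic", {
  net <- fixture_circuit("single_chip")
  # single-pass with no switching and a small donor: must abort
  cfg <- controller_config(dp_setpoint = 10, p_ooc_setpoint = 30,
                           mode = "single_pass")
  st <- plant_state(res1 = reservoir(liquid_volume = ml_to_m3(1.5)),
                    res2 = reservoir(liquid_volume = ml_to_m3(5)))
  expect_error(run_experiment(st, net, sensor_suite(), cfg, 60, 1),
               class = "perfusim_dry_run")
})

test_that("the sequence notification hook fires once per sequence", {
  net <- fixture_circuit("graetz_bridge")
  seen <- new.env(); seen$n <- 0L
  cfg <- controller_config(dp_setpoint = 10, p_ooc_setpoint = 30,
                           mode = "graetz", switch_low_volume = 4,
                           lockout_s = 3,
                           on_sequence = function(s) seen$n <- seen$n + 1L)
  run <- run_experiment(plant_state(), net, sensor_suite(), cfg, 40, 5)
  expect_equal(seen$n, length(run$summaries))
})
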