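test_that("head pressure is the hydrostatic column of the cylinder", {
  r0 <- reservoir(liquid_volume = 0)
  expect_identical(head_pressure(r0), 0)
  # 5 mL in a 14 mm tube of water: rho g V / A, about 319 Pa (3.2 mbar)
  r5 <- reservoir(liquid_volume = ml_to_m3(5))
  expect_equal(head_pressure(r5),
               1000 * 9.81 * 5e-6 / (pi * 0.014^2 / 4), tolerance = 1e-12)
  expect_equal(head_pressure(r5), 319, tolerance = 2e-3)
  # linear in volume
  r10 <- reservoir(liquid_volume = ml_to_m3(10))
  expect_equal(head_pressure(r10), 2 * head_pressure(r5),
               tolerance = 1e-12)
})

test_that("combined head drift per displaced mL matches the geometry", {
  d <- head_drift_per_ml()
  expect_equal(d, pa_to_mbar(1000 * 9.81 * 2 / (pi * 0.014^2 / 4) * 1e-6),
               tolerance = 1e-12)
  # two equal reservoirs drift exactly twice the single-reservoir term
  single <- pa_to_mbar(1000 * 9.81 / (pi * 0.014^2 / 4) * 1e-6)
  expect_equal(d, 2 * single, tolerance = 1e-12)
  # an effectively infinite reservoir contributes nothing
  huge <- reservoir(inner_diameter = 10)
  expect_lt(head_drift_per_ml(huge, huge), 1e-5)
  expect_equal(head_drift_per_ml(reservoir(), huge), single,
               tolerance = 1e-4)
})

test_that("effective driving pressure combines air and head, flags dry runs", {
  st <- plant_state()
  expect_equal(as.numeric(effective_driving_pressure(st)), 0)
  expect_false(attr(effective_driving_pressure(st), "dry_run"))
  # fixed air dP, 2 mL transferred from balance: dP drops by 2 x drift
  st2 <- plant_state(res1 = reservoir(liquid_volume = ml_to_m3(3),
                                      applied_air_pressure = 2900),
                     res2 = reservoir(liquid_volume = ml_to_m3(7)))
  dp <- as.numeric(effective_driving_pressure(st2))
  expect_equal(dp, 2900 - mbar_to_pa(2 * head_drift_per_ml()),
               tolerance = 1e-9)
  # donor at its dead volume: dry-run flag
  st3 <- plant_state(res1 = reservoir(liquid_volume = ml_to_m3(1),
                                      dead_volume = ml_to_m3(1),
                                      applied_air_pressure = 2900))
  expect_true(attr(effective_driving_pressure(st3), "dry_run"))
})

test_that("pneumatic channels settle first-order with asymmetric venting", {
  pn <- pneumatic_channel(command = 20000, current_pressure = 0,
                          pressurize_tau = 0.3)
  for (i in 1:150) pn <- pneumatic_relax_for_test(pn, 0.01)
  # 1.5 s = 5 time constants: settled to better than 99%
  expect_gt(pn$current_pressure, 0.99 * 20000)
  # venting: slower channel decays less over the same time
  slow <- pneumatic_channel(command = 0, current_pressure = 20000,
                            vent_tau = 2)
  fast <- pneumatic_channel(command = 0, current_pressure = 20000,
                            vent_tau = 1)
  for (i in 1:100) {
    slow <- pneumatic_relax_for_test(slow, 0.01)
    fast <- pneumatic_relax_for_test(fast, 0.01)
  }
  expect_gt(slow$current_pressure, fast$current_pressure)
  # exact exponential: one 1 s vent step with tau 1 leaves exp(-1)
  one <- pneumatic_relax_for_test(
    pneumatic_channel(command = 0, current_pressure = 1000, vent_tau = 1), 1)
  expect_equal(one$current_pressure, 1000 * exp(-1), tolerance = 1e-12)
})

test_that("plant stepping conserves volume and holds at equilibrium", {
  net <- fixture_circuit("tubing_loop_48h")
  st <- plant_state(res1 = reservoir(liquid_volume = ml_to_m3(6),
                                     applied_air_pressure = 2900),
                    res2 = reservoir(liquid_volume = ml_to_m3(4)))
  st$pn1$command <- 2900; st$pn1$current_pressure <- 2900
  st$pn2$command <- 0
  v0 <- st$res1$liquid_volume + st$res2$liquid_volume
  for (i in 1:1000) st <- plant_step(st, net, 0.01)
  v1 <- st$res1$liquid_volume + st$res2$liquid_volume
  expect_lt(abs(v1 - v0), 1e-12 * 1e-6)   # < 1e-12 mL
  expect_gt(st$res2$liquid_volume, ml_to_m3(4))  # flow went 1 -> 2
  # command equal to current pressure: pressures unchanged
  stq <- plant_state()
  stq$pn1$command <- stq$pn1$current_pressure <- 5000
  stq2 <- plant_step(stq, net, 0.01)
  expect_equal(stq2$pn1$current_pressure, 5000, tolerance = 1e-12)
  # over-long steps warn
  expect_warning(plant_step(stq, net, 0.5), "large")
})

test_that("under constant commands the flow decays at the head-drift rate", {
  net <- fixture_circuit("tubing_loop_48h")
  rh <- resistance_circular(circular_tube(0.08, 250e-6),
                            fluid("water-20C"))
  st <- plant_state(res1 = reservoir(liquid_volume = ml_to_m3(9),
                                     applied_air_pressure = 2900),
                    res2 = reservoir(liquid_volume = ml_to_m3(1)))
  st$pn1$command <- st$pn1$current_pressure <- 2900
  flows <- numeric(0)
  vols <- numeric(0)
  for (i in 1:4000) {   # 40 s
    st <- plant_step(st, net, 0.01)
    if (i %% 100 == 0) {
      flows <- c(flows, st$last_flow)
      vols <- c(vols, st$res2$liquid_volume)
    }
  }
  expect_false(st$dry_run)
  # monotone decrease as volume is displaced
  expect_true(all(diff(flows) < 0))
  # decay in mbar per displaced mL equals the closed-form head drift
  dp_drop_mbar <- pa_to_mbar((flows[1] - flows[length(flows)]) * rh)
  displaced_ml <- m3_to_ml(vols[length(vols)] - vols[1])
  expect_equal(dp_drop_mbar / displaced_ml, head_drift_per_ml(),
               tolerance = 0.01)
})

test_that("a reservoir is clamped at its dead volume and flagged", {
  net <- fixture_circuit("single_chip")  # fast drain
  st <- plant_state(res1 = reservoir(liquid_volume = ml_to_m3(1.2),
                                     dead_volume = ml_to_m3(1),
                                     applied_air_pressure = 2900),
                    res2 = reservoir(liquid_volume = ml_to_m3(5)))
  st$pn1$command <- st$pn1$current_pressure <- 2900
  for (i in 1:500) st <- plant_step(st, net, 0.01)
  expect_true(st$dry_run)
  expect_equal(st$res1$liquid_volume, ml_to_m3(1), tolerance = 1e-9)
})
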