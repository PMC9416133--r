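med <- fluid("medium-37C")
wat <- fluid("water-20C")

test_that("rectangular channel resistance matches the Poiseuille approximation", {
  # 1.1 cm x 500 um x 500 um chip in culture medium: hand evaluation of
  # 12 mu L / (w h^3 (1 - 0.63)) = 4.509e9 Pa s m^-3
  rh <- resistance_rectangular(rect_channel(0.011, 500e-6, 500e-6), med)
  expect_equal(rh, 12 * 0.00079 * 0.011 / (500e-6 * (500e-6)^3 * 0.37),
               tolerance = 1e-12)
  expect_equal(rh, 4.509e9, tolerance = 1e-3)
  # linear in length
  rh2 <- resistance_rectangular(rect_channel(0.022, 500e-6, 500e-6), med)
  expect_equal(rh2, 2 * rh, tolerance = 1e-12)
  # square channel correction factor is exactly 1 - 0.63
  # orientation invariance: swapping width and height changes nothing
  a <- resistance_rectangular(rect_channel(0.01, 1e-3, 2e-4), med)
  b <- resistance_rectangular(rect_channel(0.01, 2e-4, 1e-3), med)
  expect_identical(a, b)
  expect_gt(rh, 0)
})

test_that("circular tube resistance follows the d^4 law", {
  rh <- resistance_circular(circular_tube(0.08, 250e-6), wat)
  expect_equal(rh, 128 * 0.001 * 0.08 / (pi * (250e-6)^4), tolerance = 1e-12)
  expect_equal(rh, 8.344e11, tolerance = 1e-3)
  rh_half <- resistance_circular(circular_tube(0.08, 125e-6), wat)
  expect_equal(rh_half / rh, 16, tolerance = 1e-10)
})

test_that("invalid geometry is rejected", {
  expect_error(rect_channel(0, 1e-3, 1e-3), "positive")
  expect_error(rect_channel(0.01, -1e-3, 1e-3), "positive")
  expect_error(circular_tube(0.08, 0), "positive")
  expect_error(circular_tube(-1, 1e-3), "positive")
  expect_error(fixed_resistor(-5), ">= 0")
  expect_error(fluid_properties(0), "positive")
})

test_that("series and parallel reduction laws hold", {
  expect_identical(series_total(numeric(0)), 0)
  expect_equal(series_total(c(1e9, 2e9, 3e9)), 6e9)
  expect_equal(series_total(c(5e8, 0)), 5e8)
  r <- c(3e9, 1e9, 7e9)
  expect_equal(series_total(r), series_total(rev(r)))
  expect_equal(parallel_total(c(4e9, 4e9)), 2e9)
  expect_equal(parallel_total(rep(4.5e9, 6)), 4.5e9 / 6)
  expect_equal(parallel_total(5e9), 5e9)
  expect_identical(parallel_total(c(1e9, 0)), 0)  # short circuit
  expect_error(parallel_total(numeric(0)), "at least one")
})

test_that("branch flow is the fluidic Ohm's law", {
  rh <- resistance_circular(circular_tube(0.08, 250e-6), wat)
  expect_identical(branch_flow(0, rh), 0)
  # 29 mbar across the long-term tubing: about 200 uL/min on the bench
  q <- m3s_to_ulmin(branch_flow(mbar_to_pa(29), rh))
  expect_equal(q, 200, tolerance = 0.1)
  expect_equal(branch_flow(2 * 2900, rh), 2 * branch_flow(2900, rh))
  expect_error(branch_flow(100, 0), "> 0")
})

test_that("two resistors in series solve to the series-reduced flow", {
  els <- list(fixed_resistor(1e9, from = "T1", to = "m", id = "r1"),
              fixed_resistor(2e9, from = "m", to = "T2", id = "r2"))
  net <- fluidic_network(els, c(T1 = 3000, T2 = 0), wat)
  sol <- solve_network(net)
  expect_true(sol$converged)
  q_expect <- 3000 / 3e9
  expect_equal(unname(sol$element_flows[["r1"]]), q_expect,
               tolerance = 1e-9)
  expect_equal(unname(sol$element_flows[["r2"]]), q_expect,
               tolerance = 1e-9)
})

test_that("solver matches the series-parallel reduction oracle", {
  set.seed(42)
  for (i in 1:20) {
    lad <- random_ladder()
    sol <- solve_network(lad$net)
    q <- terminal_flow(sol, lad$net, "T1")
    expect_equal(q, 2000 / lad$r_total, tolerance = 1e-9)
  }
})

test_that("independent parallel branches each carry dP/Rh", {
  set.seed(7)
  rs <- 10^runif(6, 9, 11)
  els <- lapply(seq_along(rs), function(b)
    fixed_resistor(rs[b], from = "T1", to = "T2", id = paste0("b", b)))
  net <- fluidic_network(els, c(T1 = 2900, T2 = 0), wat)
  sol <- solve_network(net)
  for (b in seq_along(rs))
    expect_equal(unname(sol$element_flows[[paste0("b", b)]]),
                 branch_flow(2900, rs[b]), tolerance = 1e-12)
})

test_that("flows scale linearly with the terminal pressure difference", {
  set.seed(11)
  lad <- random_ladder()
  s1 <- solve_network(lad$net, terminals = c(T1 = 1000, T2 = 0))
  s3 <- solve_network(lad$net, terminals = c(T1 = 3000, T2 = 0))
  expect_equal(unname(s3$element_flows), unname(3 * s1$element_flows),
               tolerance = 1e-9)
})

test_that("mass is conserved at internal nodes", {
  set.seed(5)
  for (i in 1:5) {
    lad <- random_ladder()
    sol <- solve_network(lad$net)
    expect_lt(sol$kcl_residual,
              1e-12 * max(abs(sol$element_flows)))
  }
  sol <- solve_network(fixture_circuit("graetz_bridge"))
  expect_lt(sol$kcl_residual, 1e-12 * max(abs(sol$element_flows)))
})

test_that("the Graetz bridge rectifies the sample flow", {
  gb <- fixture_circuit("graetz_bridge")
  fwd <- solve_network(gb, terminals = c(res1 = 2900, res2 = 0))
  rev <- solve_network(gb, terminals = c(res1 = 0, res2 = 2900))
  expect_true(fwd$converged && rev$converged)
  qf <- unname(fwd$element_flows[["sample"]])
  qr <- unname(rev$element_flows[["sample"]])
  # sample flow keeps its sign; reservoir-side flow reverses
  expect_gt(qf, 0)
  expect_equal(qr, qf, tolerance = 1e-9)
  expect_equal(terminal_flow(rev, gb, "res1"),
               -terminal_flow(fwd, gb, "res1"), tolerance = 1e-9)
  # equal terminal pressures: no flow anywhere
  eq <- solve_network(gb, terminals = c(res1 = 1500, res2 = 1500))
  expect_lt(max(abs(eq$element_flows)), 1e-15)
  # the diagonal valve pair conducts, the other pair is shut with zero flow
  expect_identical(unname(fwd$valve_states[c("v1", "v4")]),
                   c("open", "open"))
  expect_identical(unname(fwd$valve_states[c("v2", "v3")]),
                   c("closed", "closed"))
  expect_identical(unname(fwd$element_flows[c("v2", "v3")]), c(0, 0))
})

test_that("cracking pressure shifts the bridge flow and can block it", {
  pc <- 500  # Pa
  gb <- fixture_circuit("graetz_bridge", cracking_pressure = pc)
  sol <- solve_network(gb, terminals = c(res1 = 2900, res2 = 0))
  cc <- compile_network(gb)
  rs <- 1 / cc$g[cc$ids == "sample"]
  rv <- 1 / cc$g[cc$ids == "v1"]
  # two open valves each drop their cracking pressure plus Q * Rf
  expect_equal(unname(sol$element_flows[["sample"]]),
               (2900 - 2 * pc) / (rs + 2 * rv), tolerance = 1e-9)
  # below twice the cracking pressure nothing conducts
  low <- solve_network(gb, terminals = c(res1 = 900, res2 = 0))
  expect_lt(max(abs(low$element_flows)), 1e-15)
})

test_that("network validation catches malformed inputs", {
  expect_error(fluidic_network(
    list(fixed_resistor(1e9, from = "a", to = "b", id = "r1"),
         fixed_resistor(1e9, from = "c", to = "d", id = "r2")),
    c(a = 100, d = 0), wat), "not connected")
  expect_error(fluidic_network(
    list(fixed_resistor(1e9, from = "a", to = "b")),
    c(a = 100, z = 0), wat), "not present")
  expect_error(fluidic_network(
    list(fixed_resistor(1e9, from = "a", to = "b", id = "x"),
         fixed_resistor(2e9, from = "a", to = "b", id = "x")),
    c(a = 100, b = 0), wat), "duplicate")
  # zero-resistance links are rejected at compile time
  expect_error(solve_network(fluidic_network(
    list(fixed_resistor(0, from = "a", to = "b")),
    c(a = 100, b = 0), wat)), "non-positive resistance")
})
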