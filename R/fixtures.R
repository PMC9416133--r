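#' Reference fixture circuits
#'
#' Builders for the bench circuits the package is validated against:
#'
#' * `single_chip`: one 1.1 cm x 500 um x 500 um PDMS channel perfused
#'   with culture medium between the two reservoirs.
#' * `tubing_loop_48h`: the long-term rig -- an 8 cm length of 250 um
#'   inner-diameter tubing perfused with water; at a controlled dP of
#'   29 mbar it carries roughly 200 uL/min. An optional lumped
#'   flow-sensor resistance can be placed in series (default 0 =
#'   omitted).
#' * `fcb_6ch` / `fcb_12ch`: the multiplexing board with two devices
#'   (6 channels) or four devices (12 channels) connected.
#' * `graetz_bridge`: four check valves in bridge orientation around a
#'   single chip, so the sample flow stays unidirectional while the
#'   reservoir-side flow alternates.
#' * `full_system`: the recirculating long-term rig -- the tubing sample
#'   inside the Graetz bridge.
#'
#' @param name Fixture name.
#' @param dp_mbar Default terminal pressure difference, mbar.
#' @param sensor_resistance Lumped flow-sensor resistance in Pa s m^-3
#'   (tubing fixtures; 0 omits the element).
#' @param cracking_pressure Check-valve cracking pressure, Pa (bridge
#'   fixtures).
#' @return A [fluidic_network()].
#' @examples
#' solve_network(fixture_circuit("tubing_loop_48h"))
#' @export
fixture_circuit <- function(name = c("single_chip", "tubing_loop_48h",
                                     "fcb_6ch", "fcb_12ch",
                                     "graetz_bridge", "full_system"),
                            dp_mbar = 29, sensor_resistance = 0,
                            cracking_pressure = 0) {
  name <- match.arg(name)
  dp <- mbar_to_pa(dp_mbar)
  chip <- function(from, to, id = "chip")
    rect_channel(0.011, 500e-6, 500e-6, from = from, to = to, id = id)
  tube <- function(from, to, id = "tube")
    circular_tube(0.08, 250e-6, from = from, to = to, id = id)
  bridge <- function(sample_els, sample_id) {
    els <- c(list(
      check_valve(cracking_pressure, from = "res1", to = "A", id = "v1"),
      check_valve(cracking_pressure, from = "res2", to = "A", id = "v2"),
      check_valve(cracking_pressure, from = "B", to = "res1", id = "v3"),
      check_valve(cracking_pressure, from = "B", to = "res2", id = "v4")),
      sample_els)
    fluidic_network(els, terminals = c(res1 = dp, res2 = 0),
                    fluid = fluid("water-20C"), sample_ids = sample_id)
  }
  switch(name,
    single_chip = fluidic_network(
      list(chip("res1", "res2")),
      terminals = c(res1 = dp, res2 = 0),
      fluid = fluid("medium-37C"), sample_ids = "chip"),
    tubing_loop_48h = {
      els <- if (sensor_resistance > 0) list(
        tube("res1", "n1"),
        fixed_resistor(sensor_resistance, from = "n1", to = "res2",
                       id = "flow_sensor"))
      else list(tube("res1", "res2"))
      fluidic_network(els, terminals = c(res1 = dp, res2 = 0),
                      fluid = fluid("water-20C"), sample_ids = "tube")
    },
    fcb_6ch = build_fcb_network(
      fcb_layout(occupancy = c(TRUE, TRUE, FALSE, FALSE)),
      fluid("medium-37C"), dp_mbar),
    fcb_12ch = build_fcb_network(
      fcb_layout(occupancy = rep(TRUE, 4)),
      fluid("medium-37C"), dp_mbar),
    graetz_bridge = bridge(list(chip("A", "B", id = "sample")), "sample"),
    full_system = bridge(list(tube("A", "B", id = "sample")), "sample"))
}

#' Write the fixture circuits and run configurations to disk
#'
#' Emits each fixture as a JSON circuit file plus a matching run
#' configuration (`<name>_config.json`): recirculating (graetz) configs
#' for the bridge fixtures, single-pass for the rest.
#'
#' @param out_dir Writable directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
generate_fixtures <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  names <- c("single_chip", "tubing_loop_48h", "fcb_6ch", "fcb_12ch",
             "graetz_bridge", "full_system")
  paths <- character(0)
  for (nm in names) {
    net <- fixture_circuit(nm)
    p <- file.path(out_dir, paste0(nm, ".json"))
    write_circuit(net, p)
    # the chip-sample bridge drains a 15 mL reservoir in seconds at
    # 29 mbar; its config uses a gentler setpoint and a short lockout
    ctl <- if (nm == "graetz_bridge")
      list(mode = "graetz", dp_setpoint_mbar = 10,
           p_ooc_setpoint_mbar = 30, switch_low_ml = 4, lockout_s = 3)
    else if (nm == "full_system") list(mode = "graetz")
    else list(mode = "single_pass")
    cfgp <- file.path(out_dir, paste0(nm, "_config.json"))
    save_config(normalize_config(c(list(circuit = paste0(nm, ".json")),
                                   list(controller = ctl))),
                cfgp)
    paths <- c(paths, p, cfgp)
  }
  invisible(paths)
}
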