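#' Write a fluidic network to a JSON circuit file
#'
#' The circuit format uses explicit unit suffixes in all human-facing
#' fields: geometric lengths in `_mm`/`_um`, pressures in `_mbar`,
#' resistances in `_pa_s_m3`. Element kinds are `rect`, `tube`,
#' `resistor` and `check_valve`.
#'
#' @param net A [fluidic_network()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_circuit <- function(net, path) {
  stopifnot(inherits(net, "fluidic_network"))
  serialize_el <- function(el) {
    base <- list(id = el$id, from = el$from, to = el$to)
    if (inherits(el, "rect_channel"))
      c(base, list(kind = "rect", length_mm = el$length * 1e3,
                   width_um = el$width * 1e6, height_um = el$height * 1e6))
    else if (inherits(el, "circular_tube"))
      c(base, list(kind = "tube", length_mm = el$length * 1e3,
                   diameter_um = el$diameter * 1e6))
    else if (inherits(el, "fixed_resistor"))
      c(base, list(kind = "resistor",
                   resistance_pa_s_m3 = el$resistance))
    else if (inherits(el, "check_valve")) {
      out <- c(base, list(kind = "check_valve",
                          cracking_pressure_mbar =
                            pa_to_mbar(el$cracking_pressure)))
      if (!is.null(el$forward_resistance))
        out$forward_resistance_pa_s_m3 <- el$forward_resistance
      out
    } else stop("unserialisable element kind")
  }
  doc <- list(
    fluid = list(label = net$fluid$label,
                 viscosity_pa_s = net$fluid$dynamic_viscosity,
                 density_kg_m3 = net$fluid$density),
    terminals = lapply(as.list(net$terminals),
                       function(p) list(pressure_mbar = pa_to_mbar(p))),
    elements = lapply(net$elements, serialize_el),
    sample_ids = as.list(net$sample_ids))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

required_keys <- function(x, keys, where) {
  miss <- setdiff(keys, names(x))
  if (length(miss))
    stop(where, ": missing key(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
}

reject_unknown <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop(where, ": unknown key(s) ", paste(extra, collapse = ", "),
         call. = FALSE)
}

#' Read a fluidic network from a JSON circuit file
#'
#' Validates the schema strictly: unknown element kinds or keys are
#' rejected with a message naming the offender, and all quantities are
#' converted to SI internally.
#'
#' @param path Circuit file path.
#' @return A [fluidic_network()].
#' @export
read_circuit <- function(path) {
  if (!file.exists(path)) stop("circuit file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  reject_unknown(doc, c("fluid", "terminals", "elements", "sample_ids"),
                 "circuit")
  required_keys(doc, c("fluid", "terminals", "elements"), "circuit")
  fl <- doc$fluid
  reject_unknown(fl, c("label", "viscosity_pa_s", "density_kg_m3"),
                 "fluid")
  required_keys(fl, "viscosity_pa_s", "fluid")
  fluid <- fluid_properties(fl$viscosity_pa_s,
                            if (is.null(fl$density_kg_m3)) 1000
                            else fl$density_kg_m3,
                            if (is.null(fl$label)) "custom" else fl$label)
  parse_el <- function(e, k) {
    where <- sprintf("element %d", k)
    required_keys(e, c("id", "from", "to", "kind"), where)
    switch(as.character(e$kind),
      rect = {
        reject_unknown(e, c("id", "from", "to", "kind", "length_mm",
                            "width_um", "height_um"), where)
        required_keys(e, c("length_mm", "width_um", "height_um"), where)
        rect_channel(e$length_mm / 1e3, e$width_um / 1e6,
                     e$height_um / 1e6, e$from, e$to, e$id)
      },
      tube = {
        reject_unknown(e, c("id", "from", "to", "kind", "length_mm",
                            "diameter_um"), where)
        required_keys(e, c("length_mm", "diameter_um"), where)
        circular_tube(e$length_mm / 1e3, e$diameter_um / 1e6,
                      e$from, e$to, e$id)
      },
      resistor = {
        reject_unknown(e, c("id", "from", "to", "kind",
                            "resistance_pa_s_m3"), where)
        required_keys(e, "resistance_pa_s_m3", where)
        fixed_resistor(e$resistance_pa_s_m3, e$from, e$to, e$id)
      },
      check_valve = {
        reject_unknown(e, c("id", "from", "to", "kind",
                            "cracking_pressure_mbar",
                            "forward_resistance_pa_s_m3"), where)
        check_valve(mbar_to_pa(if (is.null(e$cracking_pressure_mbar)) 0
                               else e$cracking_pressure_mbar),
                    e$forward_resistance_pa_s_m3, e$from, e$to, e$id)
      },
      stop(where, ": unknown element kind '", e$kind, "'", call. = FALSE))
  }
  els <- Map(parse_el, doc$elements, seq_along(doc$elements))
  terms <- vapply(doc$terminals, function(t) {
    reject_unknown(t, "pressure_mbar", "terminal")
    required_keys(t, "pressure_mbar", "terminal")
    mbar_to_pa(t$pressure_mbar)
  }, numeric(1))
  sample_ids <- if (length(doc$sample_ids))
    unlist(doc$sample_ids) else NULL
  fluidic_network(unname(els), terms, fluid, sample_ids)
}

config_defaults <- function() {
  list(
    circuit = "tubing_loop_48h",
    seed = 1L,
    duration_s = 600,
    out = NULL,
    controller = list(dp_setpoint_mbar = 29, p_ooc_setpoint_mbar = 50,
                      mode = "single_pass", switch_low_ml = 3,
                      switch_high_ml = 12, hysteresis_ml = 0.25,
                      lockout_s = 30, command_limit_mbar = 345,
                      loop_rate_hz = 10, kp = 0.5, ki = 0.2, kd = 0,
                      ki_mid = 0.2, plant_dt_s = 0.01),
    plant = list(reservoir_diameter_mm = 14, volume1_ml = 5,
                 volume2_ml = 5, dead_volume_ml = 1, capacity_ml = 15,
                 density_kg_m3 = 1000, pressurize_tau_s = 0.3,
                 vent_tau1_s = 2.0, vent_tau2_s = 1.0),
    sensors = list(flow_size = "L", fouling_gain = 1,
                   flow_noise_ulmin = 2, pressure_noise_pa = 5,
                   level_mode = "direct", level_tube_diameter_mm = 3,
                   level_noise_pa = 0.5))
}

#' Validate and default-fill a run configuration
#'
#' @param x A (possibly partial) configuration list; unknown keys are
#'   rejected with a message naming the key.
#' @param base_dir Directory against which a relative circuit path is
#'   resolved.
#' @return An object of class `run_config` whose `raw` field holds the
#'   normalized configuration (all defaults filled, interface units).
#' @export
normalize_config <- function(x, base_dir = ".") {
  def <- config_defaults()
  reject_unknown(x, names(def), "config")
  for (sect in c("controller", "plant", "sensors")) {
    if (is.null(x[[sect]])) next
    reject_unknown(x[[sect]], names(def[[sect]]), sect)
    def[[sect]][names(x[[sect]])] <- x[[sect]]
  }
  for (key in c("circuit", "seed", "duration_s", "out"))
    if (!is.null(x[[key]])) def[[key]] <- x[[key]]
  ctl <- def$controller
  if (!ctl$mode %in% c("graetz", "active_valve", "single_pass"))
    stop("controller: unknown mode '", ctl$mode, "'")
  if (!def$sensors$level_mode %in% c("direct", "remote"))
    stop("sensors: unknown level_mode '", def$sensors$level_mode, "'")
  stopifnot(def$duration_s >= 0)
  structure(list(raw = def, base_dir = base_dir), class = "run_config")
}

#' Load a run configuration file
#'
#' @param path JSON configuration file.
#' @return A `run_config` (see [normalize_config()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  normalize_config(x, base_dir = dirname(path))
}

#' Save a normalized run configuration
#'
#' @param cfg A `run_config`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  jsonlite::write_json(cfg$raw, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Instantiate simulation objects from a run configuration
#'
#' @param cfg A `run_config`.
#' @return List with `net`, `plant`, `sensors`, `config` (controller),
#'   `seed` and `duration_s`, ready for [run_experiment()].
#' @export
build_simulation <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  r <- cfg$raw
  fixture_names <- c("single_chip", "tubing_loop_48h", "fcb_6ch",
                     "fcb_12ch", "graetz_bridge", "full_system")
  net <- if (r$circuit %in% fixture_names) fixture_circuit(r$circuit)
  else {
    p <- r$circuit
    if (!file.exists(p)) p <- file.path(cfg$base_dir, r$circuit)
    read_circuit(p)
  }
  pl <- r$plant
  mk_res <- function(v) reservoir(
    inner_diameter = pl$reservoir_diameter_mm / 1e3,
    liquid_volume = ml_to_m3(v),
    dead_volume = ml_to_m3(pl$dead_volume_ml),
    density = pl$density_kg_m3,
    capacity = ml_to_m3(pl$capacity_ml))
  plant <- plant_state(
    res1 = mk_res(pl$volume1_ml), res2 = mk_res(pl$volume2_ml),
    pn1 = pneumatic_channel(pressurize_tau = pl$pressurize_tau_s,
                            vent_tau = pl$vent_tau1_s),
    pn2 = pneumatic_channel(pressurize_tau = pl$pressurize_tau_s,
                            vent_tau = pl$vent_tau2_s))
  sn <- r$sensors
  sensors <- sensor_suite(
    flow = flow_sensor(sn$flow_size, fouling_gain = sn$fouling_gain,
                       noise_sd = sn$flow_noise_ulmin),
    pressure = gauge_pressure_pair(noise_sd = sn$pressure_noise_pa),
    level = level_sensor(sn$level_mode,
                         tube_diameter = sn$level_tube_diameter_mm / 1e3),
    level_noise_sd = sn$level_noise_pa)
  ctl <- r$controller
  config <- controller_config(
    dp_setpoint = ctl$dp_setpoint_mbar,
    p_ooc_setpoint = ctl$p_ooc_setpoint_mbar, mode = ctl$mode,
    switch_low_volume = ctl$switch_low_ml,
    switch_high_volume = ctl$switch_high_ml,
    hysteresis = ctl$hysteresis_ml, lockout_s = ctl$lockout_s,
    command_limits = c(0, ctl$command_limit_mbar),
    loop_rate = ctl$loop_rate_hz,
    gains = pid_gains(ctl$kp, ctl$ki, ctl$kd),
    ki_mid = ctl$ki_mid, plant_dt = ctl$plant_dt_s)
  list(net = net, plant = plant, sensors = sensors, config = config,
       seed = r$seed, duration_s = r$duration_s, out = r$out)
}

#' Run a configured experiment and persist its outputs
#'
#' @param cfg A `run_config` (from [load_config()] or
#'   [normalize_config()]).
#' @param duration_s Optional override of the configured duration, s.
#' @param out Optional override of the telemetry CSV path; per-sequence
#'   summaries are written beside it as JSON lines
#'   (`<out>.summaries.jsonl`).
#' @return The [run_experiment()] result, invisibly if written to disk.
#' @export
run_from_config <- function(cfg, duration_s = NULL, out = NULL) {
  sim <- build_simulation(cfg)
  if (is.null(duration_s)) duration_s <- sim$duration_s
  if (is.null(out)) out <- sim$out
  run <- run_experiment(sim$plant, sim$net, sim$sensors, sim$config,
                        duration_s, sim$seed)
  if (!is.null(out)) {
    utils::write.csv(run$telemetry, out, row.names = FALSE)
    sf <- paste0(out, ".summaries.jsonl")
    con <- file(sf, "w")
    for (s in run$summaries)
      writeLines(jsonlite::toJSON(s, auto_unbox = TRUE, digits = NA), con)
    close(con)
    return(invisible(run))
  }
  run
}
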