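#' Thermal flow sensor model
#'
#' Thermal mass-flow sensors are accurate when clean but are fouled by
#' culture-medium deposits during long-term perfusion, after which they
#' systematically under-read. The model is a constant multiplicative
#' fouling gain (1 = clean, smaller = fouled), additive Gaussian noise,
#' and clipping to the sensor's calibrated range. Two stock ranges are
#' provided: size L (-1100 to +1000 uL/min) and size XL (-5500 to
#' +5500 uL/min).
#'
#' @param size `"L"` or `"XL"`; ignored if `range` is given.
#' @param range Length-2 numeric, calibrated range in uL/min.
#' @param fouling_gain Multiplicative gain in (0, 1]; 1 means clean.
#' @param noise_sd Gaussian noise standard deviation, uL/min.
#' @return An object of class `flow_sensor`.
#' @export
flow_sensor <- function(size = c("L", "XL"), range = NULL,
                        fouling_gain = 1, noise_sd = 0) {
  if (is.null(range)) {
    size <- match.arg(size)
    range <- switch(size, L = c(-1100, 1000), XL = c(-5500, 5500))
  } else {
    size <- "custom"
    stopifnot(length(range) == 2L, range[1] < range[2])
  }
  if (!is.numeric(fouling_gain) || fouling_gain <= 0 || fouling_gain > 1)
    stop("fouling_gain must be in (0, 1]")
  stopifnot(noise_sd >= 0)
  structure(list(size = size, range = range, fouling_gain = fouling_gain,
                 noise_sd = noise_sd),
            class = "flow_sensor")
}

#' Read a (possibly fouled) flow sensor
#'
#' @param sensor A [flow_sensor()].
#' @param true_q True volumetric flow in uL/min.
#' @param t Time in s (accepted for interface symmetry; the constant-gain
#'   fouling model does not use it).
#' @return Measured flow in uL/min:
#'   `clip(fouling_gain * true_q + noise, range)`. Noise is drawn from the
#'   current RNG stream; seed at the run level for reproducibility.
#' @examples
#' s <- flow_sensor("L", fouling_gain = 0.25)
#' read_flow(s, 400)   # reads 100: a fouled sensor under-reports
#' @export
read_flow <- function(sensor, true_q, t = 0) {
  stopifnot(inherits(sensor, "flow_sensor"))
  m <- sensor$fouling_gain * true_q
  if (sensor$noise_sd > 0)
    m <- m + stats::rnorm(length(m), 0, sensor$noise_sd)
  pmin(pmax(m, sensor$range[1]), sensor$range[2])
}

#' Steady-state flow reached by fixed-flow-rate control on a fouled sensor
#'
#' Simulates the documented failure mode of running a pressure controller
#' in constant-flow-rate mode against a fouled thermal sensor: the
#' internal PID raises the driving pressure until the *measured* flow
#' matches the setpoint, so the *true* flow settles at
#' `setpoint / fouling_gain` -- a sensor reading a quarter of the real
#' flow drives the sample at four times the intended rate. The loop is
#' actually integrated (discrete PI on the fouled reading against a
#' linear circuit), not evaluated from the closed form, so pressure
#' saturation is detected naturally.
#'
#' @param fouling_gain Sensor gain in (0, 1].
#' @param setpoint Flow setpoint in uL/min (> 0).
#' @param rh Total hydraulic resistance of the circuit, Pa s m^-3.
#' @param p_max Controller pressure limit in mbar (default 345).
#' @param ki Integral gain of the internal loop, mbar per (uL/min x s).
#' @param dt,max_time Integration step and horizon, s.
#' @return List with `true_flow` (uL/min), `measured_flow`, `pressure_mbar`
#'   and `saturated` (TRUE when the required pressure exceeds `p_max`).
#' @examples
#' rh <- resistance_circular(circular_tube(0.08, 250e-6), fluid("water-20C"))
#' closed_loop_flow_bias(0.25, 50, rh)$true_flow   # about 200
#' @export
closed_loop_flow_bias <- function(fouling_gain, setpoint, rh,
                                  p_max = 345, ki = 0.05,
                                  dt = 0.1, max_time = 600) {
  stopifnot(fouling_gain > 0, fouling_gain <= 1, setpoint > 0, rh > 0)
  u <- 0                                   # commanded pressure, mbar
  n <- ceiling(max_time / dt)
  true_q <- 0
  for (i in seq_len(n)) {
    true_q <- m3s_to_ulmin(mbar_to_pa(u) / rh)
    meas <- fouling_gain * true_q
    e <- setpoint - meas
    u <- min(max(u + ki * e * dt, 0), p_max)
    if (abs(e) < 1e-9 * setpoint && i > 10) break
  }
  true_q <- m3s_to_ulmin(mbar_to_pa(u) / rh)
  list(true_flow = true_q,
       measured_flow = fouling_gain * true_q,
       pressure_mbar = u,
       saturated = u >= p_max &&
         fouling_gain * true_q < setpoint * (1 - 1e-6))
}

#' Paired gauge pressure sensors with signal dampening
#'
#' The pressure difference across the samples is measured with two
#' separate gauge sensors rather than one differential sensor; their
#' noisy streams (nominally 100 Hz) are dampened by averaging a window of
#' samples before the difference is formed, trading response time for a
#' stable dP estimate.
#'
#' @param offset Length-2 numeric, per-sensor zero offsets in Pa.
#' @param noise_sd Per-sample Gaussian noise SD in Pa.
#' @param sample_rate Sampling rate in Hz (default 100).
#' @param window Dampening window length in samples (>= 1).
#' @param full_scale Full scale in Pa for optional quantisation
#'   (default 300 mbar gauge).
#' @return An object of class `gauge_pressure_pair`.
#' @export
gauge_pressure_pair <- function(offset = c(0, 0), noise_sd = 0,
                                sample_rate = 100, window = 10,
                                full_scale = 30000) {
  stopifnot(length(offset) == 2L, noise_sd >= 0, sample_rate > 0,
            window >= 1, full_scale > 0)
  structure(list(offset = offset, noise_sd = noise_sd,
                 sample_rate = sample_rate, window = as.integer(window),
                 full_scale = full_scale),
            class = "gauge_pressure_pair")
}

#' Dampened differential pressure reading
#'
#' Draws `window` noisy samples from each gauge sensor at the true inlet
#' and outlet pressures, averages each stream, and returns the dampened
#' difference. For white noise the variance of the dP estimate scales as
#' 1/window.
#'
#' @param pair A [gauge_pressure_pair()].
#' @param p_inlet,p_outlet True pressures at the two sensors, Pa.
#' @param quantize If TRUE, apply 24-bit quantisation over the configured
#'   full scale to each averaged reading.
#' @return List with `dp`, `p_inlet`, `p_outlet` (all Pa, dampened).
#' @export
read_dp <- function(pair, p_inlet, p_outlet, quantize = FALSE) {
  stopifnot(inherits(pair, "gauge_pressure_pair"))
  w <- pair$window
  s1 <- p_inlet + pair$offset[1] +
    if (pair$noise_sd > 0) stats::rnorm(w, 0, pair$noise_sd) else 0
  s2 <- p_outlet + pair$offset[2] +
    if (pair$noise_sd > 0) stats::rnorm(w, 0, pair$noise_sd) else 0
  m1 <- mean(s1); m2 <- mean(s2)
  if (quantize) {
    m1 <- quantize_pressure(m1, pair$full_scale)
    m2 <- quantize_pressure(m2, pair$full_scale)
  }
  list(dp = m1 - m2, p_inlet = m1, p_outlet = m2)
}

#' 24-bit quantisation of a pressure reading
#'
#' @param p Pressure in Pa.
#' @param full_scale Full scale in Pa.
#' @param bits Resolution (default 24).
#' @return Quantised pressure; differs from `p` by at most one count
#'   (`full_scale / 2^bits`).
#' @export
quantize_pressure <- function(p, full_scale = 30000, bits = 24) {
  lsb <- full_scale / 2^bits
  round(p / lsb) * lsb
}

#' Liquid level (volume) from a hydrostatic pressure difference
#'
#' A pressure sensor at the bottom of a reservoir reads the air pressure
#' above the liquid plus the head of the column, so the contained volume
#' follows from the difference with the headspace air pressure:
#' `V = (p_bottom - p_air) / (rho g) * area`. This is the fouling-immune
#' level measurement that recirculation switching relies on.
#'
#' @param p_bottom Pressure at the reservoir bottom, Pa.
#' @param p_air Air pressure above the liquid, Pa.
#' @param rho Fluid density, kg m^-3.
#' @param area Reservoir cross-section, m^2.
#' @return Volume in m^3, with attribute `negative_head = TRUE` when the
#'   difference is negative (sensor above the liquid, or a trapped
#'   bubble).
#' @export
level_from_pressure <- function(p_bottom, p_air, rho, area) {
  stopifnot(area > 0, rho > 0)
  head <- p_bottom - p_air
  v <- head / (rho * GRAVITY) * area
  structure(v, negative_head = head < 0)
}

#' Liquid-level sensor (direct or remote)
#'
#' Direct sensing couples the sensor to the reservoir bottom through a
#' punched port; remote sensing reads through a tube dipped to the low
#' liquid level, which avoids wetting the sensor but picks up an offset
#' when the reservoir is pressurised: liquid is forced up the measurement
#' tube, more so the narrower the tube. The offset is modelled as linear
#' in the applied air pressure with a coefficient inversely proportional
#' to the tube cross-section; its default magnitude is a plausible,
#' uncalibrated placeholder (only the diameter ordering is established).
#'
#' @param mode `"direct"` or `"remote"`.
#' @param tube_diameter Measurement-tube diameter in m (remote mode).
#' @param pressurization_offset_coeff Offset coefficient in m^2 (Pa of
#'   offset per Pa applied, times tube area); default 2e-8.
#' @return An object of class `level_sensor`.
#' @export
level_sensor <- function(mode = c("direct", "remote"),
                         tube_diameter = 3e-3,
                         pressurization_offset_coeff = 2e-8) {
  mode <- match.arg(mode)
  if (mode == "remote") stopifnot(tube_diameter > 0)
  stopifnot(pressurization_offset_coeff >= 0)
  structure(list(mode = mode, tube_diameter = tube_diameter,
                 pressurization_offset_coeff = pressurization_offset_coeff),
            class = "level_sensor")
}

#' Head pressure as seen by a level sensor
#'
#' @param sensor A [level_sensor()].
#' @param true_head True hydrostatic head, Pa.
#' @param applied_air Applied air pressure in the reservoir headspace, Pa.
#' @return Measured head in Pa. In direct mode the reading is exact; in
#'   remote mode it carries the pressurisation offset
#'   `coeff * applied_air / tube_area`.
#' @export
remote_level_reading <- function(sensor, true_head, applied_air = 0) {
  stopifnot(inherits(sensor, "level_sensor"))
  if (sensor$mode == "direct") return(true_head)
  area <- pi * sensor$tube_diameter^2 / 4
  true_head + sensor$pressurization_offset_coeff * applied_air / area
}
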