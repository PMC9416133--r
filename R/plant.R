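#' Medium reservoir with hydrostatic pressure head
#'
#' Reservoirs are modelled as vertical cylinders (the conical tip of a
#' 15 mL tube is folded into `dead_volume`, the liquid that sits below the
#' outlet and cannot be perfused). The liquid column contributes a
#' hydrostatic pressure head `rho * g * h` on top of the applied air
#' pressure; as medium is displaced from one reservoir to the other the
#' donor head falls while the receiver head rises, so the effective
#' driving pressure decays even under constant air commands.
#'
#' @param inner_diameter Inner diameter in m (default 14 mm, a 15 mL
#'   centrifuge tube).
#' @param liquid_volume Liquid volume in m^3.
#' @param dead_volume Volume below the outlet in m^3 (default 1 mL).
#' @param density Fluid density in kg m^-3.
#' @param applied_air_pressure Gauge air pressure above the liquid, Pa.
#' @param capacity Reservoir capacity in m^3 (default 15 mL).
#' @return An object of class `reservoir`.
#' @examples
#' r <- reservoir(liquid_volume = ml_to_m3(5))
#' pa_to_mbar(head_pressure(r))   # about 3.2 mbar
#' @export
reservoir <- function(inner_diameter = 0.014, liquid_volume = ml_to_m3(5),
                      dead_volume = ml_to_m3(1), density = 1000,
                      applied_air_pressure = 0, capacity = ml_to_m3(15)) {
  stopifnot(inner_diameter > 0, liquid_volume >= 0, dead_volume >= 0,
            density > 0, capacity > 0)
  if (liquid_volume > capacity)
    stop("liquid_volume exceeds reservoir capacity")
  structure(list(inner_diameter = inner_diameter,
                 liquid_volume = liquid_volume,
                 dead_volume = dead_volume,
                 density = density,
                 applied_air_pressure = applied_air_pressure,
                 capacity = capacity,
                 cross_section = pi * inner_diameter^2 / 4),
            class = "reservoir")
}

#' Hydrostatic pressure head of a reservoir
#'
#' @param res A [reservoir()].
#' @return Head pressure in Pa: `rho * g * liquid_volume / cross_section`.
#' @export
head_pressure <- function(res) {
  stopifnot(inherits(res, "reservoir"))
  res$density * GRAVITY * res$liquid_volume / res$cross_section
}

#' Combined head change per millilitre displaced between two reservoirs
#'
#' When fluid moves from one reservoir to the other, the donor loses head
#' while the receiver gains it, so both cross-sections contribute to the
#' decay of the driving pressure difference:
#' `rho * g * (1/A1 + 1/A2)` per unit volume. For two 15 mL tubes of
#' 14 mm inner diameter filled with water this is about 1.27 mbar per mL,
#' within the 1.2-1.5 mbar/mL range observed on the bench.
#'
#' @param res1,res2 [reservoir()] objects (defaults: `res2` same geometry
#'   as `res1`).
#' @return Head-difference change in mbar per displaced mL.
#' @export
head_drift_per_ml <- function(res1 = reservoir(), res2 = res1) {
  stopifnot(inherits(res1, "reservoir"), inherits(res2, "reservoir"))
  dp_pa_per_m3 <- GRAVITY * (res1$density / res1$cross_section +
                             res2$density / res2$cross_section)
  pa_to_mbar(dp_pa_per_m3 * 1e-6)   # per mL
}

#' First-order pneumatic pressure channel
#'
#' A commercial pressure controller reaches a commanded pressure through
#' an internal regulation loop; venting down is typically slower than
#' pressurising up, and the two units on a rig need not vent equally fast.
#' This is captured as a first-order lag with separate pressurise and vent
#' time constants.
#'
#' @param command Commanded pressure, Pa.
#' @param current_pressure Present output pressure, Pa.
#' @param pressurize_tau,vent_tau Time constants in s (> 0).
#' @param range Output limits in Pa (default 0 to 34 500 Pa, a 345 mbar
#'   controller).
#' @return An object of class `pneumatic_channel`.
#' @export
pneumatic_channel <- function(command = 0, current_pressure = 0,
                              pressurize_tau = 0.3, vent_tau = 1.0,
                              range = c(0, 34500)) {
  stopifnot(pressurize_tau > 0, vent_tau > 0, length(range) == 2L,
            range[1] < range[2])
  structure(list(command = command, current_pressure = current_pressure,
                 pressurize_tau = pressurize_tau, vent_tau = vent_tau,
                 range = range),
            class = "pneumatic_channel")
}

#' Assemble the plant state
#'
#' @param res1,res2 The two medium [reservoir()]s; reservoir 1 is attached
#'   to the first terminal of the circuit, reservoir 2 to the second.
#' @param pn1,pn2 The two [pneumatic_channel()]s pressurising them.
#'   Channel 1 defaults to the slower vent (2.0 s vs 1.0 s), reproducing
#'   the asymmetric venting seen between the two bench controllers.
#' @param time Simulation time, s.
#' @return An object of class `plant_state`.
#' @export
plant_state <- function(res1 = reservoir(), res2 = reservoir(),
                        pn1 = pneumatic_channel(vent_tau = 2.0),
                        pn2 = pneumatic_channel(),
                        time = 0) {
  structure(list(time = time, res1 = res1, res2 = res2,
                 pn1 = pn1, pn2 = pn2,
                 last_flow = 0, dry_run = FALSE),
            class = "plant_state")
}

#' Effective driving pressure across the circuit
#'
#' The terminal pressure difference handed to the hydraulic solver:
#' `(P_air1 + P_head1) - (P_air2 + P_head2)`. If the donor side (the side
#' at higher total pressure) is at or below its dead volume the value
#' carries a `dry_run` attribute, the condition the level-triggered
#' recirculation switch exists to prevent.
#'
#' @param state A [plant_state()].
#' @return Pressure difference in Pa, with attribute `dry_run`.
#' @export
effective_driving_pressure <- function(state) {
  stopifnot(inherits(state, "plant_state"))
  p1 <- state$res1$applied_air_pressure + head_pressure(state$res1)
  p2 <- state$res2$applied_air_pressure + head_pressure(state$res2)
  dp <- p1 - p2
  donor <- if (dp >= 0) state$res1 else state$res2
  structure(dp, dry_run = donor$liquid_volume <= donor$dead_volume)
}

# exact first-order relaxation of one pneumatic channel over dt
pneumatic_relax <- function(pn, dt) {
  cmd <- min(max(pn$command, pn$range[1]), pn$range[2])
  tau <- if (cmd >= pn$current_pressure) pn$pressurize_tau else pn$vent_tau
  pn$current_pressure <- cmd + (pn$current_pressure - cmd) * exp(-dt / tau)
  pn$current_pressure <- min(max(pn$current_pressure, pn$range[1]),
                             pn$range[2])
  pn
}

#' Advance the plant by one time step
#'
#' Explicit fixed-step integration of the rig: pneumatic pressures relax
#' toward their commands (exact exponential update, pressurise or vent
#' constant chosen by the sign of the error), the circuit is solved
#' quasi-statically at the current terminal pressures, and the resulting
#' flow transfers volume from reservoir 1 to reservoir 2 (signed). Total
#' liquid volume is conserved exactly; a reservoir is never drained below
#' its dead volume (the step is clamped and `dry_run` flagged instead).
#'
#' @param state A [plant_state()].
#' @param net A [fluidic_network()] or [compile_network()] result whose
#'   first terminal is reservoir 1 and second terminal is reservoir 2.
#' @param dt Time step in s; should be below a fifth of the fastest
#'   pneumatic time constant (a warning is issued otherwise).
#' @return The advanced `plant_state` (with `last_flow` in m^3 s^-1).
#' @export
plant_step <- function(state, net, dt) {
  stopifnot(inherits(state, "plant_state"), dt > 0)
  tau_min <- min(state$pn1$pressurize_tau, state$pn1$vent_tau,
                 state$pn2$pressurize_tau, state$pn2$vent_tau)
  if (dt > tau_min / 5)
    warning("dt = ", dt, " s is large for the fastest pneumatic time ",
            "constant (", tau_min, " s); integration may be inaccurate")
  cc <- if (inherits(net, "compiled_network")) net else compile_network(net)
  state$pn1 <- pneumatic_relax(state$pn1, dt)
  state$pn2 <- pneumatic_relax(state$pn2, dt)
  state$res1$applied_air_pressure <- state$pn1$current_pressure
  state$res2$applied_air_pressure <- state$pn2$current_pressure
  tnames <- names(cc$net$terminals)
  p1 <- state$res1$applied_air_pressure + head_pressure(state$res1)
  p2 <- state$res2$applied_air_pressure + head_pressure(state$res2)
  sol <- solve_network(cc, terminals = stats::setNames(c(p1, p2),
                                                       tnames[1:2]))
  q <- terminal_flow(sol, cc, tnames[1])   # out of reservoir 1
  dv <- q * dt
  state$dry_run <- FALSE
  if (dv > 0) {
    avail <- state$res1$liquid_volume - state$res1$dead_volume
    if (dv > avail) { dv <- max(avail, 0); state$dry_run <- TRUE }
  } else if (dv < 0) {
    avail <- state$res2$liquid_volume - state$res2$dead_volume
    if (-dv > avail) { dv <- -max(avail, 0); state$dry_run <- TRUE }
  }
  state$res1$liquid_volume <- state$res1$liquid_volume - dv
  state$res2$liquid_volume <- state$res2$liquid_volume + dv
  state$last_flow <- q
  state$time <- state$time + dt
  state
}

#' @export
print.plant_state <- function(x, ...) {
  cat(sprintf("Plant state at t = %.2f s\n", x$time))
  cat(sprintf("  reservoir 1: %.3f mL, air %.2f mbar, head %.3f mbar\n",
              m3_to_ml(x$res1$liquid_volume),
              pa_to_mbar(x$res1$applied_air_pressure),
              pa_to_mbar(head_pressure(x$res1))))
  cat(sprintf("  reservoir 2: %.3f mL, air %.2f mbar, head %.3f mbar\n",
              m3_to_ml(x$res2$liquid_volume),
              pa_to_mbar(x$res2$applied_air_pressure),
              pa_to_mbar(head_pressure(x$res2))))
  cat(sprintf("  last flow: %.2f uL/min%s\n", m3s_to_ulmin(x$last_flow),
              if (x$dry_run) "  [DRY RUN]" else ""))
  invisible(x)
}
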