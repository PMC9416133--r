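#' PID gains for the pressure-difference controller
#'
#' Gains are expressed in mbar of command per mbar of dP error (and per
#' integrated / differentiated error). The defaults were tuned on the
#' single-chip fixture; they are deliberately exposed because matching
#' the controller to the fluidic circuit is essential for clean
#' direction switches.
#'
#' @param kp,ki,kd Proportional, integral (s^-1) and derivative (s)
#'   gains, all >= 0.
#' @return An object of class `pid_gains`.
#' @export
pid_gains <- function(kp = 0.5, ki = 0.2, kd = 0) {
  stopifnot(kp >= 0, ki >= 0, kd >= 0)
  structure(list(kp = kp, ki = ki, kd = kd), class = "pid_gains")
}

#' Controller configuration
#'
#' Holds the setpoints, mode, switching thresholds and loop timing of the
#' perfusion controller. The controller maintains two quantities at once:
#' the pressure difference across the samples (`dp_setpoint`, which sets
#' flow) and the mean sample pressure (`p_ooc_setpoint`, set via the back
#' pressure of the receiving reservoir); commands decompose as
#' `p_mid +/- u/2`. Recirculation switching is triggered by liquid level
#' (hydrostatic sensing), not by integrated flow, so a fouled flow sensor
#' cannot run a reservoir dry.
#'
#' @param dp_setpoint Target pressure difference, mbar.
#' @param p_ooc_setpoint Target mean sample pressure, mbar.
#' @param mode `"graetz"` (passive four-valve rectifier), `"active_valve"`
#'   (3/2-valve rerouting synchronised with the command swap) or
#'   `"single_pass"` (no recirculation).
#' @param switch_low_volume Donor volume (mL) below which a direction
#'   switch is requested.
#' @param switch_high_volume Upper guard volume, mL (must exceed
#'   `switch_low_volume`).
#' @param hysteresis Level hysteresis, mL.
#' @param lockout_s Minimum time between switches, s.
#' @param command_limits Actuator pressure limits, mbar (default 0-345).
#' @param loop_rate Control loop rate, Hz (sensor stream is decimated by
#'   averaging down to this rate).
#' @param gains A [pid_gains()] object.
#' @param ki_mid Integral trim gain for the mean-pressure channel, s^-1.
#' @param plant_dt Plant integration step, s.
#' @param valve_lag_ticks (active_valve only) delay, in control ticks,
#'   between the command swap and the valve toggle; a deliberate
#'   desynchronisation hook for studying backflow.
#' @param on_sequence Optional callback invoked with each sequence
#'   summary (the notification hook; no-op by default).
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(dp_setpoint = 29, p_ooc_setpoint = 50,
                              mode = c("graetz", "active_valve",
                                       "single_pass"),
                              switch_low_volume = 3,
                              switch_high_volume = 12,
                              hysteresis = 0.25, lockout_s = 30,
                              command_limits = c(0, 345),
                              loop_rate = 10, gains = pid_gains(),
                              ki_mid = 0.2, plant_dt = 0.01,
                              valve_lag_ticks = 0,
                              on_sequence = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(command_limits) == 2L,
            command_limits[1] < command_limits[2],
            loop_rate > 0, plant_dt > 0, lockout_s >= 0, hysteresis >= 0,
            inherits(gains, "pid_gains"), valve_lag_ticks >= 0)
  if (switch_low_volume >= switch_high_volume)
    stop("switch_low_volume must be below switch_high_volume")
  if (p_ooc_setpoint + dp_setpoint / 2 > command_limits[2] ||
      p_ooc_setpoint - dp_setpoint / 2 < command_limits[1])
    stop("setpoints exceed command limits: p_ooc +/- dp/2 must lie in [",
         command_limits[1], ", ", command_limits[2], "] mbar")
  structure(list(dp_setpoint = dp_setpoint,
                 p_ooc_setpoint = p_ooc_setpoint, mode = mode,
                 switch_low_volume = switch_low_volume,
                 switch_high_volume = switch_high_volume,
                 hysteresis = hysteresis, lockout_s = lockout_s,
                 command_limits = command_limits, loop_rate = loop_rate,
                 gains = gains, ki_mid = ki_mid, plant_dt = plant_dt,
                 valve_lag_ticks = as.integer(valve_lag_ticks),
                 on_sequence = on_sequence),
            class = "controller_config")
}

#' Initial PID state
#'
#' The dP integral is pre-loaded so the initial command realises the
#' setpoint (bumpless start); the mean-pressure trim starts at zero.
#'
#' @param config A [controller_config()].
#' @return An object of class `pid_state`.
#' @export
pid_init <- function(config) {
  stopifnot(inherits(config, "controller_config"))
  integral <- if (config$gains$ki > 0)
    config$dp_setpoint / config$gains$ki else 0
  structure(list(integral = integral, prev_error = NA_real_,
                 mid_integral = 0, anti_windup_active = FALSE,
                 last_cmd = c(NA_real_, NA_real_),
                 nan_hold = FALSE),
            class = "pid_state")
}

#' One positional PID update
#'
#' Computes the high/low pressure command pair from the dampened dP and
#' mean-pressure measurements. The PID output `u` tracks `dp_setpoint`;
#' the mid-pressure `p_mid` tracks `p_ooc_setpoint` through a slow
#' integral trim; commands are `p_mid + u/2` and `p_mid - u/2`, clamped
#' to the actuator limits with clamping anti-windup (no integral is
#' accumulated while either command is saturated). A non-finite
#' measurement holds the previous command and flags `nan_hold`.
#'
#' @param state A [pid_init()] state.
#' @param config A [controller_config()].
#' @param measured_dp Dampened dP measurement, mbar.
#' @param measured_mean_p Dampened mean sample pressure, mbar.
#' @param dt Time since the previous update, s.
#' @return List with `commands` (c(high, low), mbar) and the updated
#'   `state`.
#' @export
pid_update <- function(state, config, measured_dp, measured_mean_p, dt) {
  stopifnot(inherits(state, "pid_state"),
            inherits(config, "controller_config"), dt > 0)
  lim <- config$command_limits
  if (!is.finite(measured_dp) || !is.finite(measured_mean_p)) {
    state$nan_hold <- TRUE
    cmd <- state$last_cmd
    if (any(is.na(cmd)))
      cmd <- c(config$p_ooc_setpoint + config$dp_setpoint / 2,
               config$p_ooc_setpoint - config$dp_setpoint / 2)
    return(list(commands = cmd, state = state))
  }
  state$nan_hold <- FALSE
  g <- config$gains
  e <- config$dp_setpoint - measured_dp
  deriv <- if (is.na(state$prev_error)) 0 else (e - state$prev_error) / dt
  i_try <- state$integral + e * dt
  e_mid <- config$p_ooc_setpoint - measured_mean_p
  m_try <- state$mid_integral + e_mid * dt
  u <- g$kp * e + g$ki * i_try + g$kd * deriv
  p_mid <- config$p_ooc_setpoint + config$ki_mid * m_try
  cmd_hi <- p_mid + u / 2
  cmd_lo <- p_mid - u / 2
  sat <- cmd_hi > lim[2] || cmd_hi < lim[1] ||
         cmd_lo > lim[2] || cmd_lo < lim[1]
  if (!sat) {
    state$integral <- i_try
    state$mid_integral <- m_try
    state$anti_windup_active <- FALSE
  } else {
    state$anti_windup_active <- TRUE
  }
  cmd <- c(min(max(cmd_hi, lim[1]), lim[2]),
           min(max(cmd_lo, lim[1]), lim[2]))
  state$prev_error <- e
  state$last_cmd <- cmd
  list(commands = cmd, state = state)
}

#' Decide whether to switch recirculation direction
#'
#' Fires when the donor reservoir has drained to the low-volume threshold
#' (minus the hysteresis band) and the lockout window since the previous
#' switch has elapsed. Stale (NA) level readings are treated
#' conservatively: no switch, with a warning.
#'
#' @param levels Numeric length-2, measured reservoir volumes in mL
#'   (reservoir 1, reservoir 2).
#' @param config A [controller_config()].
#' @param current_direction +1 (reservoir 1 is the donor) or -1.
#' @param time Current time, s.
#' @param last_switch_time Time of the previous switch, s (-Inf if none).
#' @return Logical.
#' @export
should_switch <- function(levels, config, current_direction = 1,
                          time = 0, last_switch_time = -Inf) {
  stopifnot(inherits(config, "controller_config"), length(levels) == 2L)
  if (any(!is.finite(levels))) {
    warning("stale or invalid level reading; holding direction")
    return(FALSE)
  }
  if (time - last_switch_time < config$lockout_s) return(FALSE)
  donor <- if (current_direction > 0) levels[1] else levels[2]
  donor <= config$switch_low_volume - config$hysteresis
}

#' Execute a recirculation direction switch
#'
#' In graetz mode the passive valve bridge rectifies the sample flow, so
#' a switch is nothing more than swapping the high/low pressure command
#' targets. In active_valve mode the two 3/2 valves must be toggled in
#' the same control tick as the command swap; the returned
#' `valve_positions` flag flips accordingly.
#'
#' @param mode Controller mode (see [controller_config()]).
#' @param direction Current direction (+1/-1).
#' @param commands Current command pair (high, low), mbar; returned
#'   swapped.
#' @param valve_positions Current 3/2-valve direction (+1/-1), only
#'   meaningful in active_valve mode.
#' @return List with flipped `direction`, swapped `commands` and (for
#'   active_valve) toggled `valve_positions`.
#' @export
execute_switch <- function(mode, direction, commands = NULL,
                           valve_positions = NULL) {
  out <- list(direction = -direction,
              commands = if (!is.null(commands)) rev(commands),
              valve_positions = valve_positions)
  if (identical(mode, "active_valve") && !is.null(valve_positions))
    out$valve_positions <- -valve_positions
  out
}

#' Bundle the sensor models used by a closed-loop run
#'
#' @param flow A [flow_sensor()].
#' @param pressure A [gauge_pressure_pair()].
#' @param level A [level_sensor()].
#' @param level_noise_sd Gaussian noise on the level head reading, Pa.
#' @return An object of class `sensor_suite`.
#' @export
sensor_suite <- function(flow = flow_sensor("L", noise_sd = 2),
                         pressure = gauge_pressure_pair(noise_sd = 5),
                         level = level_sensor("direct"),
                         level_noise_sd = 0.5) {
  stopifnot(inherits(flow, "flow_sensor"),
            inherits(pressure, "gauge_pressure_pair"),
            inherits(level, "level_sensor"), level_noise_sd >= 0)
  structure(list(flow = flow, pressure = pressure, level = level,
                 level_noise_sd = level_noise_sd),
            class = "sensor_suite")
}

#' Run a closed-loop perfusion experiment against the simulated rig
#'
#' Simulates the full control chain: the plant (reservoirs + pneumatics +
#' hydraulic circuit) is integrated at `plant_dt`, the 100 Hz-style
#' sensor stream is decimated by averaging down to the control rate, the
#' PID updates the pressure commands each tick, and the recirculation
#' logic swaps direction when the donor reservoir reaches its low-level
#' threshold. Telemetry is recorded per control tick and a summary is
#' emitted for every direction sequence.
#'
#' The dP used for control and telemetry is measured across the sample
#' element(s) (`net$sample_ids`), which in graetz mode is rectified and
#' therefore keeps its sign across switches.
#'
#' @param plant A [plant_state()].
#' @param net A [fluidic_network()] whose first two terminals correspond
#'   to reservoirs 1 and 2.
#' @param sensors A [sensor_suite()].
#' @param config A [controller_config()].
#' @param duration Simulated duration, s (0 gives empty telemetry).
#' @param seed Integer seed covering every stochastic path of the run;
#'   identical seeds give bit-identical telemetry.
#' @return An object of class `perfusion_run`: list with `telemetry`
#'   (data.frame), `summaries` (list of per-sequence summaries),
#'   `switch_count`, `backflow_events` and the final `plant` state.
#' @examples
#' \donttest{
#' net <- fixture_circuit("tubing_loop_48h")
#' cfg <- controller_config(mode = "single_pass", lockout_s = 10)
#' run <- run_experiment(plant_state(), net, sensor_suite(), cfg,
#'                       duration = 30, seed = 1)
#' summary(run)
#' }
#' @export
run_experiment <- function(plant, net, sensors, config, duration,
                           seed = 1L) {
  stopifnot(inherits(plant, "plant_state"),
            inherits(sensors, "sensor_suite"),
            inherits(config, "controller_config"), duration >= 0)
  set.seed(as.integer(seed))
  cc <- if (inherits(net, "compiled_network")) net else compile_network(net)
  tick_dt <- 1 / config$loop_rate
  substeps <- max(1L, round(tick_dt / config$plant_dt))
  sub_dt <- tick_dt / substeps
  n_ticks <- floor(duration / tick_dt)
  cols <- c("time_s", "p_inlet_mbar", "p_outlet_mbar", "dp_mbar",
            "q_true_ulmin", "q_measured_ulmin", "level1_ml", "level2_ml",
            "cmd1_mbar", "cmd2_mbar", "direction")
  if (n_ticks == 0L) {
    tel <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(cols)), cols))
    return(structure(list(telemetry = tel, summaries = list(),
                          switch_count = 0L, backflow_events = 0L,
                          plant = plant, config = config, seed = seed),
                     class = "perfusion_run"))
  }

  # sample element (for dP measurement and flow telemetry)
  sid <- cc$net$sample_ids
  if (is.null(sid)) {
    nonvalve <- which(!cc$is_valve)
    if (!length(nonvalve)) stop("network has no sample element")
    sid <- cc$ids[nonvalve[1]]
  }
  s_elem <- match(sid[1], cc$ids)
  s_from <- cc$from[s_elem]; s_to <- cc$to[s_elem]

  # local plant scalars for the integration loop (same update rule as
  # plant_step, inlined for speed)
  v1 <- plant$res1$liquid_volume; v2 <- plant$res2$liquid_volume
  dead1 <- plant$res1$dead_volume; dead2 <- plant$res2$dead_volume
  a1 <- plant$res1$cross_section; a2 <- plant$res2$cross_section
  rho1 <- plant$res1$density; rho2 <- plant$res2$density
  pn1 <- plant$pn1; pn2 <- plant$pn2
  p1_air <- pn1$current_pressure; p2_air <- pn2$current_pressure

  direction <- 1
  valve_dir <- 1
  # active_valve toggle scheduling: a synchronised toggle waits for the
  # pneumatic crossover (driving dP matching the new direction); a lagged
  # toggle (desynchronisation hook) fires a fixed number of ticks after
  # the command swap regardless of the pressures
  valve_sync_pending <- FALSE
  valve_lag_countdown <- -1L
  last_switch_time <- -Inf
  switch_count <- 0L
  backflow_events <- 0L
  pid <- pid_init(config)
  cmd <- c(config$p_ooc_setpoint + config$dp_setpoint / 2,
           config$p_ooc_setpoint - config$dp_setpoint / 2)
  open_state <- NULL

  tel <- matrix(NA_real_, n_ticks, length(cols),
                dimnames = list(NULL, cols))
  summaries <- list()
  seq_start <- 0; seq_n <- 0L
  seq_dp_sum <- 0; seq_dp_min <- Inf; seq_dp_max <- -Inf
  seq_q_sum <- 0; seq_disp <- 0

  emit_summary <- function(t_end) {
    s <- list(direction = direction,
              start_s = seq_start, duration_s = t_end - seq_start,
              dp_mean_mbar = if (seq_n) seq_dp_sum / seq_n else NA_real_,
              dp_min_mbar = if (seq_n) seq_dp_min else NA_real_,
              dp_max_mbar = if (seq_n) seq_dp_max else NA_real_,
              flow_mean_ulmin = if (seq_n) seq_q_sum / seq_n else NA_real_,
              displaced_ml = m3_to_ml(seq_disp),
              switch_count = switch_count)
    summaries[[length(summaries) + 1L]] <<- s
    if (is.function(config$on_sequence)) config$on_sequence(s)
  }

  noise_p <- sensors$pressure$noise_sd
  w <- substeps  # dampening window = one control tick of the raw stream

  for (tick in seq_len(n_ticks)) {
    t_now <- tick * tick_dt
    # apply commands for this tick: high command to the donor side
    if (direction > 0) { pn1$command <- mbar_to_pa(cmd[1]); pn2$command <- mbar_to_pa(cmd[2]) }
    else               { pn1$command <- mbar_to_pa(cmd[2]); pn2$command <- mbar_to_pa(cmd[1]) }

    p_in_sub <- p_out_sub <- q_sub <- numeric(substeps)
    dry <- FALSE
    for (s in seq_len(substeps)) {
      pn1 <- pneumatic_relax(pn1, sub_dt)
      pn2 <- pneumatic_relax(pn2, sub_dt)
      p1 <- pn1$current_pressure + rho1 * GRAVITY * v1 / a1
      p2 <- pn2$current_pressure + rho2 * GRAVITY * v2 / a2
      if (valve_sync_pending && direction * (p1 - p2) > 0) {
        valve_dir <- direction     # toggle exactly at the crossover
        valve_sync_pending <- FALSE
      }
      sol <- solve_compiled(cc, c(p1, p2), open_state)
      open_state <- sol$open
      # net flow out of reservoir 1 (first terminal)
      q1 <- 0
      tp <- cc$term_pos[1]
      for (k in seq_along(sol$q)) {
        if (cc$from[k] == tp) q1 <- q1 + sol$q[k]
        if (cc$to[k] == tp) q1 <- q1 - sol$q[k]
      }
      dv <- q1 * sub_dt
      if (dv > 0 && dv > v1 - dead1) { dv <- max(v1 - dead1, 0); dry <- TRUE }
      if (dv < 0 && -dv > v2 - dead2) { dv <- -max(v2 - dead2, 0); dry <- TRUE }
      v1 <- v1 - dv; v2 <- v2 + dv
      p_in_sub[s] <- sol$p[s_from]
      p_out_sub[s] <- sol$p[s_to]
      qs <- sol$q[s_elem]
      if (config$mode == "active_valve") qs <- valve_dir * qs
      q_sub[s] <- qs
    }
    if (dry)
      stop_dry_run(t_now, v1, v2)
    # dampened sensor readings (averaged raw stream, one tick window)
    m_in <- mean(p_in_sub + sensors$pressure$offset[1] +
                   if (noise_p > 0) stats::rnorm(w, 0, noise_p) else 0)
    m_out <- mean(p_out_sub + sensors$pressure$offset[2] +
                    if (noise_p > 0) stats::rnorm(w, 0, noise_p) else 0)
    dp_meas <- pa_to_mbar(m_in - m_out)
    mean_meas <- pa_to_mbar((m_in + m_out) / 2)
    q_true <- m3s_to_ulmin(mean(q_sub))
    if (q_true < -1) backflow_events <- backflow_events + 1L  # > 1 uL/min reverse
    q_meas <- read_flow(sensors$flow, q_true)
    # level sensing via hydrostatic head
    head1 <- rho1 * GRAVITY * v1 / a1
    head2 <- rho2 * GRAVITY * v2 / a2
    h1m <- remote_level_reading(sensors$level, head1, pn1$current_pressure)
    h2m <- remote_level_reading(sensors$level, head2, pn2$current_pressure)
    if (sensors$level_noise_sd > 0) {
      h1m <- h1m + stats::rnorm(1, 0, sensors$level_noise_sd)
      h2m <- h2m + stats::rnorm(1, 0, sensors$level_noise_sd)
    }
    lvl1 <- m3_to_ml(h1m / (rho1 * GRAVITY) * a1)
    lvl2 <- m3_to_ml(h2m / (rho2 * GRAVITY) * a2)

    # control update: dP at the sample keeps its sign in graetz mode;
    # otherwise it follows the pressure direction
    pid_dp <- if (config$mode == "graetz") dp_meas else direction * dp_meas
    pid_mean <- mean_meas
    upd <- pid_update(pid, config, pid_dp, pid_mean, tick_dt)
    pid <- upd$state
    cmd <- upd$commands

    # sequence bookkeeping
    seq_n <- seq_n + 1L
    seq_dp_sum <- seq_dp_sum + pid_dp
    seq_dp_min <- min(seq_dp_min, pid_dp)
    seq_dp_max <- max(seq_dp_max, pid_dp)
    seq_q_sum <- seq_q_sum + q_true
    seq_disp <- seq_disp + abs(mean(q_sub)) * tick_dt

    # lagged (deliberately desynchronised) active_valve toggle
    if (valve_lag_countdown == 0L) {
      valve_dir <- -valve_dir
      valve_lag_countdown <- -1L
    } else if (valve_lag_countdown > 0L) {
      valve_lag_countdown <- valve_lag_countdown - 1L
    }

    # recirculation switch
    if (config$mode != "single_pass" &&
        should_switch(c(lvl1, lvl2), config, direction, t_now,
                      last_switch_time)) {
      emit_summary(t_now)
      sw <- execute_switch(config$mode, direction, cmd, valve_dir)
      direction <- sw$direction
      if (config$mode == "active_valve") {
        if (config$valve_lag_ticks == 0L) valve_sync_pending <- TRUE
        else valve_lag_countdown <- config$valve_lag_ticks
      }
      last_switch_time <- t_now
      switch_count <- switch_count + 1L
      seq_start <- t_now; seq_n <- 0L
      seq_dp_sum <- 0; seq_dp_min <- Inf; seq_dp_max <- -Inf
      seq_q_sum <- 0; seq_disp <- 0
    }

    tel[tick, ] <- c(t_now, pa_to_mbar(m_in), pa_to_mbar(m_out), dp_meas,
                     q_true, q_meas, lvl1, lvl2, cmd[1], cmd[2], direction)
  }
  emit_summary(n_ticks * tick_dt)

  plant$res1$liquid_volume <- v1
  plant$res2$liquid_volume <- v2
  plant$pn1 <- pn1; plant$pn2 <- pn2
  plant$res1$applied_air_pressure <- pn1$current_pressure
  plant$res2$applied_air_pressure <- pn2$current_pressure
  plant$time <- plant$time + n_ticks * tick_dt

  structure(list(telemetry = as.data.frame(tel), summaries = summaries,
                 switch_count = switch_count,
                 backflow_events = backflow_events,
                 plant = plant, config = config, seed = seed),
            class = "perfusion_run")
}

stop_dry_run <- function(t, v1, v2) {
  stop(structure(class = c("perfusim_dry_run", "error", "condition"),
                 list(message = sprintf(
                   paste0("dry run at t = %.1f s: reservoir volumes ",
                          "%.2f / %.2f mL at dead volume"),
                   t, m3_to_ml(v1), m3_to_ml(v2)),
                   call = NULL)))
}

#' @export
print.perfusion_run <- function(x, ...) {
  tel <- x$telemetry
  cat(sprintf("Perfusion run: %.1f s simulated, %d telemetry rows, %d switch%s\n",
              if (nrow(tel)) max(tel$time_s) else 0, nrow(tel),
              x$switch_count, if (x$switch_count == 1) "" else "es"))
  if (nrow(tel)) {
    cat(sprintf("  dP: mean %.2f mbar (target %.2f), flow: mean %.1f uL/min\n",
                mean(tel$dp_mbar), x$config$dp_setpoint,
                mean(tel$q_true_ulmin)))
  }
  if (x$backflow_events)
    cat("  backflow detected in", x$backflow_events, "tick(s)\n")
  invisible(x)
}

#' @export
summary.perfusion_run <- function(object, ...) {
  do.call(rbind, lapply(object$summaries, function(s)
    data.frame(direction = s$direction, start_s = s$start_s,
               duration_s = s$duration_s, dp_mean_mbar = s$dp_mean_mbar,
               dp_min_mbar = s$dp_min_mbar, dp_max_mbar = s$dp_max_mbar,
               flow_mean_ulmin = s$flow_mean_ulmin,
               displaced_ml = s$displaced_ml,
               switch_count = s$switch_count)))
}

#' @export
plot.perfusion_run <- function(x, ...) {
  tel <- x$telemetry
  if (!nrow(tel)) {
    warning("empty telemetry; nothing to plot")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(tel$time_s, tel$dp_mbar, type = "l", xlab = "time [s]",
                 ylab = "dP [mbar]", ...)
  graphics::abline(h = x$config$dp_setpoint, lty = 2, col = "grey40")
  graphics::plot(tel$time_s, tel$q_true_ulmin, type = "l",
                 xlab = "time [s]", ylab = "flow [uL/min]", ...)
  invisible(x)
}
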