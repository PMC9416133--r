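---
title: "Modelling pressure-driven organ-on-chip perfusion with perfusim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pressure-driven organ-on-chip perfusion with perfusim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfusim)
```

## The system being modelled

Organ-on-chip (OoC) experiments need controlled, often unidirectional,
fluid flow through microchannels for medium refreshment and for imposing
defined wall shear stress. Pressure-driven pumping -- two pneumatically
pressurised medium reservoirs on either side of the fluidic circuit --
controls the mechanical environment of every sample directly, and, unlike
constant-flow pumping, a blocked channel does not disturb the perfusion
conditions of its neighbours. `perfusim` is a desk-scale digital twin of
such a rig: the hydraulic circuit, the reservoirs and pneumatics, the
sensor chain, and the software controller that holds a constant pressure
difference (dP) across the samples while recirculating the medium.

The package is organised the way the bench system is:

* **circuit** -- steady-state lumped-element hydraulics
  (`fluidic_network()`, `solve_network()`);
* **plant** -- time-domain reservoir and pneumatic dynamics
  (`plant_state()`, `plant_step()`);
* **sensors** -- flow, pressure and liquid-level measurement models;
* **controller** -- the PID loop, recirculation switching and the
  closed-loop runner (`run_experiment()`);
* **fcb** -- the multiplexing fluidic circuit board
  (`build_fcb_network()`, `blockage_analysis()`);
* **io** -- JSON circuit/configuration files, fixtures and the
  `exec/perfusim` command line.

## Hydraulic model

Creeping flow in microchannels obeys the fluidic Ohm's law
$\Delta P = Q\,R_h$, with hydraulic resistances combining like electrical
ones: series resistances add, parallel branches combine by the
reciprocal-sum law. The element formulas are

* rectangular channel:
  $R_h \approx \dfrac{12\,\mu L}{a b^3\,(1 - 0.63\, b/a)}$ with
  $a = \max(w,h)$, $b = \min(w,h)$;
* circular tube: $R_h = \dfrac{128\,\mu L}{\pi d^4}$.

The min/max convention makes the rectangular formula invariant to which
side is called "width"; note that for channels close to square the
*approximation itself* deviates by roughly 10--15% from the exact series
solution -- a property of the formula, not of the implementation. The two
stock fluids are serum-supplemented culture medium at 37 °C
(`fluid("medium-37C")`, 0.00079 Pa s) and water (`fluid("water-20C")`,
0.001 Pa s), the latter used when rigs are validated with ddH2O.

### Nodal solver and check valves

`solve_network()` assembles the node conductance matrix, holds terminal
nodes (the reservoirs) at their imposed pressures, and solves Kirchhoff's
current law at every internal node. Check valves -- the fluidic analogue
of diodes -- make the problem piecewise linear. They are resolved by a
deterministic active-set iteration: start with every valve open, solve,
and flip the single most-violated valve (ties broken by element order)
until complementarity holds: a closed valve sees a forward pressure drop
below its cracking pressure, an open valve carries non-negative flow.
The iteration is capped at $2^{n_\text{valves}}$ rounds; hitting the cap
returns the last assignment flagged `converged = FALSE` rather than
guessing.

Numerical choices worth knowing about:

* An open valve is a small forward resistance (default $10^{-3}$ times
  the smallest non-valve resistance in the network) in series with its
  cracking pressure (default 0 Pa). The bench valves' characteristics
  are not specified by their datasheet at this fidelity, so both are
  configuration knobs.
* A vanishing shunt conductance ($10^{-18}$ of the largest element
  conductance) ties internal nodes to the reference terminal so the
  system stays nonsingular when closed valves isolate a node; its
  contribution sits far below the $10^{-12}$ relative mass-balance
  tolerance the tests enforce.
* Zero-resistance elements are rejected at compile time (they would
  require node merging); omit them instead -- hydraulically identical.
* When the manifold resistance is made negligible on purpose (ideal
  multiplexing analyses), totals are computed as sums over sample
  branches rather than terminal-node differences, avoiding a
  subtraction of nearly equal pressures.

The solver is validated against an independently coded series/parallel
reduction oracle on randomised ladder networks (relative agreement
$10^{-9}$), and the four-valve Graetz bridge fixture demonstrates
rectification: swapping the reservoir pressures reverses the
reservoir-side flow while the sample flow keeps its sign.

## Plant model

Reservoirs are vertical cylinders (default 14 mm inner diameter for a
15 mL centrifuge tube; the conical tip is folded into a 1 mL dead
volume). Only the observed head change per displaced millilitre
constrains this geometry, so the diameter is configurable. The
hydrostatic head $\rho g V/A$ adds to the applied air pressure at each
terminal; as medium moves from donor to receiver the driving difference
decays by $\rho g (1/A_1 + 1/A_2)$ per unit volume --
`head_drift_per_ml()` gives 1.27 mbar/mL for the default pair with
water, inside the 1.2--1.5 mbar/mL band observed on real rigs across
fluids and reservoir types.

Pneumatic channels are first-order lags with separate pressurise and
vent time constants (defaults 0.3 s and 1.0 s, with channel 1 venting at
2.0 s: commercial controllers vent asymmetrically, and the two units on
a rig need not match). These are calibration knobs chosen so a command
swap settles in roughly 4--8 s, the behaviour seen on the bench; they
are not instrument constants. Integration is explicit fixed-step
(default dt = 0.01 s, well below a fifth of the fastest time constant)
with the circuit solved quasi-statically each step; volume transfer uses
one subtraction and one addition of the same quantity, so total liquid
volume is conserved to floating-point exactness and a reservoir is
clamped at its dead volume (with a dry-run flag) rather than going
negative.

Deliberately out of scope: compressible headspace dynamics, tubing and
PDMS compliance, and any transient inertance inside the circuit -- the
quasi-static assumption is what makes the lumped model tractable, and
the recirculation timescales (seconds to hours) sit far above the
hydraulic settling time.

## Sensor models

**Thermal flow sensor.** Clean sensors read accurately; culture medium
fouls them over days and they then under-read systematically. Only the
endpoint behaviour is documented (no fouling-rate law), so the model is
a constant multiplicative gain in (0, 1] plus Gaussian noise and range
clipping (size L: -1100 to +1000 uL/min; size XL: +/-5500 uL/min).
`closed_loop_flow_bias()` integrates the documented failure mode: a
controller in constant-flow mode servoing on a fouled sensor raises the
pressure until the *measured* flow matches the setpoint, so the *true*
flow settles at setpoint/gain -- a quarter-reading sensor quadruples the
real perfusion rate, unless the pressure limit (345 mbar) saturates
first. This is why the package's recirculation logic never integrates
the flow signal.

**Paired gauge pressure sensors.** dP is measured as the difference of
two separately dampened gauge streams (a wet/wet differential sensor of
suitable size not being available); dampening is a moving average over
one control tick of the nominal 100 Hz stream, and for white noise the
dP variance shrinks as 1/window. Optional 24-bit quantisation over a
configurable full scale (default 300 mbar) never moves a reading by more
than one count.

**Liquid level.** The level is the hydrostatic head divided by
$\rho g / A$ -- immune to fouling. Direct sensing (sensor in the
reservoir bottom) is exact; remote sensing through a dipped tube picks
up an offset when the headspace is pressurised, modelled as linear in
the applied pressure and inversely proportional to the tube
cross-section, which reproduces the observed ordering (a 3 mm tube
offsets less than a 0.8 mm tube). The coefficient's default magnitude
(2e-8 m^2) is an uncalibrated placeholder: only the diameter dependence
is established.

## Controller

The loop runs at 10 Hz (the sensor stream decimated by averaging) and
controls two quantities at once: the PID output $u$ tracks the dP
setpoint, and a slow integral trim holds the mean sample pressure
(P_OoC, the back-pressure knob) at its own setpoint. Commands decompose
as $p_{mid} \pm u/2$, clamped to the 0--345 mbar actuator range with
clamping anti-windup (no integral accumulates while saturated). Raising
the P_OoC setpoint therefore lifts both commands equally and leaves the
steady flow unchanged in a linear circuit -- the decoupling the
two-sided architecture exists for.

Default gains (kp = 0.5, ki = 0.2 s^-1, kd = 0, in mbar per mbar) were
tuned on the single-chip fixture and are deliberately exposed: matching
the controller to the fluidic circuit is what keeps direction switches
clean. The dP integral is pre-loaded at start so the first command
realises the setpoint (bumpless start).

**Recirculation switching** is level-triggered: a switch fires when the
donor reservoir drains to `switch_low_volume` minus a hysteresis band,
with a lockout window (default 30 s) that bounds the switch rate under
noisy level readings. Volume-from-flow switching is exactly what fouling
breaks, so it is not offered. Two recirculation mechanisms are
modelled:

* **graetz** -- the passive four-check-valve rectifier: a switch is
  nothing but swapping the high/low pressure commands; the bridge keeps
  the sample flow unidirectional throughout, including the pneumatic
  crossover.
* **active_valve** -- two 3/2 valves reroute the reservoirs. A correct
  implementation toggles them exactly at the pneumatic pressure
  crossover, which the simulator detects at plant resolution; the
  `valve_lag_ticks` hook instead toggles a fixed delay after the
  command swap, reproducing the desynchronisation failure (sustained
  reverse flow at the sample, counted in `backflow_events`).

Every direction sequence is summarised (duration, dP statistics, mean
flow, displaced volume) and handed to an optional `on_sequence` callback
-- the notification hook; delivering the notification is out of scope.

## The multiplexing board

`build_fcb_network()` lays out a feeder channel, up to four device slots
of three channels each (1.1 cm x 500 um x 500 um by default), and a
waste channel. The milled manifold cross-section (1 mm x 1 mm) and
segment lengths are fixture values -- the real board's dimensions live
in its CAD files -- so they are configurable and the analyses that need
"independent" channels simply shrink them to negligible length. Dummy
chips are absent branches. `blockage_analysis()` contrasts the two
pumping philosophies: at constant total flow, blocking one of six
identical channels multiplies every remaining flow by 6/5; at constant
dP with negligible shared resistance the remaining channels are
untouched. Real fabricated boards deviate from the ideal parallel
scaling (channel-to-channel tolerance); the model reproduces the ideal
prediction only.

## What the fixtures do and do not emulate

The fixture generator (`fixture_circuit()`, `generate_fixtures()`)
reproduces the validation circuits: the single chip, the 8 cm / 250 um
tubing loop whose series reduction predicts about 208 uL/min at 29 mbar
(the rig's "approximately 200 uL/min" operating point), the 6- and
12-channel boards, the Graetz bridge, and the full recirculating system.
Simulated runs therefore validate the *control architecture* -- setpoint
tracking, head-drift rejection, switch timing, fouling immunity of the
level trigger -- under clean first-order pneumatics, Gaussian sensor
noise and rigid channels. They do not exercise compliance transients,
real fouling kinetics, bubbles, or fabrication variation, so passing
tests bound the software's behaviour, not the biology or the hardware
tolerances.

Validation problem sizes were chosen to exercise every mechanism while
staying desk-scale: the tracking run simulates 10 minutes at dt = 0.01 s
(a stand-in for the multi-day bench run, long enough for head drift to
bite), and the recirculation-conservation run simulates 30 minutes with
at least one direction switch. Randomised solver checks use 100 ladder
networks under a fixed seed. All stochastic paths derive from the single
run seed, so telemetry is bit-reproducible.

## Known limitations

* The quasi-static circuit cannot show pressure-surge transients inside
  the network during a switch; only the reservoir-side pneumatic
  transient is dynamic.
* The fouling gain is a free parameter; fitting a fouling *trajectory*
  would need calibration data the model does not presume.
* The remote-level offset coefficient is uncalibrated (ordering only).
* The rectangular-channel formula degrades near unit aspect ratio (use
  the exact series solution if a few percent matters there).
* Reservoirs are cylinders; strongly conical vessels would need a
  volume-to-head map instead of a single diameter.
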