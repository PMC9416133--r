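#' Hydraulic circuit elements
#'
#' Constructors for the lumped elements that make up a fluidic network.
#' Each element may carry `from`/`to` node names and an `id` so it can be
#' placed directly in a [fluidic_network()]; bare elements (no nodes) are
#' valid inputs to the resistance formulas.
#'
#' Under the electrical-circuit analogy, a pressure drop across an element
#' relates to the volumetric flow through it as `dP = Q * Rh` (the fluidic
#' Ohm's law), with `Rh` the hydraulic resistance in Pa s m^-3.
#'
#' @param length,width,height,diameter Geometry in metres; all positive.
#' @param resistance Hydraulic resistance in Pa s m^-3 (>= 0); used to model
#'   flow sensors, connectors and lumped organ-on-chip samples.
#' @param cracking_pressure Minimum forward pressure (Pa, >= 0) before a
#'   check valve opens.
#' @param forward_resistance Open-state resistance of a check valve in
#'   Pa s m^-3; `NULL` (default) lets the solver pick a small fraction
#'   (1e-3) of the smallest non-valve resistance in the network.
#' @param from,to Node names for network placement.
#' @param id Element identifier (unique within a network).
#' @return An object of class `c("<kind>", "hydraulic_element")`.
#' @seealso [element_resistance()], [fluidic_network()]
#' @name elements
NULL

new_element <- function(kind, fields, from = NULL, to = NULL, id = NULL) {
  structure(c(fields, list(from = from, to = to, id = id)),
            class = c(kind, "hydraulic_element"))
}

check_dim <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("invalid geometry: %s must be a positive finite number", what),
         call. = FALSE)
  x
}

#' @rdname elements
#' @export
rect_channel <- function(length, width, height, from = NULL, to = NULL,
                         id = NULL) {
  new_element("rect_channel",
              list(length = check_dim(length, "length"),
                   width = check_dim(width, "width"),
                   height = check_dim(height, "height")),
              from, to, id)
}

#' @rdname elements
#' @export
circular_tube <- function(length, diameter, from = NULL, to = NULL,
                          id = NULL) {
  new_element("circular_tube",
              list(length = check_dim(length, "length"),
                   diameter = check_dim(diameter, "diameter")),
              from, to, id)
}

#' @rdname elements
#' @export
fixed_resistor <- function(resistance, from = NULL, to = NULL, id = NULL) {
  if (!is.numeric(resistance) || length(resistance) != 1L ||
      !is.finite(resistance) || resistance < 0)
    stop("resistance must be a finite number >= 0 (Pa s m^-3)")
  new_element("fixed_resistor", list(resistance = resistance), from, to, id)
}

#' @rdname elements
#' @export
check_valve <- function(cracking_pressure = 0, forward_resistance = NULL,
                        from = NULL, to = NULL, id = NULL) {
  if (!is.numeric(cracking_pressure) || cracking_pressure < 0)
    stop("cracking_pressure must be >= 0 (Pa)")
  if (!is.null(forward_resistance)) {
    if (!is.numeric(forward_resistance) || forward_resistance <= 0)
      stop("forward_resistance must be > 0 (Pa s m^-3)")
  }
  new_element("check_valve",
              list(cracking_pressure = cracking_pressure,
                   forward_resistance = forward_resistance),
              from, to, id)
}

#' Hydraulic resistance of an element
#'
#' For a rectangular channel the Hagen-Poiseuille approximation
#' `Rh = 12 mu L / (a b^3 (1 - 0.63 b/a))` is used, with `a = max(w, h)`
#' and `b = min(w, h)` so the result does not depend on which side is
#' called the width. The approximation assumes the aspect ratio is not too
#' close to 1; for near-square channels it deviates by roughly 10-15% from
#' the exact series solution (this is a property of the formula, not of
#' the implementation). For a circular tube the exact Poiseuille result
#' `Rh = 128 mu L / (pi d^4)` applies.
#'
#' @param element A `hydraulic_element`.
#' @param fluid A [fluid_properties()] object.
#' @return Hydraulic resistance in Pa s m^-3 (strictly positive for
#'   geometric elements).
#' @examples
#' med <- fluid("medium-37C")
#' resistance_rectangular(rect_channel(0.011, 500e-6, 500e-6), med)
#' resistance_circular(circular_tube(0.08, 250e-6), fluid("water-20C"))
#' @export
element_resistance <- function(element, fluid) {
  UseMethod("element_resistance")
}

#' @export
element_resistance.rect_channel <- function(element, fluid) {
  stopifnot(inherits(fluid, "fluid_properties"))
  a <- max(element$width, element$height)
  b <- min(element$width, element$height)
  12 * fluid$dynamic_viscosity * element$length /
    (a * b^3 * (1 - 0.63 * b / a))
}

#' @export
element_resistance.circular_tube <- function(element, fluid) {
  stopifnot(inherits(fluid, "fluid_properties"))
  128 * fluid$dynamic_viscosity * element$length / (pi * element$diameter^4)
}

#' @export
element_resistance.fixed_resistor <- function(element, fluid) {
  element$resistance
}

#' @export
element_resistance.check_valve <- function(element, fluid) {
  stop("a check valve has no static resistance; its open-state resistance ",
       "is resolved by the network solver")
}

#' @rdname element_resistance
#' @param geom A [rect_channel()] (for `resistance_rectangular`) or
#'   [circular_tube()] (for `resistance_circular`).
#' @export
resistance_rectangular <- function(geom, fluid) {
  stopifnot(inherits(geom, "rect_channel"))
  element_resistance(geom, fluid)
}

#' @rdname element_resistance
#' @export
resistance_circular <- function(geom, fluid) {
  stopifnot(inherits(geom, "circular_tube"))
  element_resistance(geom, fluid)
}

#' Series and parallel combination of hydraulic resistances
#'
#' `series_total()` sums resistances of elements traversed one after the
#' other; `parallel_total()` combines branches sharing both end nodes via
#' the reciprocal-sum law `1/R_tot = sum(1/R_i)`.
#'
#' @param resistances Numeric vector of hydraulic resistances (Pa s m^-3).
#'   Series entries must be >= 0; a zero entry in a parallel combination is
#'   a short circuit and yields 0.
#' @return Combined resistance in Pa s m^-3. `series_total(numeric(0))` is
#'   0; `parallel_total()` of an empty vector is an error (no flow path).
#' @examples
#' series_total(c(1e9, 2e9, 3e9))
#' parallel_total(rep(4.5e9, 6))  # six identical channels -> R/6
#' @export
series_total <- function(resistances) {
  resistances <- as.numeric(resistances)
  if (length(resistances) == 0L) return(0)
  if (any(!is.finite(resistances)) || any(resistances < 0))
    stop("series resistances must be finite and >= 0")
  sum(resistances)
}

#' @rdname series_total
#' @export
parallel_total <- function(resistances) {
  resistances <- as.numeric(resistances)
  if (length(resistances) == 0L)
    stop("parallel_total() needs at least one branch")
  if (any(!is.finite(resistances)) || any(resistances < 0))
    stop("parallel resistances must be finite and >= 0")
  if (any(resistances == 0)) return(0)
  1 / sum(1 / resistances)
}

#' Flow through a single branch at a given pressure difference
#'
#' The fluidic Ohm's law solved for flow: `Q = dP / Rh`. Used to predict
#' the per-sample flow rate on a multiplexing board once the controlled
#' pressure difference across the samples is known.
#'
#' @param dp Pressure difference across the branch, Pa.
#' @param rh Branch hydraulic resistance, Pa s m^-3; must be > 0.
#' @return Volumetric flow in m^3 s^-1.
#' @examples
#' # 8 cm of 250 um tubing with water at 29 mbar -> about 208 uL/min
#' rh <- resistance_circular(circular_tube(0.08, 250e-6), fluid("water-20C"))
#' m3s_to_ulmin(branch_flow(mbar_to_pa(29), rh))
#' @export
branch_flow <- function(dp, rh) {
  if (!is.numeric(rh) || any(!is.finite(rh)) || any(rh <= 0))
    stop("branch resistance must be finite and > 0")
  dp / rh
}
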