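#' Fluid properties for hydraulic calculations
#'
#' Bundles the dynamic viscosity and density used by the resistance
#' formulas and the reservoir head model. Two presets cover the common
#' bench situations: serum-supplemented culture medium at 37 degrees C
#' (viscosity 0.00079 Pa s) and water at room temperature
#' (0.001 Pa s), used when a rig is validated with ddH2O.
#'
#' @param dynamic_viscosity Dynamic viscosity in Pa s; must be positive.
#' @param density Density in kg m^-3; must be positive.
#' @param label Free-text description of the fluid.
#' @return An object of class `fluid_properties`.
#' @examples
#' fluid_properties(0.00079, 1005, "EGM-2 2% serum 37C")
#' fluid("water-20C")
#' @export
fluid_properties <- function(dynamic_viscosity, density = 1000,
                             label = "custom") {
  stopifnot(is.numeric(dynamic_viscosity), length(dynamic_viscosity) == 1L,
            is.numeric(density), length(density) == 1L)
  if (!is.finite(dynamic_viscosity) || dynamic_viscosity <= 0)
    stop("dynamic_viscosity must be a positive finite number (Pa s)")
  if (!is.finite(density) || density <= 0)
    stop("density must be a positive finite number (kg m^-3)")
  structure(list(dynamic_viscosity = dynamic_viscosity,
                 density = density, label = as.character(label)[1]),
            class = "fluid_properties")
}

#' @rdname fluid_properties
#' @param name Preset name, `"medium-37C"` or `"water-20C"`.
#' @export
fluid <- function(name = c("medium-37C", "water-20C")) {
  name <- match.arg(name)
  switch(name,
    "medium-37C" = fluid_properties(0.00079, 1005, "EGM-2 2% serum 37C"),
    "water-20C"  = fluid_properties(0.001, 1000, "water 20C"))
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("Fluid: %s  (viscosity %.3g Pa s, density %g kg/m^3)\n",
              x$label, x$dynamic_viscosity, x$density))
  invisible(x)
}
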