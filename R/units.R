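#' Unit conversions between SI and bench units
#'
#' All internal computation is in SI (Pa, m, m^3 s^-1). Pressures at the
#' user interface are millibar (1 mbar = 100 Pa) and flow rates are
#' microlitres per minute (1 uL/min = 1e-9/60 m^3 s^-1), the units the
#' instruments report.
#'
#' @param x numeric vector to convert.
#' @return Converted numeric vector.
#' @name units
NULL

#' @rdname units
#' @export
mbar_to_pa <- function(x) x * 100

#' @rdname units
#' @export
pa_to_mbar <- function(x) x / 100

#' @rdname units
#' @export
ulmin_to_m3s <- function(x) x * 1e-9 / 60

#' @rdname units
#' @export
m3s_to_ulmin <- function(x) x * 6e10

#' @rdname units
#' @export
ml_to_m3 <- function(x) x * 1e-6

#' @rdname units
#' @export
m3_to_ml <- function(x) x * 1e6

# standard gravity, m s^-2
GRAVITY <- 9.81
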