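#' Waste-gas composition of the smoke source
#'
#' Mass fractions of the four measured waste-gas species at the incision.
#' The in vitro chromatography reported only that CO + CO2 dominate CH4 +
#' NH3; numeric fractions were not published, so these defaults are declared
#' placeholders satisfying that ordering, and every absolute CO result
#' downstream is composition-dependent. Fractions must lie in [0, 1] and sum
#' to at most 1; the remainder is entrained air.
#'
#' @param CO,CO2,CH4,NH3 mass fractions of each species in the source gas.
#' @return Named numeric vector of mass fractions.
#' @export
default_composition <- function(CO = 0.25, CO2 = 0.55, CH4 = 0.04, NH3 = 0.02) {
  comp <- c(CO = CO, CO2 = CO2, CH4 = CH4, NH3 = NH3)
  validate_composition(comp)
  comp
}

validate_composition <- function(comp) {
  if (!all(c("CO", "CO2", "CH4", "NH3") %in% names(comp))) {
    abort("composition must name mass fractions for CO, CO2, CH4 and NH3")
  }
  if (any(comp < 0) || any(comp > 1) || sum(comp) > 1 + 1e-12) {
    abort("composition fractions must lie in [0, 1] and sum to at most 1")
  }
  invisible(comp)
}

#' Assemble the smoke source for a knife operating point
#'
#' Resolves a requested tip temperature to a knife power (canonical lookup
#' for 200/300/400/500 degC, continuous inverse otherwise), then evaluates
#' the calibration polynomials to obtain the volumetric waste-gas flow and
#' the tar and particle injection rates. The result is the complete boundary
#' specification of the sub-grid smoke inlet at the incision.
#'
#' @param tip_temp numeric(1), knife tip temperature (degC); must exceed
#'   `ambient`.
#' @param calib a [calibration_set()].
#' @param composition named species mass fractions, see
#'   [default_composition()].
#' @param position numeric(3), source location (m); defaults to the incision
#'   point 0.1 m above the centre of the operating table.
#' @param ambient ambient temperature (degC) the source must exceed.
#' @param lookup passed to [power_for_temperature()].
#' @return A `source_spec` object: volume flow (m^3/s), temperature (degC),
#'   species mass fractions, tar and particle injection rates (g/s), the
#'   resolved power (W) and the position.
#' @examples
#' make_source_spec(500)
#' @export
make_source_spec <- function(tip_temp, calib = default_calibration(),
                             composition = default_composition(),
                             position = c(4.0, 3.0, 0.9),
                             ambient = 27, lookup = TRUE) {
  validate_composition(composition)
  stopifnot(length(position) == 3)
  if (!is.finite(tip_temp) || tip_temp <= ambient) {
    abort(sprintf("source temperature (%s degC) must exceed ambient (%s degC)",
                  format(tip_temp), format(ambient)))
  }
  power <- power_for_temperature(tip_temp, calib, lookup = lookup)
  structure(
    list(
      volume_flow = eval_waste_gas_flow(as.numeric(power), calib),
      temperature = tip_temp,
      species_mass_fractions = composition,
      tar_rate = eval_tar_rate(as.numeric(power), calib),
      particle_rate = eval_particle_rate(as.numeric(power), calib),
      power = as.numeric(power),
      position = as.numeric(position)
    ),
    class = "source_spec"
  )
}

#' @export
print.source_spec <- function(x, ...) {
  cat("<source_spec>\n")
  cat(sprintf("  tip temperature: %g degC (power %g W)\n", x$temperature, x$power))
  cat(sprintf("  volume flow:     %.4g m^3/s\n", x$volume_flow))
  cat(sprintf("  tar rate:        %.4g g/s   particle rate: %.4g g/s\n",
              x$tar_rate, x$particle_rate))
  cat("  mass fractions:  ",
      paste(names(x$species_mass_fractions),
            format(x$species_mass_fractions), sep = "=", collapse = "  "), "\n")
  cat(sprintf("  position:        (%g, %g, %g) m\n",
              x$position[1], x$position[2], x$position[3]))
  invisible(x)
}
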