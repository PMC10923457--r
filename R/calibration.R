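#' Calibration polynomials for the electro-surgical smoke source
#'
#' An electro-surgical knife run at power `P` (W) heats its tip and pyrolyses
#' tissue at the incision. In vitro power sweeps relate the operating power to
#' four responses: the tip temperature (degC), the net waste-gas flow rate at
#' standard conditions (m^3/s), and the formation rates of non-viable
#' particles and condensed tar droplets (g/s). A `calibration_set` stores the
#' polynomial coefficients of those four response curves, in ascending order
#' of power:
#'
#' * `temp_coeffs` — quadratic, tip temperature vs power;
#' * `flow_coeffs` — quadratic, net waste-gas flow vs power;
#' * `particle_coeffs` — cubic, particle formation rate vs power;
#' * `tar_coeffs` — cubic, tar formation rate vs power.
#'
#' `default_calibration()` returns the published coefficients:
#' \deqn{T_{tip} = 270 - 4.59 P + 0.095 P^2}
#' \deqn{G_{wastegas} = 9.30\times10^{-6} - 4.49\times10^{-8} P + 7.16\times10^{-9} P^2}
#' \deqn{F_{particle} = -4.14\times10^{-3} + 6.33\times10^{-4} P - 2.06\times10^{-6} P^2 + 2.80\times10^{-7} P^3}
#' \deqn{F_{tar} = 2.82\times10^{-3} + 4.69\times10^{-4} P - 9.69\times10^{-6} P^2 + 1.98\times10^{-7} P^3}
#'
#' @param temp_coeffs,flow_coeffs numeric(3), ascending-power quadratic
#'   coefficients.
#' @param particle_coeffs,tar_coeffs numeric(4), ascending-power cubic
#'   coefficients.
#' @return A `calibration_set` object (a named list of the four coefficient
#'   vectors).
#' @examples
#' calib <- default_calibration()
#' eval_tip_temperature(80, calib)
#' @export
calibration_set <- function(temp_coeffs, flow_coeffs, particle_coeffs, tar_coeffs) {
  stopifnot(length(temp_coeffs) == 3, length(flow_coeffs) == 3,
            length(particle_coeffs) == 4, length(tar_coeffs) == 4)
  structure(
    list(
      temp_coeffs = as.numeric(temp_coeffs),
      flow_coeffs = as.numeric(flow_coeffs),
      particle_coeffs = as.numeric(particle_coeffs),
      tar_coeffs = as.numeric(tar_coeffs)
    ),
    class = "calibration_set"
  )
}

#' @rdname calibration_set
#' @export
default_calibration <- function() {
  calibration_set(
    temp_coeffs     = c(270, -4.59, 0.095),
    flow_coeffs     = c(9.30e-6, -4.49e-8, 7.16e-9),
    particle_coeffs = c(-4.14e-3, 6.33e-4, -2.06e-6, 2.80e-7),
    tar_coeffs      = c(2.82e-3, 4.69e-4, -9.69e-6, 1.98e-7)
  )
}

#' @export
print.calibration_set <- function(x, ...) {
  cat("<calibration_set>\n")
  cat("  tip temperature (degC):   ", format(x$temp_coeffs), "\n")
  cat("  waste-gas flow (m^3/s):   ", format(x$flow_coeffs), "\n")
  cat("  particle rate (g/s):      ", format(x$particle_coeffs), "\n")
  cat("  tar rate (g/s):           ", format(x$tar_coeffs), "\n")
  invisible(x)
}

# Horner evaluation of an ascending-coefficient polynomial
polyval_asc <- function(coeffs, x) {
  out <- rep(0, length(x))
  for (c_i in rev(coeffs)) out <- out * x + c_i
  out
}

check_power <- function(power) {
  if (any(!is.finite(power)) || any(power < 0)) {
    abort("`power` must be finite and non-negative (W).")
  }
  invisible(power)
}

#' Evaluate the calibration responses at a knife power
#'
#' Vectorised evaluation of the four calibration polynomials. Power is the
#' electro-surgical unit setting in watts; the fitted operating range is
#' 20--80 W.
#'
#' `eval_particle_rate()` clamps negative predictions to zero by default:
#' the fitted cubic has a negative constant term, so it dips below zero at
#' very low power where a physical formation rate cannot. Set `clamp = FALSE`
#' to see the raw polynomial (needed when refitting).
#'
#' @param power numeric, knife power (W), `>= 0`.
#' @param calib a [calibration_set()]; defaults to the published coefficients.
#' @param clamp logical, floor negative particle-rate predictions at zero.
#' @return numeric vector: tip temperature (degC), net waste-gas flow
#'   (m^3/s), or formation rate (g/s).
#' @examples
#' eval_tip_temperature(c(20, 60, 70, 80))
#' eval_waste_gas_flow(80)
#' eval_particle_rate(0)           # clamped to 0
#' eval_particle_rate(0, clamp = FALSE)
#' @export
eval_tip_temperature <- function(power, calib = default_calibration()) {
  check_power(power)
  polyval_asc(calib$temp_coeffs, power)
}

#' @rdname eval_tip_temperature
#' @export
eval_waste_gas_flow <- function(power, calib = default_calibration()) {
  check_power(power)
  polyval_asc(calib$flow_coeffs, power)
}

#' @rdname eval_tip_temperature
#' @export
eval_particle_rate <- function(power, calib = default_calibration(), clamp = TRUE) {
  check_power(power)
  out <- polyval_asc(calib$particle_coeffs, power)
  if (clamp) out <- pmax(out, 0)
  out
}

#' @rdname eval_tip_temperature
#' @export
eval_tar_rate <- function(power, calib = default_calibration()) {
  check_power(power)
  polyval_asc(calib$tar_coeffs, power)
}

#' Invert the tip-temperature polynomial
#'
#' Returns the knife power that produces a requested tip temperature under
#' the quadratic temperature calibration. Two modes:
#'
#' * `lookup = TRUE` (default): the four canonical simulated temperatures
#'   200/300/400/500 degC map to the reported powers 20/60/70/80 W. The
#'   reported correspondence is used verbatim because the quadratic's exact
#'   preimages of those round temperatures differ slightly (e.g. the
#'   quadratic gives 216 degC at 20 W and cannot reach 200 degC at all).
#'   Non-canonical temperatures fall through to the continuous inverse.
#' * `lookup = FALSE`: the larger real root of
#'   `a2 P^2 + a1 P + (a0 - T) = 0`. Temperatures below the parabola minimum
#'   (about 214.6 degC at 24.16 W for the default coefficients) are
#'   unreachable; the vertex power is returned with attribute
#'   `unreachable = TRUE` and a warning.
#'
#' @param tip_temp numeric(1), requested tip temperature (degC).
#' @param calib a [calibration_set()].
#' @param lookup logical, use the canonical temperature-to-power table for
#'   200/300/400/500 degC.
#' @return numeric(1) power (W), possibly with attribute `unreachable`.
#' @examples
#' power_for_temperature(500)                  # 80 W (lookup)
#' power_for_temperature(500, lookup = FALSE)  # 78.97 W (exact root)
#' @export
power_for_temperature <- function(tip_temp, calib = default_calibration(),
                                  lookup = TRUE) {
  stopifnot(length(tip_temp) == 1, is.finite(tip_temp))
  canonical <- c(`200` = 20, `300` = 60, `400` = 70, `500` = 80)
  if (lookup && as.character(tip_temp) %in% names(canonical)) {
    return(unname(canonical[[as.character(tip_temp)]]))
  }
  a0 <- calib$temp_coeffs[1]; a1 <- calib$temp_coeffs[2]; a2 <- calib$temp_coeffs[3]
  if (a2 == 0) return((tip_temp - a0) / a1)
  disc <- a1^2 - 4 * a2 * (a0 - tip_temp)
  vertex_p <- -a1 / (2 * a2)
  if (disc < 0) {
    warn(sprintf(
      "tip temperature %.6g degC is below the calibration minimum (%.6g degC); returning the vertex power %.6g W",
      tip_temp, polyval_asc(calib$temp_coeffs, vertex_p), vertex_p))
    out <- vertex_p
    attr(out, "unreachable") <- TRUE
    return(out)
  }
  (-a1 + sqrt(disc)) / (2 * a2)
}

#' Fit calibration polynomials to a power sweep
#'
#' Ordinary least-squares polynomial fits of the four responses against
#' power: degree 2 for tip temperature and waste-gas flow, degree 3 for
#' particle and tar formation rates. The input is a power-sweep tibble as
#' produced by [generate_sweep()] or [read_power_sweep()], with columns
#' `power`, `tip_temp`, `waste_gas_flow`, `particle_rate`, `tar_rate`.
#'
#' @param records a data frame of power-sweep measurements.
#' @return A `smoke_calibration` object: the fitted [calibration_set()] in
#'   `$calibration`, per-response residual sums of squares in `$rss`, and the
#'   underlying `lm` fits in `$fits`. [generics::tidy()] returns the
#'   coefficient table, [generics::glance()] one row per response.
#' @examples
#' sweep <- generate_sweep(sweep_design(noise_cv = 0))
#' fit <- fit_calibration(sweep)
#' tidy(fit)
#' @export
fit_calibration <- function(records) {
  records <- tibble::as_tibble(records)
  needed <- c("power", "tip_temp", "waste_gas_flow", "particle_rate", "tar_rate")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("power-sweep table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  n_distinct_p <- length(unique(records$power))
  if (n_distinct_p < 4) {
    abort("need >= 4 distinct power levels to fit the quadratic responses")
  }
  responses <- list(
    tip_temp       = list(col = "tip_temp", degree = 2),
    waste_gas_flow = list(col = "waste_gas_flow", degree = 2),
    particle_rate  = list(col = "particle_rate", degree = 3),
    tar_rate       = list(col = "tar_rate", degree = 3)
  )
  if (n_distinct_p < 5) {
    abort("need >= 5 distinct power levels to fit the cubic responses")
  }
  fits <- purrr::imap(responses, function(spec, nm) {
    fml <- stats::as.formula(
      paste0(spec$col, " ~ ", paste0("I(power^", seq_len(spec$degree), ")",
                                     collapse = " + ")))
    lm(fml, data = records)
  })
  rss <- purrr::map_dbl(fits, ~ sum(stats::residuals(.x)^2))
  calib <- calibration_set(
    temp_coeffs     = unname(coef(fits$tip_temp)),
    flow_coeffs     = unname(coef(fits$waste_gas_flow)),
    particle_coeffs = unname(coef(fits$particle_rate)),
    tar_coeffs      = unname(coef(fits$tar_rate))
  )
  structure(
    list(calibration = calib, rss = rss, fits = fits, records = records,
         n = nrow(records), n_powers = n_distinct_p),
    class = "smoke_calibration"
  )
}

#' @export
print.smoke_calibration <- function(x, ...) {
  cat("<smoke_calibration> fitted on", x$n, "records at", x$n_powers,
      "power levels\n")
  print(x$calibration)
  cat("  RSS:", paste(names(x$rss), format(x$rss, digits = 4),
                      sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_calibration
#' @param x a `smoke_calibration` object.
#' @param ... unused.
#' @export
tidy.smoke_calibration <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(fit, nm) {
    s <- suppressWarnings(summary(fit))$coefficients
    tibble::tibble(
      response = nm,
      term = paste0("power^", seq_len(nrow(s)) - 1L),
      estimate = s[, "Estimate"],
      std.error = s[, "Std. Error"]
    )
  })
}

#' @rdname fit_calibration
#' @export
glance.smoke_calibration <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(fit, nm) {
    s <- suppressWarnings(summary(fit))
    tibble::tibble(
      response = nm,
      r.squared = s$r.squared,
      sigma = s$sigma,
      rss = sum(stats::residuals(fit)^2),
      df.residual = fit$df.residual,
      nobs = length(fit$residuals)
    )
  })
}

#' Read and write power-sweep CSV tables
#'
#' The on-disk interchange format for in vitro power sweeps is a CSV with
#' header `power_W, tip_temp_C, waste_gas_m3s, tar_gs, particle_gs`. In
#' memory the same data is a tibble with columns `power`, `tip_temp`,
#' `waste_gas_flow`, `tar_rate`, `particle_rate` (and optionally `replicate`).
#'
#' @param path file path.
#' @param records power-sweep tibble.
#' @return `read_power_sweep()` returns the tibble; `write_power_sweep()`
#'   returns `path` invisibly.
#' @export
read_power_sweep <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("power_W", "tip_temp_C", "waste_gas_m3s", "tar_gs", "particle_gs")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("power-sweep CSV is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tibble::tibble(
    power = df$power_W,
    tip_temp = df$tip_temp_C,
    waste_gas_flow = df$waste_gas_m3s,
    tar_rate = df$tar_gs,
    particle_rate = df$particle_gs
  )
}

#' @rdname read_power_sweep
#' @export
write_power_sweep <- function(records, path) {
  out <- tibble::tibble(
    power_W = records$power,
    tip_temp_C = records$tip_temp,
    waste_gas_m3s = records$waste_gas_flow,
    tar_gs = records$tar_rate,
    particle_gs = records$particle_rate
  )
  readr::write_csv(out, path)
  invisible(path)
}
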