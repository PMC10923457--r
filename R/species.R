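#' Steady passive-scalar transport on a converged flow
#'
#' The waste-gas species (CO, CO2, CH4, NH3) and the dispersed-phase
#' concentrations are passive: they ride on the converged flow without
#' feeding back on it (density responds only to temperature). Their steady
#' transport equations are therefore linear in the converged face fluxes and
#' are solved exactly, once, by a sparse LU factorisation — upwind
#' convection keeps every mass fraction within its inflow bounds.
#'
#' `solve_species()` fills `field$Y` with the four species mass-fraction
#' arrays. `concentration_field()` solves the same transport equation for a
#' dispersed-phase mass concentration (g/m^3): at the assumed 2 micron
#' diameter the Stokes number is far below one, so the dispersed mixture
#' follows the carrier gas and its Eulerian description reduces to passive
#' transport of the injected mass.
#'
#' @param field a converged `field_state` from [solve_steady()].
#' @return `solve_species()`: the field with `$Y` set.
#'   `concentration_field()`: the concentration array (g/m^3).
#' @export
solve_species <- function(field) {
  check_converged(field)
  sm <- solver_mesh(field$mesh)
  Gam <- field$props$mu / field$constants$Sc +
    field$mu_t_last / field$constants$Sc_t
  species <- c("CO", "CO2", "CH4", "NH3")
  Y <- purrr::map(setNames(species, species), function(sp) {
    rate <- if (is.null(field$source)) 0 else field$source$species[[sp]]
    solve_passive_scalar(sm, field$flux, Gam, rate, field$source)
  })
  field$Y <- Y
  field
}

#' @rdname solve_species
#' @param phase `"tar"` or `"particle"`.
#' @param injection_rate override of the injection rate (g/s); defaults to
#'   the rate carried by the field's source.
#' @export
concentration_field <- function(field, phase = c("tar", "particle"),
                                injection_rate = NULL) {
  check_converged(field)
  phase <- match.arg(phase)
  sm <- solver_mesh(field$mesh)
  rho <- field$props$rho_ref
  if (is.null(injection_rate)) {
    injection_rate <- if (is.null(field$source)) 0 else
      switch(phase, tar = field$source$tar_rate,
             particle = field$source$particle_rate)
  }
  # volumetric fluxes (m^3/s) carry c in g/m^3; eddy diffusivity in m^2/s
  vol_flux <- list(fx = field$flux$fx / rho, fy = field$flux$fy / rho,
                   fz = field$flux$fz / rho)
  Gam <- (field$props$mu / field$constants$Sc +
            field$mu_t_last / field$constants$Sc_t) / rho
  src <- field$source
  if (!is.null(src)) src$mass <- src$mass / rho   # source volume flow basis
  solve_passive_scalar(sm, vol_flux, Gam, injection_rate, src)
}

solve_passive_scalar <- function(sm, flux, Gam, source_rate, source) {
  co <- scalar_coeffs(sm, flux, Gam, inflow_value = list(inlet = 0, outlet = 0))
  if (!is.null(source) && source_rate != 0) {
    cc <- source$cell
    co$b[cc[1], cc[2], cc[3]] <- co$b[cc[1], cc[2], cc[3]] + source_rate
  }
  co <- fix_cells(co, sm$mesh$solid, 0)
  # guard isolated/degenerate rows
  iso <- co$aP <= 0
  if (any(iso)) { co$aP[iso] <- 1; co$b[iso] <- 0 }
  direct_solve(co, sm$n)
}

check_converged <- function(field) {
  if (!inherits(field, "field_state")) abort("expected a `field_state`")
  if (!isTRUE(field$converged)) {
    abort("flow field is not converged; refusing to transport scalars on it")
  }
  invisible(field)
}

#' Global mass audits of a converged case
#'
#' Balances computed from the discrete face fluxes: total mass (inlet +
#' source vs outlet), each species (source injection vs outlet advection)
#' and each dispersed phase. A well-converged case closes all balances to a
#' fraction of a percent of the throughput.
#'
#' @param field a `field_state`, after [solve_species()] /
#'   [concentration_field()] as applicable.
#' @param c_tar,c_particle optional concentration arrays from
#'   [concentration_field()].
#' @return tibble with columns `quantity`, `inflow`, `outflow`,
#'   `imbalance_rel`.
#' @export
mass_audit <- function(field, c_tar = NULL, c_particle = NULL) {
  sm <- solver_mesh(field$mesh)
  n <- sm$n
  rho <- field$props$rho_ref
  inlet_in <- -sum(field$flux$fz[, , n[3] + 1])
  src_in <- sum(field$s_mass)
  out0 <- -field$flux$fy[, 1, ]      # positive = leaving through y = 0
  out1 <- field$flux$fy[, n[2] + 1, ]
  total_out <- sum(out0) + sum(out1)
  rows <- list(tibble::tibble(
    quantity = "mass", inflow = inlet_in + src_in, outflow = total_out,
    imbalance_rel = abs(inlet_in + src_in - total_out) / max(inlet_in, 1e-300)
  ))
  if (!is.null(field$Y)) {
    for (sp in names(field$Y)) {
      yin <- if (is.null(field$source)) 0 else field$source$species[[sp]]
      yout <- sum(pmax(out0, 0) * field$Y[[sp]][, 1, ]) +
        sum(pmax(out1, 0) * field$Y[[sp]][, n[2], ])
      rows <- c(rows, list(tibble::tibble(
        quantity = paste0("Y_", sp), inflow = yin, outflow = yout,
        imbalance_rel = abs(yin - yout) / max(yin, 1e-300))))
    }
  }
  disp <- list(tar = c_tar, particle = c_particle)
  for (ph in names(disp)) {
    cc <- disp[[ph]]
    if (is.null(cc)) next
    rate_in <- if (is.null(field$source)) 0 else
      switch(ph, tar = field$source$tar_rate, particle = field$source$particle_rate)
    rate_out <- sum(pmax(out0, 0) / rho * cc[, 1, ]) +
      sum(pmax(out1, 0) / rho * cc[, n[2], ])
    rows <- c(rows, list(tibble::tibble(
      quantity = paste0("c_", ph), inflow = rate_in, outflow = rate_out,
      imbalance_rel = abs(rate_in - rate_out) / max(rate_in, 1e-300))))
  }
  dplyr::bind_rows(rows)
}
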