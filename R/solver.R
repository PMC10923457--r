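#' Model constants and settings for the theatre flow solver
#'
#' `turbulence_constants()` returns the k-epsilon closure constants. The
#' defaults are the values used for this theatre model (`C1 = 1.43`,
#' `C2 = 1.93`, `Cmu = 0.09`, `sigma_k = 1.0`, `sigma_eps = 1.43`, and the
#' energy-equation Prandtl-like numbers `sigma_T = 1.00`, `sigma_tT = 0.9`);
#' note `C1`, `C2` and `sigma_eps` differ slightly from the canonical
#' Launder-Spalding 1.44/1.92/1.3, which `canonical = TRUE` selects instead.
#' `kappa` and `E` are the log-law constants of the standard wall function;
#' `Sc`/`Sc_t` the laminar/turbulent Schmidt numbers for species transport.
#'
#' @param canonical use the canonical k-epsilon constants instead.
#' @return named list of constants.
#' @export
turbulence_constants <- function(canonical = FALSE) {
  out <- list(C1 = 1.43, C2 = 1.93, Cmu = 0.09, sigma_k = 1.0,
              sigma_eps = 1.43, sigma_T = 1.00, sigma_tT = 0.9,
              kappa = 0.41, E = 9.8, Sc = 0.7, Sc_t = 0.7)
  if (canonical) {
    out$C1 <- 1.44; out$C2 <- 1.92; out$sigma_eps <- 1.3
  }
  out
}

#' @rdname turbulence_constants
#' @description `air_properties()` holds the carrier-gas (air) properties:
#' reference density at the inlet temperature, dynamic viscosity, specific
#' heat, and gravity. Density varies only in the gravity term, as an ideal
#' gas at constant pressure: `rho(T) = rho_ref * T_ref / T` (the source is
#' ~470 K above ambient, far outside the Boussinesq range).
#' @param rho_ref reference density (kg/m^3) at `T_ref_C`.
#' @param mu dynamic viscosity (Pa s).
#' @param cp specific heat (J/kg/K).
#' @param T_ref_C reference temperature (degC).
#' @param g gravitational acceleration (m/s^2).
#' @export
air_properties <- function(rho_ref = 1.177, mu = 1.85e-5, cp = 1006,
                           T_ref_C = 27, g = 9.81) {
  list(rho_ref = rho_ref, mu = mu, cp = cp, T_ref_C = T_ref_C,
       T_ref_K = T_ref_C + 273.15, g = g)
}

#' @rdname turbulence_constants
#' @description `boundary_conditions()` holds the theatre boundary data: the
#' ceiling inlet blows down at `V_in = 0.096` m/s and 27 degC with 3.7%
#' turbulence intensity and a turbulence length scale of 0.07 times the
#' 2.4 m inlet width; the wall outlets are fixed-pressure; the four side
#' walls are no-slip with a Robin heat condition (transfer coefficient
#' 1.5 W/m^2/K to a 30 degC exterior); ceiling, floor and table are no-slip
#' adiabatic.
#' @param V_in inlet downward velocity (m/s).
#' @param T_in_C inlet air temperature (degC).
#' @param Ti inlet turbulence intensity (fraction).
#' @param length_scale turbulence length scale at the inlet (m).
#' @param h_wall side-wall heat transfer coefficient (W/m^2/K).
#' @param T_ext_C exterior temperature behind the side walls (degC).
#' @export
boundary_conditions <- function(V_in = 0.096, T_in_C = 27, Ti = 0.037,
                                length_scale = 0.07 * 2.4,
                                h_wall = 1.5, T_ext_C = 30) {
  stopifnot(V_in > 0, Ti > 0, Ti < 1, length_scale > 0, h_wall >= 0)
  list(V_in = V_in, T_in_C = T_in_C, T_in_K = T_in_C + 273.15,
       Ti = Ti, length_scale = length_scale,
       h_wall = h_wall, T_ext_C = T_ext_C, T_ext_K = T_ext_C + 273.15)
}

#' @rdname turbulence_constants
#' @description `solver_settings()` holds the numerical controls: implicit
#' under-relaxation factors, the normalized-residual convergence tolerance
#' (residuals are normalized by their largest value over the first five
#' outer iterations), the outer-iteration cap and inner Jacobi sweep count.
#' @param relax_mom,relax_p,relax_scalar under-relaxation factors in (0, 1].
#' @param tol convergence tolerance on normalized residuals.
#' @param max_iter outer-iteration cap.
#' @param sweeps inner Jacobi sweeps per equation per outer iteration.
#' @param buoyancy include the temperature-dependent gravity term.
#' @export
solver_settings <- function(relax_mom = 0.7, relax_p = 0.3, relax_scalar = 0.5,
                            tol = 1e-4, max_iter = 2000, sweeps = 4,
                            buoyancy = TRUE) {
  stopifnot(relax_mom > 0, relax_mom <= 1, relax_p > 0, relax_p <= 1,
            relax_scalar > 0, relax_scalar <= 1, tol > 0, max_iter >= 1)
  list(relax_mom = relax_mom, relax_p = relax_p, relax_scalar = relax_scalar,
       tol = tol, max_iter = max_iter, sweeps = sweeps, buoyancy = buoyancy)
}

#' Inlet turbulence quantities
#'
#' Turbulent kinetic energy and dissipation rate at the ceiling inlet:
#' \deqn{k_{inlet} = 1.5 (V_{in} T_i)^2}
#' \deqn{\varepsilon_{inlet} = C_\mu^{0.75} k^{1.5} / l}
#'
#' @param V_in inlet velocity (m/s), `> 0`.
#' @param Ti turbulence intensity (fraction), `> 0`.
#' @param l turbulence length scale (m), `> 0`.
#' @param Cmu eddy-viscosity constant.
#' @return list with `k` (m^2/s^2) and `eps` (m^2/s^3).
#' @examples
#' inlet_turbulence(0.096, 0.037, 0.07 * 2.4)
#' @export
inlet_turbulence <- function(V_in, Ti, l, Cmu = 0.09) {
  if (any(c(V_in, Ti, l, Cmu) <= 0)) {
    abort("V_in, Ti, l and Cmu must all be positive (k must be > 0 at the inlet)")
  }
  k <- 1.5 * (V_in * Ti)^2
  list(k = k, eps = Cmu^0.75 * k^1.5 / l)
}

#' Effective viscosity of the k-epsilon closure
#'
#' `mu_eff = mu + mu_t` with `mu_t = rho * Cmu * k^2 / eps`, bounded below
#' by the molecular viscosity.
#'
#' @param k turbulent kinetic energy (m^2/s^2), array or scalar.
#' @param eps dissipation rate (m^2/s^3), must be positive wherever used.
#' @param props [air_properties()].
#' @param constants [turbulence_constants()].
#' @return `mu_eff` with the same shape as `k`.
#' @export
effective_viscosity <- function(k, eps, props = air_properties(),
                                constants = turbulence_constants()) {
  bad <- which(eps <= 0)
  if (length(bad) > 0) {
    abort(sprintf("non-positive dissipation rate at %d cell(s) (first index %d)",
                  length(bad), bad[1]))
  }
  props$mu + props$rho_ref * constants$Cmu * k^2 / eps
}

#' Shear production of turbulent kinetic energy
#'
#' `G_k = mu_t (du_j/dx_i)(du_i/dx_j + du_j/dx_i)` with all gradients taken
#' by central differences (one-sided at closed faces). Zero for uniform flow
#' and for rigid rotation; `mu_t S^2` for simple shear `u(z) = S z`.
#'
#' @param u,v,w cell-centred velocity component arrays (m/s).
#' @param mu_t turbulent viscosity array or scalar (Pa s).
#' @param sm internal solver-mesh cache (from a [build_mesh()] result via
#'   the internal `solver_mesh()`).
#' @return per-cell production array (W/m^3).
#' @export
production_Gk <- function(u, v, w, mu_t, sm) {
  g <- list(
    list(cell_gradient(sm, u, 1), cell_gradient(sm, u, 2), cell_gradient(sm, u, 3)),
    list(cell_gradient(sm, v, 1), cell_gradient(sm, v, 2), cell_gradient(sm, v, 3)),
    list(cell_gradient(sm, w, 1), cell_gradient(sm, w, 2), cell_gradient(sm, w, 3))
  )
  out <- 0
  for (i in 1:3) for (j in 1:3) {
    out <- out + g[[j]][[i]] * (g[[i]][[j]] + g[[j]][[i]])
  }
  mu_t * out
}

#' Standard wall function
#'
#' Bridges the no-slip wall and the first cell centre: with the k-based
#' friction scale `u* = Cmu^(1/4) sqrt(k)` and `y+ = rho u* y / mu`, the
#' wall shear stress is `tau_w = rho u* kappa u_t / ln(E y+)` in the
#' log-law range (`y+ > 11.63`) and the viscous `tau_w = mu u_t / y` below
#' it. The near-wall dissipation rate is pinned to
#' `eps = Cmu^(3/4) k^(3/2) / (kappa y)`.
#'
#' @param u_tan tangential velocity magnitude at the first cell centre (m/s).
#' @param y wall-normal distance of the first cell centre (m).
#' @param k turbulent kinetic energy at the first cell centre (m^2/s^2).
#' @param props [air_properties()].
#' @param constants [turbulence_constants()].
#' @return list of vectors: `tau_w` (Pa), `coef` (`tau_w / u_tan`, the
#'   implicit drag coefficient, Pa s/m), `yplus`, and `eps_wall` (m^2/s^3).
#' @examples
#' wall_treatment(0.1, 0.05, 1e-4)
#' @export
wall_treatment <- function(u_tan, y, k, props = air_properties(),
                           constants = turbulence_constants()) {
  ustar <- constants$Cmu^0.25 * sqrt(pmax(k, 0))
  yplus <- props$rho_ref * ustar * y / props$mu
  coef_log <- props$rho_ref * constants$kappa * ustar /
    log(pmax(constants$E * yplus, 1 + 1e-12))
  coef_lin <- props$mu / y
  coef <- ifelse(yplus > 11.63, coef_log, coef_lin)
  list(tau_w = coef * u_tan, coef = coef, yplus = yplus,
       eps_wall = constants$Cmu^0.75 * pmax(k, 0)^1.5 /
         (constants$kappa * y))
}

#' Volumetric source terms for the smoke inlet
#'
#' The physical smoke inlet at the incision is far below any practical grid
#' resolution, so it enters the discrete equations as volumetric sources in
#' the cell containing the incision point: a mass source
#' `rho_gas(T_source) * volume_flow` (ideal-gas density of the hot source
#' gas), a vertical momentum source equal to that mass flux times the
#' injection velocity `volume_flow / incision_area`, matching sensible-heat
#' and species sources, and the tar/particle mass injection rates.
#'
#' @param source a [make_source_spec()].
#' @param mesh a [build_mesh()] result.
#' @param props [air_properties()].
#' @param incision_area effective area of the incision opening (m^2) used to
#'   convert the volume flow to an injection velocity.
#' @return list: `cell` (i, j, k), `mass` (kg/s), `w_inj` (m/s),
#'   `momentum_w` (N), `T_src_K`, `species` (named kg/s), `tar_rate`,
#'   `particle_rate` (g/s).
#' @export
assemble_source <- function(source, mesh, props = air_properties(),
                            incision_area = 1e-4) {
  cell <- locate_cell(mesh, source$position)
  if (attr(cell, "solid")) {
    abort(sprintf("smoke source at (%g, %g, %g) lies in a solid (table) cell",
                  source$position[1], source$position[2], source$position[3]))
  }
  T_src_K <- source$temperature + 273.15
  rho_src <- props$rho_ref * props$T_ref_K / T_src_K
  mass <- rho_src * source$volume_flow
  w_inj <- if (source$volume_flow > 0) source$volume_flow / incision_area else 0
  list(
    cell = as.integer(cell),
    mass = mass,
    w_inj = w_inj,
    momentum_w = mass * w_inj,
    T_src_K = T_src_K,
    species = source$species_mass_fractions * mass,
    tar_rate = source$tar_rate,
    particle_rate = source$particle_rate,
    spec = source
  )
}

# ---------------------------------------------------------------------------
# steady SIMPLEC driver
# ---------------------------------------------------------------------------

# Rhie-Chow face mass fluxes; d_cell is the SIMPLEC pressure-velocity
# coupling coefficient V / (aP/alpha - sum a_nb)
face_fluxes <- function(sm, u, v, w, p, d_cell, bc, props, prev = NULL) {
  n <- sm$n
  rho <- props$rho_ref
  dpx <- cell_gradient(sm, p, 1)
  dpy <- cell_gradient(sm, p, 2)
  dpz <- cell_gradient(sm, p, 3)

  fx <- array(0, n + c(1, 0, 0))
  i1 <- seq_len(n[1] - 1)
  ubar <- 0.5 * (u[i1, , , drop = FALSE] + u[i1 + 1, , , drop = FALSE])
  df <- 0.5 * (d_cell[i1, , , drop = FALSE] + d_cell[i1 + 1, , , drop = FALSE])
  dp_face <- (p[i1 + 1, , , drop = FALSE] - p[i1, , , drop = FALSE]) / sm$mesh$d[1]
  dp_avg <- 0.5 * (dpx[i1, , , drop = FALSE] + dpx[i1 + 1, , , drop = FALSE])
  fx[i1 + 1, , ] <- rho * sm$Ax * (ubar - df * (dp_face - dp_avg)) *
    sm$open_fx[i1 + 1, , , drop = FALSE]

  fy <- array(0, n + c(0, 1, 0))
  j1 <- seq_len(n[2] - 1)
  vbar <- 0.5 * (v[, j1, , drop = FALSE] + v[, j1 + 1, , drop = FALSE])
  df <- 0.5 * (d_cell[, j1, , drop = FALSE] + d_cell[, j1 + 1, , drop = FALSE])
  dp_face <- (p[, j1 + 1, , drop = FALSE] - p[, j1, , drop = FALSE]) / sm$mesh$d[2]
  dp_avg <- 0.5 * (dpy[, j1, , drop = FALSE] + dpy[, j1 + 1, , drop = FALSE])
  fy[, j1 + 1, ] <- rho * sm$Ay * (vbar - df * (dp_face - dp_avg)) *
    sm$open_fy[, j1 + 1, , drop = FALSE]

  fz <- array(0, n + c(0, 0, 1))
  k1 <- seq_len(n[3] - 1)
  wbar <- 0.5 * (w[, , k1, drop = FALSE] + w[, , k1 + 1, drop = FALSE])
  df <- 0.5 * (d_cell[, , k1, drop = FALSE] + d_cell[, , k1 + 1, drop = FALSE])
  dp_face <- (p[, , k1 + 1, drop = FALSE] - p[, , k1, drop = FALSE]) / sm$mesh$d[3]
  dp_avg <- 0.5 * (dpz[, , k1, drop = FALSE] + dpz[, , k1 + 1, drop = FALSE])
  fz[, , k1 + 1] <- rho * sm$Az * (wbar - df * (dp_face - dp_avg)) *
    sm$open_fz[, , k1 + 1, drop = FALSE]

  # inlet: fixed downward velocity through the labelled ceiling faces
  fz[, , n[3] + 1] <- -rho * bc$V_in * sm$Az * sm$inlet_mask
  # outlets: the outlet face flux is a persistent unknown advanced only by
  # the pressure correction (its Dirichlet conductance); recomputing it from
  # the wall-cell velocity would be inconsistent with the cell-gradient
  # velocity correction and leaves a standing continuity imbalance
  if (is.null(prev)) {
    fy[, 1, ] <- rho * sm$Ay * v[, 1, ] * sm$outlet_ymin
    fy[, n[2] + 1, ] <- rho * sm$Ay * v[, n[2], ] * sm$outlet_ymax
  } else {
    fy[, 1, ] <- prev$fy[, 1, ] * sm$outlet_ymin
    fy[, n[2] + 1, ] <- prev$fy[, n[2] + 1, ] * sm$outlet_ymax
  }
  list(fx = fx, fy = fy, fz = fz)
}

# net mass leaving each cell minus its mass source
continuity_imbalance <- function(sm, flux, s_mass) {
  n <- sm$n
  out <- (flux$fx[-1, , ] - flux$fx[-(n[1] + 1), , ]) +
    (flux$fy[, -1, ] - flux$fy[, -(n[2] + 1), ]) +
    (flux$fz[, , -1] - flux$fz[, , -(n[3] + 1)])
  out - s_mass
}

#' Steady buoyant RANS solve of the theatre flow
#'
#' Solves the steady incompressible momentum, continuity, k-epsilon and
#' energy equations on the theatre mesh with SIMPLEC pressure-velocity
#' coupling: first-order upwind convection, central diffusion, Rhie-Chow
#' face-flux interpolation on the collocated grid, implicit under-relaxation,
#' damped-Jacobi inner sweeps for momentum and scalars and an exact sparse
#' solve of the pressure-correction equation. Buoyancy enters the vertical
#' momentum equation through the ideal-gas density deficit
#' `g (rho_ref - rho(T))`. Each equation's residual is normalized by its
#' largest value over the first five iterations; the solve stops when all
#' normalized residuals drop below `settings$tol`.
#'
#' @param mesh a [build_mesh()] result.
#' @param bc [boundary_conditions()].
#' @param source optional [assemble_source()] result (or `NULL` for the
#'   unforced room).
#' @param settings [solver_settings()].
#' @param constants [turbulence_constants()].
#' @param props [air_properties()].
#' @param init optional previous `field_state` used as the initial guess
#'   (warm start).
#' @param verbose print residuals every 50 iterations.
#' @return A `field_state` object: velocity components `u`, `v`, `w` (m/s),
#'   pressure `p` (Pa), temperature `T_K` (K), `k`, `eps`, the face fluxes,
#'   a `converged` flag, the iteration count and the long-format residual
#'   history tibble.
#' @export
solve_steady <- function(mesh, bc = boundary_conditions(), source = NULL,
                         settings = solver_settings(),
                         constants = turbulence_constants(),
                         props = air_properties(),
                         init = NULL, verbose = FALSE) {
  sm <- solver_mesh(mesh)
  n <- sm$n
  solid <- mesh$solid
  vol <- mesh$vol
  rho <- props$rho_ref

  inl <- inlet_turbulence(bc$V_in, bc$Ti, bc$length_scale, constants$Cmu)
  k_floor <- 1e-12; eps_floor <- 1e-12

  # conserve the physical volumetric inflow on the grid-quantized inlet
  # patch: the labelled patch area differs from the geometric 2.4 x 2.6 m
  # rectangle by up to one cell dimension, so the face velocity is rescaled
  # to keep V_in x A_geometric fixed
  if (!is.null(mesh$scene)) {
    A_geom <- diff(mesh$scene$inlet$x) * diff(mesh$scene$inlet$y)
    A_label <- sum(sm$inlet_mask) * sm$Az
    bc$V_in <- bc$V_in * A_geom / A_label
  }

  if (!is.null(init)) {
    u <- init$u; v <- init$v; w <- init$w; p <- init$p
    Tk <- init$T_K; tk <- init$k; te <- init$eps
  } else {
    u <- array(0, n); v <- array(0, n); w <- array(0, n)
    p <- array(0, n)
    Tk <- array(bc$T_in_K, n)
    tk <- array(inl$k, n)
    te <- array(inl$eps, n)
  }

  # volumetric sources
  s_mass <- array(0, n)
  src_cell <- NULL
  if (!is.null(source)) {
    src_cell <- source$cell
    s_mass[src_cell[1], src_cell[2], src_cell[3]] <- source$mass
  }

  # wall-adjacency data for the energy Robin condition
  cond_robin <- function(Gam) {
    # series resistance: exterior film (h) + half-cell conduction
    cx <- sm$robinA_x / (props$cp / bc$h_wall + (mesh$d[1] / 2) / pmax(Gam, 1e-12))
    cy <- sm$robinA_y / (props$cp / bc$h_wall + (mesh$d[2] / 2) / pmax(Gam, 1e-12))
    cx + cy
  }
  wall_any <- (sm$wallA_x + sm$wallA_y + sm$wallA_z) > 0 & sm$fluid
  y_wall <- min(mesh$d) / 2

  # initial face fluxes: plain averaged velocities, no Rhie-Chow term yet
  # (the coupling coefficient is only available after a momentum assembly)
  d_cell <- array(0, n)
  flux <- face_fluxes(sm, u, v, w, p, d_cell, bc, props)

  inflow_ref <- rho * bc$V_in * sm$Az * sum(sm$inlet_mask) +
    sum(s_mass)

  eq_names <- c("u", "v", "w", "continuity", "k", "eps", "T")
  ref_res <- setNames(rep(NA_real_, length(eq_names)), eq_names)
  # absolute residual scales: an equation whose raw residual sits at rounding
  # noise relative to its throughput is converged even if its normalization
  # reference is itself noise (e.g. the energy equation of an isothermal room)
  abs_scale <- setNames(c(rep(inflow_ref * bc$V_in, 3), inflow_ref,
                          inflow_ref * inl$k, inflow_ref * inl$eps,
                          inflow_ref * bc$T_in_K), eq_names)
  hist <- vector("list", settings$max_iter)
  converged <- FALSE
  pc_cache <- new.env(parent = emptyenv())

  a_mom <- settings$relax_mom
  a_sc <- settings$relax_scalar

  for (it in seq_len(settings$max_iter)) {
    mu_t <- rho * constants$Cmu * tk^2 / pmax(te, eps_floor)
    mu_eff <- props$mu + mu_t

    # wall drag coefficients per wall orientation (tangential: wall function)
    wf_x <- wall_treatment(1, mesh$d[1] / 2, tk, props, constants)$coef
    wf_y <- wall_treatment(1, mesh$d[2] / 2, tk, props, constants)$coef
    wf_z <- wall_treatment(1, mesh$d[3] / 2, tk, props, constants)$coef

    raw_res <- c()

    # ---- momentum ----
    dpx <- cell_gradient(sm, p, 1)
    dpy <- cell_gradient(sm, p, 2)
    dpz <- cell_gradient(sm, p, 3)

    mom <- list(
      u = list(phi = u, bsrc = -vol * dpx,
               wall = wf_y * sm$wallA_y + wf_z * sm$wallA_z +
                 (props$mu / (mesh$d[1] / 2)) * sm$wallA_x,
               inlet_val = 0),
      v = list(phi = v, bsrc = -vol * dpy,
               wall = wf_x * sm$wallA_x + wf_z * sm$wallA_z +
                 (props$mu / (mesh$d[2] / 2)) * sm$wallA_y,
               inlet_val = 0),
      w = list(phi = w, bsrc = -vol * dpz,
               wall = wf_x * sm$wallA_x + wf_y * sm$wallA_y +
                 (props$mu / (mesh$d[3] / 2)) * sm$wallA_z,
               inlet_val = -bc$V_in)
    )
    if (settings$buoyancy) {
      rho_T <- rho * props$T_ref_K / Tk
      mom$w$bsrc <- mom$w$bsrc + vol * props$g * (rho - rho_T)
    }
    if (!is.null(source)) {
      mom$w$bsrc[src_cell[1], src_cell[2], src_cell[3]] <-
        mom$w$bsrc[src_cell[1], src_cell[2], src_cell[3]] + source$momentum_w
    }

    aPu <- NULL; denom <- NULL
    new_uvw <- list()
    for (nm in names(mom)) {
      m <- mom[[nm]]
      co <- scalar_coeffs(sm, flux, mu_eff,
                          inflow_value = list(inlet = m$inlet_val, outlet = 0))
      co$aP <- co$aP + m$wall
      co$b <- co$b + m$bsrc
      sum_nb <- co$a_xm + co$a_xp + co$a_ym + co$a_yp + co$a_zm + co$a_zp
      co$b <- co$b + (1 - a_mom) / a_mom * co$aP * m$phi
      co$aP <- co$aP / a_mom
      co <- fix_cells(co, solid, 0)
      raw_res[nm] <- coeffs_residual(co, m$phi, sm$fluid)
      new_uvw[[nm]] <- jacobi_sweeps(co, m$phi, settings$sweeps)
      if (nm == "u") {
        # SIMPLEC coupling denominator; aP - sum(a_nb) equals the relaxation
        # surplus plus the cell's net outflow, which can dip negative while
        # continuity is still unconverged — keep it a sane positive fraction
        # of the diagonal
        denom <- pmax(co$aP - sum_nb, 0.05 * co$aP)
      }
    }
    u <- new_uvw$u; v <- new_uvw$v; w <- new_uvw$w
    u[solid] <- 0; v[solid] <- 0; w[solid] <- 0
    d_cell <- vol / denom
    d_cell[solid] <- 0

    # ---- continuity / pressure correction ----
    flux <- face_fluxes(sm, u, v, w, p, d_cell, bc, props, prev = flux)
    imb <- continuity_imbalance(sm, flux, s_mass)
    raw_res["continuity"] <- sum(abs(imb[sm$fluid]))

    pc <- pressure_correction(sm, d_cell, imb, rho, pc_cache)
    p <- p + settings$relax_p * pc$pp
    u <- u - d_cell * cell_gradient(sm, pc$pp, 1)
    v <- v - d_cell * cell_gradient(sm, pc$pp, 2)
    w <- w - d_cell * cell_gradient(sm, pc$pp, 3)
    u[solid] <- 0; v[solid] <- 0; w[solid] <- 0
    flux <- pc$correct_flux(flux)

    # ---- turbulence ----
    Gk <- production_Gk(u, v, w, mu_t, sm)
    co <- scalar_coeffs(sm, flux, mu_eff / constants$sigma_k,
                        inflow_value = list(inlet = inl$k, outlet = 0))
    co$b <- co$b + vol * Gk
    co$aP <- co$aP + vol * rho * te / pmax(tk, k_floor)
    co$b <- co$b + (1 - a_sc) / a_sc * co$aP * tk
    co$aP <- co$aP / a_sc
    co <- fix_cells(co, solid, k_floor)
    raw_res["k"] <- coeffs_residual(co, tk, sm$fluid)
    tk <- pmax(jacobi_sweeps(co, tk, settings$sweeps), k_floor)

    co <- scalar_coeffs(sm, flux, mu_eff / constants$sigma_eps,
                        inflow_value = list(inlet = inl$eps, outlet = 0))
    co$b <- co$b + vol * constants$C1 * te / pmax(tk, k_floor) * pmax(Gk, 0)
    co$aP <- co$aP + vol * constants$C2 * rho * te / pmax(tk, k_floor)
    co$b <- co$b + (1 - a_sc) / a_sc * co$aP * te
    co$aP <- co$aP / a_sc
    co <- fix_cells(co, solid, eps_floor)
    # standard wall treatment: near-wall dissipation is a Dirichlet pin,
    # imposed inside the equation so neighbours relax against a fixed value
    eps_w <- pmax(constants$Cmu^0.75 * tk^1.5 / (constants$kappa * y_wall),
                  eps_floor)
    co <- fix_cells(co, wall_any, eps_w)
    raw_res["eps"] <- coeffs_residual(co, te, sm$fluid & !wall_any)
    te <- pmax(jacobi_sweeps(co, te, settings$sweeps), eps_floor)

    # ---- energy ----
    GamT <- props$mu / constants$sigma_T + mu_t / constants$sigma_tT
    co <- scalar_coeffs(sm, flux, GamT,
                        inflow_value = list(inlet = bc$T_in_K,
                                            outlet = bc$T_in_K))
    cr <- cond_robin(GamT)
    co$aP <- co$aP + cr
    co$b <- co$b + cr * bc$T_ext_K
    if (!is.null(source)) {
      co$b[src_cell[1], src_cell[2], src_cell[3]] <-
        co$b[src_cell[1], src_cell[2], src_cell[3]] + source$mass * source$T_src_K
    }
    co$b <- co$b + (1 - a_sc) / a_sc * co$aP * Tk
    co$aP <- co$aP / a_sc
    co <- fix_cells(co, solid, bc$T_in_K)
    raw_res["T"] <- coeffs_residual(co, Tk, sm$fluid)
    Tk <- jacobi_sweeps(co, Tk, settings$sweeps)

    # ---- residual bookkeeping ----
    if (it <= 5) {
      ref_res <- pmax(ref_res, raw_res, na.rm = TRUE)
    }
    norm_res <- raw_res / pmax(ref_res, 1e-300)
    norm_res[raw_res < 1e-8 * abs_scale] <- 0
    hist[[it]] <- norm_res
    if (any(!is.finite(norm_res))) {
      abort_with_history("solver diverged (non-finite residual)", hist, it)
    }
    if (it > 20 && any(norm_res > 1e4)) {
      abort_with_history("solver diverged (residual growth)", hist, it)
    }
    if (verbose && it %% 50 == 0) {
      message(sprintf("iter %4d  %s", it,
                      paste(sprintf("%s=%.2e", names(norm_res), norm_res),
                            collapse = " ")))
    }
    if (it > 5 && all(norm_res < settings$tol)) {
      converged <- TRUE
      break
    }
  }

  iterations <- if (converged) it else settings$max_iter
  res_hist <- residual_history(hist, iterations)

  structure(
    list(
      mesh = mesh, u = u, v = v, w = w, p = p, T_K = Tk, k = tk, eps = te,
      flux = flux, s_mass = s_mass, mu_t_last = rho * constants$Cmu * tk^2 / pmax(te, eps_floor),
      converged = converged, iterations = iterations, residuals = res_hist,
      source = source, bc = bc, settings = settings, constants = constants,
      props = props, Y = NULL, c_disp = NULL
    ),
    class = "field_state"
  )
}

abort_with_history <- function(msg, hist, it) {
  h <- residual_history(hist, it)
  rlang::abort(msg, class = "surgsmoke_solver_fault", history = h)
}

residual_history <- function(hist, iterations) {
  hist <- hist[seq_len(iterations)]
  hist <- hist[!vapply(hist, is.null, logical(1))]
  purrr::imap_dfr(hist, function(r, i) {
    tibble::tibble(iteration = i, equation = names(r), residual = unname(r))
  })
}

# Exact sparse solve of the SIMPLEC pressure-correction equation.
#
# The conductance field (and its Cholesky factor) is frozen and only rebuilt
# every `rebuild_every` outer iterations: the coupling coefficients drift
# slowly with the momentum diagonal, and any conductance field paired with
# ITS OWN exact solve still annihilates the continuity imbalance identically
# (the correction is `imb_new = imb + A p' = 0` whatever A was used to build
# both the matrix and the flux correction), so staleness only affects the
# convergence path, never the corrected fluxes' conservation.
pressure_correction <- function(sm, d_cell, imb, rho, cache,
                                rebuild_every = 25L) {
  n <- sm$n
  mesh <- sm$mesh
  cache$count <- (cache$count %||% 0L) + 1L
  if (is.null(cache$cf) || (cache$count - 1L) %% rebuild_every == 0L) {
    i1 <- seq_len(n[1] - 1); j1 <- seq_len(n[2] - 1); k1 <- seq_len(n[3] - 1)
    cfx <- array(0, n + c(1, 0, 0))
    cfx[i1 + 1, , ] <- rho * sm$Ax *
      0.5 * (d_cell[i1, , , drop = FALSE] + d_cell[i1 + 1, , , drop = FALSE]) /
      mesh$d[1] * sm$open_fx[i1 + 1, , , drop = FALSE]
    cfy <- array(0, n + c(0, 1, 0))
    cfy[, j1 + 1, ] <- rho * sm$Ay *
      0.5 * (d_cell[, j1, , drop = FALSE] + d_cell[, j1 + 1, , drop = FALSE]) /
      mesh$d[2] * sm$open_fy[, j1 + 1, , drop = FALSE]
    cfz <- array(0, n + c(0, 0, 1))
    cfz[, , k1 + 1] <- rho * sm$Az *
      0.5 * (d_cell[, , k1, drop = FALSE] + d_cell[, , k1 + 1, drop = FALSE]) /
      mesh$d[3] * sm$open_fz[, , k1 + 1, drop = FALSE]
    # outlet faces: Dirichlet p' = 0 at the face, half-cell distance
    cout0 <- rho * sm$Ay * d_cell[, 1, ] / (mesh$d[2] / 2) * sm$outlet_ymin
    cout1 <- rho * sm$Ay * d_cell[, n[2], ] / (mesh$d[2] / 2) * sm$outlet_ymax

    co <- new_coeffs(n)
    co$a_xm[-1, , ] <- cfx[i1 + 1, , ]
    co$a_xp[-n[1], , ] <- cfx[i1 + 1, , ]
    co$a_ym[, -1, ] <- cfy[, j1 + 1, ]
    co$a_yp[, -n[2], ] <- cfy[, j1 + 1, ]
    co$a_zm[, , -1] <- cfz[, , k1 + 1]
    co$a_zp[, , -n[3]] <- cfz[, , k1 + 1]
    co$aP <- co$a_xm + co$a_xp + co$a_ym + co$a_yp + co$a_zm + co$a_zp
    co$aP[, 1, ] <- co$aP[, 1, ] + cout0
    co$aP[, n[2], ] <- co$aP[, n[2], ] + cout1
    co <- fix_cells(co, sm$mesh$solid, 0)
    iso <- co$aP <= 0
    if (any(iso)) co$aP[iso] <- 1

    idx <- array(seq_len(prod(n)), n)
    ii <- c(idx, idx[-1, , ], idx[, -1, ], idx[, , -1])
    jj <- c(idx, idx[-n[1], , ], idx[, -n[2], ], idx[, , -n[3]])
    vv <- c(co$aP, -co$a_xm[-1, , ], -co$a_ym[, -1, ], -co$a_zm[, , -1])
    A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = rep(prod(n), 2),
                              symmetric = TRUE)
    if (is.null(cache$chol)) {
      cache$chol <- Matrix::Cholesky(A, LDL = FALSE)
    } else {
      cache$chol <- Matrix::update(cache$chol, A)
    }
    cache$cf <- list(cfx = cfx, cfy = cfy, cfz = cfz, cout0 = cout0,
                     cout1 = cout1, iso = iso)
  }
  cf <- cache$cf
  rhs <- -imb
  rhs[sm$mesh$solid] <- 0
  rhs[cf$iso] <- 0
  pp <- array(as.numeric(Matrix::solve(cache$chol, as.vector(rhs))), n)

  correct_flux <- function(flux) {
    i1 <- seq_len(n[1] - 1); j1 <- seq_len(n[2] - 1); k1 <- seq_len(n[3] - 1)
    flux$fx[i1 + 1, , ] <- flux$fx[i1 + 1, , ] +
      cf$cfx[i1 + 1, , ] * (pp[i1, , ] - pp[i1 + 1, , ])
    flux$fy[, j1 + 1, ] <- flux$fy[, j1 + 1, ] +
      cf$cfy[, j1 + 1, ] * (pp[, j1, ] - pp[, j1 + 1, ])
    flux$fz[, , k1 + 1] <- flux$fz[, , k1 + 1] +
      cf$cfz[, , k1 + 1] * (pp[, , k1] - pp[, , k1 + 1])
    flux$fy[, 1, ] <- flux$fy[, 1, ] - cf$cout0 * pp[, 1, ]
    flux$fy[, n[2] + 1, ] <- flux$fy[, n[2] + 1, ] + cf$cout1 * pp[, n[2], ]
    flux
  }
  list(pp = pp, correct_flux = correct_flux)
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("<field_state> %d x %d x %d cells, %s after %d iterations\n",
              x$mesh$n[1], x$mesh$n[2], x$mesh$n[3],
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat(sprintf("  |w| max %.3g m/s, T range %.4g..%.4g K\n",
              max(abs(x$w)), min(x$T_K[!x$mesh$solid]), max(x$T_K)))
  if (!is.null(x$source)) {
    cat(sprintf("  source: %g degC at cell (%d, %d, %d)\n",
                x$source$T_src_K - 273.15,
                x$source$cell[1], x$source$cell[2], x$source$cell[3]))
  }
  invisible(x)
}
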