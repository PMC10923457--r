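# Finite-volume core on a uniform structured grid, collocated arrangement.
#
# Conventions:
#  * cell arrays have dim (nx, ny, nz)
#  * face arrays: fx (nx+1, ny, nz), fy (nx, ny+1, nz), fz (nx, ny, nz+1);
#    fx[i,,] is the face between cells i-1 and i, positive flux points +x
#  * a coefficient set `co` holds aP, a<dir>, b with the 7-point stencil
#    a_xm..a_zp naming the neighbour the coefficient multiplies; fixed cells
#    (solid) carry aP = 1, b = value, zero neighbour links.

# neighbour-value lookup: nb_xm(a)[i,j,k] = a[i-1,j,k], zero-padded
nb_xm <- function(a) { o <- array(0, dim(a)); o[-1, , ] <- a[-dim(a)[1], , ]; o }
nb_xp <- function(a) { o <- array(0, dim(a)); o[-dim(a)[1], , ] <- a[-1, , ]; o }
nb_ym <- function(a) { o <- array(0, dim(a)); o[, -1, ] <- a[, -dim(a)[2], ]; o }
nb_yp <- function(a) { o <- array(0, dim(a)); o[, -dim(a)[2], ] <- a[, -1, ]; o }
nb_zm <- function(a) { o <- array(0, dim(a)); o[, , -1] <- a[, , -dim(a)[3]]; o }
nb_zp <- function(a) { o <- array(0, dim(a)); o[, , -dim(a)[3]] <- a[, , -1]; o }

new_coeffs <- function(n) {
  z <- array(0, n)
  list(aP = z, a_xm = z, a_xp = z, a_ym = z, a_yp = z, a_zm = z, a_zp = z,
       b = z)
}

# Geometry/topology cache used by every equation: open internal faces
# (fluid-fluid), per-cell wall areas by face orientation, boundary masks.
solver_mesh <- function(mesh) {
  n <- mesh$n
  fluid <- !mesh$solid
  open_fx <- array(FALSE, n + c(1, 0, 0))
  open_fx[2:n[1], , ] <- fluid[-n[1], , ] & fluid[-1, , ]
  open_fy <- array(FALSE, n + c(0, 1, 0))
  open_fy[, 2:n[2], ] <- fluid[, -n[2], ] & fluid[, -1, ]
  open_fz <- array(FALSE, n + c(0, 0, 1))
  open_fz[, , 2:n[3]] <- fluid[, , -n[3]] & fluid[, , -1]

  # wall faces bounding each fluid cell, by orientation (domain boundary
  # faces that are not inlet/outlet, plus faces onto solid cells)
  blocked_x <- !open_fx; blocked_y <- !open_fy; blocked_z <- !open_fz
  # remove inlet (top plane) and outlets (y planes) from the wall count
  outlet_ymin <- array(FALSE, n + c(0, 1, 0))
  outlet_ymin[, 1, ] <- mesh$outlet_ymin_mask
  outlet_ymax <- array(FALSE, n + c(0, 1, 0))
  outlet_ymax[, n[2] + 1, ] <- mesh$outlet_ymax_mask
  inlet_z <- array(FALSE, n + c(0, 0, 1))
  inlet_z[, , n[3] + 1] <- mesh$inlet_mask

  wall_x <- blocked_x
  wall_y <- blocked_y & !outlet_ymin & !outlet_ymax
  wall_z <- blocked_z & !inlet_z

  count_x <- wall_x[-(n[1] + 1), , ] + wall_x[-1, , ]
  count_y <- wall_y[, -(n[2] + 1), ] + wall_y[, -1, ]
  count_z <- wall_z[, , -(n[3] + 1)] + wall_z[, , -1]

  Ax <- mesh$d[2] * mesh$d[3]; Ay <- mesh$d[1] * mesh$d[3]
  Az <- mesh$d[1] * mesh$d[2]

  # side-wall faces carrying the Robin heat condition: the four vertical
  # domain walls minus the outlet openings (table & ceiling/floor adiabatic)
  robin_x <- array(0, n)
  robin_x[1, , ] <- robin_x[1, , ] + 1
  robin_x[n[1], , ] <- robin_x[n[1], , ] + 1
  robin_y <- array(0, n)
  robin_y[, 1, ] <- robin_y[, 1, ] + !mesh$outlet_ymin_mask
  robin_y[, n[2], ] <- robin_y[, n[2], ] + !mesh$outlet_ymax_mask

  list(
    mesh = mesh, n = n, fluid = fluid,
    open_fx = open_fx, open_fy = open_fy, open_fz = open_fz,
    wallA_x = count_x * Ax, wallA_y = count_y * Ay, wallA_z = count_z * Az,
    robinA_x = robin_x * Ax, robinA_y = robin_y * Ay,
    Ax = Ax, Ay = Ay, Az = Az,
    outlet_ymin = mesh$outlet_ymin_mask, outlet_ymax = mesh$outlet_ymax_mask,
    inlet_mask = mesh$inlet_mask
  )
}

# Upwind convection + central diffusion coefficients for a conserved scalar.
#
# flux:  list(fx, fy, fz) of face mass (or volume) fluxes; fluxes across
#        closed faces must be zero except at the inlet plane (fz top) and the
#        outlet strips (fy planes), which are domain in/outflows.
# Gamma: cell-centred diffusion coefficient (units of flux per length);
#        arithmetic face mean; zero across closed faces.
# inflow_value: scalar or list of per-plane boundary values carried by
#        inflowing boundary fluxes (inlet plane value `inlet`, outlet
#        backflow value `outlet`).
scalar_coeffs <- function(sm, flux, Gamma, inflow_value = list(inlet = 0, outlet = 0)) {
  n <- sm$n
  mesh <- sm$mesh
  co <- new_coeffs(n)
  if (length(Gamma) == 1) Gamma <- array(Gamma, n)

  Dx <- sm$Ax / mesh$d[1]; Dy <- sm$Ay / mesh$d[2]; Dz <- sm$Az / mesh$d[3]

  # --- internal x faces ---
  Gf <- 0.5 * (Gamma[-n[1], , ] + Gamma[-1, , ]) * Dx
  open <- sm$open_fx[2:n[1], , , drop = FALSE]
  Gf <- Gf * open
  Fi <- flux$fx[2:n[1], , , drop = FALSE] * open
  # face between W = (1:nx-1) and E = (2:nx); F > 0 leaves W, enters E
  co$a_xp[-n[1], , ] <- co$a_xp[-n[1], , ] + Gf + pmax(-Fi, 0)  # W's east nb
  co$aP[-n[1], , ]   <- co$aP[-n[1], , ]   + Gf + pmax(Fi, 0)
  co$a_xm[-1, , ]    <- co$a_xm[-1, , ]    + Gf + pmax(Fi, 0)   # E's west nb
  co$aP[-1, , ]      <- co$aP[-1, , ]      + Gf + pmax(-Fi, 0)

  # --- internal y faces ---
  Gf <- 0.5 * (Gamma[, -n[2], ] + Gamma[, -1, ]) * Dy
  open <- sm$open_fy[, 2:n[2], , drop = FALSE]
  Gf <- Gf * open
  Fi <- flux$fy[, 2:n[2], , drop = FALSE] * open
  co$a_yp[, -n[2], ] <- co$a_yp[, -n[2], ] + Gf + pmax(-Fi, 0)
  co$aP[, -n[2], ]   <- co$aP[, -n[2], ]   + Gf + pmax(Fi, 0)
  co$a_ym[, -1, ]    <- co$a_ym[, -1, ]    + Gf + pmax(Fi, 0)
  co$aP[, -1, ]      <- co$aP[, -1, ]      + Gf + pmax(-Fi, 0)

  # --- internal z faces ---
  Gf <- 0.5 * (Gamma[, , -n[3]] + Gamma[, , -1]) * Dz
  open <- sm$open_fz[, , 2:n[3], drop = FALSE]
  Gf <- Gf * open
  Fi <- flux$fz[, , 2:n[3], drop = FALSE] * open
  co$a_zp[, , -n[3]] <- co$a_zp[, , -n[3]] + Gf + pmax(-Fi, 0)
  co$aP[, , -n[3]]   <- co$aP[, , -n[3]]   + Gf + pmax(Fi, 0)
  co$a_zm[, , -1]    <- co$a_zm[, , -1]    + Gf + pmax(Fi, 0)
  co$aP[, , -1]      <- co$aP[, , -1]      + Gf + pmax(-Fi, 0)

  # --- boundary in/outflow: inlet plane (top z faces) ---
  Ftop <- flux$fz[, , n[3] + 1]            # positive = leaving through top
  co$aP[, , n[3]] <- co$aP[, , n[3]] + pmax(Ftop, 0)
  co$b[, , n[3]] <- co$b[, , n[3]] + pmax(-Ftop, 0) * inflow_value$inlet

  # --- boundary in/outflow: outlet strips on the y walls ---
  Fy0 <- flux$fy[, 1, ]                    # positive = entering through y=0
  co$aP[, 1, ] <- co$aP[, 1, ] + pmax(-Fy0, 0)
  co$b[, 1, ] <- co$b[, 1, ] + pmax(Fy0, 0) * inflow_value$outlet
  Fy1 <- flux$fy[, n[2] + 1, ]             # positive = leaving through y=Ly
  co$aP[, n[2], ] <- co$aP[, n[2], ] + pmax(Fy1, 0)
  co$b[, n[2], ] <- co$b[, n[2], ] + pmax(-Fy1, 0) * inflow_value$outlet

  # also honour any boundary flux on the x planes / bottom plane (normally 0)
  Fx0 <- flux$fx[1, , ]
  co$aP[1, , ] <- co$aP[1, , ] + pmax(-Fx0, 0)
  Fx1 <- flux$fx[n[1] + 1, , ]
  co$aP[n[1], , ] <- co$aP[n[1], , ] + pmax(Fx1, 0)
  Fz0 <- flux$fz[, , 1]
  co$aP[, , 1] <- co$aP[, , 1] + pmax(-Fz0, 0)

  co
}

# pin solid (and otherwise fixed) cells to a value (scalar or array)
fix_cells <- function(co, mask, value = 0) {
  if (!any(mask)) return(co)
  for (nm in c("a_xm", "a_xp", "a_ym", "a_yp", "a_zm", "a_zp")) co[[nm]][mask] <- 0
  co$aP[mask] <- 1
  co$b[mask] <- if (length(value) > 1) value[mask] else value
  co
}

coeffs_apply <- function(co, phi) {
  co$a_xm * nb_xm(phi) + co$a_xp * nb_xp(phi) +
    co$a_ym * nb_ym(phi) + co$a_yp * nb_yp(phi) +
    co$a_zm * nb_zm(phi) + co$a_zp * nb_zp(phi)
}

# L1 residual of the current iterate over non-fixed cells
coeffs_residual <- function(co, phi, mask = NULL) {
  r <- abs(co$aP * phi - coeffs_apply(co, phi) - co$b)
  if (!is.null(mask)) r <- r[mask]
  sum(r)
}

# damped Jacobi sweeps (the equations carry implicit under-relaxation in aP,
# so plain Jacobi is stable and cheap)
jacobi_sweeps <- function(co, phi, sweeps = 4) {
  for (s in seq_len(sweeps)) {
    phi <- (co$b + coeffs_apply(co, phi)) / co$aP
  }
  phi
}

# exact solve of the 7-point system via a sparse LU (used for the steady
# passive scalars, where one direct solve replaces an outer iteration)
direct_solve <- function(co, n) {
  idx <- array(seq_len(prod(n)), n)
  ii <- c(idx, idx[-1, , ], idx[-n[1], , ], idx[, -1, ], idx[, -n[2], ],
          idx[, , -1], idx[, , -n[3]])
  jj <- c(idx, idx[-n[1], , ], idx[-1, , ], idx[, -n[2], ], idx[, -1, ],
          idx[, , -n[3]], idx[, , -1])
  vv <- c(co$aP,
          -co$a_xm[-1, , ], -co$a_xp[-n[1], , ],
          -co$a_ym[, -1, ], -co$a_yp[, -n[2], ],
          -co$a_zm[, , -1], -co$a_zp[, , -n[3]])
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = rep(prod(n), 2))
  sol <- Matrix::solve(A, as.vector(co$b))
  array(as.numeric(sol), n)
}

# central-difference cell gradient with one-sided differences at boundaries
# and across closed faces (gradient of pressure for the momentum source)
cell_gradient <- function(sm, phi, axis) {
  n <- sm$n
  d <- sm$mesh$d[axis]
  if (axis == 1) {
    open_lo <- sm$open_fx[1:n[1], , , drop = FALSE]
    open_hi <- sm$open_fx[2:(n[1] + 1), , , drop = FALSE]
    lo <- nb_xm(phi); hi <- nb_xp(phi)
  } else if (axis == 2) {
    open_lo <- sm$open_fy[, 1:n[2], , drop = FALSE]
    open_hi <- sm$open_fy[, 2:(n[2] + 1), , drop = FALSE]
    lo <- nb_ym(phi); hi <- nb_yp(phi)
  } else {
    open_lo <- sm$open_fz[, , 1:n[3], drop = FALSE]
    open_hi <- sm$open_fz[, , 2:(n[3] + 1), drop = FALSE]
    lo <- nb_zm(phi); hi <- nb_zp(phi)
  }
  lo <- ifelse(open_lo, lo, phi)
  hi <- ifelse(open_hi, hi, phi)
  span <- (open_lo + open_hi) * d
  out <- (hi - lo) / pmax(span, d / 2)
  out[span == 0] <- 0
  out
}
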