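#' Dispersed-phase material specification
#'
#' Condensed tar droplets and non-viable particles are modelled as
#' monodisperse spheres of 2 micron diameter. Material densities default to
#' 1000 kg/m^3 (tar) and 1200 kg/m^3 (particles); both are configurable
#' assumptions, as the measured property table was not published.
#'
#' @param diameter particle diameter (m), `> 0`.
#' @param rho_tar,rho_particle material densities (kg/m^3), `> 0`.
#' @return list with the phase properties.
#' @export
dispersed_phase_spec <- function(diameter = 2e-6, rho_tar = 1000,
                                 rho_particle = 1200) {
  stopifnot(diameter > 0, rho_tar > 0, rho_particle > 0)
  list(diameter = diameter, rho_tar = rho_tar, rho_particle = rho_particle)
}

#' One drag-law step of a parcel
#'
#' Integrates the particle momentum equation with Schiller-Naumann drag,
#' \deqn{du_p/dt = \frac{18\mu}{\rho_p d_p^2}\,(1 + 0.15\,Re_p^{0.687})\,(u - u_p),}
#' over a step `dt` using the exact exponential update of the linearised
#' equation: with the drag rate frozen at the step's start,
#' `u_p(t+dt) = u + (u_p - u) exp(-dt/tau_eff)` where
#' `tau_eff = rho_p d_p^2 / (18 mu (1 + 0.15 Re_p^0.687))`, and the position
#' advances by the exact integral of that velocity. The particle Reynolds
#' number `Re_p = rho d_p |u - u_p| / mu` is recomputed every step. The
#' update is unconditionally stable: for `dt >> tau` the parcel relaxes
#' exactly onto the local gas velocity. No gravity term is included by
#' default (the settling speed of a 2 micron particle is ~0.1 mm/s,
#' negligible against the room flow); `gravity = TRUE` adds it.
#'
#' @param position,velocity numeric(3), parcel state (m, m/s).
#' @param u_fluid numeric(3), local gas velocity (m/s).
#' @param dt time step (s), `> 0`.
#' @param rho_p particle material density (kg/m^3).
#' @param d_p particle diameter (m).
#' @param props [air_properties()].
#' @param gravity include gravitational acceleration.
#' @return list `position`, `velocity` after the step.
#' @examples
#' parcel_step(c(0, 0, 1), c(0, 0, 0), u_fluid = c(0.1, 0, 0), dt = 1e-3)
#' @export
parcel_step <- function(position, velocity, u_fluid, dt, rho_p = 1000,
                        d_p = 2e-6, props = air_properties(),
                        gravity = FALSE) {
  if (!is.numeric(dt) || dt <= 0) abort("`dt` must be positive")
  tau0 <- rho_p * d_p^2 / (18 * props$mu)
  rel <- velocity - u_fluid
  Re_p <- props$rho_ref * d_p * sqrt(sum(rel^2)) / props$mu
  corr <- 1 + 0.15 * Re_p^0.687
  tau <- tau0 / corr
  # with gravity the equilibrium (terminal) state is offset by g * tau
  u_eq <- u_fluid
  if (gravity) u_eq <- u_eq + c(0, 0, -props$g * tau)
  decay <- exp(-dt / tau)
  vel_new <- u_eq + (velocity - u_eq) * decay
  pos_new <- position + u_eq * dt + (velocity - u_eq) * tau * (1 - decay)
  list(position = pos_new, velocity = vel_new)
}

# trilinear interpolation of a cell-centred field at a point (clamped to the
# cell-centre lattice at the boundaries)
interp_trilinear <- function(mesh, arr, pt) {
  n <- mesh$n
  frac_idx <- function(x, centers, d) {
    f <- (x - centers[1]) / d
    min(max(f, 0), length(centers) - 1)
  }
  fx <- frac_idx(pt[1], mesh$xc, mesh$d[1])
  fy <- frac_idx(pt[2], mesh$yc, mesh$d[2])
  fz <- frac_idx(pt[3], mesh$zc, mesh$d[3])
  i0 <- floor(fx) + 1; j0 <- floor(fy) + 1; k0 <- floor(fz) + 1
  i1 <- min(i0 + 1, n[1]); j1 <- min(j0 + 1, n[2]); k1 <- min(k0 + 1, n[3])
  tx <- fx - (i0 - 1); ty <- fy - (j0 - 1); tz <- fz - (k0 - 1)
  c00 <- arr[i0, j0, k0] * (1 - tx) + arr[i1, j0, k0] * tx
  c10 <- arr[i0, j1, k0] * (1 - tx) + arr[i1, j1, k0] * tx
  c01 <- arr[i0, j0, k1] * (1 - tx) + arr[i1, j0, k1] * tx
  c11 <- arr[i0, j1, k1] * (1 - tx) + arr[i1, j1, k1] * tx
  c0 <- c00 * (1 - ty) + c10 * ty
  c1 <- c01 * (1 - ty) + c11 * ty
  c0 * (1 - tz) + c1 * tz
}

#' Track parcels through a converged flow field
#'
#' Injects `n_parcels` parcels uniformly within the incision cell at the gas
#' velocity there, then steps each with [parcel_step()] (time step = half
#' the local cell-crossing time; the exponential drag update is exact
#' through many relaxation times, so the crossing time is the binding
#' scale). Gas velocity is trilinearly interpolated. A parcel that crosses
#' an outlet strip exits; one that reaches any other boundary or the table
#' deposits; the rest are aloft at `t_max`.
#'
#' @param field a converged `field_state`.
#' @param phase `"tar"` or `"particle"`.
#' @param spec [dispersed_phase_spec()].
#' @param n_parcels number of parcels.
#' @param seed RNG seed (injection positions).
#' @param t_max tracking horizon (s).
#' @param gravity include settling, see [parcel_step()].
#' @param keep_trajectories record positions every `save_every` steps.
#' @param save_every trajectory subsampling stride.
#' @return list: `fates` tibble (`parcel`, `fate`, `time`, `x`, `y`, `z`),
#'   summary counts in `attr(, "summary")`, and if requested `trajectories`
#'   (`parcel`, `t`, `x`, `y`, `z`).
#' @export
track_parcels <- function(field, phase = c("tar", "particle"),
                          spec = dispersed_phase_spec(), n_parcels = 100,
                          seed = 1L, t_max = 300, gravity = FALSE,
                          keep_trajectories = FALSE, save_every = 10L) {
  check_converged(field)
  phase <- match.arg(phase)
  mesh <- field$mesh
  rho_p <- switch(phase, tar = spec$rho_tar, particle = spec$rho_particle)
  src <- field$source
  if (is.null(src)) abort("field has no smoke source; nothing to inject")
  cc <- src$cell
  lo <- c(mesh$xe[cc[1]], mesh$ye[cc[2]], mesh$ze[cc[3]])

  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  starts <- matrix(runif(3 * n_parcels), ncol = 3) %*% diag(mesh$d) +
    matrix(lo, n_parcels, 3, byrow = TRUE)

  room <- mesh$room
  in_outlet <- function(pt, jside) {
    sc <- mesh$scene
    o <- if (jside == 1) sc$outlets$ymin else sc$outlets$ymax
    pt[1] >= o$x[1] && pt[1] <= o$x[2] && pt[3] >= o$z[1] && pt[3] <= o$z[2]
  }

  fates <- vector("list", n_parcels)
  trajs <- if (keep_trajectories) vector("list", n_parcels)
  for (pidx in seq_len(n_parcels)) {
    pos <- starts[pidx, ]
    ug <- c(interp_trilinear(mesh, field$u, pos),
            interp_trilinear(mesh, field$v, pos),
            interp_trilinear(mesh, field$w, pos))
    vel <- ug
    t_now <- 0
    fate <- "aloft"
    step_i <- 0L
    rec <- if (keep_trajectories) list(c(0, pos))
    while (t_now < t_max) {
      ug <- c(interp_trilinear(mesh, field$u, pos),
              interp_trilinear(mesh, field$v, pos),
              interp_trilinear(mesh, field$w, pos))
      speed <- sqrt(sum(ug^2)) + sqrt(sum((vel - ug)^2)) + 1e-6
      dt <- min(min(mesh$d) / (2 * speed), t_max - t_now)
      st <- parcel_step(pos, vel, ug, dt, rho_p = rho_p, d_p = spec$diameter,
                        props = field$props, gravity = gravity)
      pos <- st$position; vel <- st$velocity
      t_now <- t_now + dt
      step_i <- step_i + 1L
      if (keep_trajectories && step_i %% save_every == 0L) {
        rec[[length(rec) + 1]] <- c(t_now, pos)
      }
      # boundary and table checks
      if (pos[2] <= 0 || pos[2] >= room[2]) {
        jside <- if (pos[2] <= 0) 1 else 2
        fate <- if (in_outlet(pos, jside)) "exited" else "deposited"
        break
      }
      if (pos[1] <= 0 || pos[1] >= room[1] || pos[3] <= 0 || pos[3] >= room[3]) {
        fate <- "deposited"
        break
      }
      tb <- mesh$scene$table
      if (pos[1] >= tb$x[1] && pos[1] <= tb$x[2] &&
          pos[2] >= tb$y[1] && pos[2] <= tb$y[2] && pos[3] <= tb$z[2]) {
        fate <- "deposited"
        break
      }
    }
    fates[[pidx]] <- tibble::tibble(parcel = pidx, fate = fate, time = t_now,
                                    x = pos[1], y = pos[2], z = pos[3])
    if (keep_trajectories) {
      m <- do.call(rbind, rec)
      trajs[[pidx]] <- tibble::tibble(parcel = pidx, t = m[, 1], x = m[, 2],
                                      y = m[, 3], z = m[, 4])
    }
  }
  fates <- dplyr::bind_rows(fates)
  out <- list(fates = fates,
              summary = dplyr::count(fates, .data$fate, name = "parcels"))
  if (keep_trajectories) out$trajectories <- dplyr::bind_rows(trajs)
  out
}

#' Bin parcel end-of-life or pass-through positions onto the mesh
#'
#' Counts, for each fluid cell, the time parcels spent in it (residence-time
#' binning of trajectories), as a qualitative Lagrangian counterpart of the
#' Eulerian concentration field.
#'
#' @param trajectories tibble from [track_parcels()] with
#'   `keep_trajectories = TRUE`.
#' @param mesh the mesh.
#' @return array of visit counts per cell.
#' @export
bin_parcels <- function(trajectories, mesh) {
  counts <- array(0, mesh$n)
  idx <- cbind(pmin(pmax(floor(trajectories$x / mesh$d[1]), 0), mesh$n[1] - 1),
               pmin(pmax(floor(trajectories$y / mesh$d[2]), 0), mesh$n[2] - 1),
               pmin(pmax(floor(trajectories$z / mesh$d[3]), 0), mesh$n[3] - 1)) + 1
  for (r in seq_len(nrow(idx))) {
    counts[idx[r, 1], idx[r, 2], idx[r, 3]] <-
      counts[idx[r, 1], idx[r, 2], idx[r, 3]] + 1
  }
  counts
}
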