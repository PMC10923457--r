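# Transport-scheme oracles: the upwind/central finite-volume machinery is
# checked against closed-form solutions on quasi-1-D configurations before it
# is trusted inside the coupled solver.

# a minimal open-box pseudo-mesh (no table, no labelled patches) for driving
# the scalar machinery directly
pseudo_mesh <- function(n, L) {
  d <- L / n
  list(
    n = n, d = d, room = L, vol = prod(d),
    xc = (seq_len(n[1]) - 0.5) * d[1],
    yc = (seq_len(n[2]) - 0.5) * d[2],
    zc = (seq_len(n[3]) - 0.5) * d[3],
    solid = array(FALSE, n),
    inlet_mask = matrix(FALSE, n[1], n[2]),
    outlet_ymin_mask = matrix(FALSE, n[1], n[3]),
    outlet_ymax_mask = matrix(FALSE, n[1], n[3]),
    scene = NULL
  )
}

test_that("steady 1-D advection-diffusion matches the exponential closed form", {
  n <- c(200, 3, 3)
  L <- c(1, 0.3, 0.3)
  mesh <- pseudo_mesh(n, L)
  sm <- surgsmoke:::solver_mesh(mesh)
  Gam <- 0.01            # diffusion coefficient (flux units per length)
  Pe <- 4                # global Peclet number u L / D
  A <- mesh$d[2] * mesh$d[3]
  Fface <- Pe * Gam * A / L[1]   # uniform mass flux through every x face

  flux <- list(fx = array(Fface, n + c(1, 0, 0)),
               fy = array(0, n + c(0, 1, 0)),
               fz = array(0, n + c(0, 0, 1)))
  co <- surgsmoke:::scalar_coeffs(sm, flux, Gam)
  # Dirichlet ends via half-cell diffusive links: phi(0) = 0, phi(L) = 1
  Dbc <- Gam * A / (mesh$d[1] / 2)
  co$aP[1, , ] <- co$aP[1, , ] + Dbc          # value 0: no b contribution
  co$aP[n[1], , ] <- co$aP[n[1], , ] + Dbc
  co$b[n[1], , ] <- co$b[n[1], , ] + Dbc * 1
  phi <- surgsmoke:::direct_solve(co, n)

  x <- mesh$xc
  analytic <- (exp(Pe * x / L[1]) - 1) / (exp(Pe) - 1)
  numeric <- phi[, 2, 2]
  l2 <- sqrt(mean((numeric - analytic)^2)) / sqrt(mean(analytic^2))
  expect_lt(l2, 0.01)
  # boundedness of the upwind scheme
  expect_true(all(phi >= -1e-12 & phi <= 1 + 1e-12))
})

test_that("diffusion-only conduction through a Robin wall matches the resistance network", {
  # 1-D slab: Robin exterior on the x = 0 side (coefficient h, exterior T_ext),
  # Dirichlet T1 at x = L; zero flow. The steady profile is linear with the
  # series-resistance flux, and the discrete solution must reproduce it.
  n <- c(50, 3, 3)
  L <- c(1, 0.3, 0.3)
  mesh <- pseudo_mesh(n, L)
  sm <- surgsmoke:::solver_mesh(mesh)
  Gam <- 0.02; h_over_cp <- 0.004   # wall conductance per area, T-units
  T_ext <- 303.15; T1 <- 300.15
  A <- mesh$d[2] * mesh$d[3]
  flux <- list(fx = array(0, n + c(1, 0, 0)), fy = array(0, n + c(0, 1, 0)),
               fz = array(0, n + c(0, 0, 1)))
  co <- surgsmoke:::scalar_coeffs(sm, flux, Gam)
  Crob <- A / (1 / h_over_cp + (mesh$d[1] / 2) / Gam)
  co$aP[1, , ] <- co$aP[1, , ] + Crob
  co$b[1, , ] <- co$b[1, , ] + Crob * T_ext
  Dbc <- Gam * A / (mesh$d[1] / 2)
  co$aP[n[1], , ] <- co$aP[n[1], , ] + Dbc
  co$b[n[1], , ] <- co$b[n[1], , ] + Dbc * T1
  Tsol <- surgsmoke:::direct_solve(co, n)

  # closed form: q = (T_ext - T1) / (1/h + L/Gam) per unit area,
  # T(x) = T1 + q * (L - x) / Gam
  q <- (T_ext - T1) / (1 / h_over_cp + L[1] / Gam)
  analytic <- T1 + q * (L[1] - mesh$xc) / Gam
  expect_equal(Tsol[, 2, 2], analytic, tolerance = 1e-10)
  # interior profile is linear
  expect_equal(diff(Tsol[, 2, 2], differences = 2),
               rep(0, n[1] - 2), tolerance = 1e-10)
})

test_that("the unforced isothermal room converges to a species-free downflow at the inlet temperature", {
  mesh <- build_mesh(theatre_scene(), c(16, 12, 10))
  bc <- boundary_conditions(T_ext_C = 27)   # isothermal walls at inlet temp
  fs <- solve_steady(mesh, bc = bc,
                     settings = solver_settings(tol = 1e-3, max_iter = 800))
  expect_true(fs$converged)
  # temperature stays at 27 degC throughout
  expect_equal(max(abs(fs$T_K - (27 + 273.15))), 0, tolerance = 1e-6)
  # downflow under the inlet
  core <- fs$w[7:10, 5:8, 8]
  expect_true(all(core < 0))
  # species transport on the unforced field is identically zero
  fs <- solve_species(fs)
  expect_equal(max(abs(fs$Y$CO)), 0)
  expect_equal(max(abs(fs$Y$CO2)), 0)
  # dispersed concentration with zero injection is zero
  c0 <- concentration_field(fs, "tar")
  expect_equal(max(abs(c0)), 0)
})

test_that("global mass balance closes at convergence", {
  fs <- coarse_case(NULL, resolution = c(16, 12, 10), max_iter = 800)
  aud <- mass_audit(fs)
  expect_lt(aud$imbalance_rel[aud$quantity == "mass"], 1e-3)
})

test_that("a symmetric unforced room yields a mirror-symmetric converged field", {
  fs <- coarse_case(NULL, resolution = c(16, 12, 10), max_iter = 800)
  expect_true(fs$converged)
  flipx <- function(a) a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
  flipy <- function(a) a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
  tol_w <- 0.02 * max(abs(fs$w))
  # w is even under both reflections, u odd under x, v odd under y
  expect_lt(max(abs(fs$w - flipx(fs$w))), tol_w)
  expect_lt(max(abs(fs$w - flipy(fs$w))), tol_w)
  expect_lt(max(abs(fs$u + flipx(fs$u))), 0.02 * max(abs(fs$u)))
  expect_lt(max(abs(fs$v + flipy(fs$v))), 0.02 * max(abs(fs$v)))
  expect_lt(max(abs(fs$T_K - flipx(fs$T_K))),
            0.02 * max(fs$T_K - min(fs$T_K)) + 1e-9)
})

test_that("buoyant plume above a centred source rises and the field stays symmetric", {
  # odd cell counts put the incision exactly at a cell centre, so the
  # discrete problem inherits the scene's mirror symmetry; the source is
  # strengthened (20x the calibrated flow) so the plume is unambiguous at
  # this very coarse grid — this is a solver property check, not a study
  # condition
  mesh <- build_mesh(theatre_scene(), c(15, 11, 9))
  ss <- make_source_spec(500)
  ss$volume_flow <- ss$volume_flow * 20
  src <- assemble_source(ss, mesh)
  fs <- solve_steady(mesh, source = src,
                     settings = solver_settings(tol = 1e-3, max_iter = 1500))
  expect_true(fs$converged)
  cc <- src$cell
  # buoyant upwelling right above the incision, against the down-curtain
  expect_gt(fs$w[cc[1], cc[2], cc[3]], 0)
  flipx <- function(a) a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
  flipy <- function(a) a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
  expect_lt(max(abs(fs$w - flipx(fs$w))), 0.02 * max(abs(fs$w)))
  expect_lt(max(abs(fs$w - flipy(fs$w))), 0.02 * max(abs(fs$w)))
})
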