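test_that("inlet turbulence follows the intensity/length-scale formulas", {
  it <- inlet_turbulence(0.096, 0.037, 0.07 * 2.4)
  expect_equal(it$k, 1.5 * (0.096 * 0.037)^2)
  expect_equal(it$k, 1.8925e-5, tolerance = 1e-4)
  expect_equal(it$eps, 0.09^0.75 * it$k^1.5 / 0.168)
  expect_equal(it$eps, 8.05e-8, tolerance = 1e-3)
  # degenerate inputs rejected: k must be positive at the inlet
  expect_error(inlet_turbulence(0.096, 0, 0.168), "positive")
  expect_error(inlet_turbulence(0.096, 0.037, 0), "positive")
})

test_that("effective viscosity is mu + rho Cmu k^2 / eps with the laminar floor", {
  props <- air_properties()
  # laminar limit
  expect_equal(effective_viscosity(0, 1e-6, props), props$mu)
  # frozen arithmetic case: rho = 1.2, k = 1e-4, eps = 1e-6 -> mu_t = 1.08e-3
  p12 <- air_properties(rho_ref = 1.2)
  expect_equal(effective_viscosity(1e-4, 1e-6, p12) - p12$mu, 1.08e-3)
  # quadratic scaling in k
  mt1 <- effective_viscosity(1e-4, 1e-6, props) - props$mu
  mt2 <- effective_viscosity(2e-4, 1e-6, props) - props$mu
  expect_equal(mt2 / mt1, 4)
  # non-positive dissipation is a solver fault with a location
  expect_error(effective_viscosity(c(1e-4, 1e-4), c(1e-6, 0), props),
               "non-positive dissipation")
})

test_that("shear production vanishes for uniform flow and rigid rotation, and equals mu_t S^2 for simple shear", {
  mesh <- build_mesh(theatre_scene(c(8, 6, 3)), c(16, 12, 10))
  sm <- surgsmoke:::solver_mesh(mesh)
  n <- mesh$n
  Z <- array(rep(mesh$zc, each = n[1] * n[2]), n)
  X <- array(rep(mesh$xc, times = n[2] * n[3]), n)
  Y <- array(rep(rep(mesh$yc, each = n[1]), times = n[3]), n)
  zero <- array(0, n)
  mu_t <- 1e-3
  interior <- array(FALSE, n)
  interior[3:(n[1] - 2), 3:(n[2] - 2), 3:(n[3] - 2)] <- TRUE
  interior <- interior & !mesh$solid &
    !surgsmoke:::nb_xm(mesh$solid) & !surgsmoke:::nb_xp(mesh$solid) &
    !surgsmoke:::nb_ym(mesh$solid) & !surgsmoke:::nb_yp(mesh$solid) &
    !surgsmoke:::nb_zm(mesh$solid) & !surgsmoke:::nb_zp(mesh$solid)

  # uniform flow
  g0 <- production_Gk(array(1, n), array(0.5, n), zero, mu_t, sm)
  expect_equal(max(abs(g0[interior])), 0)
  # simple shear u = S z
  S <- 0.7
  gs <- production_Gk(S * Z, zero, zero, mu_t, sm)
  expect_equal(gs[interior], rep(mu_t * S^2, sum(interior)), tolerance = 1e-10)
  # rigid rotation about z: u = -omega y, v = omega x
  om <- 0.3
  gr <- production_Gk(-om * Y, om * X, zero, mu_t, sm)
  expect_equal(max(abs(gr[interior])), 0, tolerance = 1e-12)
})

test_that("the wall-function branches join continuously near y+ = 11.63", {
  props <- air_properties()
  cst <- turbulence_constants()
  # pick k and y so that y+ is exactly 11.63
  y <- 0.05
  ustar_target <- 11.63 * props$mu / (props$rho_ref * y)
  k_target <- (ustar_target / cst$Cmu^0.25)^2
  below <- wall_treatment(0.3, y, k_target * 0.999, props, cst)
  above <- wall_treatment(0.3, y, k_target * 1.001, props, cst)
  expect_lt(abs(below$tau_w - above$tau_w) / below$tau_w, 0.01)
  # u+ = ln(E y+)/kappa at 11.63 agrees with the linear branch within 1%
  expect_equal(log(cst$E * 11.63) / cst$kappa, 11.63, tolerance = 0.01)
  # zero tangential velocity -> zero shear on both branches
  expect_equal(wall_treatment(0, y, k_target, props, cst)$tau_w, 0)
  expect_equal(wall_treatment(0, y, 0, props, cst)$tau_w, 0)
  # near-wall dissipation pin
  wt <- wall_treatment(0.3, y, 1e-4, props, cst)
  expect_equal(wt$eps_wall, cst$Cmu^0.75 * (1e-4)^1.5 / (cst$kappa * y))
})

test_that("source assembly converts the operating point into consistent cell sources", {
  mesh <- build_mesh(theatre_scene(), c(40, 30, 15))
  props <- air_properties()
  src <- assemble_source(make_source_spec(500), mesh, props)
  # ideal-gas density of the 773 K source gas times the calibrated flow
  rho_773 <- props$rho_ref * props$T_ref_K / 773.15
  expect_equal(src$mass, rho_773 * 5.1532e-5, tolerance = 1e-12)
  expect_equal(sum(src$species), src$mass * sum(default_composition()))
  expect_equal(src$w_inj, 5.1532e-5 / 1e-4)
  expect_equal(src$momentum_w, src$mass * src$w_inj)
  expect_equal(src$tar_rate, 0.07970, tolerance = 1e-10)
  # zero-flow source has all-zero source terms
  ss0 <- make_source_spec(500)
  ss0$volume_flow <- 0
  src0 <- assemble_source(ss0, mesh, props)
  expect_equal(src0$mass, 0)
  expect_equal(src0$momentum_w, 0)
  expect_equal(unname(sum(src0$species)), 0)
  # a source inside the table is refused
  ss_bad <- make_source_spec(500)
  ss_bad$position <- c(4, 3, 0.5)
  expect_error(assemble_source(ss_bad, mesh, props), "solid")
  # half-open convention: the incision point maps to one deterministic cell
  expect_equal(src$cell, as.integer(locate_cell(mesh, c(4, 3, 0.9))))
})
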