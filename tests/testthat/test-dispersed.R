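test_that("the drag integrator reproduces the Stokes relaxation time", {
  props <- air_properties(mu = 1.8e-5)
  tau <- 1000 * (2e-6)^2 / (18 * 1.8e-5)   # 1.235e-5 s
  expect_equal(tau, 1.2346e-5, tolerance = 1e-4)
  # velocity error decays by e per tau in the Stokes (Re -> 0) limit
  u <- c(1e-4, 0, 0)   # tiny slip so Re_p correction is negligible
  st <- parcel_step(c(0, 0, 0), c(0, 0, 0), u, dt = tau, rho_p = 1000,
                    d_p = 2e-6, props = props)
  err0 <- sqrt(sum(u^2))
  err1 <- sqrt(sum((st$velocity - u)^2))
  expect_equal(err1 / err0, exp(-1), tolerance = 0.01)
  # ... and the measured relaxation time matches tau within 1%
  expect_equal(-tau / log(err1 / err0), tau, tolerance = 0.01)
})

test_that("the exponential update is exact and stable through many relaxation times", {
  props <- air_properties(mu = 1.8e-5)
  tau <- 1000 * (2e-6)^2 / (18 * 1.8e-5)
  u <- c(0.3, -0.1, 0.05)
  st <- parcel_step(c(1, 1, 1), c(0, 0, 0), u, dt = 100 * tau,
                    rho_p = 1000, d_p = 2e-6, props = props)
  expect_equal(st$velocity, u, tolerance = 1e-10)
  # equilibrium: a parcel moving with the gas keeps doing so exactly
  st2 <- parcel_step(c(0, 0, 0), u, u, dt = 1)
  expect_equal(st2$velocity, u)
  expect_equal(st2$position, u * 1)
  expect_error(parcel_step(c(0, 0, 0), u, u, dt = 0), "positive")
})

test_that("Schiller-Naumann correction shortens the response time at finite Re", {
  props <- air_properties()
  d_big <- 1e-4  # a larger droplet so Re_p is appreciable
  u <- c(1, 0, 0)
  tau0 <- 1000 * d_big^2 / (18 * props$mu)
  Re <- props$rho_ref * d_big * 1 / props$mu
  corr <- 1 + 0.15 * Re^0.687
  st <- parcel_step(c(0, 0, 0), c(0, 0, 0), u, dt = tau0 / (20 * corr),
                    rho_p = 1000, d_p = d_big, props = props)
  expected <- 1 - exp(-(tau0 / (20 * corr)) / (tau0 / corr))
  expect_equal(st$velocity[1], expected, tolerance = 1e-6)
})

test_that("gravity-enabled settling matches the Stokes terminal velocity within 1%", {
  props <- air_properties(mu = 1.8e-5)
  v_term <- props$g * 1000 * (2e-6)^2 / (18 * 1.8e-5)  # ~1.2e-4 m/s
  st <- parcel_step(c(0, 0, 1), c(0, 0, 0), c(0, 0, 0), dt = 1,
                    rho_p = 1000, d_p = 2e-6, props = props, gravity = TRUE)
  expect_equal(st$velocity[3], -v_term, tolerance = 0.01)
  # without gravity there is no body force: a parcel in still gas stays put
  st0 <- parcel_step(c(0, 0, 1), c(0, 0, 0), c(0, 0, 0), dt = 10,
                     rho_p = 1000, d_p = 2e-6, props = props)
  expect_equal(st0$velocity, c(0, 0, 0))
  expect_equal(st0$position, c(0, 0, 1))
})

make_uniform_field <- function(wval, resolution = c(16, 12, 10)) {
  mesh <- build_mesh(theatre_scene(), resolution)
  n <- mesh$n
  src <- assemble_source(make_source_spec(500), mesh)
  structure(
    list(mesh = mesh, u = array(0, n), v = array(0, n),
         w = array(wval, n), p = array(0, n),
         T_K = array(300.15, n), k = array(1e-6, n), eps = array(1e-6, n),
         converged = TRUE, source = src, props = air_properties(),
         constants = turbulence_constants()),
    class = "field_state")
}

test_that("parcels in a still gas stay at the injection cell", {
  fld <- make_uniform_field(0)
  tr <- track_parcels(fld, "tar", n_parcels = 20, seed = 3, t_max = 5)
  expect_true(all(tr$fates$fate == "aloft"))
  # never moved beyond the injection cell
  cc <- fld$source$cell
  lo <- c(fld$mesh$xe[cc[1]], fld$mesh$ye[cc[2]], fld$mesh$ze[cc[3]])
  expect_true(all(tr$fates$x >= lo[1] & tr$fates$x <= lo[1] + fld$mesh$d[1]))
  expect_true(all(tr$fates$z >= lo[3] & tr$fates$z <= lo[3] + fld$mesh$d[3]))
})

test_that("a uniform downward flow deposits every parcel on the table within the kinematic time", {
  fld <- make_uniform_field(-0.2)
  # the farthest possible fall is from the cell top (z = 1 m) to the floor:
  # 1 / 0.2 = 5 s; parcels over the table deposit much sooner
  tr <- track_parcels(fld, "particle", n_parcels = 30, seed = 8, t_max = 10)
  expect_true(all(tr$fates$fate == "deposited"))
  expect_true(all(tr$fates$time < 6))
  expect_lt(min(tr$fates$time), 1.25)
})

test_that("tracking is reproducible for a fixed seed", {
  fld <- make_uniform_field(-0.05)
  a <- track_parcels(fld, "tar", n_parcels = 15, seed = 42, t_max = 20)
  b <- track_parcels(fld, "tar", n_parcels = 15, seed = 42, t_max = 20)
  expect_identical(a$fates, b$fates)
  c_ <- track_parcels(fld, "tar", n_parcels = 15, seed = 43, t_max = 20)
  expect_false(identical(a$fates, c_$fates))
})

test_that("a non-converged field is refused", {
  fld <- make_uniform_field(0)
  fld$converged <- FALSE
  expect_error(track_parcels(fld, "tar"), "not converged")
  expect_error(concentration_field(fld, "tar"), "not converged")
})

test_that("Eulerian concentration is linear in the injection rate", {
  fs <- coarse_case(NULL, resolution = c(16, 12, 10), max_iter = 800)
  fs$source <- assemble_source(make_source_spec(500), fs$mesh)
  # note: flow solved without the source; linearity of the passive scalar in
  # its own injection rate holds on any fixed carrier field
  c1 <- concentration_field(fs, "tar", injection_rate = 0.05)
  c2 <- concentration_field(fs, "tar", injection_rate = 0.10)
  expect_equal(c2, 2 * c1, tolerance = 1e-10)
  expect_true(all(c1 >= -1e-12))
})

test_that("Lagrangian residence binning agrees with the Eulerian field on the hot-case plume", {
  fs <- coarse_case(500)
  ct <- concentration_field(fs, "tar")
  tr <- track_parcels(fs, "tar", n_parcels = 60, seed = 5, t_max = 120,
                      keep_trajectories = TRUE, save_every = 3L)
  counts <- bin_parcels(tr$trajectories, fs$mesh)
  # the two descriptions must agree on where the smoke is: the most
  # concentrated Eulerian cell is the most visited cell, nearly all of the
  # top-10 Eulerian cells carry parcel residence (deterministic tracers hug
  # the plume centre line while the Eulerian field spreads by diffusion, so
  # exact top-10 identity is not expected), and concentration rank
  # correlates positively with residence over the visited region
  expect_equal(arrayInd(which.max(counts), fs$mesh$n)[1, ],
               fs$source$cell, ignore_attr = TRUE)
  top_euler <- order(ct, decreasing = TRUE)[1:10]
  expect_gte(sum(counts[top_euler] > 0), 8)
  nz <- counts > 0
  expect_gt(suppressWarnings(cor(ct[nz], counts[nz], method = "spearman")), 0)
})
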