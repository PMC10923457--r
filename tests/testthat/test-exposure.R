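make_synthetic_field <- function(wfun, resolution = c(16, 12, 10)) {
  mesh <- build_mesh(theatre_scene(), resolution)
  n <- mesh$n
  Z <- array(rep(mesh$zc, each = n[1] * n[2]), n)
  structure(
    list(mesh = mesh, u = array(0, n), v = array(0, n), w = wfun(Z),
         p = array(0, n), T_K = array(300.15, n),
         k = array(1e-6, n), eps = array(1e-6, n),
         converged = TRUE, source = NULL, props = air_properties(),
         constants = turbulence_constants()),
    class = "field_state")
}

test_that("the ascent height is the interpolated first positive-to-negative crossing", {
  # w(z) = sin(pi (z - 0.9)) above the incision: analytic zero at z = 1.9
  fld <- make_synthetic_field(function(Z) sin(pi * (Z - 0.9)),
                              resolution = c(16, 12, 30))
  H <- compute_H_smoke(fld)
  expect_equal(attr(H, "flag"), "ok")
  expect_equal(as.numeric(H), 1.9, tolerance = 0.01)
  # a pure downflow has no upwelling: flagged, NA
  fld_dn <- make_synthetic_field(function(Z) array(-0.1, dim(Z)))
  H_dn <- compute_H_smoke(fld_dn)
  expect_true(is.na(H_dn))
  expect_equal(attr(H_dn, "flag"), "no_upwelling")
  # an everywhere-rising column reaches the ceiling: room height + flag
  fld_up <- make_synthetic_field(function(Z) array(0.1, dim(Z)))
  H_up <- compute_H_smoke(fld_up)
  expect_equal(as.numeric(H_up), 3)
  expect_equal(attr(H_up, "flag"), "reached_ceiling")
  # the FIRST crossing counts even when the profile changes sign again higher
  fld2 <- make_synthetic_field(function(Z) sin(pi * (Z - 0.9) / 0.5),
                               resolution = c(16, 12, 30))
  expect_equal(as.numeric(compute_H_smoke(fld2)), 1.4, tolerance = 0.01)
})

test_that("zone labels partition the fluid volume and capture the flow structure", {
  # a synthetic flow: rising inside the incision column, rising along the
  # x walls, sinking elsewhere
  mesh <- build_mesh(theatre_scene(), c(16, 12, 10))
  n <- mesh$n
  X <- array(rep(mesh$xc, times = n[2] * n[3]), n)
  Y <- array(rep(rep(mesh$yc, each = n[1]), times = n[3]), n)
  w <- array(-0.05, n)
  w[sqrt((X - 4)^2 + (Y - 3)^2) <= 0.5] <- 0.1
  w[X < 0.8 | X > 7.2] <- 0.03
  fld <- make_synthetic_field(function(Z) w)
  zones <- classify_zones(fld)
  cc <- locate_cell(mesh, c(4, 3, 1.2))
  expect_equal(zones[cc[1], cc[2], cc[3]], "upwelling_above_incision")
  expect_equal(zones[1, 6, 8], "wall_natural_convection_up")
  tb_cc <- locate_cell(mesh, c(3.2, 3.2, 2.5))
  expect_equal(zones[tb_cc[1], tb_cc[2], tb_cc[3]],
               "laminar_downflow_above_table")
  # labels are exclusive and exhaustive over fluid cells
  zv <- zone_volumes(zones, mesh)
  expect_equal(sum(zv$cells), sum(!mesh$solid))
  expect_equal(sum(zv$fraction), 1)
  expect_equal(sum(is.na(zones)), sum(mesh$solid))
  # a still room is all "other"
  zones0 <- classify_zones(make_synthetic_field(function(Z) array(0, dim(Z))))
  expect_true(all(zones0[!is.na(zones0)] == "other"))
})

test_that("profile extraction reproduces a linear field exactly", {
  mesh <- build_mesh(theatre_scene(), c(16, 12, 10))
  n <- mesh$n
  X <- array(rep(mesh$xc, times = n[2] * n[3]), n)
  Z <- array(rep(mesh$zc, each = n[1] * n[2]), n)
  arr <- 2 + 3 * X - 0.5 * Z
  pr <- extract_profile(arr, mesh, from = c(0.5, 3, 1.1), to = c(7.5, 3, 1.1),
                        spacing = 0.1)
  expect_equal(pr$value, 2 + 3 * pr$x - 0.5 * 1.1, tolerance = 1e-12)
  # a constant field gives a constant profile
  prc <- extract_profile(array(7, n), mesh, c(0.5, 3, 1.5), c(7.5, 3, 1.5))
  expect_true(all(prc$value == 7))
  expect_error(extract_profile(arr, mesh, c(0, 3, 1.1), c(9, 3, 1.1)),
               "outside the room")
})

test_that("CO ppm conversion is the molar-mass-scaled mass fraction", {
  expect_equal(co_ppm(0), 0)
  expect_equal(co_ppm(1, M_mix = 28.01, M_CO = 28.01), 1e6)
  expect_equal(co_ppm(9.66e-6), 9.99, tolerance = 1e-3)
  # linear in Y_CO at fixed mixture molar mass
  y <- c(1e-6, 2e-6, 4e-6)
  expect_equal(co_ppm(y) / co_ppm(y[1]), c(1, 2, 4))
  expect_error(co_ppm(1e-6, M_mix = 0), "positive")
})

test_that("the published ascent-height curve reproduces its printed endpoints", {
  expect_equal(hsmoke_published(200), 1.1106)
  expect_equal(hsmoke_published(500), 1.4340, tolerance = 1e-12)
  # within 1.5% of the printed 1.1 m and 1.45 m
  expect_lt(abs(hsmoke_published(200) - 1.1) / 1.1, 0.015)
  expect_lt(abs(hsmoke_published(500) - 1.45) / 1.45, 0.015)
  # rises monotonically over the simulated temperature range
  tt <- seq(200, 500, by = 10)
  expect_true(all(diff(hsmoke_published(tt)) > 0))
})

test_that("quadratic ascent-height fits interpolate three noiseless points exactly", {
  truth <- c(1.0, 2e-4, 1e-6)
  pts <- tibble::tibble(tip_temp = c(200, 350, 500))
  pts$H_smoke <- truth[1] + truth[2] * pts$tip_temp + truth[3] * pts$tip_temp^2
  fit <- fit_H_smoke_curve(pts)
  expect_equal(fit$coefficients, truth, tolerance = 1e-9)
  expect_equal(fit$residuals, rep(0, 3), tolerance = 1e-12)
  expect_error(fit_H_smoke_curve(pts[1:2, ]), ">= 3 distinct")
  td <- tidy(fit)
  expect_equal(td$estimate, truth, tolerance = 1e-9)
})

test_that("a zero-source room yields a well-formed all-clear report", {
  fs <- coarse_case(NULL, resolution = c(16, 12, 10), max_iter = 800)
  fs <- solve_species(fs)
  rep <- build_report(fs)
  expect_s3_class(rep, "exposure_report")
  expect_false(any(rep$flags$exceeded))
  expect_equal(rep$surgeon_co_ppm, 0)
  expect_equal(rep$wound_tar_gm3, 0)
  expect_true(all(rep$profiles$value >= -1e-12))
  expect_equal(sum(rep$zone_volumes$fraction), 1)
  td <- tidy(rep)
  expect_equal(nrow(td), 5)
})
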