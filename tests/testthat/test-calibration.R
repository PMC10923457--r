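test_that("calibration polynomials reproduce their printed coefficients exactly", {
  calib <- default_calibration()
  # constant terms at P = 0
  expect_identical(eval_tip_temperature(0, calib), 270)
  expect_identical(eval_waste_gas_flow(0, calib), 9.30e-6)
  expect_identical(eval_particle_rate(0, calib, clamp = FALSE), -4.14e-3)
  expect_identical(eval_particle_rate(0, calib, clamp = TRUE), 0)
  expect_identical(eval_tar_rate(0, calib), 2.82e-3)
  # frozen hand-computed values at sweep powers
  expect_equal(eval_tip_temperature(80, calib), 510.8)
  expect_equal(eval_waste_gas_flow(80, calib), 5.1532e-5)
  expect_equal(eval_waste_gas_flow(20, calib), 1.1266e-5)
  expect_equal(eval_particle_rate(80, calib), 0.176676, tolerance = 1e-10)
  expect_equal(eval_tar_rate(80, calib), 0.07970, tolerance = 1e-10)
  expect_equal(eval_tar_rate(20, calib), 9.908e-3, tolerance = 1e-10)
})

test_that("polynomial evaluation agrees with an independent Horner oracle over the operating range", {
  calib <- default_calibration()
  P <- seq(0, 100, by = 0.5)
  expect_equal(eval_tip_temperature(P, calib),
               horner_oracle(calib$temp_coeffs, P), tolerance = 1e-14)
  expect_equal(eval_waste_gas_flow(P, calib),
               horner_oracle(calib$flow_coeffs, P), tolerance = 1e-14)
  expect_equal(eval_particle_rate(P, calib, clamp = FALSE),
               horner_oracle(calib$particle_coeffs, P), tolerance = 1e-14)
  expect_equal(eval_tar_rate(P, calib),
               horner_oracle(calib$tar_coeffs, P), tolerance = 1e-14)
  # waste-gas flow stays positive over 0..100 W
  expect_true(all(eval_waste_gas_flow(P, calib) > 0))
})

test_that("responses are monotone on the operating range", {
  P_hi <- seq(24.2, 100, by = 0.2)
  expect_true(all(diff(eval_tip_temperature(P_hi)) > 0))
  P_flow <- seq(20, 100, by = 0.2)
  expect_true(all(diff(eval_waste_gas_flow(P_flow)) > 0))
})

test_that("negative power is rejected", {
  expect_error(eval_tip_temperature(-1), "non-negative")
  expect_error(eval_waste_gas_flow(-5), "non-negative")
  expect_error(eval_particle_rate(c(10, -0.1)), "non-negative")
  expect_error(eval_tar_rate(-1e-9), "non-negative")
})

test_that("temperature inversion returns the larger quadratic root and the canonical lookup", {
  # exact root: (4.59 + sqrt(4.59^2 - 4*0.095*(270-500))) / (2*0.095)
  expect_equal(power_for_temperature(500, lookup = FALSE), 78.9726399,
               tolerance = 1e-7)
  # canonical printed correspondence
  expect_identical(power_for_temperature(200), 20)
  expect_identical(power_for_temperature(300), 60)
  expect_identical(power_for_temperature(400), 70)
  expect_identical(power_for_temperature(500), 80)
  # round-trip identity on the increasing branch
  for (P in c(30, 50, 75, 95)) {
    Tt <- eval_tip_temperature(P)
    expect_equal(power_for_temperature(Tt, lookup = FALSE), P,
                 tolerance = 1e-9)
  }
  # unreachable temperature: vertex power with a warning flag
  expect_warning(p200 <- power_for_temperature(200, lookup = FALSE),
                 "below the calibration minimum")
  expect_equal(as.numeric(p200), 4.59 / (2 * 0.095), tolerance = 1e-12)
  expect_true(attr(p200, "unreachable"))
})

test_that("noiseless fits recover the generating coefficients to high relative accuracy", {
  sweep <- generate_sweep(sweep_design(noise_cv = 0))
  fit <- fit_calibration(sweep)
  truth <- default_calibration()
  for (nm in names(truth)) {
    expect_equal(fit$calibration[[nm]], truth[[nm]],
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_true(all(fit$rss < 1e-12))
})

test_that("noisy fits match an independent normal-equations oracle", {
  sweep <- generate_sweep(sweep_design(noise_cv = 0.02, seed = 11))
  fit <- fit_calibration(sweep)
  # oracle: solve the least-squares normal equations directly
  X2 <- cbind(1, sweep$power, sweep$power^2)
  X3 <- cbind(X2, sweep$power^3)
  beta2 <- solve(t(X2) %*% X2, t(X2) %*% sweep$tip_temp)
  beta3 <- solve(t(X3) %*% X3, t(X3) %*% sweep$tar_rate)
  expect_equal(fit$calibration$temp_coeffs, as.numeric(beta2), tolerance = 1e-8)
  expect_equal(fit$calibration$tar_coeffs, as.numeric(beta3), tolerance = 1e-6)
})

test_that("underdetermined designs are refused", {
  sweep <- generate_sweep(sweep_design(powers = c(20, 40, 60), noise_cv = 0))
  expect_error(fit_calibration(sweep), ">= 4 distinct power")
  sweep4 <- generate_sweep(sweep_design(powers = c(20, 40, 60, 80), noise_cv = 0))
  expect_error(fit_calibration(sweep4), ">= 5 distinct power")
})

test_that("tidy and glance summarise the calibration fit", {
  fit <- fit_calibration(generate_sweep(sweep_design(noise_cv = 0.01, seed = 2)))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3 + 3 + 4 + 4)
  gl <- glance(fit)
  expect_equal(gl$response,
               c("tip_temp", "waste_gas_flow", "particle_rate", "tar_rate"))
  expect_true(all(gl$r.squared > 0.9))
})

test_that("power-sweep CSV round-trips through the interchange header", {
  sweep <- generate_sweep(sweep_design(noise_cv = 0.05, seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_power_sweep(sweep, path)
  header <- readLines(path, n = 1)
  expect_equal(header, "power_W,tip_temp_C,waste_gas_m3s,tar_gs,particle_gs")
  back <- read_power_sweep(path)
  expect_equal(back$tip_temp, sweep$tip_temp, tolerance = 1e-12)
  expect_equal(back$particle_rate, sweep$particle_rate, tolerance = 1e-12)
})

test_that("source spec chains the calibration evaluations at the canonical cases", {
  ss <- make_source_spec(500)
  expect_equal(ss$power, 80)
  expect_equal(ss$volume_flow, 5.1532e-5)
  expect_equal(ss$tar_rate, 0.07970, tolerance = 1e-10)
  expect_equal(ss$particle_rate, 0.176676, tolerance = 1e-10)
  expect_equal(ss$temperature, 500)
  expect_equal(make_source_spec(300)$power, 60)
  # source must be hotter than ambient
  expect_error(make_source_spec(27), "exceed ambient")
  # invalid composition refused
  expect_error(make_source_spec(500, composition = c(CO = 0.8, CO2 = 0.5,
                                                     CH4 = 0, NH3 = 0)),
               "sum")
})
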