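#' Run configuration
#'
#' A single YAML-serialisable configuration describes a complete simulation:
#' scene geometry, solver resolution and numerics, source operating point
#' and waste-gas composition, dispersed-phase properties, analysis zones and
#' thresholds, and the seed feeding every random component. All model
#' constants appear as defaults, so a bare `default_config()` reproduces the
#' reference theatre setup.
#'
#' @param tip_temp knife tip temperature (degC) of the simulated case.
#' @param resolution mesh cell counts `(nx, ny, nz)`.
#' @param tol solver convergence tolerance.
#' @param max_iter solver iteration cap.
#' @param seed integer seed.
#' @return a nested `run_config` list.
#' @export
default_config <- function(tip_temp = 500, resolution = c(40, 30, 15),
                           tol = 1e-3, max_iter = 2000, seed = 1L) {
  structure(list(
    version = 1L,
    scene = list(room = c(8, 6, 3), inlet_size = c(2.4, 2.6),
                 outlet_size = c(4, 0.3), outlet_bottom = 0.1,
                 table_size = c(1.8, 0.8, 0.8), incision_height = 0.1),
    solver = list(resolution = as.integer(resolution),
                  relax_mom = 0.7, relax_p = 0.3, relax_scalar = 0.5,
                  tol = tol, max_iter = as.integer(max_iter), sweeps = 4L,
                  buoyancy = TRUE, canonical_constants = FALSE),
    boundary = list(V_in = 0.096, T_in_C = 27, Ti = 0.037,
                    length_scale = 0.07 * 2.4, h_wall = 1.5, T_ext_C = 30),
    source = list(tip_temp = tip_temp,
                  composition = as.list(default_composition()),
                  incision_area = 1e-4,
                  calibration = unclass(default_calibration())),
    dispersed = list(diameter = 2e-6, rho_tar = 1000, rho_particle = 1200),
    analysis = list(w_eps = 0.005, r_upwell = 0.5,
                    surgeon_r_horiz = 0.5, surgeon_z_range = c(1.1, 1.45),
                    profile_spacing = 0.05,
                    thresholds = list(co_ppm = c(9, 50, 200),
                                      tar_gm3 = 20, particle_gm3 = 12)),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' @rdname default_config
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname default_config
#' @param config a `run_config` (for `write_config`).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- modifyList(unclass(default_config()), raw)
  validate_config(structure(cfg, class = "run_config"))
}

#' @rdname default_config
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  with(config, {
    stopifnot(length(scene$room) == 3, all(unlist(scene$room) > 0),
              length(solver$resolution) == 3,
              solver$tol > 0, solver$max_iter >= 1,
              boundary$V_in > 0, boundary$Ti > 0, boundary$Ti < 1,
              source$tip_temp > boundary$T_in_C,
              dispersed$diameter > 0)
  })
  validate_composition(unlist(config$source$composition))
  config
}

config_calibration <- function(config) {
  cc <- config$source$calibration
  calibration_set(cc$temp_coeffs, cc$flow_coeffs, cc$particle_coeffs,
                  cc$tar_coeffs)
}

config_scene <- function(config) {
  sc <- config$scene
  theatre_scene(room = unlist(sc$room), inlet_size = unlist(sc$inlet_size),
                outlet_size = unlist(sc$outlet_size),
                outlet_bottom = sc$outlet_bottom,
                table_size = unlist(sc$table_size),
                incision_height = sc$incision_height)
}
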