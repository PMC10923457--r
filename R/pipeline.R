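#' Run one simulated electro-surgery case
#'
#' End-to-end driver: builds the scene and mesh from the configuration,
#' assembles the smoke source for the configured tip temperature from the
#' calibration polynomials, runs the steady RANS solve, transports the
#' waste-gas species and the two dispersed phases, and assembles the
#' exposure report.
#'
#' @param config a [default_config()].
#' @param tip_temp optional override of the configured tip temperature
#'   (degC).
#' @param init optional `field_state` used as a warm start.
#' @param verbose print solver progress.
#' @return list: `field` (with species), `c_tar`, `c_particle`, `report`.
#' @export
simulate_case <- function(config = default_config(), tip_temp = NULL,
                          init = NULL, verbose = FALSE) {
  config <- validate_config(config)
  if (!is.null(tip_temp)) config$source$tip_temp <- tip_temp
  scene <- config_scene(config)
  mesh <- build_mesh(scene, unlist(config$solver$resolution))
  calib <- config_calibration(config)
  src_spec <- make_source_spec(
    config$source$tip_temp, calib,
    composition = unlist(config$source$composition),
    position = scene$incision_point,
    ambient = config$boundary$T_in_C
  )
  props <- air_properties()
  source <- assemble_source(src_spec, mesh, props,
                            incision_area = config$source$incision_area)
  bc <- boundary_conditions(
    V_in = config$boundary$V_in, T_in_C = config$boundary$T_in_C,
    Ti = config$boundary$Ti, length_scale = config$boundary$length_scale,
    h_wall = config$boundary$h_wall, T_ext_C = config$boundary$T_ext_C
  )
  settings <- solver_settings(
    relax_mom = config$solver$relax_mom, relax_p = config$solver$relax_p,
    relax_scalar = config$solver$relax_scalar, tol = config$solver$tol,
    max_iter = config$solver$max_iter, sweeps = config$solver$sweeps,
    buoyancy = config$solver$buoyancy
  )
  constants <- turbulence_constants(canonical = isTRUE(config$solver$canonical_constants))
  field <- solve_steady(mesh, bc, source, settings, constants, props,
                        init = init, verbose = verbose)
  field <- solve_species(field)
  c_tar <- concentration_field(field, "tar")
  c_particle <- concentration_field(field, "particle")
  report <- build_report(
    field, c_tar, c_particle,
    surgeon_zone = list(r_horiz = config$analysis$surgeon_r_horiz,
                        z_range = unlist(config$analysis$surgeon_z_range))
  )
  list(field = field, c_tar = c_tar, c_particle = c_particle, report = report)
}

#' Sweep the canonical tip-temperature cases
#'
#' Runs [simulate_case()] for each requested tip temperature (the four
#' canonical cases 200/300/400/500 degC by default), warm-starting each case
#' from the previous one, then fits the ascent-height-vs-temperature
#' quadratic when at least three cases succeeded. When `out_dir` is given,
#' per-case reports are written as JSON and finished cases are skipped on
#' rerun (resumable).
#'
#' @param config a [default_config()].
#' @param temperatures tip temperatures (degC) to simulate.
#' @param out_dir optional output directory for per-case artifacts.
#' @param verbose print solver progress.
#' @return A `smoke_sweep` object: `cases` (named list of per-case results),
#'   `H_table` (tibble `tip_temp`, `H_smoke`, `converged`), and `H_fit` (an
#'   `hsmoke_fit`, or `NULL` if fewer than 3 cases).
#' @export
run_sweep <- function(config = default_config(),
                      temperatures = c(200, 300, 400, 500),
                      out_dir = NULL, verbose = FALSE) {
  cases <- list()
  init <- NULL
  for (tt in temperatures) {
    key <- as.character(tt)
    if (!is.null(out_dir)) {
      f <- file.path(out_dir, sprintf("report_T%s.json", key))
      if (file.exists(f)) {
        cases[[key]] <- list(report = report_from_json(f), cached = TRUE)
        next
      }
    }
    res <- simulate_case(config, tip_temp = tt, init = init, verbose = verbose)
    init <- res$field
    cases[[key]] <- res
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      report_to_json(res$report, file.path(out_dir, sprintf("report_T%s.json", key)))
      readr::write_csv(res$report$profiles,
                       file.path(out_dir, sprintf("profiles_T%s.csv", key)))
    }
  }
  H_table <- purrr::imap_dfr(cases, function(cs, key) {
    tibble::tibble(tip_temp = as.numeric(key), H_smoke = cs$report$H_smoke,
                   converged = isTRUE(cs$report$converged))
  })
  H_fit <- NULL
  ok <- H_table[is.finite(H_table$H_smoke), ]
  if (length(unique(ok$tip_temp)) >= 3) {
    H_fit <- fit_H_smoke_curve(ok)
  } else {
    warn("fewer than 3 usable cases; ascent-height fit not computed")
  }
  structure(list(cases = cases, H_table = H_table, H_fit = H_fit,
                 config = config),
            class = "smoke_sweep")
}

#' @export
print.smoke_sweep <- function(x, ...) {
  cat("<smoke_sweep>", nrow(x$H_table), "cases\n")
  print(x$H_table)
  if (!is.null(x$H_fit)) print(x$H_fit)
  invisible(x)
}

#' Rebuild an exposure report from exported field files
#'
#' Reads the `*_flow.vtk`, `*_species.vtk` and `*_dispersed.vtk` files
#' written by [export_field_state()] and re-assembles the exposure report
#' without re-running the solver.
#'
#' @param dir directory holding the exported files.
#' @param prefix the file-name prefix used at export time.
#' @param config the [default_config()] the case was run with (for the
#'   scene, resolution and analysis settings).
#' @param tip_temp tip temperature (degC) recorded in the report.
#' @return an `exposure_report`.
#' @export
analyze_fields <- function(dir, prefix, config = default_config(),
                           tip_temp = NA_real_) {
  mesh <- build_mesh(config_scene(config), unlist(config$solver$resolution))
  flow <- read_vtk_fields(file.path(dir, paste0(prefix, "_flow.vtk")))
  species <- read_vtk_fields(file.path(dir, paste0(prefix, "_species.vtk")))
  disp <- read_vtk_fields(file.path(dir, paste0(prefix, "_dispersed.vtk")))
  field <- structure(
    list(mesh = mesh, u = flow$u, v = flow$v, w = flow$w, p = flow$p,
         T_K = flow$T_K, k = flow$k, eps = flow$eps, Y = species,
         converged = TRUE, source = NULL, props = air_properties(),
         constants = turbulence_constants(), bc = boundary_conditions()),
    class = "field_state")
  rep <- build_report(
    field, c_tar = disp$c_tar, c_particle = disp$c_particle,
    surgeon_zone = list(r_horiz = config$analysis$surgeon_r_horiz,
                        z_range = unlist(config$analysis$surgeon_z_range)))
  rep$tip_temp <- tip_temp
  rep
}

#' Serialise an exposure report to JSON
#'
#' @param report an `exposure_report`.
#' @param path JSON path.
#' @return for the reader, an `exposure_report` rebuilt from the file.
#' @export
report_to_json <- function(report, path) {
  out <- unclass(report)
  out$profiles <- as.data.frame(out$profiles)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname report_to_json
#' @export
report_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  # JSON null (an unavailable metric, e.g. H_smoke with no plume) -> NA
  for (nm in c("tip_temp", "H_smoke", "surgeon_co_ppm", "wound_co_ppm",
               "wound_tar_gm3", "wound_particle_gm3")) {
    raw[[nm]] <- if (is.null(raw[[nm]])) NA_real_ else as.numeric(raw[[nm]])
  }
  raw$profiles <- tibble::as_tibble(raw$profiles)
  raw$flags <- tibble::as_tibble(raw$flags)
  raw$peaks <- tibble::as_tibble(raw$peaks)
  raw$zone_volumes <- tibble::as_tibble(raw$zone_volumes)
  structure(raw, class = "exposure_report")
}

#' Fit a calibration from a CSV sweep or a synthetic one
#'
#' Command-line-facing wrapper: reads a power-sweep CSV (or generates a
#' synthetic sweep when `csv = NULL`), fits the calibration polynomials and
#' optionally writes the fitted coefficients as JSON.
#'
#' @param csv path to a power-sweep CSV, or `NULL` for synthetic data.
#' @param noise_cv,seed synthetic-sweep parameters (ignored with a CSV).
#' @param out optional JSON output path for the fitted coefficients.
#' @return the [fit_calibration()] result.
#' @export
run_fit <- function(csv = NULL, noise_cv = 0.02, seed = 1L, out = NULL) {
  records <- if (is.null(csv)) {
    generate_sweep(sweep_design(noise_cv = noise_cv, seed = seed))
  } else {
    read_power_sweep(csv)
  }
  fit <- fit_calibration(records)
  if (!is.null(out)) {
    jsonlite::write_json(unclass(fit$calibration), out, auto_unbox = TRUE,
                         digits = NA)
  }
  fit
}
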