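# Shared fixtures. Expensive converged cases are memoised per test session so
# several test files can analyse the same flow solve.

fixture_env <- new.env(parent = emptyenv())

# a small but buoyancy-resolving theatre case; cases at the same resolution
# warm-start from the most recent converged one
coarse_case <- function(tip_temp = NULL, resolution = c(40, 30, 15),
                        tol = 1e-3, max_iter = 2500) {
  res_key <- paste(resolution, collapse = "x")
  key <- paste0("case_", res_key, "_", tip_temp %||% "nosource")
  if (!is.null(fixture_env[[key]])) return(fixture_env[[key]])
  mesh <- build_mesh(theatre_scene(), resolution)
  source <- NULL
  if (!is.null(tip_temp)) {
    source <- assemble_source(make_source_spec(tip_temp), mesh)
  }
  init <- fixture_env[[paste0("last_", res_key)]]
  fs <- solve_steady(mesh, source = source,
                     settings = solver_settings(tol = tol, max_iter = max_iter),
                     init = init)
  fixture_env[[key]] <- fs
  if (fs$converged) fixture_env[[paste0("last_", res_key)]] <- fs
  fs
}

# independent Horner-scheme polynomial oracle (ascending coefficients)
horner_oracle <- function(coeffs, x) {
  vapply(x, function(xi) {
    acc <- 0
    for (c_i in rev(coeffs)) acc <- acc * xi + c_i
    acc
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
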