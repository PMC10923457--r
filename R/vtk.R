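#' Write fields as a legacy-VTK structured-points file
#'
#' Writes one ASCII legacy VTK `STRUCTURED_POINTS` dataset with any number
#' of cell-centred scalar fields, for inspection in ParaView or similar.
#' `read_vtk_fields()` reads files written by this writer back (round-trip
#' support for the package's own artifacts, not a general VTK parser).
#'
#' @param fields named list of 3-D arrays, all with the mesh's dimensions.
#' @param mesh the [build_mesh()] result the fields live on.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vtk_fields <- function(fields, mesh, path) {
  stopifnot(is.list(fields), length(fields) > 0, !is.null(names(fields)))
  n <- mesh$n
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "surgsmoke fields",
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d %d", n[1], n[2], n[3]),
    sprintf("ORIGIN %g %g %g", mesh$d[1] / 2, mesh$d[2] / 2, mesh$d[3] / 2),
    sprintf("SPACING %g %g %g", mesh$d[1], mesh$d[2], mesh$d[3]),
    sprintf("POINT_DATA %d", prod(n))
  ), con)
  for (nm in names(fields)) {
    arr <- fields[[nm]]
    stopifnot(all(dim(arr) == n))
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
               con)
    # VTK expects x fastest, z slowest: R's native array order
    writeLines(format(as.vector(arr), digits = 9, scientific = TRUE,
                      trim = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_vtk_fields
#' @export
read_vtk_fields <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(trimws(sub("DIMENSIONS", "",
                                         grep("^DIMENSIONS", lines, value = TRUE))),
                              "\\s+")[[1]])
  npts <- prod(dims)
  fields <- list()
  i <- 1
  while (i <= length(lines)) {
    if (grepl("^SCALARS", lines[i])) {
      nm <- strsplit(lines[i], "\\s+")[[1]][2]
      vals <- as.numeric(lines[(i + 2):(i + 1 + npts)])
      fields[[nm]] <- array(vals, dims)
      i <- i + 2 + npts
    } else {
      i <- i + 1
    }
  }
  fields
}

#' Export a field state to files
#'
#' Writes the velocity/pressure/temperature/turbulence set, species mass
#' fractions and dispersed concentrations (when present) as legacy VTK, plus
#' the residual history as CSV.
#'
#' @param field a `field_state`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param c_tar,c_particle optional dispersed-phase concentration arrays to
#'   include.
#' @return tibble of the files written.
#' @export
export_field_state <- function(field, dir, prefix = "case", c_tar = NULL,
                               c_particle = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c()
  f1 <- file.path(dir, paste0(prefix, "_flow.vtk"))
  write_vtk_fields(list(u = field$u, v = field$v, w = field$w, p = field$p,
                        T_K = field$T_K, k = field$k, eps = field$eps),
                   field$mesh, f1)
  files <- c(files, f1)
  if (!is.null(field$Y)) {
    f2 <- file.path(dir, paste0(prefix, "_species.vtk"))
    write_vtk_fields(field$Y, field$mesh, f2)
    files <- c(files, f2)
  }
  if (!is.null(c_tar) && !is.null(c_particle)) {
    f4 <- file.path(dir, paste0(prefix, "_dispersed.vtk"))
    write_vtk_fields(list(c_tar = c_tar, c_particle = c_particle),
                     field$mesh, f4)
    files <- c(files, f4)
  }
  f3 <- file.path(dir, paste0(prefix, "_residuals.csv"))
  readr::write_csv(field$residuals, f3)
  files <- c(files, f3)
  tibble::tibble(file = files)
}
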