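#' Maximum smoke ascent height above the incision
#'
#' The smoke plume rises from the incision against the downward laminar air
#' curtain until its vertical velocity crosses zero. On the vertical line of
#' cell centres through the incision, the lowest positive-to-negative sign
#' change of `w` above the incision defines the maximum ascent height
#' `H_smoke`, linearly interpolated between the bracketing cell centres and
#' measured from the floor.
#'
#' @param field a converged `field_state`.
#' @param incision_point numeric(3); defaults to the scene's incision point.
#' @return numeric(1) height (m) with attributes `flag` (`"ok"`,
#'   `"no_upwelling"` when `w` is never positive above the incision —
#'   returned as `NA` — or `"reached_ceiling"` when `w` never turns
#'   negative — returned as the room height).
#' @examples
#' \dontrun{
#' compute_H_smoke(field)
#' }
#' @export
compute_H_smoke <- function(field, incision_point = NULL) {
  mesh <- field$mesh
  if (is.null(incision_point)) incision_point <- mesh$scene$incision_point
  cc <- locate_cell(mesh, incision_point)
  ks <- which(mesh$zc >= incision_point[3])
  wline <- field$w[cc[1], cc[2], ks]
  zline <- mesh$zc[ks]
  if (all(wline <= 0)) {
    out <- NA_real_
    attr(out, "flag") <- "no_upwelling"
    return(out)
  }
  pos <- wline > 0
  cross <- which(pos[-length(pos)] & !pos[-1])
  if (length(cross) == 0) {
    out <- mesh$room[3]
    attr(out, "flag") <- "reached_ceiling"
    return(out)
  }
  i <- cross[1]
  z0 <- zline[i]; z1 <- zline[i + 1]
  w0 <- wline[i]; w1 <- wline[i + 1]
  out <- z0 + (z1 - z0) * w0 / (w0 - w1)
  attr(out, "flag") <- "ok"
  out
}

#' Flow-zone decomposition of the theatre
#'
#' Labels each fluid cell into one of seven zones by sign and magnitude
#' rules on the vertical velocity and position, following the qualitative
#' structure of the simulated theatre flow: (1) the upwelling column right
#' above the incision, (2) the downward laminar curtain over the table,
#' (4) horizontal flow carrying smoke toward the wall outlets, (5) slow
#' peripheral downflow, (6) horizontal flow toward the outlet-free walls and
#' (7) upward natural convection hugging those walls (the exterior is warmer
#' than the room, so the wall boundary layer rises). Cells matching no rule
#' are labelled `"other"` — one enumerated zone of the original description
#' is never defined, and `"other"` absorbs the gap.
#'
#' @param field a converged `field_state`.
#' @param w_eps vertical-velocity magnitude (m/s) separating "horizontal"
#'   from "vertical" cells.
#' @param r_upwell horizontal radius (m) of the upwelling column test.
#' @param wall_layer distance (m) from an outlet-free wall within which
#'   rising air counts as wall natural convection.
#' @return character array of zone labels over the mesh (solid cells `NA`).
#' @export
classify_zones <- function(field, w_eps = 0.005, r_upwell = 0.5,
                           wall_layer = NULL) {
  mesh <- field$mesh
  n <- mesh$n
  if (is.null(wall_layer)) wall_layer <- 1.5 * mesh$d[1]
  ip <- mesh$scene$incision_point
  X <- array(rep(mesh$xc, times = n[2] * n[3]), n)
  Y <- array(rep(rep(mesh$yc, each = n[1]), times = n[3]), n)
  Z <- array(rep(mesh$zc, each = n[1] * n[2]), n)
  w <- field$w; v <- field$v; u <- field$u
  horiz <- sqrt(u^2 + v^2)
  tb <- mesh$scene$table

  over_table <- X >= tb$x[1] & X <= tb$x[2] & Y >= tb$y[1] & Y <= tb$y[2]
  near_axis <- sqrt((X - ip[1])^2 + (Y - ip[2])^2) <= r_upwell
  near_xwall <- X <= wall_layer | X >= mesh$room[1] - wall_layer

  lab <- array("other", n)
  # precedence: first matching rule wins (applied in reverse here)
  lab[horiz > abs(w) & abs(u) >= abs(v)] <- "horizontal_toward_blank_walls"
  lab[horiz > abs(w) & abs(v) > abs(u)] <- "horizontal_toward_outlets"
  lab[w < -w_eps & !over_table] <- "downward_slow_peripheral"
  lab[w < -w_eps & over_table] <- "laminar_downflow_above_table"
  lab[w > w_eps & near_xwall] <- "wall_natural_convection_up"
  lab[w > w_eps & near_axis & Z > ip[3] - mesh$d[3]] <- "upwelling_above_incision"
  lab[mesh$solid] <- NA_character_
  lab
}

#' Zone volume fractions
#'
#' @param zones label array from [classify_zones()].
#' @param mesh the mesh.
#' @return tibble `zone`, `cells`, `volume`, `fraction` (of fluid volume).
#' @export
zone_volumes <- function(zones, mesh) {
  tab <- table(zones[!is.na(zones)])
  tibble::tibble(
    zone = names(tab),
    cells = as.integer(tab),
    volume = as.integer(tab) * mesh$vol,
    fraction = as.integer(tab) / sum(tab)
  )
}

#' Sample a field along an axis-aligned line
#'
#' Trilinear interpolation of a cell-centred field along a horizontal line,
#' e.g. the operating-table centre line at the lying patient's nose height
#' (Z = 1.1 m) or the table border at the standing surgeon's nose height
#' (Z = 1.5 m).
#'
#' @param arr 3-D field array on the mesh.
#' @param mesh the mesh.
#' @param from,to numeric(3) line end points (m), inside the room.
#' @param spacing sample spacing along the line (m).
#' @return tibble `position` (distance from `from`, m), `x`, `y`, `z`,
#'   `value`.
#' @export
extract_profile <- function(arr, mesh, from, to, spacing = 0.05) {
  stopifnot(length(from) == 3, length(to) == 3)
  eps <- 1e-9
  for (pt in list(from, to)) {
    if (any(pt < -eps) || any(pt > mesh$room + eps)) {
      abort(sprintf("profile end point (%g, %g, %g) lies outside the room",
                    pt[1], pt[2], pt[3]))
    }
  }
  len <- sqrt(sum((to - from)^2))
  s <- seq(0, len, by = spacing)
  if (tail(s, 1) < len - eps) s <- c(s, len)
  pts <- t(sapply(s, function(si) from + (to - from) * si / max(len, eps)))
  pts <- pmin(pmax(pts, eps), matrix(mesh$room - eps, nrow(pts), 3, byrow = TRUE))
  vals <- apply(pts, 1, function(pt) interp_trilinear(mesh, arr, pt))
  tibble::tibble(position = s, x = pts[, 1], y = pts[, 2], z = pts[, 3],
                 value = vals)
}

#' Convert a CO mass fraction to volumetric ppm
#'
#' `ppm = Y_CO * (M_mix / M_CO) * 1e6`; the mixture molar mass defaults to
#' dry air (dilute-smoke approximation).
#'
#' @param Y_CO mass-fraction array or vector.
#' @param M_mix,M_CO molar masses (g/mol), `> 0`.
#' @return ppm values, same shape as `Y_CO`.
#' @examples
#' co_ppm(9.66e-6)
#' @export
co_ppm <- function(Y_CO, M_mix = 28.96, M_CO = 28.01) {
  if (M_mix <= 0 || M_CO <= 0) abort("molar masses must be positive")
  Y_CO * (M_mix / M_CO) * 1e6
}

#' The fitted ascent-height curve and its published counterpart
#'
#' `fit_H_smoke_curve()` least-squares fits a quadratic to
#' `(T_tip, H_smoke)` points. `hsmoke_published()` evaluates the published
#' quadratic relating ascent height to tip temperature; its printed
#' coefficients lost their exponents in typesetting and are restored here as
#' `H = 1.14 - 6.37e-4 T + 2.45e-6 T^2`, which reproduces the published
#' endpoint heights (1.11 m at 200 degC, 1.43 m at 500 degC).
#'
#' @param points data frame with columns `tip_temp` (degC) and `H_smoke`
#'   (m); at least 3 distinct temperatures.
#' @return An `hsmoke_fit` object: `coefficients` (ascending), `points`,
#'   `residuals`; `tidy()` and `glance()` methods, [autoplot()] for the
#'   curve.
#' @examples
#' hsmoke_published(c(200, 500))
#' @export
fit_H_smoke_curve <- function(points) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("tip_temp", "H_smoke") %in% names(points)))
  pts <- points[is.finite(points$H_smoke), ]
  if (length(unique(pts$tip_temp)) < 3) {
    abort("need >= 3 distinct tip temperatures to fit the ascent-height quadratic")
  }
  fit <- lm(H_smoke ~ tip_temp + I(tip_temp^2), data = pts)
  structure(
    list(coefficients = unname(coef(fit)), points = pts,
         residuals = unname(stats::residuals(fit)), fit = fit),
    class = "hsmoke_fit"
  )
}

#' @rdname fit_H_smoke_curve
#' @param tip_temp temperatures (degC) at which to evaluate.
#' @export
hsmoke_published <- function(tip_temp) {
  polyval_asc(c(1.14, -6.37e-4, 2.45e-6), tip_temp)
}

#' @export
print.hsmoke_fit <- function(x, ...) {
  cat("<hsmoke_fit> H_smoke =",
      sprintf("%.4g %+.4g T %+.4g T^2", x$coefficients[1], x$coefficients[2],
              x$coefficients[3]), "\n")
  cat("  fitted on", nrow(x$points), "points, RMS residual",
      format(sqrt(mean(x$residuals^2)), digits = 3), "m\n")
  invisible(x)
}

#' @rdname fit_H_smoke_curve
#' @param x an `hsmoke_fit`.
#' @param ... unused.
#' @export
tidy.hsmoke_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(term = c("1", "tip_temp", "tip_temp^2"),
                 estimate = unname(s[, "Estimate"]),
                 std.error = unname(s[, "Std. Error"]))
}

#' @rdname fit_H_smoke_curve
#' @export
glance.hsmoke_fit <- function(x, ...) {
  tibble::tibble(r.squared = summary(x$fit)$r.squared,
                 sigma = summary(x$fit)$sigma,
                 nobs = nrow(x$points))
}

#' Exposure thresholds
#'
#' Reference levels the report compares against: the EPA 9 ppm 8-hour CO
#' limit, the 50 ppm and 200 ppm CO levels discussed for the surgeon's
#' operating zone, and the 20 g/m^3 tar / 12 g/m^3 particle levels discussed
#' for the open wound.
#'
#' @export
exposure_thresholds <- function() {
  list(co_ppm = c(epa_8h = 9, surgeon_50 = 50, surgeon_200 = 200),
       tar_gm3 = 20, particle_gm3 = 12)
}

#' Assemble the exposure report for a converged case
#'
#' Collects the headline exposure quantities: `H_smoke`, nose-height
#' profiles (patient at Z = 1.1 m along the table centre line, surgeon at
#' Z = 1.5 m along the table border), peak concentrations and their
#' locations, mean CO ppm in the surgeon's operating zone (the box within
#' 0.5 m horizontally of the incision between 1.1 m and 1.45 m height), the
#' wound-zone (incision cell and face neighbours) dispersed-phase
#' concentrations, strict threshold flags, and zone volume fractions.
#'
#' @param field a converged `field_state`, with species solved via
#'   [solve_species()].
#' @param c_tar,c_particle concentration arrays from
#'   [concentration_field()]; computed here if missing.
#' @param thresholds [exposure_thresholds()].
#' @param surgeon_zone list with `r_horiz` (m) and `z_range` (m) overriding
#'   the surgeon-zone box.
#' @return An `exposure_report` object.
#' @export
build_report <- function(field, c_tar = NULL, c_particle = NULL,
                         thresholds = exposure_thresholds(),
                         surgeon_zone = list(r_horiz = 0.5,
                                             z_range = c(1.1, 1.45))) {
  check_converged(field)
  if (is.null(field$Y)) field <- solve_species(field)
  if (is.null(c_tar)) c_tar <- concentration_field(field, "tar")
  if (is.null(c_particle)) c_particle <- concentration_field(field, "particle")
  mesh <- field$mesh
  n <- mesh$n
  ip <- mesh$scene$incision_point
  tb <- mesh$scene$table

  H <- compute_H_smoke(field)
  ppm <- co_ppm(field$Y$CO)
  Ytot <- field$Y$CO + field$Y$CO2 + field$Y$CH4 + field$Y$NH3

  # surgeon operating zone: within r_horiz of the incision axis, z band
  X <- array(rep(mesh$xc, times = n[2] * n[3]), n)
  Yc <- array(rep(rep(mesh$yc, each = n[1]), times = n[3]), n)
  Z <- array(rep(mesh$zc, each = n[1] * n[2]), n)
  sz <- abs(X - ip[1]) <= surgeon_zone$r_horiz &
    abs(Yc - ip[2]) <= surgeon_zone$r_horiz &
    Z >= surgeon_zone$z_range[1] & Z <= surgeon_zone$z_range[2] &
    !mesh$solid

  # wound zone: incision cell plus face neighbours
  cc <- locate_cell(mesh, ip)
  wound <- array(FALSE, n)
  nb <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  for (r in seq_len(nrow(nb))) {
    id <- pmin(pmax(as.integer(cc) + nb[r, ], 1L), n)
    wound[id[1], id[2], id[3]] <- TRUE
  }
  wound <- wound & !mesh$solid

  zone_mean <- function(arr, mask) if (any(mask)) mean(arr[mask]) else NA_real_
  surgeon_co <- zone_mean(ppm, sz)
  wound_co <- zone_mean(ppm, wound)
  wound_tar <- zone_mean(c_tar, wound)
  wound_particle <- zone_mean(c_particle, wound)

  peak_of <- function(arr) {
    i <- arrayInd(which.max(arr), n)
    tibble::tibble(value = arr[i], x = mesh$xc[i[1]], y = mesh$yc[i[2]],
                   z = mesh$zc[i[3]])
  }

  patient_from <- c(0, ip[2], 1.1); patient_to <- c(mesh$room[1], ip[2], 1.1)
  surgeon_from <- c(tb$x[1], tb$y[1], 1.5); surgeon_to <- c(tb$x[2], tb$y[1], 1.5)
  profiles <- dplyr::bind_rows(
    dplyr::mutate(extract_profile(Ytot, mesh, patient_from, patient_to),
                  line = "patient_z1.1", quantity = "waste_gas_mass_fraction"),
    dplyr::mutate(extract_profile(c_particle, mesh, patient_from, patient_to),
                  line = "patient_z1.1", quantity = "particle_gm3"),
    dplyr::mutate(extract_profile(c_tar, mesh, patient_from, patient_to),
                  line = "patient_z1.1", quantity = "tar_gm3"),
    dplyr::mutate(extract_profile(c_particle, mesh, surgeon_from, surgeon_to),
                  line = "surgeon_z1.5", quantity = "particle_gm3"),
    dplyr::mutate(extract_profile(c_tar, mesh, surgeon_from, surgeon_to),
                  line = "surgeon_z1.5", quantity = "tar_gm3")
  )
  class(profiles) <- c("smoke_profiles", class(profiles))

  zones <- classify_zones(field)
  thr <- thresholds
  flags <- tibble::tibble(
    flag = c("surgeon_co_over_epa9", "surgeon_co_over_50",
             "surgeon_co_over_200", "wound_tar_over_20",
             "wound_particle_over_12"),
    value = c(surgeon_co, surgeon_co, surgeon_co, wound_tar, wound_particle),
    threshold = c(thr$co_ppm[["epa_8h"]], thr$co_ppm[["surgeon_50"]],
                  thr$co_ppm[["surgeon_200"]], thr$tar_gm3, thr$particle_gm3),
    exceeded = .data$value > .data$threshold
  )

  structure(
    list(
      tip_temp = if (!is.null(field$source)) field$source$spec$temperature else NA_real_,
      H_smoke = as.numeric(H), H_flag = attr(H, "flag"),
      surgeon_co_ppm = surgeon_co, wound_co_ppm = wound_co,
      wound_tar_gm3 = wound_tar, wound_particle_gm3 = wound_particle,
      peaks = dplyr::bind_rows(
        dplyr::mutate(peak_of(ppm), quantity = "co_ppm"),
        dplyr::mutate(peak_of(c_tar), quantity = "tar_gm3"),
        dplyr::mutate(peak_of(c_particle), quantity = "particle_gm3")
      ),
      profiles = profiles,
      flags = flags,
      zone_volumes = zone_volumes(zones, mesh),
      converged = field$converged
    ),
    class = "exposure_report"
  )
}

#' @export
print.exposure_report <- function(x, ...) {
  cat("<exposure_report>",
      if (is.finite(x$tip_temp)) sprintf("tip temperature %g degC", x$tip_temp),
      "\n")
  cat(sprintf("  H_smoke: %s m (%s)\n",
              format(x$H_smoke, digits = 4), x$H_flag))
  cat(sprintf("  surgeon zone CO: %s ppm   wound CO: %s ppm\n",
              format(x$surgeon_co_ppm, digits = 4),
              format(x$wound_co_ppm, digits = 4)))
  cat(sprintf("  wound tar: %s g/m^3   wound particles: %s g/m^3\n",
              format(x$wound_tar_gm3, digits = 4),
              format(x$wound_particle_gm3, digits = 4)))
  ex <- x$flags[x$flags$exceeded, "flag", drop = TRUE]
  cat("  thresholds exceeded:",
      if (length(ex) > 0) paste(ex, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' @rdname build_report
#' @param x an `exposure_report`.
#' @param ... unused.
#' @export
tidy.exposure_report <- function(x, ...) {
  tibble::tibble(
    metric = c("H_smoke_m", "surgeon_co_ppm", "wound_co_ppm",
               "wound_tar_gm3", "wound_particle_gm3"),
    value = c(x$H_smoke, x$surgeon_co_ppm, x$wound_co_ppm,
              x$wound_tar_gm3, x$wound_particle_gm3)
  )
}

#' @rdname build_report
#' @export
glance.exposure_report <- function(x, ...) {
  tibble::tibble(tip_temp = x$tip_temp, H_smoke = x$H_smoke,
                 flags_exceeded = sum(x$flags$exceeded),
                 converged = x$converged)
}
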