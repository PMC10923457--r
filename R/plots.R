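#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the fitted calibration curves over their data
#'
#' @param object a `smoke_calibration` from [fit_calibration()].
#' @param ... unused.
#' @return a ggplot faceted by response.
#' @export
autoplot.smoke_calibration <- function(object, ...) {
  dat <- tidyr::pivot_longer(
    object$records[, c("power", "tip_temp", "waste_gas_flow",
                       "particle_rate", "tar_rate")],
    -"power", names_to = "response", values_to = "value")
  pgrid <- seq(min(dat$power), max(dat$power), length.out = 100)
  calib <- object$calibration
  curves <- dplyr::bind_rows(
    tibble::tibble(response = "tip_temp", power = pgrid,
                   value = eval_tip_temperature(pgrid, calib)),
    tibble::tibble(response = "waste_gas_flow", power = pgrid,
                   value = eval_waste_gas_flow(pgrid, calib)),
    tibble::tibble(response = "particle_rate", power = pgrid,
                   value = eval_particle_rate(pgrid, calib, clamp = FALSE)),
    tibble::tibble(response = "tar_rate", power = pgrid,
                   value = eval_tar_rate(pgrid, calib))
  )
  ggplot2::ggplot(dat, ggplot2::aes(.data$power, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curves, colour = "steelblue") +
    ggplot2::facet_wrap(~response, scales = "free_y") +
    ggplot2::labs(x = "knife power (W)", y = NULL,
                  title = "Calibration polynomial fits")
}

#' Plot nose-height concentration profiles
#'
#' @param object the `profiles` tibble of an `exposure_report` (class
#'   `smoke_profiles`).
#' @param ... unused.
#' @return a ggplot faceted by sampled line and quantity.
#' @export
autoplot.smoke_profiles <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$position, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(quantity ~ line, scales = "free") +
    ggplot2::labs(x = "position along line (m)", y = NULL,
                  title = "Nose-height profiles")
}

#' Plot the ascent-height curve
#'
#' @param object an `hsmoke_fit`.
#' @param show_published overlay the published quadratic.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.hsmoke_fit <- function(object, show_published = TRUE, ...) {
  tgrid <- seq(min(object$points$tip_temp), max(object$points$tip_temp),
               length.out = 100)
  fit_curve <- tibble::tibble(
    tip_temp = tgrid,
    H_smoke = polyval_asc(object$coefficients, tgrid),
    curve = "fitted"
  )
  curves <- fit_curve
  if (show_published) {
    curves <- dplyr::bind_rows(
      fit_curve,
      tibble::tibble(tip_temp = tgrid, H_smoke = hsmoke_published(tgrid),
                     curve = "published")
    )
  }
  ggplot2::ggplot(object$points,
                  ggplot2::aes(.data$tip_temp, .data$H_smoke)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(linetype = .data$curve)) +
    ggplot2::labs(x = "tip temperature (degC)",
                  y = "maximum smoke ascent height (m)",
                  title = "Smoke ascent height vs knife tip temperature")
}

#' Vertical-velocity slice through the incision
#'
#' Filled contour of `w` on the vertical plane through the incision, the
#' view in which the upwelling column, the laminar curtain and the wall
#' convection zones are visible.
#'
#' @param field a `field_state`.
#' @param axis `"x"` (plane y = y_incision) or `"y"`.
#' @return a ggplot.
#' @export
plot_w_slice <- function(field, axis = c("x", "y")) {
  axis <- match.arg(axis)
  mesh <- field$mesh
  ip <- mesh$scene$incision_point
  if (axis == "x") {
    j <- locate_cell(mesh, ip)[2]
    df <- tidyr::expand_grid(z = mesh$zc, x = mesh$xc)
    df$w <- as.vector(field$w[, j, ])
    df$solid <- as.vector(mesh$solid[, j, ])
    xlab <- "x (m)"
  } else {
    i <- locate_cell(mesh, ip)[1]
    df <- tidyr::expand_grid(z = mesh$zc, x = mesh$yc)
    df$w <- as.vector(field$w[i, , ])
    df$solid <- as.vector(mesh$solid[i, , ])
    xlab <- "y (m)"
  }
  df$w[df$solid] <- NA
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$z, fill = .data$w)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  na.value = "grey40") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = xlab, y = "z (m)", fill = "w (m/s)",
                  title = "Vertical velocity through the incision plane")
}
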