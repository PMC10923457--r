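#' Design of a synthetic in vitro power sweep
#'
#' Describes a simulated cutting experiment: the knife powers visited, the
#' relative measurement noise, the number of replicate cuts per power and the
#' random seed. Defaults mirror the in vitro protocol: powers 20--80 W in
#' 10 W steps, a single cut per power, and a 2% coefficient of variation
#' (the study reported no replicate counts or measurement uncertainties, so
#' the noise level is a declared assumption).
#'
#' @param powers numeric, distinct positive knife powers (W).
#' @param noise_cv multiplicative noise coefficient of variation, `>= 0`.
#' @param replicate_count replicates per power, `>= 1`.
#' @param seed integer random seed.
#' @return A `sweep_design` list.
#' @export
sweep_design <- function(powers = seq(20, 80, by = 10), noise_cv = 0.02,
                         replicate_count = 1, seed = 1L) {
  if (any(powers <= 0) || anyDuplicated(powers)) {
    abort("`powers` must be positive and distinct")
  }
  if (noise_cv < 0) abort("`noise_cv` must be >= 0")
  if (replicate_count < 1) abort("`replicate_count` must be >= 1")
  structure(
    list(powers = as.numeric(powers), noise_cv = noise_cv,
         replicate_count = as.integer(replicate_count), seed = as.integer(seed)),
    class = "sweep_design"
  )
}

# Independent substream per response: adding a response never perturbs the
# noise drawn for the others under the same design seed.
response_substream_seed <- function(seed, response) {
  offsets <- c(tip_temp = 1L, waste_gas_flow = 2L, particle_rate = 3L,
               tar_rate = 4L)
  (as.integer(seed) * 101L + offsets[[response]] * 10007L) %% .Machine$integer.max
}

#' Generate a synthetic power sweep
#'
#' Simulates one in vitro sweep: for every power and replicate each response
#' is the truth polynomial perturbed by multiplicative Gaussian noise,
#' `value = truth * (1 + N(0, noise_cv))`, clamped below at zero (a weighed
#' tar mass or metered flow cannot be negative). Multiplicative noise is used
#' because the four responses span several orders of magnitude, making
#' relative error the natural scale. Output is reproducible for a fixed
#' design seed.
#'
#' @param design a [sweep_design()].
#' @param truth the generating [calibration_set()].
#' @return A tibble with columns `power`, `replicate`, `tip_temp`,
#'   `waste_gas_flow`, `particle_rate`, `tar_rate` — the in-memory
#'   power-sweep format consumed by [fit_calibration()].
#' @examples
#' generate_sweep(sweep_design(noise_cv = 0, seed = 42))
#' @export
generate_sweep <- function(design, truth = default_calibration()) {
  stopifnot(inherits(design, "sweep_design"))
  grid <- tidyr::expand_grid(power = design$powers,
                             replicate = seq_len(design$replicate_count))
  truths <- list(
    tip_temp = eval_tip_temperature(grid$power, truth),
    waste_gas_flow = eval_waste_gas_flow(grid$power, truth),
    particle_rate = eval_particle_rate(grid$power, truth, clamp = FALSE),
    tar_rate = eval_tar_rate(grid$power, truth)
  )
  noisy <- purrr::imap(truths, function(mu, nm) {
    eps <- withr_seed_rnorm(response_substream_seed(design$seed, nm),
                            n = length(mu), sd = design$noise_cv)
    pmax(mu * (1 + eps), 0)
  })
  dplyr::bind_cols(grid, tibble::as_tibble(noisy))
}

# rnorm under a local seed without disturbing the caller's RNG state
withr_seed_rnorm <- function(seed, n, sd) {
  if (sd == 0) return(rep(0, n))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  rnorm(n, mean = 0, sd = sd)
}

#' Monte-Carlo recovery experiment for the calibration fit
#'
#' Repeatedly generates a synthetic sweep and refits the calibration,
#' summarising how well each polynomial coefficient is recovered. Trial `t`
#' uses design seed `design$seed + t` so trials are independent yet the whole
#' experiment is reproducible.
#'
#' @param design a [sweep_design()].
#' @param truth the generating [calibration_set()].
#' @param trials number of generate-and-fit trials, `>= 1`.
#' @return A tibble with one row per response coefficient: `response`,
#'   `term`, `truth`, `mean_estimate`, `bias`, `rmse`, `se_bias` (Monte-Carlo
#'   standard error of the bias) and `trials`.
#' @export
recovery_experiment <- function(design, truth = default_calibration(),
                                trials = 100) {
  stopifnot(trials >= 1)
  truth_tbl <- tibble::tibble(
    response = rep(c("tip_temp", "waste_gas_flow", "particle_rate", "tar_rate"),
                   times = c(3, 3, 4, 4)),
    term = c(paste0("power^", 0:2), paste0("power^", 0:2),
             paste0("power^", 0:3), paste0("power^", 0:3)),
    truth = c(truth$temp_coeffs, truth$flow_coeffs,
              truth$particle_coeffs, truth$tar_coeffs)
  )
  est <- purrr::map_dfr(seq_len(trials), function(t) {
    d <- design
    d$seed <- design$seed + t
    fit <- fit_calibration(generate_sweep(d, truth))
    dplyr::mutate(tidy(fit)[, c("response", "term", "estimate")], trial = t)
  })
  est |>
    dplyr::left_join(truth_tbl, by = c("response", "term")) |>
    dplyr::group_by(.data$response, .data$term, .data$truth) |>
    dplyr::summarise(
      mean_estimate = mean(.data$estimate),
      bias = mean(.data$estimate - .data$truth),
      rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
      se_bias = if (trials > 1) sd(.data$estimate) / sqrt(trials) else 0,
      .groups = "drop"
    ) |>
    dplyr::mutate(trials = trials)
}
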