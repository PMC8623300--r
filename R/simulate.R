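# Seed-reproducible synthetic herbarium collections.
#
# Generative chain per specimen:
#   site (latitude, longitude, elevation) -> year -> climate
#   (spring Tmax declining with elevation + noise; winter PPT
#   log-normal) -> latent reproductive stage u ~ Uniform(0, 3),
#   PI_true = 1 + u -> organ totals ~ negative binomial, composition ~
#   multinomial with a Gaussian stage kernel over the class indices ->
#   DOY = alpha + beta_year (year - 1950) + beta_tmax Tmax
#   + beta_ppt PPT + d (PI_manual - 1) + Normal(0, residual_sd)
#   -> detector counts by class-specific binomial thinning.
# DOY is driven by the phenological status the sheet displays (the PI of
# its manual counts), so the progression rate d is the true coefficient
# of the PI covariate the downstream models see.

#' Configuration of a synthetic herbarium collection
#'
#' Bundles and validates every generative parameter of
#' \code{\link{simulate_collection}}.  Defaults emulate a western North
#' American montane annual sampled over the twentieth century: per-class
#' organ means of 27.4 buds / 28.5 flowers / 11.0 immature fruits /
#' 12.5 mature fruits per sheet, detector recall of 0.16 / 0.22 / 0.30 /
#' 0.28 predicted per manual organ, a flowering-date model with climate
#' sensitivities of -5.3 days/degree C (spring Tmax) and +0.0072 days/mm
#' (winter PPT), a temporal shift of -0.10 days/year, a phenological
#' progression rate of 17 days per PI unit, and 15 days of residual
#' scatter.
#'
#' @param n_specimens Number of sheets to generate.
#' @param seed Integer seed; \code{NULL} leaves the RNG stream alone.
#' @param year_range Calendar-year range sampled uniformly.
#' @param latitude_range,longitude_range,elevation_range Site windows
#'   (degrees, degrees, metres).
#' @param tmax_intercept,tmax_lapse,tmax_sd Spring Tmax model:
#'   mean = intercept + lapse x elevation, plus Normal(0, sd) site-year
#'   noise (degrees C; lapse in degrees C/m).
#' @param ppt_meanlog,ppt_sdlog Winter PPT log-normal parameters (mm).
#' @param alpha Baseline DOY (days) at year 1950, Tmax 0, PPT 0, stage 0.
#' @param beta_year Temporal shift (days/year).
#' @param beta_tmax Temperature sensitivity (days/degree C).
#' @param beta_ppt Precipitation sensitivity (days/mm).
#' @param progression Days per PI unit of phenological progression.
#' @param residual_sd Residual DOY scatter (days).
#' @param class_means Marginal mean organ count per class (organs/sheet).
#' @param dispersion Negative-binomial size parameter of the per-sheet
#'   organ total (smaller = more overdispersed).
#' @param tau Width of the Gaussian stage kernel over class indices
#'   (PI units); controls how mixed the composition is around the
#'   latent stage.
#' @param detection_probs Per-class probability that the detector finds
#'   a manually counted organ (binomial thinning rates), in (0, 1].
#' @param age_error_rate Optional relative drift of detection
#'   probability per year of specimen age: effective
#'   p_k x (1 + rate x (year - 2000)), clamped to [0, 1].  Default 0
#'   (no age effect).
#' @return A validated \code{simulation_config} object (list).
#' @export
simulation_config <- function(n_specimens = 709,
                              seed = NULL,
                              year_range = c(1900, 2013),
                              latitude_range = c(35.5, 41.5),
                              longitude_range = c(-122.5, -118),
                              elevation_range = c(150, 3200),
                              tmax_intercept = 26,
                              tmax_lapse = -0.0065,
                              tmax_sd = 1.5,
                              ppt_meanlog = log(600),
                              ppt_sdlog = 0.55,
                              alpha = 232,
                              beta_year = -0.10,
                              beta_tmax = -5.3,
                              beta_ppt = 0.0072,
                              progression = 17,
                              residual_sd = 15,
                              class_means = c(buds = 27.4, flowers = 28.5,
                                              immature_fruits = 11.0,
                                              mature_fruits = 12.5),
                              dispersion = 3,
                              tau = 0.6,
                              detection_probs = c(buds = 0.16,
                                                  flowers = 0.22,
                                                  immature_fruits = 0.30,
                                                  mature_fruits = 0.28),
                              age_error_rate = 0) {
  cfg <- list(n_specimens = n_specimens, seed = seed,
              year_range = year_range, latitude_range = latitude_range,
              longitude_range = longitude_range,
              elevation_range = elevation_range,
              tmax_intercept = tmax_intercept, tmax_lapse = tmax_lapse,
              tmax_sd = tmax_sd, ppt_meanlog = ppt_meanlog,
              ppt_sdlog = ppt_sdlog, alpha = alpha,
              beta_year = beta_year, beta_tmax = beta_tmax,
              beta_ppt = beta_ppt, progression = progression,
              residual_sd = residual_sd, class_means = class_means,
              dispersion = dispersion, tau = tau,
              detection_probs = detection_probs,
              age_error_rate = age_error_rate)
  .validate_sim_config(cfg)
  structure(cfg, class = "simulation_config")
}

.validate_sim_config <- function(cfg) {
  stop_cfg <- function(...) stop("invalid simulation config: ", ...,
                                 call. = FALSE)
  if (!is.numeric(cfg$n_specimens) || length(cfg$n_specimens) != 1L ||
      cfg$n_specimens < 1 ||
      abs(cfg$n_specimens - round(cfg$n_specimens)) > 1e-8)
    stop_cfg("n_specimens must be a positive integer")
  if (!is.null(cfg$seed) &&
      (!is.numeric(cfg$seed) || length(cfg$seed) != 1L))
    stop_cfg("seed must be a single number or NULL")
  for (rg in c("year_range", "latitude_range", "longitude_range",
               "elevation_range")) {
    v <- cfg[[rg]]
    if (!is.numeric(v) || length(v) != 2L || v[1L] > v[2L])
      stop_cfg(rg, " must be numeric c(min, max)")
  }
  if (length(cfg$class_means) != 4L || any(cfg$class_means <= 0))
    stop_cfg("class_means must be 4 positive means")
  if (length(cfg$detection_probs) != 4L ||
      any(cfg$detection_probs <= 0) || any(cfg$detection_probs > 1))
    stop_cfg("detection_probs must be 4 probabilities in (0, 1]")
  if (!is.numeric(cfg$tau) || cfg$tau <= 0)
    stop_cfg("tau must be positive")
  if (!is.numeric(cfg$dispersion) || cfg$dispersion <= 0)
    stop_cfg("dispersion must be positive")
  if (!is.numeric(cfg$residual_sd) || cfg$residual_sd < 0)
    stop_cfg("residual_sd must be non-negative")
  if (!is.numeric(cfg$ppt_sdlog) || cfg$ppt_sdlog < 0)
    stop_cfg("ppt_sdlog must be non-negative")
  if (!is.numeric(cfg$tmax_sd) || cfg$tmax_sd < 0)
    stop_cfg("tmax_sd must be non-negative")
  invisible(cfg)
}

# Expected kernel mass per class under u ~ Uniform(0, 3):
# kappa_k = (1/3) integral_0^3 exp(-(k - 1 - u)^2 / (2 tau^2)) du.
# Scaling each class's kernel by class_mean / kappa_k makes the marginal
# expected count of class k equal class_mean_k exactly, while the
# within-sheet composition still tracks the latent stage.
.kernel_mass <- function(tau) {
  k <- 1:4
  tau * sqrt(2 * pi) / 3 *
    (stats::pnorm((k - 1) / tau) - stats::pnorm((k - 4) / tau))
}

# n x 4 matrix of stage-conditional expected class counts.
.stage_class_intensity <- function(pi_true, tau, class_means) {
  kappa <- .kernel_mass(tau)
  k <- 1:4
  kern <- exp(-outer(pi_true, k, function(p, k) (k - p)^2) / (2 * tau^2))
  sweep(kern, 2L, unname(class_means) / kappa, `*`)
}

#' Simulate a synthetic herbarium collection
#'
#' Draws \code{n_specimens} sheets from the generative model described
#' in \code{\link{simulation_config}}: site and year, climate, a latent
#' reproductive stage \code{u ~ Uniform(0, 3)} with
#' \code{PI_true = 1 + u}, per-sheet organ totals from a negative
#' binomial whose mean follows the stage-conditional class intensities
#' (zero totals are redrawn: a scored collection contains fertile
#' sheets only), a multinomial split of the total across classes with a
#' Gaussian kernel centred on the latent stage, a collection DOY driven
#' linearly by year, climate, and the displayed phenological status —
#' the PI of the manual counts — clamped to \[1, 366\], and detector
#' counts by class-specific binomial thinning of the manual counts.
#' Driving DOY by the displayed PI (rather than the latent stage) makes
#' the configured progression rate the true coefficient of the PI
#' covariate that downstream regressions estimate.
#'
#' Output is byte-reproducible for a fixed seed; sub-draws are ordered
#' site, year, climate, stage, totals, composition, DOY, thinning.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return Specimen table (canonical schema, see
#'   \code{\link{specimen_columns}}) with two extra generator-only
#'   columns: \code{stage} (latent u) and \code{pi_true}.
#' @export
simulate_collection <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- as.integer(config$n_specimens)

  latitude <- runif(n, config$latitude_range[1L], config$latitude_range[2L])
  longitude <- runif(n, config$longitude_range[1L],
                     config$longitude_range[2L])
  elevation <- runif(n, config$elevation_range[1L],
                     config$elevation_range[2L])
  year <- sample(seq(config$year_range[1L], config$year_range[2L]), n,
                 replace = TRUE)
  spring_tmax <- config$tmax_intercept + config$tmax_lapse * elevation +
    stats::rnorm(n, 0, config$tmax_sd)
  winter_ppt <- stats::rlnorm(n, config$ppt_meanlog, config$ppt_sdlog)

  u <- runif(n, 0, 3)
  pi_true <- 1 + u

  intensity <- .stage_class_intensity(pi_true, config$tau,
                                      config$class_means)
  mu_total <- rowSums(intensity)
  total <- stats::rnbinom(n, size = config$dispersion, mu = mu_total)
  redraw <- which(total == 0L)
  while (length(redraw)) {
    total[redraw] <- stats::rnbinom(length(redraw),
                                    size = config$dispersion,
                                    mu = mu_total[redraw])
    redraw <- redraw[total[redraw] == 0L]
  }
  manual <- t(vapply(seq_len(n),
                     function(i) stats::rmultinom(1L, total[i],
                                                  intensity[i, ])[, 1L],
                     integer(4L)))
  pi_manual <- as.numeric(manual %*% organ_classes()) / total

  doy <- config$alpha + config$beta_year * (year - 1950) +
    config$beta_tmax * spring_tmax + config$beta_ppt * winter_ppt +
    config$progression * (pi_manual - 1) +
    stats::rnorm(n, 0, config$residual_sd)
  doy <- as.integer(pmin(pmax(round(doy), 1), 366))

  p_eff <- matrix(rep(unname(config$detection_probs), each = n), nrow = n)
  if (config$age_error_rate != 0) {
    p_eff <- p_eff * (1 + config$age_error_rate * (year - 2000))
    p_eff <- pmin(pmax(p_eff, 0), 1)
  }
  pred <- matrix(0L, nrow = n, ncol = 4L)
  for (k in 1:4)
    pred[, k] <- stats::rbinom(n, manual[, k], p_eff[, k])

  out <- data.frame(id = sprintf("SYN%05d", seq_len(n)),
                    year = year, doy = doy,
                    latitude = latitude, longitude = longitude,
                    elevation = elevation, spring_tmax = spring_tmax,
                    winter_ppt = winter_ppt,
                    stringsAsFactors = FALSE)
  out[.count_cols("manual")] <- as.data.frame(manual)
  out[.count_cols("predicted")] <- as.data.frame(pred)
  out$stage <- u
  out$pi_true <- pi_true
  validate_specimens(out)
  out
}

#' Tiny deterministic example collection
#'
#' A 25-sheet synthetic collection generated with a fixed seed, for
#' examples and unit tests; every sheet is fertile (organ total at
#' least 1), so every PI is defined.
#'
#' @return Specimen table of 25 rows.
#' @export
fixture_small <- function() {
  simulate_collection(simulation_config(n_specimens = 25, seed = 421))
}
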