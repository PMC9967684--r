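#' Draw the latent true vitamin D intake
#'
#' Generates the unobservable true habitual intake T of each subject as a
#' log-normal variable with the configured median and log-scale SD, the
#' right-skewed shape typical of nutrient intake distributions.  T is the
#' ground truth every downstream validity estimate is judged against.
#'
#' @param config a [cohort_config()].
#' @return numeric vector of length `n_subjects`, ug/day; deterministic
#'   given `config$seed`.
#' @export
#' @examples
#' t <- generate_latent_truth(cohort_config(n_subjects = 500, seed = 7))
#' median(t)
generate_latent_truth <- function(config) {
  config <- validate_cohort_config(config)
  set.seed(stage_seed(config$seed, "truth"))
  exp(stats::rnorm(config$n_subjects,
                   mean = log(config$true_intake_median),
                   sd = config$true_intake_log_sd))
}

#' Closed-form error scales for a target correlation with truth
#'
#' For an additive measurement model `X = alpha + lambda * T + eps` with
#' `eps` independent of `T`, the Pearson correlation of X with T equals
#' `lambda * sd_T / sqrt(lambda^2 sd_T^2 + sigma^2)`.  Inverting gives the
#' noise SD that attains a target correlation `rho`:
#' `sigma = lambda * sd_T * sqrt(1/rho^2 - 1)`.
#'
#' This closed form is exact on the scale on which the model is additive
#' (the generator uses the log-intake scale) and serves as the starting
#' point for the rank-scale calibration in [simulate_cohort()].
#'
#' @param target_vc numeric vector of target correlations, each in (0, 1].
#' @param latent_sd SD of T on the additive scale.
#' @param lambda proportionality constant(s), default 1.
#' @return numeric vector of noise SDs, one per target.
#' @export
#' @examples
#' solve_error_scales(c(q = 0.5), latent_sd = 1)  # sqrt(3)
solve_error_scales <- function(target_vc, latent_sd, lambda = 1) {
  target_vc <- unlist(target_vc)
  if (any(!is.finite(target_vc)) || any(target_vc <= 0) || any(target_vc > 1))
    stopf("target correlations must lie in (0, 1]; rho = 0 leaves the noise scale undefined")
  if (latent_sd < 0) stopf("latent_sd must be >= 0")
  lambda * latent_sd * sqrt(1 / target_vc^2 - 1)
}

# Calibrate the three noise scales so the *Spearman* correlation of each
# measurement with T hits its target.  The analysis battery is rank-based
# throughout, so the generator is calibrated on the rank scale by
# simulation (monotone root finding) rather than by Gaussian-copula
# algebra: each channel's achieved Spearman correlation is a strictly
# decreasing function of its noise SD, and uniroot solves it on a large
# deterministic calibration sample.
calibrate_error_scales <- function(config) {
  config <- validate_cohort_config(config)
  n <- config$n_calibration
  set.seed(stage_seed(config$seed, "calibration"))
  logT <- stats::rnorm(n, log(config$true_intake_median),
                       config$true_intake_log_sd)
  T <- exp(logT)
  ses <- pmax(0, stats::rnorm(n, config$ses_mean, config$ses_sd))
  bmi <- exp(stats::rnorm(n, log(config$bmi_median), config$bmi_log_sd))
  urban <- stats::rbinom(n, 1, config$urban_fraction)
  epsq <- stats::rnorm(n); epsr <- stats::rnorm(n); epsb <- stats::rnorm(n)

  tv <- config$target_vc
  lsd <- config$true_intake_log_sd

  solve_channel <- function(target, achieved, upper) {
    if (target == 1) return(0)
    f <- function(s) achieved(s) - target
    if (f(0) <= 0)
      stopf(paste("target Spearman correlation %.3f with truth is not",
                  "attainable: the noiseless channel already correlates",
                  "below the target"), target)
    while (f(upper) > 0 && upper < 1e3) upper <- upper * 2
    stats::uniroot(f, c(1e-9, upper), tol = 1e-4)$root
  }

  sq <- solve_channel(tv[["q"]], function(s)
    corr2(logT + s * epsq, T), 10 * max(solve_error_scales(tv[["q"]], lsd), 0.1))
  sr <- solve_channel(tv[["r"]], function(s)
    corr2(logT + s * epsr, T), 10 * max(solve_error_scales(tv[["r"]], lsd), 0.1))

  co <- config$status_coefs
  pred <- co[["intercept"]] + co[["intake"]] * T + co[["ses"]] * ses +
    co[["bmi"]] * bmi + co[["urban"]] * urban
  sb <- solve_channel(tv[["b"]], function(s)
    corr2(pmax(config$b_floor, pred * exp(s * epsb - s^2 / 2)), T), 0.5)

  c(q = sq, r = sr, b = sb)
}

#' Generate the three measurements from latent truth and covariates
#'
#' The FFQ intake Q and food-record intake R follow additive
#' measurement-error models on the log-intake scale,
#' `log X = alpha_X + log T + sigma_X * eps`, with mutually independent
#' normal errors; Q additionally carries the configured multiplicative
#' FFQ bias.  Serum 25(OH)D is generated from the linear status model on
#' (T, SES, BMI, urban residence) with multiplicative log-normal noise,
#' which keeps concentrations positive and right-skewed.  All outputs are
#' floored at the configured small positive values and the flooring rate
#' is reported as an attribute.
#'
#' @param T latent true intake, ug/day.
#' @param ses,bmi,urban covariate vectors of the same length as `T`
#'   (`urban` coded 0/1).
#' @param config a [cohort_config()].
#' @param scales named noise SDs `c(q=, r=, b=)`; when `NULL` they are
#'   calibrated from `config` by [simulate_cohort()]'s rank-scale routine.
#' @return data.frame with columns `Q`, `R`, `B` and attribute
#'   `floor_rates` (named proportions of floored values per channel).
#' @export
generate_measurements <- function(T, ses, bmi, urban, config, scales = NULL) {
  n <- length(T)
  if (length(ses) != n || length(bmi) != n || length(urban) != n)
    stopf("T, ses, bmi and urban must have equal length (got %d, %d, %d, %d)",
          n, length(ses), length(bmi), length(urban))
  if (any(T <= 0)) stopf("latent intake T must be positive")
  if (is.null(scales)) scales <- calibrate_error_scales(config)
  scales <- unlist(scales)

  logT <- log(T)
  Qraw <- exp(log(config$q_median_ratio) + logT + scales[["q"]] * stats::rnorm(n))
  Rraw <- exp(logT + scales[["r"]] * stats::rnorm(n))
  co <- config$status_coefs
  pred <- co[["intercept"]] + co[["intake"]] * T + co[["ses"]] * ses +
    co[["bmi"]] * bmi + co[["urban"]] * urban
  sb <- scales[["b"]]
  Braw <- pred * exp(sb * stats::rnorm(n) - sb^2 / 2)

  out <- data.frame(Q = pmax(config$intake_floor, Qraw),
                    R = pmax(config$intake_floor, Rraw),
                    B = pmax(config$b_floor, Braw))
  attr(out, "floor_rates") <- c(Q = mean(Qraw < config$intake_floor),
                                R = mean(Rraw < config$intake_floor),
                                B = mean(Braw < config$b_floor))
  out
}

# Person-level covariates: age, employment, education, localization,
# height/weight/BMI, phototype, and the sun-exposure score target.  SES is
# snapped to the grid reachable by 15 items scored 0..4 under the person's
# phototype factor and the weather index, so the item-level questionnaire
# synthesis can reproduce it exactly.
simulate_covariates <- function(config) {
  n <- config$n_subjects
  set.seed(stage_seed(config$seed, "covariates"))
  age <- round(20 + 24 * stats::rbeta(n, 1.3, 3.2))
  employment <- sample(c("student", "housewife", "professor", "liberal"),
                       n, replace = TRUE,
                       prob = c(0.7246, 0.1831, 0.0790, 0.0133))
  education <- sample(c("primary", "secondary", "university"),
                      n, replace = TRUE, prob = c(0.0988, 0.1644, 0.7368))
  localization <- ifelse(stats::runif(n) < config$urban_fraction,
                         "urban", "rural")
  height <- round(stats::rnorm(n, 1.64, 0.05), 2)
  bmi <- exp(stats::rnorm(n, log(config$bmi_median), config$bmi_log_sd))
  weight <- bmi * height^2
  phototype <- sample(names(config$phototype_factor_map), n, replace = TRUE,
                      prob = c(0.02, 0.08, 0.35, 0.35, 0.15, 0.05))
  pfac <- unname(config$phototype_factor_map[phototype])

  ses_target <- pmax(0, stats::rnorm(n, config$ses_mean, config$ses_sd))
  step <- pfac * config$weather_index           # SES per unit item total
  total <- pmin(60L, pmax(0L, as.integer(round(ses_target / step))))
  ses <- total * step

  data.frame(id = sprintf("P%04d", seq_len(n)), age = age,
             employment = employment, education = education,
             localization = localization, height = height,
             weight = weight, bmi = bmi, phototype = phototype,
             phototype_factor = pfac, seq_total = total, ses = ses,
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic validation cohort
#'
#' Draws the latent true intake, person-level covariates, and the three
#' measurements (FFQ intake Q, 7-day food-record intake R, serum 25(OH)D
#' B), with noise scales calibrated by simulation so the Spearman
#' correlation of each measurement with truth matches `config$target_vc`.
#'
#' @param config a [cohort_config()].
#' @return a `vitd_cohort` data.frame with one row per person and columns
#'   `id, age, employment, education, localization, height, weight, bmi,
#'   phototype, ses, T, Q, R, B`.  Attributes: `config`, `scales`
#'   (calibrated noise SDs) and `floor_rates`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(n_subjects = 200, seed = 3))
#' summary(coh$Q)
simulate_cohort <- function(config) {
  config <- validate_cohort_config(config)
  T <- generate_latent_truth(config)
  cov <- simulate_covariates(config)
  scales <- calibrate_error_scales(config)
  set.seed(stage_seed(config$seed, "measurement"))
  meas <- generate_measurements(T, cov$ses, cov$bmi,
                                as.integer(cov$localization == "urban"),
                                config, scales = scales)
  out <- cbind(cov[c("id", "age", "employment", "education", "localization",
                     "height", "weight", "bmi", "phototype",
                     "phototype_factor", "seq_total", "ses")],
               T = T, meas)
  class(out) <- c("vitd_cohort", "data.frame")
  attr(out, "config") <- config
  attr(out, "scales") <- scales
  attr(out, "floor_rates") <- attr(meas, "floor_rates")
  out
}

#' @export
print.vitd_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Synthetic validation cohort: %d subjects (seed %d)\n",
              nrow(x), cfg$seed))
  cat(sprintf("  median Q %.2f, R %.2f ug/day; median 25(OH)D %.2f ng/mL\n",
              stats::median(x$Q), stats::median(x$R), stats::median(x$B)))
  fr <- attr(x, "floor_rates")
  cat(sprintf("  floor rates: Q %.2f%%, R %.2f%%, B %.2f%%\n",
              100 * fr[["Q"]], 100 * fr[["R"]], 100 * fr[["B"]]))
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
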