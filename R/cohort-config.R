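#' Configuration of a synthetic validation cohort
#'
#' Builds and validates the full parameter set of the synthetic cohort
#' generator.  The defaults emulate the statistical structure of a
#' real-world validation study of a vitamin D FFQ in women of
#' reproductive age: a right-skewed habitual intake with median about
#' 6.3 ug/day, low serum 25(OH)D (median about 8.5 ng/mL), sun-exposure
#' scores around 16 +/- 6, median BMI about 26.5 kg/m2, and target
#' validity coefficients (0.90, 0.70, 0.53) for the FFQ, the 7-day food
#' record and the biomarker, which induce pairwise Spearman correlations
#' of roughly (0.64, 0.46, 0.36).
#'
#' @param n_subjects number of persons (>= 4 so quartiles are definable).
#' @param seed integer seed; all randomness of the generator flows from it.
#' @param true_intake_median median of the latent true intake T, ug/day.
#' @param true_intake_log_sd standard deviation of log(T) (dimensionless).
#' @param target_vc named numeric `c(q=, r=, b=)`: target Spearman
#'   correlations of the FFQ (Q), food record (R) and biomarker (B) with
#'   the latent true intake; each in (0, 1].
#' @param status_coefs named numeric `c(intercept=, intake=, ses=, bmi=,
#'   urban=)` generating serum 25(OH)D (ng/mL) linearly from true intake,
#'   sun-exposure score, BMI and urban residence.  The default slopes are
#'   those of the predictive status model (0.56 per ug/day intake, 0.32
#'   per SES unit, 3.17 for urban residence); the intercept is anchored so
#'   the cohort 25(OH)D median sits near 8.5 ng/mL.
#' @param q_median_ratio multiplicative bias of the FFQ relative to the
#'   food record (default 7.10/6.33, the ratio of the two intake medians
#'   the generator emulates).
#' @param ses_mean,ses_sd mean and SD of the sun-exposure score.
#' @param bmi_median,bmi_log_sd median and log-scale SD of BMI (kg/m2).
#' @param urban_fraction proportion of the cohort living in an urban area.
#' @param intake_floor,b_floor positive floors applied to generated
#'   intakes (ug/day) and 25(OH)D (ng/mL); flooring events are counted.
#' @param weather_index multiplicative weather attenuation of the
#'   sun-exposure score, in (0, 1].
#' @param phototype_factor_map named multipliers (> 0) per Fitzpatrick
#'   phototype I..VI applied in the sun-exposure score.
#' @param n_calibration sample size of the rank-scale noise calibration.
#'
#' @return an object of class `cohort_config` (a validated list).
#' @seealso [simulate_cohort()], [generate_latent_truth()],
#'   [solve_error_scales()]
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 152, seed = 1)
#' cfg$target_vc
cohort_config <- function(n_subjects = 152L,
                          seed = 1L,
                          true_intake_median = 6.33,
                          true_intake_log_sd = 0.5,
                          target_vc = c(q = 0.90, r = 0.70, b = 0.53),
                          status_coefs = c(intercept = -2.14, intake = 0.56,
                                           ses = 0.32, bmi = 0, urban = 3.17),
                          q_median_ratio = 7.10 / 6.33,
                          ses_mean = 16, ses_sd = 6,
                          bmi_median = 26.45, bmi_log_sd = 0.21,
                          urban_fraction = 0.618,
                          intake_floor = 0.1, b_floor = 1,
                          weather_index = 0.75,
                          phototype_factor_map = c(I = 1, II = 1, III = 1,
                                                   IV = 1, V = 1, VI = 1),
                          n_calibration = 20000L) {
  target_vc <- unlist(target_vc)
  status_coefs <- unlist(status_coefs)
  phototype_factor_map <- unlist(phototype_factor_map)
  cfg <- list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
              true_intake_median = true_intake_median,
              true_intake_log_sd = true_intake_log_sd,
              target_vc = target_vc, status_coefs = status_coefs,
              q_median_ratio = q_median_ratio,
              ses_mean = ses_mean, ses_sd = ses_sd,
              bmi_median = bmi_median, bmi_log_sd = bmi_log_sd,
              urban_fraction = urban_fraction,
              intake_floor = intake_floor, b_floor = b_floor,
              weather_index = weather_index,
              phototype_factor_map = phototype_factor_map,
              n_calibration = as.integer(n_calibration))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  if (!is_count(cfg$n_subjects) || cfg$n_subjects < 4)
    stopf("n_subjects must be an integer >= 4 (quartiles must be definable)")
  if (!is_number(cfg$seed) || abs(cfg$seed) >= .Machine$integer.max - 10)
    stopf("seed must be a finite integer below 2^31")
  if (!is_number(cfg$true_intake_median) || cfg$true_intake_median <= 0)
    stopf("true_intake_median must be > 0 ug/day")
  if (!is_number(cfg$true_intake_log_sd) || cfg$true_intake_log_sd < 0)
    stopf("true_intake_log_sd must be >= 0")
  tv <- cfg$target_vc
  if (length(tv) != 3L || is.null(names(tv)) ||
      !setequal(names(tv), c("q", "r", "b")))
    stopf("target_vc must be a named triple c(q=, r=, b=)")
  if (any(!is.finite(tv)) || any(tv <= 0) || any(tv > 1))
    stopf("each target validity coefficient must lie in (0, 1]")
  sc <- cfg$status_coefs
  need <- c("intercept", "intake", "ses", "bmi", "urban")
  if (is.null(names(sc)) || !all(need %in% names(sc)))
    stopf("status_coefs must carry names: %s", paste(need, collapse = ", "))
  if (!is_number(cfg$urban_fraction) ||
      cfg$urban_fraction < 0 || cfg$urban_fraction > 1)
    stopf("urban_fraction must lie in [0, 1]")
  if (cfg$intake_floor <= 0 || cfg$b_floor <= 0)
    stopf("floors must be positive")
  if (cfg$weather_index <= 0 || cfg$weather_index > 1)
    stopf("weather_index must lie in (0, 1]")
  if (any(cfg$phototype_factor_map <= 0))
    stopf("phototype factors must be positive")
  if (!is_count(cfg$n_calibration) || cfg$n_calibration < 1000)
    stopf("n_calibration must be an integer >= 1000")
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic validation-cohort configuration\n")
  cat(sprintf("  n = %d subjects, seed = %d\n", x$n_subjects, x$seed))
  cat(sprintf("  latent intake: log-normal, median %.2f ug/day, log-SD %.2f\n",
              x$true_intake_median, x$true_intake_log_sd))
  cat(sprintf("  target validity coefficients: Q %.2f, R %.2f, B %.2f\n",
              x$target_vc[["q"]], x$target_vc[["r"]], x$target_vc[["b"]]))
  cat(sprintf("  status model: B = %.2f + %.2f*T + %.2f*SES + %.2f*BMI + %.2f*urban\n",
              x$status_coefs[["intercept"]], x$status_coefs[["intake"]],
              x$status_coefs[["ses"]], x$status_coefs[["bmi"]],
              x$status_coefs[["urban"]]))
  invisible(x)
}

#' Write / read a cohort configuration as JSON
#'
#' @param cfg a [cohort_config()] object.
#' @param path file path of the JSON sidecar.
#' @return `write_cohort_config` returns `path` invisibly;
#'   `read_cohort_config` returns a validated `cohort_config`.
#' @export
write_cohort_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "cohort_config"))
  out <- unclass(cfg)
  # keep the names of named vectors: serialise them as JSON objects
  for (f in c("target_vc", "status_coefs", "phototype_factor_map"))
    out[[f]] <- as.list(out[[f]])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(cohort_config, raw)
}
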