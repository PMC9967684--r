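#' Classify vitamin D status from serum 25(OH)D
#'
#' Deficient below 20 ng/mL, insufficient in [20, 30), sufficient in
#' [30, 40), optimal at or above 40 ng/mL.  The [30, 40) band sits
#' between the defined insufficiency and optimal thresholds and is
#' labelled "sufficient" by convention.
#'
#' @param b serum 25(OH)D concentration(s), ng/mL, > 0.
#' @return character vector of status categories.
#' @export
#' @examples
#' classify_vitd_status(c(8.48, 20, 40))
classify_vitd_status <- function(b) {
  if (any(!is.finite(b)) || any(b <= 0))
    stopf("serum 25(OH)D must be positive")
  lab <- c("deficient", "insufficient", "sufficient", "optimal")
  lab[1L + (b >= 20) + (b >= 30) + (b >= 40)]
}

#' Classify body-mass index
#'
#' Standard adult bins: underweight below 18.5 kg/m2, normal [18.5, 25),
#' overweight [25, 30), obese at or above 30.  A `severe_obesity`
#' attribute flags BMI in [30, 35) -- an idiosyncratic labelling some
#' cohort descriptions use for that sub-band of obesity.
#'
#' @param bmi BMI value(s), kg/m2, > 0.
#' @return character vector of categories with logical attribute
#'   `severe_obesity`.
#' @export
#' @examples
#' classify_bmi(c(18.5, 26.45, 30))
classify_bmi <- function(bmi) {
  if (any(!is.finite(bmi)) || any(bmi <= 0)) stopf("BMI must be positive")
  lab <- c("underweight", "normal", "overweight", "obese")
  out <- lab[1L + (bmi >= 18.5) + (bmi >= 25) + (bmi >= 30)]
  attr(out, "severe_obesity") <- bmi >= 30 & bmi < 35
  out
}

#' Predictor presets of the serum 25(OH)D status models
#'
#' Model I explains 25(OH)D from FFQ intake, the sun-exposure score and
#' urban residence; Model II from food-record intake, the sun-exposure
#' score and BMI.
#'
#' @param preset `"model1"` or `"model2"`.
#' @return character vector of predictor column names.
#' @export
status_model_preset <- function(preset = c("model1", "model2")) {
  preset <- match.arg(preset)
  if (preset == "model1") c("Q", "ses", "urban") else c("R", "ses", "bmi")
}

#' Fit a predictive linear model of serum 25(OH)D with VIF screening
#'
#' Ordinary least squares of 25(OH)D on the chosen predictors, after
#' removing multicollinear predictors: exactly collinear columns are
#' dropped first (the later-entered column loses), then the predictor
#' with the largest variance inflation factor is removed iteratively
#' while any VIF exceeds 10.  Coefficients are reported with standard
#' errors, two-sided 95% confidence limits and p-values, together with
#' the multiple correlation R, R-squared, and residual diagnostics
#' (Shapiro-Wilk normality and Breusch-Pagan homoscedasticity flags at
#' the 0.05 level).
#'
#' @param data data.frame; must contain `response` and the predictors.
#'   A `localization` column is converted to an `urban` indicator when
#'   `urban` is requested but absent.
#' @param preset `"model1"` or `"model2"` (ignored when `predictors`
#'   is given).
#' @param predictors character vector of predictor columns, in priority
#'   order (earlier columns win collinearity ties).
#' @param response response column, default `"B"`.
#' @param vif_cutoff removal threshold, default 10.
#' @return object of class `status_model`; see [predict.status_model()].
#' @export
#' @examples
#' coh <- data.frame(Q = runif(50, 3, 20), ses = runif(50, 5, 30),
#'                   urban = rbinom(50, 1, 0.6))
#' coh$B <- 0.56 * coh$Q + 0.32 * coh$ses + 3.17 * coh$urban - 8.58
#' coef(fit_status_model(coh, predictors = c("Q", "ses", "urban")))
fit_status_model <- function(data, preset = c("model1", "model2"),
                             predictors = NULL, response = "B",
                             vif_cutoff = 10) {
  if (is.null(predictors)) predictors <- status_model_preset(preset)
  data <- as.data.frame(data)
  if ("urban" %in% predictors && !("urban" %in% names(data)) &&
      "localization" %in% names(data))
    data$urban <- as.integer(data$localization == "urban")
  miss <- setdiff(c(response, predictors), names(data))
  if (length(miss))
    stopf("data lacks column(s): %s", paste(miss, collapse = ", "))
  df <- data[c(response, predictors)]
  cc <- stats::complete.cases(df)
  if (!all(cc)) {
    message(sprintf("dropping %d incomplete case(s)", sum(!cc)))
    df <- df[cc, , drop = FALSE]
  }
  n <- nrow(df)
  if (n < 10 * length(predictors))
    stopf("need >= 10 observations per predictor (%d obs, %d predictors)",
          n, length(predictors))

  removed <- character()

  ## exact collinearity: drop later-entered columns until full rank
  repeat {
    X <- cbind(1, as.matrix(df[predictors]))
    qx <- qr(X)
    if (qx$rank == ncol(X)) break
    # the last-entered predictor involved in the dependency is dropped
    dep <- qx$pivot[(qx$rank + 1):ncol(X)] - 1L
    drop_this <- predictors[max(dep)]
    removed <- c(removed, drop_this)
    predictors <- setdiff(predictors, drop_this)
    if (!length(predictors))
      stopf("all predictors removed as collinear; no model to fit")
  }

  fit_lm <- function(preds) {
    stats::lm(stats::reformulate(preds, response = response), data = df)
  }
  fit <- fit_lm(predictors)

  ## iterative VIF screen
  while (length(predictors) >= 2L) {
    v <- car::vif(fit)
    if (max(v) <= vif_cutoff) break
    worst <- which(v == max(v))
    # tie-break: remove the later-entered predictor
    drop_this <- predictors[max(worst)]
    removed <- c(removed, drop_this)
    predictors <- setdiff(predictors, drop_this)
    fit <- fit_lm(predictors)
  }
  vifs <- if (length(predictors) >= 2L) car::vif(fit) else
    stats::setNames(1, predictors)

  sm <- summary(fit)
  cf <- sm$coefficients
  ci <- stats::confint(fit, level = 0.95)
  coef_table <- data.frame(term = rownames(cf), estimate = cf[, 1],
                           se = cf[, 2], ci_low = ci[, 1], ci_high = ci[, 2],
                           p = cf[, 4], row.names = NULL,
                           stringsAsFactors = FALSE)
  res <- stats::residuals(fit)
  sw_p <- tryCatch(stats::shapiro.test(
    if (length(res) > 5000) res[seq_len(5000)] else res)$p.value,
    error = function(e) NA_real_)
  bp_p <- tryCatch(lmtest::bptest(fit)$p.value, error = function(e) NA_real_)

  structure(list(fit = fit, coef_table = coef_table,
                 predictors = predictors, removed_by_vif = removed,
                 vif = vifs, response = response,
                 r_squared = sm$r.squared,
                 model_r = sqrt(sm$r.squared), n = n,
                 diagnostics = list(shapiro_p = sw_p, bp_p = bp_p,
                                    normal_residuals = isTRUE(sw_p >= 0.05),
                                    homoscedastic = isTRUE(bp_p >= 0.05)),
                 call = match.call()),
            class = "status_model")
}

#' @export
print.status_model <- function(x, ...) {
  cat(sprintf("Predictive model of serum 25(OH)D (n = %d): R = %.3f, R2 = %.3f\n",
              x$n, x$model_r, x$r_squared))
  print(format(x$coef_table, digits = 4), row.names = FALSE)
  if (length(x$removed_by_vif))
    cat("  removed by collinearity/VIF screen:",
        paste(x$removed_by_vif, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.status_model <- function(object, ...) {
  print(object)
  cat(sprintf("  residual diagnostics: Shapiro-Wilk p = %.3g, Breusch-Pagan p = %.3g\n",
              object$diagnostics$shapiro_p, object$diagnostics$bp_p))
  cat(sprintf("  VIF: %s\n",
              paste(sprintf("%s %.2f", names(object$vif), object$vif),
                    collapse = ", ")))
  invisible(object)
}

#' @export
coef.status_model <- function(object, ...) stats::coef(object$fit)

#' @export
residuals.status_model <- function(object, ...) stats::residuals(object$fit)

#' Predict serum 25(OH)D from a fitted status model
#'
#' @param object a [fit_status_model()] result.
#' @param newdata data.frame carrying every retained predictor (a
#'   `localization` column is converted to `urban` when needed).
#' @param ... unused.
#' @return numeric predictions, ng/mL.
#' @export
predict.status_model <- function(object, newdata, ...) {
  if (missing(newdata)) return(stats::predict(object$fit))
  newdata <- as.data.frame(newdata)
  if ("urban" %in% object$predictors && !("urban" %in% names(newdata)) &&
      "localization" %in% names(newdata))
    newdata$urban <- as.integer(newdata$localization == "urban")
  miss <- setdiff(object$predictors, names(newdata))
  if (length(miss))
    stopf("newdata lacks predictor(s): %s", paste(miss, collapse = ", "))
  unname(stats::predict(object$fit, newdata = newdata))
}
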