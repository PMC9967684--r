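#' Pairwise Spearman correlations of the three assessment methods
#'
#' @param Q,R,B equal-length vectors (length >= 5, no missing values):
#'   FFQ intake, reference food-record intake, and biomarker.
#' @param method `"spearman"` (default; the analysis is rank-based) or
#'   `"pearson"` for sensitivity analyses.
#' @return named numeric of class `correlation_triple`:
#'   `r_qr`, `r_qb`, `r_rb`.
#' @export
#' @examples
#' correlation_triple(1:10, (1:10)^2, log(1:10))
correlation_triple <- function(Q, R, B, method = "spearman") {
  n <- length(Q)
  if (length(R) != n || length(B) != n)
    stopf("Q, R and B must have equal length")
  if (n < 5L) stopf("at least 5 observations are required")
  if (anyNA(Q) || anyNA(R) || anyNA(B)) stopf("missing values are not allowed")
  for (nm in c("Q", "R", "B"))
    if (stats::sd(get(nm)) == 0)
      stopf("correlation undefined: %s is constant", nm)
  out <- c(r_qr = corr2(Q, R, method), r_qb = corr2(Q, B, method),
           r_rb = corr2(R, B, method))
  class(out) <- "correlation_triple"
  out
}

#' @export
print.correlation_triple <- function(x, ...) {
  cat(sprintf("r(Q,R) = %.3f, r(Q,B) = %.3f, r(R,B) = %.3f\n",
              x[["r_qr"]], x[["r_qb"]], x[["r_rb"]]))
  invisible(x)
}

#' Method-of-triads validity coefficients
#'
#' Under the triad model -- three measurements linearly related to the
#' unknown true intake T with mutually independent errors -- the
#' correlation of each instrument with T is identified from the three
#' pairwise correlations:
#' \deqn{\rho_{QT} = \sqrt{r_{QR} r_{QB} / r_{RB}},\quad
#'       \rho_{RT} = \sqrt{r_{QR} r_{RB} / r_{QB}},\quad
#'       \rho_{BT} = \sqrt{r_{QB} r_{RB} / r_{QR}}.}
#'
#' A coefficient is refused (NA with flag) when one of its input
#' correlations is not positive, and capped at 1 with a Heywood flag
#' when sampling error pushes the raw value above 1; the raw value is
#' kept in `vc_raw`.
#'
#' @param triple a [correlation_triple()] or named numeric
#'   `c(r_qr=, r_qb=, r_rb=)`.
#' @return list of class `triads_vc`: `vc` (named q/r/b, capped),
#'   `vc_raw`, `heywood` (named logicals), `refused` (named logicals),
#'   `labels` (interpretation per coefficient), `triple`.
#' @export
#' @examples
#' triads_vc(c(r_qr = 0.64, r_qb = 0.46, r_rb = 0.36))
triads_vc <- function(triple) {
  r <- unclass(unlist(triple))
  need <- c("r_qr", "r_qb", "r_rb")
  if (is.null(names(r)) || !all(need %in% names(r))) {
    if (length(r) == 3L) names(r) <- need else
      stopf("triple must carry names r_qr, r_qb, r_rb")
  }
  r <- r[need]
  eps <- 1e-12
  num <- list(q = c("r_qr", "r_qb"), r = c("r_qr", "r_rb"),
              b = c("r_qb", "r_rb"))
  den <- c(q = "r_rb", r = "r_qb", b = "r_qr")
  vc_raw <- vc <- stats::setNames(rep(NA_real_, 3), c("q", "r", "b"))
  refused <- heywood <- stats::setNames(rep(FALSE, 3), c("q", "r", "b"))
  for (k in c("q", "r", "b")) {
    ins <- c(r[num[[k]]], r[den[[k]]])
    if (any(ins <= 0) || abs(r[den[[k]]]) <= eps) {
      refused[k] <- TRUE
      next
    }
    v <- sqrt(r[num[[k]]][1] * r[num[[k]]][2] / r[den[[k]]])
    vc_raw[k] <- v
    heywood[k] <- v > 1
    vc[k] <- min(v, 1)
  }
  labels <- stats::setNames(rep(NA_character_, 3), c("q", "r", "b"))
  ok <- !is.na(vc)
  labels[ok] <- interpret_vc(vc[ok])
  structure(list(vc = vc, vc_raw = vc_raw, heywood = heywood,
                 refused = refused, labels = labels, triple = r),
            class = "triads_vc")
}

#' @export
print.triads_vc <- function(x, ...) {
  cat("Method-of-triads validity coefficients:\n")
  for (k in c("q", "r", "b")) {
    nm <- c(q = "FFQ", r = "food record", b = "biomarker")[[k]]
    if (x$refused[k]) {
      cat(sprintf("  %-11s: refused (non-positive input correlation)\n", nm))
    } else {
      cat(sprintf("  %-11s: %.3f%s (%s)\n", nm, x$vc[k],
                  if (x$heywood[k])
                    sprintf(" [Heywood, raw %.3f, capped]", x$vc_raw[k])
                  else "", x$labels[k]))
    }
  }
  invisible(x)
}

#' Interpretation band of a validity coefficient
#'
#' Low below 0.2, moderate in the closed band [0.2, 0.6], high above
#' 0.6 (both boundaries belong to moderate).
#'
#' @param vc numeric in [0, 1] (vectorised).
#' @return character labels.
#' @export
interpret_vc <- function(vc) {
  if (any(vc < 0 | vc > 1, na.rm = TRUE)) stopf("vc must lie in [0, 1]")
  ifelse(vc < 0.2, "low", ifelse(vc <= 0.6, "moderate", "high"))
}

#' Validity range of the FFQ
#'
#' The correlation between FFQ and biomarker is the lower limit of the
#' FFQ's validity, and the triads coefficient of the FFQ the upper
#' limit.
#'
#' @param triple a correlation triple (needs `r_qb`).
#' @param vcs a [triads_vc()] result (needs `vc["q"]`).
#' @return named numeric `c(lower=, upper=)` with attribute
#'   `heywood_capped` if the upper limit was capped.
#' @export
#' @examples
#' vc_range(c(r_qr = 0.64, r_qb = 0.46, r_rb = 0.36),
#'          triads_vc(c(r_qr = 0.64, r_qb = 0.46, r_rb = 0.36)))
vc_range <- function(triple, vcs) {
  r <- unclass(unlist(triple))
  if (is.null(names(r)) && length(r) == 3L)
    names(r) <- c("r_qr", "r_qb", "r_rb")
  if (is.na(vcs$vc[["q"]]))
    stopf("FFQ validity coefficient undefined; range not reported")
  structure(c(lower = unname(r[["r_qb"]]), upper = unname(vcs$vc[["q"]])),
            heywood_capped = unname(vcs$heywood[["q"]]))
}

#' Covariate-adjusted (partial) Spearman correlation
#'
#' All variables are rank-transformed (average ranks for ties), `x` and
#' `y` are residualised on the rank-transformed covariates by least
#' squares, and the residuals are correlated.  With no covariates this
#' reduces exactly to the ordinary Spearman correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame/matrix of covariates, or `NULL`.
#' @return adjusted correlation (numeric scalar).
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  if (length(x) != length(y)) stopf("x and y must be paired")
  rx <- rank(x); ry <- rank(y)
  if (is.null(covariates) || NCOL(covariates) == 0L)
    return(stats::cor(rx, ry))
  cv <- as.matrix(as.data.frame(covariates))
  if (nrow(cv) != length(x)) stopf("covariates must match x in length")
  Z <- cbind(`(Intercept)` = 1, apply(cv, 2, rank))
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    drop_cols <- colnames(Z)[qz$pivot[(qz$rank + 1):ncol(Z)]]
    stopf("collinear covariate(s): %s", paste(drop_cols, collapse = ", "))
  }
  ex <- stats::lm.fit(Z, rx)$residuals
  ey <- stats::lm.fit(Z, ry)$residuals
  # a variable fully explained by the covariates leaves only numerical
  # noise; its adjusted correlation with anything is zero
  tol <- 1e-8 * length(x)
  if (stats::sd(ex) < tol || stats::sd(ey) < tol) return(0)
  stats::cor(ex, ey)
}

# The adjustment scheme of the validation design: the Q-R pair is
# adjusted for BMI only (both are dietary self-reports; sun exposure
# does not confound them), while each pair involving the biomarker is
# adjusted for both the sun-exposure score and BMI.
.adjusted_triple <- function(Q, R, B, ses, bmi) {
  out <- c(r_qr = partial_spearman(Q, R, data.frame(bmi = bmi)),
           r_qb = partial_spearman(Q, B, data.frame(ses = ses, bmi = bmi)),
           r_rb = partial_spearman(R, B, data.frame(ses = ses, bmi = bmi)))
  class(out) <- "correlation_triple"
  out
}

#' Fit the method of triads to a validation cohort
#'
#' The central fitting function: computes the Spearman correlation
#' triple among FFQ intake (Q), reference food-record intake (R) and
#' biomarker (B), derives the three validity coefficients by the triads
#' formulas, and attaches percentile-bootstrap confidence intervals
#' from resampling persons with replacement.  With `adjust = TRUE` the
#' correlations are partial Spearman correlations: the Q-R pair
#' adjusted for BMI, the Q-B and R-B pairs for the sun-exposure score
#' and BMI (columns `ses` and `bmi` must then be present).
#'
#' Bootstrap replicates in which a coefficient is refused (non-positive
#' input correlation) or Heywood (raw value above 1) are counted and
#' excluded from that coefficient's percentiles; if more than half the
#' replicates of a coefficient are degenerate its interval is withheld.
#'
#' @param data data.frame with columns `Q`, `R`, `B` (and `ses`, `bmi`
#'   when adjusting), e.g. a [simulate_cohort()] result.
#' @param adjust logical; apply the covariate-adjustment scheme.
#' @param n_boot number of bootstrap replicates (>= 100), default 1000.
#' @param seed integer seed for the bootstrap resampling.
#' @param conf_level confidence level of the percentile interval.
#' @param method correlation basis, `"spearman"` (default) or
#'   `"pearson"`.
#' @return object of class `triads_fit`; see [print.triads_fit()],
#'   [coef.triads_fit()], [confint.triads_fit()], [plot.triads_fit()].
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(n_subjects = 152, seed = 11,
#'                                      n_calibration = 2000))
#' fit <- triads(coh, n_boot = 200, seed = 1)
#' fit
triads <- function(data, adjust = FALSE, n_boot = 1000, seed = 1,
                   conf_level = 0.95, method = "spearman") {
  need <- c("Q", "R", "B", if (adjust) c("ses", "bmi"))
  miss <- setdiff(need, names(data))
  if (length(miss))
    stopf("data lacks column(s): %s", paste(miss, collapse = ", "))
  if (n_boot < 100) stopf("n_boot must be >= 100")
  cc <- stats::complete.cases(data[need])
  if (!all(cc)) {
    message(sprintf("dropping %d incomplete case(s)", sum(!cc)))
    data <- data[cc, , drop = FALSE]
  }
  n <- nrow(data)

  triple_of <- function(d) {
    if (adjust) .adjusted_triple(d$Q, d$R, d$B, d$ses, d$bmi)
    else correlation_triple(d$Q, d$R, d$B, method = method)
  }
  triple <- triple_of(data)
  vcs <- triads_vc(triple)

  set.seed(stage_seed(seed, "bootstrap"))
  boot_vc <- matrix(NA_real_, n_boot, 3,
                    dimnames = list(NULL, c("q", "r", "b")))
  boot_heywood <- matrix(FALSE, n_boot, 3,
                         dimnames = list(NULL, c("q", "r", "b")))
  for (bidx in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    d <- data[idx, , drop = FALSE]
    rep_vc <- tryCatch(triads_vc(triple_of(d)), error = function(e) NULL)
    if (is.null(rep_vc)) next   # e.g. constant resample; counts as refused
    boot_vc[bidx, ] <- rep_vc$vc_raw
    boot_heywood[bidx, ] <- rep_vc$heywood
  }
  alpha <- (1 - conf_level) / 2
  ci <- matrix(NA_real_, 3, 2, dimnames = list(c("q", "r", "b"),
                                               c("low", "high")))
  n_refused <- n_heywood <- stats::setNames(integer(3), c("q", "r", "b"))
  for (k in c("q", "r", "b")) {
    vals <- boot_vc[, k]
    hw <- boot_heywood[, k]
    n_refused[k] <- sum(is.na(vals))
    n_heywood[k] <- sum(hw, na.rm = TRUE)
    keep <- !is.na(vals) & !hw
    if (sum(!keep) > n_boot / 2) {
      warnf("coefficient %s: >50%% degenerate bootstrap replicates; CI withheld", k)
      next
    }
    ci[k, ] <- stats::quantile(vals[keep], c(alpha, 1 - alpha), names = FALSE)
  }

  structure(list(triple = triple, vc = vcs$vc, vc_raw = vcs$vc_raw,
                 heywood = vcs$heywood, refused = vcs$refused,
                 labels = vcs$labels,
                 range_q = if (!is.na(vcs$vc[["q"]]))
                   vc_range(triple, vcs) else NULL,
                 ci = ci, conf_level = conf_level, n = n,
                 n_boot = n_boot, seed = seed, adjust = adjust,
                 method = method,
                 boot = list(n_refused = n_refused, n_heywood = n_heywood),
                 call = match.call()),
            class = "triads_fit")
}

#' @describeIn triads Print the fitted correlation triple, validity
#'   coefficients, intervals and flags.
#' @param x,object a `triads_fit`.
#' @param ... unused.
#' @export
print.triads_fit <- function(x, ...) {
  cat(sprintf("Method of triads (%s correlations%s), n = %d\n",
              x$method, if (x$adjust) ", covariate-adjusted" else "", x$n))
  print(x$triple)
  for (k in c("q", "r", "b")) {
    nm <- c(q = "FFQ", r = "food record", b = "biomarker")[[k]]
    if (x$refused[k]) {
      cat(sprintf("  vc %-11s: refused (non-positive input correlation)\n", nm))
    } else {
      cat(sprintf("  vc %-11s: %.3f (%d%% CI %.3f to %.3f)%s -> %s\n",
                  nm, x$vc[k], round(100 * x$conf_level),
                  x$ci[k, 1], x$ci[k, 2],
                  if (x$heywood[k]) " [Heywood-capped]" else "",
                  x$labels[k]))
    }
  }
  if (!is.null(x$range_q))
    cat(sprintf("  FFQ validity range: %.3f to %.3f\n",
                x$range_q[["lower"]], x$range_q[["upper"]]))
  invisible(x)
}

#' @describeIn triads Named validity coefficients `c(q=, r=, b=)`.
#' @export
coef.triads_fit <- function(object, ...) object$vc

#' @describeIn triads Percentile-bootstrap confidence intervals (rows
#'   q/r/b).  `level` recomputes nothing; intervals are stored at the
#'   fitted level.
#' @param parm,level standard [stats::confint()] arguments; `parm`
#'   selects rows among q/r/b.
#' @export
confint.triads_fit <- function(object, parm, level, ...) {
  ci <- object$ci
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @describeIn triads Summary with bootstrap degeneracy accounting.
#' @export
summary.triads_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  bootstrap: %d replicates; refused per coefficient q/r/b: %d/%d/%d; Heywood: %d/%d/%d\n",
              object$n_boot,
              object$boot$n_refused[["q"]], object$boot$n_refused[["r"]],
              object$boot$n_refused[["b"]],
              object$boot$n_heywood[["q"]], object$boot$n_heywood[["r"]],
              object$boot$n_heywood[["b"]]))
  invisible(object)
}

#' @describeIn triads Point-and-interval plot of the three validity
#'   coefficients.
#' @export
plot.triads_fit <- function(x, ...) {
  at <- 1:3
  graphics::plot(at, x$vc, ylim = c(0, 1.05), xlim = c(0.5, 3.5),
                 xaxt = "n", xlab = "", pch = 19,
                 ylab = "Validity coefficient", ...)
  graphics::axis(1, at = at, labels = c("FFQ", "Food record", "Biomarker"))
  graphics::segments(at, x$ci[, 1], at, x$ci[, 2])
  graphics::abline(h = c(0.2, 0.6), lty = 3, col = "grey50")
  invisible(x)
}
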