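#' Wilcoxon signed-rank test with effect size
#'
#' Paired signed-rank test on `x - y` using the normal approximation
#' with tie correction and (by default) a continuity correction.
#' Zero differences are excluded before ranking (`zero_method =
#' "wilcox"`); the Pratt variant ranks them first and then discards
#' their ranks (`zero_method = "pratt"`).  The effect size is
#' `r = |Z| / sqrt(2 n)` with `n` the number of supplied pairs
#' (`effect_denominator = "n"` switches to `|Z| / sqrt(n)`), labelled
#' small below 0.30, medium in [0.30, 0.50) and large at or above 0.50.
#'
#' @param x,y paired numeric vectors of equal length >= 5.
#' @param zero_method `"wilcox"` (drop zero differences) or `"pratt"`.
#' @param correct apply the 0.5 continuity correction (default TRUE).
#' @param effect_denominator `"2n"` (default) or `"n"`.
#' @return list of class `wilcoxon_effect`: `z` (signed, positive when
#'   `x` tends to exceed `y`), `p` (two-sided), `effect_r`,
#'   `effect_label`, `n_pairs`, `n_zero`, `note`.
#' @export
wilcoxon_effect <- function(x, y, zero_method = c("wilcox", "pratt"),
                            correct = TRUE,
                            effect_denominator = c("2n", "n")) {
  zero_method <- match.arg(zero_method)
  effect_denominator <- match.arg(effect_denominator)
  if (length(x) != length(y)) stopf("x and y must be paired (equal length)")
  if (length(x) < 5L) stopf("at least 5 pairs are required")
  d <- x - y
  n_pairs <- length(d)
  n_zero <- sum(d == 0)
  note <- NULL

  if (n_zero == n_pairs) {
    z <- 0; p <- 1
    note <- "all paired differences are zero"
  } else {
    if (zero_method == "wilcox") {
      dd <- d[d != 0]
      n <- length(dd)
      rk <- rank(abs(dd))
      W <- sum(rk[dd > 0])
      mu <- n * (n + 1) / 4
      tie_tab <- table(rk)
      sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
        sum(tie_tab^3 - tie_tab) / 48
    } else {
      n <- length(d)
      n0 <- n_zero
      rk <- rank(abs(d))
      W <- sum(rk[d > 0])
      mu <- (n * (n + 1) - n0 * (n0 + 1)) / 4
      tie_tab <- table(rk[d != 0])
      sig2 <- (n * (n + 1) * (2 * n + 1) -
                 n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
        sum(tie_tab^3 - tie_tab) / 48
    }
    if (sig2 <= 0) {
      z <- 0; p <- 1
      note <- "no rank variation after zero handling"
    } else {
      cc <- if (correct) 0.5 * sign(W - mu) else 0
      z <- (W - mu - cc) / sqrt(sig2)
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  denom <- if (effect_denominator == "2n") sqrt(2 * n_pairs) else
    sqrt(n_pairs)
  r <- abs(z) / denom
  structure(list(z = z, p = min(1, p), effect_r = r,
                 effect_label = effect_size_label(r),
                 n_pairs = n_pairs, n_zero = n_zero, note = note),
            class = "wilcoxon_effect")
}

#' Effect-size label for a signed-rank effect r
#'
#' Bands: large at or above 0.50, medium in [0.30, 0.50), small below
#' 0.30 (values under 0.10 are conventionally negligible but still
#' reported as small).
#'
#' @param r non-negative effect size.
#' @return `"small"`, `"medium"` or `"large"`.
#' @export
effect_size_label <- function(r) {
  ifelse(r >= 0.5, "large", ifelse(r >= 0.3, "medium", "small"))
}

#' @export
print.wilcoxon_effect <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: Z = %.3f, p = %.4g (n = %d pairs, %d zero)\n",
              x$z, x$p, x$n_pairs, x$n_zero))
  cat(sprintf("  effect size r = %.3f (%s)\n", x$effect_r, x$effect_label))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Bland-Altman agreement analysis with BA index
#'
#' Bias is the mean paired difference `x - y`; the limits of agreement
#' are `bias +/- k * SD` of the differences (sample SD, `k = 1.96` by
#' default).  The BA index is the percentage of differences falling
#' strictly outside the limits; below 5% is conventionally taken as
#' good agreement.  Proportional bias is quantified by least-squares
#' regression of the differences on the pair means.
#'
#' @param x,y paired numeric vectors (length >= 3).
#' @param k limit-of-agreement multiplier, default 1.96.
#' @return object of class `bland_altman`: `bias`, `loa_low`,
#'   `loa_high`, `sd_diff`, `n`, `n_outside`, `ba_index` (%),
#'   `within_pct` (%), `good_agreement`, and `prop_bias` (slope, r2, p).
#' @export
#' @examples
#' set.seed(1)
#' a <- rlnorm(60, 2, 0.3); ba <- bland_altman(a + rnorm(60, 0.2, 1), a)
#' ba
bland_altman <- function(x, y, k = 1.96) {
  if (length(x) != length(y)) stopf("x and y must be paired (equal length)")
  n <- length(x)
  if (n < 3L) stopf("at least 3 pairs are required for the SD of differences")
  d <- x - y
  m <- (x + y) / 2
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  loa <- bias + c(-1, 1) * k * sd_diff
  n_outside <- sum(d < loa[1] | d > loa[2])
  ba_index <- 100 * n_outside / n

  if (stats::var(m) > 0) {
    fit <- stats::lm(d ~ m)
    sm <- summary(fit)
    slope <- unname(stats::coef(fit)[2])
    r2 <- sm$r.squared
    pval <- sm$coefficients[2, 4]
  } else {
    slope <- 0; r2 <- 0; pval <- NA_real_
  }
  structure(list(bias = bias, loa_low = loa[1], loa_high = loa[2],
                 sd_diff = sd_diff, k = k, n = n, n_outside = n_outside,
                 ba_index = ba_index, within_pct = 100 - ba_index,
                 good_agreement = ba_index < 5,
                 prop_bias = list(slope = slope, r2 = r2, p = pval),
                 differences = d, means = m),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f, LOA [%.3f, %.3f] (k = %.2f, n = %d)\n",
              x$bias, x$loa_low, x$loa_high, x$k, x$n))
  cat(sprintf("  %d outside LOA; BA index %.2f%% -> %s agreement\n",
              x$n_outside, x$ba_index,
              if (x$good_agreement) "good" else "poor"))
  cat(sprintf("  proportional bias: slope %.4f, R2 %.4f, p %.3g\n",
              x$prop_bias$slope, x$prop_bias$r2, x$prop_bias$p))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "Mean of methods",
                              ylab = "Difference between methods", ...) {
  graphics::plot(x$means, x$differences, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2), col = c("black", "grey40", "grey40"))
  invisible(x)
}

#' Assign empirical quartile labels
#'
#' Cut points are the 25/50/75 empirical percentiles (linear
#' interpolation, quantile type 7).  A value equal to a cut point goes
#' to the lower quartile, so tied observations always share a quartile.
#' Heavy ties can empty a quartile; the result then carries an
#' `imbalance` attribute flag (and the labels remain valid).
#'
#' @param v numeric vector, length >= 4.
#' @return integer labels 1..4 with attribute `imbalance` (logical).
#' @export
#' @examples
#' assign_quartiles(1:8)
assign_quartiles <- function(v) {
  if (length(v) < 4L) stopf("at least 4 values are needed to form quartiles")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  lab <- 1L + (v > q[1]) + (v > q[2]) + (v > q[3])
  imb <- length(unique(lab)) < 4L
  if (imb) warnf("heavy ties: at least one quartile is empty")
  structure(as.integer(lab), imbalance = imb)
}

#' Cross-classification of two quartile assignments
#'
#' Tallies the percentage of persons classified into the same quartile
#' (|difference| = 0), adjacent quartiles (1), two apart (2) and
#' opposite quartiles (3), and checks the two conventional criteria:
#' at least 50% in the same quartile and fewer than 10% grossly
#' misclassified into the opposite quartile.
#'
#' @param qx,qy integer quartile labels 1..4 of equal length.
#' @return list of class `cross_class`: the four percentages (summing
#'   to 100), `meets_same_criterion`, `meets_opposite_criterion`, `n`.
#' @export
cross_classify <- function(qx, qy) {
  if (length(qx) != length(qy)) stopf("quartile vectors must be paired")
  if (any(!(qx %in% 1:4)) || any(!(qy %in% 1:4)))
    stopf("quartile labels must lie in 1..4")
  dd <- abs(as.integer(qx) - as.integer(qy))
  n <- length(dd)
  pct <- 100 * vapply(0:3, function(k) mean(dd == k), numeric(1))
  structure(list(pct_same = pct[1], pct_adjacent = pct[2],
                 pct_two_off = pct[3], pct_opposite = pct[4],
                 meets_same_criterion = pct[1] >= 50,
                 meets_opposite_criterion = pct[4] < 10, n = n),
            class = "cross_class")
}

#' @export
print.cross_class <- function(x, ...) {
  cat(sprintf("Cross-classification (n = %d): same %.2f%%, adjacent %.2f%%, two off %.2f%%, opposite %.2f%%\n",
              x$n, x$pct_same, x$pct_adjacent, x$pct_two_off, x$pct_opposite))
  cat(sprintf("  criteria: same >= 50%%: %s; opposite < 10%%: %s\n",
              x$meets_same_criterion, x$meets_opposite_criterion))
  invisible(x)
}

# disagreement weights for ordered k-level categories
.kappa_weights <- function(k, scheme) {
  d <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  if (scheme == "quadratic") d^2 else d
}

#' Weighted kappa for ordered categorical agreement
#'
#' Chance-corrected agreement `kappa = 1 - sum(w O) / sum(w E)` where
#' `O` is the observed contingency table, `E` the expected table from
#' the row and column margins, and `w` distance-based disagreement
#' weights (`|i-j|/(k-1)`, or its square for `weights = "quadratic"`).
#' The confidence interval uses the large-sample delta-method standard
#' error of Fleiss, Cohen and Everitt (1969).
#'
#' Interpretation bands: up to 0.20 poor, above 0.20 up to 0.60
#' acceptable, above 0.60 good.
#'
#' @param qx,qy paired ordinal labels (integers 1..k, k >= 2).
#' @param weights `"linear"` (default) or `"quadratic"`.
#' @param conf_level confidence level, default 0.95.
#' @return list of class `kappa_result`: `kappa`, `ci_low`, `ci_high`,
#'   `se`, `label`, `weights`, `n`.
#' @export
weighted_kappa <- function(qx, qy, weights = c("linear", "quadratic"),
                           conf_level = 0.95) {
  weights <- match.arg(weights)
  if (length(qx) != length(qy)) stopf("label vectors must be paired")
  k <- max(qx, qy)
  if (k < 2L || any(c(qx, qy) < 1) || any(c(qx, qy) != round(c(qx, qy))))
    stopf("labels must be integers 1..k with k >= 2")
  tab <- table(factor(qx, 1:k), factor(qy, 1:k))
  n <- sum(tab)
  p <- tab / n
  rmar <- rowSums(p); cmar <- colSums(p)
  if (sum(rmar > 0) < 2L || sum(cmar > 0) < 2L)
    stopf("degenerate margins: agreement beyond chance is undefined when a rater uses a single category")
  wd <- .kappa_weights(k, weights)
  wo <- sum(wd * p)                 # observed weighted disagreement
  we <- sum(wd * outer(rmar, cmar)) # expected under independence
  if (we == 0) stopf("expected disagreement is zero; kappa undefined")
  kappa <- 1 - wo / we

  # Fleiss-Cohen-Everitt (1969) large-sample SE, agreement-weight form
  wa <- 1 - wd
  po <- sum(wa * p); pe <- sum(wa * outer(rmar, cmar))
  wbar_r <- as.vector(wa %*% cmar)   # row-wise expected agreement weight
  wbar_c <- as.vector(rmar %*% wa)
  term <- outer(wbar_r, wbar_c, "+") * (1 - kappa)
  v <- (sum(p * (wa - term)^2) - (kappa - pe * (1 - kappa))^2) /
    (n * (1 - pe)^2)
  se <- sqrt(max(v, 0))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(kappa = kappa, ci_low = kappa - zq * se,
                 ci_high = kappa + zq * se, se = se,
                 label = kappa_label(kappa), weights = weights, n = n),
            class = "kappa_result")
}

#' Interpretation band of a kappa value
#' @param kappa numeric kappa value(s).
#' @return `"poor"` (<= 0.20), `"acceptable"` ((0.20, 0.60]) or
#'   `"good"` (> 0.60).
#' @export
kappa_label <- function(kappa) {
  ifelse(kappa > 0.6, "good", ifelse(kappa > 0.2, "acceptable", "poor"))
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Weighted kappa (%s weights): %.3f (95%% CI %.3f to %.3f) -> %s\n",
              x$weights, x$kappa, x$ci_low, x$ci_high, x$label))
  invisible(x)
}

#' Interpretation band of a Spearman correlation
#'
#' Named bands: below 0.20 poor, 0.20-0.50 fair, 0.60-0.70 moderate,
#' 0.80-0.90 very strong (absolute value).  Correlations falling in the
#' gaps between named bands (0.50-0.60, 0.70-0.80, above 0.90) are
#' assigned to the nearer named band and flagged.
#'
#' @param rho correlation value in [-1, 1].
#' @return list: `band`, `outside_named_bands` (logical).
#' @export
spearman_band <- function(rho) {
  a <- abs(rho)
  if (a > 1) stopf("rho must lie in [-1, 1]")
  if (a < 0.2) return(list(band = "poor", outside_named_bands = FALSE))
  if (a <= 0.5) return(list(band = "fair", outside_named_bands = FALSE))
  if (a < 0.6)
    return(list(band = if (a - 0.5 < 0.6 - a) "fair" else "moderate",
                outside_named_bands = TRUE))
  if (a <= 0.7) return(list(band = "moderate", outside_named_bands = FALSE))
  if (a < 0.8)
    return(list(band = if (a - 0.7 < 0.8 - a) "moderate" else "very strong",
                outside_named_bands = TRUE))
  if (a <= 0.9) return(list(band = "very strong", outside_named_bands = FALSE))
  list(band = "very strong", outside_named_bands = TRUE)
}

#' Spearman correlation with interpretation band
#'
#' @param x,y paired numeric vectors, length >= 5, non-constant.
#' @return list: `rho`, `p` (asymptotic, two-sided), `band`,
#'   `outside_named_bands`.
#' @export
spearman_banded <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must be paired")
  if (length(x) < 5L) stopf("at least 5 pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("constant input: Spearman correlation is undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  b <- spearman_band(unname(ct$estimate))
  list(rho = unname(ct$estimate), p = ct$p.value, band = b$band,
       outside_named_bands = b$outside_named_bands)
}

#' Normality screen (Shapiro-Wilk and Lilliefors Kolmogorov-Smirnov)
#'
#' Both tests are reported; when either rejects at `alpha` the
#' recommendation flag `nonparametric_recommended` is set, mirroring
#' the analysis policy of falling back to rank-based methods.  Samples
#' smaller than 8 are skipped with a notice.  Shapiro-Wilk is limited
#' to 5000 observations; larger samples are screened on their first
#' 5000 values (noted in the result).
#'
#' @param v numeric vector.
#' @param alpha decision level, default 0.05.
#' @return list: `shapiro` (statistic, p), `ks` (statistic, p),
#'   `nonparametric_recommended`, `skipped`, `note`.
#' @export
normality_check <- function(v, alpha = 0.05) {
  if (length(v) < 8L) {
    message("fewer than 8 observations; normality tests skipped")
    return(list(shapiro = NULL, ks = NULL,
                nonparametric_recommended = NA, skipped = TRUE,
                note = "n < 8"))
  }
  note <- NULL
  vs <- v
  if (length(vs) > 5000L) {
    vs <- vs[seq_len(5000L)]
    note <- "Shapiro-Wilk computed on the first 5000 observations"
  }
  sw <- stats::shapiro.test(vs)
  ks <- nortest::lillie.test(v)
  list(shapiro = list(statistic = unname(sw$statistic), p = sw$p.value),
       ks = list(statistic = unname(ks$statistic), p = ks$p.value),
       nonparametric_recommended = (sw$p.value < alpha) || (ks$p.value < alpha),
       skipped = FALSE, note = note)
}
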