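test_that("signed-rank z, p and effect size behave as documented", {
  x <- c(3, 5, 2, 8, 7, 1)
  r0 <- wilcoxon_effect(x, x)
  expect_equal(r0$z, 0)
  expect_equal(r0$effect_label, "small")
  expect_match(r0$note, "zero")

  # a uniform +10 shift on every pair is maximally significant
  set.seed(1)
  a <- rnorm(50)
  rs <- wilcoxon_effect(a + 10, a)
  expect_lt(rs$p, 0.001)
  expect_gt(rs$z, 0)

  # p agrees with the reference implementation (normal approximation)
  set.seed(2)
  u <- rlnorm(40); v <- u * exp(rnorm(40, 0.1, 0.3))
  ours <- wilcoxon_effect(u, v)
  ref <- wilcox.test(u, v, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)

  # effect size is shift-invariant in the pairs
  shifted <- wilcoxon_effect(u + 5, v + 5)
  expect_equal(shifted$effect_r, ours$effect_r)

  # the printed-Z convention: |Z|/sqrt(2n) with n pairs
  expect_equal(abs(-1.538) / sqrt(2 * 152), 0.0882, tolerance = 1e-3)
  expect_equal(effect_size_label(0.0882), "small")
  expect_equal(effect_size_label(c(0.31, 0.5)), c("medium", "large"))
})

test_that("Bland-Altman reports bias, limits, BA index and proportional bias", {
  set.seed(5)
  y <- rlnorm(152, 2, 0.4)
  x <- y + rnorm(152, 0.6, 2)
  ba <- bland_altman(x, y)
  expect_equal(ba$bias, mean(x - y))
  expect_equal((ba$loa_low + ba$loa_high) / 2, ba$bias)
  expect_equal(ba$loa_high - ba$bias, 1.96 * sd(x - y))
  d <- x - y
  expect_equal(ba$n_outside, sum(d < ba$loa_low | d > ba$loa_high))
  expect_equal(ba$ba_index, 100 * ba$n_outside / 152)
  expect_equal(ba$within_pct + ba$ba_index, 100)
  expect_equal(ba$good_agreement, ba$ba_index < 5)

  # identical methods: everything collapses
  z <- bland_altman(y, y)
  expect_equal(z$bias, 0)
  expect_equal(z$ba_index, 0)
  expect_equal(z$prop_bias$slope, 0)

  # antisymmetry under swapping the methods
  ab <- bland_altman(y, x)
  expect_equal(ab$bias, -ba$bias)
  expect_equal(ab$loa_low, -ba$loa_high)
  expect_equal(ab$loa_high, -ba$loa_low)

  expect_error(bland_altman(1:2, 2:3), "at least 3")
})

test_that("quartile assignment uses type-7 cuts with lower-quartile ties", {
  expect_equal(as.integer(assign_quartiles(1:8)),
               c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  # rank invariance under monotone transforms
  set.seed(9)
  v <- rlnorm(100)
  expect_equal(as.integer(assign_quartiles(v)),
               as.integer(assign_quartiles(exp(v))))
  # constant vector: all in quartile 1, imbalance flagged
  expect_warning(qc <- assign_quartiles(rep(2, 10)), "ties")
  expect_true(all(qc == 1L))
  expect_true(attr(qc, "imbalance"))
  # a value equal to a cut point goes to the lower quartile
  q <- assign_quartiles(c(1, 2, 3, 4, 5, 6, 7, 8))
  expect_equal(as.integer(q[quantile(1:8, 0.25) == 1:8]), integer(0))
  expect_error(assign_quartiles(1:3), "at least 4")
})

test_that("cross-classification tallies the four distance classes", {
  q <- rep(1:4, each = 5)
  same <- cross_classify(q, q)
  expect_equal(same$pct_same, 100)
  expect_true(same$meets_same_criterion)

  rev <- cross_classify(q, 5 - q)
  expect_equal(rev$pct_opposite, 50)
  expect_equal(rev$pct_adjacent, 50)
  expect_equal(rev$pct_same, 0)
  expect_false(rev$meets_opposite_criterion)

  adj <- cross_classify(1:4, c(2, 1, 4, 3))
  expect_equal(adj$pct_adjacent, 100)

  set.seed(11)
  a <- sample(1:4, 200, TRUE); b <- sample(1:4, 200, TRUE)
  cc <- cross_classify(a, b)
  expect_equal(cc$pct_same + cc$pct_adjacent + cc$pct_two_off +
                 cc$pct_opposite, 100, tolerance = 1e-6)
  expect_error(cross_classify(c(1, 5), c(1, 2)), "1\\.\\.4")
})

# independent brute-force evaluation of kappa = 1 - sum(w O)/sum(w E)
kappa_oracle <- function(tab, scheme = "linear") {
  k <- nrow(tab); n <- sum(tab)
  rmar <- rowSums(tab); cmar <- colSums(tab)
  num <- 0; den <- 0
  for (i in 1:k) for (j in 1:k) {
    w <- abs(i - j) / (k - 1)
    if (scheme == "quadratic") w <- w^2
    num <- num + w * tab[i, j]
    den <- den + w * rmar[i] * cmar[j] / n
  }
  1 - num / den
}

test_that("weighted kappa equals the observed/expected oracle and the null", {
  q <- rep(1:4, each = 10)
  expect_equal(weighted_kappa(q, q)$kappa, 1)

  set.seed(21)
  a <- sample(1:4, 50000, TRUE); b <- sample(1:4, 50000, TRUE)
  expect_lt(abs(weighted_kappa(a, b)$kappa), 0.02)

  for (i in 1:50) {
    tab <- matrix(rpois(16, 5) + 1, 4, 4)
    qx <- rep(rep(1:4, times = 4), times = as.vector(t(tab)))
    qy <- rep(rep(1:4, each = 4), times = as.vector(t(tab)))
    for (scheme in c("linear", "quadratic")) {
      expect_equal(weighted_kappa(qx, qy, weights = scheme)$kappa,
                   unname(kappa_oracle(table(qx, qy), scheme)),
                   tolerance = 1e-12)
    }
  }
  # unweighted special case agrees with an established implementation
  if (requireNamespace("e1071", quietly = TRUE)) {
    set.seed(22)
    a2 <- sample(1:2, 300, TRUE); b2 <- ifelse(runif(300) < 0.7, a2,
                                               sample(1:2, 300, TRUE))
    # with k = 2 the linear weights reduce to the 0/1 disagreement of
    # Cohen's unweighted kappa
    expect_equal(weighted_kappa(a2, b2)$kappa,
                 e1071::classAgreement(table(a2, b2))$kappa,
                 tolerance = 1e-10)
  }
  expect_error(weighted_kappa(rep(1, 20), rep(1:4, 5)), "degenerate")
  expect_equal(kappa_label(c(0.2, 0.37, 0.61)),
               c("poor", "acceptable", "good"))
})

test_that("Spearman bands follow the named ranges with flagged gaps", {
  expect_equal(spearman_banded(1:20, (1:20)^3)$rho, 1)
  expect_equal(spearman_banded(1:20, rev(1:20))$rho, -1)
  expect_error(spearman_banded(rep(1, 10), 1:10), "constant")

  expect_equal(spearman_band(0.46)$band, "fair")
  expect_equal(spearman_band(-0.46)$band, "fair")
  expect_equal(spearman_band(0.15)$band, "poor")
  expect_equal(spearman_band(0.65)$band, "moderate")
  expect_equal(spearman_band(0.85)$band, "very strong")
  # gap values go to the nearer named band, flagged
  g1 <- spearman_band(0.52)
  expect_equal(g1$band, "fair"); expect_true(g1$outside_named_bands)
  g2 <- spearman_band(0.58)
  expect_equal(g2$band, "moderate"); expect_true(g2$outside_named_bands)
  g3 <- spearman_band(0.95)
  expect_equal(g3$band, "very strong"); expect_true(g3$outside_named_bands)
})

test_that("normality screening has level and power and skips tiny samples", {
  # type-I control: normal samples rarely flagged
  rejections <- vapply(1:100, function(s) {
    set.seed(s)
    normality_check(rnorm(5000))$shapiro$p < 0.05
  }, logical(1))
  expect_gte(mean(!rejections), 0.90)

  # power under gross skew
  set.seed(1)
  nc <- normality_check(rlnorm(500, 0, 1))
  expect_lt(nc$shapiro$p, 0.05)
  expect_lt(nc$ks$p, 0.05)
  expect_true(nc$nonparametric_recommended)

  expect_message(sk <- normality_check(rnorm(5)), "skipped")
  expect_true(sk$skipped)
})
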