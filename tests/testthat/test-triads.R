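test_that("correlation triples are Spearman and reject degenerate input", {
  tr <- correlation_triple(1:10, (1:10)^2, log(1:10))
  expect_equal(unname(unclass(tr)), c(1, 1, 1))
  expect_error(correlation_triple(rep(1, 10), 1:10, 1:10), "Q is constant")

  set.seed(31)
  n <- 50000
  tr0 <- correlation_triple(runif(n), runif(n), runif(n))
  expect_true(all(abs(unclass(tr0)) < 0.02))
})

test_that("triads formulas reproduce the square-root ratios and cap Heywood cases", {
  # the printed simple correlation triple
  vs <- triads_vc(c(r_qr = 0.64, r_qb = 0.46, r_rb = 0.36))
  expect_equal(round(vs$vc[["q"]], 2), 0.90)
  expect_equal(vs$vc[["q"]], sqrt(0.64 * 0.46 / 0.36), tolerance = 1e-12)
  expect_equal(round(vs$vc[["r"]], 2), 0.71)
  expect_equal(abs(vs$vc[["r"]] - 0.70) < 0.015, TRUE)

  # the adjusted triple
  va <- triads_vc(c(r_qr = 0.53, r_qb = 0.46, r_rb = 0.46))
  expect_equal(round(va$vc[["b"]], 2), 0.63)
  expect_equal(va$vc[["q"]], sqrt(0.53), tolerance = 1e-12)

  # symmetric case: (r, r, r) -> sqrt(r) for all three
  for (r in seq(0.05, 1, by = 0.05)) {
    v <- triads_vc(c(r_qr = r, r_qb = r, r_rb = r))
    expect_equal(unname(v$vc), rep(sqrt(r), 3), tolerance = 1e-12)
  }

  # Heywood: raw value above 1 is capped and flagged
  vh <- triads_vc(c(r_qr = 0.9, r_qb = 0.8, r_rb = 0.3))
  expect_true(vh$heywood[["q"]])
  expect_equal(vh$vc[["q"]], 1)
  expect_gt(vh$vc_raw[["q"]], 1)

  # non-positive correlations refuse the affected coefficients
  vn <- triads_vc(c(r_qr = -0.2, r_qb = 0.4, r_rb = 0.3))
  expect_true(vn$refused[["q"]])
  expect_true(is.na(vn$vc[["q"]]))
})

test_that("validity range and interpretation bands follow the conventions", {
  tr <- c(r_qr = 0.64, r_qb = 0.46, r_rb = 0.36)
  rng <- vc_range(tr, triads_vc(tr))
  expect_equal(as.numeric(rng), c(0.46, sqrt(0.64 * 0.46 / 0.36)))

  sym <- c(r_qr = 0.49, r_qb = 0.49, r_rb = 0.49)
  expect_equal(as.numeric(vc_range(sym, triads_vc(sym))), c(0.49, 0.7))

  capped <- triads_vc(c(r_qr = 0.9, r_qb = 0.8, r_rb = 0.3))
  rngc <- vc_range(c(r_qr = 0.9, r_qb = 0.8, r_rb = 0.3), capped)
  expect_equal(rngc[["upper"]], 1)
  expect_true(attr(rngc, "heywood_capped"))

  expect_equal(interpret_vc(0.90), "high")
  expect_equal(interpret_vc(0.19), "low")
  expect_equal(interpret_vc(0.2), "moderate")
  expect_equal(interpret_vc(0.60), "moderate")  # boundary closed on both ends
})

test_that("triads coefficients are invariant under monotone transforms", {
  coh <- simulate_cohort(small_config(n = 152, seed = 61))
  f1 <- triads_vc(correlation_triple(coh$Q, coh$R, coh$B))
  f2 <- triads_vc(correlation_triple(log(coh$Q), rank(coh$R), exp(coh$B / 40)))
  expect_equal(f1$vc, f2$vc, tolerance = 1e-12)
})

test_that("partial Spearman removes covariates and reports collinearity", {
  set.seed(71)
  x <- rnorm(200); y <- rnorm(200)
  expect_equal(partial_spearman(x, y), cor(x, y, method = "spearman"))

  z <- rnorm(200)
  expect_lt(abs(partial_spearman(x, z, data.frame(z = z))), 1e-10)

  # shared confounder: raw correlation is large, adjusted is near zero
  n <- 20000
  w <- rnorm(n)
  a <- w + rnorm(n); b <- w + rnorm(n)
  raw <- cor(a, b, method = "spearman")
  adj <- partial_spearman(a, b, data.frame(w = w))
  expect_gt(raw, 0.4)
  expect_lt(abs(adj), 0.03)

  expect_error(partial_spearman(x, y, data.frame(u = z, v = z)),
               "collinear.*v")
})

test_that("triads estimates converge to the generator's targets as n grows", {
  tv <- c(q = 0.9, r = 0.7, b = 0.5)
  est <- function(n) {
    coh <- simulate_cohort(cohort_config(n_subjects = n, seed = 81,
                                         target_vc = tv,
                                         n_calibration = 20000))
    triads_vc(correlation_triple(coh$Q, coh$R, coh$B))$vc
  }
  e_small <- est(2000)
  e_large <- est(20000)
  expect_lt(max(abs(e_small - tv[c("q", "r", "b")])), 0.08)
  expect_lt(max(abs(e_large - tv[c("q", "r", "b")])), 0.03)
})

test_that("the triads fit bundles estimates, intervals and diagnostics", {
  coh <- simulate_cohort(small_config(n = 152, seed = 91))
  fit <- triads(coh, n_boot = 200, seed = 4)
  expect_s3_class(fit, "triads_fit")
  expect_named(coef(fit), c("q", "r", "b"))
  ci <- confint(fit)
  expect_true(all(ci[, "low"] <= coef(fit) + 1e-9, na.rm = TRUE))
  expect_true(all(ci[, "high"] >= coef(fit) - 1e-9 | fit$heywood, na.rm = TRUE))
  expect_equal(fit$range_q[["lower"]], fit$triple[["r_qb"]])
  expect_equal(fit$range_q[["upper"]], fit$vc[["q"]])

  # bootstrap determinism under a fixed seed
  fit2 <- triads(coh, n_boot = 200, seed = 4)
  expect_identical(fit$ci, fit2$ci)

  # interval endpoints are monotone in the nominal level
  fit90 <- triads(coh, n_boot = 200, seed = 4, conf_level = 0.90)
  expect_gte(fit90$ci["q", "low"], fit$ci["q", "low"])
  expect_lte(fit90$ci["q", "high"], fit$ci["q", "high"])

  # noiseless cohort: all coefficients 1, intervals collapse
  noiseless <- data.frame(Q = coh$T, R = coh$T, B = coh$T)
  fitn <- triads(noiseless, n_boot = 100, seed = 1)
  expect_equal(unname(fitn$vc), rep(1, 3))
  expect_equal(unname(fitn$ci[, "low"]), rep(1, 3))
  expect_equal(unname(fitn$ci[, "high"]), rep(1, 3))

  # printing and plotting work
  expect_output(print(fit), "Method of triads")
  expect_output(summary(fit), "bootstrap")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("covariate adjustment changes the biomarker coefficient as designed", {
  coh <- simulate_cohort(small_config(n = 2000, seed = 101))
  simple <- triads(coh, adjust = FALSE, n_boot = 100, seed = 1)
  adj <- triads(coh, adjust = TRUE, n_boot = 100, seed = 1)
  # SES and urban residence inflate B independently of intake; removing
  # them (partial Spearman) strengthens the biomarker's validity
  expect_gt(adj$vc[["b"]], simple$vc[["b"]])
  expect_error(triads(coh[c("Q", "R", "B")], adjust = TRUE),
               "ses")
})
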