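test_that("latent truth is log-normal with the configured median and reproducible", {
  cfg <- cohort_config(n_subjects = 100000, seed = 1,
                       true_intake_median = 6.33, true_intake_log_sd = 0.45)
  t1 <- generate_latent_truth(cfg)
  expect_lt(abs(median(t1) - 6.33) / 6.33, 0.02)
  expect_true(all(t1 > 0))

  # degenerate dispersion collapses to the median
  cfg0 <- cohort_config(n_subjects = 50, seed = 2, true_intake_log_sd = 0)
  expect_equal(generate_latent_truth(cfg0), rep(6.33, 50))

  # bit-identical under the same seed
  expect_identical(t1, generate_latent_truth(cfg))
})

test_that("closed-form error scales match the stated inversion", {
  expect_equal(solve_error_scales(1, latent_sd = 1), 0)
  expect_equal(solve_error_scales(0.5, latent_sd = 1), sqrt(3))
  expect_equal(solve_error_scales(0.9, latent_sd = 2),
               2 * sqrt(1 / 0.81 - 1), tolerance = 1e-10)
  expect_error(solve_error_scales(0, latent_sd = 1), "\\(0, 1]")
  expect_error(cohort_config(target_vc = c(q = 0, r = 0.5, b = 0.5)),
               "\\(0, 1]")
})

test_that("noiseless measurement generation is the identity on truth", {
  cfg <- small_config(n = 50, seed = 3,
                      status_coefs = c(intercept = 0, intake = 1,
                                       ses = 0, bmi = 0, urban = 0),
                      q_median_ratio = 1)
  T <- generate_latent_truth(cfg)
  set.seed(99)
  m <- generate_measurements(T, ses = rep(16, 50), bmi = rep(25, 50),
                             urban = rep(1, 50), cfg,
                             scales = c(q = 0, r = 0, b = 0))
  expect_equal(m$B, T)
  expect_equal(m$Q, T)
  expect_equal(m$R, T)
  expect_equal(attr(m, "floor_rates"), c(Q = 0, R = 0, B = 0))
  expect_error(generate_measurements(T, ses = rep(16, 10),
                                     bmi = rep(25, 50),
                                     urban = rep(1, 50), cfg,
                                     scales = c(q = 0, r = 0, b = 0)),
               "equal length")
})

test_that("default cohorts floor fewer than 1% of measurements", {
  coh <- simulate_cohort(cohort_config(n_subjects = 20000, seed = 5))
  expect_true(all(attr(coh, "floor_rates") < 0.01))
  expect_true(all(coh$Q > 0 & coh$R > 0 & coh$B > 0))
  expect_equal(coh$bmi, coh$weight / coh$height^2, tolerance = 1e-9)
})

test_that("cohort simulation is deterministic given config and seed", {
  cfg <- small_config(n = 60, seed = 11)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
})

test_that("achieved rank correlations are monotone in the validity targets", {
  lo <- simulate_cohort(small_config(n = 10000, seed = 21,
                                     target_vc = c(q = 0.6, r = 0.7, b = 0.53)))
  hi <- simulate_cohort(small_config(n = 10000, seed = 21,
                                     target_vc = c(q = 0.95, r = 0.7, b = 0.53)))
  r_lo <- correlation_triple(lo$Q, lo$R, lo$B)
  r_hi <- correlation_triple(hi$Q, hi$R, hi$B)
  expect_gt(r_hi[["r_qr"]], r_lo[["r_qr"]])
  expect_gt(r_hi[["r_qb"]], r_lo[["r_qb"]])
})

test_that("item-level files round-trip person-level quantities", {
  cfg <- small_config(n = 60, seed = 31)
  coh <- simulate_cohort(cfg)
  comp <- read_composition()
  items <- generate_item_level(coh, comp, cfg)

  # FFQ responses reproduce Q within the stated 5% relative tolerance
  ffq <- compute_ffq_intakes(items$ffq, comp)
  q_hat <- ffq$intake[match(coh$id, ffq$person_id)]
  expect_lt(max(abs(q_hat - coh$Q) / coh$Q), 0.05)

  # food-record grams reproduce R closely (rounding to 0.1 g only)
  fr <- compute_fr_intakes(items$fr, comp)
  r_hat <- fr$intake[match(coh$id, fr$person_id)]
  expect_lt(max(abs(r_hat - coh$R) / coh$R), 0.01)

  # SEQ items reproduce the SES exactly
  ses <- compute_ses_table(items$seq)
  expect_equal(ses$ses[match(coh$id, ses$person_id)], coh$ses)

  # identical files under the same seed
  items2 <- generate_item_level(coh, comp, cfg)
  expect_identical(items, items2)
})

test_that("unreachable FFQ targets raise an error naming the person", {
  cfg <- small_config(n = 4, seed = 41)
  coh <- simulate_cohort(cfg)
  coh$Q[2] <- 500  # far beyond what the composition table can provide
  expect_error(generate_item_level(coh, read_composition(), cfg),
               "unreachable.*P0002")
})

test_that("written cohort files are byte-stable across runs", {
  cfg <- small_config(n = 20, seed = 51)
  coh <- simulate_cohort(cfg)
  items <- generate_item_level(coh, read_composition(), cfg)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  write_cohort_files(coh, items, d1)
  write_cohort_files(coh, items, d2)
  for (f in c("cohort.csv", "ffq_responses.csv", "fr_records.csv",
              "seq_responses.csv", "config.json", "metadata.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  cfg2 <- read_cohort_config(file.path(d1, "config.json"))
  expect_equal(cfg2$target_vc, cfg$target_vc)
  expect_equal(cfg2$n_subjects, cfg$n_subjects)
})
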