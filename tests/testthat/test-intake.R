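test_that("frequency categories map to the documented servings/day", {
  expect_equal(round(frequency_to_daily("1 d/week"), 2), 0.14)
  expect_equal(frequency_to_daily("never or less than once a month"), 0)
  expect_equal(frequency_to_daily("2-4 d/week"), 3 / 7)
  expect_equal(frequency_to_daily("1-3 d/month"), 2 / 30)
  expect_equal(frequency_to_daily("5-6 d/week"), 5.5 / 7)
  expect_equal(frequency_to_daily("every day"), 1)
  # en-dash variants are normalised
  expect_equal(frequency_to_daily("2–4 d/week"), 3 / 7)
  expect_error(frequency_to_daily("twice a fortnight"),
               "accepted labels.*never or less")
})

test_that("FFQ intake is servings x portion x density, with group shares", {
  comp <- tiny_composition()
  # one item, once a week, 100 g portion: 1/7 servings x 100 g x
  # 10 ug/100 g / 100 = 10/7 ug/day
  comp1 <- comp[comp$item_id == "c_fish", ]
  comp1$vitd_per_100g <- 10
  comp1$portions[[1]] <- 100
  r <- compute_ffq_intakes(ffq_row(item = "c_fish", freq = "1 d/week"),
                           comp1)
  expect_equal(r$intake, 10 / 7)
  # and with a 1 ug/100 g food the daily intake equals the 0.14
  # servings/day conversion itself
  comp1$vitd_per_100g <- 1
  r1 <- compute_ffq_intakes(ffq_row(item = "c_fish", freq = "1 d/week"),
                            comp1)
  expect_equal(round(r1$intake, 2), 0.14)

  # all never: zero intake, shares undefined
  rn <- compute_ffq_intakes(
    ffq_row(item = c("a_milk", "b_egg"),
            freq = "never or less than once a month"), comp)
  expect_equal(rn$intake, 0)
  expect_true(all(is.na(rn$group_shares[[1]])))
  expect_equal(rn$n_items_consumed, 0L)

  # two items contributing equally in different groups: 50/50 shares
  comp2 <- comp[comp$item_id %in% c("a_milk", "b_egg"), ]
  comp2$vitd_per_100g <- c(1, 1)
  comp2$portions <- list(100, 100)
  r2 <- compute_ffq_intakes(ffq_row(item = c("a_milk", "b_egg"),
                                    freq = "every day"), comp2)
  sh <- r2$group_shares[[1]]
  expect_equal(unname(sh[c("dairy & beverages", "eggs")]), c(50, 50))
  expect_equal(sum(sh), 100, tolerance = 1e-6)

  expect_error(compute_ffq_intakes(ffq_row(item = "nope", freq = "every day"),
                                   comp), "unknown item_id: nope")
  expect_error(compute_ffq_intakes(
    rbind(ffq_row(item = "a_milk", freq = "every day"),
          ffq_row(item = "a_milk", freq = "1 d/week")), comp),
    "at most once")
})

test_that("FFQ intake is additive, scales with density, and is monotone in frequency", {
  comp <- tiny_composition()
  resp <- data.frame(person_id = "p1", item_id = comp$item_id,
                     frequency_category = c("1 d/week", "2-4 d/week",
                                            "every day", "1-3 d/month",
                                            "5-6 d/week", "1 d/week",
                                            "every day", "2-4 d/week"),
                     portion_index = c(1, 2, 3, 1, 2, 3, 2, 1),
                     stringsAsFactors = FALSE)
  whole <- compute_ffq_intakes(resp, comp)$intake
  part1 <- compute_ffq_intakes(resp[1:3, ], comp)$intake
  part2 <- compute_ffq_intakes(resp[4:8, ], comp)$intake
  expect_equal(whole, part1 + part2)

  comp2 <- comp
  comp2$vitd_per_100g <- 2 * comp$vitd_per_100g
  expect_equal(compute_ffq_intakes(resp, comp2)$intake, 2 * whole)

  up <- resp
  up$frequency_category[4] <- "every day"  # raise one category
  expect_gte(compute_ffq_intakes(up, comp)$intake, whole)
})

test_that("food-record intake averages the 7 days and enforces completeness", {
  comp <- tiny_composition()
  comp_fish <- comp[comp$item_id == "c_fish", ]
  comp_fish$vitd_per_100g <- 10
  r <- compute_fr_intakes(fr_week(grams = 100), comp_fish)
  expect_equal(r$intake, 10)

  expect_error(compute_fr_intakes(fr_week(days = 1), comp_fish),
               "incomplete food record.*p1")
  expect_message(
    out <- compute_fr_intakes(rbind(fr_week("p1"), fr_week("p2", days = 1:5)),
                              comp_fish, incomplete = "drop"),
    "dropping 1 person")
  expect_equal(out$person_id, "p1")

  # zero-vitamin-D foods over a complete week give zero intake
  comp0 <- comp_fish
  comp0$vitd_per_100g <- 0
  expect_equal(compute_fr_intakes(fr_week(), comp0)$intake, 0)

  expect_error(compute_fr_intakes(fr_week(days = c(1:6, 9)), comp_fish),
               "day must lie in 1..7")
  expect_error(compute_fr_intakes(transform(fr_week(), grams = -1), comp_fish),
               "grams must be positive")
})

test_that("RDA adequacy counts strictly-below proportions", {
  expect_equal(unname(rda_adequacy(rep(20, 10), c(x = 15))), 0)
  got <- rda_adequacy(c(5, 12, 16), thresholds = c(t10 = 10, t15 = 15))
  expect_equal(unname(got), c(100 / 3, 200 / 3), tolerance = 1e-10)
  # a person exactly at the threshold is not below it
  expect_equal(unname(rda_adequacy(c(5, 15, 16), c(t15 = 15))), 100 / 3)
  expect_error(rda_adequacy(numeric(0)), "empty")
})
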