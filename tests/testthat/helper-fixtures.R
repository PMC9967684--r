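# shared fixtures: a tiny composition table and small cohort configs
tiny_composition <- function() {
  df <- data.frame(
    item_id = c("a_milk", "b_egg", "c_fish", "d_meat", "e_marg",
                "f_cereal", "g_biscuit", "h_cocoa"),
    name = letters[1:8],
    group = ffq_food_groups(),
    vitd_per_100g = c(1.0, 2.0, 11.0, 0.5, 7.5, 4.2, 0.4, 2.4),
    portion_g_1 = c(125, 50, 80, 80, 5, 30, 25, 10),
    portion_g_2 = c(250, 60, 130, 120, 10, 45, 50, 20),
    portion_g_3 = c(330, NA, 200, 180, 20, 60, NA, 30),
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  read_composition(path)
}

small_config <- function(n = 152, seed = 1, ...) {
  cohort_config(n_subjects = n, seed = seed, n_calibration = 4000, ...)
}

# one-person FFQ response table
ffq_row <- function(person = "p1", item, freq, portion = 1) {
  data.frame(person_id = person, item_id = item,
             frequency_category = freq, portion_index = portion,
             stringsAsFactors = FALSE)
}

# a complete 7-day record of one food eaten once per day
fr_week <- function(person = "p1", item = "c_fish", grams = 100,
                    days = 1:7) {
  data.frame(person_id = person, day = days, occasion = "lunch",
             item_id = item, grams = grams, stringsAsFactors = FALSE)
}
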