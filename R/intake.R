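#' FFQ consumption-frequency categories and their servings-per-day values
#'
#' The questionnaire records how often each food was eaten in the last
#' month on a closed six-level scale.  Each category maps to an average
#' number of servings per day: the weekly categories use the midpoint of
#' their range divided by 7 (so "1 d/week" is 1/7 = 0.14 servings/day),
#' and "1-3 d/month" uses 2 servings per 30-day month.
#'
#' @return `ffq_frequency_levels()`: the six category labels, in
#'   increasing order of frequency.  `ffq_frequency_values()`: the named
#'   servings/day mapping.
#' @export
ffq_frequency_levels <- function() {
  c("never or less than once a month", "1-3 d/month", "1 d/week",
    "2-4 d/week", "5-6 d/week", "every day")
}

#' @rdname ffq_frequency_levels
#' @export
ffq_frequency_values <- function() {
  stats::setNames(c(0, 2 / 30, 1 / 7, 3 / 7, 5.5 / 7, 1),
                  ffq_frequency_levels())
}

#' Convert an FFQ frequency category to servings per day
#'
#' @param frequency_category character vector of categories from the
#'   closed six-level set (en dashes are tolerated and normalised).
#' @param values optional alternative named servings/day mapping, e.g. to
#'   test a 30.44-day-month convention.
#' @return numeric servings/day.
#' @export
#' @examples
#' round(frequency_to_daily("1 d/week"), 2)   # 0.14
#' frequency_to_daily("2-4 d/week")           # 3/7
frequency_to_daily <- function(frequency_category,
                               values = ffq_frequency_values()) {
  cat_norm <- gsub("\u2013", "-", trimws(frequency_category))
  unknown <- setdiff(unique(cat_norm), names(values))
  if (length(unknown))
    stopf("unknown frequency category: %s\n  accepted labels: %s",
          paste(sQuote(unknown), collapse = ", "),
          paste(sQuote(names(values)), collapse = ", "))
  unname(values[cat_norm])
}

# shared lookup of composition rows for a response/record table
.match_items <- function(item_id, composition) {
  idx <- match(item_id, composition$item_id)
  if (anyNA(idx))
    stopf("unknown item_id: %s",
          paste(unique(item_id[is.na(idx)]), collapse = ", "))
  idx
}

.intake_result <- function(person_id, contrib, group, n_items) {
  split_by <- factor(person_id)
  intake <- as.numeric(tapply(contrib, split_by, sum))
  persons <- levels(split_by)
  groups <- ffq_food_groups()
  shares <- matrix(NA_real_, length(persons), length(groups),
                   dimnames = list(persons, groups))
  gsum <- tapply(contrib, list(split_by, factor(group, groups)), sum)
  gsum[is.na(gsum)] <- 0
  pos <- intake > 0
  shares[pos, ] <- gsum[pos, , drop = FALSE] * (100 / intake[pos])
  out <- data.frame(person_id = persons, intake = as.numeric(intake),
                    n_items_consumed = as.integer(n_items[persons]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$group_shares <- lapply(persons, function(p) shares[p, ])
  out
}

#' Per-person daily vitamin D intake from FFQ responses
#'
#' Each response row contributes `servings/day x portion grams x
#' vitamin D per 100 g / 100` micrograms per day; a person's intake is
#' the sum over items.  Group shares (percent of intake per food group)
#' are reported alongside; when intake is zero the shares are undefined
#' and returned as `NA`.
#'
#' @param responses data.frame with columns `person_id`, `item_id`,
#'   `frequency_category` (six-level set) and `portion_index` (1-based
#'   index into the item's portion options).
#' @param composition a [read_composition()] table.
#' @param frequency_values optional alternative servings/day mapping.
#' @return data.frame with `person_id`, `intake` (ug/day),
#'   `n_items_consumed` and a list column `group_shares` (percent per
#'   group, summing to 100 when intake > 0).
#' @export
compute_ffq_intakes <- function(responses, composition,
                                frequency_values = ffq_frequency_values()) {
  if (anyDuplicated(responses[c("person_id", "item_id")]))
    stopf("each (person_id, item_id) pair may appear at most once")
  idx <- .match_items(responses$item_id, composition)
  serv <- frequency_to_daily(responses$frequency_category, frequency_values)
  pidx <- as.integer(responses$portion_index)
  nopt <- lengths(composition$portions)[idx]
  if (any(pidx < 1 | pidx > nopt))
    stopf("portion_index out of range for item(s): %s",
          paste(unique(responses$item_id[pidx < 1 | pidx > nopt]),
                collapse = ", "))
  grams <- mapply(function(i, j) composition$portions[[i]][j], idx, pidx)
  if (any(grams < 0)) stopf("negative portion grams")
  contrib <- serv * grams * composition$vitd_per_100g[idx] / 100
  n_items <- tapply(serv > 0, factor(responses$person_id), sum)
  .intake_result(responses$person_id, contrib,
                 composition$group[idx], n_items)
}

#' Per-person daily vitamin D intake from a 7-day food record
#'
#' Sums `grams x vitamin D per 100 g / 100` over all recorded entries
#' and divides by 7.  Persons whose record does not span all seven days
#' are incomplete; the study design excludes them, so by default they
#' raise an error (set `incomplete = "drop"` to remove them with a
#' message instead, as the pipeline does).
#'
#' @param records data.frame with columns `person_id`, `day` (1..7),
#'   `occasion` (one of the six eating occasions), `item_id`, `grams`.
#' @param composition a [read_composition()] table.
#' @param incomplete `"error"` or `"drop"`.
#' @return data.frame as in [compute_ffq_intakes()].
#' @export
compute_fr_intakes <- function(records, composition,
                               incomplete = c("error", "drop")) {
  incomplete <- match.arg(incomplete)
  if (any(!(records$day %in% 1:7)))
    stopf("day must lie in 1..7")
  occ <- c("breakfast", "morning snack", "lunch", "afternoon snack",
           "dinner", "evening snack")
  if (any(!(records$occasion %in% occ)))
    stopf("occasion must be one of: %s", paste(occ, collapse = ", "))
  if (any(records$grams <= 0)) stopf("grams must be positive")

  ndays <- tapply(records$day, records$person_id,
                  function(d) length(unique(d)))
  bad <- names(ndays)[ndays < 7]
  if (length(bad)) {
    if (incomplete == "error")
      stopf("incomplete food record (fewer than 7 distinct days) for: %s",
            paste(bad, collapse = ", "))
    message(sprintf("dropping %d person(s) with incomplete food records: %s",
                    length(bad), paste(bad, collapse = ", ")))
    records <- records[!(records$person_id %in% bad), , drop = FALSE]
    if (!nrow(records)) stopf("no complete food records remain")
  }
  idx <- .match_items(records$item_id, composition)
  contrib <- records$grams * composition$vitd_per_100g[idx] / 100 / 7
  n_items <- tapply(records$item_id, factor(records$person_id),
                    function(x) length(unique(x)))
  .intake_result(records$person_id, contrib, composition$group[idx], n_items)
}

#' Proportion of persons below recommended daily allowances
#'
#' @param intakes numeric vector of daily intakes (ug/day).
#' @param thresholds positive RDA thresholds, default 15 ug/day
#'   (EFSA/national) and 10 ug/day (WHO/IOM).
#' @return named numeric: percentage of persons with intake strictly
#'   below each threshold (a person exactly at the threshold is not
#'   counted).
#' @export
#' @examples
#' rda_adequacy(c(5, 12, 16))
rda_adequacy <- function(intakes, thresholds = c(efsa_15 = 15, who_10 = 10)) {
  if (!length(intakes)) stopf("empty intake vector")
  if (any(thresholds <= 0)) stopf("thresholds must be positive")
  vapply(thresholds, function(th) 100 * mean(intakes < th), numeric(1))
}
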