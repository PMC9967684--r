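#' Score one sun-exposure questionnaire response
#'
#' The questionnaire holds 15 items scored 0..4, partitioned into three
#' domains (indoor exposure, outdoor exposure, sun-protection
#' practices).  The sun-exposure score is the sum of the three domain
#' sums multiplied by the respondent's phototype factor and by the
#' weather index:
#' `SES = (sum of all item scores) x phototype_factor x weather_index`.
#'
#' The phototype-to-factor map is configurable and defaults to 1.0 for
#' every Fitzpatrick phototype, because no authoritative tabulation of
#' per-phototype multipliers accompanies the instrument; the weather
#' index defaults to 0.75.
#'
#' @param item_scores numeric vector of 15 scores, each in 0..4.
#' @param domains length-15 assignment of items to the three domains
#'   (default: items 1-5 indoor, 6-10 outdoor, 11-15 protection).
#' @param phototype_factor positive multiplier for the respondent's
#'   phototype.
#' @param weather_index multiplier in (0, 1], default 0.75.
#' @return list of class `ses_result`: `domain_sums`, `ses`, `category`.
#' @seealso [classify_ses()], [compute_ses_table()]
#' @export
#' @examples
#' compute_ses(c(rep(2, 5), rep(1, 5), rep(1, 5)))
compute_ses <- function(item_scores,
                        domains = rep(c("indoor", "outdoor", "protection"),
                                      each = 5L),
                        phototype_factor = 1,
                        weather_index = 0.75) {
  if (length(item_scores) != 15L)
    stopf("exactly 15 item scores are required (got %d)", length(item_scores))
  if (any(!is.finite(item_scores)) ||
      any(item_scores < 0 | item_scores > 4))
    stopf("item scores must lie in 0..4")
  if (length(domains) != 15L || length(unique(domains)) != 3L)
    stopf("domains must assign the 15 items to exactly 3 domains")
  if (!is_number(phototype_factor) || phototype_factor <= 0)
    stopf("phototype_factor must be positive")
  if (!is_number(weather_index) || weather_index <= 0 || weather_index > 1)
    stopf("weather_index must lie in (0, 1]")
  domain_sums <- tapply(item_scores, factor(domains, unique(domains)), sum)
  ses <- sum(domain_sums) * phototype_factor * weather_index
  structure(list(domain_sums = domain_sums, ses = unname(ses),
                 category = classify_ses(ses)),
            class = "ses_result")
}

#' @export
print.ses_result <- function(x, ...) {
  cat(sprintf("SES %.2f (%s); domain sums: %s\n", x$ses, x$category,
              paste(sprintf("%s %g", names(x$domain_sums), x$domain_sums),
                    collapse = ", ")))
  invisible(x)
}

#' Categorise a sun-exposure score
#'
#' Bins: insufficient `[0, 7.5)`, moderate `[7.5, 15)`, sufficient
#' `[15, 30]`, high `(30, Inf)`.  The boundary 7.5 belongs to moderate
#' and 15 to sufficient, making the four categories a total,
#' non-overlapping partition of the non-negative line.
#'
#' @param ses numeric score(s), >= 0.
#' @return character vector of categories.
#' @export
#' @examples
#' classify_ses(c(0, 7.5, 15.75, 31))
classify_ses <- function(ses) {
  if (any(!is.finite(ses)) || any(ses < 0))
    stopf("SES must be non-negative")
  cut_lab <- c("insufficient", "moderate", "sufficient", "high")
  idx <- 1L + (ses >= 7.5) + (ses >= 15) + (ses > 30)
  cut_lab[idx]
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' `alpha = k/(k-1) * (1 - sum of item variances / variance of the total
#' score)` for `k` items.  The conventional acceptability cutoff of 0.7
#' is applied inclusively (alpha = 0.7 passes).
#'
#' @param item_matrix numeric matrix or data.frame, respondents in rows,
#'   items in columns (>= 2 of each).
#' @param cutoff acceptability threshold, default 0.7.
#' @return list: `alpha`, `k`, `n`, `acceptable`.
#' @export
cronbach_alpha <- function(item_matrix, cutoff = 0.7) {
  m <- as.matrix(item_matrix)
  if (ncol(m) < 2L || nrow(m) < 2L)
    stopf("cronbach_alpha needs >= 2 items and >= 2 respondents")
  total_var <- stats::var(rowSums(m))
  if (total_var == 0)
    stopf("total-score variance is zero; alpha is undefined")
  k <- ncol(m)
  alpha <- k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
  list(alpha = alpha, k = k, n = nrow(m), acceptable = alpha >= cutoff)
}

#' Score a table of sun-exposure questionnaire responses
#'
#' @param seq_responses long data.frame with columns `person_id`,
#'   `domain`, `item`, `score` (0..4) and optionally `phototype`
#'   (I..VI, mapped through `phototype_factor_map`).
#' @param phototype_factor_map named positive multipliers per phototype.
#' @param weather_index multiplier in (0, 1], default 0.75.
#' @return data.frame with one row per person: domain sums, `ses` and
#'   `category`.
#' @export
compute_ses_table <- function(seq_responses,
                              phototype_factor_map = c(I = 1, II = 1, III = 1,
                                                       IV = 1, V = 1, VI = 1),
                              weather_index = 0.75) {
  persons <- unique(seq_responses$person_id)
  rows <- lapply(persons, function(p) {
    d <- seq_responses[seq_responses$person_id == p, , drop = FALSE]
    d <- d[order(match(d$domain, unique(d$domain)), d$item), , drop = FALSE]
    pf <- 1
    if ("phototype" %in% names(d)) {
      pt <- unique(d$phototype)
      if (length(pt) != 1L || !(pt %in% names(phototype_factor_map)))
        stopf("person %s: phototype must be single-valued and mapped", p)
      pf <- unname(phototype_factor_map[pt])
    }
    r <- compute_ses(d$score, domains = d$domain, phototype_factor = pf,
                     weather_index = weather_index)
    data.frame(person_id = p, indoor = r$domain_sums[["indoor"]],
               outdoor = r$domain_sums[["outdoor"]],
               protection = r$domain_sums[["protection"]],
               ses = r$ses, category = r$category, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarise sun-exposure scores across exposure categories
#'
#' Medians and interquartile ranges per domain and for the total score,
#' plus a Kruskal-Wallis trend test of the total SES across the
#' populated exposure categories.
#'
#' @param ses_table output of [compute_ses_table()].
#' @return list: `summary` (data.frame of median/IQR per domain and
#'   total), `category_counts`, `kruskal` (`statistic`, `p_value`, or
#'   `NULL` with a message when fewer than two categories are populated).
#' @export
summarize_ses <- function(ses_table) {
  if (is.null(ses_table) || !nrow(ses_table)) stopf("empty SES table")
  cols <- c("indoor", "outdoor", "protection", "ses")
  summ <- do.call(rbind, lapply(cols, function(cl) {
    mi <- med_iqr(ses_table[[cl]])
    data.frame(measure = cl, median = mi[["median"]], iqr = mi[["iqr"]])
  }))
  counts <- table(ses_table$category)
  kw <- NULL
  if (sum(counts > 0) >= 2L) {
    if (stats::var(ses_table$ses) == 0) {
      # all scores identical: no rank variation, H is 0 by convention
      kw <- list(statistic = 0, p_value = 1)
    } else {
      kt <- stats::kruskal.test(ses_table$ses,
                                factor(ses_table$category))
      kw <- list(statistic = unname(kt$statistic), p_value = kt$p.value)
    }
  } else {
    message("only one exposure category populated; trend test skipped")
  }
  list(summary = summ, category_counts = counts, kruskal = kw)
}
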