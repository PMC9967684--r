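# Greedy FFQ allocation: pick, per item, the (frequency, portion) pair
# with the largest contribution not exceeding the remaining target.
# Items are revisited from the largest remaining contribution downwards,
# so the final shortfall is below the smallest positive contribution of
# any unused item.  Deterministic by construction.
.allocate_ffq_person <- function(target, composition, freq_values) {
  nitem <- nrow(composition)
  fpos <- freq_values[freq_values > 0]
  combos <- lapply(seq_len(nitem), function(i) {
    g <- composition$portions[[i]]
    grid <- expand.grid(freq = names(fpos), portion_index = seq_along(g),
                        stringsAsFactors = FALSE)
    grid$contrib <- fpos[grid$freq] * g[grid$portion_index] *
      composition$vitd_per_100g[i] / 100
    grid[order(-grid$contrib), , drop = FALSE]
  })
  chosen <- data.frame(item = integer(), freq = character(),
                       portion_index = integer(), stringsAsFactors = FALSE)
  remaining <- target
  used <- rep(FALSE, nitem)
  repeat {
    best_item <- 0L; best_row <- NULL; best_contrib <- 0
    for (i in which(!used)) {
      cand <- combos[[i]]
      ok <- which(cand$contrib <= remaining & cand$contrib > 0)
      if (length(ok) && cand$contrib[ok[1]] > best_contrib) {
        best_item <- i; best_row <- cand[ok[1], ]
        best_contrib <- cand$contrib[ok[1]]
      }
    }
    if (best_item == 0L) break
    used[best_item] <- TRUE
    chosen <- rbind(chosen, data.frame(item = best_item,
                                       freq = best_row$freq,
                                       portion_index = best_row$portion_index,
                                       stringsAsFactors = FALSE))
    remaining <- remaining - best_row$contrib
    if (remaining / target <= 1e-6) break
  }
  list(chosen = chosen, remaining = remaining)
}

# Allocate `total` units over k cells capped at `cap`, starting from a
# multinomial draw and moving any overflow to the lowest-index cell with
# spare capacity (deterministic tie-break).
.allocate_capped <- function(total, k, cap, prob) {
  if (total > k * cap) stopf("total %d exceeds capacity %d", total, k * cap)
  x <- if (total > 0) as.integer(stats::rmultinom(1, total, prob)) else
    integer(k)
  over <- pmax(0L, x - cap)
  x <- pmin(x, cap)
  excess <- sum(over)
  while (excess > 0) {
    i <- which(x < cap)[1]
    add <- min(cap - x[i], excess)
    x[i] <- x[i] + add
    excess <- excess - add
  }
  x
}

#' Synthesize item-level instrument files for a cohort
#'
#' Expands each person's generated intakes and sun-exposure score into
#' raw instrument responses, so the intake engine and the sun-exposure
#' scorer can be exercised end to end:
#'
#' * FFQ responses: a deterministic greedy allocation over the
#'   frequency-by-portion grid reproduces the person-level FFQ intake Q
#'   within a 5% relative tolerance (an error names the person when the
#'   composition table cannot reach the target).
#' * Food-record entries: seven days of gram amounts whose weekly mean
#'   matches the person's R (two eating occasions per day across the
#'   highest-density items; grams rounded to 0.1 g).
#' * Sun-exposure responses: per-domain multinomial draws of the fifteen
#'   0..4 item scores, rescaled (overflow moved to the lowest item index)
#'   so that scoring the items reproduces the person's SES exactly.
#'
#' @param cohort a [simulate_cohort()] data.frame.
#' @param composition a [read_composition()] table.
#' @param config the cohort's [cohort_config()]; defaults to the config
#'   attached to `cohort`.
#' @param tolerance maximum relative FFQ round-trip error (default 0.05).
#' @return list of data.frames `ffq`, `fr`, `seq` in the CSV schemas of
#'   [compute_ffq_intakes()], [compute_fr_intakes()] and
#'   [compute_ses_table()].
#' @export
generate_item_level <- function(cohort, composition,
                                config = attr(cohort, "config"),
                                tolerance = 0.05) {
  if (!nrow(composition)) stopf("composition table is empty")
  set.seed(stage_seed(config$seed, "items"))
  freq_values <- ffq_frequency_values()

  ffq <- list(); fr <- list(); seqr <- list()
  dens_order <- order(-composition$vitd_per_100g)
  main_items <- composition$item_id[dens_order[seq_len(min(3, nrow(composition)))]]
  main_dens <- composition$vitd_per_100g[match(main_items, composition$item_id)]
  if (any(main_dens <= 0))
    stopf("composition table needs items with positive vitamin D content")

  domains <- rep(c("indoor", "outdoor", "protection"), each = 5L)
  dom_prob <- c(indoor = 0.30, outdoor = 0.45, protection = 0.25)

  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$id[i]

    ## FFQ
    alloc <- .allocate_ffq_person(cohort$Q[i], composition, freq_values)
    if (alloc$remaining / cohort$Q[i] > tolerance)
      stopf("FFQ target intake %.3f ug/day unreachable within %.0f%% for person %s",
            cohort$Q[i], 100 * tolerance, pid)
    ch <- alloc$chosen
    ffq[[i]] <- data.frame(person_id = pid,
                           item_id = composition$item_id[ch$item],
                           frequency_category = ch$freq,
                           portion_index = ch$portion_index,
                           stringsAsFactors = FALSE)

    ## 7-day food record: per day, 80% of the target from one main item
    ## and 20% from another, cycling through the three densest items.
    day_target <- cohort$R[i]
    rows <- vector("list", 7L)
    for (d in 1:7) {
      i1 <- (d - 1L) %% length(main_items) + 1L
      i2 <- d %% length(main_items) + 1L
      g1 <- round(0.8 * day_target * 100 / main_dens[i1], 1)
      g2 <- round(0.2 * day_target * 100 / main_dens[i2], 1)
      rows[[d]] <- data.frame(person_id = pid, day = d,
                              occasion = c("lunch", "dinner"),
                              item_id = main_items[c(i1, i2)],
                              grams = pmax(0.1, c(g1, g2)),
                              stringsAsFactors = FALSE)
    }
    fr[[i]] <- do.call(rbind, rows)

    ## SEQ items
    total <- cohort$seq_total[i]
    dom_tot <- .allocate_capped(total, 3L, 20L, dom_prob)
    scores <- unlist(lapply(1:3, function(d)
      .allocate_capped(dom_tot[d], 5L, 4L, rep(0.2, 5))))
    seqr[[i]] <- data.frame(person_id = pid, domain = domains,
                            item = rep(1:5, times = 3L), score = scores,
                            phototype = cohort$phototype[i],
                            stringsAsFactors = FALSE)
  }
  list(ffq = do.call(rbind, ffq), fr = do.call(rbind, fr),
       seq = do.call(rbind, seqr))
}

#' Write a synthetic cohort and its item-level files to disk
#'
#' Writes `cohort.csv`, `ffq_responses.csv`, `fr_records.csv`,
#' `seq_responses.csv` (UTF-8, comma-separated, header row, "." decimal),
#' the generating configuration as `config.json`, and a `metadata.json`
#' recording the seed, calibrated noise scales and flooring rates.
#'
#' @param cohort a [simulate_cohort()] object.
#' @param items the matching [generate_item_level()] list.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_files <- function(cohort, items, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                        row.names = FALSE, quote = TRUE,
                                        fileEncoding = "UTF-8")
  wr(as.data.frame(cohort), "cohort.csv")
  wr(items$ffq, "ffq_responses.csv")
  wr(items$fr, "fr_records.csv")
  wr(items$seq, "seq_responses.csv")
  cfg <- attr(cohort, "config")
  write_cohort_config(cfg, file.path(dir, "config.json"))
  meta <- list(seed = cfg$seed,
               n_subjects = cfg$n_subjects,
               noise_scales = as.list(attr(cohort, "scales")),
               floor_rates = as.list(attr(cohort, "floor_rates")))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
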