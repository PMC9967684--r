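#' The eight food groups of the vitamin D FFQ
#' @return character vector of the closed 8-label group set.
#' @export
ffq_food_groups <- function() {
  c("dairy & beverages", "eggs", "fish & sea products", "meat products",
    "fat products", "breakfast cereals", "bakery & Moroccan biscuit",
    "chocolate & cacao")
}

#' Read a food-composition table
#'
#' The CSV schema is: `item_id`, `name`, `group` (one of the eight fixed
#' FFQ groups), `vitd_per_100g` (ug vitamin D per 100 g, >= 0) and up to
#' three portion weights `portion_g_1..portion_g_3` in grams.  Portion
#' weights are the pre-averaged gram value of each serving-size category
#' (household measures are resolved to grams before they reach this
#' table).
#'
#' @param path CSV file; default is the packaged composition fixture
#'   covering all eight groups.
#' @return a validated `food_composition` data.frame with a list column
#'   `portions` of gram weights per item.
#' @export
#' @examples
#' comp <- read_composition()
#' table(comp$group)
read_composition <- function(path = system.file("extdata",
                                                "food_composition.csv",
                                                package = "vitdval")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("item_id", "name", "group", "vitd_per_100g")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stopf("composition table lacks columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(raw$item_id))
    stopf("duplicated item_id in composition table: %s",
          paste(unique(raw$item_id[duplicated(raw$item_id)]), collapse = ", "))
  bad <- setdiff(unique(raw$group), ffq_food_groups())
  if (length(bad))
    stopf("unknown food group(s): %s (accepted: %s)",
          paste(bad, collapse = ", "), paste(ffq_food_groups(), collapse = "; "))
  if (any(raw$vitd_per_100g < 0)) stopf("vitd_per_100g must be >= 0")
  pcols <- grep("^portion_g_", names(raw), value = TRUE)
  if (!length(pcols)) stopf("composition table needs >= 1 portion_g_ column")
  portions <- lapply(seq_len(nrow(raw)), function(i) {
    p <- unlist(raw[i, pcols])
    p <- p[!is.na(p)]
    if (!length(p) || any(p <= 0))
      stopf("item %s needs >= 1 positive portion weight", raw$item_id[i])
    unname(p)
  })
  out <- raw[c(need, pcols)]
  out$portions <- portions
  class(out) <- c("food_composition", "data.frame")
  out
}
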