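#' @keywords internal
"_PACKAGE"

# Stage offsets for deriving per-stage RNG seeds from the single top-level
# seed.  Every stochastic stage seeds itself as `seed + offset` so that a
# cohort, its calibration and its item-level files are independently
# reproducible while still flowing from one integer.
.stage_offsets <- c(
  truth       = 0L,
  covariates  = 1L,
  calibration = 2L,
  measurement = 3L,
  items       = 4L,
  bootstrap   = 5L
)

stage_seed <- function(seed, stage) {
  offset <- .stage_offsets[[stage]]
  s <- as.integer(seed) + offset
  if (s >= .Machine$integer.max) s <- s %% .Machine$integer.max
  s
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x > 0
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Spearman rank correlation; thin wrapper so the rank basis of the whole
# analysis is switchable in one place (Pearson sensitivity switch).
corr2 <- function(x, y, method = "spearman") {
  stats::cor(x, y, method = method)
}

# Interquartile range as quantile(.75) - quantile(.25), type 7.
iqr7 <- function(x) unname(diff(stats::quantile(x, c(0.25, 0.75), type = 7)))

med_iqr <- function(x) {
  c(median = stats::median(x), iqr = iqr7(x))
}
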