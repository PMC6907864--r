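# Independent straight-line scoring oracle.
#
# A literal, unrolled transcription of the scoring rules, sharing no code
# with the pipeline (its own rounding via integer arithmetic, its own
# deduplication loop, its own band ladder). Used to verify ground truth in
# the synthetic-data generator and in the test suite; deliberately written
# as plain conditionals, not calls into the scoring functions.

#' Reference re-scoring of one country (verification oracle)
#'
#' Recomputes the consensus score and band for one country from first
#' principles, independently of [score_country()]. Intended for
#' verification: the pipeline and this oracle must agree exactly on every
#' input.
#'
#' @inheritParams score_country
#' @return One-row data frame with columns country, part, score, category.
#' @export
score_country_oracle <- function(country, who, price, records,
                                 haq = NA_real_, sdi = NA_real_,
                                 lf_endemic = NA, leprosy_endemic = NA,
                                 tu_endemic = NA,
                                 weights = misdiagnosis_weights()) {
  who <- toupper(who)
  price <- toupper(price)
  n_rec <- nrow(records)

  if (n_rec > 0L) {
    # -- organisation agreement ------------------------------------------
    org <- 0L
    if (who == "PRESENT" && price == "PRESENT") org <- 3L
    if (who == "ABSENT" && price == "ABSENT") org <- -3L

    # -- contemporariness: best single record ----------------------------
    contemp <- 0L
    for (y in records$year) {
      s <- if (is.na(y)) 1L else if (y >= 2000) 3L else if (y >= 1990) 2L else 1L
      if (s > contemp) contemp <- s
    }

    # -- diagnostics: best single record ---------------------------------
    diag <- 0L
    for (d in records$diagnostic) {
      s <- if (d == "SIME_ALGORITHM") 3L else if (d == "CLINICAL_PLUS_ICT") 2L else 1L
      if (s > diag) diag <- s
    }

    # -- deduplicated cases: earliest study per source -------------------
    total_cases <- 0L
    for (src in unique(records$source_id)) {
      best_year <- Inf
      best_id <- ""
      best_count <- 0L
      for (j in seq_len(n_rec)) {
        if (records$source_id[j] != src) next
        if (records$study_year[j] < best_year ||
            (records$study_year[j] == best_year &&
             records$study_id[j] < best_id)) {
          best_year <- records$study_year[j]
          best_id <- records$study_id[j]
          best_count <- records$case_count[j]
        }
      }
      total_cases <- total_cases + best_count
    }
    cases <- if (total_cases > 30L) 6L else if (total_cases > 15L) 4L else
      if (total_cases > 5L) 2L else 0L

    raw <- org + contemp + diag + cases
    # percent = raw/15*100 rounded half away from zero, in exact integer
    # arithmetic: |raw|*200 + 15, integer-divided by 30
    pct <- as.integer(sign(raw) * ((abs(raw) * 200L + 15L) %/% 30L))
    part <- "A"
  } else if (who == "PRESENT" || price == "PRESENT") {
    pct <- 0L
    part <- "ORG_ONLY"
  } else {
    w_sum <- weights$lf + weights$leprosy + weights$tu
    comp <- 0
    if (isTRUE(lf_endemic)) comp <- comp + weights$lf
    if (isTRUE(leprosy_endemic)) comp <- comp + weights$leprosy
    if (isTRUE(tu_endemic)) comp <- comp + weights$tu
    comp <- comp / w_sum
    capacity <- (100 - haq) / 100
    absence <- comp * capacity + capacity + (1 - sdi)
    x <- (1 - absence / 3) * 100            # in [0, 100]
    # same 1e-9 half-tie guard as the pipeline, via its own arithmetic
    pct <- -as.integer(floor(round(x, 9) + 0.5))
    part <- "B"
  }

  band <-
    if (pct == 100L) "Consensus presence" else
    if (pct >= 75L) "Very strong evidence for presence" else
    if (pct >= 50L) "Strong evidence for presence" else
    if (pct >= 25L) "Moderate evidence for presence" else
    if (pct >= 0L) "Indeterminate" else
    if (pct >= -24L) "Weak evidence of absence" else
    if (pct >= -49L) "Moderate evidence of absence" else
    if (pct >= -74L) "Strong evidence of absence" else
    if (pct >= -99L) "Very strong evidence of absence" else
    "Consensus absence"

  data.frame(country = country, part = part, score = pct, category = band,
             stringsAsFactors = FALSE)
}
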