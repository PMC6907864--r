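#' Consensus band labels, ordered from strongest presence to strongest absence
#'
#' The ten ordinal categories used to interpret an evidence-consensus
#' percentage: complete consensus at +/-100, then very strong (75-99),
#' strong (50-74) and moderate (25-49) evidence on either side, an
#' indeterminate zone (0 to 24) and a weak-absence zone (-1 to -24).
#'
#' @return Character vector of the ten band labels in order.
#' @export
#' @examples
#' consensus_bands()
consensus_bands <- function() {
  c("Consensus presence",
    "Very strong evidence for presence",
    "Strong evidence for presence",
    "Moderate evidence for presence",
    "Indeterminate",
    "Weak evidence of absence",
    "Moderate evidence of absence",
    "Strong evidence of absence",
    "Very strong evidence of absence",
    "Consensus absence")
}

# Round half away from zero to the nearest integer (base round() is
# banker's rounding; the published scores require 66.67 -> 67, 6.67 -> 7).
# Values within 1e-9 of a half are treated as exact halves first, so that
# decimal inputs whose true percentage is k + 0.5 are not pushed below the
# boundary by floating-point representation error.
round_half_away <- function(x) {
  sign(x) * floor(round(abs(x), 9) + 0.5)
}

#' Convert a Part A raw sum to an evidence-consensus percentage
#'
#' The raw sum over the four presence-evidence categories (health
#' organisations, contemporariness, diagnostics, case count) is divided by
#' the maximum attainable score of 15, multiplied by 100 and rounded half
#' away from zero to an integer.
#'
#' @param total Integer raw sum in \[-3, 15\].
#' @return Integer percentage in \[-20, 100\].
#' @export
#' @examples
#' consensus_percent_part_a(15) # 100
#' consensus_percent_part_a(10) # 67, not 66
consensus_percent_part_a <- function(total) {
  stopifnot(is.numeric(total), length(total) == 1L, !is.na(total))
  if (total < -3 || total > 15) {
    stop("Part A raw sum must lie in [-3, 15], got ", total, call. = FALSE)
  }
  as.integer(round_half_away(total / 15 * 100))
}

#' Convert a Part B absence score to an evidence-consensus percentage
#'
#' Part B applies to countries with no occurrence records and no
#' organisational presence claim. The absence score in \[0, 3\] measures how
#' plausibly podoconiosis could be present yet unreported (misdiagnosis
#' propensity, weak surveillance, low development). A score of 0 means the
#' absence of reports is fully informative (percent -100, consensus
#' absence); a score of 3 means it carries no information (percent 0).
#'
#' @param absence_total Real absence score in \[0, 3\].
#' @return Integer percentage in \[-100, 0\].
#' @export
#' @examples
#' consensus_percent_part_b(0)   # -100
#' consensus_percent_part_b(2.4) # -20
consensus_percent_part_b <- function(absence_total) {
  stopifnot(is.numeric(absence_total), length(absence_total) == 1L,
            !is.na(absence_total))
  if (absence_total < 0 || absence_total > 3) {
    stop("absence score must lie in [0, 3], got ", absence_total,
         call. = FALSE)
  }
  as.integer(-round_half_away((1 - absence_total / 3) * 100))
}

#' Classify an integer consensus percentage into its band
#'
#' Bands operate on the rounded integer percentage: +100 is consensus
#' presence, 75-99 very strong, 50-74 strong, 25-49 moderate presence,
#' 0-24 indeterminate, -1 to -24 weak absence, then the mirrored absence
#' bands down to consensus absence at -100.
#'
#' @param percent Integer percentage in \[-100, 100\] (vectorised).
#' @return Character vector of band labels (see [consensus_bands()]).
#' @export
#' @examples
#' classify_band(c(100, 73, 27, 7, -20, -100))
classify_band <- function(percent) {
  stopifnot(is.numeric(percent), !anyNA(percent))
  if (any(percent < -100 | percent > 100)) {
    stop("consensus percent must lie in [-100, 100]", call. = FALSE)
  }
  if (any(percent != trunc(percent))) {
    stop("consensus percent must be an integer; round before banding",
         call. = FALSE)
  }
  bands <- consensus_bands()
  out <- character(length(percent))
  for (i in seq_along(percent)) {
    p <- percent[i]
    out[i] <-
      if (p == 100) bands[1L]
      else if (p >= 75) bands[2L]
      else if (p >= 50) bands[3L]
      else if (p >= 25) bands[4L]
      else if (p >= 0) bands[5L]
      else if (p >= -24) bands[6L]
      else if (p >= -49) bands[7L]
      else if (p >= -74) bands[8L]
      else if (p >= -99) bands[9L]
      else bands[10L]
  }
  out
}
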