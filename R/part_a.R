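#' Score agreement between health reporting organisations
#'
#' The WHO distribution map and the Price monograph give a general overview
#' of presence: +3 when both claim presence, -3 when both claim absence,
#' and 0 in every other configuration, including when either source makes
#' no claim.
#'
#' @param who,price Claim of each source: "PRESENT", "ABSENT" or
#'   "NO_CLAIM".
#' @return Integer score in \{-3, 0, +3\}.
#' @export
#' @examples
#' score_health_orgs("PRESENT", "PRESENT") # +3
#' score_health_orgs("PRESENT", "NO_CLAIM") # 0
score_health_orgs <- function(who, price) {
  who <- match.arg(toupper(who), org_statuses())
  price <- match.arg(toupper(price), org_statuses())
  if (who == "PRESENT" && price == "PRESENT") return(3L)
  if (who == "ABSENT" && price == "ABSENT") return(-3L)
  0L
}

#' Score the contemporariness of a country's published evidence
#'
#' Each record is scored by its evidence year: 3 for 2000 onwards, 2 for
#' the 1990s, 1 before 1990. A record with no year still evidences
#' presence and scores the most conservative positive class, 1. The
#' country score is the maximum over its records (evidence categories
#' saturate at the best single item; they do not accumulate). An empty
#' record set scores 0 (category omitted).
#'
#' @param years Integer vector of evidence years, NA allowed.
#' @return Integer score in \{0, 1, 2, 3\}.
#' @export
#' @examples
#' score_contemporariness(c(1939, 2013)) # 3
#' score_contemporariness(1993)          # 2
score_contemporariness <- function(years) {
  if (length(years) == 0L) return(0L)
  per_record <- vapply(as.integer(years), function(y) {
    if (is.na(y)) 1L
    else if (y >= 2000L) 3L
    else if (y >= 1990L) 2L
    else 1L
  }, integer(1))
  max(per_record)
}

#' Score the diagnostic rigour of a country's published evidence
#'
#' The Sime clinical algorithm (history, examination and disease-specific
#' tests) is the gold standard and scores 3; clinical diagnosis plus an
#' immunochromatographic card test (ICT) to exclude filarial infection
#' scores 2; case reports without diagnostic detail score 1. The country
#' score is the maximum over records; an empty set scores 0.
#'
#' @param diagnostics Character vector of diagnostic classes
#'   ("SIME_ALGORITHM", "CLINICAL_PLUS_ICT", "UNSPECIFIED").
#' @return Integer score in \{0, 1, 2, 3\}.
#' @export
#' @examples
#' score_diagnostics(c("SIME_ALGORITHM", "UNSPECIFIED")) # 3
score_diagnostics <- function(diagnostics) {
  if (length(diagnostics) == 0L) return(0L)
  lookup <- c(SIME_ALGORITHM = 3L, CLINICAL_PLUS_ICT = 2L, UNSPECIFIED = 1L)
  per_record <- lookup[match(diagnostics, names(lookup))]
  if (anyNA(per_record)) {
    stop("unknown diagnostic label: ",
         diagnostics[which(is.na(per_record))[1L]], call. = FALSE)
  }
  max(per_record)
}

#' Total reported cases for one country after source deduplication
#'
#' Records sharing a `source_id` describe the same underlying case series;
#' to avoid double counting, only the original study (earliest
#' `study_year`, ties broken by study_id order) contributes its case
#' count. The country total is the sum over distinct sources.
#'
#' @param records Data frame of one country's occurrence records with
#'   columns case_count, source_id, study_year.
#' @return Non-negative integer case total.
#' @export
deduplicated_case_total <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) return(0L)
  total <- 0L
  for (src in unique(records$source_id)) {
    grp <- records[records$source_id == src, , drop = FALSE]
    grp <- grp[order(grp$study_year, grp$study_id), , drop = FALSE]
    total <- total + grp$case_count[1L]
  }
  as.integer(total)
}

#' Score a deduplicated case total into its evidence band
#'
#' More than 30 cases scores 6; more than 15 and at most 30 scores 4; more
#' than 5 and at most 15 scores 2; at most 5 cases scores 0. Lower bounds
#' are strict, upper bounds inclusive.
#'
#' @param n Non-negative integer case total.
#' @return Integer score in \{0, 2, 4, 6\}.
#' @export
#' @examples
#' score_case_count(31) # 6
#' score_case_count(30) # 4
score_case_count <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, !is.na(n))
  if (n < 0) stop("case total must be non-negative, got ", n, call. = FALSE)
  if (n > 30) 6L else if (n > 15) 4L else if (n > 5) 2L else 0L
}

#' Part A category scores for a country with published occurrence records
#'
#' Sums the four presence-evidence categories: health-organisation
#' agreement (-3/0/+3), contemporariness (1-3), diagnostics (1-3) and the
#' deduplicated case-count band (0/2/4/6). The maximum possible raw sum is
#' 15; with at least one record the minimum is -1.
#'
#' @param who,price Organisation claims (see [score_health_orgs()]).
#' @param records Non-empty data frame of the country's occurrence records
#'   (columns year, diagnostic, case_count, source_id, study_id,
#'   study_year).
#' @return List with components org, contemporariness, diagnostics, cases,
#'   total and max_possible (15).
#' @export
part_a_total <- function(who, price, records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    stop("Part A requires at least one occurrence record; ",
         "countries without records are scored on the Part B pathway",
         call. = FALSE)
  }
  org <- score_health_orgs(who, price)
  contemporariness <- score_contemporariness(records$year)
  diagnostics <- score_diagnostics(records$diagnostic)
  cases <- score_case_count(deduplicated_case_total(records))
  list(org = org,
       contemporariness = contemporariness,
       diagnostics = diagnostics,
       cases = cases,
       total = org + contemporariness + diagnostics + cases,
       max_possible = 15L)
}
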