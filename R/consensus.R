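#' Evidence-consensus result for a single country
#'
#' Routes a country down one of three mutually exclusive pathways:
#' \describe{
#'   \item{Part A}{at least one occurrence record: the four
#'     presence-evidence categories are summed (maximum 15) and expressed
#'     as a percentage of the maximum.}
#'   \item{Organisation-only}{no records but the WHO map or the Price
#'     monograph claims presence: the claim without literature support is
#'     treated as uninformative and the country is pinned to 0,
#'     indeterminate.}
#'   \item{Part B}{no records and no presence claim: the absence score
#'     (maximum 3) measures how little the lack of reports means; a fully
#'     uninformative absence maps to 0 and a fully informative one to
#'     -100.}
#' }
#'
#' @param country ISO3 code (used in error messages and the result row).
#' @param who,price Organisation claims ("PRESENT", "ABSENT", "NO_CLAIM").
#' @param records Data frame of the country's occurrence records (0 rows
#'   allowed).
#' @param haq,sdi,lf_endemic,leprosy_endemic,tu_endemic Country metrics;
#'   may be NA for countries resolved on the Part A or organisation-only
#'   pathway, but are required for Part B.
#' @param weights A [misdiagnosis_weights()] object.
#' @return One-row data frame with columns country, part ("A", "B" or
#'   "ORG_ONLY"), raw_sum, max_possible, score (integer percent in
#'   \[-100, 100\]) and category (band label).
#' @export
#' @examples
#' recs <- data.frame(country = "ETH", year = 2013L,
#'                    diagnostic = "SIME_ALGORITHM", case_count = 1537L,
#'                    study_id = "s1", source_id = "eth1",
#'                    study_year = 2013L)
#' score_country("ETH", "PRESENT", "PRESENT", recs)
score_country <- function(country, who, price, records,
                          haq = NA_real_, sdi = NA_real_,
                          lf_endemic = NA, leprosy_endemic = NA,
                          tu_endemic = NA,
                          weights = misdiagnosis_weights()) {
  stopifnot(is.data.frame(records))
  if (nrow(records) > 0L) {
    a <- part_a_total(who, price, records)
    raw <- a$total
    maxp <- 15
    part <- "A"
    pct <- consensus_percent_part_a(raw)
  } else if (toupper(who) == "PRESENT" || toupper(price) == "PRESENT") {
    raw <- score_health_orgs(who, price)
    maxp <- 15
    part <- "ORG_ONLY"
    pct <- 0L
  } else {
    if (anyNA(c(haq, sdi)) || anyNA(c(lf_endemic, leprosy_endemic,
                                      tu_endemic))) {
      stop("country '", country, "' has no occurrence records and no ",
           "organisational presence claim, but its metrics (HAQ, SDI, ",
           "endemicity flags) are missing, so the Part B absence score ",
           "cannot be computed", call. = FALSE)
    }
    b <- part_b_total(weights, haq, sdi, lf_endemic, leprosy_endemic,
                      tu_endemic)
    raw <- b$absence_total
    maxp <- 3
    part <- "B"
    pct <- consensus_percent_part_b(raw)
  }
  data.frame(country = country, part = part, raw_sum = raw,
             max_possible = maxp, score = pct,
             category = classify_band(pct), stringsAsFactors = FALSE)
}

#' Fit an evidence consensus over a set of countries
#'
#' The main entry point: joins the evidence, organisation and metrics
#' tables on ISO3 code, scores every country that appears in any of them
#' via [score_country()], and returns a classed object with print, summary
#' and plot methods. Countries absent from the organisation table are
#' treated as NO_CLAIM by both sources.
#'
#' @param evidence Data frame of occurrence records (see
#'   [read_evidence_table()]); may have 0 rows.
#' @param orgs Data frame of organisation assessments (see
#'   [read_orgs_table()]).
#' @param metrics Data frame of country metrics (see
#'   [read_metrics_table()]).
#' @param weights A [misdiagnosis_weights()] object.
#' @param haq_rescale How to turn the HAQ Index into the 0-1 capacity
#'   deficit: `"fixed"` (default) uses the index's own 0-100 scale,
#'   `1 - haq/100`, so a country's score never depends on which other
#'   countries are loaded; `"minmax"` rescales over the loaded set.
#' @return Object of class `evidence_consensus` with components `results`
#'   (one row per country: country, part, raw_sum, max_possible, score,
#'   category, continent), `weights`, `haq_rescale` and `call`.
#' @export
evidence_consensus <- function(evidence, orgs, metrics,
                               weights = misdiagnosis_weights(),
                               haq_rescale = c("fixed", "minmax")) {
  haq_rescale <- match.arg(haq_rescale)
  evidence <- validate_evidence(evidence)
  orgs <- validate_orgs(orgs)
  metrics <- validate_metrics(metrics)

  countries <- sort(unique(c(evidence$country, orgs$country,
                             metrics$country)))
  if (length(countries) == 0L) {
    stop("no countries found in any input table", call. = FALSE)
  }

  haq_eff <- metrics$haq
  if (haq_rescale == "minmax" && nrow(metrics) > 1L) {
    rng <- range(metrics$haq)
    if (diff(rng) > 0) {
      haq_eff <- 100 * (metrics$haq - rng[1L]) / diff(rng)
    }
  }

  rows <- vector("list", length(countries))
  for (i in seq_along(countries)) {
    cc <- countries[i]
    o <- orgs[orgs$country == cc, , drop = FALSE]
    who <- if (nrow(o)) o$who else "NO_CLAIM"
    price <- if (nrow(o)) o$price else "NO_CLAIM"
    m <- which(metrics$country == cc)
    rows[[i]] <- score_country(
      country = cc, who = who, price = price,
      records = evidence[evidence$country == cc, , drop = FALSE],
      haq = if (length(m)) haq_eff[m] else NA_real_,
      sdi = if (length(m)) metrics$sdi[m] else NA_real_,
      lf_endemic = if (length(m)) metrics$lf_endemic[m] else NA,
      leprosy_endemic = if (length(m)) metrics$leprosy_endemic[m] else NA,
      tu_endemic = if (length(m)) metrics$tu_endemic[m] else NA,
      weights = weights)
  }
  results <- do.call(rbind, rows)
  results$continent <- metrics$continent[match(results$country,
                                               metrics$country)]
  results <- results[order(-results$score, results$country), ]
  rownames(results) <- NULL

  structure(list(results = results, weights = weights,
                 haq_rescale = haq_rescale, call = match.call()),
            class = "evidence_consensus")
}

#' @export
print.evidence_consensus <- function(x, ...) {
  cat("Evidence consensus over", nrow(x$results), "countries\n")
  cat("  pathways: ")
  print(table(x$results$part))
  top <- utils::head(x$results[, c("country", "score", "category")], 10L)
  print(top, row.names = FALSE)
  if (nrow(x$results) > 10L) {
    cat("  ...", nrow(x$results) - 10L, "more countries\n")
  }
  invisible(x)
}

#' @export
as.data.frame.evidence_consensus <- function(x, ...) {
  x$results
}

#' Summarise an evidence-consensus fit into the headline counts
#'
#' Computes the band tabulation, the number of countries in any presence
#' band (score of at least 25, i.e. positive values outside the
#' indeterminate range), the number with indeterminate status (0-24), and
#' the continental breakdown of the presence-band countries. Continent
#' comes from the metrics table supplied to the fit; a presence-band
#' country without a continent raises an error naming it.
#'
#' @param object An `evidence_consensus` fit.
#' @param ... Unused.
#' @return Object of class `summary.evidence_consensus` with components
#'   `by_band` (named integer vector over all ten bands),
#'   `presence_total`, `indeterminate_total`, `by_continent_presence` and
#'   `n`.
#' @export
summary.evidence_consensus <- function(object, ...) {
  r <- object$results
  by_band <- table(factor(r$category, levels = consensus_bands()))
  by_band <- setNames(as.integer(by_band), names(by_band))
  presence <- r[r$score >= 25, , drop = FALSE]
  if (nrow(presence) && anyNA(presence$continent)) {
    stop("no continent recorded for country '",
         presence$country[which(is.na(presence$continent))[1L]],
         "'; add it to the metrics table", call. = FALSE)
  }
  by_cont <- table(factor(presence$continent, levels = continent_levels()))
  structure(list(
    by_band = by_band,
    presence_total = sum(r$score >= 25),
    indeterminate_total = sum(r$score >= 0 & r$score <= 24),
    by_continent_presence = setNames(as.integer(by_cont), names(by_cont)),
    n = nrow(r)), class = "summary.evidence_consensus")
}

#' @export
print.summary.evidence_consensus <- function(x, ...) {
  cat("Countries scored:", x$n, "\n")
  cat("Presence bands (score >= 25):", x$presence_total, "\n")
  cat("Indeterminate (0-24):", x$indeterminate_total, "\n")
  cat("Presence by continent:\n")
  print(x$by_continent_presence[x$by_continent_presence > 0])
  cat("By band:\n")
  print(x$by_band[x$by_band > 0])
  invisible(x)
}

#' Plot the band distribution of an evidence-consensus fit
#'
#' Horizontal bar chart of country counts per consensus band, ordered from
#' consensus presence down to consensus absence.
#'
#' @param x An `evidence_consensus` fit.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.evidence_consensus <- function(x, ...) {
  counts <- summary(x)$by_band
  op <- graphics::par(mar = c(4, 14, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(counts), horiz = TRUE, las = 1,
                    xlab = "countries",
                    main = "Evidence consensus bands", ...)
  invisible(x)
}
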