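#' Configuration for a synthetic evidence landscape
#'
#' Describes a simulated world of countries with controllable evidence
#' density, study quality, case-count distribution, source sharing,
#' organisational claims and country metrics. Defaults emulate the broad
#' shape of the real landscape: most countries have no published
#' occurrence records, organisational claims are sparse, case series are
#' small with a heavy tail, and a modest fraction of studies re-report an
#' existing case series.
#'
#' @param n_countries Number of countries to simulate (positive integer).
#' @param seed Integer random seed; the same config always yields the same
#'   tables.
#' @param p_records Probability a country has any occurrence records
#'   (default 0.3).
#' @param record_year_range Inclusive year interval records are drawn from
#'   (default 1900-2019).
#' @param p_missing_year Probability a record's evidence year is missing
#'   (default 0.05).
#' @param diagnostic_mix Probabilities over the diagnostic classes
#'   (SIME_ALGORITHM, CLINICAL_PLUS_ICT, UNSPECIFIED); default
#'   c(0.2, 0.2, 0.6).
#' @param case_count_meanlog,case_count_sdlog Log-normal parameters of the
#'   per-study case count (rounded down; default meanlog log(12), sdlog
#'   1.2 — small series with a heavy tail).
#' @param mean_studies Mean number of studies for a country that has
#'   records (1 + Poisson(mean_studies - 1); default 2).
#' @param p_shared_source Probability a study after the first re-reports
#'   an earlier study's source (default 0.2).
#' @param org_claim_probabilities Probabilities over the three claim
#'   states (PRESENT, ABSENT, NO_CLAIM), applied independently to the WHO
#'   and Price sources; default c(0.25, 0.25, 0.5).
#' @param haq_range,sdi_range Uniform sampling intervals for the HAQ Index
#'   and SDI (defaults 20-95 and 0.2-0.9).
#' @param endemicity_probabilities Per-disease endemicity probabilities
#'   (lf, leprosy, tu); default c(0.4, 0.4, 0.3).
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(n_countries = 50L,
                            seed = 1L,
                            p_records = 0.3,
                            record_year_range = c(1900L, 2019L),
                            p_missing_year = 0.05,
                            diagnostic_mix = c(0.2, 0.2, 0.6),
                            case_count_meanlog = log(12),
                            case_count_sdlog = 1.2,
                            mean_studies = 2,
                            p_shared_source = 0.2,
                            org_claim_probabilities = c(0.25, 0.25, 0.5),
                            haq_range = c(20, 95),
                            sdi_range = c(0.2, 0.9),
                            endemicity_probabilities =
                              c(lf = 0.4, leprosy = 0.4, tu = 0.3)) {
  if (!is.numeric(n_countries) || n_countries < 1) {
    stop("n_countries must be a positive integer", call. = FALSE)
  }
  probs <- c(p_records, p_missing_year, p_shared_source,
             diagnostic_mix, org_claim_probabilities,
             endemicity_probabilities)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(diagnostic_mix) - 1) > 1e-9 ||
      abs(sum(org_claim_probabilities) - 1) > 1e-9) {
    stop("diagnostic_mix and org_claim_probabilities must each sum to 1",
         call. = FALSE)
  }
  if (diff(record_year_range) < 0 || diff(haq_range) < 0 ||
      diff(sdi_range) < 0) {
    stop("intervals must be well-ordered (low, high)", call. = FALSE)
  }
  structure(list(
    n_countries = as.integer(n_countries), seed = as.integer(seed),
    p_records = p_records, record_year_range = as.integer(record_year_range),
    p_missing_year = p_missing_year, diagnostic_mix = diagnostic_mix,
    case_count_meanlog = case_count_meanlog,
    case_count_sdlog = case_count_sdlog,
    mean_studies = mean_studies, p_shared_source = p_shared_source,
    org_claim_probabilities = org_claim_probabilities,
    haq_range = haq_range, sdi_range = sdi_range,
    endemicity_probabilities = endemicity_probabilities),
    class = "scenario_config")
}

synthetic_iso3 <- function(n) {
  # X-prefixed synthetic codes: XAA, XAB, ... never collide with real ISO3
  first <- (seq_len(n) - 1L) %/% 26L
  second <- (seq_len(n) - 1L) %% 26L
  if (any(first >= 26L)) stop("at most 676 synthetic countries", call. = FALSE)
  paste0("X", LETTERS[first + 1L], LETTERS[second + 1L])
}

#' Generate a synthetic evidence landscape with known ground truth
#'
#' Draws the three input tables from a [scenario_config()] and scores
#' every country with the independent oracle
#' ([score_country_oracle()]) to produce ground-truth results. The same
#' config (including seed) always returns identical tables.
#'
#' @param config A [scenario_config()].
#' @param weights [misdiagnosis_weights()] used for the ground truth.
#' @return List with components `evidence`, `orgs`, `metrics` (data frames
#'   in the standard schemas) and `truth` (oracle results, one row per
#'   country).
#' @export
#' @examples
#' sim <- generate_scenario(scenario_config(n_countries = 5, seed = 42))
#' sim$truth
generate_scenario <- function(config, weights = misdiagnosis_weights()) {
  stopifnot(inherits(config, "scenario_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  n <- config$n_countries
  iso3 <- synthetic_iso3(n)

  draw_status <- function(k) {
    sample(org_statuses(), k, replace = TRUE,
           prob = config$org_claim_probabilities)
  }
  orgs <- data.frame(country = iso3, who = draw_status(n),
                     price = draw_status(n), stringsAsFactors = FALSE)

  metrics <- data.frame(
    country = iso3,
    haq = round(runif(n, config$haq_range[1L], config$haq_range[2L]), 1),
    sdi = round(runif(n, config$sdi_range[1L], config$sdi_range[2L]), 3),
    lf_endemic = runif(n) < config$endemicity_probabilities[["lf"]],
    leprosy_endemic = runif(n) < config$endemicity_probabilities[["leprosy"]],
    tu_endemic = runif(n) < config$endemicity_probabilities[["tu"]],
    continent = sample(continent_levels(), n, replace = TRUE),
    stringsAsFactors = FALSE)

  ev_rows <- list()
  for (i in seq_len(n)) {
    if (runif(1) >= config$p_records) next
    n_studies <- 1L + rpois(1L, max(config$mean_studies - 1, 0))
    sources <- character(n_studies)
    for (s in seq_len(n_studies)) {
      if (s > 1L && runif(1) < config$p_shared_source) {
        sources[s] <- sample(sources[seq_len(s - 1L)], 1L)
      } else {
        sources[s] <- paste0(iso3[i], "_src", s)
      }
    }
    years <- sample(seq(config$record_year_range[1L],
                        config$record_year_range[2L]), n_studies,
                    replace = TRUE)
    years[runif(n_studies) < config$p_missing_year] <- NA_integer_
    ev_rows[[length(ev_rows) + 1L]] <- data.frame(
      country = iso3[i],
      year = years,
      diagnostic = sample(diagnostic_classes(), n_studies, replace = TRUE,
                          prob = config$diagnostic_mix),
      case_count = as.integer(floor(stats::rlnorm(
        n_studies, config$case_count_meanlog, config$case_count_sdlog))),
      study_id = paste0(iso3[i], "_study", seq_len(n_studies)),
      source_id = sources,
      study_year = ifelse(is.na(years),
                          config$record_year_range[2L],
                          pmin(years + sample(0:5, n_studies, replace = TRUE),
                               config$record_year_range[2L])),
      stringsAsFactors = FALSE)
  }
  evidence <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(country = character(), year = integer(),
               diagnostic = character(), case_count = integer(),
               study_id = character(), source_id = character(),
               study_year = integer(), stringsAsFactors = FALSE)
  evidence <- validate_evidence(evidence)
  orgs <- validate_orgs(orgs)
  metrics <- validate_metrics(metrics)

  truth <- do.call(rbind, lapply(seq_len(n), function(i) {
    score_country_oracle(
      country = iso3[i], who = orgs$who[i], price = orgs$price[i],
      records = evidence[evidence$country == iso3[i], , drop = FALSE],
      haq = metrics$haq[i], sdi = metrics$sdi[i],
      lf_endemic = metrics$lf_endemic[i],
      leprosy_endemic = metrics$leprosy_endemic[i],
      tu_endemic = metrics$tu_endemic[i],
      weights = weights)
  }))

  list(evidence = evidence, orgs = orgs, metrics = metrics, truth = truth)
}

#' Write a generated scenario to a directory
#'
#' @param sim A list as returned by [generate_scenario()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_scenario <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("evidence.csv", "orgs.csv", "metrics.csv",
                            "truth.csv"))
  write.csv(sim$evidence, paths[1L], row.names = FALSE, quote = FALSE,
            na = "")
  write.csv(sim$orgs, paths[2L], row.names = FALSE, quote = FALSE)
  m <- sim$metrics
  for (col in c("lf_endemic", "leprosy_endemic", "tu_endemic")) {
    m[[col]] <- as.integer(m[[col]])
  }
  write.csv(m, paths[3L], row.names = FALSE, quote = FALSE)
  write.csv(sim$truth, paths[4L], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
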