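#' @keywords internal
"_PACKAGE"

#' @importFrom utils read.csv write.csv
#' @importFrom stats rbinom rpois runif setNames
NULL

org_statuses <- function() c("PRESENT", "ABSENT", "NO_CLAIM")
diagnostic_classes <- function() {
  c("SIME_ALGORITHM", "CLINICAL_PLUS_ICT", "UNSPECIFIED")
}
continent_levels <- function() c("AFRICA", "ASIA", "LATIN_AMERICA", "OTHER")

check_iso3 <- function(country, what) {
  bad <- is.na(country) | !grepl("^[A-Za-z]{3}$", country)
  if (any(bad)) {
    stop(what, ": invalid ISO3 code at row ", which(bad)[1L], " ('",
         country[which(bad)[1L]], "')", call. = FALSE)
  }
  toupper(country)
}

check_header <- function(df, expected, path) {
  if (!identical(names(df), expected)) {
    stop("'", path, "': header must be '", paste(expected, collapse = ","),
         "', found '", paste(names(df), collapse = ","), "'", call. = FALSE)
  }
}

#' Validate an evidence table of occurrence records
#'
#' One row per study-country evidence item: ISO3 country, evidence year
#' (may be missing), diagnostic class, non-negative case count, a study
#' identifier, a source identifier marking records that describe the same
#' underlying case series (deduplication group), and the publication year
#' of the study.
#'
#' @param df Data frame with columns country, year, diagnostic, case_count,
#'   study_id, source_id, study_year.
#' @return The validated data frame (ISO3 upper-cased, types coerced).
#' @export
validate_evidence <- function(df) {
  stopifnot(is.data.frame(df))
  df$country <- check_iso3(as.character(df$country), "evidence table")
  df$year <- suppressWarnings(as.integer(df$year))
  df$diagnostic <- as.character(df$diagnostic)
  df$case_count <- suppressWarnings(as.integer(df$case_count))
  df$study_id <- as.character(df$study_id)
  df$source_id <- as.character(df$source_id)
  df$study_year <- suppressWarnings(as.integer(df$study_year))

  bad <- !df$diagnostic %in% diagnostic_classes()
  if (any(bad)) {
    stop("evidence table: unknown diagnostic label '",
         df$diagnostic[which(bad)[1L]], "' at row ", which(bad)[1L],
         call. = FALSE)
  }
  bad <- is.na(df$case_count) | df$case_count < 0L
  if (any(bad)) {
    stop("evidence table: case_count must be a non-negative integer at row ",
         which(bad)[1L], call. = FALSE)
  }
  bad <- !is.na(df$year) & (df$year < 1800L | df$year > 2019L)
  if (any(bad)) {
    stop("evidence table: year out of [1800, 2019] at row ", which(bad)[1L],
         call. = FALSE)
  }
  bad <- is.na(df$study_year)
  if (any(bad)) {
    stop("evidence table: missing study_year at row ", which(bad)[1L],
         call. = FALSE)
  }
  df
}

#' Validate a health-organisation assessment table
#'
#' One row per country carrying the WHO distribution-map claim and the
#' Price monograph claim, each PRESENT, ABSENT or NO_CLAIM.
#'
#' @param df Data frame with columns country, who, price.
#' @return The validated data frame.
#' @export
validate_orgs <- function(df) {
  stopifnot(is.data.frame(df))
  df$country <- check_iso3(as.character(df$country), "orgs table")
  for (col in c("who", "price")) {
    df[[col]] <- toupper(as.character(df[[col]]))
    bad <- !df[[col]] %in% org_statuses()
    if (any(bad)) {
      stop("orgs table: '", col, "' must be one of ",
           paste(org_statuses(), collapse = "|"), " at row ", which(bad)[1L],
           call. = FALSE)
    }
  }
  if (anyDuplicated(df$country)) {
    stop("orgs table: duplicate country '",
         df$country[anyDuplicated(df$country)], "'", call. = FALSE)
  }
  df
}

#' Validate a country metrics table
#'
#' One row per country: the Healthcare Access and Quality (HAQ) Index on
#' 0-100, the Socio-Demographic Index (SDI) on 0-1, endemicity flags for
#' the three confounding diseases (lymphatic filariasis, leprosy, tropical
#' ulcer) and the continent grouping used for regional summaries.
#'
#' @param df Data frame with columns country, haq, sdi, lf_endemic,
#'   leprosy_endemic, tu_endemic, continent.
#' @return The validated data frame (flags coerced to logical).
#' @export
validate_metrics <- function(df) {
  stopifnot(is.data.frame(df))
  df$country <- check_iso3(as.character(df$country), "metrics table")
  if (anyDuplicated(df$country)) {
    stop("metrics table: duplicate country '",
         df$country[anyDuplicated(df$country)], "'", call. = FALSE)
  }
  df$haq <- suppressWarnings(as.numeric(df$haq))
  df$sdi <- suppressWarnings(as.numeric(df$sdi))
  bad <- is.na(df$haq) | df$haq < 0 | df$haq > 100
  if (any(bad)) {
    stop("metrics table: haq outside [0, 100] at row ", which(bad)[1L],
         call. = FALSE)
  }
  bad <- is.na(df$sdi) | df$sdi < 0 | df$sdi > 1
  if (any(bad)) {
    stop("metrics table: sdi outside [0, 1] at row ", which(bad)[1L],
         call. = FALSE)
  }
  for (col in c("lf_endemic", "leprosy_endemic", "tu_endemic")) {
    v <- df[[col]]
    if (is.character(v)) {
      v <- trimws(v)
      conv <- rep(NA, length(v))
      conv[v %in% c("1", "TRUE", "true", "T")] <- TRUE
      conv[v %in% c("0", "FALSE", "false", "F")] <- FALSE
      v <- conv
    } else {
      v <- as.logical(v)
    }
    if (anyNA(v)) {
      stop("metrics table: '", col, "' must be 0/1 at row ",
           which(is.na(v))[1L], call. = FALSE)
    }
    df[[col]] <- v
  }
  df$continent <- toupper(as.character(df$continent))
  bad <- !df$continent %in% continent_levels()
  if (any(bad)) {
    stop("metrics table: continent must be one of ",
         paste(continent_levels(), collapse = "|"), " at row ",
         which(bad)[1L], call. = FALSE)
  }
  df
}

#' Read an evidence table from CSV
#'
#' @param path Path to a comma-delimited UTF-8 file with header
#'   `country,year,diagnostic,case_count,study_id,source_id,study_year`.
#'   Missing evidence years are written as empty fields.
#' @return Validated data frame of occurrence records (possibly 0 rows).
#' @export
read_evidence_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, colClasses = "character", strip.white = TRUE)
  check_header(df, c("country", "year", "diagnostic", "case_count",
                     "study_id", "source_id", "study_year"), path)
  df$year[df$year == ""] <- NA_character_
  validate_evidence(df)
}

#' Read a health-organisation assessment table from CSV
#'
#' @param path Path to a CSV with header `country,who,price`.
#' @return Validated data frame.
#' @export
read_orgs_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, colClasses = "character", strip.white = TRUE)
  check_header(df, c("country", "who", "price"), path)
  validate_orgs(df)
}

#' Read a country metrics table from CSV
#'
#' @param path Path to a CSV with header
#'   `country,haq,sdi,lf_endemic,leprosy_endemic,tu_endemic,continent`.
#' @return Validated data frame, one row per country.
#' @export
read_metrics_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, colClasses = "character", strip.white = TRUE)
  check_header(df, c("country", "haq", "sdi", "lf_endemic", "leprosy_endemic",
                     "tu_endemic", "continent"), path)
  validate_metrics(df)
}

#' Write an evidence table to CSV
#'
#' Inverse of [read_evidence_table()]; a write followed by a read
#' reproduces the same records.
#'
#' @param df Validated evidence data frame.
#' @param path Output path.
#' @export
write_evidence_table <- function(df, path) {
  df <- validate_evidence(df)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write consensus results to CSV
#'
#' Rows are sorted by descending consensus score, ties broken
#' alphabetically by country code, mirroring the published presentation.
#'
#' @param results Data frame of consensus results (as returned in the
#'   `results` component of an [evidence_consensus()] fit), with columns
#'   country, score, category, raw_sum, max_possible, part.
#' @param path Output path.
#' @export
write_results_table <- function(results, path) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L)
  cols <- c("country", "score", "category", "raw_sum", "max_possible", "part")
  missing_cols <- setdiff(cols, names(results))
  if (length(missing_cols)) {
    stop("results table missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  results <- results[order(-results$score, results$country), cols]
  write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
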