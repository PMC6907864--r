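iso3_property <- function(props) {
  candidates <- c("iso3", "ISO3", "iso_a3", "ISO_A3", "adm0_a3", "ADM0_A3")
  hit <- intersect(candidates, names(props))
  if (length(hit) == 0L) {
    stop("boundary file carries no ISO3 attribute (looked for ",
         paste(candidates, collapse = ", "), ")", call. = FALSE)
  }
  hit[1L]
}

#' Export consensus results as a band-attributed choropleth
#'
#' Joins consensus results to a country-boundary GeoJSON feature
#' collection keyed by ISO3 code and writes a new feature collection whose
#' properties are `iso3`, `score` and `band`. Boundary geometries pass
#' through untouched. Countries present in the boundary file but not
#' scored get band `"NOT_SCORED"` and a null score.
#'
#' @param results An `evidence_consensus` fit, or its results data frame
#'   (columns country, score, category); may have 0 rows.
#' @param boundaries Path to a GeoJSON FeatureCollection whose feature
#'   properties include an ISO3 code (any of iso3 / ISO_A3 / ADM0_A3,
#'   case-insensitively), or the already-parsed list.
#' @param path Output GeoJSON path.
#' @return Invisibly, the output path.
#' @export
export_choropleth <- function(results, boundaries, path) {
  if (inherits(results, "evidence_consensus")) results <- results$results
  stopifnot(is.data.frame(results))
  if (is.character(boundaries)) {
    if (!file.exists(boundaries)) {
      stop("boundary file not found: ", boundaries, call. = FALSE)
    }
    boundaries <- jsonlite::read_json(boundaries, simplifyVector = FALSE)
  }
  feats <- boundaries$features
  if (is.null(feats) || length(feats) == 0L) {
    stop("boundary file contains no features", call. = FALSE)
  }
  key <- iso3_property(feats[[1L]]$properties)

  out_feats <- lapply(feats, function(f) {
    iso3 <- toupper(as.character(f$properties[[key]]))
    i <- match(iso3, results$country)
    props <- if (is.na(i)) {
      list(iso3 = iso3, score = NULL, band = "NOT_SCORED")
    } else {
      list(iso3 = iso3, score = results$score[i],
           band = results$category[i])
    }
    list(type = "Feature", properties = props, geometry = f$geometry)
  })
  fc <- list(type = "FeatureCollection", features = out_feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' Write a plain-text summary report
#'
#' @param object A `summary.evidence_consensus` (or an
#'   `evidence_consensus` fit, which is summarised first).
#' @param path Output path.
#' @return Invisibly, the output path.
#' @export
write_summary_report <- function(object, path) {
  if (inherits(object, "evidence_consensus")) object <- summary(object)
  stopifnot(inherits(object, "summary.evidence_consensus"))
  writeLines(utils::capture.output(print(object)), path)
  invisible(path)
}
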