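# Build a one-country record set with sensible defaults.
make_records <- function(country = "ETH", year = 2013L,
                         diagnostic = "SIME_ALGORITHM", case_count = 100L,
                         study_id = NULL, source_id = NULL,
                         study_year = NULL) {
  n <- max(length(year), length(diagnostic), length(case_count))
  year <- rep_len(as.integer(year), n)
  if (is.null(study_id)) study_id <- paste0("study", seq_len(n))
  if (is.null(source_id)) source_id <- paste0("src", seq_len(n))
  if (is.null(study_year)) study_year <- ifelse(is.na(year), 2019L, year)
  data.frame(country = rep_len(country, n), year = year,
             diagnostic = rep_len(diagnostic, n),
             case_count = rep_len(as.integer(case_count), n),
             study_id = rep_len(study_id, n),
             source_id = rep_len(source_id, n),
             study_year = rep_len(as.integer(study_year), n),
             stringsAsFactors = FALSE)
}

empty_records <- function() {
  make_records()[0L, ]
}

# Toy 3-country boundary FeatureCollection written to a temp file.
make_boundaries <- function(iso3 = c("ETH", "KEN", "XXA"),
                            key = "ISO_A3") {
  feats <- lapply(seq_along(iso3), function(i) {
    ring <- list(list(i, 0), list(i + 1, 0), list(i + 1, 1), list(i, 1),
                 list(i, 0))
    props <- stats::setNames(list(iso3[i]), key)
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  path <- tempfile(fileext = ".geojson")
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  path
}
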