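#' Disease-specific misdiagnosis weights
#'
#' Relative propensities for podoconiosis to be misdiagnosed as each of
#' its confounding lymphedema causes: lymphatic filariasis (LF), leprosy
#' and tropical ulcer (TU). The weights are configuration inputs derived
#' from lymphedema surveys; equal weights are the default.
#'
#' @param lf,leprosy,tu Non-negative weights; at least one must be
#'   positive.
#' @return Named list of class `misdiagnosis_weights`.
#' @export
#' @examples
#' misdiagnosis_weights()            # equal weights 1/3 each
#' misdiagnosis_weights(0.5, 0.3, 0.2)
misdiagnosis_weights <- function(lf = 1 / 3, leprosy = 1 / 3, tu = 1 / 3) {
  w <- c(lf = lf, leprosy = leprosy, tu = tu)
  if (anyNA(w) || any(w < 0)) {
    stop("misdiagnosis weights must be non-negative", call. = FALSE)
  }
  if (sum(w) <= 0) {
    stop("misdiagnosis weights must not all be zero", call. = FALSE)
  }
  structure(as.list(w), class = "misdiagnosis_weights")
}

#' Composite misdiagnosis score for one country
#'
#' Sums the misdiagnosis weights of the confounding diseases the country
#' is endemic for and rescales by the attainable maximum (the sum of all
#' three configured weights), so a country co-endemic for LF, leprosy and
#' tropical ulcer always scores 1 regardless of the weight values.
#'
#' @param weights A [misdiagnosis_weights()] object.
#' @param lf_endemic,leprosy_endemic,tu_endemic Logical endemicity flags.
#' @return Real in \[0, 1\].
#' @export
composite_misdiagnosis <- function(weights, lf_endemic, leprosy_endemic,
                                   tu_endemic) {
  stopifnot(inherits(weights, "misdiagnosis_weights"))
  num <- weights$lf * isTRUE(lf_endemic) +
    weights$leprosy * isTRUE(leprosy_endemic) +
    weights$tu * isTRUE(tu_endemic)
  num / (weights$lf + weights$leprosy + weights$tu)
}

#' Diagnostic capacity factor from the HAQ Index
#'
#' The inverse of the Healthcare Access and Quality Index rescaled to
#' 0-1 on its fixed 0-100 scale: `1 - haq/100`. Higher for countries with
#' lower personal health-care access and quality, where misdiagnosis and
#' non-detection are more likely.
#'
#' @param haq HAQ Index value in \[0, 100\].
#' @return Real in \[0, 1\].
#' @export
#' @examples
#' diagnostic_capacity_factor(60) # 0.4
diagnostic_capacity_factor <- function(haq) {
  stopifnot(is.numeric(haq), length(haq) == 1L, !is.na(haq))
  if (haq < 0 || haq > 100) {
    stop("HAQ Index must lie in [0, 100], got ", haq, call. = FALSE)
  }
  1 - haq / 100
}

#' Diagnosis component of the Part B absence score
#'
#' The composite misdiagnosis score down-weighted by diagnostic capacity:
#' countries with strong health systems get little credit for confounder
#' endemicity because their absence of reports is more trustworthy.
#'
#' @inheritParams composite_misdiagnosis
#' @param haq HAQ Index value in \[0, 100\].
#' @return Real in \[0, 1\].
#' @export
diagnosis_score <- function(weights, haq, lf_endemic, leprosy_endemic,
                            tu_endemic) {
  composite_misdiagnosis(weights, lf_endemic, leprosy_endemic, tu_endemic) *
    diagnostic_capacity_factor(haq)
}

#' Surveillance component of the Part B absence score
#'
#' Equal to the diagnostic capacity factor: low health-care access and
#' quality is taken as a proxy for low surveillance capacity.
#'
#' @param haq HAQ Index value in \[0, 100\].
#' @return Real in \[0, 1\].
#' @export
surveillance_score <- function(haq) {
  diagnostic_capacity_factor(haq)
}

#' Sociodemographic component of the Part B absence score
#'
#' The inverse of the Socio-Demographic Index, `1 - sdi`, so the least
#' developed countries (highest propensity for podoconiosis) score 1.
#'
#' @param sdi SDI value in \[0, 1\].
#' @return Real in \[0, 1\].
#' @export
sociodemographic_score <- function(sdi) {
  stopifnot(is.numeric(sdi), length(sdi) == 1L, !is.na(sdi))
  if (sdi < 0 || sdi > 1) {
    stop("SDI must lie in [0, 1], got ", sdi, call. = FALSE)
  }
  1 - sdi
}

#' Part B absence score for a country with no occurrence records
#'
#' Sum of the three equally weighted components — diagnosis, surveillance
#' and sociodemographic development — each in \[0, 1\]. The total in
#' \[0, 3\] is maximal for countries co-endemic for LF, leprosy and
#' tropical ulcer with low HAQ Index and low SDI, i.e. where absence of
#' reports is least informative.
#'
#' @param weights A [misdiagnosis_weights()] object.
#' @param haq HAQ Index in \[0, 100\].
#' @param sdi SDI in \[0, 1\].
#' @param lf_endemic,leprosy_endemic,tu_endemic Logical endemicity flags.
#' @return List with components diagnosis, surveillance, sociodemographic,
#'   absence_total and max_possible (3).
#' @export
#' @examples
#' w <- misdiagnosis_weights()
#' part_b_total(w, haq = 60, sdi = 0.5, TRUE, TRUE, TRUE)$absence_total # 1.3
part_b_total <- function(weights, haq, sdi, lf_endemic, leprosy_endemic,
                         tu_endemic) {
  d <- diagnosis_score(weights, haq, lf_endemic, leprosy_endemic, tu_endemic)
  s <- surveillance_score(haq)
  sd <- sociodemographic_score(sdi)
  list(diagnosis = d,
       surveillance = s,
       sociodemographic = sd,
       absence_total = d + s + sd,
       max_possible = 3)
}
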