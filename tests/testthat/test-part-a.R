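test_that("health organisation agreement scores +3 / 0 / -3", {
  expect_equal(score_health_orgs("PRESENT", "PRESENT"), 3L)
  expect_equal(score_health_orgs("ABSENT", "ABSENT"), -3L)
  expect_equal(score_health_orgs("PRESENT", "ABSENT"), 0L)
  expect_equal(score_health_orgs("ABSENT", "PRESENT"), 0L)
  # a lone claim (other source silent) is not agreement
  expect_equal(score_health_orgs("PRESENT", "NO_CLAIM"), 0L)
  expect_equal(score_health_orgs("NO_CLAIM", "ABSENT"), 0L)
  expect_equal(score_health_orgs("NO_CLAIM", "NO_CLAIM"), 0L)
})

test_that("contemporariness takes the best era among records", {
  expect_equal(score_contemporariness(c(1939L, 2013L)), 3L)
  expect_equal(score_contemporariness(1993L), 2L)
  expect_equal(score_contemporariness(1939L), 1L)
  expect_equal(score_contemporariness(integer()), 0L)
  # era boundaries
  expect_equal(score_contemporariness(1999L), 2L)
  expect_equal(score_contemporariness(2000L), 3L)
  expect_equal(score_contemporariness(1990L), 2L)
  expect_equal(score_contemporariness(1989L), 1L)
  # missing year still evidences presence, most conservative class
  expect_equal(score_contemporariness(NA_integer_), 1L)
  expect_equal(score_contemporariness(c(NA, 1995L)), 2L)
})

test_that("diagnostic rigour takes the best method among records", {
  expect_equal(score_diagnostics(c("SIME_ALGORITHM", "UNSPECIFIED")), 3L)
  expect_equal(score_diagnostics("CLINICAL_PLUS_ICT"), 2L)
  expect_equal(score_diagnostics("UNSPECIFIED"), 1L)
  expect_equal(score_diagnostics(character()), 0L)
  expect_error(score_diagnostics("PCR"), "unknown diagnostic")
})

test_that("case totals deduplicate by source, keeping the original study", {
  # same source: earliest study_year wins
  recs <- make_records(year = c(1980L, 2005L), case_count = c(40L, 35L),
                       diagnostic = "UNSPECIFIED",
                       source_id = c("s", "s"), study_year = c(1980L, 2005L))
  expect_equal(deduplicated_case_total(recs), 40L)
  # distinct sources sum
  recs2 <- make_records(year = c(1980L, 2005L), case_count = c(10L, 10L),
                        diagnostic = "UNSPECIFIED")
  expect_equal(deduplicated_case_total(recs2), 20L)
  expect_equal(deduplicated_case_total(make_records(case_count = 12L)), 12L)
  expect_equal(deduplicated_case_total(empty_records()), 0L)
  # tie on study_year broken deterministically by study_id order
  recs3 <- make_records(case_count = c(7L, 9L), source_id = c("s", "s"),
                        study_id = c("b", "a"), study_year = c(2000L, 2000L))
  expect_equal(deduplicated_case_total(recs3), 9L)
})

test_that("case-count bands use strict lower, inclusive upper boundaries", {
  cases <- c(0L, 5L, 6L, 12L, 15L, 16L, 30L, 31L, 1537L)
  bands <- c(0L, 0L, 2L, 2L, 2L, 4L, 4L, 6L, 6L)
  expect_equal(vapply(cases, score_case_count, integer(1)), bands)
  expect_error(score_case_count(-1), "non-negative")
})

test_that("part A totals sum the four categories and cap at 15", {
  a <- part_a_total("PRESENT", "PRESENT", make_records(case_count = 1537L))
  expect_equal(a[c("org", "contemporariness", "diagnostics", "cases")],
               list(org = 3L, contemporariness = 3L, diagnostics = 3L,
                    cases = 6L))
  expect_equal(a$total, 15L)
  expect_equal(a$max_possible, 15L)

  weak <- part_a_total("PRESENT", "ABSENT",
                       make_records(year = 1939L, diagnostic = "UNSPECIFIED",
                                    case_count = 0L))
  expect_equal(weak$total, 2L)

  negative <- part_a_total("ABSENT", "ABSENT",
                           make_records(year = 1939L,
                                        diagnostic = "UNSPECIFIED",
                                        case_count = 3L))
  expect_equal(negative$total, -1L)

  expect_error(part_a_total("PRESENT", "PRESENT", empty_records()), "Part B")
})

test_that("adding evidence never decreases any Part A category or the total", {
  set.seed(101)
  years <- c(NA, 1850:2019)
  diags <- c("SIME_ALGORITHM", "CLINICAL_PLUS_ICT", "UNSPECIFIED")
  for (rep in 1:50) {
    n <- sample(1:6, 1)
    recs <- make_records(
      year = sample(years, n, replace = TRUE),
      diagnostic = sample(diags, n, replace = TRUE),
      case_count = sample(0:60, n, replace = TRUE),
      source_id = paste0("s", sample(1:4, n, replace = TRUE)),
      study_year = sample(1900:2019, n, replace = TRUE))
    extra <- make_records(
      year = sample(years, 1), diagnostic = sample(diags, 1),
      case_count = sample(0:60, 1), source_id = "s_new",
      study_id = "study_new", study_year = sample(1900:2019, 1))
    before <- part_a_total("PRESENT", "NO_CLAIM", recs)
    after <- part_a_total("PRESENT", "NO_CLAIM", rbind(recs, extra))
    expect_gte(after$contemporariness, before$contemporariness)
    expect_gte(after$diagnostics, before$diagnostics)
    expect_gte(after$cases, before$cases)
    expect_gte(after$total, before$total)
    expect_gte(deduplicated_case_total(rbind(recs, extra)),
               deduplicated_case_total(recs))
    # range invariant for any country with at least one record
    expect_true(before$total >= -1L && before$total <= 15L)
  }
})
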