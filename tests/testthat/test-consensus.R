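test_that("Part A percentages round half away from zero, not by truncation", {
  expect_equal(consensus_percent_part_a(15), 100L)
  expect_equal(consensus_percent_part_a(14), 93L)
  expect_equal(consensus_percent_part_a(10), 67L)  # 66.67 rounds up
  expect_equal(consensus_percent_part_a(7), 47L)   # 46.67
  expect_equal(consensus_percent_part_a(4), 27L)   # 26.67
  expect_equal(consensus_percent_part_a(1), 7L)    # 6.67
  expect_equal(consensus_percent_part_a(-1), -7L)  # away from zero
  expect_error(consensus_percent_part_a(16), "\\[-3, 15\\]")
})

test_that("rounding matches an exact rational computation for every raw sum", {
  for (k in -3:15) {
    # percent = 20k/3; half-away = sign * floor((|40k| + 3) / 6), exactly
    exact <- sign(k) * ((abs(k) * 40L + 3L) %/% 6L)
    expect_identical(consensus_percent_part_a(k), as.integer(exact))
  }
})

test_that("Part B percentages run from -100 (informative absence) to 0", {
  expect_equal(consensus_percent_part_b(0), -100L)
  expect_equal(consensus_percent_part_b(3), 0L)
  expect_equal(consensus_percent_part_b(2.4), -20L)
  expect_equal(consensus_percent_part_b(0.2), -93L)
  expect_error(consensus_percent_part_b(3.1), "\\[0, 3\\]")
  # monotone: more absence-score (less informative) -> closer to 0
  vals <- vapply(seq(0, 3, by = 0.1), consensus_percent_part_b, integer(1))
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals <= 0L))
})

test_that("every integer percent maps to exactly one band", {
  percents <- -100:100
  bands <- classify_band(percents)
  expect_true(all(bands %in% consensus_bands()))
  expect_equal(classify_band(100L), "Consensus presence")
  expect_equal(classify_band(73L), "Strong evidence for presence")
  expect_equal(classify_band(27L), "Moderate evidence for presence")
  expect_equal(classify_band(7L), "Indeterminate")
  expect_equal(classify_band(-20L), "Weak evidence of absence")
  expect_equal(classify_band(-100L), "Consensus absence")
  # boundaries on both sides
  expect_equal(classify_band(c(99L, 75L, 74L, 50L, 49L, 25L, 24L, 0L)),
               c("Very strong evidence for presence",
                 "Very strong evidence for presence",
                 "Strong evidence for presence",
                 "Strong evidence for presence",
                 "Moderate evidence for presence",
                 "Moderate evidence for presence",
                 "Indeterminate", "Indeterminate"))
  expect_equal(classify_band(c(-1L, -24L, -25L, -49L, -50L, -74L, -75L, -99L)),
               c("Weak evidence of absence", "Weak evidence of absence",
                 "Moderate evidence of absence", "Moderate evidence of absence",
                 "Strong evidence of absence", "Strong evidence of absence",
                 "Very strong evidence of absence",
                 "Very strong evidence of absence"))
  # each band is a contiguous run covering the full range
  expect_equal(length(rle(bands)$values), 10L)
  expect_error(classify_band(101), "\\[-100, 100\\]")
  expect_error(classify_band(12.5), "integer")
})

test_that("score_country routes the three pathways with the right signs", {
  w <- misdiagnosis_weights()
  # Part A: strong recent gold-standard evidence
  a <- score_country("ETH", "PRESENT", "PRESENT",
                     make_records(case_count = 1537L), weights = w)
  expect_equal(a$part, "A")
  expect_equal(a$score, 100L)
  expect_equal(a$category, "Consensus presence")

  # organisation-only claim pins to 0 / indeterminate
  b <- score_country("AGO", "NO_CLAIM", "PRESENT", empty_records(),
                     weights = w)
  expect_equal(b$part, "ORG_ONLY")
  expect_equal(b$score, 0L)
  expect_equal(b$category, "Indeterminate")
  b2 <- score_country("NER", "PRESENT", "NO_CLAIM", empty_records(),
                      haq = 35.8, sdi = 0.23, lf_endemic = TRUE,
                      leprosy_endemic = TRUE, tu_endemic = TRUE, weights = w)
  expect_equal(b2$score, 0L)  # metrics present but the claim still overrides

  # Part B: developed, non-endemic country -> near consensus absence
  # diagnosis 0 (no confounders), surveillance 0.05, sociodemographic 0.1:
  # absence 0.15 -> -(1 - 0.05) * 100 = -95
  c1 <- score_country("ZZZ", "NO_CLAIM", "NO_CLAIM", empty_records(),
                      haq = 95, sdi = 0.9, lf_endemic = FALSE,
                      leprosy_endemic = FALSE, tu_endemic = FALSE,
                      weights = w)
  expect_equal(c1$part, "B")
  expect_equal(c1$score, -95L)
  expect_equal(c1$category, "Very strong evidence of absence")

  # Part B: low-HAQ co-endemic country -> weak absence, never positive
  # absence = 0.8 + 0.8 + 0.85 = 2.45 -> -(1 - 2.45/3) * 100 = -18.33
  c2 <- score_country("ZZY", "NO_CLAIM", "ABSENT", empty_records(),
                      haq = 20, sdi = 0.15, lf_endemic = TRUE,
                      leprosy_endemic = TRUE, tu_endemic = TRUE, weights = w)
  expect_equal(c2$score, -18L)
  expect_equal(c2$category, "Weak evidence of absence")

  # Part B without metrics is an error naming the country
  expect_error(score_country("ZZX", "NO_CLAIM", "NO_CLAIM", empty_records(),
                             weights = w), "ZZX")
})

test_that("pathway sign conventions hold over a sweep of inputs", {
  w <- misdiagnosis_weights()
  # Part A floor: worst case org -3 with one record is -1/15 -> -7
  worst <- score_country("AAA", "ABSENT", "ABSENT",
                         make_records(year = 1939L,
                                      diagnostic = "UNSPECIFIED",
                                      case_count = 0L), weights = w)
  expect_gte(worst$score, -20L)
  # Part B is never positive
  for (haq in c(0, 50, 100)) for (sdi in c(0, 0.5, 1)) {
    s <- score_country("BBB", "NO_CLAIM", "NO_CLAIM", empty_records(),
                       haq = haq, sdi = sdi, lf_endemic = TRUE,
                       leprosy_endemic = FALSE, tu_endemic = TRUE,
                       weights = w)
    expect_lte(s$score, 0L)
    expect_gte(s$score, -100L)
  }
})

test_that("evidence_consensus joins the three tables and orders results", {
  fx <- table1_fixture()
  fit <- evidence_consensus(fx$evidence, fx$orgs, fx$metrics)
  expect_s3_class(fit, "evidence_consensus")
  expect_equal(nrow(fit$results), 27L)
  # descending score, ties alphabetical
  expect_true(all(diff(fit$results$score) <= 0))
  expect_equal(fit$results$country[1L], "CMR")
  # a country in orgs but not metrics still scores on the A/org pathways
  fit2 <- evidence_consensus(fx$evidence, fx$orgs, fx$metrics[1:26, ])
  expect_equal(nrow(fit2$results), 27L)
  # print and as.data.frame work
  expect_output(print(fit), "Evidence consensus over 27 countries")
  expect_equal(as.data.frame(fit), fit$results)
})

test_that("min-max HAQ rescaling is available but off by default", {
  fx <- table1_fixture()
  fit_fixed <- evidence_consensus(fx$evidence, fx$orgs, fx$metrics)
  fit_mm <- evidence_consensus(fx$evidence, fx$orgs, fx$metrics,
                               haq_rescale = "minmax")
  # no Part B country in the fixture, so the switch changes nothing here
  expect_equal(fit_fixed$results$score, fit_mm$results$score)
  # with a Part B country, the extremes of the loaded set define the scale
  orgs <- data.frame(country = c("XAA", "XAB"), who = "NO_CLAIM",
                     price = "NO_CLAIM")
  metrics <- data.frame(country = c("XAA", "XAB"), haq = c(40, 80),
                        sdi = c(0.5, 0.5), lf_endemic = TRUE,
                        leprosy_endemic = TRUE, tu_endemic = TRUE,
                        continent = "OTHER")
  ev <- empty_records()
  mm <- evidence_consensus(ev, orgs, metrics, haq_rescale = "minmax")
  r <- mm$results
  # lowest-HAQ country behaves as haq 0, highest as haq 100
  expect_equal(r$raw_sum[r$country == "XAA"], 1 + 1 + 0.5)
  expect_equal(r$raw_sum[r$country == "XAB"], 0 + 0 + 0.5)
})
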