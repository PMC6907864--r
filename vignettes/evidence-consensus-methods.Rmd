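---
title: "Evidence-consensus scoring of national podoconiosis status: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-consensus scoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(podoconsensus)
```

## The problem

Podoconiosis (non-filarial elephantiasis) is a lower-leg lymphedema caused
by long-term barefoot exposure to irritant red-clay soils. Its global
distribution is poorly known: it is routinely misdiagnosed as lymphatic
filariasis (LF), leprosy-related lymphedema or tropical ulcer (TU), and
surveillance is weakest exactly where the disease is most plausible. A
binary endemic/non-endemic call per country would overstate what the
evidence supports. This package instead assigns every country an
*evidence consensus*: a percentage in [−100, +100] expressing how strongly
the assembled evidence supports presence (positive) or absence (negative),
which is then binned into ordinal certainty bands (consensus at ±100, very
strong, strong, moderate, then an indeterminate zone at 0–24 and a weak
absence zone at −1 to −24).

## The scoring model

Every country is routed down exactly one of three mutually exclusive
pathways.

**Part A — countries with at least one published occurrence record.**
Four categories are summed:

| category              | values        | rule |
|-----------------------|---------------|------|
| health organisations  | −3, 0, +3     | +3 if the WHO map and the Price monograph agree on presence, −3 if they agree on absence, 0 otherwise (including any lone claim) |
| contemporariness      | 1, 2, 3       | 3 for evidence from 2000 onwards, 2 for the 1990s, 1 before 1990 |
| diagnostics           | 1, 2, 3       | 3 for the Sime clinical algorithm (gold standard), 2 for clinical diagnosis plus an ICT card test excluding LF, 1 for case reports without diagnostic detail |
| case count            | 0, 2, 4, 6    | after source deduplication: >30 cases → 6, 16–30 → 4, 6–15 → 2, ≤5 → 0 |

The contemporariness and diagnostics categories take the **maximum over a
country's records**, not the sum. This is forced by the score ceiling: a
country with many high-quality studies must top out at the Part A maximum
of 15, so each category saturates at its best single item. Case counts,
by contrast, are summed across *distinct sources*: when several studies
report the same case series (same `source_id`), only the original study —
the one with the earliest publication year, ties broken by study
identifier — contributes, so cases are never double-counted.

The consensus percentage is `raw / 15 × 100`, rounded half away from zero.

**Organisation-only countries.** A country with no literature but a
presence claim from the WHO map *or* the Price monograph is pinned to 0,
indeterminate. A claim without supporting literature is treated as exactly
balanced evidence: it neither raises nor lowers the score.

**Part B — countries with no records and no presence claim.** Absence of
reports is only informative where podoconiosis would have been detected if
present. The absence score sums three equally weighted components, each in
[0, 1]:

* **diagnosis** — a composite misdiagnosis score (the weights of the
  confounders the country is endemic for, rescaled by the sum of all three
  configured weights) multiplied by the diagnostic capacity deficit
  `1 − HAQ/100`;
* **surveillance** — the capacity deficit `1 − HAQ/100` itself;
* **sociodemographic** — `1 − SDI`, the propensity for podoconiosis by
  development level.

The total in [0, 3] is highest where absence of reports means least. The
percentage is `−(1 − absence/3) × 100`: a fully developed, non-endemic
country (absence ≈ 0) lands at consensus absence (−100), while a low-HAQ
country co-endemic for LF, leprosy and TU drifts toward 0, ending in the
weak-absence band. The direction is fixed by the published band outcomes;
the superficially simpler `−absence/3 × 100` would invert them and is
rejected.

## Tunable parameters

* **Misdiagnosis weights** (`misdiagnosis_weights()`): non-negative
  relative propensities for misdiagnosis as LF, leprosy and TU,
  dimensionless. The published values derive from lymphedema surveys in a
  supplement that is not machine-readable, so the package defaults to
  equal weights (1/3 each) and takes real values as configuration. Because
  the composite is rescaled by the sum of all three weights, a fully
  co-endemic country scores composite 1 under *any* positive weights, and
  the Part A pathway never touches them — so the packaged 27-country
  results are invariant to this choice.
* **HAQ rescaling** (`haq_rescale`): the capacity deficit uses the HAQ
  Index's own fixed 0–100 scale by default (`1 − haq/100`), so one
  country's score never changes when another country is added to the
  table. A min–max alternative over the loaded country set is exposed as a
  switch for sensitivity analysis, with the determinism caveat that it
  makes scores dataset-relative.

## Numerical choices

* **Rounding** is half away from zero to integers (10/15 → 67, 1/15 → 7);
  truncation or banker's rounding would contradict the published scores.
  Bands are applied to the rounded integer, not the raw real value.
* **Half ties**: with decimal HAQ/SDI inputs the Part B percentage can be
  an exact half that floating point represents just below it. Values
  within 1e-9 of a half are treated as halves and rounded away from zero,
  in both the pipeline and the verification oracle (each through its own
  arithmetic).
* **Missing evidence year** scores contemporariness 1: the record still
  evidences presence, so it takes the most conservative positive class.
  Years after 2019 would score 3 — the 2000–2019 window is a search
  cutoff, not an evidentiary ceiling.
* **Degenerate inputs**: a Part A call with no records is an error
  directing the caller to Part B; a Part B country with no metrics row is
  an error naming the country; readers reject, with a row number, any row
  violating a type invariant rather than coercing.

## The packaged 27-country fixture

`table1_fixture()` ships input tables for the 27 countries of the
published national listing (17 presence-band, 10 indeterminate) together
with their expected scores and bands, plus the continent lookup used by
the regional summaries. The published listing prints only (country, score,
category); the underlying per-country evidence ledger is not
machine-readable. The packaged evidence rows are therefore **synthetic
reconstructions**: study years, diagnostic classes, case counts and
organisational claims chosen to match the published narrative where it
speaks and to reproduce every printed score exactly. Where several input
combinations give the same score, the narrative-closest one was chosen;
two countries could not satisfy both constraints at once and follow the
score (per-country notes sit beside the fixture accessor in the source):

* **Democratic Republic of Congo** (printed 7, raw sum 1): only attainable
  with organisational agreement on absence (−3) plus a pre-1990 record and
  a 6–15 case series, although the narrative describes a lone monograph
  claim (which would give 0 and a minimum sum of 2).
* **Brazil** (printed 40, raw sum 6): with the narrative's three total
  cases (band 0) this requires organisational agreement on presence.

```{r fixture}
fx <- table1_fixture()
fit <- evidence_consensus(fx$evidence, fx$orgs, fx$metrics)
summary(fit)
```

## The synthetic-data generator and what passing tests show

`generate_scenario()` draws a world of countries from a
`scenario_config()`: a fraction with occurrence records (default 0.3, so
most countries exercise the Part B / organisation-only pathways), study
years over 1900–2019 with 5% missing, a diagnostic mix dominated by
unspecified reports (0.2/0.2/0.6), heavy-tailed log-normal case series
(median 12), a 0.2 chance that a later study re-reports an existing source,
independent sparse organisational claims (0.25/0.25/0.5 over
present/absent/no-claim per source), uniform HAQ over 20–95 and SDI over
0.2–0.9, and confounder endemicity probabilities 0.4/0.4/0.3. These
defaults are fixed descriptive choices emulating the broad shape of the
real evidence landscape — sparse, old, low-quality evidence for most
countries — not quantities estimated from it.

Ground truth comes from `score_country_oracle()`, a deliberately
straight-line transcription of the scoring rules (unrolled conditionals,
its own integer rounding, its own deduplication loop) sharing no code with
the pipeline. The test suite checks exact agreement between pipeline and
oracle on over a thousand seeded synthetic countries, alongside band
exhaustiveness over every integer percentage and monotonicity of both
pathways. Problem sizes in the default test run (4 × 300 synthetic
countries for the agreement checks, 80-country scenarios for schema
checks) keep the suite fast while covering all three pathways many times
over.

What the generator does *not* emulate: real geographic correlation between
neighbouring countries, correlation between HAQ, SDI and endemicity (in
reality strongly dependent), or realistic bibliographic structure. Passing
tests therefore demonstrate the *scoring rules* are implemented exactly —
not that the packaged reconstruction recovers the original evidence
ledger, and not anything about the true distribution of podoconiosis.

## Known limitations

* The framework produces a national point score with no uncertainty
  interval and no subnational resolution; heterogeneity within countries
  (well documented for this disease) is out of scope.
* Part B magnitudes depend on the configured misdiagnosis weights, whose
  published values are not machine-readable; with default equal weights,
  Part B band *boundaries* (limits at 0 and −100, monotonicity, sign) are
  exact but individual country magnitudes are configuration-dependent.
* The choropleth export attaches band labels to ISO3-keyed boundary
  geometries and deliberately leaves styling to downstream tools.
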