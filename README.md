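# podoconsensus

Evidence-consensus scoring of national podoconiosis status.

Podoconiosis (non-filarial elephantiasis) is a neglected tropical disease
caused by long-term barefoot exposure to irritant red-clay soils. Its
global distribution is uncertain: the disease is widely misdiagnosed as
lymphatic filariasis (LF), leprosy or tropical ulcer (TU), and
surveillance is weakest where it is most plausible. This package is for
epidemiologists and NTD programme analysts who need a defensible,
reproducible country-level classification of presence/absence with graded
certainty, rather than a binary endemic list.

## The scoring framework

Every country receives an **evidence consensus** percentage in
[−100, +100], via one of three mutually exclusive pathways:

* **Part A** (countries with published occurrence records): four evidence
  categories are summed — health-organisation agreement (−3/0/+3),
  contemporariness of the evidence (1–3), diagnostic rigour (1–3, with the
  Sime clinical algorithm as gold standard) and the source-deduplicated
  case-count band (0/2/4/6) — then expressed as a percentage of the
  maximum 15, rounded half away from zero:
  `percent = round(raw / 15 × 100)`.
* **Organisation-only**: a presence claim from the WHO map or Price's
  monograph with no supporting literature pins the country to 0
  (indeterminate).
* **Part B** (no records, no claim): an absence score in [0, 3] sums three
  equally weighted components — misdiagnosis propensity × diagnostic
  capacity deficit, the capacity deficit `1 − HAQ/100` itself, and
  development propensity `1 − SDI` — and maps to
  `percent = −(1 − absence/3) × 100`, so informative absence lands at −100
  and uninformative absence at 0.

Percentages bin into ordinal bands: consensus (±100), very strong
(±75–99), strong (±50–74), moderate (±25–49) presence or absence,
indeterminate (0–24) and weak evidence of absence (−1 to −24).

See the methods vignette
(`vignettes/evidence-consensus-methods.Rmd`) for the full model,
parameter and design discussion.

## Worked example

The package ships a 27-country fixture encoding the published national
results listing (evidence inputs are score-consistent synthetic
reconstructions; see the vignette):

```r
library(podoconsensus)
fx  <- table1_fixture()
fit <- evidence_consensus(fx$evidence, fx$orgs, fx$metrics)
summary(fit)
```

```
Countries scored: 27
Presence bands (score >= 25): 17
Indeterminate (0-24): 10
Presence by continent:
       AFRICA          ASIA LATIN_AMERICA
           12             2             3
By band:
               Consensus presence Very strong evidence for presence
                                6                                 1
     Strong evidence for presence    Moderate evidence for presence
                                4                                 6
                    Indeterminate
                               10
```

Seventeen countries carry evidence of presence (score ≥ 25): 12 in
Africa, 3 in Latin America, 2 in Asia, with complete consensus (score
100) in six. Ten countries are indeterminate — either a lone
organisational claim without literature (score 0) or weak, dated evidence
(Democratic Republic of Congo, score 7).

Other entry points:

* `score_country()` — one country, one pathway;
* `generate_scenario()` / `scenario_config()` — synthetic evidence
  landscapes with ground truth from an independent oracle
  (`score_country_oracle()`);
* `export_choropleth()` — band-attributed GeoJSON over any ISO3-keyed
  country-boundary file;
* `write_results_table()` / `write_summary_report()` — delimited and
  plain-text reports;
* `inst/cli/podoconsensus.R` — shell entry point with `score`,
  `simulate`, `map` and `validate-fixture` subcommands.

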