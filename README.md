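# metafrag

Fragility analysis of pairwise meta-analyses with binary outcomes.

A meta-analysis (MA) pools two-arm studies that each report event counts
`e1/n1` (treatment) and `e0/n0` (control). Its conclusion — whether the 95%
confidence interval of the pooled effect excludes the null — can hinge on
the outcomes of remarkably few patients. The **fragility index (FI)** of an
MA is the minimum number of single-patient event-status modifications,
distributed across the included studies, that alters the significance of
the pooled effect; the **fragility quotient (FQ)** is FI divided by the
total sample size. `metafrag` computes both under the analysis choices that
drive them, and quantifies how much an MA improves on the fragility of the
studies it includes.

## What is implemented

- **Study effects**: log odds ratio, log relative risk, and risk
  difference with their standard errors, applying the 0.5
  continuity correction to every study with a zero cell (events or
  non-events, either arm); double-zero studies are excluded for relative
  measures (configurable).
- **Pooling**: the fixed-effect (common-effect) model and the
  random-effects model `y_i ~ N(theta_i, s_i^2)`, `theta_i ~ N(theta,
  tau^2)`, with inverse-variance weights; `tau^2` by DerSimonian–Laird
  (closed form) or REML (fixed-point iteration, non-convergence reported,
  not raised); Cochran's Q, `I^2 = max(0, (Q - df)/Q)`; normal or
  Hartung–Knapp–Sidik–Jonkman (HKSJ) intervals. Five named scenarios: `FE`
  and `S1`–`S4` (REML/DL crossed with HKSJ/normal).
- **Fragility**: `fragility_ma()` — a greedy beam search over admissible
  single-patient flips, re-fitting the complete scenario after every
  candidate flip; `fragility_ma_exact()` — an exhaustive breadth-first
  oracle that enumerates all modification sets by size and returns the
  true minimum; `fragility_study()` — the per-trial index under Fisher's
  exact test.
- **Improvement**: the proportion of included studies whose FI is strictly
  smaller than the MA's FI, in percent, categorised as
  no (0%) / slight ((0, 50]) / considerable ((50, 100)) / complete (100%).
- **Corpus tooling**: scenario comparison across a corpus, paired FI and
  CI-length differences, sample-size/event bins, overlapping `I^2` bands,
  OR/RR magnitude bands, corpus summaries, and a seeded generator of
  Cochrane-like synthetic corpora.

## Worked example

```r
library(metafrag)

ma <- tibble::tibble(
  e1 = c(12, 11), n1 = c(20, 20),
  e0 = c(4, 5),   n0 = c(20, 20)
)

fit <- meta_pool(ma, scenario = "FE", measure = "OR")
fit
#> Meta-analysis (FE: FE), measure = OR
#>   log OR = 1.5325, 95% CI [0.5591, 2.5060], p = 0.002032  (significant)
#>   k = 2, tau2 = 0.0000, Q = 0.2451 (df = 1, p = 0.6205), I2 = 0.0%

frag <- fragility_ma(ma, scenario = "FE", measure = "OR")
frag
#> <fragility> greedy search, FE/OR, initially significant
#>   FI = 5 (toward_null), FQ = 0.0625 (total n = 80)

tidy(frag)
#> # A tibble: 5 x 6
#>    step study study_id   arm delta p_after
#>   <int> <int> <chr>    <int> <int>   <dbl>
#> 1     1     2 study_2      0     1 0.00447
#> 2     2     2 study_2      0     1 0.00935
#> 3     3     2 study_2      0     1 0.0185
#> 4     4     2 study_2      0     1 0.0344
#> 5     5     2 study_2      1    -1 0.0606
```

Five patients — four control-arm non-events becoming events and one
treatment-arm event becoming a non-event, all in study 2 — overturn the
significant pooled odds ratio (the final p-value crosses 0.05). The
exhaustive oracle `fragility_ma_exact(ma, "FE", "OR")` confirms 5 is the
true minimum, and `improvement(ma, "FE", "OR")` reports that both included
studies are individually more fragile than the MA (improvement proportion
100%, complete improvement).

Corpus-scale analysis follows the same grammar:

```r
corpus  <- generate_corpus(synthetic_config(n_mas = 200, seed = 1))
results <- run_scenarios(corpus, measures = "OR", fi = "significant")
summarize_corpus(results)
paired_differences(results, "S2", "S1")   # effect of dropping HKSJ
```

A thin command-line wrapper over the same functions ships at
`system.file("scripts", "metafrag", package = "metafrag")` with
subcommands `analyze`, `fi`, `scenarios`, `simulate`, `summarize`.

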