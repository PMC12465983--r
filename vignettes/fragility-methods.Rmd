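---
title: "Fragility of meta-analyses: models, search, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragility of meta-analyses: models, search, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`metafrag` measures how fragile the conclusion of a pairwise meta-analysis
(MA) of binary outcomes is: the minimum number of individual patients whose
event status would have to change for the pooled result to cross the
significance boundary. This vignette is the package's own account of the
models it fits, the search it runs, the choices that were genuinely open,
and what the synthetic-data machinery does and does not establish.

## The models

Each study $i$ contributes a 2×2 table $(e_{i1}, n_{i1}, e_{i0}, n_{i0})$,
arm 1 treatment, arm 0 control. Effects are analysed on the scale where the
null is 0: $\log \mathrm{OR}$, $\log \mathrm{RR}$, or the risk difference.
Standard errors use the usual closed forms (e.g.
$\sqrt{1/a + 1/b + 1/c + 1/d}$ for the log odds ratio). Any study with a
zero cell among events and non-events in either arm receives the 0.5
continuity correction **in all four cells**, so corrected arm sizes are
$n + 1$; the correction is re-resolved on every fit because event flips
create and remove zero cells. Studies with no events in either arm carry no
information about relative effects and are excluded for OR/RR by default
(`double_zero = "correct"` retains them; for RD they are always retained —
the risk difference is estimable there). These two policies are the
conventional ones; neither is forced by the estimands, which is why both
are configurable.

Pooling assumes $y_i \sim N(\theta_i, s_i^2)$ with $s_i$ known. The
fixed-effect model sets $\theta_i = \theta$ and pools with inverse-variance
weights. The random-effects model draws $\theta_i \sim N(\theta, \tau^2)$
and pools with weights $w_i^* = 1/(s_i^2 + \hat\tau^2)$. Between-study
variance is estimated by:

* **DerSimonian–Laird**: $\hat\tau^2_{DL} = \max\!\big(0,\, (Q - df) /
  (\sum w_i - \sum w_i^2 / \sum w_i)\big)$ with fixed-effect weights —
  non-iterative, never fails;
* **REML**: the fixed-point iteration
  $\tau^2 \leftarrow \sum w_i^{*2}\big[(y_i - \hat\theta)^2 - s_i^2\big] /
  \sum w_i^{*2} + 1/\sum w_i^*$, truncated at 0, started at
  $\hat\tau^2_{DL}$, tolerance $10^{-8}$ on successive iterates, at most
  100 iterations. Non-convergence is a reported state (`converged =
  FALSE`, missing estimates), mirroring how REML behaves on small or
  sparse MAs in practice; such MAs keep their DL and FE results and are
  excluded from REML-based corpus summaries. The iteration settings are
  package choices — REML itself does not prescribe them; in the
  equal-variance case the iteration provably converges to
  $\max(0, S^2_y - v)$, which the tests exploit as a closed-form oracle.

Confidence intervals are either normal ($\hat\theta \pm z_{0.975}
(\sum w_i^*)^{-1/2}$) or **HKSJ**: variance $\sum w_i^*(y_i -
\hat\theta)^2 / \big[(k-1)\sum w_i^*\big]$ with a $t_{k-1}$ interval. We
implement the *unmodified* HKSJ: no truncation guard, so with zero
dispersion (all informative $y_i$ equal) the interval collapses to a point;
such results are flagged `degenerate` and judged by the interval as
computed rather than patched. This is deliberate — patching would silently
change which datasets count as significant, which is exactly the quantity
under study. Five scenarios cover the analysis space: `FE`, and
`S1`–`S4` = {REML, DL} × {HKSJ, normal}. Significance always means the 95%
interval excludes 0 on the analysis scale, at $\alpha = 0.05$.

## The fragility search

One *modification* flips one patient's event status in one arm of one
study. After every candidate flip the entire scenario is re-fitted from raw
counts — corrections re-resolved, $\tau^2$ re-estimated — because a flip
can change the correction status of its study.

`fragility_ma()` runs a layered **beam search**: at each depth every
retained state is expanded by its admissible flips, all new states are
fitted in one vectorised batch, and the `beam` states (default 30) whose
p-values lie furthest toward the boundary survive. For an initially
significant MA with $\hat\theta > 0$ the admissible flips are
$e_{i1} \to e_{i1} - 1$ or $e_{i0} \to e_{i0} + 1$ (mirrored for
$\hat\theta < 0$), so every step of the returned plan weakly moves the
estimate toward the null. Two subtleties, found by adjudicating against
the exhaustive oracle, shaped the final design:

* A *second, unrestricted* run accompanies the directional one for
  significant MAs, and the shorter plan wins. Rarely, the true minimum
  works through the variance rather than the estimate — e.g. a
  "wrong-direction" flip creates a zero cell whose correction inflates the
  standard error enough to de-significate the result. The `candidates`
  field records which run produced the plan; directional winners satisfy
  the monotone-estimate property, widened winners legitimately need not.
* For initially nonsignificant MAs all four flip types per study are
  admissible, which subsumes searching both significance directions and
  also reaches HKSJ "dispersion-collapse" solutions (flips that align the
  $y_i$, shrinking the HKSJ variance) that no single-direction candidate
  set contains.

When the beam exhausts its cap without a flip on a small instance
($k \le 5$, cap $\le 6$), non-attainability is confirmed by exhaustive
enumeration, so a reported `NOT_ATTAINABLE` is never a beam-pruning
artefact where enumeration is affordable. The default cap is twice the
total event count.

`fragility_ma_exact()` is the independent oracle: breadth-first enumeration
of all modification multisets of total size $1, 2, \dots$, deduplicated by
resulting count configuration, fitted in vectorised batches; the first size
achieving a verdict flip is the true minimum, and by construction no
smaller set flips. It is exponential in depth and intended for small
instances and verification.

`fragility_study()` computes the single-trial index under a two-sided
Fisher exact test (the per-study convention; Pearson's chi-squared without
continuity correction is available) by direct enumeration over $(\Delta
e_1, \Delta e_0)$, so it is exact. The quotient is always the exact ratio
$\mathrm{FI} / \sum_i (n_{i1} + n_{i0})$.

## Improvement over included studies

The improvement proportion of an MA is
$N^{-1} \sum_{i=1}^N I(\mathrm{FI}_i < \mathrm{FI}_{MA}) \times 100\%$ —
the share of included studies strictly more fragile than the MA.
Categories: **no** (exactly 0%), **slight** ((0, 50]), **considerable**
((50, 100)), **complete** (exactly 100%). The 50% boundary is not defined
by the verbal scale; we assign it to *slight* so that *considerable*
matches the strict inequalities 50% < p < 100%. Studies whose own index is
not attainable are treated as infinitely robust — they never count as
smaller — and their number is reported. This is the conservative reading;
the alternative (dropping them from $N$) would inflate the proportion.

## Bins, bands, magnitudes

Total sample size is binned `<50, 50–100, 100–200, 200–500, 500–1000,
≥1000` and total events `<10, 10–50, 50–100, 100–500, 500–1000, ≥1000`,
half-open $[a, b)$ throughout (the verbal labels are ambiguous at both
edges; one convention is applied everywhere, so 50 and 1000 land in the bin
they open). $I^2$ gets the deliberately *overlapping* guideline bands
$[0, 0.4]$ not-important, $[0.3, 0.6]$ moderate, $[0.5, 0.9]$ substantial,
$[0.75, 1]$ considerable; where a mutually exclusive stratification is
needed (improvement analyses) the default strata are $[0, 0.4)$,
$[0.4, 0.6)$, $[0.6, 0.75)$, $[0.75, 1]$ — a package choice, configurable,
since the overlapping bands admit no unique partition. Effect magnitudes
invert sub-unit ratios ($x \to 1/x$) and band OR at 1.68/3.47/6.71 and RR
at 1.22/1.86/3.00, half-open; the risk difference has no accepted magnitude
scale and gets none.

## The synthetic corpus generator

No MA database ships with the package, so `generate_corpus()` produces
seeded corpora with the structure the analysis assumes: per MA, $k = 2 +
\mathrm{NB}(\text{size}=1.1, \mu=3.0)$ studies; per study, treatment-arm
size $\mathrm{LogNormal}(\log 55, 1.2)$ (control within 10%, floors at 2),
control risk $\mathrm{Beta}(1.4, 5.0)$ truncated to $[0.01, 0.95]$, true
effect $\theta_i \sim N(\theta, \tau^2)$ on the log-OR scale with defaults
$\theta = -0.5$, $\tau^2 = 0.16$, and binomial event counts (the treatment
risk inverts the log odds ratio at the control risk). True effects are
always generated on the log-OR scale; RR and RD analyses run on the same
tables. The defaults were calibrated once against published Cochrane
corpus marginals — studies per MA with quartiles 3/4/6 (target 4, IQR
3–8), median total sample size 772 (target 723), median total events 135
(target 130), and 30% of MAs significant under the primary scenario
(target ≈29%) — and then frozen. The generated IQRs are somewhat narrower
than the Cochrane ones: a single lognormal size distribution cannot
reproduce the heavy right tail of real review sizes.

What the generator does *not* emulate: clinical topic mixture, small-study
effects and publication bias, mega-trials that dominate the weights, and
correlated arm sizes beyond the 1:1 design. Tests passing on these corpora
therefore establish the internal correctness of the estimators and the
search, and the qualitative method contrasts (e.g. HKSJ results being more
fragile); they do not certify the numeric corpus summaries as estimates
for any real collection of reviews.

## Numerical and degenerate-input choices

* Ties in the beam search break deterministically: larger p-movement
  first, then study order, then arm 1 before arm 0 (the candidate
  generation order), so results are reproducible bit-for-bit.
* All randomised paths take explicit seeds; per-MA generator seeds derive
  from `(seed, index)` and stay below $2^{31}$.
* JSON output fixes 17 significant digits so repeated runs are
  byte-identical.
* Pooling requires ≥ 2 informative studies (a typed error otherwise); a
  study whose corrected standard error is still non-finite is a typed
  `degenerate-study` error at the effects stage.
* Quantiles in corpus summaries use type 2, matching the convention of
  reporting medians/IQRs of integer FIs as integers or half-integers.

## Problem sizes used in the shipped checks

The test-suite and acceptance script run, by design, at desk scale: the
oracle-equivalence sweep uses ~200 random 2–4-study MAs with arm sizes
≤ 25 and a shared search/enumeration cap of 4 across all five scenarios;
parameter recovery and coverage use 2,000 effect-level MAs of $k = 10$
(with $s_i \sim U(0.1, 0.3)$, so the truncation-at-zero bias of
$\hat\tau^2$ stays well inside Monte-Carlo error); the HKSJ
paired-fragility contrast uses corpora of 1,000–1,400 MAs with the
fragility cap at 50–60 and the corpus beam width of 10. Monte-Carlo
assertions use ~3–3.5 standard-error bands.

## Known limitations

* The beam search is a heuristic. It matches the exhaustive oracle on
  every instance we enumerated (~3,000 scenario-fits across several
  seeds), and the small-instance fallback removes false
  non-attainability, but no global optimality proof exists for large
  instances; `fragility_ma_exact()` remains available for adjudication.
* Per-study and per-MA significance use different tests (exact conditional
  vs. interval-based pooling), which is the field convention for the
  improvement metric but mixes inferential frameworks.
* REML exclusion counts depend on the iteration settings; a different
  tolerance or cap reclassifies borderline MAs.
* Survival and continuous outcomes, network meta-analysis, Peto/arcsine
  effect measures, and multiplicity-adjusted significance are out of
  scope.
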