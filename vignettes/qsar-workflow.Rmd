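---
title: "Descriptor-based QSAR/QSPR modeling on small compound panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptor-based QSAR/QSPR modeling on small compound panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarpipe)
```

## The modeling problem

`qsarpipe` implements the standard small-panel QSAR/QSPR workflow used in
early-stage medicinal chemistry: a handful of synthesized compounds (order
10–100) is assayed for continuous endpoints (percent radical scavenging,
IC50-derived pIC50) and a categorical endpoint (antimicrobial active /
inactive from MIC records), descriptor-generation software produces
hundreds to thousands of numeric molecular descriptors per compound, and
the analyst must (i) reduce raw assay readings to modeling endpoints,
(ii) select a small set of informative descriptors, (iii) fit interpretable
models — a multiple linear regression `Y = m1 x1 + ... + mn xn + b` for the
continuous endpoints and a shallow decision tree for the class endpoint —
(iv) validate them hard enough to trust anything at `n ≈ 11`, and
(v) use them to rank newly designed analogs before synthesis.

Descriptor computation itself (PaDEL, Dragon, Mold2, quantum-chemical
descriptors) is out of scope: descriptor tables arrive as CSV. The bundled
example data are an eleven-compound panel of 8-aminoquinoline sulfonamide
hybrids with DPPH, superoxide-scavenging (SOD-mimic) and MIC endpoints,
together with the two published four-descriptor regression equations
(`published_models()`) and the published two-node classification tree
(`paper_tree()`) carried as fixtures.

## Assay reduction

Percent inhibition is `(1 - Abs_sample / Abs_control) × 100`; negative
values (pro-oxidant readings) are retained with a warning rather than
clipped, so models see the measured value. IC50 is located on a two-fold
dilution series: undefined when no response reaches 50% (the convention in
the bundled panel, where DPPH never crossed 50% and one compound's SOD
response stayed below it), the exact concentration on an exact hit, and
otherwise linear interpolation of response against log2(concentration)
between the bracketing dilutions. The log2 axis is a package decision, not
something the assay description fixes: it is the natural scale of a
two-fold design, and on it the interpolant is invariant to which pair of
adjacent dilutions brackets the crossing. A series whose responses all
exceed 50% returns the lowest tested concentration flagged `"<="`
(censored), matching how `<=` MIC bounds are stored and propagated.

Conversions: `pIC50 = 6 − log10(IC50 µM)` (reported to 3 decimals) and
`MIC µM = MIC µg/ml / MW × 1000` (2 decimals). A compound is
antimicrobial-`active` iff it has at least one MIC record.

## Feature selection

Zero-variance and exactly duplicated columns are dropped first. Two
selectors are provided:

* `stepwise_select()` — classical forward-entry / backward-removal driven
  by partial-F p-values, defaults `alpha_enter = 0.05`,
  `alpha_remove = 0.10` (the textbook defaults; the source method names
  stepwise MLR without thresholds). Ties break by column order, then name,
  for reproducibility. When the current model already fits to numerical
  precision (residual sum of squares below `1e-10 × SStot`), entry
  p-values are reported as 1 and removal p-values of redundant columns as
  1, so the procedure terminates at the minimal exact model instead of
  churning on numerical noise.
* `cfs_bestfirst()` — correlation-based feature subset selection scoring
  subsets by `k·mean|r_cf| / sqrt(k + k(k−1)·mean|r_ff|)` with best-first
  forward search, stopping after `stale_limit = 5` non-improving
  expansions.

`intercorrelation_check()` applies the conventional `|r| ≤ 0.9`
independence screen to the final set.

A caution that the package's own synthetic experiments make quantitative:
at `n = 11` with ~40 candidate descriptors, a pure-noise column reaches
`|r| ≈ 0.9` with the response by chance alone. Forward stepwise at
`alpha_enter = 0.05` then frequently stalls after such a column enters,
and no selector can separate planted from chance signal on every draw.
For exact-recovery demonstrations the package therefore runs stepwise with
liberal entry (`alpha = 0.3`) on an exactly linear response and lets the
backward pass prune, which recovers the planted four-descriptor set in
roughly 70–80% of replicates; the tests assert this majority rate rather
than a per-seed certainty. This is also the honest reading of any
published small-`n`, wide-`p` QSAR equation: selection itself is the
step most exposed to chance correlation, which is why the validation
battery below matters.

## Regression fitting and validation

`fit_ols()` fits by QR decomposition with the intercept always included;
rank deficiency or a design condition number above `1e10` is an error
(a reported equation must be unique), never a silent pseudo-inverse.

`validation_report()` computes, with thresholds `R² > 0.6`, `Q² > 0.5`,
`MAE < 0.6`, `CCC > 0.85` stored in `qsar_thresholds`:

* training `R²`, `R²_adj = 1 − (1−R²)(n−1)/(n−p−1)`, RMSE, MAE;
* leave-one-out `Q² = 1 − PRESS/SStot`, via the exact hat-matrix shortcut
  `e_(i) = e_i/(1−h_ii)` (tested equal to explicit refits to 1e-10). The
  PRESS denominator uses SStot about the full-sample mean — the standard
  PRESS-based Q²; the source does not print its formula, so this choice is
  documented rather than inherited;
* k-fold `Q²` (default `k = 5`) with a seeded uniform random partition,
  pooling PRESS across folds (pooling vs averaging per-fold was open; the
  pooled form reduces exactly to LOO at `k = n`, which the tests pin);
* Lin's concordance correlation coefficient with population (1/n)
  moments — at `n ≈ 11` the 1/n vs 1/(n−1) choice is visible, so it is
  stated: `ccc = 2 cov(y,ŷ) / (var y + var ŷ + (mean y − mean ŷ)²)`.

`y_randomization()` permutes the response (default 10 times, seeded),
refits, and passes only if every scrambled model's R² and Q² fall below
the original's — the standard guard against chance correlation.

## Applicability domain

`williams_report()` combines hat-matrix leverages of the design (intercept
included) with standardized residuals. The critical leverage is
`h* = 3(p+1)/n`, the conventional warning leverage — it reproduces the two
published panel thresholds (1.36 at `p = 4, n = 11`; 1.50 at `n = 10`)
exactly, which is why this form was adopted over alternatives. Residuals
are standardized by their sample standard deviation by default; internally
studentized residuals (`e_i / (s√(1−h_i))`) are available via
`studentized = TRUE` since the published analysis does not state its
variant. A compound is in-domain iff `h_i < h*` and its standardized
residual is within ±3σ.

## Decision-tree classification

`induce_tree()` is a C4.5-style learner for binary active/inactive
endpoints: candidate thresholds are midpoints between consecutive distinct
sorted values of each descriptor, splits are chosen by maximal information
gain ratio (gain / split information), ties break by column order, and
recursion stops at purity, at `min_leaf` (default 2, the common J48
convention), or when no split has positive gain. No pruning is applied —
the reference tree for the bundled panel is a two-node unpruned structure,
and at these sample sizes pruning decisions would be driven by one or two
compounds. Rows route left on `value ≤ threshold`.

`classification_metrics()` scores with `active` as the positive class;
accuracy in percent, precision/recall/F per class averaged with true-class
support weights (macro averaging is a flag). Weighted averaging is the
variant under which the bundled worked example reproduces its published
0.920 / 0.909 / 0.906 exactly; it also makes weighted recall ≡
accuracy/100, an identity the tests exercise on random confusion matrices.
`cv_classification()` re-induces the tree per fold (LOO or seeded
stratified k-fold) and scores pooled out-of-fold predictions; a
single-class training fold yields a single-leaf tree rather than an error.

## Candidate screening

`screen()` applies stored regression models and the tree to a candidate
descriptor table, ranks per endpoint (descending prediction, ties by id),
and flags candidates predicted to improve on their mapped prototype
compound. Predicted percent endpoints are reported unclipped with an
out-of-range flag — a linear model does not guarantee [0, 100]. The
candidate→prototype mapping is a user input; published screens of designed
analogs keep this mapping in supplementary material, so nothing is
hard-coded.

## Synthetic data: what it emulates and what it does not

`gen_regression()` plants an exact (optionally noisy) linear signal in a
few named descriptors among an equicorrelated nuisance block
(`rho = 0.6` by default — real autocorrelation-family descriptors are
strongly mutually correlated, which makes the `|r| ≤ 0.9` screen and the
chance-correlation hazard real in tests). Optional Bernoulli columns mimic
binary atom-pair flags. `gen_classification()` draws points around a
two-level threshold rule with a guaranteed margin; `gen_assay()` builds
two-fold dilution series through 50% at a known IC50. All generators are
pure functions of scenario + seed, using an internal RNG stream that
leaves `.Random.seed` untouched.

The generators emulate the *statistical shape* of descriptor data (scale,
intercorrelation, small-n/wide-p, planted rules), not the marginal
distributions of any real descriptor family. Passing tests therefore show
the algorithms are correct and behave as claimed under the stated
structure; they do not certify predictive performance on real compounds.
Problem sizes in tests (n = 11–200 compounds, up to 40 descriptors,
10-seed replicate loops) were chosen so the full suite exercises every
code path in a few seconds.

## Numerical choices and degenerate inputs

* JSON serialization of models uses 17 significant digits (lossless
  round-trip); descriptor CSVs are written with `%.17g` for the same
  reason. Reports round to 4 decimals (coefficients) and 2–3 (statistics)
  when printed.
* Zero-variance responses, zero residual spread, saturated designs and
  rank deficiency are errors with named culprits, not NaNs.
* An exact fit has numerically degenerate residuals; applicability-domain
  standardization is only meaningful with nonzero residual spread, so the
  end-to-end demonstrations validate against a small-noise response.
* Descriptor names match exactly and case-sensitively; the one typographic
  alias (`B08[C-O]` for the en-dash form `B08[C–O]`) is resolved by
  `canonical_descriptor_name()`. The 2D connectivity descriptor is
  standardized as `D211` (source tables use both `D21` and `D211` for the
  same column).
* Default seed 20260417 is recorded in reports; every stochastic function
  takes an explicit seed.

## Interfaces

The exported functions are the interface; serialized artifacts (model and
tree JSON, report CSVs, YAML configs via `pipeline_config()` /
`read_pipeline_config()`) make every stage scriptable. A shell entry point
was deliberately not shipped: the package targets analysts working in R,
and `scripts/acceptance.R` shows the end-to-end invocation pattern.

## Known limitations

* No regularized or robust regression; no bootstrap or external-test-set
  validation (none of which the implemented workflow uses).
* The tree learner is binary, two-class, with no missing-value routing or
  pruning beyond the size floor.
* The published regression equations and tree are carried as fixtures with
  their printed coefficients; the full descriptor matrices needed to refit
  them are not distributable, so training statistics of the originals are
  not re-derived. The synthetic suite reproduces the *regime* (near-unity
  R²/Q², all compounds in-domain, training-to-CV accuracy drop), not the
  printed values.
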