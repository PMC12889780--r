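---
title: "Calling gr/gr deletions from binned WGS depth: model, assumptions, validation"
author: "azfcCaller"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling gr/gr deletions from binned WGS depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(azfcCaller)
```

## The measurement model

The AZFc region is composed of families of near-identical repeats
("amplicon classes"), so short reads originating from any copy of a class
map interchangeably across its copies. Base-level breakpoint mapping is
therefore hopeless, but the *class-level dosage* survives: if a sample
carries `n_c` copies of class `c` where the reference carries `k_c`, the
expected read depth over the class's reference intervals scales by
`n_c / k_c`. All calling in this package happens at that dosage level.

For a sample with mean bin depths `d(b)`:

* Bins of fixed size (default 1000 bp) tile every class interval
  left-to-right; a trailing partial bin is kept iff it is at least half a
  bin long. This keeps estimates unbiased at interval edges without
  letting tiny fragments add noise.
* Per class, two summary statistics are always computed: the **median bin
  depth** (robust to scattered artifacts) and the **aggregate depth**
  (total read-bases / total length, the efficient choice when most bins
  hold only a handful of reads).
* Copy number: `raw_cn[c] = k_c * depth_c / depth_ctrl`, with the control
  depth taken from one or more single-copy (`is_control`) classes. A
  control depth of zero makes the sample unnormalizable; it is reported as
  `CALL_FAILED`, never silently dropped.

**Mode selection.** With `mode = "auto"` the aggregate statistic is used
when the control aggregate depth is below 2.0x, else the median-bin
statistic. The threshold marks where the per-bin median degenerates: at
0.7x and 1-kb bins the expected count is ~5 reads per bin and the median is
dominated by small integers, while the aggregate over tens of bins retains
a stable mean. The chosen mode is recorded in every profile and call row,
and can be forced.

**Mapping quality.** Depth here deliberately includes multi-mapped
(MAPQ 0) primary alignments. The amplicon copies are near-identical, so
dosage information is carried almost entirely by reads that cannot be
placed uniquely; a MAPQ filter would null the signal.

## Median centering

Marker-specific biases (library chemistry, mappability, batch) scale each
class's depth by an unknown factor shared across samples in a batch. Per
class, the cohort median of `raw_cn` estimates `k_c * bias_c` provided
carriers are a minority (< 50% per class), so

```
centered_cn[c, s] = raw_cn[c, s] * k_c / median_s(raw_cn[c, .])
```

restores the cohort median to the reference copy number exactly. Properties
the test suite verifies: idempotence (a second pass is the identity),
equivariance under per-class multiplicative bias, and scale invariance of
`raw_cn` under global depth rescaling.

The carrier-minority assumption is checked: if any class's *rounded*
cohort median differs from its reference copy number, a warning is raised.
Note a strong but legitimate bias (e.g. x1.2 on a 4-copy class) also trips
this check — the warning flags the assumption for inspection, it does not
invalidate the run.

Centering needs a cohort; with fewer than 3 profiles `medianCenter()`
refuses and directs to `skipCentering()`, which copies raw to centered and
flags the profile `UNCENTERED` so single-sample operation is explicit,
never accidental.

## Signature matching

Centered values are rounded to integers (exact halves away from zero,
floored at 0) and matched **exactly** against a catalog of copy-number
signatures. There is no distance threshold: a near-miss vector is not
force-assigned to the closest signature but becomes `OTHER_AZFC_CNV`,
which is conservative for association because such samples are excluded
from testing anyway (rarer AZFc CNVs could themselves associate with the
phenotype and confound the carrier contrast). The catalog enforces
pairwise-distinct vectors, so matching is unambiguous and tie-breaking
never arises. The three known gr/gr breakpoint subtypes produce identical
class-level copy changes and are intentionally not distinguished.

Whether inverted-repeat (IR) classes participate in matching is a
catalog-level choice: the shipped catalogs include them (with unchanged
dosage in the gr/gr signature, matching the published architecture), and a
user catalog omitting IR keys simply restricts the match to amplicon
classes. Including them is the stricter default.

The packaged GRCh38 definition set (`loadDefaultDefinitions()`) is an
approximate one-time transcription of the published AZFc architecture and
is shipped as editable configuration. No exactness-sensitive test depends
on it; all such tests build synthetic catalogs in code.

## The synthetic cohort generator

`simulateDepths()` draws per-bin read counts as
`Poisson(coverage * bin_len / read_len * (n_c / k_c) * bias_c)` and
converts to depth. This emulates: haploid chrY coverage levels (0.7x /
7.4x / 30x in the validation design), class-level dosage, batch-level
marker biases (default draws log-uniform in [0.8, 1.25] in the validation
tests), and samtools-style read thinning (`downsampleDepths()`, binomial
with retention `p`; thinning Poisson counts is exactly a Poisson at
`p * lambda`, which the tests verify by moment matching). Cohorts draw
carrier labels per arm with the case frequency implied by the target odds
ratio, `p1 = OR*q / (1 - q + OR*q)`.

What it does **not** emulate: read placement and insert-size structure, GC
and mappability waves along the chromosome, sequence errors, reference
artifacts, contamination, or ancestry-correlated depth structure. A green
simulation-based test therefore establishes the *statistical* correctness
of the dosage -> signature -> association chain at given noise levels, not
robustness to platform artifacts; the latter requires real cohort data
outside this package's scope. Simulation sizes in the acceptance tests
mirror the published validation design (1194 samples, 47 carriers, three
coverage levels); seeds are fixed and mandatory, and identical specs with
identical seeds reproduce byte-identical tables.

## Benchmark metrics

`performanceMetrics()` reports sensitivity, specificity, and **two**
false-positive-rate variants: `fpr_standard = FP/(FP+TN)`
(= 1 - specificity) and `fpr_reported = FP/(FP+TP)`, the fraction of positive
calls that are wrong (a false discovery rate). Published benchmark tables
in this caller family report the latter under the name "false positive
rate" (1 false positive among 48 positive calls printed as 0.021, where
the standard rate would be 1/1147 = 0.001). Both are computed; the
labeling makes reproduction unambiguous without guessing intent.

## Firth's bias-reduced logistic regression

Rare hemizygous carriers and extreme case-control imbalance put ordinary
logistic regression in the regime where maximum-likelihood estimates are
badly biased or (under separation) infinite. `fitFirth()` maximizes the
Jeffreys-penalized likelihood `l(beta) + 0.5 log det I(beta)` by Newton
iteration on the Firth-modified score with step halving, so the penalized
log-likelihood is non-decreasing across accepted steps; convergence is
declared when the modified score and the step are both below 1e-8
(cap 100 iterations). Frequency weights collapse identical covariate
patterns with no change to the likelihood, which makes biobank-scale 2x2
fits constant-time.

* **CIs** default to profile penalized likelihood (each bound solves a
  drop of `qchisq(0.95, 1)/2` in the constrained maximum); Wald intervals
  are available and the method used is always recorded, since the two can
  differ materially in sparse tables.
* **p-values** are penalized likelihood-ratio tests (refit with the
  coefficient fixed at zero, penalty still computed from the full
  information matrix).
* The normal quantile is carried as 1.959964 rather than 1.96 to minimize
  rounding drift against printed intervals.
* The unadjusted 2x2 path uses the Woolf CI and the **Yates-corrected**
  chi-square: the corrected statistic is what reproduces printed 2x2
  p-values in this literature (0.53 for the TECAC counts, where the
  uncorrected statistic gives ~0.43).
* In a saturated 2x2 the Firth estimate equals the add-1/2-to-each-cell
  odds ratio. This is visible at small counts: with cells
  (38, 1546, 12, 635) the penalized OR is 1.27 against an unadjusted
  1.30. The two converge as all cells grow (the suite checks agreement at
  2 d.p. with cells scaled x10) — the small-sample difference is the bias
  reduction working, not a defect.
* All-zero covariate columns are dropped with a message (they carry no
  information and would otherwise fail the collinearity check, which
  reports offending columns by name).

## Meta-analysis

Per-dataset effects are combined on the log-OR scale by inverse-variance
weighting: fixed-effect (`w = 1/se^2`) and DerSimonian-Laird
random-effects (`w* = 1/(se^2 + tau2)` with the moment estimator
`tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`). When per-study
standard errors are not published, `estimateFromCI()` reconstructs them
from printed ORs and 95% CIs as `(ln hi - ln lo) / (2 * 1.959964)` — the
canonical path for reproducing printed summary rows, with tolerances in
tests sized for the 2-d.p. rounding of those inputs. `Q <= k - 1`
truncates `tau2` to zero, making random-effects collapse to fixed-effect
exactly (an identity the tests assert rather than approximate).

The I^2 confidence interval uses the test-based log-H method, is labeled
method-sensitive, and is never used as a gate: for k = 2 with small Q the
method is undefined and `NA` is returned. Published I^2 intervals for
two-study meta-analyses are not generally reproducible without knowing the
exact method used.

## Numerical and interface choices

* Coordinates are BED-convention 0-based half-open on disk and `GRanges`
  internally; the conversion happens only at I/O boundaries.
* Rounding is half-away-from-zero (2.5 -> 3), floored at 0, so dosage
  noise around an integer boundary resolves deterministically and
  symmetrically.
* Validation failures raise *named* conditions (`azfc_missing_control`,
  `azfc_duplicate_signature`, `azfc_interval_overlap`,
  `azfc_unknown_class`, `azfc_key_mismatch`, `azfc_normalization_error`,
  ...) so pipelines can branch without parsing messages; cohort-level
  drivers convert normalization failures to `CALL_FAILED` rows instead of
  aborting the batch.
* Every written artifact carries a header with the package version and the
  seed; simulation seeds are mandatory arguments, not defaults.

## Known limitations

* No GC-content or mappability correction; depth biases that are not
  class-wide multiplicative factors are not removed by median centering.
* Exact-match calling cannot represent mosaic or partial dosage, and
  breakpoint subtypes within a signature are indistinguishable by design.
* The carrier-minority assumption bounds applicability: a batch in which
  one class's CNV carriers exceed 50% would be mis-centered (the warning
  fires, but the run proceeds).
* The Poisson noise model has no overdispersion; real platforms show
  modest extra-Poisson variance, so simulated sensitivities at a given
  coverage are best-case.
* Ancestry structure, principal-component computation, and wet-lab
  validation workflows are out of scope; covariates enter the association
  model as given numeric columns.
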