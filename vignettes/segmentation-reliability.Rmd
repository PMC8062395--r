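---
title: "Measuring segmentation reliability with a mixture-error model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring segmentation reliability with a mixture-error model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segrel)
```

## Why agreement coefficients fail on boundary times

A word-boundary annotation is a time in milliseconds from the trial
start. Within one word token, annotators disagree by a few
milliseconds; across tokens, boundary times range over seconds. Any
coefficient of the form "1 − observed/expected disagreement"
(Krippendorff's interval alpha) or "between-unit share of total
variance" (ICC) therefore saturates: the expected disagreement is
dominated by the between-token spread, which carries no information
about segmentation quality. `sensitivity_sweep()` makes this concrete:
it rebuilds each annotation as `median + λ·deviation + ε` and shows
that α and ICC move by less than 10⁻³ while the error scale λ varies
four-fold, whereas the mixture statistic below tracks λ approximately
linearly. Tolerance percentages (`pct_within_tolerance()`) do respond,
but compress everything beyond the tolerance into a single number.

## The error model

Deviations are defined against the **pooled median**: for each token
and boundary, the median annotated time across all annotators *and both
modalities* is the reference, and each annotation's signed deviation
from it (ms) is the datum. Pooling both modalities keeps the reference
neutral between workflows; a singleton annotation necessarily has
deviation 0, and even counts use the mean of the two central values.

The deviation sample is modeled as a mixture of three zero-mean
Gaussians. The components are interpretable bands of segmentation
quality, enforced by box constraints on their standard deviations:

| component | σ bounds (ms) | reading                         |
|-----------|---------------|---------------------------------|
| narrow    | 0.0001 – 2    | essentially exact agreement     |
| medium    | 1.5 – 8       | moderate disagreement           |
| wide      | 2.5 – 40      | poor segmentations              |

All means are clamped at 0 — the pooled median removes any systematic
offset, so components differ only in spread — and the mixing weights θ
sum to 1. The boxes deliberately overlap so the data, not the
constraints, decide where mass goes; no label-switching penalty is
applied, and none is needed because the reliability summary

\[ \sigma_w \;=\; \sum_i \theta_i \sigma_i \quad\text{(ms)} \]

is invariant to which overlapping component picks up a given band.
σ\_w is the package's reliability statistic: smaller means tighter
clustering around the reference.

## The fitting objective and its discretization

The fit criterion is the mean of the two directed Kullback–Leibler
divergences between the observed and the model distribution, both
discretized on a shared grid. The package's discretization
(`kl_binning()`) uses 1-ms bins on [−50, 50] ms. The support covers the
widest permitted component (σ = 40 ms) to ±1.25 SD and the region where
deviation histograms have visible structure; 1 ms matches the
resolution at which boundary times are recorded. Model bin masses come
from CDF differences; model tail mass beyond ±50 ms and any sample
values outside the support are folded into the edge bins, so both
distributions keep total mass 1 (a sample entirely outside the support
is an error). Every bin is floored at ε = 10⁻⁹ and renormalized so both
directed divergences stay finite when a bin is empty on one side. The
binning is a configuration parameter, not a constant, because other
corpora may need a wider support or coarser bins.

## Particle swarm optimization

The objective is cheap but non-convex (overlapping boxes, histogram
plateaus), so it is optimized by bounded global-best PSO rather than
gradient methods. Particles move in six raw dimensions: three
unnormalized weights in [0, 1] that are normalized to θ at evaluation
(keeping the simplex constraint exact without penalties; a particle
whose raw weights sum below 10⁻⁶ is re-drawn), plus the three sigmas in
their boxes. Hyperparameters are the standard constriction values —
inertia 0.7298, cognitive = social = 1.49618 — with velocities clamped
to half the per-dimension range and positions clamped to the bounds
(the clamped velocity component is zeroed). The full-scale
configuration is 60 particles for at most 2000 iterations, with early
stopping once the global best improves by less than 10⁻⁹ for 200
consecutive iterations; in practice fits on 3600-deviation samples
early-stop within a few hundred iterations. The entire final swarm is
returned, not just the optimum, because the downstream regression uses
every particle.

The test suite runs reduced swarms (20 particles, 300 iterations),
which for this 6-dimensional problem reach the same weighted sigmas to
well within the tolerances tested; the parameter-recovery check (3600
draws from σ = (1, 4, 20), θ = (0.6, 0.3, 0.1)) recovers the
generating σ\_w = 3.8 ms with a median relative error under 20 % across
20 seeds. Two sources of mild downward bias are inherent to the
method and worth knowing: deviations are computed against a median that
contains the annotation itself (shrinking their spread slightly
relative to the true error), and the finite KL support truncates the
wide component's tails.

## Attributing reliability to modality and rate

To estimate how modality and speaking rate shift the fitted sigmas, the
package builds all 252 composition cells — rate proportions in tenths,
each between 0.1 and 0.8 and summing to 1 (36 compositions), crossed
with manual-annotation proportions 0.2–0.8 in steps of 0.1 — draws a
proportion-matched subset per cell (largest-remainder allocation,
modality margin first, so every count is within 1 of the exact
product), fits the mixture per subset, and regresses sigma on
`p_ponss`, `p_fast`, `p_slow`, a sum-to-zero component factor and their
interactions. `p_manual` and `p_medium` are excluded because they are
linear functions of the included predictors. Each swarm particle
contributes one row per component, weighted by θ·(1 − KL) clamped at 0
(a KL above 1 would otherwise produce a meaningless negative weight).

The estimation is weighted least squares. A Bayesian distributional
regression (Student-t response with component-specific scale) over the
same design would additionally model the spread of the swarm per
component; the fixed-effect design matrix here is identical, WLS point
estimates and standard errors are the comparable quantities, and the
`sigma_regression()` surface is the hook where a Bayesian backend could
be substituted. The subset size is a required parameter (600 records
per subset in the tests) — it trades per-fit histogram stability
against the number of independent draws from the pool.

## Efficiency: the rejection-aware bootstrap

Per-word costs differ structurally between workflows. The conventional
workflow is timed per trial, so each good word receives
`trial time / good words`; trials with zero good words are excluded
(their count is reported as an attribute) since there is no word to
carry their time. The candidate-based workflow sums *all* interactions
with a word — every triage pass and every retrim pass, across
annotators — and flags whether the word ended up accepted; this counts
multiple passes where the baseline implicitly assumes a single pass,
a deliberate conservative bias against the candidate-based workflow,
and a single-pass-only variant can be had by filtering the timing log
before aggregation.

Each bootstrap replicate samples words without replacement until it
contains `n_good` accepted ones, summing the time of every sampled
word, rejected ones included; with rejection fraction r the expected
total inflates by ≈ 1/(1 − r), which the tests verify within 2 % at
r = 0.05 over 1000 replicates. With no rejected words in the pool the
procedure reduces exactly to summing `n_good` sampled words, so the two
modalities are treated identically in that limit. Distributions are
compared by mean difference, percent reduction (denominator: the slower
modality's mean) and Cohen's d with the pooled SD.

## The synthetic generator

`generate_study()` emulates the structure the analyses assume: trials
of 8 prompted disyllabic words at three rates (mean word durations
250/400/600 ms for fast/medium/slow, jittered, with rate-dependent
gaps); suffix-biased word omission (per-position probabilities, default
rising to 0.2 at position 8, enforced monotone); per-cell
mixture-distributed boundary errors, identical across modalities by
default (so modality effects are null unless injected) and wider for
fast speech; keyboard-step quantization of retrim-derived deviations
(default: 10 % of retrimmed boundaries snapped to 20-ms multiples,
producing the characteristic side-modes at ±20 ms); ~5 % candidate
rejection and 20 % double triage; and log-normal interaction times
(right-skewed and positive, as human handling times are; default
medians 3 s triage, 10 s retrim, 20 s per word of baseline trial time).
The default study size (4 speakers × 15 trials × 8 words) is the
smallest that leaves every modality × rate × boundary cell comfortably
above the 300 records the balanced evaluation sample draws.

What the generator does **not** emulate: acoustic content of any kind,
annotator-specific bias or drift (all error is exchangeable within a
cell), correlation between a word's onset and offset errors, and
quorum dynamics in triage. Passing tests therefore show that the
statistical machinery recovers known structure from data of this shape
— not that real annotator error is mixture-of-three-Gaussian
distributed.

Boundary annotations are generated for all produced words in both
modalities regardless of later rejection; the rejection flag drives
only the timing/efficiency pipeline. True boundaries are used only for
generation — analyses always rebuild the empirical median reference, so
tests exercise the same code path real data would.

## Numerical conventions and degenerate inputs

* Medians of even counts: mean of the central pair. Tolerance
  comparisons are inclusive (|d| ≤ tol).
* Alpha/ICC: units with fewer than two ratings are excluded from
  pairing; a dataset with no pairable values, or zero variance
  everywhere, raises an error rather than returning NaN.
* ICC variant: one-way random effects ICC(1,1) with the unbalanced n₀
  coefficient — each token is rated by whatever annotators it happens
  to have, so a two-way (rater-crossed) model is not identified here.
* "Removing noise" in the sensitivity sweep is multiplicative shrinkage
  of deviations toward the median (λ < 1); additive Gaussian noise is a
  separate axis. This parametrization is the package's choice.
* Largest-remainder allocation breaks ties by the order of the larger
  fractional remainders; subset draws and swarm fits derive per-cell
  seeds from one master seed by a fixed affine counter scheme, so any
  cell can be re-run in isolation.
* TextGrids: long and short dialects are read, long is written; times
  are seconds in files and milliseconds everywhere else, converted only
  at the I/O boundary; UTF-16 exports are detected and refused, never
  silently transcoded; word intervals are matched positionally, never
  by label.

## Known limitations

* σ\_w is bounded by the component boxes: error scales far outside
  [0, 40] ms cannot be represented and the fit will saturate.
* The KL support [−50, 50] ms truncates extreme outliers into edge
  bins; corpora with grosser errors need a wider `kl_binning()`.
* WLS standard errors treat swarm particles as independent
  observations, which they are not (they are correlated draws from one
  optimization); the SEs are comparative, not inferential, quantities.
* The heuristic transcription rule is defined only for suffix
  omissions; peak counts implying mid-sequence omissions still yield
  the prefix of that length.
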