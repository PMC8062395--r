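# segrel

Reliability and efficiency analysis for multi-annotator word-boundary
segmentation of speech recordings.

## The problem

When several annotators place the onset and offset of each word in a
speech corpus — possibly with different tools or workflows
("modalities") — two questions decide whether a faster workflow is
usable: *is it as reliable as the conventional one?* and *how much
annotator time does it actually save?*

Classic agreement coefficients are nearly useless for the first
question. With boundary times measured from the trial start, words occur
at widely different absolute times, so between-word variance dwarfs the
few-millisecond placement error that distinguishes good from sloppy
segmentation. Krippendorff's interval alpha,

&nbsp;&nbsp;&nbsp;&nbsp;α = 1 − D₀/Dₑ,&nbsp;&nbsp; δ(v, v′) = (v − v′)²,

and the one-way intraclass correlation both sit at ≈ 1 regardless of how
much boundary noise is injected (`sensitivity_sweep()` demonstrates this
directly). `segrel` instead implements a distribution-fitting
reliability statistic:

1. For every word token and boundary, compute the **median** annotated
   time pooled across all annotators and both modalities, and the signed
   **deviation** of each individual annotation from it (ms).
2. Fit the deviation sample with a **zero-mean mixture of three
   Gaussians** — a narrow component (σ ∈ [0.0001, 2] ms; boundaries
   everyone agrees on), a medium component (σ ∈ [1.5, 8] ms) and a wide
   component (σ ∈ [2.5, 40] ms; poor segmentations) with mixing weights
   θ₁ + θ₂ + θ₃ = 1. The fit minimizes the symmetrized, discretized
   Kullback–Leibler divergence between sample and model, by bounded
   global-best **particle swarm optimization** (60 particles, up to
   2000 iterations).
3. Summarize reliability as the **weighted sigma** Σᵢ θᵢσᵢ (ms); smaller
   is better, and unlike α it scales with the actual error.
4. To attribute reliability differences to modality and speaking rate,
   fit the mixture to **252 subsets** whose modality / rate composition
   is varied on a grid, and regress the fitted sigmas on the composition
   with weights θ·(1 − KL) (weighted least squares over the entire final
   swarm of every fit).

For the second question, `segrel` aggregates per-interaction timing logs
into per-word costs (per-trial division for the conventional workflow;
summed triage + retrim passes across annotators for the candidate-based
one) and runs a **rejection-aware bootstrap**: each replicate keeps
sampling words until it contains `n_good` accepted ones, counting the
time of rejected candidates too, and the resulting annotator-hour
distributions are compared (difference, percent reduction, Cohen's d).

A synthetic-study generator (`generate_study()`) produces complete
token / annotation / timing / harmonicity-peak datasets with the
statistical structure these analyses assume, so the whole pipeline runs
and is tested without any corpus data. The harmonicity-peak
transcription heuristic (`peaks_to_word_count()`,
`candidate_transcription()`) maps vowel-peak counts to candidate
transcriptions: with disyllabic words, ⌈peaks/2⌉ words, clamped at the
prompted maximum.

## Worked example

```r
library(segrel)

study <- generate_study(generator_config(seed = 2026))
dev   <- compute_deviations(study$annotations)

# classic coefficients are blind on raw boundary times:
# alpha = 0.999979, icc = 0.999979 on this study

eval_sample <- balanced_sample(dev, per_cell_n = 300, seed = 1) # 3600 records
fit <- pso_fit(eval_sample, pso_config(seed = 1))
fit
#> <mixture_fit> 60 particles, 300 iteration(s) (early-stopped), best KL 0.0190038
#> <mixture_spec> zero-mean 3-Gaussian mixture
#>   sigma (ms): narrow 0.9041, medium 3.639, wide 13.85
#>   theta:      narrow 0.486, medium 0.354, wide 0.160
#>   weighted sigma: 3.945 ms
```

About half of the mass sits in a sub-millisecond narrow component, a
third in a ~4 ms medium component, and 16 % in a ~14 ms wide component;
the weighted sigma of **3.95 ms** is the study's reliability on a scale
that tolerance rates confirm (91.4 % of segmentations fall within
10 ms). `autoplot(fit)` overlays the fitted density on the deviation
histogram; `tidy(fit)` exposes the full final swarm.

The efficiency side, on the same synthetic study:

```r
words <- dplyr::bind_rows(
  baseline_word_times(study$timing, study$good_words_per_trial),
  ponss_word_times(study$timing, study$final_status))
bb <- bootstrap_hours(dplyr::filter(words, modality == "baseline"),
                      n_good = 400, n_reps = 500, seed = 3)
bp <- bootstrap_hours(dplyr::filter(words, modality == "ponss"),
                      n_good = 400, n_reps = 500, seed = 4)
compare_modalities(bb, bp)
#> # A tibble: 1 × 3
#>   mean_diff_hours pct_reduction cohens_d
#> 1            1.50          64.7     144.
```

(The size of the saving simply reflects the generator's default timing
model — triage is far cheaper than per-trial manual segmentation.)

A command-line front end covering the same pipeline
(`simulate`, `deviations`, `classic`, `sensitivity`, `fit-mixture`,
`subsets`, `regress`, `efficiency`, `report`) is installed at
`inst/cli/segrel`; every run writes a `run_manifest.json` from which it
can be reproduced exactly.

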