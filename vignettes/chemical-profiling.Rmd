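---
title: "From GC-MS peak lists to fertility-cue candidates: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From GC-MS peak lists to fertility-cue candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semioprofile)
```

## The problem

Female common marmosets advertise reproductive state through anogenital
scent marks. Profiling those secretions by thermal-desorption GC-MS yields,
after spectral deconvolution, one *peak list* per sample: retention times,
fragment spectra (m/z 30–300) and integrated areas. The analytical question
is whether the chemical composition of these profiles carries information
about ovarian cycle state (follicular, peri-ovulatory, luteal), age and
parity — and, if it does, *which* substances carry that information.

`semioprofile` implements the full path from peak lists to candidate
substances:

1. **Alignment** — per-batch retention-time (RT) adjustment, gap-based
   grouping of peaks into retention-time ranges, occurrence filtering,
   prominent-mass extraction with a spectral-consistency check, and
   quantification into a samples × substances area matrix.
2. **Preprocessing** — known-contaminant exclusion, blank-based background
   exclusion, relative peak areas (percent of the sample's total included
   area), and the response transforms used by the statistics.
3. **Whole-profile similarity** — Bray–Curtis dissimilarities on
   `log(x + 1)` relative areas and an ANOSIM whose permutation null respects
   repeated sampling of the same female.
4. **Substance screening** — the samples × substances matrix is vectorised
   into one long response vector and modelled with a crossed-random-effects
   linear mixed model; substances are ranked by the conditional modes
   (BLUP analogues) of the test predictors and the *most affected* ones are
   flagged.
5. **Bioassay statistics** — exact Wilcoxon signed-rank tests for paired
   male investigation durations, and a two-way single-measure intraclass
   correlation for inter-observer reliability.

A first-class synthetic-data module generates complete studies — peak
lists, blanks, contaminants, planted effects, recorded ground truth — so
every stage is testable without instrument data.

## The synthetic study generator

`design_config()` defaults encode the study layout this package models:
12 females (discrete ages 1–11 years), 27 sampled cycles, 56 + 104 + 52
animal samples across the three cycle states (212 in total), and 31 blanks
(9 handling, 22 room-air). A *batch* is one (female, cycle) pair; genital
side, ultrasound timing and which one of four assistants handled the animal
are randomised per sample. Parity is assigned independently of age, so the
two remain separately estimable — this mirrors a deliberate property of the
real study population.

`effect_spec()` defines the latent chemistry. Intensities follow a
log-normal model:

$$\log A_{is} = b_s + c_{s}[\mathrm{state}_i] + a_s\, z(\mathrm{age}_i)
  + p_s\,[\mathrm{parous}_i] + \mathrm{nuisance}_{is}
  + u_{\mathrm{female}(i)} + u_{\mathrm{batch}(i)} + \varepsilon_{is}$$

with female-level, batch-level and residual SDs `sigma_id = 0.4`,
`sigma_batch = 0.25`, `sigma_e = 0.4` (log units). The log-normal form is a
tooling choice made because every downstream transform is log-based; it is
an assumption, not an empirical claim. Default planted counts — 6 cycle-,
11 age-, 7 parity-affected substances out of 160 — mirror the scale of
per-predictor effects reported for real marmoset profiles; the planted sets
are disjoint so that ground truth is unambiguous. Effect magnitudes
(`cycle_effect = 1.6`, i.e. a 4-residual-SD bump of one state;
`age_effect = 1.2` per z-scored year; `parity_effect = 1.2`) are
deliberately strong single choices: nothing is published about real
magnitudes, and the generator's job is to give the pipeline unambiguous
truth to recover, not to reproduce any particular dataset. Most age slopes
are negative and most parity shifts favour nulliparous females, matching
the direction patterns reported in the field.

Contaminants (default 10) originate from the sampling material: blanks see
them at full intensity, animal samples attenuated by
`contaminant_animal_fraction = 0.5` (the blank tube samples the background
undiluted, the animal tube shares it alongside a dominating biological
matrix). Blanks also receive every true substance at a
`carryover = 0.01` trace fraction, so the blank filter faces genuine
positives *and* negatives. Rendering adds Gaussian RT jitter
(`jitter_sd = 0.005` min), independent peak dropout
(`dropout_rate = 0.02`), optional per-batch RT shifts, and scales each
substance's fixed fragment pattern to the peak area. Substances flagged
`inconsistent` draw a fresh fragment set per peak and are the planted
failures for the spectral-consistency check.

Each stage draws from its own RNG stream derived from the master seed, so
`(config, spec, seed)` reproduces any stage bit-for-bit and stages can be
regenerated independently.

What the generator does **not** emulate: chromatographic peak shapes,
co-elution and saturation, RT drift *within* a batch, non-log-normal
intensity distributions, and structured (non-independent) dropout of weak
peaks. Passing tests therefore demonstrate correctness of the algorithms
under a clean generative model, not robustness to every pathology of real
chromatography.

## Alignment choices

**Gap clustering, not binning.** Pooled peaks are sorted by RT and a new
range starts when the gap to the previous peak exceeds `gap_tol`
(default 0.05 min). This is single-linkage clustering at a threshold; unlike
fixed-width bins it cannot split a substance across a bin boundary. The
grouping is invariant to input order, and raising `gap_tol` can only merge
ranges. The original study's grouping script is unpublished, so this rule
is a documented stand-in with the tolerance exposed.

**One peak per sample per range.** When a sample contributes several peaks
to a range, the peak closest to the range's median RT wins, ties going to
the larger area; discards are logged. The choice is ours — the source
procedure is silent on it.

**Batch RT adjustment** is a global per-batch shift, not warping: each
batch is grouped on its own, ranges present in ≥ 80 % of the batch's
samples become anchors, anchors are matched to the reference batch's
anchors by nearest RT within `max_shift = 0.5` min, and the batch is
shifted by minus the median anchor difference. Matching by nearest RT
(rather than shared pooled ranges) keeps the procedure valid when the drift
exceeds the gap tolerance.

**Occurrence filter.** Ranges are kept when they occur in at least 14
samples — the published threshold for 212 animal samples, exposed as
`min_occurrence`.

**Spectral consistency.** The manual inspection step of the original
workflow is replaced by an automated surrogate: a range is `verified` when
the mean pairwise Jaccard similarity of its member peaks' top-`top_k`
(default 5) fragment sets reaches `jaccard_min` (default 0.5);
single-member ranges pass by convention, and unverified ranges are dropped
at quantification. Quantification sums the member peak's intensity over the
range's prominent m/z, falling back to the peak's total area when the
spectrum shares none of them; absent peaks are 0 — not missing — because
the relative-area denominator is the sum over all included areas.

## Preprocessing choices

Filters run in the order contaminants → blanks. A known contaminant removes
a range only when both the RT window *and* at least one characteristic m/z
match. The blank filter compares the mean (configurable to median) raw area
over blanks against the mean over animal samples and excludes the substance
when the blank statistic equals or *exceeds* the animal one — the tie goes
to exclusion, deliberately. The filters are idempotent, and on fixtures
where their target sets are disjoint the order does not matter.

Three responses feed the statistics:

* `normalised` — per-substance z-scores (sample SD, n−1), putting all
  substances on the same footing so the model sees changes *between
  samples*;
* `log1p` — `ln(x + 1)`, used for the Bray–Curtis dissimilarities;
* `log_arcsine` — `ln(x + 0.001)` rescaled linearly over the whole matrix
  to [−1, 1], then arcsine-transformed. A log-then-arcsine recipe is
  ambiguous as stated anywhere we have seen it (the log output is negative,
  outside the arcsine domain); the rescaled composition implemented here is
  one documented reading and is not claimed to reproduce anyone's numbers.

## ANOSIM with restricted permutations

The R statistic is standard: rank all pairwise dissimilarities (average
ranks on ties) and contrast mean between-group and within-group ranks,
scaled by M/2 with M = n(n−1)/2. What is not standard is the null: samples
from the same female are not exchangeable with everyone else's. Two schemes
are implemented:

* `within_individual` — labels shuffle only among a female's own samples,
  independently per female. This is the appropriate scheme for cycle state,
  which varies within females.
* `individual_level` — the females' factor values are permuted across
  females and propagated to their samples. This is the only coherent scheme
  for between-female factors (age, parity): within-individual shuffling of
  a factor that is constant within every female is a no-op and is rejected
  with an error.

This split is the largest inferential judgement call in the package. The
original description of the customised ANOSIM does not say how
between-individual factors were permuted, so results for age and parity
under `individual_level` are this package's choice and are not claimed to
match any published R or p. Note also that with 12 females an
individual-level permutation test has limited resolution.

p-values are one-sided on the upper tail of R with the add-one correction,
resolution 1/(n_perm + 1) at the default `n_perm = 1000`; `exact = TRUE`
enumerates all distinct restricted arrangements instead (capped at
250,000) and then includes the identity arrangement in the numerator and
denominator. Under the generator's null both schemes hold their level
(checked by simulation in the test suite).

## The mixed-model screen

`vectorise()` stacks the matrix into one row per (sample, substance) —
212 × 160 = 33,920 rows at study scale — and `build_model_spec()`
enumerates the model: 9 fixed effects (cycle state, z-scored age, parity,
genital side, ultrasound timing, four assistant indicators), random
intercepts for sample, substance, female, room and batch, an uncorrelated
random age slope within substance, and random interaction intercepts of the
design factors within substance, female, room and batch — 33 predictor
variables in all. The three *test predictors* are substance × cycle,
substance × parity and the age slope within substance: they encode
"different substances respond differently to the predictor", which is
exactly what a substance screen needs.

Design decisions worth spelling out:

* **Independent variance components.** Every random interaction is one
  `(1 | grouping:factor)` component contributing exactly one variance
  parameter, so each per-predictor likelihood-ratio test has df = 1. A
  correlated-slope parameterisation would change the counting and is not
  the default.
* **ML for testing, REML for reporting.** All fits feeding LRTs use ML so
  likelihoods are comparable; REML is available for variance-component
  reporting.
* **Boundary conservatism.** Dropping a variance component tests a
  parameter on the boundary of its space; the nominal chi-square reference
  is conservative (simulated type-I error ≈ 0–3 % at nominal 5 %). We
  report the nominal p-value, as is common practice, and document the
  conservatism instead of correcting it.
* **Conditional modes as slope estimates.** The per-substance "slopes" are
  the conditional modes (BLUP analogues) from `lme4::ranef()`; scores are
  |mode| for age, the absolute contrast of the two level modes for parity,
  and the largest absolute deviation of a state mode from the substance's
  state-mode mean for cycle, with directions reported as the sign
  (age), the higher level (parity), or the state with the highest mode
  (cycle). Whether published "slope estimates" for a three-level factor are
  contrasts or per-level modes is unstated; the max-deviation rule is our
  documented choice.
* **The two-SD flag rule.** A substance is *most affected* when its score
  is at least `mean(score) + 2 * SD(score)`. The SD uses the population
  (n-denominator) convention: with the n−1 convention a homogeneous
  strongly-affected subset at 20 % prevalence could never be flagged even
  without noise, because the threshold would sit strictly above the common
  score (the one-sided Chebyshev bound is attained exactly by a two-point
  distribution at that prevalence). The degenerate edge is defined as:
  all scores equal and positive → all flagged; all scores zero → none.
* **The flag rule selects the extreme few — by design.** A consequence of
  mean + 2 SD is that at most one fifth of substances can ever exceed the
  threshold (Cantelli), and in noisy data a dense cluster of comparable
  effects pushes the threshold into its own midst. The rule is therefore a
  *shortlist* device, well matched to the regime where a small minority of
  substances is affected (6–11 of 160 per predictor at study scale). When a
  fifth of all substances carries comparable planted effects, roughly half
  of them necessarily fall below the threshold, however large the effect —
  users screening dense effect structures should rank by score rather than
  rely on the flag.
* **Convergence and initialisation** follow `lme4` defaults (derivative
  checks disabled for speed); non-converged fits are flagged and refused by
  `lrt()`.

`vif()` reports collinearity of the fixed design as `1/(1 − R²)` per
design-matrix column, with `Inf` (not an error) for aliased columns.

As a consistency check between transform and model: a dataset whose
substances differ only by a location shift produces, after the `normalised`
transform, no substance-level signal at all — the substance × cycle
variance lands on the boundary and nothing is flagged.

## Bioassay statistics

The paired investigation durations of bioassay males are compared with an
exact Wilcoxon signed-rank test: zero differences are dropped, tied
absolute differences get midranks, and the p-value comes from full
enumeration of the 2^n sign-flip null via a generating-function convolution
over doubled ranks (exact up to 20 nonzero pairs; two-sided p is twice the
smaller tail, capped at 1). With n = 8 all-positive differences this gives
V = 36 and one-sided p = 1/256 ≈ 0.0039 exactly.

Inter-observer reliability uses the two-way single-measure intraclass
correlation computed from mean squares, defaulting to the
absolute-agreement variant ICC(A,1) — "two-way single measure" alone does
not pin the variant down — with the consistency variant ICC(C,1) available;
confidence intervals are F-based (Satterthwaite degrees of freedom for
agreement).

## Problem sizes used by the test suite

The packaged checks run the statistics at sizes chosen to exercise every
code path while remaining quick on a single CPU: screening-recovery
fixtures of 24 samples × 40 substances over 10 seeds, 200 null simulations
each for the ANOSIM calibration and the LRT level, exhaustive permutation
enumeration on designs of 6–8 samples, and one full study-scale pass
(243 samples, 170 rendered substances) through alignment, preprocessing and
ANOSIM. These sizes are the package's own choices; the acceptance script
(`scripts/acceptance.R`) re-runs the study-scale pipeline from scratch.

## Known limitations

* The alignment stage assumes drift is constant within a batch; no RT
  warping is attempted.
* The spectral-consistency check is a Jaccard surrogate for expert
  inspection; it will pass any range whose members share most top
  fragments, including genuinely co-eluting isomers.
* Individual-level permutation with 12 females has coarse p-value
  resolution, and the within/between-individual scheme split for the
  customised ANOSIM is this package's interpretation.
* The screen's flag rule is prevalence-sensitive (see above); scores and
  ranks are always reported so users are not bound to the flag.
* No substance identification: ranges remain anonymous RT/m-z entities;
  library search and standards are out of scope.
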