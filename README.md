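# semioprofile

Chemical-cue analysis of mammalian scent profiles from deconvoluted GC-MS
peak lists.

Scent marks of female common marmosets encode reproductive information —
ovarian cycle state, age, parity. Thermal-desorption GC-MS turns each scent
sample into a *peak list* (retention time, fragment spectrum over m/z
30–300, integrated area). `semioprofile` takes a directory's worth of such
peak lists and answers two questions:

1. **Do whole profiles differ** by cycle state, age or parity? —
   Bray–Curtis dissimilarities on `log(x+1)` relative peak areas, tested
   with an ANOSIM whose permutation null respects repeated samples per
   female (labels are shuffled only within a female, or whole females are
   permuted for between-female factors).
2. **Which substances drive the difference?** — the samples × substances
   matrix is vectorised (212 × 160 = 33,920 rows at study scale) and fitted
   with a crossed-random-effects linear mixed model (33 predictor
   variables: 9 fixed effects; random intercepts for sample, substance,
   female, room, batch; an age slope within substance; and random
   interactions of the design factors within substance, female, room and
   batch). Likelihood-ratio tests assess the three test predictors
   (substance × cycle, substance × parity, age-slope-in-substance), and a
   substance is flagged *most affected* when its absolute conditional-mode
   score `s` satisfies

   `s >= mean(s) + 2 * SD(s)`.

In between sit the chromatography-facing stages: per-batch retention-time
adjustment, gap-based grouping of peaks into retention-time ranges
(default gap 0.05 min), an occurrence filter (>= 14 samples), prominent-mass
extraction with an automated spectral-consistency check, known-contaminant
and blank-based exclusion, and normalisation to relative peak areas
(percent of each sample's total). Exact bioassay statistics (enumerated
Wilcoxon signed-rank, two-way single-measure ICC) round out the toolkit.

A synthetic-data module (`design_config()`, `effect_spec()`,
`simulate_study()`) generates complete studies — peak lists, blanks,
contaminants, batch structure, RT jitter, peak dropout — with planted
cycle/age/parity effects and a recorded ground truth, so the entire
pipeline is testable without any instrument data.

The package is written for chemical ecologists and analysts who have
deconvolution output in hand and want a reproducible, tested path to
"these N substances are the candidates".

## Worked example

Simulate a small study (6 females, 36 animal samples, 6 blanks, 40 true
substances of which 3 cycle-, 4 age- and 2 parity-affected, plus 4
contaminants), then run the full pipeline:

```r
library(semioprofile)

study <- simulate_study(
  design_config(n_females = 6,
                state_quota = c("follicular" = 10, "peri-ovulatory" = 16,
                                "luteal" = 10),
                n_cycles = 12, n_handling_blanks = 3, n_air_blanks = 3),
  effect_spec(n_substances = 40, n_contaminants = 4, n_cycle = 3,
              n_age = 4, n_parity = 2, seed = 1),
  seed = 1)

aligned <- align_peaks(study$peaks, min_occurrence = 5)
rel     <- preprocess_profiles(aligned, study$contaminants, study$design)
rel$provenance
#>   step               detail
#> 1 quantify           44 ranges quantified over 42 samples (0 unverified dropped)
#> 2 contaminant_filter removed 4 range(s): R0003,R0011,R0029,R0038
#> 3 blank_filter       removed 0 range(s) by mean comparison; 6 blank row(s) dropped
#> 4 relative_areas     36 samples normalised to 100%
```

Whole-profile similarity by cycle state, with the restricted permutation
scheme chosen automatically:

```r
tidy(profile_anosim(rel, study$design, "cycle_state", n_perm = 999, seed = 1))
#>   factor      scheme                R     p n_perm exact
#> 1 cycle_state within_individual 0.461 0.001    999 FALSE
```

Substance screening:

```r
long <- vectorise(transform_response(rel, "normalised"), study$design)
spec <- build_model_spec(
  fixed = c("cycle_state", "age_z", "parity"),
  random_intercept = c("sample_id", "substance", "female_id", "batch"),
  random_slope = c(substance = "age_z"),
  random_interaction = list(substance = c("cycle_state", "parity")),
  test_predictors = c("(1|substance:cycle_state)", "(1|substance:parity)",
                      "(0+age_z|substance)"))
tab <- lrt_table(long, spec)
tab
#>   predictor  chisq    df        p n_flagged
#> 1 full-null 102.       3 6.58e-22        NA
#> 2 age        89.9      1 2.51e-21         3
#> 3 cycle      25.1      1 5.58e- 7         3
#> 4 parity      1.92     1 1.66e- 1        NA

screen <- screen_substances(attr(tab, "fits")$full, "cycle")
head(tidy(screen), 5)
#>   substance score direction      flagged threshold predictor
#> 1 R0015     0.889 peri-ovulatory TRUE        0.456 cycle
#> 2 R0004     0.491 follicular     TRUE        0.456 cycle
#> 3 R0013     0.458 luteal         TRUE        0.456 cycle
#> 4 R0008     0.241 luteal         FALSE       0.456 cycle
#> 5 R0017     0.215 peri-ovulatory FALSE       0.456 cycle
```

Reading the output: the chemical composition responds strongly to age and
cycle state (per-predictor LRTs, df = 1 each) but not parity; three
substances exceed the mean + 2 SD score threshold for cycle. Checking
against the generator's ground truth confirms the flags are exactly the
planted cycle substances:

```r
dplyr::filter(match_ranges(aligned, study$truth$spec),
              range_id %in% screen$substance[screen$flagged])
#>   range_id substance   rt_diff
#> 1 R0004    sub004    -0.000845
#> 2 R0013    sub013     0.000195
#> 3 R0015    sub015    -0.000534
study$truth$cycle_substances
#> [1] "sub013" "sub015" "sub004"
```

`autoplot()` methods visualise screen results and permutation
distributions; `plot_substance_effect()` shows a single substance against
cycle state, age or parity.

## Documentation

The methods vignette (`vignettes/chemical-profiling.Rmd`) describes the
generative model behind the synthetic studies, every tunable parameter with
its default and rationale, the permutation schemes, the mixed-model
parameterisation, the numerical edge cases, and the known limitations —
including where the flag rule's prevalence sensitivity makes ranking by
score preferable to relying on the flag.
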