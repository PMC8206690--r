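# actiscreen

Automated pre-screening of **chronic insomnia (CI)** from multi-night
wrist-actigraphy recordings.

Actigraphs record an integer *activity count* per 60-second epoch — the
number of times wrist acceleration exceeded a device reference. Sleep
clinicians would like to use week-long home recordings to flag people whose
nocturnal movement patterns look like chronic insomnia before committing
them to polysomnography or structured interviews. The difficulty is that a
single night is uninformative: healthy sleepers have occasional bad nights
and people with CI have occasional good ones, and no single actigraphy
feature separates the groups. `actiscreen` implements a fully automated
analysis of multi-night time-in-bed (TIB) count series that addresses this
with three ingredients:

1. **Intensity-filter bank.** Each night's signal `x` is passed through
   wake-sensitivity filters InF ∈ {0, 20, 40, 80}: counts with
   `x[i] ≤ InF` are set to zero. The four filtered signals expose
   different mixtures of subtle and gross movement.
2. **48 night features.** On each filtered signal, 12 features: mean and
   s.d.; Poincaré plot descriptors SD1, SD2, SD1/SD2 and the complex
   correlation measure CCM (normalised mean triangle area of consecutive
   lag-1 plot points, C·n = π·SD1·SD2); sample entropy SampEn(m = 2,
   r = 0.2·s.d.); and rule-based sleep parameters from the sleep-onset
   rule (SO = start of the first 10-minute run of zero counts): TST, SL,
   WASO, SWR = TST/WASO and SE = 100·TST/TIB.
3. **Two-layer classification.** Layer 1 labels every night of every CI
   subject "bad" (1) and of every healthy subject "good" (0), and
   predicts night labels with a random forest (100 trees, √p features per
   split) or a linear SVM (box constraint 1, standardized features) under
   leave-one-subject-out (LOSO) cross-validation. Layer 2 learns, again
   leaving the test subject out, a threshold Th on the count of predicted
   bad nights: a subject with ≥ Th predicted bad nights is screened as
   CI. Sensitivity/specificity/accuracy are reported in percent at both
   levels.

Because clinical actigraphy cohorts of cohabiting CI/healthy couples are
not freely available, the package ships a seeded synthetic cohort
generator (`simulate_cohort()`): a two-state sleep/wake Markov chain per
night with log-normal wake emissions, zero-inflated sleep emissions,
subject-level random effects and a night-quality mixture, calibrated so
unfiltered group mean activity, TST/WASO/SE directions and night-to-night
heterogeneity match what is reported for real couples cohorts.

## Worked example

```r
library(actiscreen)

coh <- simulate_cohort(n_pairs = 40, nights = 7, seed = 11)
print(coh)
#> actigraphy cohort: 80 subjects (40 CI / 40 healthy), 560 nights
#> nights per subject: 7-7; TIB range 399-577 min

fit <- ci_screen(coh, classifier = "rf", seed = 11)
print(fit)
#> Two-layer actigraphy screening (rf, leave-one-subject-out)
#> subjects: 80 (40 CI / 40 healthy), nights: 560
#> learned bad-night threshold (modal): 3
#> subject level: accuracy 92.5%, sensitivity 95.0%, specificity 90.0%
#> night level:   accuracy 76.6%, sensitivity 72.1%, specificity 81.1%

head(fit$subject_table, 3)
#>   subject_id   group n_nights bad_nights bad_fraction threshold predicted
#> 1       ci01      CI        7          5    0.7142857         3        CI
#> 2       hc01 healthy        7          2    0.2857143         3   healthy
#> 3       ci02      CI        7          6    0.8571429         3        CI
```

The night level is deliberately noisy (blanket good/bad labelling is only
a proxy), but aggregating each subject's predicted bad nights against the
learned threshold recovers the groups: here 92.5% of the 80 subjects are
screened correctly, with the threshold learned at 3 bad nights for this
cohort. `summary(fit)` adds the threshold sweep, `plot(fit)` draws it,
`plot(fit, "roc")` the subject-level ROC, and `predict(fit, new_cohort)`
screens unseen subjects.

Evaluation helpers mirror the rest of a typical study: `feature_stats()`
(per-feature group mean ± s.d., Mann-Whitney p, AUC), `threshold_sweep()`,
`night_ablation()` (first k = 3..7 nights), `randomization_control()`
(random night labels) and `run_pipeline()`, which wires
simulate → features → screen → evaluate into files next to a manifest
that makes the run byte-reproducible. A thin command-line wrapper lives
at `inst/cli/actiscreen.R`.

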