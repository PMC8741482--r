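# dysfscreen

Quantitative scoring of dysferlin missense variants for plasma-membrane
localization, chemical-chaperone rescue screening, and membrane-repair
kinetics.

Dysferlinopathies are recessive muscular dystrophies caused by
loss-of-function mutations in dysferlin (*DYSF*), a tail-anchored
plasma-membrane (PM) protein of skeletal muscle that reseals the sarcolemma
after injury. Many patient missense mutations (PMMs) misfold the protein so
it never reaches the PM — a defect that is measurable, and in some cases
pharmacologically correctable. This package is for researchers analyzing two
such assays:

**Surface-localization score (flow cytometry).** A bicistronic
DYSF-T2A/DsRed reporter yields equimolar surface-taggable dysferlin and
cytosolic DsRed. On gated live, DsRed-positive cells, a variant's score is
the wild-type-normalized ratio of geometric-mean fluorescence intensities
(gMFI):

```
value = (gMFI_farred(mut) / gMFI_DsRed(mut)) / (gMFI_farred(WT) / gMFI_DsRed(WT))
```

Variants scoring strictly below 0.25 (25% of wild type) are classified
localization-defective. On top of the score sit replicate statistics
(mean ± SD, Student's t vs WT), registry tallies, concordance with binary
microscopy calls, and rescue-screen hit calling (a treatment is a hit when
it lifts a defective variant to ≥ 0.25, significantly above vehicle).

**Membrane-repair kinetics (laser wounding).** The ROI dye-influx signal
after wounding is modeled as exponential breach resealing,
`ΔF(t) = k_a0·τ·(1 − exp(−t/τ))`, whose τ → ∞ limit is the sustained linear
influx of repair-deficient membranes. The package extracts ROI traces from
TIFF stacks, computes ΔF against the pre-wound baseline, fits both models
with AICc selection, classifies proficient/deficient, and compares groups.

Both assays come with seeded synthetic generators (`simulate_events()`,
`simulate_trace()`/`simulate_stack()`) with known ground truth, used by the
test suite to verify every estimator.

## Worked example

```r
library(dysfscreen)

# simulate an untransfected control, a wild-type and a mutant population
# whose true membrane-localized fraction is 50% of wild type
ctrl <- simulate_events(cyto_sim_config(n_events = 10000,
                                        frac_transfected = 0), seed = 101)
wt   <- simulate_events(cyto_sim_config(n_events = 10000, p_pm = 1.0), seed = 102)
mut  <- simulate_events(cyto_sim_config(n_events = 10000, p_pm = 0.5), seed = 103)

two_a_value(mut, wt, gating_config(), control = ctrl)
#> # A tibble: 1 × 7
#>   gmfi_far_red gmfi_dsred raw_ratio wt_raw_ratio value n_events n_events_wt
#>          <dbl>      <dbl>     <dbl>        <dbl> <dbl>    <int>       <int>
#> 1        2411.      4797.     0.503        0.959 0.524     1922        1961
```

The `value` column is the estimated fraction of wild-type surface
expression: 0.524 for a population whose ground truth is 0.5 (the ~+0.02
offset is the documented autofluorescence bias). ~2000 of 10000 events
survive gating, consistent with 20% transfection efficiency and 5% dead
cells. A mean value below 0.25 would classify the variant defective:

```r
classify(tibble::tibble(label = "L1341P", mean_value = 0.14))
#> # A tibble: 1 × 4
#>   label  mean_value defective threshold
#>   <chr>       <dbl> <lgl>         <dbl>
#> 1 L1341P       0.14 TRUE           0.25
```

Repair kinetics from a simulated noisy trace (true τ = 10 s, k_a0 = 50/s):

```r
fit <- fit_kinetics(delta_f(simulate_trace(
  repair_sim_config(tau = 10, k_a0 = 50, noise_sd = 25), seed = 7)))
glance(fit)
#> # A tibble: 1 × 9
#>   model       k_a0   tau plateau_delta_f    rss aicc_deficient aicc_proficient
#>   <chr>      <dbl> <dbl>           <dbl>  <dbl>          <dbl>           <dbl>
#> 1 proficient  43.7  10.5            461. 72582.          1318.            961.
classify_repair(fit)
#> [1] "proficient"
```

The saturating model wins AICc decisively and recovers the resealing time
constant (10.5 s vs true 10 s); τ below a third of the 169 s horizon
classifies the membrane repair-proficient.

See `vignettes/dysfscreen-methods.Rmd` for the generative models, gating
rules, estimator design and limitations.

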