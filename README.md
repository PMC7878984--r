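# tagrates

Division and death rate estimation for microbial populations from neutral
sequence-tag (barcode) frequency drift and CFU time series — with analytic
correction for technical bottlenecks.

## The problem

A CFU growth curve only gives the net growth rate `r = β − δ`. A population
dividing fast and dying fast looks identical, on a plate count, to one
turning over slowly — yet the two differ in everything that matters for
resistance evolution and antibiotic action. `tagrates` separates β
(division, min⁻¹) from δ (death, min⁻¹) using hundreds to thousands of
fitness-neutral random barcodes: stochastic drift in tag frequencies encodes
the total event rate β + δ, while the census encodes β − δ.

The drift of all `k` tags is aggregated into the **founder population
size**

    N_B(t) = 1 / [ (1/k) Σᵢ (fᵢ(t) − ⟨fᵢ(0)⟩)² / (⟨fᵢ(0)⟩(1 − ⟨fᵢ(0)⟩)) ]

whose birth–death ensemble mean has the closed form

    ⟨N_B(t)⟩ ≈ (β − δ) N(0) / [ (β + δ)(1 − e^{−(β−δ)t}) ],

independent of the tag distribution. Together with `N(t) = N(0)e^{rt}` this
inverts to

    δ̂ = (r/2) [ N(0) / (N_B(t)(1 − N(0)/N(t))) − 1 ],    β̂ = r + δ̂.

Technical sampling events (pipetting, finite sequencing depth) add spurious
drift; modeling each as a multinomial draw, their mean inverse sample sizes
are simply subtracted from 1/N_B before inverting. A bottleneck
**sensitivity measure** `s_B(t)` (sampling variance over birth–death
variance, threshold 0.17) flags experiments whose rate estimates are fragile
to errors in those corrections — before any sequencing is done.

The package also ships: a vectorized tau-leaping birth–death simulator with
multinomial bottleneck chains (plus an exact Gillespie reference), a barcode
FASTQ counting pipeline with a binomial sequencing-error model for spurious
read removal, a plasmid-segregation comparator, tag-extinction forecasting,
death-process emulation schedules, and synthetic-data generators with exact
ground truth.

## Worked example

Generate a synthetic experiment with known truth (β = 0.01, δ = 0.03,
k = 1000 geometric tags, triplicate references, bottleneck chains
I = {10⁶, 10⁶}, S = {10⁵, 10⁶}), then run the full estimation pipeline:

```r
library(tagrates)

ex <- generate_experiment_tables(beta = 0.01, delta = 0.03, times = c(60, 120),
                                 k = 1000, prob = 1/1000, seed = 87)
res <- estimate_experiment(ex$timepoints, ex$reference, ex$cfu, ex$ledger,
                           sensitivity_nb = 1e6)
#> Warning: bottleneck sensitivity exceeds 0.17 at timepoint(s) 60 min; rate
#> estimates there are fragile to correction errors.
res
#>   time_min nb_raw      nb negative_flag    cfu beta_hat delta_hat   r_hat    s_b
#> 1       60 66696. 501669. FALSE         285530 -0.00185    0.0182 -0.0200 0.480
#> 2      120 29923.  48973. FALSE          85771  0.00927    0.0293 -0.0200 0.0490
glance(res)
#>         r r_conf.low r_conf.high     n0 mean_beta_hat mean_delta_hat ...
#> 1 -0.0200    -0.0202     -0.0198 947424       0.00371         0.0237
```

Reading the output: the net growth rate (−0.0200 min⁻¹) is recovered almost
exactly from the CFU series. At t = 120 min the corrected founder size
(48 973; closed-form target 47 262) yields δ̂ = 0.0293 and β̂ = 0.0093
against the true 0.03 / 0.01. At t = 60 min the sensitivity s_B = 0.48 sits
far above the 0.17 threshold — drift accumulated in one hour is still small
compared to the sampling noise of the 10⁵-cell harvest bottleneck — and,
exactly as the flag predicts, that timepoint's estimates are unreliable.
Later sampling, or a larger harvest, is the fix; `sensitivity_grid()`
automates that design check.

Death-emulation schedules reproduce published control-experiment volumes:

```r
death_emulation_volumes(100, 0.015, c(0, 20, 25, 30, 35, 40))
#>   time_min volume_ul
#> 1        0     100
#> 2       20      74.1
#> 3       25      68.7
#> 4       30      63.8
#> 5       35      59.2
#> 6       40      54.9
```

A thin CLI wraps the same functions
(`exec/tagrates count|estimate|simulate|emulate|sensitivity|ps|make-fixtures`);
every run writes a JSON provenance record.

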