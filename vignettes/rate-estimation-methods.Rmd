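---
title: "Estimating microbial division and death rates from sequence-tag drift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating microbial division and death rates from sequence-tag drift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagrates)
```

## The problem

A culture's colony-forming-unit (CFU) curve only reveals the *net* growth
rate $r = \beta - \delta$: a population dividing at $\beta = 0.03\,\mathrm{min^{-1}}$
while dying at $\delta = 0.01\,\mathrm{min^{-1}}$ traces the same census
trajectory as one dividing at $0.02\,\mathrm{min^{-1}}$ with no death at all.
Separating the two matters — division rates drive mutation accumulation and
therefore resistance evolution, and death rates report on antibiotics and
immune clearance.

`tagrates` separates them using hundreds to thousands of fitness-neutral
random sequence tags (barcodes) inserted at a neutral genomic locus. Each
tagged subpopulation drifts stochastically as its cells divide and die; the
*amount* of drift in tag frequencies carries the information that the census
alone lacks. The same framework corrects, analytically, for the spurious
drift added by technical sampling (pipetting a subvolume, finite sequencing
depth), which otherwise biases rate estimates.

## The model

Each of $k$ tagged subpopulations evolves as an independent linear
birth–death process with common rates $\beta$ (division) and $\delta$
(death), both in $\mathrm{min^{-1}}$. The standard moments are

$$\langle n_i(t)\rangle = n_i(0)e^{rt}, \qquad
  \mathrm{Var}(n_i(t)) = n_i(0)\tfrac{\beta+\delta}{\beta-\delta}e^{rt}(e^{rt}-1),$$

and error propagation on $f_i(t) = n_i(t)/N(t)$ gives the frequency
variance implemented in `bd_freq_variance()`:

$$\mathrm{Var}(f_i(t)) \approx
  \frac{(\beta+\delta)(1-e^{-rt})}{r\,N(0)}\,f_i(0)(1-f_i(0)).$$

### Founder population size

Drift over all tags is aggregated into a single number, the founder
population size, computed by `founder_size()`:

$$N_B(t) = \left[\frac{1}{k}\sum_{i=1}^{k}
  \frac{(f_i(t)-\langle f_i(0)\rangle)^2}
       {\langle f_i(0)\rangle(1-\langle f_i(0)\rangle)}\right]^{-1}.$$

Its interpretation: the size of the sample in a hypothetical multinomial
sampling event that would have produced the same drift. The key closed form
(`founder_theory()`) is the ensemble mean after a birth–death process,

$$\langle N_B(t)\rangle \approx
  \frac{(\beta-\delta)N(0)}{(\beta+\delta)(1-e^{-(\beta-\delta)t})},$$

which is *independent of the tag distribution* — an arbitrarily skewed
library works, so the number of tags is limited only by sequencing depth.
Solving this together with $N(t) = N(0)e^{rt}$ for the individual rates
gives the estimator in `rate_estimates()`:

$$\hat\delta = \frac{r}{2}\left[
  \frac{N(0)}{N_B(t)\left(1-N(0)/N(t)\right)}-1\right],
  \qquad \hat\beta = r + \hat\delta,$$

with $r$ measured as the OLS slope of $\ln \mathrm{CFU/ml}$ on time
(`growth_rate()`).

All three ingredients are per-volume quantities and must refer to the *same*
volume: if CFUs are counted per ml but tags were sequenced from 200 µl, the
measured founder size is multiplied by 5 (`scale_volume()` records the
factor).

### Correcting technical bottlenecks

Each technical sampling event — harvesting $S_1$ cells, sequencing $S_2$
reads, and likewise $I_1, I_2$ on the time-0 reference side — is modeled as
a multinomial draw and adds $1/\text{size}$ to the mean inverse founder
size. Iterating the laws of total expectation and variance shows the
additions are simply summed, so `founder_size()` with a
`bottleneck_ledger()` subtracts

$$\sum_{j=1}^{m_S}\langle S_j^{-1}\rangle + \sum_{j=1}^{m_I}\langle I_j^{-1}\rangle$$

from the inverse estimate before inverting. Replicate size measurements of
one stage enter as the mean of their inverses (not the inverse of the mean).
A non-positive corrected denominator is returned **flagged, never clipped**:
it is a diagnostic that technical bottlenecks drowned the biological signal,
and `rate_estimates()` refuses flagged inputs with advice to re-design the
experiment.

One caveat we document deliberately: when the reference profile is the
average of $R$ replicate time-0 samples, averaging reduces the
reference-side sampling variance by $1/R$, while the correction above
(applied literally) subtracts the full $\sum\langle I_j^{-1}\rangle$. With
stringent inoculum-side bottlenecks and several replicates this over-corrects
— visible as negative-flagged estimates. In the validation harness each
replicate therefore carries its own single reference chain, where the
literal correction is exact; with deep reference sampling
($I_j \gg N_B^{BD}$) the distinction is negligible.

### Bottleneck sensitivity

`bottleneck_sensitivity()` computes the ratio of sampling-induced to
birth–death-induced frequency variance,

$$s_B(t) = \frac{r\,N(0)}{(\beta+\delta)(1-e^{-rt})\,N_B},$$

with $N_B$ the technical sample size and $N(0)$ in CFU/ml. Large $s_B$ means
a small relative error in the correction terms translates into a large error
in the corrected founder size (and, through the estimator, roughly the same
relative error in the rates). The threshold 0.17 is an empirical calibration
carried as a constant: death-emulation control experiments become unreliable
above it. `sensitivity_grid()` evaluates $s_B$ over a grid of plausible
rates — bounded, for instance, by `rate_from_doubling_time()` on the fastest
plausible doubling and halving times — which is the recommended
experiment-design step before any sequencing: if a corner of plausible rate
space exceeds the threshold, sample more cells, lower $N(0)$, or sample
later. Sensitivity rises sharply as both rates approach zero, so
slow-turnover (stationary-like) cultures are the hard case.

### Degenerate regimes

Every closed form above has a removable singularity at $r = 0$. We switch to
the analytic limits when $|r|t < 10^{-8}$:
$\langle N_B\rangle \to N(0)/((\beta+\delta)t)$,
$\mathrm{Var}(f_i) \to (\beta+\delta)t\,f(1-f)/N(0)$,
$s_B \to N(0)/((\beta+\delta)\,t\,N_B)$, and
$\hat\delta \to N(0)/(2N_Bt) - r/2$ (which is why `rate_estimates()` asks
for `t` when the census did not change). Tests verify continuity across the
switch to $10^{-6}$ relative accuracy. Tags whose mean reference frequency
is exactly 0 or 1 cannot be standardized and are excluded from the sum with
a logged count; identical profiles return `Inf`, flagged.

## Death emulation and the plasmid comparator

A pure death process can be emulated without waiting: sampling
$\Delta v_t = \Delta v_0 e^{-\delta t}$ from a well-mixed culture reproduces
the census of a death process with rate $\delta$
(`death_emulation_volumes()`), so the true rates are known in advance. The
sampling variance per cell is $\propto(1-f_i(0))$ whereas a death process
gives $\propto(1-p)$ with $p = e^{-\delta t}$; matching the founder size
therefore requires multiplying by $1/(1-p)$ (`scale_death_emulation()`; for
$k \sim 1000$ tags the $(1-f_i(0))$ factor is within 0.1% of 1 and is
absorbed into the approximation).

The independent comparator is plasmid segregation (`plasmid_rates()`): a
conditionally non-replicative plasmid dilutes as
$F(t) = F(0)e^{-\beta t}$, giving
$\beta = t^{-1}\ln[F(0)/F(t)]$ and
$\delta = t^{-1}\ln[F(0)N(0)/(F(t)N(t))]$. On noiseless input generated
from one $(\beta, \delta)$ the two estimators agree to numerical precision
(tested); the tag-based method's advantage is its unlimited observation time
while the marker survives only $\sim 1/\beta$ generations.

`expected_surviving_tags()` forecasts the opposite failure mode — tag
extinction under heavy death — from the closed-form extinction probability
of a linear birth–death process,
$p_{ext}(t) = [\delta(e^{rt}-1)/(\beta e^{rt}-\delta)]^{n_0}$ per tag
(limit $[\delta t/(1+\delta t)]^{n_0}$ at $\beta=\delta$). Libraries heading
below ~400–500 surviving tags should be enlarged before the experiment.

## The simulator

`simulate_bd()` is a fixed-step tau-leaping simulator: per step of
`dt` minutes each tag draws $\mathrm{Poisson}(\beta n\,dt)$ births and
$\mathrm{Poisson}(\delta n\,dt)$ deaths. Numerical choices:

* **Death overdraw.** Poisson deaths exceeding the current count are capped
  at the count. At the default `dt = 0.01` and rates $\le 0.14$, the
  per-cell event probability per step is $< 2\times10^{-3}$, so the induced
  bias is negligible; the cap only guards the tail. Zero is absorbing.
* **Vectorization.** All replicates advance as one `k × n_reps` matrix under
  a single seeded RNG stream, so a 100-replicate ensemble costs little more
  than one trajectory and is bit-reproducible for a given seed and plan.
  (Per-replicate RNG streams would only matter for parallel execution, which
  we do not do.)
* **Heterogeneity.** `rate_sd > 0` draws per-tag rates once at $t=0$ from
  truncated normals. Relative spreads below ~10% leave ensemble behavior in
  the homogeneous error band; larger spreads inflate the mean census (and
  downstream rate estimates) by convexity — the model's stated limitation
  for persister-like phenotypic heterogeneity.

`simulate_bd_exact()` is the independent event-driven (Gillespie) reference
used by the test suite on small instances; the tau-leap ensemble mean and
variance are checked against both the closed forms and the exact simulator.

`run_insilico_experiment()` reproduces the validation study: a
geometric($p = 1/1000$) library of $k = 1000$ tags (support $\{1,2,\dots\}$
so every constructed clone exists; census $\approx 10^6$), 100 tau-leap
iterations to $t = 120$ min, endpoint chains $S = \{10^5, 10^6\}$ and
reference chains $I = \{10^6, 10^6\}$, with the founder size computed
ideally, uncorrected, and corrected per iteration. For the dying case
($\beta = 0.01$, $\delta = 0.03$) the three ensemble means land near
$\{4.9, 3.0, 4.9\}\times10^4$ and the recovered rates hit the targets within
a few percent; for the growing case ($\beta = 0.03$, $\delta = 0.01$) the
corrected estimator is unbiased but wildly dispersed because the endpoint
bottleneck $S_1 = 10^5$ is tiny relative to the $\sim 10^7$-cell endpoint
census — the worked demonstration of why the sensitivity measure exists.
Cell sampling is multinomial (with replacement) rather than hypergeometric,
matching the analytic framework even at large sampling fractions.

## The read-counting model

`count_tags()` turns raw reads (30 bp random barcode + 21 bp fixed strain
barcode) into a count table:

1. **Filter** on an exact strain-barcode match. Under position-independent
   per-base errors the pass rate is $p^{N_S}$, so
   `estimate_error_rate()` recovers $p = (n_F/N)^{1/N_S}$ — typically
   0.98–0.99, estimated per sample with no recourse to quality scores (the
   model is deliberately quality-blind).
2. **Budget**: the mismatch count in the random region is
   $\mathrm{Binomial}(N_R, q)$, so the expected number of reads with $m$
   mismatches is $\tilde n_m = n_F\binom{N_R}{m}q^m(1-q)^{N_R-m}$;
   $m_{max}$ is the largest class still expecting $\ge 1$ read.
3. **Despurify**: after exact clustering and abundance sorting (ties
   lexicographic), the top $k$ sequences are the true barcodes. Each
   extraneous sequence gets the Hamming distance to its *nearest* true
   barcode as its mismatch class — the mean distance to all $k$ barcodes is
   $\approx 3N_R/4$ for any sequence and cannot discriminate, so nearest
   distance is the operational reading of "mismatches to the barcodes".
   Classes beyond $m_{max}$ are discarded; within each class at most
   $\mathrm{round}(\tilde n_m)$ most-abundant sequences are retained and,
   by default, merged back into their parent's count (a `merge = FALSE`
   diagnostic mode keeps them separate). Substitution-only: no indel
   alignment, matching the binomial model.

The synthetic generator (`generate_barcode_library()`, `generate_reads()`)
enforces a minimum pairwise barcode distance (default 5) so error classes up
to $m_{max}$ cannot collide, plants optional contaminants distant from every
barcode, and records the error-free source of every read, so assignment
accuracy is measured against exact ground truth (≥99% at $q = 0.01$, exact
at $q = 0$, in the test suite).

## What the synthetic data does and does not emulate

The generators reproduce: skewed geometric libraries, birth–death drift,
chained multinomial technical bottlenecks, position-independent substitution
errors, and strain-barcode filtering. They do **not** emulate PCR
amplification bias (assumed unbiased, as in the analytic framework), indels,
chimeras, quality-score structure, fitness differences between tags beyond
the optional normal heterogeneity, or non-exponential (e.g. logistic)
growth. Passing tests therefore validate the estimators under the model's
own assumptions; on real data, the places those assumptions bend (PCR bias,
persisters, density dependence) are exactly the stated limitations.

## Problem sizes and reproducibility

The shipped tests run the full validation ensembles (two 100-iteration,
$k = 1000$, $dt = 0.01$, $t = 120$ min experiments, a few minutes of CPU),
smaller tau-leap/Gillespie cross-checks (hundreds of replicates at
$N(0) \le 10^3$), and a $10^5$-read synthetic sequencing run — sizes chosen
to hold Monte-Carlo standard errors at a few percent. Every stochastic
function takes an explicit `seed`; identical seed and configuration give
bit-identical output, and `scripts/acceptance.R` re-derives the headline
quantities from scratch at any seed.
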