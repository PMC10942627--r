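---
title: "Accounting for plasma cfDNA against cellular turnover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accounting for plasma cfDNA against cellular turnover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfdnaflux)
```

## The model

Cell-free DNA (cfDNA) in plasma is thought to derive from dying cells. The
package asks a mass-balance question: for each cell type, what plasma
concentration *would* we see if every haploid genome copy of every dying
cell entered the bloodstream, and how does that compare with what methylome
deconvolution actually attributes to the type?

At steady state, a cell type with turnover $d_c$ (cells/day) and ploidy
$p_c$ (haploid genome sets per dying cell) feeding a plasma compartment of
volume $V_{plasma}$, where molecules persist for a mean lifetime $\tau$,
would maintain the **potential concentration**

$$X_c = \frac{d_c \, p_c \, \tau}{V_{plasma}}$$

in genome equivalents (GE) per ml (multiplying by the haploid genome mass
$m_h = 3.2\times10^{-12}$ g gives g/ml). Intuitively: the amount of DNA
discarded during one clearance lifetime, spread over the plasma volume.

The **measured concentration** of a type is the total plasma concentration
(about 1000 GE/ml in healthy adults), corrected for under-recovered
ultrashort fragments (see below), times the deconvolution fraction. The
**capture ratio** measured/potential is the quantity of interest: the
fraction of dying-cell DNA that ends up as measurable plasma cfDNA. Its
reciprocal is reported with labels like "1:30".

Assumptions worth keeping in mind: steady state (healthy, homeostatic
turnover; no acute injury), a single well-mixed plasma compartment with
first-order clearance, one shared $\tau$ for all cell types, and deconvolution
fractions that refer to genome equivalents rather than mass.

## Uncertainty propagation

Inputs span orders of magnitude and their uncertainties are multiplicative,
so every estimate is carried as a lognormal quantity: a median plus a
multiplication error factor $f \ge 1$, with shape parameter $s = \ln f$
(the SD of the log-transformed variable). $f = 2$ means a 68% chance the
true value is between half and double the median.

* **Products and ratios** stay lognormal; medians multiply and shapes add in
  quadrature: $f_{xy} = \exp\!\sqrt{\ln^2 f_x + \ln^2 f_y}$. All operands
  are treated as independent — no covariance terms, which matches the
  product rule used and means a self-ratio $x/x$ keeps spread.
* **Sums** have no closed form; `bootstrap_sum()` draws 1000 samples per
  summand (configurable), sums per draw, and refits a lognormal.
* **Reported confidence intervals** are converted with `from_interval()`:
  $s = \ln(\mathrm{hi}/\mathrm{lo})/(2\times1.96)$, symmetrizing asymmetric
  intervals on the log scale while keeping the stated median.
* **Lognormal refits** (`fit_lognormal()`) use the log-scale mean and
  *population* SD. This estimator exactly inverts sampling from a lognormal
  quantity in the large-n limit and is robust to the heavy right tail of
  lognormal sums; moment matching on the raw scale would be neither.
* Every stochastic operation takes an explicit integer seed and is
  bit-reproducible; pipeline-level seeds derive per-operation child seeds
  deterministically. Seeds are never defaulted silently.

## Parameters and defaults

| parameter | default | unit | why |
|---|---|---|---|
| plasma volume $V_{plasma}$ | 3 | L | adult blood plasma volume |
| mean cfDNA lifetime $\tau$ | 0.7 (factor 1.70) | h | half-life/ln 2; the factor fits the literature half-life range 15–120 min read as a ~95% band |
| haploid genome mass $m_h$ | 3.2e-12 | g | converts GE to grams |
| total plasma cfDNA | 1000 (factor 1.41) | GE/ml | median in healthy adults under 47; factor combines the reported median's CI (reconstructed as 850–1150 GE/ml) with a 1.4 inter-individual/preanalytic variation factor |
| ultrashort adjustment | uniform [1, 2] | — | single-stranded ~25–60 bp fragments carry a genome-copy content comparable to nucleosomal fragments but are missed by standard assays; midpoint 1.5 |
| detection band | [1, 10] | GE/ml | targeted marker assays resolve ~0.1% of total (~1 GE/ml); genome-wide deconvolution ~1% (~10 GE/ml) |
| bootstrap iterations | 1000 (sums), 10,000 (adjustment) | — | convention of the analysis; configurable |

The ultrashort-fragment adjustment is a uniform, not lognormal, uncertainty:
the data only bound the correction between "no effect" (1) and "doubling"
(2). `apply_uniform_factor()` propagates it by bootstrap and refits a
lognormal. Note the refit median of a uniform [1, 2] multiplier is its
*geometric* mean $e^{2\ln 2 - 1} \approx 1.47$, slightly below the
arithmetic midpoint 1.5 — a property of the lognormal summary, not a bug.

Detection status is classified on the potential *median* against the band:
the detection limit is itself a gradient, so the classifier reports which
band the point estimate falls in rather than intersecting CIs with it.

## Bespoke turnover estimators

Two cell types need more than a literature value:

* **Megakaryocytes** are estimated two ways — marrow pool / maturation time
  (~5 days), and platelet production / platelets per megakaryocyte — and
  merged by `combine_estimates()`: geometric-mean median, factor =
  max(either route's factor, $\sqrt{\text{larger}/\text{smaller median}}$).
  The merge rule is this package's choice (the source analysis does not
  state one); it deliberately penalizes disagreement between routes instead
  of averaging it away. Megakaryocytes are polyploid; their ploidy (16 here)
  is a table input, never hard-coded.
* **Hepatocytes** combine cell counts and death rates per ploidy class
  (diploid/tetraploid/octoploid). The turnover median is the exact sum of
  class death fluxes; the factor is propagated by `bootstrap_sum()` over the
  class fluxes; the effective ploidy is the death-flux-weighted mean ploidy
  and is treated as exact (its variation is second-order relative to the
  flux factors).

## The reference table is a reconstruction

The shipped cell-type table
(`inst/extdata/celltype_table_synthetic.csv`, `reference_celltype_table()`)
is **synthetic**: the original per-type supplementary data were not
available when the package was built. Turnover rates follow the published
whole-body turnover regime (erythroid progenitors 2e11 cells/day dominating,
externally shed epithelia carrying no plasma fraction), and the
deconvolution fractions were chosen to be jointly consistent with published
plasma methylome compositions and with the published capture-ratio anchors
(~1:30 for megakaryocytes and endothelium, ~1:30,000 for erythroid
progenitors). Headline checks against those anchors therefore validate the
pipeline's arithmetic and propagation on a faithful reconstruction of the
stated inputs — not an independent re-derivation from raw data.

## What the synthetic cohorts establish

`generate_cohort()` simulates a world where the model is exactly true:
true turnovers log-uniform over 1e9–3e11 cells/day, true capture fractions
log-uniform over 3e-5–3e-2 (the observed 1:30,000–1:30 regime), diploid
cells, and every observed quantity (turnover, fraction, total
concentration) perturbed by lognormal noise with a stated factor (default
1.5). Hidden "unprofiled" types carry half of the true cfDNA flux, so
profiled fractions sum to ~0.5 as in real plasma, where profiled cell types
do not account for the full concentration; this also avoids a
renormalization step that would correlate the observation errors. The
synthetic constants use an exact lifetime and an adjustment range of
[1, 1], so the pipeline's error model is *correctly specified*.

Under those conditions `recovery_report()` shows unbiased log-ratio
estimates and 95% CI coverage statistically at the nominal level (the test
suite checks coverage within [0.90, 0.99] over 500 replicates). That is
what a green test establishes — the propagation machinery is calibrated.
It does **not** establish that real inputs are lognormal, that $\tau$ is
shared across cell types, or that deconvolution fractions are unbiased;
real-data conclusions inherit those assumptions.

## Numerical choices and degenerate inputs

* Factors of exactly 1 are legal everywhere and degrade gracefully
  (zero-width CIs, exact arithmetic); the noiseless synthetic limit
  reproduces truth exactly, guarded only by a 1e-9 relative tolerance for
  float round-off in coverage checks.
* Ratio labels round the *reciprocal* to one significant figure
  (0.032 → "1:30").
* Cell types without a deconvolution fraction get potential concentrations
  and detection status but never an imputed zero ratio; externally shed
  types are structurally barred from carrying fractions.
* Fractions are not renormalized when they sum below 1 (unprofiled sources
  exist); tables whose fractions sum above 1 on the medians are the user's
  responsibility — per-row validation only enforces each fraction in (0, 1].
* `derive_seed()` keeps all derived seeds below $2^{31}$.

## Known limitations

Single-compartment clearance with one global $\tau$; no correlated errors;
no age, sex, or disease stratification (total concentration varies ~30%
with age, small against the thousand-fold effects here, but the ratios
themselves may shift in disease); methylome deconvolution is consumed, not
implemented; and the reference table is a reconstruction, as stressed above.
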