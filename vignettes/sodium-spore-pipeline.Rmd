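---
title: "From single particles to the sodium budget: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From single particles to the sodium budget: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sporesalt)
```

## The scientific question

Coarse-mode particles containing mixed sodium salts are routinely observed
over the central Amazon and are conventionally attributed to marine aerosol
transported from the Atlantic. An alternative source is the forest itself:
fungal spores are emitted in large numbers, contain sodium, and — when their
sodium content is high — take up water almost like salt particles. This
package implements the desk-scale computational chain that supports that
attribution:

1. **Single-particle classification** of SEM/EDX output into composition
   classes (Na-rich, dust, mixed biological-dust, sulfate, carbonaceous,
   other) plus two flags: *fungal spore* (morphology, size, carbonaceous
   matrix, phosphorus marker) and *sodium-containing* (Na at or above the
   3 wt% detection limit).
2. **Sodium quantification** of spores from their carbon content, the
   carbon-to-sodium mass ratio, and their size.
3. **Hygroscopic growth factors** from hydration imaging: area growth
   factors from ESEM frame pairs, mass growth factors from STXM
   transmission maps via Beer–Lambert optical density.
4. **Sodium mass-budget apportionment** between sodium-rich spores and sea
   salt on concentration time series, with uncertainty bounds, diel splits,
   and threshold-exceedance statistics.

A synthetic-data module generates every input (particle tables, image
pairs, concentration series) with the statistical structure the analysis
assumes, so the whole chain runs and is tested without any external data.

## Classification model

EDX reports composition as atomic fractions $a_i$; thresholds are stated in
weight terms, so records are converted with
$w_i = a_i M_i / \sum_j a_j M_j$ using standard atomic masses. Cu is
stripped before normalization — on Cu mesh grids it is substrate
background. The class rules are applied in precedence order (first match
wins):

| order | class | rule (weight fractions) |
|---|---|---|
| 1 | `na_rich` | Na ≥ 0.03 and Na the largest non-C/N/O element |
| 2 | `mixed_bio_dust` | C+N+O ≥ 0.50, P ≥ 0.005, Al+Fe ≥ 0.01 |
| 3 | `dust` | Al+Fe (+Si if Al or Fe ≥ 0.01) ≥ 0.10 |
| 4 | `sulfate` | S ≥ 0.05 |
| 5 | `carbonaceous` | C+O ≥ 0.90 |
| 6 | `other` | always |

The scheme is total and deterministic, and monotone in sodium: raising a
particle's Na weight fraction can move it into `na_rich` but never out.
Design choices worth flagging:

* **Si needs corroboration.** Bare Si without Al or Fe is treated as
  substrate background, not crustal material.
* **"Na-rich" vs "sodium-containing" are distinct.** The 3 wt% flag defines
  the *sodium salt particle* population that the budget apportions; the
  Na-rich class additionally requires sodium to dominate the non-CNO
  elements. The spore contribution to sodium salt particles is computed as
  Na-containing spores over all Na-containing particles. The two labels are
  cross-tabulated, never forced disjoint, because whether the original
  "biological" and "Na-rich" classes overlap is ambiguous; keeping both
  flags avoids committing to either reading.
* **Morphology is an input label.** Automated shape classification from
  images is out of scope; the generator (or an external annotator) supplies
  it.
* **Diameters are geometric area-equivalent diameters**,
  $d = 2\sqrt{A/\pi}$; the impactor stage window is metadata, not
  recomputed aerodynamically.
* The printed ± values on number fractions are binomial standard errors
  $\sqrt{p(1-p)/n}$; whether the original uncertainties were computed this
  way is not stated, so the formula is documented rather than assumed
  equivalent.

## Sodium content of spores

Spore carbon content spans 42–66 wt% of dry mass with mean 0.51, and the
average carbon-to-sodium mass ratio is 4:1, so the population sodium
dry-mass fraction is $0.51/4 = 0.1275$, i.e. ~13%. The budget module stores
the rounded constant 0.13 (the stated model input) while the derivation
check keeps 0.1275; both are asserted in the tests. Spore mass uses the
unit-density sphere, $m = (\pi/6)d^3\rho$, which at $\rho = 1$ g cm$^{-3}$
makes a 4 µm spore (the emission size used for number-to-mass conversion)
33.51 pg. Per-particle sodium mass prefers the particle's own measured Na
weight fraction and falls back to the population 0.1275 where none is
available. The 13% constant is applied to the *sodium-rich* spore
subpopulation in the budget, not to all spores — the sodium-poor majority
is handled through the `p_rich` assumption below.

## Growth factors from images

Segmentation uses Otsu's threshold on each frame independently (no
segmentation procedure is prescribed by the measurement protocol, and Otsu
is the standard parameter-free choice for bimodal microscopy frames),
followed by connected-component labelling; the largest foreground blob is
the particle. The **area growth factor** is the wet/dry ratio of
area-equivalent diameters — the diameter-ratio definition used with ESEM
hydration stages — with the projected-area ratio (its exact square)
reported alongside for transparency.

For STXM maps, per-pixel optical density is $-\ln(I_d/I_0)$; when $I_0$ is
not supplied it is estimated as the median intensity of the one-pixel frame
border, assumed particle-free. At the oxygen absorption edge the integrated
OD over the particle is proportional to oxygen mass, so the **mass growth
factor** is the wet/dry ratio of integrated OD. The integration mask is the
*union* of the dry and wet masks, so water condensed beyond the dry
boundary is counted, and noise pixels outside the union can never leak into
the ratio. Sub-pixel effects are ignored throughout; tolerances are
budgeted in pixel-quantization units (for a dry particle $k$ pixels across,
the diameter quantization error is ~$1/k$ of the growth factor).

## The budget model

With spore and sea-salt mass concentrations $C_s$ and $C_m$ (µg m$^{-3}$),
the per-step fraction of particulate sodium contributed by spores is

$$ f = \frac{p\,w_s\,C_s}{p\,w_s\,C_s + w_m\,C_m} $$

with $w_s = 0.13$ (Na dry-mass fraction of sodium-rich spores),
$w_m = 0.30$ (sea salt), and $p = 0.70$ the assumed sodium-rich spore
fraction (an upper-bound assumption; 0.30 and 0.50 are standard sensitivity
variants and the mean is strictly increasing in $p$). Bounds come from
perturbing concentrations by fixed factors — spores ÷/× 10, sea salt ×/÷ 2
— recomputing per-step fractions, and averaging; because the perturbation
moves every step the same way, `bound_low ≤ mean ≤ bound_high` is an exact
per-series identity, not a statistical one. A factor-of-2 spore
perturbation (appropriate where spore emissions are well constrained) is
available by setting `spore_factor = 2`.

**Averaging order.** The reported quantity is the *mean of per-step
fractions*, consistent with a distribution of daily mean sodium fractions;
the fraction of mean masses is a different number on heterogeneous series
(Jensen's inequality) and is computed as a labelled diagnostic, never
silently substituted. Whether the original bounds were averaged per-day or
computed on seasonal means is not stated; both are available, with
per-day-then-average the default.

**Conventions.** The night window is half-open [18:00, 06:00): the 18:00
step is night, the 06:00 step is day (the stated endpoints do not fix the
boundary assignment, so it is fixed here by convention and asserted by
construction). Wet season is January–June, dry season July–December,
configurable. `pct_days_above` aggregates sub-daily fractions to daily
means of fractions before thresholding. Steps where both concentrations
are zero have no defined fraction and propagate as flagged `NA`s.

## What the generator emulates — and what it does not

The synthetic module exists so that every operator has an input whose
ground truth is known:

* **Particle tables.** Classes are drawn from a configured mixture; each
  class has mean elemental weight fractions with Gaussian spreads
  (truncated at zero, renormalized), a morphology distribution, and a
  lognormal size distribution. Compositions are converted to atomic
  fractions on output — the exact inverse of the classifier's conversion.
  The shipped profiles are **calibration choices, not measured data**: means
  sit far from the rule thresholds so that the default coarse mixture
  (48% Na-rich, 25% dust, 19% spores, 5% sulfate, 3% carbonaceous) and the
  below-canopy mixture (60% spores) are recovered by the classifier within
  binomial error. The default spore profile carries 2 wt% Na (below
  detection) so the generator's `fungal_spore` and `na_rich` classes are
  disjoint populations; sodium-rich spores live inside the `na_rich` class.
* **Images** are filled disks, ellipses (1.4:1 aspect) and capsules on a
  uniform background with optional Gaussian noise — sufficient to exercise
  threshold-and-measure operators, with the wet shape's area exactly
  $\mathrm{GF}^2$ times the dry area on the continuous shape (rasterization
  adds the pixel-quantization error the tolerances budget for). STXM pairs
  set the wet per-pixel OD so the wet/dry integrated-OD ratio equals the
  configured mass ratio *exactly* on the rasterized masks.
* **Concentration series** are lognormal daily draws; sea salt suffers
  Bernoulli scavenging days (probability 0.35 wet / 0.08 dry, depletion
  factor 0.2 — wet removal is stated qualitatively, so these are
  calibration values), and hourly spore series apply a two-level night/day
  cycle with amplitude 2 (nighttime enhancement is reported, its model
  amplitude is not), normalized to preserve the daily mean. Wet-season
  sea-salt medians (0.15 µg m$^{-3}$) sit below dry-season ones
  (0.60 µg m$^{-3}$). Grid series multiply the sea-salt median by a
  per-cell gradient with per-cell seeds.

What passing tests therefore show: the operators recover known ground truth
under the stated noise, and the pipeline's statistics behave as their
definitions require. What they do not show: performance on real SEM images
(real spores are textured, clustered, unevenly illuminated), real EDX noise
structure (which is spectral, not Gaussian in weight space), or real
atmospheric covariance between spore and sea-salt concentrations (generated
independently here). In particular, the headline 69% (31–95%) wet-season
sodium contribution depends on chemistry-transport model output that is not
reproducible at a desk; this package verifies the budget's formulas,
bounds logic and statistics on synthetic series instead, and its seasonal
means on the default series (~73% wet, ~37% dry in the shipped drivers) are
properties of the generator calibration, not reproductions of the reported
values.

## Numerical choices and degenerate inputs

* Problem sizes: recovery tests use 2000-particle tables (binomial SE
  ~1.1% on a 48% fraction, tested at 3 SE), 256-px ESEM frames (dry
  particle 60 px across), 128-px STXM maps, and series of 90–400 days —
  large enough that sampling error is well below the tested tolerances,
  small enough that the full suite runs in seconds.
* Seeds are explicit in every generator config; a fixed seed gives
  byte-identical output (asserted), and RNG state is restored afterwards.
* Otsu thresholding errors out on zero-contrast frames ("no foreground")
  rather than returning an arbitrary mask; ties between equal-sized blobs
  resolve to the first label, and the largest blob always wins otherwise.
* Nonpositive intensities have no defined OD and become `NA`, excluded
  from masked integrals.
* Composition draws that truncate to all-zero fall back to the profile
  mean (vanishingly rare at the shipped spreads).
* Empty groups are dropped from fraction tables with a warning; an empty
  class yields a zero histogram; a single-occupied-bin size trend is an
  error, as no trend is identifiable.

## Known limitations

* Morphology must be supplied; no shape recognition from images.
* No EDX spectrum deconvolution or ZAF correction — inputs are already
  quantified atomic fractions.
* No chemical speciation of sodium (NaCl vs organic salts), no κ-Köhler
  activation, no deliquescence kinetics: growth factors are endpoint
  ratios.
* The budget is a two-source apportionment; any third sodium source would
  bias the fraction upward.
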