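---
title: "From 15N tracer recoveries to the N-deposition-induced forest carbon sink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From 15N tracer recoveries to the N-deposition-induced forest carbon sink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndepsink)
```

## The scientific chain

Atmospheric nitrogen reaches forests in reduced (NH~x~, mostly ammonium) and
oxidized (NO~y~, mostly nitrate) form. What that nitrogen does to the carbon
balance depends on where it ends up: N built into woody tissue or immobilized
in soil organic matter stores carbon at the carbon-to-nitrogen ratio of that
compartment, while N that leaches or denitrifies stores none. `ndepsink`
implements the full chain from ecosystem-scale ^15^N-labelling experiments to
a global-scale, per-form estimate of that carbon sink, in five stages:

1. **Isotopic mass balance.** An experiment adds a known mass of ^15^N
   (as ^15^NH~4~^+^ or ^15^NO~3~^-^) to a plot. A compartment's percent
   recovery follows from the rise of its ^15^N abundance:
   \[
   rec = 100 \times
   \frac{N_{pool} \times (A_{after} - A_{before})/100}{{}^{15}N_{added}},
   \]
   with \(N_{pool}\) the pre-labelling pool (kg N ha^-1^) and \(A\) the atom
   \% ^15^N (`recovery_percent()`). The two-inventory variant
   (`full_balance_recovery()`) uses both pool inventories; it reduces to the
   constant-pool form when the pool is unchanged, but apparent pool growth at
   background abundance inflates it (a 10 kg inventory artifact at natural
   abundance already masquerades as ~37 % recovery of a 0.1 kg addition),
   which is why the constant-pool estimator is the default for one-year
   experiments. Whatever the plant, organic-layer and mineral-soil pools do
   not recover is the loss fraction: `ecosystem_recovery()` enforces
   \(eco + loss = 100\) exactly and flags (never clips) over-recovery.

2. **Cross-site regression.** Site-mean retention and loss fractions are
   regressed on nine candidate predictors — MAT, MAP, mineral-soil C/N, clay,
   leaf C/N, N deposition, organic-layer mass, wood biomass, NPP — by
   exhaustive enumeration of all \(2^9 - 1 = 511\) subsets
   (`select_best()`). Models are ranked by the small-sample corrected AIC,
   \[
   AICc = n\ln(RSS/n) + 2k' + \frac{2k'(k'+1)}{n-k'-1},
   \qquad k' = p + 2,
   \]
   and any subset whose maximum variance inflation factor exceeds 3 is
   excluded before ranking. The full ranked ledger is retained rather than
   hard-coding any particular winner.

3. **Upscaling.** The selected relations are evaluated on co-registered
   predictor rasters (`grid_stack`). Two wirings are offered
   (`upscale_retention()`):
   * **chained** (default): predict the loss fraction and the organic-layer
     retention, then split the remainder between plant and mineral soil by
     the predicted plant:(plant+mineral) ratio, and take the woody share
     within plant. The published relationship chain is presented exactly in
     this cascade form, which is why it is the default; it also sums to 100
     by construction.
   * **regression**: predict each pool directly and rescale the four
     fractions proportionally to 100. The two modes coincide exactly when
     the per-pool models are the linearization of the chain (a property the
     test suite checks).

4. **Stoichiometric conversion.** Per cell and per form,
   \[
   C_{sink} = N_{dep}\left(
     N^R_{org}\tfrac{C}{N}_{org}\,s +
     N^R_{min}\tfrac{C}{N}_{min}\,s +
     N^R_{wood}\tfrac{C}{N}_{wood}\,f(N_{dep})\right),
   \]
   where \(s = 0.8\) is the fraction of soil-retained N immobilized in
   persistent soil organic matter and \(f\) is a flexible-stoichiometry
   factor that damps the wood term as deposition saturates growth
   (`csink_cell()`, `f_wood()`). Non-woody plant retention (foliage, fine
   roots, understory) turns over quickly and contributes zero. Setting
   \(s = 1, f \equiv 1\) recovers the classical rigid-stoichiometry product
   form as a limit.

5. **Monte Carlo uncertainty.** `run_ensemble()` resamples 10 of the 13
   sites without replacement, refits and re-upscales per draw, and crosses
   every retention draw with every deposition map and wood C/N set; the
   member ensemble is summarized by mean and percentile 95 % intervals.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| VIF cutoff | 3 | – | collinearity screen on each candidate subset |
| forest threshold | 0.2 | cover fraction | cells above it count as forest; 0.1 variant available |
| `f` breakpoints | (15, 1), (30, 0.5), (100, 0) | kg N ha^-1^ yr^-1^ | growth response flattens near 15–30 and vanishes near 100 |
| soil immobilization `s` | 0.8 | fraction | share of soil-retained N entering persistent SOM; applied to both soil terms |
| wood C/N sets | 150–400 (6 values) | ratio | spans typical stemwood stoichiometry |
| retention draws | 50 (desk) / 1000 (full) | – | crossed with 4 deposition maps × 6 wood C/N sets |
| sites per draw | 10 of 13 | – | without-replacement subsampling |
| CI level | 0.95 | – | empirical percentile bounds |

Open choices resolved here, as this package's own conventions:

* **AICc ties** (ΔAICc < 10^-9^) break toward fewer predictors, then the
  alphabetically first predictor set — parsimony first, and selection becomes
  invariant to candidate order.
* **VIF is evaluated per candidate subset**, not on the full nine-predictor
  pool: the cutoff constrains the models actually considered. Inside the
  enumeration it is computed from the inverse correlation matrix, which is
  algebraically identical to the defining one-on-rest regressions; perfect
  collinearity yields an `Inf` sentinel and exclusion, not an error.
* **Loss is predicted by its own regression**, not as the residual of the
  three pools; in regression mode all four fractions are then rescaled
  proportionally to 100. In chained mode the identity holds by construction.
* **`f` is evaluated from total (NH~x~ + NO~y~) deposition** even when a
  single form's sink is computed: growth saturation responds to the whole N
  load. Per-form evaluation is available (`f_from_total = FALSE`).
* **The 0.8 immobilization factor multiplies both soil terms** (organic
  layer and mineral soil), the reading under which the headline estimate is
  defined.
* **Multi-year tracer additions** enter the recovery denominator as the
  cumulative added ^15^N mass.
* **Forest cover is contradictorily cut at "> 20 %" and "> 10 %" in the
  source material**; the default is 0.2 with 0.1 one argument away.
* **Biome bands** are |lat| < 23.5° tropical, 23.5–50° temperate, > 50°
  boreal — the source aggregates by biome without defining boundaries, so a
  transparent latitude rule is used.

## What the synthetic generators emulate — and what they do not

`make_site_table()` draws 13 sites with predictors uniform over the observed
study ranges (MAP 700–2500 mm, MAT 3–22 °C, N deposition 6–54 kg N ha^-1^
yr^-1^) and generates the four responses from linear relations plus Gaussian
noise: loss declining with mineral-soil C/N, organic-layer retention rising
with organic-layer mass, the plant:(plant+mineral) ratio declining with NPP,
and the woody share rising with wood biomass. Nitrate rows receive additive
offsets (more loss and plant share, less organic-layer retention) so plants
take up more nitrate than ammonium while soils retain more ammonium. Noise
standard deviations (7 % loss, 5 % organic, 0.08 ratio, 0.05 woody share)
were set so the single-predictor \(R^2\) of the four relations match the
reported cross-site values (≈ 0.43, 0.73, 0.64, 0.86); at n = 13 this is a
genuinely weak-signal regime, and exhaustive selection over nine candidates
recovers the weakest (loss) relation's predictor in only ~85 % of
replicates — a property of the study design, not of the selector, which the
tests verify against an independent brute-force oracle. Pool recoveries are
back-computed so plant + organic + mineral + loss = 100 per site before
clipping; sites where loss + organic reach 100 carry no information about
the plant:mineral split and are dropped from that one fit.
`make_plot_measurements()` inverts the mass balance to produce plot-level
enrichment data consistent with the table, so the mass-balance stage is
exercised end to end.

`make_world()` produces smoothly varying (3×3-kernel-smoothed noise)
predictor fields within the site ranges on a coarse lat/lon grid (default
72 × 36, i.e. 5°; the real products are 1-km), four deposition maps sharing
a common pattern plus model spread and split into NH~x~/NO~y~ by a smooth
reduced fraction (0.35–0.75), a forest-cover field in [0, 1], and soil C/N
layers. Cell areas are exact spherical-zone areas, so area sums match the
analytic band area to rounding.

The generators deliberately do **not** emulate: real spatial covariance
between predictors (e.g. NPP–MAT coupling beyond a shared latitudinal
trend), land-cover classes, the internal structure of any deposition model,
observation error in the predictors, or between-plot variance structure
beyond i.i.d. noise. Passing tests therefore demonstrate the correctness and
statistical calibration of the machinery under the stated generative
assumptions — not that real-world retention maps would be accurate. Global
totals computed on synthetic worlds (deposition everywhere between 6 and 54
kg N ha^-1^ yr^-1^ over ~50 % forest cover) are intentionally not comparable
to real-world totals; the reported-number identities are checked separately
by `consistency_report()` from the published totals themselves.

## Numerical choices

* Negative single-pool recoveries (enrichment noise below background) are
  floored at zero with a warning and a count — negative mass recovery is
  unphysical; the whole-ecosystem balance flags but does not clip
  over-recovery so data problems stay visible.
* Predictions are clipped to [0, 100] (ratios to [0, 1]) before the
  sum-to-100 normalization; cells whose pools all predict zero are assigned
  full loss.
* `AICc = Inf` when \(n - k' - 1 \le 0\), so oversized models are never
  selected; `fit_subset()` refuses \(n \le k + 2\) outright.
* Per-cell ensemble SDs accumulate moments relative to the first completed
  draw, avoiding catastrophic cancellation when draws are near-identical.
* Ensemble substreams: one master seed draws per-draw seeds once, so any
  single draw can be reproduced in isolation and results are bit-identical
  across runs of the same seed.
* Draws whose selection fails (every subset VIF-excluded) are skipped and
  logged in the member ledger, never imputed.

## Problem sizes

The shipped analysis scripts and tests run at desk scale: 13 sites × 2
forms, a 72 × 36 world, 50 retention draws × 4 deposition maps × 6 wood C/N
sets = 1200 ensemble members (the full-scale design is 1000 draws for
24,000 members, reachable by setting `n_retention_draws = 1000`). A complete
end-to-end run takes a few minutes on one core.

## Worked micro-example

```{r example}
tr <- tracer_application("ammonium", n15_added = 0.1)
p <- pool_measurement("mineral", n_pool_before = 1000,
                      atom_pct_before = 0.3663, atom_pct_after = 0.3763)
recovery_percent(p, tr)

ecosystem_recovery(c(plant = 12, organic = 33, mineral = 24))

s <- stoichiometry_set(cn_wood = 300, cn_org = 30, cn_min = 15)
csink_cell(10, frac_wood = 10, frac_org = 30, frac_min = 20, stoich = s)
```

## Known limitations

* Reflects the first-year fate of deposited N; no multi-decadal C–N
  turnover, so estimates built on it are short-term and best read as upper
  bounds.
* No gaseous-vs-leaching partition of the loss term, and no δ^15^N-to-atom-%
  conversion chain for raw spectrometry output.
* No reprojection or resampling: grid layers must arrive co-registered.
* Extrapolation beyond the 13-site predictor hull is allowed but only
  flagged (per-cell mask), not constrained.
* The ensemble varies sites × deposition maps × wood C/N only; predictor-map
  and soil-C/N uncertainty are not propagated.
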