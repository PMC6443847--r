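---
title: "Whole-plant 15N mass balance: model, assumptions, and validation by simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-plant 15N mass balance: model, assumptions, and validation by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(n15budget)
```

## The question the mass balance answers

Maize grain nitrogen has two sources: N taken up before silking and later
remobilized out of vegetative organs, and N newly acquired by the roots
during grain fill. Dual-phase 15N labelling separates the two. Plants are
labelled in exactly one phase: a plant fed 15N-enriched KNO3 during
vegetative growth carries the label only in its pre-silking N pool, so any
excess 15N found in the grain at maturity must have been remobilized there;
a plant labelled after silking carries the label only in its post-silking
uptake, so the distribution of excess 15N across organs at maturity reveals
where post-silking N ended up.

## Isotope arithmetic

Enrichment is expressed in atom% 15N. Two reference constants are kept
strictly separate in `iso_config()`:

* the **international standard** (atmospheric N2, 0.3663 atom% 15N), which
  anchors delta notation: a sample's δ15N (‰) is the per-mil deviation of
  its 15N/14N ratio from the standard's ratio;
* the **empirical natural-abundance baseline** A0 of unlabelled plant
  tissue (default 0.3733 atom%), which is what gets subtracted when
  computing tracer-derived N.

Unlabelled tissue routinely sits a few per-mil away from the atmospheric
standard, so conflating the two constants biases every excess-15N number.
All δ ↔ atom% conversions use exact ratio algebra
(`R = ap / (100 − ap)`, `R_sample = R_std (1 + δ/1000)`), never the linear
small-δ approximation; the round trip is exact to below 1e-10 ‰ across the
full range relevant to tracer work (δ from near −1000 to +10000 ‰).

The tracer-derived 15N in organ *x* is

    q(x) = (A(x) − A0) / 100 × Q(x)

with A(x) the organ's measured atom% and Q(x) its N content in grams.
Tracer doses can be entered either as the salt mass dissolved — the 15N
mass then follows from K15NO3 stoichiometry, with the salt's N molar mass
taken as the label-weighted mean of 14N and 15N — or as a stated 15N mass
taken at face value (`tracer_dose()`). Both modes exist because published
nominal doses do not always match the salt stoichiometry; the package does
not attempt to reconcile such discrepancies, it records which entry mode
was used.

## The mass-balance equations

For a **vegetative-labelled** plant at maturity:

* remobilized fraction of pre-silking N:
  `rem% = 100 × q(grain) / q(wpm)`, where q(wpm) sums q over all organs;
* grams remobilized to the grain: `Q_rem(grain) = Q(wps) × rem% / 100`;
* remobilized share of grain N: `Grain_rem = 100 × Q_rem(grain) / Q(grain)`.

For a **reproductive-labelled** plant:

* per-organ partition of post-silking uptake:
  `Post%(x) = 100 × q(x) / q(wpm)`, which closes to 100 by construction;
* grams to organ *x*: `Q_post(x) = (Q(wpm) − Q(wps)) × Post%(x) / 100`;
* remobilized share of grain N by difference:
  `Grain_rem = 100 × (1 − Q_post(grain) / Q(grain))`.

`Q(wps)`, whole-plant N at silking, is not observable on a maturity plant;
the reference is the **treatment mean** over silking-harvested plants of
the same vegetative treatment (`q_wps_reference()`), which is how the
underlying experimental design defines it. A per-plant override column is
supported for sensitivity analysis.

The calculus assumes: no isotopic discrimination within the plant or in N
metabolism; no N loss from the plant between silking and maturity; uniform
distribution of the label in the root medium; and no uptake of residual
vegetative-phase label after silking (the silking leach-out; see below).
No residual-uptake correction factor is applied — `leach_event()` and the
simulator exist partly to show what the estimates do when that assumption
fails.

## Numerical and reporting policies

* **Negative excess.** Unlabelled or barely labelled tissue measured
  slightly below A0 gives a small negative q(x). The budget layer clamps
  |q| ≤ `clamp_tol` (default 1e-3 g 15N) to zero with a warning; a more
  negative value is an error, because it indicates a baseline or data
  problem rather than measurement noise.
* **Out-of-range ratios.** With noisy data `Grain_rem` can leave [0, 100]
  — in particular because the grain N in the denominator belongs to the
  individual plant while `Q(wps)` in the numerator is a treatment mean.
  Values are reported raw with a quality flag (`grain_rem_pct_outside_0_100`),
  never clipped; clipping would hide exactly the plants one should inspect.
* **Negative post-silking uptake** (Q(wpm) < Q(wps)) is flagged and kept,
  as it is the visible symptom of the no-loss assumption failing.
* **Rounding** happens only in rendered report tables (1 d.p. for
  percentages, 2 d.p. for gram quantities, counts to integers, half away
  from zero); machine-readable outputs keep full precision.
* **Organ taxonomy** is fixed: four organ groups at silking, six at
  maturity, related by `organ_taxonomy()`. Unknown labels are errors, not
  skips — silent organ dropping would corrupt q(wpm).

## What the simulator emulates

`generate_experiment()` reproduces the statistical and isotopic structure
of the dual-phase design: 2 vegetative N levels × 4 post-silking N × water
treatments; per cell, vegetative-labelled, reproductive-labelled and
unlabelled maturity plants (default 4 + 4 + 2, assigned to six blocks in
two greenhouses) plus 12 silking-harvest plants per vegetative treatment
for the Q_wps reference.

Per plant, the generator draws pre-silking uptake and post-silking uptake
from treatment-cell distributions, allocates pre-silking N to silking
organs, moves the cell's true remobilized fraction to the grain (withdrawn
from organs in proportion to pool size times a mobilization weight — stalk
most mobilizable, reproductive structures least), splits the remaining
leaf pool into green and senesced leaves, and allocates post-silking
uptake by the cell's partition vector. Labelled-phase pools are enriched
as `A0 + φ (label − A0)`, with φ the fertilizer-derived fraction of that
phase's uptake; final organ enrichment is the mass-weighted mixture of its
pre- and post-silking-derived N. Whole-plant N at maturity equals
pre-silking uptake plus post-silking uptake minus any configured loss,
exactly, in every plant; measurement noise perturbs only recorded values.

Default parameter choices, made once as study conditions:

* **Cell means** for pre-silking uptake (2.76 / 1.61 g N), post-silking
  uptake, partition vectors, grain yield, kernel number, spikelet count
  and biomass are the published treatment-cell means of the emulated
  experiment; per-cell true remobilized fractions are back-solved as
  remobilized grams divided by mean pre-silking uptake (0.37–0.61).
* **Between-plant SDs** are reconstructed from published standard errors
  as SE × √n (n = 12 for silking quantities, 4 for labelled maturity
  plants per cell, 10 for yield components). These SEs fold in block and
  greenhouse variance, so the simulated between-plant spread is, if
  anything, generous.
* **Label doses** are 40 mg 15N (vegetative, over four applications) and
  90 mg 15N (reproductive, over nine) at 10 atom%; φ follows from a
  fertilizer-N uptake efficiency of 0.7, a convention chosen as realistic
  for daily-irrigated inert medium — the emulated experiment reports no
  per-plant enrichment variance, so φ and the noise SDs (0.002 atom-points
  on enrichment, 5% CV on N content, 8% CV on dry mass) are stated
  conventions, not published values.
* **Dry masses** are anchored to the plant's own N pools through per-cell
  reference concentrations derived from the configured mean N and biomass:
  organ mass = organ N / reference concentration × noise. This makes
  biomass and N covary within a cell as in real plants (and keeps N
  concentrations physically plausible in the tails) while cell-mean
  biomass and grain yield match the configured statistics.
* **Leach-out** default is full efficiency: the design assumption is that
  no vegetative label survives to be taken up after silking, and the
  emulated experiment's own bioassay (tissue at or below natural
  abundance) supports carryover ≈ 0. `leach_event()` defaults to the
  measured 99% removal when used as a standalone operation, and
  `sim_config(leach_efficiency = ...)` exposes partial or absent leaching
  for sensitivity runs, where remobilization estimates become biased
  (upward wherever the grain's post-silking share exceeds the remobilized
  fraction).

`perturb_assumptions()` deliberately violates one assumption at a time:
fractional N loss during grain fill (post-silking uptake then estimated
low by the lost mass), or organ-specific label mixing (over-enriched
leaves and stalk inflate rem%).

**What the simulator does not emulate:** multi-timepoint N cycling and
protein turnover (organs are sampled once, at maturity), soil/medium N
transport, transpiration-driven N accessibility, mechanistic links from N
supply to kernel set (phenotypes are drawn from treatment-level
statistics), and isotopic discrimination. Passing recovery tests therefore
shows the estimator is correct *under the stated assumptions and noise
model*, not that those assumptions hold in any particular glasshouse.

## Validation strategy and problem sizes

The test suite validates the pipeline three ways:

1. **Worked examples** that are pure functions of published numbers
   (δ-conversion of the leach-validation range, dose stoichiometry,
   cross-treatment averages, abortion percentages) reproduce exactly.
2. **Parameter recovery**: with all noise zeroed, budgets equal the
   generator's truth to 1e-6 (the treatment-mean Q_wps then coincides with
   every plant's own, which is also what makes the vegetative-label and
   reproductive-label routes to `Grain_rem` agree to 1e-6); with default
   noise, mean rem% bias over a 1000-plant vegetative-labelled cohort
   stays under half a point.
3. **An independent oracle**: budgets on simulated cohorts are recomputed
   by a deliberately plain brute-force routine and must agree to 1e-12.

Default validation runs use the experiment-sized cohort (80 maturity + 24
silking plants) and a 1000-plant cohort for the bias check; both sizes
were chosen as the smallest that make the Monte-Carlo checks sharp.

## Known limitations

* The treatment-mean Q_wps reference makes per-plant `Grain_rem` a ratio
  of a cell-level numerator to a plant-level denominator; its SE within a
  cell is accordingly wide, and individual plants can exceed 100% (they
  are flagged). Cell means remain well behaved.
* Cross-treatment narrative averages (`stress_average()`) are unweighted
  means of cell means; pooled per-plant averages will differ when cell
  sizes differ.
* The leaf-dimension calibration defaults to the Montgomery form
  `area = k × length × width` with k fitted (shape factor ≈ 0.75 in
  maize); an affine alternative is available since the original
  calibration's functional form is not fixed by the design. Neither is
  asserted against published coefficients.
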