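---
title: "TR-FRET screening triage and binding analysis: methods"
author: "fretscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TR-FRET screening triage and binding analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretscreen)
```

## The assay and its readout

TR-FRET (time-resolved FRET, commercialized as HTRF) is a proximity assay:
a europium-cryptate donor on one antibody and a d2 acceptor on another
produce energy transfer only when the two tagged proteins they recognize
interact. The plate reader records two channels per well — acceptor
emission at 665 nm and donor emission at 620 nm — and the per-well readout
is their quotient, the **FRET ratio**. Ratioing out the donor channel
removes most well-to-well pipetting and lamp variation, which is why the
noise that remains is well described as multiplicative.

Each 384-well plate carries its own controls: **max controls** (vehicle-
treated lysate with the interacting pair, full signal) and **min controls**
(non-transfected lysate, background). All normalization is per plate, from
on-plate controls; plate-to-plate drift dominates campaign-wide effects in
practice, so a campaign-wide window is deliberately not used.

Three derived statistics drive everything downstream:

* **fold signal** = mean max-control ratio / mean min-control ratio, the
  assay window in fold units (1 = no signal);
* **percent inhibition** of a compound well,
  $100 - 100\,(R_{c} - \bar R_{min})/(\bar R_{max} - \bar R_{min})$, anchored
  so the min control is 100% and the max control 0%. Values outside
  [0, 100] (signal enhancers, over-quenchers) are *not* clamped — they are
  returned as-is and flagged, because clamping hides exactly the compounds
  one should inspect;
* the **Z'-factor**,
  $1 - 3(\sigma_{max}+\sigma_{min})/|\mu_{max}-\mu_{min}|$, the standard
  screening-window statistic. Z' is at most 1; above 0.5 is conventionally
  screenable. A plate passes QC when its Z' reaches the configured
  threshold (default 0.75, the first-screen gate) and at most 10% of its
  control wells were excluded for missing or degenerate readings. Control
  statistics are plain mean/SD by default; a robust mode
  (median, MAD × 1.4826) is available for outlier-prone data.

## The three-stage triage

The cascade mirrors how PPI-inhibitor screens are actually triaged:

1. **Primary screen.** Compounds are screened at a single concentration
   (50 µM by default); replicate wells on QC-passing plates are averaged,
   and compounds *strictly* above the inhibition threshold (default 15%; a
   threshold phrased "over 15%" is read as >, not ≥) advance, ranked by
   inhibition with ties broken by compound id so output is deterministic.
2. **Counter screen.** A FRET signal can fall for reasons that have nothing
   to do with the targeted interaction: the compound may block a tag-
   antibody interaction or interfere with the energy transfer itself. A
   monomolecular counter assay — one protein carrying both tags, generating
   FRET with no PPI — exposes these. Plotting primary vs counter inhibition
   splits compounds into **region A** (both above threshold: interferer,
   rejected), **region B** (primary only: genuine candidate, advances) and
   inactive. Compounds missing a counter measurement are reported as
   unclassified and excluded rather than silently dropped or passed.
3. **Dose-dependence triage.** Stage-2 survivors are re-tested over a
   5-point titration (150, 75, 37.5, 19, 9.5 µM by default). "Concentration-
   dependent" is a judgement call in practice; here it is made reproducible
   as a composite rule: the log-logistic fit converges with positive slope,
   the Spearman rank correlation between concentration and inhibition is at
   least 0.8, and the fitted span (top − bottom) exceeds the primary
   threshold. Each sub-criterion is a configuration knob
   (`cascadeConfig()`), because the right stringency depends on the
   campaign.

Stage lists are nested by construction (stage 3 ⊆ stage 2 ⊆ stage 1), and
raising any threshold can only shrink downstream lists — both properties
are tested. The report (`CascadeReport`) records every exclusion with its
reason and echoes the configuration, so a run can be reconstructed from the
report alone; serialization to JSON is deterministic (no timestamps), so
identical runs produce byte-identical reports. The wet-lab confirmation
step that follows a screen (e.g. co-immunoprecipitation) is outside the
package; the report carries an `external_annotation` field for its results.

## Dose-response model

The dose-response curve is the field-standard four-parameter log-logistic,
$f(d) = bottom + (top-bottom)/(1+(IC_{50}/d)^{slope})$. Fitting is ordinary
least squares (no weighting: a replicate-variance model would be
unidentifiable from 5-point series) via Levenberg–Marquardt, with
multi-start initialization — IC50 on a 5-point log grid spanning the dose
range, crossed with slope starts {0.5, 1, 2} — keeping the best-RSS start.
IC50 is optimized on the log scale, which enforces positivity and makes the
step sizes scale-free. `top`/`bottom` can be fixed for 2–3-parameter
variants. The reported IC50 is the inflection dose (relative IC50); the
absolute 50%-crossing dose is also emitted since the two differ whenever
the plateaus are not 0 and 100. Optimizer failure and flat series return
`converged = FALSE` with a diagnostic rather than throwing, so a campaign's
worth of fits can run unattended.

## Fluorescence-polarization binding model

FP titrations of a fluorescent probe against a receptor use the **exact
(ligand-depletion) quadratic isotherm**: with total probe $L_T$, total
receptor $R_T$ and dissociation constant $K_d$, the complex concentration
is the smaller root of the mass-action quadratic, and

$$P = P_L + \frac{P_{RL}-P_L}{L_T}\cdot\tfrac12\Big[(L_T+R_T+K_d) -
\sqrt{(L_T+R_T+K_d)^2 - 4R_TL_T}\Big].$$

The simple hyperbola $P_L + (P_{RL}-P_L)R_T/(R_T+K_d)$ assumes free ≈ total
probe; the quadratic form is exact and reduces to the hyperbola when
$L_T \ll \min(K_d, R_T)$ (verified to 0.1% of dynamic range in the tests).
The discriminant is analytically non-negative; floating-point excursions
within $10^{-9}$ of zero (relative) are clamped to zero.

`fitFP` estimates $(P_L, P_{RL}, K_d)$ by least squares, optimizing
$\log K_d$ (non-negativity by construction) with a 7-point log-grid
initialization spanning the titration range in both orientations
(polarization rising or falling with binding). Two honesty guards return
`converged = FALSE` instead of a number: a flat titration, and a titration
whose fitted bound fraction changes by less than 0.2 across the measured
range — a curve that never leaves one plateau cannot constrain $K_d$, and
the 0.2 cut is deliberately permissive so genuinely informative titrations
are never rejected. Confidence intervals come from residual-bootstrap
resampling (percentile, 95%, seeded); with few replicates a percentile
interval can exclude the point estimate, so intervals are widened to
contain it. The polarization readings are treated as polarization (mP)
throughout; no anisotropy conversion or G-factor correction is applied.

Peptide-competition curves (FRET signal vs competitor concentration) are
fitted with the same log-logistic machinery; no mechanistic three-species
competition model is implemented.

## What the simulator emulates — and what it does not

`simulateCampaign()` generates a desk-scale campaign with known truth. Its
defaults are the study conditions the analyses assume:

| parameter | default | rationale |
|---|---|---|
| compounds / plates | 5,000 / 16 | desk-scale stand-in for a ~160k-compound campaign; large enough for stable hit statistics, small enough to simulate in seconds |
| controls per plate | 16 max + 16 min | layout is not dictated by the assay; two dedicated control columns is a common 384-well convention and is configurable |
| fold signal | 10 | a robust TR-FRET window of the order seen in well-optimized PPI assays |
| per-well noise CV | 3% (2% for assay characterization) | ratio readouts of strong TR-FRET signals typically show few-percent CVs; 3% places plate Z' around 0.85–0.9, a realistic good screen |
| hit rate / interferer rate | 1% / 0.5% | primary hit rates of order 1% are typical of PPI screens at 50 µM; interferers are rarer but non-negligible |
| effect sizes | uniform(0.2, 0.95) | declared, not inferred — the true effect distribution of a physical library is unknowable |

Signal model: a compound with inhibition effect $e$ has expected FRET ratio
$R_{min}(fold - (fold-1)e)$, so $e=0$ sits at the max-control level and
$e=1$ at background. True inhibitors act only in the PPI assay
(counter effect 0); interferers suppress both assays equally — the
region-A phenotype of compounds hitting the tags or the energy transfer;
inactives act in neither. Noise is multiplicative log-normal with unit mean
and configured CV, applied to the acceptor channel with the donor held
fixed, so the ratio inherits exactly the configured CV and `noise_cv = 0`
yields *exact* signals — the zero-noise identities (pipeline inhibition
= 100·effect, region-B = true-inhibitor set) are tested as equalities, not
approximations.

A compound's true IC50 is derived from its effect at the screening dose
under a unit-slope full-span curve ($IC_{50} = 50\,(1-e)/e$ µM), so the
single-dose campaign and the titration generator describe the same
underlying compound. Dose-series noise is additive Gaussian with SD =
`noise_cv` × 100 percent points (multiplicative noise is meaningless at 0%
inhibition). FP titrations add Gaussian noise in mP to the quadratic
isotherm at log-spaced receptor concentrations.

Not modelled (and therefore not demonstrated by passing tests):
compound autofluorescence spectra, plate-edge and gradient effects,
dispense carryover, donor-channel noise, correlated plate-level drift, and
any chemistry (structures are passed through untouched). Success on this
generator shows the *analysis* is correct and calibrated, not that any
particular physical library behaves this way.

## Numerical and design choices

* Well addresses accept padded ("A01") and unpadded ("A1") forms; the
  canonical emitted form is unpadded. Geometry is fixed at 384 wells
  (A–P × 1–24).
* Wells with missing or degenerate readings (donor ≤ 0) are excluded from
  statistics and counted; a plate fails QC when more than 10% of its
  controls are excluded.
* Import is forgiving at the row level (each malformed row is rejected and
  reported with its file line number; accepted + rejected = input) but
  strict structurally (missing mandatory columns and duplicate plate/well
  addresses abort).
* All ranked outputs use stable sorts with compound-id tie-breaks; reports
  serialize deterministically.
* Generators save and restore the global RNG state, so simulation calls do
  not perturb a user's session randomness.
* Problem sizes in the shipped tests: campaigns of 100–5,000 compounds,
  oracle cross-checks on 100 random instances per metric and 50 per fitted
  model against coarse-grid brute-force minimizers, a 1,000-point
  depletion-limit sweep, and 20-replicate $K_d$ recovery — sizes chosen as
  the smallest that exercise every code path with stable statistics.

## Known limitations

* The dose-dependence call is a surrogate for expert judgement; its
  defaults are sensible but not canonical, which is why every sub-criterion
  is configurable.
* Percent inhibition relies on the per-plate window being well estimated;
  with very few controls the Z' gate, not the inhibition estimate, is the
  effective guard.
* The FP fit assumes a single binding site and no probe aggregation;
  fluorescence-intensity changes upon binding are not corrected.
* Bootstrap intervals are percentile intervals; for very small titrations
  they are approximate.
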