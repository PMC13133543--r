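---
title: "MIA-QSAR modeling of a congeneric herbicide series: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MIA-QSAR methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miaqsar)
```

## The modeling problem

The package models the protoporphyrinogen oxidase (PPO) inhibitory potency
of a congeneric series of phenyltriazolinone herbicides. Every compound in
such a series shares one scaffold and differs only at defined substituent
slots — here the two heteroring atoms `X` and `Y`, the benzene para
position `R1`, and the heteroring 3/5 positions encoded by `R2`. Potency is
expressed as pIC50, the negative decadic logarithm of the half-maximal
inhibitory concentration in mol/L; mass concentrations (mg/L) are converted
with the molar mass of the assembled structure,

    pIC50 = -log10( IC50 / (1000 * MW) ).

Multivariate image analysis QSAR (MIA-QSAR) sidesteps descriptor selection
entirely: the descriptors are the pixels of aligned 2D ball-and-stick
depictions. Because all compounds are drawn on one canvas with the scaffold
at identical pixel positions, every pixel is comparable across compounds,
and pixels covered by varying substituents become the informative
variables. Plain RGB pixel values carry no chemistry beyond drawing
conventions, so each atom's disk is painted with a physical property of its
element instead — either the Pauling electronegativity (dimensionless) or
the Bondi van der Waals radius (Angstrom) — giving two parallel encodings
of the same series: one more electrostatic, one more steric.

## Image model and its parameters

A compound image is produced by `rasterize()` on an `mia_canvas`:

* **Canvas**: 300 x 348 px, fixed for the study; the unfolded descriptor
  vector therefore has length 104,400 and the 33-compound series yields a
  33 x 104,400 matrix.
* **Scale** (default 16 px/Angstrom) and **origin** (pixel (140, 200)):
  chosen once so the widest series member plus the proposed analogs span
  at most 90% of the canvas width. Atoms that would not fit raise an error
  naming the atom — never silent clipping.
* **Disk proportionality** `k = 0.25`: disks have radius
  `round(k * r_vdW * scale)` px, the usual ball-and-stick convention where
  balls are scaled to, but much smaller than, the full van der Waals
  sphere. Full-radius disks would make neighboring atoms swallow each
  other.
* **Draw order**: disks are painted in decreasing vdW radius, so smaller
  atoms (H, F) stay visible on top of larger neighbors, as in ball-and-
  stick artwork with explicit hydrogens; ties break by atom index, making
  the raster fully deterministic (integer pixel geometry only — images are
  byte-identical across runs and platforms).
* **Bonds**: not painted by default. Uniform 1-px sticks valued at
  carbon's property would contribute either constant columns (removed by
  the mask anyway) or weak carbon-valued signal; a `draw_bonds` flag
  exists for fidelity experiments.
* **Pixel mapping**: column = round-half-up of `origin_x + x * scale`,
  row = round-half-up of `origin_y - y * scale` (row 0 at the top). This
  convention is frozen; R's banker's rounding is deliberately not used.

Background pixels are exactly 0, which is unambiguous because every
painted property value is at least 0.7 (electronegativity of the least
electronegative supported element) or 1.1 (smallest vdW radius in
Angstrom).

`build_descriptor_matrix()` unfolds each image row-major and removes
columns that are constant across the series (background plus invariant
scaffold pixels) via `column_mask`; on the packaged dataset roughly 2,000
of the 104,400 columns vary and enter the model.

## Scaffold template

The series geometry lives in a template library (`default_template()`,
also shipped as `inst/extdata/phenyltriazolinone_template.json`): scaffold
atoms with fixed Angstrom coordinates, plus per-slot attachment points,
outward directions and admissible substituent codes. Substituent swaps
never move scaffold atoms, so the "perfect overlap at common points"
alignment holds by construction, to the bit.

No coordinate deposition exists for this series, so the template was
transcribed from the published 2D depiction and validated against the
activity table itself: the base scaffold mass is over-determined by the 33
(IC50, pIC50) pairs, whose printed precision confines it to a window of
about 0.4 g/mol. The chosen core — an N1-aryl 4-methyl-triazolin-5-one
with a methylene linker to the five-membered heteroring, base formula
C14H13N3OS, 271.34 g/mol — satisfies the +/-0.01 log-unit IC50/pIC50
round-trip for every row; this back-calculation is asserted in the test
suite. One table quirk is normalized during assembly: a 5-methyl in `R2`
always replaces the hydrogen of the position-5 ring atom (the `Y` slot),
whether the table prints `Y` as `CH` or as `C`; both spellings assemble
identical molecules.

Element constants are hard-coded (Pauling/Allred electronegativities,
Bondi 1964 radii, IUPAC standard atomic weights) for exactly the eight
elements occurring in the series.

## Regression model

`pls_fit()` implements single-response PLS1 by NIPALS on column-mean-
centered X and mean-centered y. For one response the stage weight vector
is `w_a = X_a' y / ||X_a' y||` in closed form, so there is no iteration
and no random initialization; fitting is deterministic. No autoscaling is
applied beyond centering — all pixel descriptors within a model share one
unit, and scaling would inflate near-constant columns.

Derived quantities follow the standard chemometric definitions:

* regression vector `b = W (P'W)^{-1} q`, used for prediction
  (`yhat = (x - x_mean) b + y_mean`) and for the coefficient map;
* VIP with `sum(VIP^2) = p`, used for the importance map;
* leverages `h = 1/n + t'(T'T)^{-1} t` with new-sample scores projected
  through the model weights.

The number of latent variables is chosen by `select_components()` as the
global minimizer of leave-one-out RMSECV, ties toward fewer components,
capped at `min(n_train - 2, 15)`. The selection criterion used in the
original Chemoface workflow is not documented; the LOO minimum is the
plainest defensible rule and is recorded in every report. Held-out
predictions for all truncations are obtained from a single `A_max` fit,
exploiting the nestedness of NIPALS score spaces (verified against
explicit refits in the tests). When a leave-one-out subset has deficient
rank the search range shrinks automatically.

## Validation protocol

`run_study()` reproduces the full validation battery per encoding:

1. **Applicability domain first**: a preliminary PLS model on all 33
   compounds yields a Williams plot — leverage against standardized
   residual with cutoffs `h* = 3(A+1)/n` and +/-3. Compounds are screened
   before splitting; the packaged series flags none. The standardized
   residual denominator is the RMSE of this assessment fit (a calibration
   residual, the simplest defensible choice; cross-validated residuals
   would be stricter and are noted as a variant). PLS partially
   accommodates response outliers because its weights depend on y, so
   Williams flags are a coarse screen, not a formal test.
2. **Kennard-Stone split** (75/25) on the masked descriptor matrix:
   maximin selection of the *training* set — the standard use, giving a
   representative calibration set — with the test size as round-half-up
   (33 rows give 25/8). The split is deterministic per descriptor matrix,
   which is why the two encodings legitimately hold out different
   compounds.
3. **Calibration and LOO cross-validation** on the training set (RMSEC,
   r2 as squared Pearson correlation, RMSECV, q2 = 1 - PRESS/SS).
4. **External validation** on the held-out set: RMSEP, MAE, squared
   Pearson r2_pred, Roy's modified r2m (forward/reverse pair with the
   absolute value inside the square root, through-origin slope
   `k = sum(obs * pred)/sum(pred^2)`), Lin's concordance correlation
   coefficient with 1/n variances, and Q2F1/Q2F2 referenced to the
   training and test response means respectively. r2 and r2_pred are
   squared correlations, distinct from the Q2 family — the source tables
   list them as separate rows with separate values, which rules out a
   shared definition.
5. **y-randomization** (default 10 cycles, seeded): the training response
   is permuted, the model refit at the selected A, and the corrected
   statistic `c_r2p = r * sqrt(r2 - mean(r2_yrand))` summarizes the gap to
   chance. The implementation reproduces both published worked cells of
   this statistic to four decimals, which pins down the formula. The
   reported randomized RMSE/r2 are means across cycles.
6. **Bootstrap stability** (default 10 cycles, seeded): test sets of the
   same size are redrawn uniformly *without replacement* — random test-set
   re-selection, not resampling rows with replacement — and the entire
   calibration/validation battery is rerun
   per cycle, reporting mean and standard deviation of every metric.
   Component selection is repeated inside each cycle, so its variability
   is included.

Acceptability bounds enforced in the acceptance tests are the published
ones: calibration r2 >= 0.6, LOO q2 >= 0.5, external CCC >= 0.85 and
c_r2p >= 0.5.

## Interpretation maps and proposal prediction

`fold_map()` writes VIP or `b` back to pixel space (masked columns render
as exact 0); `export_heatmap()` emits a PNG (sequential scale for VIP,
diverging blue-white-red for coefficients) with a raw-value CSV sidecar as
the artifact of record — the rendered colors are presentation only.

`predict_proposals()` encodes query compounds on the study canvas and
averages the per-encoding predictions arithmetically (no weighting).
Prediction uses models refit on all 33 compounds rather than the training
split alone: the split exists to *estimate* predictivity, and discarding a
quarter of a 33-compound series for production predictions would waste
information. Queries whose leverage exceeds `h*` are flagged as
extrapolations.

## Synthetic generator

`generate_series()` emulates the real design: categorical substituent
slots drawn without duplicates from the series alphabets, an additive
per-slot effect table (defaults plant the para-substituent potency ladder
CF3 >> F > Cl > Br > H > CH3 with a ~2 log-unit range, plus smaller
heteroring effects), Gaussian noise, and a known noiseless truth. An
optional interaction term injects slot synergy for stress tests. What it
deliberately does not emulate: assay heteroscedasticity, activity cliffs,
scaffold rearrangements, or any 3D/conformational signal — passing
recovery tests therefore demonstrates that the pipeline recovers additive
substituent signals from pixel descriptors, not that real assay data meet
those assumptions.

`recovery_check()` reports LOO q2, exact group-mean effect recovery (exact
only when a single slot varies or noise is zero), the sign agreement of
the coefficient map on substituent-unique pixels, and the overlap of
top-decile VIP pixels with substituent-covered regions.

## Numerical choices and degenerate inputs

* Ties: Kennard-Stone breaks all ties toward the lowest row index;
  component selection toward fewer components; the rasterizer's draw
  order by atom index within equal radii.
* Zero-variance responses, degenerate correlations, all-identical rows
  (Kennard-Stone), singular score covariances and out-of-canvas atoms all
  raise explicit errors rather than producing NaNs.
* `c_r2p` is reported as 0 with a warning when the scrambled models are on
  average as good as the real one.
* All stochastic stages (y-randomization, bootstrap, synthetic
  generation) flow from explicit integer seeds and restore the caller's
  RNG state; Kennard-Stone, encoding and fitting are seed-independent.

## Problem sizes

The test suite exercises the full 300 x 348 study once end-to-end
(33 compounds, both encodings, 10 + 10 randomization/bootstrap cycles) and
runs all other unit and property tests on a reduced 160 x 120 canvas at
8 px/Angstrom with the identical geometry; synthetic recovery uses series
of 20-24 compounds across 20 seeds and three noise levels. These sizes
keep the whole suite around a minute while covering every stage at full
fidelity at least once.

## Known limitations

* The rasterization is a stylized re-implementation, not a reproduction
  of any particular drawing program's palette or anti-aliasing, so point
  statistics of the original study are matched in kind and in
  acceptability bounds, not digit-for-digit.
* The scaffold template is validated by mass back-calculation, which
  pins the molecular formula but not the true 2D pose; a different pose
  would relocate informative pixels without changing the modeling
  mathematics.
* PLS1 only (single response); no multi-response, kernel or sparse
  variants, and no applicability-domain method beyond the Williams plot.
* 2D pixel descriptors cannot express conformational or electronic
  effects beyond what atom identity at a position carries.
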