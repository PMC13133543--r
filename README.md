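# miaqsar

Multivariate image analysis QSAR (MIA-QSAR) for congeneric small-molecule
series, built around the 33-compound phenyltriazolinone inhibitors of
protoporphyrinogen oxidase (PPO), the target enzyme of an important class
of herbicides.

## What it does, and for whom

Medicinal and agrochemical chemists working with a congeneric series — one
scaffold, a handful of substituent slots — often want a predictive
activity model without curating molecular descriptors. MIA-QSAR uses the
pixels of aligned 2D ball-and-stick depictions as the descriptors: every
compound is drawn on a shared 300 × 348 canvas with the scaffold at
identical pixel positions, each atom disk is painted with an atomic
property of its element (Pauling electronegativity ε or van der Waals
radius r_vdW), and each image is unfolded row-major into a 1 × 104,400
vector. Stacking the series gives the descriptor matrix **X** (33 ×
104,400 here), which is regressed against potency by single-response
partial least squares:

- activities are pIC₅₀ = −log₁₀(IC₅₀ / (1000·MW)), IC₅₀ in mg/L;
- PLS1 via NIPALS on mean-centered data, components chosen by the
  leave-one-out RMSECV minimum;
- train/test splitting by Kennard–Stone maximin sampling (75/25);
- validation: RMSEC/RMSECV/RMSEP, r², q², r²_pred, Roy's r²_m pair,
  Lin's CCC, Q²F1/Q²F2, MAE, y-randomization with the corrected
  ᶜr²_p = r·√(r² − r̄²_y-rand), and 10 bootstrap test-set cycles
  (mean ± sd of every statistic);
- applicability domain by Williams plot (leverage vs standardized
  residual, h* = 3(A+1)/n, ±3 cutoff);
- interpretation by folding the VIP and regression-coefficient vectors
  back into image space (MIA plots);
- activity prediction for proposed analogs, averaging the ε and r_vdW
  models.

A synthetic congeneric-series generator with planted, known substituent
effects makes every stage testable end to end.

## Worked example

```r
library(miaqsar)

series <- ppo_compounds()                     # packaged 33-compound table
report <- run_study(series, run_config(seed = 1))
tab    <- summary_table(report)
round(tab[c("A", "rmsec", "r2", "r2_yrand", "c_r2p", "rmsecv", "q2",
            "rmsep", "r2_pred", "avg_r2m", "ccc", "q2_f1", "q2_f2",
            "mae"), 1:2], 4)
```

```
         vdw_radius (K-S) vdw_radius (bootst. mean)
A                 10.0000                    9.5000
rmsec              0.0332                    0.0301
r2                 0.9968                    0.9974
r2_yrand           0.3702                    0.4368
c_r2p              0.7903                    0.7471
rmsecv             0.0581                    0.0539
q2                 0.9902                    0.9916
rmsep              0.0576                    0.0555
r2_pred            0.9921                    0.9920
avg_r2m            0.9726                    0.9579
ccc                0.9958                    0.9942
q2_f1              0.9915                    0.9899
q2_f2              0.9913                    0.9885
mae                0.0458                    0.0464
```

Reading the column for the Kennard–Stone split of the r_vdW encoding:
the 25-compound calibration fits with r² = 0.997 (RMSEC 0.033 pIC₅₀
units), leave-one-out cross-validation holds up (q² = 0.990), the 8
held-out compounds are predicted with r²_pred = 0.992 and concordance
CCC = 0.996, and scrambling the response collapses the fit
(r̄²_y-rand = 0.37), giving ᶜr²_p = 0.79 — comfortably above the 0.5
chance-correlation threshold. The bootstrap column shows the same
statistics as means over 10 random re-splits, so the model is not an
artifact of one particular test set. All four published acceptability
bounds (r² ≥ 0.6, q² ≥ 0.5, CCC ≥ 0.85, ᶜr²_p ≥ 0.5) are met by both
encodings.

Predicting the eight proposed analogs with the two models averaged:

```r
predict_proposals(report, ppo_proposals())
```

```
  id pred_vdw_radius pred_electronegativity average extrapolation
1 P1            6.29                   6.29    6.29         FALSE
2 P2            5.27                   5.27    5.27         FALSE
3 P3            5.05                   5.05    5.05         FALSE
4 P4            6.76                   6.76    6.76         FALSE
5 P5            6.61                   6.61    6.61         FALSE
6 P6            5.37                   5.37    5.37         FALSE
7 P7            7.08                   7.08    7.08         FALSE
8 P8            5.55                   5.56    5.55         FALSE
```

P7 (X = S, R¹ = CF₃, R² = 3,5-CH₃) ranks first at a predicted pIC₅₀ of
7.08 — above the most potent training compound — and the CF₃ > F > CH₃
para-substituent ordering holds within matched scaffolds (P4 > P1 > P3,
P7 > P5 > P6). No proposal exceeds the leverage threshold, so none is an
extrapolation. Williams screening of the full series
(`report$models$vdw_radius$ad`) flags zero outliers.

See `vignettes/miaqsar-methods.Rmd` for the model, its assumptions, all
tunable parameters and the design decisions.

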