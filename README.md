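# dualperf

Dual-modality quantification of myocardial blood flow (MBF) from dynamic
^15^O-water PET and dynamic contrast-enhanced (DCE) MRI curves, with the
agreement analysis between the two — for researchers comparing MRI-based
perfusion quantification against the PET reference standard, and for anyone
who needs a controlled testbed for the estimators involved.

^15^O-water is freely diffusible, so the single-tissue model

    C_PET(t) = PTF · F · [C_A ⊗ exp(−(F/p)·t)] + Va · C_A(t)

identifies flow F (mL/g/min) from a single time-activity curve through its
washout rate F/p (partition coefficient p = 0.91 mL/g, fixed). Gd-DOTA is
extracted incompletely: the one-tissue MRI model

    C_T(t) = K1 · [C_A ⊗ exp(−(K1/Ve)·t)] + vb · C_A(t),   K1 = F·(1 − e^(−PS/F))

carries flow only through the Renkin–Crone influx K1, whose extraction
fraction E = K1/F falls as flow rises — so plain K1 underestimates
hyperaemic perfusion, and any extraction correction amplifies noise by
dF/dK1 = 1/(1 − (1 + PS/F)·e^(−PS/F)), which grows without bound as K1
approaches the permeability–surface-area product PS.

The package provides:

* the kinetic core: gamma-variate input functions, an exponential
  convolution recursion exact for piecewise-linear inputs on non-uniform
  grids, Renkin–Crone forward/inverse maps, and both forward models;
* a saturation-recovery signal model and its self-calibrating inversion
  from MRI signal to gadolinium concentration;
* weighted, box-constrained, multi-start fitters for the water model and
  the three MRI analysis routes — plain K1, extraction-corrected K1 at a
  calibrated population PS, and direct flow/permeability estimation with
  per-subject PS anchored on the simultaneous PET flows;
* AHA 17-segment / coronary-territory / global aggregation, myocardial
  flow reserve (MFR), and Bland–Altman, Spearman and paired-t agreement
  statistics;
* a fully deterministic synthetic rest/stress cohort generator with known
  ground truth, so every estimator is testable without image data.

## Worked example

The analysis is organised as four thin scripts over the package functions.
With the default study conditions (12 subjects; rest MBF truth
1.02 ± 0.28, stress 3.13 ± 1.16, PS 2.91 ± 0.37 mL/g/min; PET frame noise
scale 1, MRI SNR 20):

```sh
Rscript analysis/01_simulate.R 1    # seed 1
Rscript analysis/02_fit_pet.R
Rscript analysis/03_fit_mri.R
Rscript analysis/04_agreement.R
```

prints (seed 1, abridged):

```
true global rest MBF: 1.02 +/- 0.28 mL/g/min
true global stress MBF: 3.60 +/- 1.10 mL/g/min
true PS: 2.85 +/- 0.33 mL/g/min
fitted global rest MBF: 1.03 +/- 0.32 mL/g/min (n = 12)
fitted global stress MBF: 3.64 +/- 1.08 mL/g/min (n = 12)
plain route: global K1 0.94 (rest) / 1.86 (stress) vs PET MBF 1.03 / 3.64
population PS calibrated against PET: 2.66 mL/g/min
direct route: per-subject PS 2.77 +/- 0.70 mL/g/min
direct route global rest MBF: 1.06 +/- 0.30 mL/g/min
direct route global stress MBF: 3.61 +/- 1.06 mL/g/min
segments excluded as unreliable: 12 of 408
global    pooled  n= 24  bias +0.005  LoA [-0.30,  0.31]  rho 0.99
segment   stress  n=192  bias +0.454  LoA [-0.99,  1.90]  rho 0.83  excl 12
MFR: MRI 3.53 vs PET 3.71, rho 0.78, bias -0.18
```

Reading it: PET fits recover the generating flows essentially unbiased. The
plain MRI K1 tracks flow at rest (0.94 vs 1.03) but underestimates it badly
at stress (1.86 vs 3.64) — the low-extraction regime. The direct
flow/permeability route removes the underestimation (3.61 vs 3.64 at
stress) at the price of noise amplification, visible as the wider
stress-segment limits of agreement, the excluded unreliable segment fits,
and a flow-reserve correlation below the pooled-flow one. Outputs land
under `results/` (fit tables as TSV, agreement summary as JSON, scatter and
Bland–Altman plots as SVG). `run_pipeline()` performs the same stages in
one call.

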