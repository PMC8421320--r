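---
title: "Dual-modality myocardial blood flow quantification: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-modality myocardial blood flow quantification: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualperf)
```

## The problem

Myocardial blood flow (MBF, mL/g/min) can be quantified from dynamic
^15^O-water PET — the accepted non-invasive reference — and from dynamic
contrast-enhanced (DCE) MRI after a gadolinium bolus. The two measurements
disagree in characteristic ways: water is freely diffusible, so its kinetics
carry flow information directly, whereas Gd-DOTA crosses the capillary wall
incompletely, with an extraction fraction that *falls* as flow rises. A naive
one-tissue analysis of the MRI data therefore underestimates hyperaemic flow,
and every correction for that underestimation amplifies noise. `dualperf`
implements both quantification chains and the agreement analysis between
them, exercised end to end on a synthetic rest/stress cohort with known
ground truth, so that every estimator's bias and noise behaviour can be
measured rather than argued.

## Kinetic models

### Water PET

The tissue activity concentration follows the single-tissue compartment
model with perfusable tissue fraction (PTF) and arterial blood-volume
spillover:

$$C_{PET}(t) = \mathrm{PTF}\cdot F \left[C_A \otimes e^{-(F/p)t}\right]
  + V_a\, C_A(t)$$

with flow $F$ in mL/g/min (converted to s$^{-1}$ at the model boundary),
partition coefficient $p = 0.91$ mL/g held fixed (the conventional cardiac
value; it is not fitted), $\mathrm{PTF} \in (0,1]$ g/mL and
$V_a \in [0,1)$. Because water equilibrates freely, the washout rate $F/p$
identifies $F$ from a single curve — amplitude and washout carry independent
information, which is why the PET fit recovers $F$, PTF and $V_a$ jointly.

### Gadolinium MRI

Tissue gadolinium concentration follows the extended one-tissue model

$$C_T(t) = K_1 \left[C_A \otimes e^{-(K_1/V_e)t}\right] + v_b\, C_A(t)$$

with the influx tied to flow and the permeability–surface-area product (PS)
by the Renkin–Crone relation

$$K_1 = F\,E(F),\qquad E(F) = 1 - e^{-\mathrm{PS}/F}.$$

At rest ($F \approx 1$, $\mathrm{PS} \approx 2.9$ mL/g/min) extraction is
near-complete ($E \approx 0.95$) and $K_1 \approx F$; at stress
($F \approx 3$) extraction drops to $E \approx 0.6$ and $K_1$ substantially
underestimates flow. The package offers the three analysis routes built on
this model:

1. **Plain one-tissue** (`fit_gd_plain_1tcm`): free $K_1$, $V_e$, $v_b$;
   $K_1$ is reported as the perfusion-related parameter.
2. **Extraction-corrected** (`apply_extraction_correction`): plain $K_1$
   inverted through the Renkin–Crone relation at a population PS obtained by
   `calibrate_population_ps` — least squares of paired $(K_1, F_{PET})$
   observations. The inversion's noise amplification
   $dF/dK_1 = \left[1-(1+\mathrm{PS}/F)e^{-\mathrm{PS}/F}\right]^{-1}$
   is ~1.4 at rest but >4 at stress and unbounded as $K_1 \to \mathrm{PS}$,
   which is why corrected values scatter badly at high flow.
3. **Direct flow/permeability estimation** (`fit_gd_1tcm_ps`): the forward
   model is parameterised in $(F, \mathrm{PS})$ with $K_1$ derived, so flow
   is fitted directly.

### Identifiability of the direct route

A point this package treats explicitly: the one-tissue curve depends on
$(F, \mathrm{PS})$ *only through* $K_1$. A single tissue curve therefore
determines $(K_1, V_e, v_b)$ and nothing more — the $(F, \mathrm{PS})$ pair
lies on an exact one-dimensional ridge, and no optimizer can recover both
from one curve, noiseless or not. Joint rest+stress fitting with a shared PS
does not resolve it either: two curves give two $K_1$ values but three
unknowns $(F_{rest}, F_{stress}, \mathrm{PS})$. The free fit is provided and
behaves honestly: it reproduces the identifiable $K_1$ to machine precision,
reports an effectively infinite relative standard error on $F$ (singular
Gauss–Newton information), and flags itself unreliable.

The working direct route uses the dual-modality design itself: each
subject's PS is estimated by Renkin–Crone least squares on that subject's
rest and stress $(K_1^{MRI}, F^{PET})$ pairs — two flow states, one
parameter (`estimate_subject_ps`) — and every region is then refitted with
PS fixed at the subject's value, which makes $F$ identifiable. Without
noise this chain recovers every generating flow and PS to better than 0.1%.
The per-subject PS search is confined to the same box the direct fit
declares for PS (0.5–6 mL/g/min); an estimate pinned at a bound is an
unreliable fit, returned as NA and excluded from aggregation — the same
exclusion mechanism applied to unreliable region fits. This matters for
cohort summaries because the two-point calibration is right-skewed: noise on
the near-saturated stress $K_1$ maps to PS with amplification
$\sim e^{\mathrm{PS}/F}$, so an unbounded mean would drift upward while the
median stays put.

## Signal model and concentration conversion

MRI signal is mapped to gadolinium concentration with a simplified
saturation-recovery equation,

$$S = S_0\left(1 - e^{-T_D R_1}\right),\qquad R_1 = 1/T_{10} + r_1 c,$$

with preparation delay $T_D = 120$ ms and relaxivity $r_1 = 3.6$
L mmol$^{-1}$s$^{-1}$. The readout pulse train, $B_1$ inhomogeneity and
$T_2^*$ losses are not modelled; flip angle and TR are carried as metadata
only. The inversion (`signal_to_concentration`) is self-calibrating: $S_0$
is inferred from the mean of the pre-contrast baseline frames (default 5)
through the same equation, then each sample is inverted through the strictly
monotone signal map. Samples at or above the implied asymptote — possible
under noise or true saturation — are clipped to a ceiling of 20 mmol/L and
counted; baseline noise maps to small positive and negative concentrations
that average to zero and are retained. Blood ($T_{10} = 1.66$ s) and
myocardium ($T_{10} = 1.2$ s) are converted with their own relaxation
times. These constants are conventional 3 T literature values, exposed as
configuration; they are not estimates from any dataset.

## The synthetic cohort

`simulate_cohort` draws per-subject truths and simulates both scans:

* rest MBF ~ truncated normal (1.02, 0.28; lower 0.3), stress MBF ~
  truncated normal (3.13, 1.16; lower 1.0), one PS per subject ~ truncated
  normal (2.91, 0.37; lower 0.5) shared across conditions — the reference
  cohort moments. (Truncation shifts the effective stress mean to ~3.22;
  recovered cohort means are compared against the realized truth draws, not
  the nominal figure.)
* 17 AHA-segment flows = global flow × lognormal multipliers (CV 10%)
  renormalised so the equal-weighted segment mean equals the global truth
  exactly; segments map to LAD/RCA/LCx territories by the standard
  assignment.
* PET: gamma-variate arterial input (peak-normalised form
  $A\,[(t-t_0)/\alpha\beta]^\alpha e^{\alpha-(t-t_0)/\beta}$ so the
  `amplitude` parameter *is* the peak, plus a recirculation tail — the
  first pass convolved with $e^{-t/\tau}/\tau$ and scaled by a
  dimensionless fraction), amplitude proportional to the 400 MBq dose;
  frames 24×5 s + 12×10 s + 6×20 s = 360 s, sampled at frame midpoints;
  frame noise SD $= s\sqrt{\mathrm{value}/\mathrm{duration}}$ with scale
  $s = 1$ by default.
* MRI: one frame per heartbeat for 65 beats (66/82 bpm rest/stress);
  arterial concentration peak set by dose (0.05 mmol/kg × 75 kg) over a
  nominal 0.9 L first-pass mixing volume (~4.2 mmol/L); Gaussian signal
  noise with SD = baseline/SNR, SNR 20 by default.

The generator is fully deterministic given the config (seed included):
rerunning yields byte-identical cohorts. What it deliberately does *not*
emulate: motion and breathing artifacts, ECG-gating failures, dual-bolus or
dual-sequence acquisitions, image-domain effects (everything here is
curve-domain), dispersion of the input function, and model mismatch — the
simulated curves come from the same model families the fitters use. Passing
tests therefore demonstrate estimator correctness and noise behaviour under
the stated conditions, not robustness to the physiological and acquisition
error sources a real scanner adds.

## Numerical choices

* **Convolution**: all $C_A \otimes e^{-kt}$ terms use a recursion exact for
  piecewise-linear inputs on the native non-uniform grid (closed-form
  integral per segment, Taylor fallback for $k\,\Delta t < 10^{-6}$), not
  FFT — correct on short, unevenly sampled clinical curves, and it makes
  fitting the exact inverse of simulation. The input is treated as constant
  at its first sample over $[0, t_1]$ (a no-op for bolus curves that start
  at zero). `rate = 0` degenerates to the running time integral.
* **Optimisation**: box-constrained Levenberg–Marquardt (`minpack.lm`),
  multi-start (flow starts {0.5, 1.5, 3}; direct-fit PS starts {1.5, 3}),
  best converged start by residual sum of squares; ties broken by the first
  minimum found. Bounds: $F \in [0.05, 8]$, $\mathrm{PTF} \in [0.01, 1]$,
  $V_a \in [0, 0.5]$, $K_1 \in [0.01, 4]$, $V_e \in [0.05, 1]$,
  $v_b \in [0, 0.3]$, $\mathrm{PS} \in [0.5, 6]$.
* **Weights**: PET residuals weighted by $\sqrt{\mathrm{frame\ duration}}$
  (uniform when durations are absent); MRI residuals unweighted.
* **Standard errors**: Gauss–Newton covariance from a forward-difference
  Jacobian at the solution (stepping inward at active bounds); a singular
  information matrix yields infinite SEs rather than an error.
* **Reliability rule**: a fit is unreliable when the relative SE of its
  perfusion parameter exceeds 50% or any parameter sits within 1% of a
  bound; unreliable fits are excluded from agreement aggregation. The
  degenerate blood-only curve illustrates why the rule watches bounds: with
  PTF free, $F$ and PTF are jointly unidentified (only their product
  enters) and the optimizer parks PTF at its floor.
* **AIF delay**: an optional ±10 s, 1-s grid search refits at each shift;
  off by default because the simulator generates aligned input functions —
  the default path must be the generator's inverse.
* **Renkin–Crone inversion**: monotone root bracketing from $F = K_1$
  (always a lower bound) with doubling upper expansion and `uniroot` at
  $10^{-13}$ tolerance; $K_1 \ge \mathrm{PS}$ is a hard no-solution error.

## Agreement statistics

Bland–Altman bias and limits of agreement use the $n-1$ SD and a fixed 1.96
multiplier (no small-sample $t$ correction), matching the symmetric
intervals conventionally printed. Spearman correlation is the Pearson
correlation of average-ranked data with the two-sided $t$-approximation on
$n-2$ degrees of freedom. Rest and stress enter the pooled comparison as
independent pairs (24 points from 12 subjects) — statistically generous,
since the pooled correlation is inflated by the rest/stress separation
itself, which is precisely why the package also reports rest and stress
separately and why the flow-reserve comparison is the more fragile one: MFR
divides two noisy estimates, so its relative noise exceeds that of stress
MBF alone, and its correlation across modalities degrades first. Segment
weights default to equal (1/17); a volume-weighted variant can be supplied.

## Problem sizes

The test suite and the acceptance script run at desk scale on one CPU:
noiseless round trips use 2-subject cohorts; Monte-Carlo properties use
40–100 replicates; cohort-moment recoveries use 16 subjects in the tests
and 50 in the acceptance script; the per-subject PS recovery averages 12
subjects over 50 seeds; the flow-reserve degradation experiment uses 5
seeds × 40 subjects at SNR 5 and PET noise scale 2.5 — a noise level chosen
so that pooled flow agreement remains strong (Spearman ρ > 0.8) while the
reserve correlation visibly degrades. All randomness is seed-keyed.

## Known limitations

* Curve-domain only: no images, no segmentation, no partial-volume or
  motion modelling.
* The MRI signal equation ignores the readout train and $T_2^*$; real
  saturation behaviour at high concentration is only caricatured by the
  clipping ceiling.
* Simulation and fitting share model families, so model-mismatch bias —
  likely a major contributor to the wide limits of agreement seen with real
  scanners — is outside what these experiments can measure.
* The direct route's per-subject PS leans on the simultaneous PET flows;
  it is an anchored estimator, not an MRI-only one. An MRI-only per-subject
  PS is structurally out of reach for this model family (the ridge above).
* Dispersion of the arterial input is not modelled; only a rigid delay is
  offered.
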