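# petkin

Compartmental kinetic modeling of dynamic PET time-activity curves in R,
built around the question of which quantification model to trust for a
tracer whose "reference" region is not binding-free.

Quantitative PET pharmacokinetics estimates, per brain region, the
distribution volume `VT` and the non-displaceable binding potential `BPND`
from a dynamic scan plus an arterial input function — or, skipping blood
sampling, from a reference region's curve. The standard toolbox spans
plasma-input compartment models, data-driven spectral analysis, and
reference-tissue models. Which of these is adequate depends on the kinetics
of the tissue at hand: when a slow non-specific compartment or residual
specific binding in the reference region is present, the simpler models
acquire systematic, region-dependent biases. This package implements the
full toolbox together with a fully specified three-tissue simulation study
designed to expose exactly those biases.

## Models

For rate constants `K1` (mL·cm⁻³·min⁻¹) and `k2…k6` (min⁻¹):

* **1TCM / 2TCM** — serial plasma-input compartment models fitted by
  bounded Levenberg–Marquardt with seeded multistarts; the measured signal
  is `(1−vB)·C_T(t) + vB·C_b(t)` with the blood volume fraction fixed at
  `vB = 0.05`; frame values are frame averages. `VT = (K1/k2)(1 + k3/k4)`.
* **Spectral analysis (SA)** — non-negative decomposition of the TAC onto
  50 input-convolved exponentials, decay coefficients log-spaced over
  0.001–1 s⁻¹; `VT = Σ αⱼ/βⱼ`.
* **SRTM / FRTM / SRTM-2C** — reference-tissue estimates of `BPND`; SRTM
  by basis-function linearization with exact refinement, FRTM as the
  four-parameter two-exponential model, SRTM-2C with a two-compartment
  reference region and `BPND` referenced to the reference region's total
  distribution volume.
* **Model selection and agreement** — `AIC = n·ln(RSS/n) + 2k`, preference
  tallies, Bland–Altman %difference with 95% limits of agreement, percent
  bias against theoretical truth, OLS regression, Holm correction.
* **Simulation study** — a three-tissue generative model (specific `k3/k4`
  and slow non-specific `k5/k6` branches in parallel off the free
  compartment) over a 17-point binding grid (`k3` = 0.20…2.60 min⁻¹, fixed
  `K1 = 0.8, k2 = 2.25, k4 = 0.17, k5 = 0.15, k6 = 0.08`), driven by a
  packaged bolus input, with Gaussian noise scaled to late-frame uptake.

## Worked example

```r
library(petkin)

input    <- synthetic_input()           # bolus plasma + whole-blood curves
schedule <- default_frame_schedule()    # 21 frames over 60 min
grid     <- table2_grid()               # 17 binding levels, k3 = 0.20..2.60

# simulate a low-binding region and fit both plasma models
tac <- model_tac(grid$configs[[1]], input$plasma_parent,
                 input$whole_blood, schedule)
f1 <- fit_compartment_model(tac, input$plasma_parent, input$whole_blood,
                            schedule, "1T")
f2 <- fit_compartment_model(tac, input$plasma_parent, input$whole_blood,
                            schedule, "2T")
f1
#> <pk_fit 1TCM> VT = 0.7563, rss = 0.04886, AIC = -44.44
f2
#> <pk_fit 2TCM> VT = 1.415, rss = 3.179e-05, AIC = -193.5
grid$theory$VT[1]
#> [1] 1.440523
```

The two-tissue model is decisively preferred (ΔAIC ≈ 149) and lands within
2% of the theoretical `VT`, while the one-tissue fit misses the slow
non-specific compartment and underestimates `VT` by 47% — the same
low-binding failure mode seen in measured data. Running the numbered
scripts under `analysis/` reproduces, in order: the theoretical
macro-parameter table (`01`), the noiseless AIC preference and VT-recovery
surface (`02`), the noisy-replicate preference overlap (`03`), the
reference-model bias against DVR−1 (`04`), and the Bland–Altman /
regression comparison on a synthetic five-region study (`05`), each
writing its tables under `results/`.

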