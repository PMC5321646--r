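---
title: "Kinetic models, their assumptions, and the design of the simulation study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic models, their assumptions, and the design of the simulation study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petkin)
```

This vignette is the package's account of the science it implements: the
compartment models and their assumptions, the tunable parameters and why
their defaults are what they are, what the synthetic-data generator does
and does not emulate, and the numerical and design choices that were
genuinely open.

## The compartmental forward model

A region's tissue concentration is driven by the metabolite-corrected
(parent) plasma concentration $C_p(t)$ through a linear compartment
system. The package implements the serial one- and two-tissue models used
for fitting and a three-tissue generative model used for simulation. In
the three-tissue model the specific-binding compartment ($k_3, k_4$) and a
slow non-specific compartment ($k_5, k_6$) exchange *in parallel* with the
free compartment:

$$\dot C_1 = K_1 C_p - (k_2 + k_3 + k_5) C_1 + k_4 C_2 + k_6 C_3, \quad
  \dot C_2 = k_3 C_1 - k_4 C_2, \quad \dot C_3 = k_5 C_1 - k_6 C_3.$$

The parallel wiring is not arbitrary: it is the unique two-branch topology
whose total distribution volume is
$V_T = (K_1/k_2)\,[1 + k_3/k_4 + k_5/k_6]$, the formula the simulation
grid's theoretical values are built from. A serial chain would give a
different $V_T$ expression, so the macro-parameter algebra itself pins the
topology down.

The measured PET value of frame $i$ is the *frame average* of
$(1-v_B)\,C_T(t) + v_B\,C_b(t)$, with whole-blood curve $C_b$ and blood
volume fraction $v_B$ fixed at 0.05 — frame averaging matters because the
early 10-s frames sit on the steep bolus flank, where midpoint evaluation
is visibly biased. No radioactive-decay term appears anywhere: frames are
assumed decay-corrected, as reconstructed PET data are.

Numerically, tissue curves are exact convolutions of the piecewise-linear
input with the model's multi-exponential impulse response (eigenvalues of
the rate matrix; closed forms for one and two tissues) on an internal
0.5-s grid, evaluated by an $O(n)$ first-order recursion. Nearly
degenerate eigenvalue pairs — e.g. a two-tissue model with $k_3 = 0$ and
$k_2 = k_4$ — are handled by a symmetric $10^{-7}$-relative perturbation
of the branch rates, which approximates the $t\,e^{-\theta t}$ limit far
below fitting tolerance rather than failing.

## Fitting, weights, and model preference

Compartment fits minimize $\sum_i w_i (y_i - \hat y_i)^2$ over frames by
bounded Levenberg–Marquardt, restarted from 5 log-uniform draws over
$K_1 \in [0.01, 5]$, $k_{2..6} \in [0.001, 5]$ (two-tissue likelihoods are
multimodal on noisy low-binding TACs; the draws are seeded, so fits are
reproducible). Weights are uniform by default: the simulation noise model
has constant per-frame SD, making uniform weights the statistically
matched choice; frame-duration weighting is available. The blood delay is
estimated once on the whole-brain curve — a ±0.5 min search at 0.01-min
resolution (coarse grid, local refinement, parabolic vertex) minimizing
the two-tissue fit RSS — and then held fixed for every region. Which model
should anchor delay estimation is not prescribed by the problem; the
two-tissue model is used because it is the one that fits all regions, and
the choice is exposed as an argument.

Model preference uses the least-squares information criterion
$\mathrm{AIC} = n \ln(\mathrm{RSS}/n) + 2k$ without small-sample
correction: comparisons are always within one TAC, so constant offsets
cancel. Exact ties go to the simpler model; a zero-RSS fit returns
$-\infty$ with a flag rather than an error.

## Spectral analysis

The TAC is decomposed as $\sum_j \alpha_j\, C_p \otimes e^{-\beta_j t}$
with $\alpha_j \ge 0$ by non-negative least squares on 50 decay
coefficients log-spaced (endpoints included; the spacing is the standard
choice for exponential spectra) over 0.001–1 s⁻¹, i.e. 0.06–60 min⁻¹, and
$V_T = \sum_j \alpha_j/\beta_j$. Two points deserve flagging:

* Whether the blood fraction belongs inside the decomposition is
  genuinely open; the package fits the TAC as pure tissue by default and
  offers a $v_B$-subtraction pre-step, which keeps SA comparable with the
  fixed-$v_B$ compartment fits and is what the simulation pipeline uses.
* "Number of peaks" is only well-defined under floating-point NNLS output
  after thresholding (default 1% of the largest coefficient) and merging
  adjacent grid points. On *noiseless* three-tissue TACs the spectrum
  resolves all three eigenrates — at $k_3 = 2.60$ they are 0.064, 0.094
  and 5.09 min⁻¹, and the counted clusters are three. The familiar
  "two peaks for two-compartment kinetics" reading emerges only once
  noise merges the slow pair; noiseless peak counts should not be read as
  predictions for measured data.

## Reference-tissue models

All three models eliminate the plasma curve through the ratio of target
and reference transfer functions under the usual assumption of a common
non-displaceable distribution volume. SRTM (both regions one-tissue) is
solved by basis-function linearization over 100 log-spaced
$k_{2a} \in [0.006, 6]$ min⁻¹ values with an exact linear subproblem per
candidate — chosen over raw three-parameter NLS for determinism — plus a
1-D bounded refinement so the estimate is not quantized to the grid. FRTM
(target two-tissue) is the standard two-exponential four-parameter model
with $BP_{ND}$ a direct parameter ($k_4 = k_3/BP_{ND}$), keeping the
physical bound $BP_{ND} > -1$ explicit; its lower bound is $10^{-6}$ so
the degenerate target-equals-reference case can collapse to zero.

SRTM-2C — one-tissue target, two-compartment reference — has no single
canonical algebra, and the formulation here is one defensible reading,
fixed by its contract: eliminating $C_p$ gives

$$C_T = R_1\left[C_R + a\, C_R \otimes e^{-k_{2a} t}
        + b\, C_R \otimes e^{-\mu t}\right],$$

with $\mu = k_{3r}+k_{4r}$ and $a, b$ rational functions of the reference
eigenrates, fitted jointly over $(R_1, k_{2a}, k_{2r}, k_{3r}, k_{4r})$.
Two consequences of this construction matter:

* **BP normalization.** Both reference compartments are counted as
  non-displaceable — that is precisely the premise of using the region as
  a reference — so $BP_{ND} = R_1 k_{2r}/(k_{2a}(1 + k_{3r}/k_{4r})) - 1$,
  the target volume referenced to the reference region's *total*
  distribution volume. Normalizing instead by the free compartment alone
  ($R_1 k_{2r}/k_{2a} - 1$) turns the fitted second compartment into
  "binding to be added back" and overestimates DVR−1 severely (nearly
  threefold at the top of the binding grid). Either convention collapses
  to SRTM when $k_{3r} = 0$.
* **Degeneracy.** For simple targets the five-parameter model is
  over-parameterized and the RSS has flat directions; ties between
  restarts are broken toward the smallest $k_{3r}$, i.e. the solution
  closest to SRTM, which makes the identity case ($C_T \equiv C_R$)
  return $BP_{ND} = 0$ deterministically.

The reference curve is known only as 21 frame averages; it is
reconstructed on the fine grid by a shape-preserving (monotone Hermite)
spline anchored at the origin — linear interpolation through frame
midpoints misses the curve's convexity across the long late frames and
was measured to triple the forward-model error.

## The synthetic study and what it does not show

No measured input function accompanies the simulation design, so the
package ships a deterministic bolus input chosen once to be realistic for
a 60-s pump infusion in a small animal: a Feng-type total plasma curve
(appearance at 0.25 min, peak near 0.5 min, tri-exponential washout with
terminal rate 0.02 min⁻¹), a plateauing parent fraction
$f(t) = 0.25 + 0.75 e^{-0.09 t}$, and whole blood as total plasma divided
by 1.2. The binding grid runs $k_3$ from 0.20 to 2.60 min⁻¹ in steps of
0.15 — 17 configurations, with the lowest-binding one serving as the
pseudo-reference region, itself containing specific binding ($k_3/k_4 =
1.18$ on top of $k_5/k_6 = 1.875$), which is exactly what biases
reference-model $BP_{ND}$ low.

Noise is zero-mean Gaussian with a per-TAC constant SD equal to 5% or 10%
of the mean noiseless value of the last two frames. That is the literal
definition adopted here even though such noise is often loosely called
Poisson-like: the defining property is the amplitude anchor, not count
statistics; a frame-duration-scaled variant exists for sensitivity
analysis. Replicates are seeded and reproducible; the desk-scale default
is 25 replicates per configuration (100 in the full design — one argument
away; the analysis scripts use 10 to keep a full two-noise-level sweep
under two minutes).

What passing tests on this generator do *not* establish: the input curve's
shape is invented, and every bias *magnitude* — the −47% one-tissue VT
error at low binding, the ≈−6% overall reference-model bias — moves with
it; only directions, orderings and convergence patterns transfer to
measured data. The generator also emulates no image-space effects
(spillover, partial volume, reconstruction noise correlation), no
metabolite entry into tissue, and no inter-animal kinetic variability.

## Known limitations

* At the grid configuration adjacent to the pseudo-reference
  ($k_3 = 0.35$, true DVR−1 = 0.22), SRTM's bias is ≈+1% — indistinguishable
  from zero and of input-dependent sign — so the "reference models
  underestimate everywhere" rule holds only where target/reference
  contrast is meaningful ($k_3 \ge 0.5$ with this input). FRTM and
  SRTM-2C remain below truth even there.
* One-tissue and two-tissue $V_T$ agree within 1% only once specific
  binding truly dominates the non-specific pool ($k_3/k_4$ above roughly
  15× $k_5/k_6$); at the top of the standard grid the ratio is 8× and the
  difference is ≈1.8%.
* Irreversible ($k_4 = 0$) variants, graphical (Logan-type) methods,
  voxelwise fitting and $v_B$-free fitting are out of scope.
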