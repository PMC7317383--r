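---
title: "Multi-pool CEST/qMT modelling: model, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-pool CEST/qMT modelling: model, priors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cestmt)
```

## The physical model

Chemical exchange saturation transfer (CEST) detects dilute labile protons
(amides at +3.5 ppm, relayed-NOE aliphatic protons around -3.5 ppm) by
saturating them with off-resonance RF and observing the transferred
saturation as attenuation of the water signal. Semisolid macromolecular
protons produce the magnetization transfer (MT) effect: a saturation
pathway with an extremely short T2 (~10 us), whose absorption lineshape
g(Delta, T2) spans hundreds of ppm. Both effects superimpose in the
Z-spectrum Z(Delta_omega) = S(Delta_omega)/S0, so a quantitative model must
carry every pool that contributes measurable saturation.

`cestmt` implements the coupled Bloch-McConnell equations for N pools with
water-centric exchange. Mobile pools carry (Mx, My, Mz); semisolid pools
carry Mz only, with RF saturation entering as the rate
pi * omega1^2 * g(Delta, T2M). Exchange satisfies detailed balance,
k_FS = k_SF * M0r_S, where M0r is the pool's equilibrium magnetization
relative to water and k_SF the solute-to-water rate in 1/s.

Three lineshapes are provided for the semisolid pool: Lorentzian, Gaussian
(appropriate for agarose phantoms) and super-Lorentzian (tissue). All are
normalized to unit integral over angular frequency. The super-Lorentzian
diverges on resonance; for |Delta| below a configurable cutoff (default
1 kHz, `options(cestmt.sl_cutoff_hz = )`, the common quantitative-MT
convention) it is replaced by a cubic interpolation anchored on
[1, 1.5] kHz and capped at its zero-offset extrapolation. The orientation
integral uses a fixed 512-point Gauss-Legendre rule; against a 5120-point
rule it is accurate to better than 1e-6 relative away from the cutoff.

## Pulsed-saturation steady state

The pulsed sequence is modelled as a periodic cycle per shot: saturation
train (t_m) -> spoil -> free precession (t_s) -> instantaneous excitation by
alpha -> readout/recovery (t_r) -> spoil. Within each interval the equations
are linear, dM/dt = A M + b, so each interval is an affine map built from a
matrix exponential, and the pre-excitation steady state is the fixed point
of their composition, solved directly as a linear system. The saturation
interval uses the continuous-wave equivalent pulse (CWEP): the shaped pulse
train is replaced by the constant amplitude with the same mean-square
amplitude over the full pulse period, gaps included (an average-amplitude
alternative is available through `cwep_amplitude(mode = "amplitude")`).

Two independent oracles validate this closed form, and both are exported:

* `steady_state_magnetization(method = "iterated")` applies the cycle map
  repeatedly from equilibrium; the closed form matches it to better than
  1e-8 relative on randomized systems (the test suite draws 100).
* `simulate_zspectrum_timestepped()` integrates the equations with the
  shaped B1(t) sampled piecewise-constant (default 100 steps per pulse).
  For a block pulse at 100% duty the CWEP is exact. For the default shaped
  train (fifty 20-ms Gaussian pulses, 50% duty) the two agree closely over
  the CEST band *except* within roughly +/-1 ppm of water: there the pulse
  train's periodicity (period 40 ms, modulation sidebands every 25 Hz)
  saturates the narrow water line coherently, an effect the
  constant-amplitude CWEP cannot represent, and the discrepancy reaches
  tenths of Z at offsets near the first few sidebands. This is a known
  physical limitation of continuous-wave-equivalent modelling of pulsed
  saturation near resonance, and the acceptance checks report it rather
  than masking it.

Design choices where the physics is conventionally idealized: spoiling
zeroes transverse magnetization instantly; the excitation pulse is an
instantaneous rotation whose duration is folded into t_r (a 2D FLASH
readout is short relative to the shot); spoiling precedes excitation in the
cycle, which makes the sin(alpha) entries of the excitation diagonal inert.
The per-shot interval split defaults to t_s = 10 ms with t_r absorbing the
remainder of the shot interval; these are exposed on
`saturation_scheme()`. Offsets are stored in ppm (positive downfield) and
converted with the scanner frequency (default 127.7 MHz, 3 T). Matrix
exponentials use eigendecomposition with a scaling-and-squaring fallback
when the eigenvector basis is ill-conditioned (accepted only below a
condition estimate of 1e7); the per-offset hot loop is compiled
(RcppArmadillo).

## Estimation

`cest_fit()` performs maximum-a-posteriori estimation with a Gaussian
likelihood on the normalized signal and log-normal priors on positive
parameters, reporting Laplace-approximation standard deviations at the
mode. This keeps the same posterior surface a variational or MCMC backend
would explore while remaining easy to verify. Free parameters per non-water
pool are M0r, k and T2; water contributes T2 and T1 (the T1 prior is
centred on the observed T1 supplied per voxel, sd 0.05 decades); a global
B0 offset (ppm) has a Normal(0, 0.1 ppm) prior unless an image prior is
supplied. Default prior widths: one decade for M0r and k, half a decade for
T2 -- deliberately weak, so the likelihood dominates wherever the data are
informative. Prior means come from the pool template; a prior sd of zero
fixes a parameter. Noise sd is either supplied or estimated from the
residual in a second pass (floored at 2e-4 so that noiseless
self-consistency checks remain likelihood-dominated). Optimization runs
L-BFGS-B in prior-standardized coordinates with three starts (first at the
prior mean, others jittered under a fixed seed).

Analysis variants mirror common practice:

* `cest_mt` -- all pools fitted jointly.
* `two_pool` -- water + semisolid only (a classic qMT analysis).
* `qmt_fix` -- stage 1 fits water + semisolid on the |offset| > 5 ppm
  points; stage 2 fixes them and fits the CEST pools on the full schedule.
* `noe_mt` -- NOE and semisolid pools collapsed into one mobile Lorentzian
  pool at -3.5 ppm; an intentionally mis-specified model used to
  demonstrate bias.

Derived metrics: the pool size ratio (PSR) is the fitted semisolid M0r; the
MTR* of a CEST pool inserts its fitted M0r and k into an idealized two-pool
simulation (water T1 = 1.0 s, T2 = 140 ms; amide T1 = 1 s, T2 = 10 ms; NOE
T1 = 1 s, T2 = 5 ms) and subtracts it from an idealized one-pool spectrum
at the pool's offset, in percent of S0.

## Synthetic data

The generator emulates two study conditions:

* **BSA/agarose tube phantoms** (`make_pool_system("bsa_agarose")`,
  `phantom_layout()`, `generate_phantom_image()`): amide and NOE fractions
  scale linearly with BSA (6e-4 and 1.2e-3 per % w/v), a Gaussian-lineshape
  semisolid pool scales with agarose (0.015 per % w/v), and water
  relaxation rates rise linearly with both. These coefficients are a
  documented synthetic convention -- chosen once so that 9% w/v BSA yields
  an amide fraction comparable to the brain template -- not a measured
  calibration; only the monotone ordering matters to the experiments
  downstream. The default layout is the six-tube variable-BSA series (0,
  1.8, 3.6, 6, 7.2, 9% w/v).
* **A white-matter-like seven-pool spectrum**
  (`make_pool_system("brain_7pool")`): water, amide (+3.5 ppm, 30 1/s),
  creatine/guanidinium (+2 ppm, 1000 1/s), three relayed-NOE pools (-1.75,
  -2.5, -3.5 ppm, 16 1/s) and a super-Lorentzian semisolid pool with
  PSR = 20% and k_MF = 23 1/s. The values are literature-style white-matter
  parameters; the amide fraction (0.0053) is calibrated once so that the
  true amide MTR* under the simulation scheme is 11.0%. A five-pool variant
  adds a fast hydroxyl pool (+1 ppm, 2000 1/s) to probe overfitting.

Phantom images add Gaussian noise on the normalized signal (high-SNR
magnitude regime; Rician noise is out of scope) and optional smooth
polynomial B0/B1 fields. Generation is deterministic given a seed, via an
RNG stream isolated from the caller's. What passing tests on these
phantoms do **not** show: robustness to Rician noise floors, partial-volume
tube edges, motion, or imperfect spoiling -- none of which the generator
emulates.

## The bias experiments

`run_seven_pool_bias()` simulates the seven-pool spectrum on a 36-offset
+/-5 ppm grid (180 deg flip) plus MT offsets at 7.5/15/30/60/100 ppm at 180
and 540 deg, fits the reduced three-pool model (water, amide, semisolid)
and reports fitted versus true PSR and amide MTR*. With the packaged
parameters the reduced fit reproduces the spectrum to ~0.014 RMS yet its
amide MTR* is biased low by >40% -- underfitting pushes unmodeled NOE and
creatine saturation into the remaining pools. The PSR estimate sits on a
nearly flat posterior ridge that trades PSR against k_MF (and water T2):
constraining PSR 25% below its maximum-posterior value costs almost no
residual. Where an estimator lands on that ridge is therefore decided by
the inference machinery rather than the data; the MAP mode used here lands
above the true PSR, and variational schemes with other priors can land
below it. This sensitivity is itself a finding about underfitted CEST+MT
models: once the model is wrong, even the sign of the PSR bias is an
artifact of the estimator.

`bootstrap_offset_removal()` refits a two-pool model while removing 10
pseudo-random CEST offsets at a time (nested subsets, so the bias trend is
interpretable; the removal seed is recorded), always retaining the MT
offsets, and compares against a qMT-only fit, using the full-data B0
posterior as prior for the reduced fits. Whether the paper-style subsets
are nested or independently redrawn is an open convention; nesting was
chosen for monotone interpretability.

## Problem sizes and numerics

The shipped tests and the acceptance script use: single-spectrum fits on
the 41-offset dual-power schedule; 50 noisy replicates for parameter
recovery (each run from the prior-mean start with an 80-iteration
quasi-Newton budget and without the Laplace step, which changes the PSR
point estimate by well under 1%); 20 (tests) or 10 (script) bootstrap
replicates; 100 randomized systems for the steady-state property check;
the six-tube phantom series.
These sizes keep every experiment to minutes on one core while leaving the
Monte Carlo error well inside the asserted tolerances. Convergence
tolerances: iterated-cycle oracle 1e-12, shaped-pulse shot convergence
1e-8 with an error (reporting the residual) on non-convergence, optimizer
factr 1e7 with finite-difference steps of 1e-5 in standardized
coordinates.

## Known limitations

* The estimator is a mode-finder; in flat-ridge regimes (underfitted
  models, single saturation power) the reported Laplace sd understates the
  ridge direction and point estimates inherit estimator-dependence, as
  discussed above. Multiple saturation powers over the CEST band would
  break the M0r-k degeneracy.
* Exchange is water-centric; solute-solute exchange terms are not modelled.
* No spatial regularization: voxels are independent.
* Dipolar order, orientation-dependent lineshapes, imperfect spoiling and
  relaxation during excitation are out of scope.
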