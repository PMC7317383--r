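# cestmt

Quantitative modelling of chemical exchange saturation transfer (CEST) and
magnetization transfer (MT) Z-spectra, for researchers who fit multi-pool
exchange models to saturation-transfer MRI data and need to know when a
too-simple model silently corrupts the answer.

## The problem and the model

A Z-spectrum is the normalized water signal `Z(Δω) = S(Δω)/S0` acquired
while saturating at a series of frequency offsets. Dilute labile protons
(amides at +3.5 ppm, relayed-NOE aliphatic protons near −3.5 ppm) and the
broad semisolid macromolecular pool all deposit saturation into water, so
every pool contributes to every point of the spectrum. `cestmt` models N
exchanging pools with the coupled Bloch–McConnell equations

    dM/dt = (R_L + W(Δω, ω₁)) M + b,

where `R_L` carries relaxation and water-centric exchange (detailed balance
`k_FS = k_SF · M0r_S`), and `W` carries precession, the `±ω₁` saturation
coupling for mobile pools, and the absorption-lineshape rate
`π ω₁² g(Δ, T2M)` (Lorentzian, Gaussian, or super-Lorentzian) for semisolid
pools. A pulsed acquisition is one affine map per interval — saturation
train (continuous-wave-equivalent amplitude), spoiling, free precession,
excitation by `α` — and the measured magnetization is the fixed point of
their composition, solved in closed form and verified against a
time-stepped integrator of the shaped pulse train.

Voxel-wise estimation is maximum-a-posteriori with log-normal priors on
pool parameters (per pool: relative concentration `M0r`, exchange rate `k`,
`T2`; water `T2` and `T1` with the T1 prior set to the observed T1), a
normal prior on the B0 shift, a per-voxel B1 scale, and Laplace posterior
standard deviations. Derived metrics are the semisolid pool size ratio
(PSR = semisolid `M0r`) and the model-derived CEST effect size MTR* (the
fitted pool inserted into an idealized two-pool simulation, compared with a
one-pool water spectrum at the pool offset).

The package's headline experiments quantify underfitting bias: fitting a
three-pool model to a seven-pool white-matter-like spectrum biases both the
amide MTR* and the PSR, and a bootstrap that removes CEST offsets from a
two-pool qMT analysis shows the PSR bias growing with the amount of
unmodeled CEST data.

## Worked example

Simulate the 6% w/v BSA / 0.65% w/v agarose tube under the default sequence
(fifty 20-ms Gaussian pulses, 50% duty, 184° saturation flip, 2.375-s
shots; 41 CEST offsets plus dual-power MT offsets), add noise, and fit the
four-pool model:

```r
library(cestmt)
truth    <- make_pool_system("bsa_agarose", c(bsa = 6, agarose = 0.65))
scheme   <- saturation_scheme()
schedule <- schedule_invivo()
z <- simulate_zspectrum(truth, scheme, schedule)
set.seed(1)
z$z <- z$z + rnorm(nrow(z), sd = 0.005)
fit <- cest_fit(z, schedule, scheme, make_pool_system("bsa_agarose"),
                variant = "cest_mt", t1_obs = truth$pools[[1]]$t1, seed = 1)
summary(fit)
psr(fit, percent = TRUE)
fit_mtr_star(fit, "amide")
```

```
CEST/MT fit summary (variant 'cest_mt')
 parameter       mean        sd prior_mean fitted
  water.t2  1.918e-01 2.269e-02   0.190476   TRUE
  water.t1  2.067e+00 2.408e-01   2.072539   TRUE
 amide.m0r  2.647e-03 8.858e-04   0.003600   TRUE
   amide.k  4.852e+01 2.631e+01  30.000000   TRUE
  amide.t2  9.130e-03 2.026e-03   0.010000   TRUE
   noe.m0r  9.170e-03 7.179e-03   0.007200   TRUE
     noe.k  1.151e+01 1.083e+01  16.000000   TRUE
    noe.t2  6.003e-03 4.037e-03   0.005000   TRUE
    MT.m0r  1.165e-02 4.718e-03   0.009750   TRUE
      MT.k  7.249e+00 8.984e+00  40.000000   TRUE
     MT.t2  1.397e-05 2.644e-06   0.000012   TRUE
        b0 -1.644e-03 2.386e-03   0.000000   TRUE
PSR: 1.17%
Residual RMS 0.003753; B0 -0.0016 ppm; converged
[1] 1.165252
[1] 8.146399
```

Reading the output: the fitted PSR (1.17%) recovers the generated semisolid
fraction (0.975%) within its posterior uncertainty; the amide MTR* of 8.2%
is the idealized-model CEST effect size implied by the fitted amide
concentration and exchange rate; `mean`/`sd` columns are posterior means
and Laplace standard deviations, and wide `sd` on the exchange rates
reflects the familiar `M0r`–`k` degeneracy of single-power CEST data.

The underfitting experiment runs in one call and prints fitted versus true
PSR and amide MTR*:

```r
run_seven_pool_bias()
```

A command-line surface over the same functions is available via
`inst/cli/cestmt.R` (subcommands `simulate`, `fit`, `mtrstar`, `bootstrap`,
`phantom`, `bias-sim`).

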