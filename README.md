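# ivrkit

Analytics for *in vitro* release (IVR) testing of oil-solution parenterals
monitored in situ by fiber-optic UV-Vis spectrometry.

Prolonged-release oil depots (a drug dissolved in a vegetable oil with a
cosolvent, held in a dialysis bag inside a stirred USP II vessel) have no
standardized release test. A fiber-optic probe immersed in the medium
records a full absorbance spectrum at every time point, so release can be
followed in real time — but excipients that slowly cross the membrane at
late time points absorb at the drug's analysis wavelength and push the
apparent release above 100 %. `ivrkit` implements the data side of such a
method for a dexamethasone-like absorber (band maximum near 241 nm):

- **Spectral core** — a long-format CSV data model for per-vessel
  time-resolved spectra, lossless round-trip I/O, linear resampling, and
  medium-baseline subtraction.
- **Release quantification** — percent released by single-wavelength
  calibration,
  `F(t) = 100 · A_sample(λ, t) / A_standard(λ)`,
  and by **first-derivative spectroscopy**,
  `F(t) = 100 · D_sample(λ*, t) / D_standard(λ*)`,
  where `D = dA/dλ` is a Savitzky–Golay smoothing derivative and `λ*` is
  the derivative extreme of the standard (the band inflection, 252 nm for
  a Gaussian band centred at 241 nm with σ = 11 nm). Differentiation
  annihilates spectrally flat excipient contributions, so the derivative
  ratio is immune to the late-time interference that corrupts the
  single-point readout. Per-probe standards at the 100 %-release
  concentration (`dose / medium volume`) convert absorbance to percent.
- **Partitioning and sink conditions** — the mass-balance apparent
  partition coefficient
  `P_app = (c_i·V_u − c_v·V_v) / (c_v·V_u)`,
  the measured oil/aqueous concentration ratio, log10 P, and the minimum
  sink volume `factor · dose / solubility`.
- **Release kinetics** — deterministic least-squares fits of the
  first-order model `F(t) = f_inf·(1 − e^(−kt))` and the biphasic model
  `F(t) = a·(1 − e^(−k₁t)) + m·t` (fast cosolvent-assisted phase plus a
  linear terminal phase under sink conditions), and the f2 similarity
  factor `f2 = 50·log10(100 / sqrt(1 + mean((R−T)²)))`.
- **Synthetic data** — a seeded generator producing spectral runs with
  known ground truth: Gaussian drug band, near-flat placebo term rising
  linearly after a late onset, biphasic kinetics with temperature (Q10)
  and stirring (power-law) rate modifiers, and per-vessel Gaussian noise.

## Worked example

Simulate a 72 h run with placebo leakage starting at 48 h, quantify it
both ways, and fit the kinetics:

```r
library(ivrkit)

params <- simulation_params(seed = 101)           # defaults mimic the 72 h study
run <- synthesize_run(run_config(), params, n_vessels = 6,
                      times = ivr_sampling_times(72))

single <- aggregate_vessels(mapply(percent_released_single, run$series,
                                   run$standards, SIMPLIFY = FALSE))
deriv  <- aggregate_vessels(mapply(percent_released_derivative, run$series,
                                   run$standards, SIMPLIFY = FALSE))
single
#> <release_profile> [single_point] 20 times (5-4320 min), final 109.0 % (sd 0.22)
deriv
#> <release_profile> [first_derivative] 20 times (5-4320 min), final 99.8 % (sd 0.72)
```

At the late time points the single-point readout drifts past 100 % while
the derivative-corrected profile stays on the simulator's ground truth:

```
 time_h truth single derivative
     48  88.8   88.9       89.5
     60  96.0  100.5       95.8
     72 100.0  109.0       99.8
```

```r
fit_biphasic(deriv)
#> <biphasic_fit> a = 61.13 %, k1 = 0.004875 /min, m = 0.009335 %/min, t_break = 614.6 min, rss = 7.99
```

The fitted slope-change point (`t_break`, where the fast phase reaches
95 % of its amplitude) falls at ~10 h, between 6 and 12 h as expected for
these kinetics. Partitioning from a 1:1-volume shake-flask experiment
with `c_i` = 1 mg/mL and an equilibrium aqueous concentration of
0.028 mg/mL:

```r
pexp <- partition_experiment(c_i = 1, c_v = 0.028, V_u = 1, V_v = 1)
log_partition(apparent_partition_coefficient(pexp))
#> P_app = 34.71   log P = 1.54
```

A log P above 1 is the usual screen for a formulation able to sustain
prolonged release.

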