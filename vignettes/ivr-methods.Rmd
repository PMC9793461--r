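---
title: "Methods: derivative-corrected in vitro release analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: derivative-corrected in vitro release analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivrkit)
```

## The measurement problem

An oil-solution depot formulation is held in a dialysis bag inside a
stirred dissolution vessel; a fiber-optic UV-Vis probe immersed in the
medium records an absorbance spectrum `A(λ, t)` at each sampling time.
Because the probe is never removed and the medium never sampled, the
readout is continuous and automated — but also unfiltered: anything that
crosses the membrane and absorbs near the drug's band contributes to
`A`. For a dexamethasone-like drug quantified at its 241 nm band
maximum, oil excipients leaking through the membrane at late time points
inflate the apparent release, eventually past 100 %.

`ivrkit` implements the two quantification routes and the correction:

1. **Single-point**: `F(t) = 100 · A(λ₀, t) / A_std(λ₀)` with λ₀ = 241 nm,
   where `A_std` is the spectrum of a standard solution prepared at
   exactly the 100 %-release concentration `dose / medium volume`
   (`full_release_concentration()`), measured per probe. Simple, fast,
   interference-prone.
2. **First-derivative**: `F(t) = 100 · D(λ*, t) / D_std(λ*)` where
   `D = dA/dλ`. A wavelength-constant contribution differentiates to
   zero exactly, and a spectrally flat (small-slope) one is strongly
   suppressed, so a featureless excipient background drops out of the
   ratio. λ* is the extreme of `|D_std|` — for a Gaussian-like band the
   inflection at center + σ, selected by `select_analysis_wavelength()`
   within a configurable window (default 245–265 nm, which brackets the
   long-wavelength inflection of a 241/11 nm band at 252 nm while
   excluding the short-wavelength limb where backgrounds are less flat).

Both routes return unclamped percentages: values above 100 % are the
diagnostic signature of interference and must not be hidden. Signed
derivative ratios are used, not magnitudes, so that a negative-slope
extreme still yields positive percentages (the signs cancel between
sample and standard).

## Numerical choices

**Derivative estimator.** Savitzky–Golay polynomial smoothing
derivatives (`signal::sgolayfilt`), default window 7 points and
polynomial order 2 on the 1 nm grid, edge points from one-sided fits.
This is the de facto standard for noisy diode-array spectra. The
quadratic fit carries a bias proportional to the third spectral
derivative (≈ 2 % of the peak derivative for the 241/11 nm Gaussian
band); this bias is *common to sample and standard* and cancels in the
ratio, which is what the method reports. Where fidelity to an analytic
derivative itself is wanted (the test-suite oracle), raise `poly_order`
to 5: the measured deviation then drops below 1e-4 of the peak
derivative magnitude. Second derivatives are implemented
(`order = 2`) but not the default: every differentiation step narrows
the usable dynamic range, and the first derivative already removes flat
backgrounds.

**Flatness guard.** A standard whose derivative magnitude stays below
1e-4 AU/nm throughout the search window has no usable extreme and
raises an error rather than returning an arbitrary wavelength. The
threshold is an order of magnitude below the synthetic standard's
inflection derivative (≈ 4.4e-2 AU/nm). Ties in `|D|` break toward the
longest wavelength, deterministically.

**Grids.** Wavelengths in nm on a strictly increasing grid; derivative
operations require uniform spacing and refuse non-uniform grids
(resample first — linear interpolation, extrapolation refused). Times
are minutes as non-negative reals. Baseline correction subtracts the
medium spectrum pointwise and keeps negative residuals: clamping at
zero would bias derivative ratios near zero absorbance.

**Kinetics fits.** `fit_first_order()` fits `F = f_inf (1 − e^(−kt))`
by unweighted Levenberg–Marquardt (`minpack.lm`) with bounds
`f_inf ≥ 0, k > 0`. The initializer is deterministic: `f_inf⁰` is the
maximum observed percent, `k⁰` the log-linear slope of the first half
of the points, screened over the fixed multiplier grid {0.3, 1, 3} by
residual sum of squares; there are no random restarts, so the same data
always give the same fit, and the returned RSS never exceeds the best
screened start. Unweighted least squares matches how such profiles are
reported (plain SD error bars, no variance model). The degenerate
all-zero profile, where `k` is unidentifiable, returns
`f_inf = 0, k = NA, identifiable = FALSE` rather than an error.
`fit_biphasic()` fits `F = a(1 − e^(−k₁t)) + m·t` with `m ≥ 0` and
includes the first-order solution (`m = 0`) among its starts, which
guarantees the nested-model property RSS(biphasic) ≤ RSS(first-order).
The slope-change point is reported as `t_break = −ln(0.05)/k₁`, the
time at which the fast phase reaches 95 % of its amplitude.

**f2 similarity.** `f2 = 50·log10(100/√(1 + mean((R−T)²)))` over all
shared points by default; the conventional regulatory truncation
(keep at most one point after the reference first reaches 85 %) is
available via `regulatory = TRUE` but is off by default — desk-scale
transparency first, convention second.

**Partitioning.** The apparent partition coefficient uses the
mass-balance form `P_app = (c_i·V_u − c_v·V_v)/(c_v·V_u)`: the drug not
assayed in the aqueous phase must still be in the oil phase, so the
numerator over `V_u` is the equilibrium oil-phase concentration. This
form uses exactly the four quantities a shake-flask experiment records.
The directly measured oil/aqueous ratio is kept separate
(`partition_ratio()`). `c_v = 0` signals unbounded partitioning
explicitly. Sink volume is `factor · dose / solubility` with the factor
configurable (default 3, the classical pharmacopoeial usage) — reported
pharmacopoeial volumes in the literature are not always reconstructible
from a stated solubility and a single standard factor, so no factor is
hard-coded to match any particular printed volume; `is_sink()` uses a
closed lower bound.

## What the simulator emulates

`synthesize_run()` builds, per vessel,

```
A(λ, t) = truth(t)/100 · drug(λ) + amp(t) · placebo(λ) + ε,
ε ~ N(0, noise_sd²) independent per (vessel, λ, t),
```

with noise-free per-probe standards and a zero medium spectrum (the
baseline is treated as already subtracted). Defaults, chosen once to
represent the study conditions this pipeline targets:

| Parameter | Default | Why |
|---|---|---|
| `drug_peak_center`, `drug_peak_sd` | 241 nm, 11 nm | band maximum near 241 nm; σ = 11 puts the inflection at 252 nm, making wavelength selection analytically checkable |
| `drug_peak_absorbance` | 0.8 AU | typical on-scale peak for a 20 mm path at the 100 % concentration |
| `release_a`, `release_k1`, `release_m` | 60 %, 0.005 /min, 0.01 %/min | fast phase 95 %-complete at ≈ 10 h (inside the observed 6–12 h slope change), ≈ 89 % at 48 h, plateau > 90 % before 72 h |
| `placebo_onset`, `placebo_rate` | 2880 min, 5e-5 AU/min | interference visible from 48 h; ≈ 9 % single-point excess at 72 h |
| `placebo_tilt` | 1e-3 AU/nm | near-flat background; at realistic leakage amplitudes (< 0.08 AU) its derivative carries < 0.2 % into the ratio |
| `noise_sd` | 0.002 AU | quiet in-situ probe; per-vessel derivative noise ≈ 0.9 % of full scale |
| `temperature_q10`, `rpm_exponent` | 2, 0.3 | release slows markedly when cooled, mildly when stirred slower |
| sampling schedule | 5…1440 min (16 points), then every 12 h | the dense development schedule plus long-run extension |

Randomness contract: one integer seed; per-vessel streams are derived
from it deterministically, so identical seeds reproduce runs
byte-for-byte while vessels remain independent. Fixture scenarios
(`make_fixture_dataset()`: `baseline_48h`, `placebo_leakage_72h`,
`temperature_pair`, `rpm_pair`, `volume_pair`) write the CSV formats
the readers consume, plus ground truth and a JSON config snapshot.

**What it does not emulate.** The placebo term is linear-in-time after
onset (the simplest monotone model for a gradually leaking excipient)
with a fixed spectral shape; real leakage kinetics, curved excipient
spectra, light scattering from air bubbles or particles, probe fouling,
and membrane transport physics (MWCO enters only as a label and a rate
modifier) are out of scope. Temperature and stirring enter as
phenomenological multipliers, not mechanistic models. A passing test
suite therefore demonstrates that the *algorithms* are correct under
the stated statistical structure — additive near-flat interference plus
homoscedastic noise — not that any real formulation follows these
kinetics. Problem sizes in the tests and acceptance script (6 vessels,
16–20 time points, 101 wavelengths, 20 Monte-Carlo repetitions) are the
package's chosen desk-scale study conditions.

## Known limitations

- Single-component calibration only: no multivariate (CLS/PLS)
  calibration, so overlapping *structured* interferents are not
  separable — only flat-ish backgrounds cancel.
- The derivative ratio assumes sample and standard share the band shape;
  solvatochromic shifts between standard matrix and release medium
  would bias it.
- The biphasic model is descriptive; it does not resolve cosolvent
  efflux mechanistically, and `t_break` is a model-derived summary,
  not an observed changepoint.
- The Gaussian drug band is a surrogate: no claim is made that it
  matches any real spectrum quantitatively; it exists so that every
  selection and correction step has a closed-form reference.
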