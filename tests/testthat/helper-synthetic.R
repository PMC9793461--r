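# Shared fixture builders: everything is generated in code at test time.

# Gaussian absorption band on a grid (the drug-surrogate shape).
gaussian_band <- function(grid, center = 241, sd = 11, peak = 0.8) {
  peak * exp(-(grid - center)^2 / (2 * sd^2))
}

# Analytic first derivative of the Gaussian band, AU/nm.
gaussian_band_deriv <- function(grid, center = 241, sd = 11, peak = 0.8) {
  -peak * (grid - center) / sd^2 * exp(-(grid - center)^2 / (2 * sd^2))
}

# A small deterministic spectral series: percent-scaled copies of a base
# spectrum at the given times.
scaled_series <- function(vessel = "v1", times, fractions, base_spec) {
  A <- outer(fractions, base_spec$absorbance)
  spectral_series(vessel, times, base_spec$wavelength, A)
}

default_standard <- function(grid = 200:300) {
  spectrum(grid, gaussian_band(grid))
}

default_calibration <- function(grid = 200:300) {
  probe_calibration("p1", default_standard(grid), 0.004)
}
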