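#' Per-probe calibration against a 100 %-release standard
#'
#' Each fiber-optic probe is calibrated against a standard solution whose
#' concentration equals the drug concentration in the medium at complete
#' release; absorbance readings are then expressed as percent released by
#' direct ratio against that standard.
#'
#' @param probe_id Character label of the probe.
#' @param standard_spectrum Baseline-corrected `spectrum` of the standard
#'   solution measured through this probe.
#' @param standard_concentration Nominal concentration, mg/mL (the 100 %
#'   release concentration; see [full_release_concentration()]).
#' @return An object of class `probe_calibration`.
#' @export
probe_calibration <- function(probe_id, standard_spectrum,
                              standard_concentration) {
  stopifnot(inherits(standard_spectrum, "spectrum"))
  standard_concentration <- as.numeric(standard_concentration)[1]
  if (!is.finite(standard_concentration) || standard_concentration <= 0) {
    stop("standard concentration must be positive (mg/mL)", call. = FALSE)
  }
  structure(list(probe_id = as.character(probe_id)[1],
                 standard_spectrum = standard_spectrum,
                 standard_concentration = standard_concentration),
            class = "probe_calibration")
}

#' Concentration at 100 % release
#'
#' The medium concentration reached if the full dose dissolves; standard
#' solutions are prepared at exactly this concentration so that a sample to
#' standard absorbance ratio reads directly as percent released.
#'
#' @param dose_mass Drug mass in the dialysis bag, mg.
#' @param medium_volume Release-medium volume, mL.
#' @return Concentration in mg/mL.
#' @examples
#' full_release_concentration(2, 500) # 0.004 mg/mL
#' @export
full_release_concentration <- function(dose_mass, medium_volume) {
  if (!is.finite(dose_mass) || dose_mass <= 0 ||
      !is.finite(medium_volume) || medium_volume <= 0) {
    stop("dose mass and medium volume must be positive", call. = FALSE)
  }
  dose_mass / medium_volume
}

#' Construct a release profile
#'
#' Percent released over time, optionally with an across-vessel standard
#' deviation. Values are deliberately not clamped to \[0, 100\]: readings
#' above 100 % are the very signature of excipient interference that the
#' derivative method is designed to expose and remove.
#'
#' @param times Sampling times, minutes.
#' @param percent_released Percent released per time.
#' @param sd Optional standard deviation per time (>= 0).
#' @param method One of `"single_point"`, `"first_derivative"`,
#'   `"second_derivative"`, `"simulated_truth"`.
#' @return An object of class `release_profile`.
#' @export
release_profile <- function(times, percent_released, sd = NULL,
                            method = c("single_point", "first_derivative",
                                       "second_derivative", "simulated_truth")) {
  method <- match.arg(method)
  times <- as.numeric(times)
  percent_released <- as.numeric(percent_released)
  if (length(times) != length(percent_released)) {
    stop("times and percent_released lengths differ", call. = FALSE)
  }
  if (anyNA(times) || any(times < 0) ||
      (length(times) > 1L && any(diff(times) <= 0))) {
    stop("times must be non-negative and strictly increasing", call. = FALSE)
  }
  if (anyNA(percent_released) || any(!is.finite(percent_released))) {
    stop("percent_released contains non-finite values", call. = FALSE)
  }
  if (!is.null(sd)) {
    sd <- as.numeric(sd)
    if (length(sd) != length(times) || anyNA(sd) || any(sd < 0)) {
      stop("sd must be non-negative and match times in length", call. = FALSE)
    }
  }
  structure(list(times = times, percent_released = percent_released,
                 sd = sd, method = method),
            class = "release_profile")
}

#' @export
print.release_profile <- function(x, ...) {
  cat(sprintf("<release_profile> [%s] %d times (%g-%g min), final %.1f %%%s\n",
              x$method, length(x$times), min(x$times), max(x$times),
              x$percent_released[length(x$times)],
              if (is.null(x$sd)) "" else sprintf(" (sd %.2f)", x$sd[length(x$times)])))
  invisible(x)
}

#' Percent released by single-wavelength detection
#'
#' The classical fiber-optic readout: sample absorbance at the band
#' maximum (241 nm for dexamethasone) over the per-probe standard
#' absorbance at the same wavelength, times 100. Any absorber at that
#' wavelength — drug or leaking excipient — counts, which is exactly why
#' this readout drifts above 100 % at late time points.
#'
#' @param series Baseline-corrected `spectral_series`.
#' @param cal `probe_calibration` for the probe in this vessel.
#' @param wavelength Analysis wavelength in nm (default 241).
#' @return A `release_profile` with method `"single_point"`.
#' @export
percent_released_single <- function(series, cal, wavelength = 241) {
  stopifnot(inherits(series, "spectral_series"),
            inherits(cal, "probe_calibration"))
  a_std <- absorbance_at(cal$standard_spectrum, wavelength)
  if (a_std <= 0) {
    stop(sprintf("standard absorbance at %g nm is not positive; calibration unusable",
                 wavelength), call. = FALSE)
  }
  a_sample <- vapply(seq_along(series$times), function(i) {
    absorbance_at(series_spectrum(series, i), wavelength)
  }, numeric(1))
  release_profile(series$times, 100 * a_sample / a_std,
                  method = "single_point")
}

# Absorbance at an arbitrary wavelength: exact on grid, else linear
# interpolation (equivalent to resampling first).
absorbance_at <- function(spec, wavelength) {
  hit <- which(spec$wavelength == wavelength)
  if (length(hit)) return(spec$absorbance[hit[1]])
  resample_spectrum(spec, sort(c(wavelength - 1e-9, wavelength)))$absorbance[2]
}

#' Smoothed derivative of a spectrum
#'
#' Savitzky-Golay polynomial-smoothing derivative on a uniform wavelength
#' grid, the standard estimator for noisy diode-array spectra. Edge points
#' come from one-sided polynomial fits, so the result covers the full
#' grid. Units are AU/nm (order 1) or AU/nm^2 (order 2).
#'
#' The window/polynomial defaults (7 points, order 2) favour noise
#' suppression; raise `poly_order` (e.g. to 5) when bias against an
#' analytic reference matters more than noise. Fitting bias cancels in
#' sample/standard derivative ratios either way.
#'
#' @param spec A `spectrum` on a uniform grid.
#' @param order Derivative order, 1 or 2.
#' @param window_points Odd filter window length, >= `poly_order + 2` and
#'   <= grid length.
#' @param poly_order Fitting polynomial order, >= `order`.
#' @return A `spectrum` holding the derivative on the same grid.
#' @export
derivative_spectrum <- function(spec, order = 1, window_points = 7,
                                poly_order = 2) {
  stopifnot(inherits(spec, "spectrum"))
  order <- as.integer(order)
  if (!order %in% c(1L, 2L)) stop("derivative order must be 1 or 2", call. = FALSE)
  n <- as.integer(window_points)
  p <- as.integer(poly_order)
  if (n %% 2L == 0L) stop("window_points must be odd", call. = FALSE)
  if (n < p + 2L) stop("window_points must be >= poly_order + 2", call. = FALSE)
  if (p < order) stop("poly_order must be >= derivative order", call. = FALSE)
  if (n > length(spec$wavelength)) {
    stop("window larger than the wavelength grid", call. = FALSE)
  }
  h <- diff(spec$wavelength)
  if (max(h) - min(h) > 1e-9 * mean(h)) {
    stop("derivative requires a uniform wavelength grid; resample first",
         call. = FALSE)
  }
  d <- signal::sgolayfilt(spec$absorbance, p = p, n = n, m = order,
                          ts = mean(h))
  spectrum(spec$wavelength, d)
}

#' Locate the derivative extreme used for quantification
#'
#' Finds the wavelength where the magnitude of the standard's derivative
#' spectrum is largest inside a search window — for a band with maximum
#' near 241 nm this is the long-wavelength inflection, near 252 nm. Ties
#' break toward the longest wavelength. A flat derivative (no usable
#' extreme) is an error, not a silent pick.
#'
#' @param standard_derivative Derivative `spectrum` of the standard.
#' @param search_window Length-2 nm interval, default `c(245, 265)`.
#' @param flatness_threshold Minimum usable `max |derivative|` in the
#'   window, AU/nm (default 1e-4).
#' @return Analysis wavelength in nm (a grid point).
#' @export
select_analysis_wavelength <- function(standard_derivative,
                                       search_window = c(245, 265),
                                       flatness_threshold = 1e-4) {
  stopifnot(inherits(standard_derivative, "spectrum"))
  search_window <- sort(as.numeric(search_window))
  assert_grid_covers(standard_derivative$wavelength, search_window)
  inside <- standard_derivative$wavelength >= search_window[1] &
    standard_derivative$wavelength <= search_window[2]
  lam <- standard_derivative$wavelength[inside]
  mag <- abs(standard_derivative$absorbance[inside])
  if (max(mag) < flatness_threshold) {
    stop(sprintf(
      "no usable extreme: max |derivative| %.3g AU/nm in [%g, %g] nm is below the flatness threshold %.3g",
      max(mag), search_window[1], search_window[2], flatness_threshold),
      call. = FALSE)
  }
  # ties toward the longest wavelength
  best <- max(lam[mag == max(mag)])
  best
}

#' Percent released by derivative spectroscopy
#'
#' Interference-corrected readout: the ratio of the sample's smoothed
#' derivative to the standard's at the selected extreme wavelength, times
#' 100. Differentiation annihilates wavelength-constant contributions and
#' strongly suppresses spectrally flat ones, so slowly leaking excipients
#' with near-flat spectra drop out of the ratio. Signed values are used
#' (not magnitudes): on the descending limb both derivatives are negative
#' and the signs cancel, giving positive percentages.
#'
#' @param series Baseline-corrected `spectral_series`.
#' @param cal `probe_calibration`.
#' @param wavelength Analysis wavelength in nm; if `NULL`, chosen by
#'   [select_analysis_wavelength()] on the standard's derivative.
#' @param order Derivative order, 1 (default) or 2. The second derivative
#'   is supported but its usable dynamic range is much narrower, which is
#'   why the first derivative is the default.
#' @param window_points,poly_order Savitzky-Golay settings, see
#'   [derivative_spectrum()].
#' @param search_window Window passed to [select_analysis_wavelength()]
#'   when `wavelength` is `NULL`.
#' @param flatness_threshold Minimum usable standard derivative magnitude
#'   at the analysis wavelength, AU/nm.
#' @return A `release_profile` with method `"first_derivative"` or
#'   `"second_derivative"`.
#' @export
percent_released_derivative <- function(series, cal, wavelength = NULL,
                                        order = 1, window_points = 7,
                                        poly_order = 2,
                                        search_window = c(245, 265),
                                        flatness_threshold = 1e-4) {
  stopifnot(inherits(series, "spectral_series"),
            inherits(cal, "probe_calibration"))
  std_deriv <- derivative_spectrum(cal$standard_spectrum, order = order,
                                   window_points = window_points,
                                   poly_order = poly_order)
  if (is.null(wavelength)) {
    wavelength <- select_analysis_wavelength(std_deriv, search_window,
                                             flatness_threshold)
  }
  d_std <- absorbance_at(std_deriv, wavelength)
  if (abs(d_std) < flatness_threshold) {
    stop(sprintf(
      "standard derivative at %g nm (%.3g AU/nm) is below the flatness threshold %.3g",
      wavelength, d_std, flatness_threshold), call. = FALSE)
  }
  d_sample <- vapply(seq_along(series$times), function(i) {
    ds <- derivative_spectrum(series_spectrum(series, i), order = order,
                              window_points = window_points,
                              poly_order = poly_order)
    absorbance_at(ds, wavelength)
  }, numeric(1))
  release_profile(series$times, 100 * d_sample / d_std,
                  method = if (order == 1) "first_derivative" else "second_derivative")
}

#' Pool release profiles across vessels
#'
#' Pointwise mean and sample standard deviation over replicate vessels,
#' the form in which IVR profiles are reported (mean +/- SD, n vessels).
#'
#' @param profiles List of >= 2 `release_profile`s on identical time grids
#'   with identical methods.
#' @return A `release_profile` with `sd` filled in.
#' @export
aggregate_vessels <- function(profiles) {
  if (!is.list(profiles) || length(profiles) < 2L) {
    stop("need at least two vessel profiles to aggregate", call. = FALSE)
  }
  for (p in profiles) stopifnot(inherits(p, "release_profile"))
  t0 <- profiles[[1]]$times
  m0 <- profiles[[1]]$method
  for (p in profiles[-1]) {
    if (length(p$times) != length(t0) || any(p$times != t0)) {
      stop("vessel profiles have mismatched time grids", call. = FALSE)
    }
    if (!identical(p$method, m0)) {
      stop("vessel profiles have mismatched methods", call. = FALSE)
    }
  }
  M <- do.call(rbind, lapply(profiles, `[[`, "percent_released"))
  release_profile(t0, colMeans(M), sd = apply(M, 2L, stats::sd), method = m0)
}

#' Read a release profile from CSV
#'
#' Expects columns `time_min,percent_released,sd,method` (`sd` may be
#' empty).
#'
#' @param path CSV file path.
#' @return A `release_profile`.
#' @export
read_release_profile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("time_min", "percent_released", "method"), names(df))
  if (length(missing)) {
    stop("malformed release profile file, missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sd <- if ("sd" %in% names(df) && !all(is.na(df$sd))) df$sd else NULL
  release_profile(df$time_min, df$percent_released, sd = sd,
                  method = df$method[1])
}

#' Write a release profile to CSV
#'
#' @param profile A `release_profile`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_release_profile <- function(profile, path) {
  stopifnot(inherits(profile, "release_profile"))
  df <- data.frame(time_min = profile$times,
                   percent_released = profile$percent_released,
                   sd = if (is.null(profile$sd)) NA_real_ else profile$sd,
                   method = profile$method)
  utils::write.csv(format_num_df(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
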