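#' Default analysis wavelength grid
#'
#' Fiber-optic diode-array scans in this workflow cover 200-300 nm; the
#' default grid is that window at 1 nm spacing, which puts the usual
#' analysis wavelengths (241 nm band maximum, 252 nm derivative extreme)
#' exactly on grid points.
#'
#' @param from,to Window bounds in nm.
#' @param by Grid spacing in nm.
#' @return Numeric vector of wavelengths (nm), validated.
#' @export
default_grid <- function(from = 200, to = 300, by = 1) {
  wavelength_grid(seq(from, to, by = by))
}

#' Validate a wavelength grid
#'
#' A grid is a strictly increasing vector of positive wavelengths in nm.
#'
#' @param values Numeric vector of wavelengths (nm).
#' @return The validated numeric vector.
#' @export
wavelength_grid <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("wavelength grid needs at least two points", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("wavelength grid contains non-finite values", call. = FALSE)
  }
  if (any(values <= 0)) {
    stop("wavelengths must be positive (nm)", call. = FALSE)
  }
  if (any(diff(values) <= 0)) {
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  }
  values
}

#' Require that a grid covers an analysis window
#'
#' @param grid Wavelength grid (nm).
#' @param window Length-2 numeric, the requested window in nm.
#' @return Invisibly, the grid.
#' @export
assert_grid_covers <- function(grid, window) {
  grid <- wavelength_grid(grid)
  window <- sort(as.numeric(window))
  if (min(grid) > window[1] || max(grid) < window[2]) {
    stop(sprintf(
      "wavelength grid [%g, %g] nm does not cover requested window [%g, %g] nm",
      min(grid), max(grid), window[1], window[2]
    ), call. = FALSE)
  }
  invisible(grid)
}

#' Construct a single UV-Vis spectrum
#'
#' @param wavelength Wavelength grid in nm (strictly increasing, positive).
#' @param absorbance Absorbance in AU, one finite value per grid point.
#' @return An object of class `spectrum`: a list with elements
#'   `wavelength` and `absorbance`.
#' @examples
#' s <- spectrum(200:300, exp(-((200:300) - 241)^2 / (2 * 11^2)))
#' @export
spectrum <- function(wavelength, absorbance) {
  wavelength <- wavelength_grid(wavelength)
  absorbance <- as.numeric(absorbance)
  if (length(absorbance) != length(wavelength)) {
    stop("absorbance length must equal grid length", call. = FALSE)
  }
  if (anyNA(absorbance) || any(!is.finite(absorbance))) {
    stop("absorbance contains non-finite values", call. = FALSE)
  }
  structure(list(wavelength = wavelength, absorbance = absorbance),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %g-%g nm, A in [%.4g, %.4g] AU\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              min(x$absorbance), max(x$absorbance)))
  invisible(x)
}

#' Construct a time-indexed spectral series for one vessel
#'
#' Raw output of an in-situ fiber-optic probe: one full spectrum per
#' sampling time, all on a shared wavelength grid.
#'
#' @param vessel_id Character label of the vessel/probe.
#' @param times Sampling times in minutes, non-negative, strictly increasing.
#' @param wavelength Shared wavelength grid (nm).
#' @param absorbance Numeric matrix, `length(times)` rows by
#'   `length(wavelength)` columns, in AU.
#' @return An object of class `spectral_series`.
#' @export
spectral_series <- function(vessel_id, times, wavelength, absorbance) {
  vessel_id <- as.character(vessel_id)[1]
  times <- as.numeric(times)
  wavelength <- wavelength_grid(wavelength)
  absorbance <- as.matrix(absorbance)
  if (anyNA(times) || any(times < 0)) {
    stop("times must be non-negative minutes", call. = FALSE)
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (nrow(absorbance) != length(times) ||
      ncol(absorbance) != length(wavelength)) {
    stop("absorbance must be a times x wavelengths matrix", call. = FALSE)
  }
  if (anyNA(absorbance) || any(!is.finite(absorbance))) {
    stop("absorbance contains non-finite values", call. = FALSE)
  }
  storage.mode(absorbance) <- "double"
  dimnames(absorbance) <- NULL
  structure(list(vessel_id = vessel_id, times = times,
                 wavelength = wavelength, absorbance = absorbance),
            class = "spectral_series")
}

#' @export
print.spectral_series <- function(x, ...) {
  cat(sprintf("<spectral_series> vessel '%s': %d times (%g-%g min), %d wavelengths (%g-%g nm)\n",
              x$vessel_id, length(x$times), min(x$times), max(x$times),
              length(x$wavelength), min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' Extract one spectrum from a series
#'
#' @param series A `spectral_series`.
#' @param i Time index.
#' @return A `spectrum`.
#' @export
series_spectrum <- function(series, i) {
  stopifnot(inherits(series, "spectral_series"))
  i <- as.integer(i)
  if (i < 1L || i > length(series$times)) stop("time index out of range", call. = FALSE)
  spectrum(series$wavelength, series$absorbance[i, ])
}

#' Dissolution run configuration
#'
#' @param medium_volume Release-medium volume in mL.
#' @param dose_mass Drug mass loaded into the dialysis bag, mg.
#' @param temperature Bath temperature, degrees C (sanity bound 4-60).
#' @param stirring_rate Paddle speed, rpm.
#' @param membrane_mwco Dialysis membrane molecular-weight cut-off, kDa.
#' @param sample_volume Formulation volume in the bag, mL.
#' @return An object of class `run_config`.
#' @examples
#' run_config(medium_volume = 500, dose_mass = 2)
#' @export
run_config <- function(medium_volume = 500, dose_mass = 2, temperature = 37,
                       stirring_rate = 75, membrane_mwco = 300,
                       sample_volume = 1) {
  vals <- c(medium_volume = medium_volume, dose_mass = dose_mass,
            temperature = temperature, stirring_rate = stirring_rate,
            membrane_mwco = membrane_mwco, sample_volume = sample_volume)
  if (anyNA(vals) || any(vals <= 0)) {
    stop("all run configuration values must be positive", call. = FALSE)
  }
  if (temperature < 4 || temperature > 60) {
    stop("temperature outside sanity bounds [4, 60] degrees C", call. = FALSE)
  }
  structure(as.list(vals), class = "run_config")
}

# ---- file I/O ---------------------------------------------------------------
# Canonical long format: vessel,time_min,wavelength_nm,absorbance (comma
# separated, dot decimal, mandatory header). Single spectra (medium,
# standards) use wavelength_nm,absorbance.

#' Read spectral series from a long-format CSV
#'
#' Expects columns `vessel,time_min,wavelength_nm,absorbance`. Every
#' (vessel, time) block must yield the same wavelength grid within a vessel.
#'
#' @param path CSV file path.
#' @return Named list of `spectral_series`, one per vessel, names being
#'   vessel ids.
#' @export
read_spectral_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("vessel", "time_min", "wavelength_nm", "absorbance")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("malformed spectral series file, missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) return(structure(list(), names = character()))
  out <- list()
  for (v in unique(df$vessel)) {
    sub <- df[df$vessel == v, , drop = FALSE]
    times <- sort(unique(sub$time_min))
    grids <- lapply(times, function(t) {
      sort(sub$wavelength_nm[sub$time_min == t])
    })
    ref <- grids[[1]]
    for (j in seq_along(times)) {
      if (!identical(length(grids[[j]]), length(ref)) ||
          any(grids[[j]] != ref)) {
        stop(sprintf(
          "inconsistent wavelength grid in vessel '%s' at time %g min",
          v, times[j]), call. = FALSE)
      }
    }
    A <- matrix(0, nrow = length(times), ncol = length(ref))
    for (j in seq_along(times)) {
      blk <- sub[sub$time_min == times[j], , drop = FALSE]
      blk <- blk[order(blk$wavelength_nm), , drop = FALSE]
      A[j, ] <- blk$absorbance
    }
    out[[as.character(v)]] <- spectral_series(v, times, ref, A)
  }
  out
}

#' Write spectral series to a long-format CSV
#'
#' Rows are ordered by (vessel, time, wavelength), deterministically.
#'
#' @param series A `spectral_series` or a list of them.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_spectral_series <- function(series, path) {
  if (inherits(series, "spectral_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    stopifnot(inherits(s, "spectral_series"))
    data.frame(
      vessel = s$vessel_id,
      time_min = rep(s$times, each = length(s$wavelength)),
      wavelength_nm = rep(s$wavelength, times = length(s$times)),
      absorbance = as.vector(t(s$absorbance)),
      stringsAsFactors = FALSE
    )
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(vessel = character(), time_min = numeric(),
               wavelength_nm = numeric(), absorbance = numeric())
  utils::write.csv(format_num_df(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a single spectrum from CSV
#'
#' Expects columns `wavelength_nm,absorbance`.
#'
#' @param path CSV file path.
#' @return A `spectrum`.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("wavelength_nm", "absorbance"), names(df))
  if (length(missing)) {
    stop("malformed spectrum file, missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[order(df$wavelength_nm), , drop = FALSE]
  spectrum(df$wavelength_nm, df$absorbance)
}

#' Write a single spectrum to CSV
#'
#' @param spec A `spectrum`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  df <- data.frame(wavelength_nm = spec$wavelength,
                   absorbance = spec$absorbance)
  utils::write.csv(format_num_df(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Full-precision ASCII rendering of numeric columns so CSV round-trips are
# lossless for representable doubles (17 significant digits, no padding).
format_num_df <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) {
      df[[nm]] <- ifelse(is.na(df[[nm]]), "NA",
                         sprintf("%.17g", df[[nm]]))
    }
  }
  df
}

# ---- spectral arithmetic ----------------------------------------------------

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; extrapolation outside the source span is refused.
#'
#' @param spec A `spectrum`.
#' @param target_grid Target wavelengths (nm), within the source span.
#' @return A `spectrum` on `target_grid`.
#' @export
resample_spectrum <- function(spec, target_grid) {
  stopifnot(inherits(spec, "spectrum"))
  target_grid <- wavelength_grid(target_grid)
  if (min(target_grid) < min(spec$wavelength) ||
      max(target_grid) > max(spec$wavelength)) {
    stop(sprintf(
      "target grid [%g, %g] nm extends beyond source span [%g, %g] nm (extrapolation refused)",
      min(target_grid), max(target_grid),
      min(spec$wavelength), max(spec$wavelength)), call. = FALSE)
  }
  if (length(target_grid) == length(spec$wavelength) &&
      all(target_grid == spec$wavelength)) {
    return(spec)
  }
  a <- stats::approx(spec$wavelength, spec$absorbance, xout = target_grid,
                     method = "linear", ties = "ordered")$y
  spectrum(target_grid, a)
}

#' Subtract the dissolution-medium baseline from a series
#'
#' Mirrors the instrument practice of blanking against the medium before a
#' run: the medium spectrum is subtracted pointwise at every time point.
#' Small negative absorbances can result and are deliberately kept
#' (clamping would bias derivative ratios near zero).
#'
#' @param series A `spectral_series` or list of them.
#' @param medium_spectrum A `spectrum`; resampled onto the series grid if
#'   its grid differs (its span must cover the series grid).
#' @return Corrected object of the same shape as `series`.
#' @export
baseline_correct <- function(series, medium_spectrum) {
  stopifnot(inherits(medium_spectrum, "spectrum"))
  if (!inherits(series, "spectral_series")) {
    return(lapply(series, baseline_correct, medium_spectrum = medium_spectrum))
  }
  med <- resample_spectrum(medium_spectrum, series$wavelength)
  corrected <- sweep(series$absorbance, 2L, med$absorbance, "-")
  spectral_series(series$vessel_id, series$times, series$wavelength, corrected)
}
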