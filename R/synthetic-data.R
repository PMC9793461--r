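#' Simulation parameters for a synthetic IVR run
#'
#' The generator emulates a fiber-optic dissolution run on a
#' dexamethasone-like absorber: a Gaussian drug band with maximum near
#' 241 nm whose long-wavelength inflection sits at 252 nm, a spectrally
#' flat placebo contribution that starts rising after a late onset
#' (excipients slowly crossing the dialysis membrane), biphasic release
#' kinetics, and homoscedastic per-probe Gaussian noise in AU.
#'
#' @param drug_peak_center Band maximum, nm (default 241).
#' @param drug_peak_sd Gaussian band width, nm (default 11, putting the
#'   inflection at 252 nm).
#' @param drug_peak_absorbance Peak absorbance at 100 % release, AU.
#' @param release_a Fast-phase amplitude, percent.
#' @param release_k1 Fast-phase rate constant, 1/min.
#' @param release_m Terminal linear slope, percent/min.
#' @param placebo_onset Time after which placebo absorbance rises, min
#'   (default 2880 = 48 h).
#' @param placebo_rate Placebo absorbance growth at 241 nm after onset,
#'   AU/min.
#' @param placebo_tilt Gentle spectral slope of the placebo shape, AU/nm.
#' @param noise_sd Absorbance noise standard deviation, AU.
#' @param temperature_q10 Release-rate multiplier per 10 degrees C.
#' @param rpm_exponent Power-law stirring sensitivity exponent.
#' @param seed Integer seed; mandatory, no implicit entropy.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(drug_peak_center = 241, drug_peak_sd = 11,
                              drug_peak_absorbance = 0.8,
                              release_a = 60, release_k1 = 0.005,
                              release_m = 0.01,
                              placebo_onset = 2880, placebo_rate = 5e-5,
                              placebo_tilt = 1e-3, noise_sd = 0.002,
                              temperature_q10 = 2, rpm_exponent = 0.3,
                              seed) {
  if (missing(seed)) stop("a seed is mandatory (no implicit entropy)", call. = FALSE)
  seed <- as.integer(seed)
  rates <- c(release_a = release_a, release_k1 = release_k1,
             release_m = release_m, placebo_onset = placebo_onset,
             placebo_rate = placebo_rate, noise_sd = noise_sd,
             temperature_q10 = temperature_q10, rpm_exponent = rpm_exponent)
  if (anyNA(rates) || any(rates < 0)) {
    stop("rates, amplitudes and noise must be non-negative", call. = FALSE)
  }
  if (!is.finite(drug_peak_sd) || drug_peak_sd <= 0) {
    stop("drug_peak_sd must be positive", call. = FALSE)
  }
  structure(list(drug_peak_center = drug_peak_center,
                 drug_peak_sd = drug_peak_sd,
                 drug_peak_absorbance = drug_peak_absorbance,
                 release_a = release_a, release_k1 = release_k1,
                 release_m = release_m, placebo_onset = placebo_onset,
                 placebo_rate = placebo_rate, placebo_tilt = placebo_tilt,
                 noise_sd = noise_sd, temperature_q10 = temperature_q10,
                 rpm_exponent = rpm_exponent, seed = seed),
            class = "simulation_params")
}

#' Standard IVR sampling schedule
#'
#' The dense early schedule used for profile development (5-1440 min, 16
#' points), optionally extended by 12 h steps for long runs.
#'
#' @param max_hours Last sampling time in hours (24, 48 or 72 typical).
#' @return Times in minutes.
#' @export
ivr_sampling_times <- function(max_hours = 24) {
  base <- c(5, 10, 15, 20, 30, 45, 60, 90, 120, 150, 180,
            240, 300, 360, 720, 1440)
  if (max_hours * 60 <= 1440) return(base[base <= max_hours * 60])
  c(base, seq(2160, max_hours * 60, by = 720))
}

#' Synthetic drug reference spectrum
#'
#' Gaussian band surrogate for the drug chromophore:
#' `peak * exp(-(lambda - center)^2 / (2 sd^2))`.
#'
#' @param grid Wavelength grid, nm.
#' @param params A `simulation_params`.
#' @return A `spectrum`.
#' @export
drug_reference_spectrum <- function(grid, params) {
  stopifnot(inherits(params, "simulation_params"))
  grid <- wavelength_grid(grid)
  a <- params$drug_peak_absorbance *
    exp(-(grid - params$drug_peak_center)^2 / (2 * params$drug_peak_sd^2))
  spectrum(grid, a)
}

#' Synthetic placebo spectral shape (unit amplitude)
#'
#' Nearly flat shape `1 + tilt * (lambda - 241)`, clipped at zero and
#' normalized to 1 at 241 nm — the spectral signature of excipients that
#' absorb broadly but featurelessly around the drug band.
#'
#' @param grid Wavelength grid, nm.
#' @param params A `simulation_params`.
#' @return A `spectrum` with value 1 at 241 nm.
#' @export
placebo_spectrum <- function(grid, params) {
  stopifnot(inherits(params, "simulation_params"))
  grid <- wavelength_grid(grid)
  shape <- pmax(0, 1 + params$placebo_tilt * (grid - 241))
  spectrum(grid, shape) # already 1 at 241 nm by construction
}

#' Ground-truth cumulative release curve
#'
#' Biphasic release `a (1 - exp(-k t)) + m t`, capped at 100 %, with the
#' rate modified phenomenologically by temperature (Q10 rule) and
#' stirring (power law around 75 rpm); the terminal slope scales by the
#' same factor.
#'
#' @param times Times, min.
#' @param params A `simulation_params`.
#' @param temperature Bath temperature, degrees C (reference 37).
#' @param rpm Stirring rate (reference 75).
#' @return Percent released per time (monotone, capped at 100).
#' @export
true_release_curve <- function(times, params, temperature = 37, rpm = 75) {
  stopifnot(inherits(params, "simulation_params"))
  if (temperature <= 0 || rpm <= 0) {
    stop("temperature and rpm must be positive", call. = FALSE)
  }
  times <- as.numeric(times)
  fac <- params$temperature_q10^((temperature - 37) / 10) *
    (rpm / 75)^params$rpm_exponent
  k <- params$release_k1 * fac
  m <- params$release_m * fac
  pmin(100, params$release_a * (1 - exp(-k * times)) + m * times)
}

#' Placebo interference amplitude over time
#'
#' Zero before the onset, then growing linearly: the simplest monotone
#' model for excipients whose absorbance rises from a late time point on.
#'
#' @param times Times, min.
#' @param params A `simulation_params`.
#' @return Placebo amplitude in AU at 241 nm per time.
#' @export
placebo_amplitude_curve <- function(times, params) {
  stopifnot(inherits(params, "simulation_params"))
  times <- as.numeric(times)
  pmax(0, times - params$placebo_onset) * params$placebo_rate
}

#' Synthesize a full fiber-optic IVR run
#'
#' Generates, per vessel, a time-indexed spectral series
#' `A(lambda, t) = truth(t)/100 * drug(lambda) + placebo_amp(t) *
#' placebo(lambda) + noise`, with independent Gaussian noise per
#' (vessel, wavelength, time); noise-free per-probe standard spectra at
#' the 100 %-release concentration; a zero medium spectrum (the baseline
#' is already abstracted away); and the ground truth. Per-vessel noise
#' streams are derived deterministically from the single seed, so the
#' same seed reproduces the run bit for bit while different vessels see
#' different noise.
#'
#' @param config A `run_config`.
#' @param params A `simulation_params`.
#' @param n_vessels Number of vessels/probes (>= 1).
#' @param seed Integer seed; defaults to `params$seed`.
#' @param times Sampling schedule in minutes; default
#'   `ivr_sampling_times(48)`.
#' @param grid Wavelength grid; default [default_grid()].
#' @return List with elements `series` (named list of `spectral_series`),
#'   `standards` (list of `probe_calibration`), `medium` (`spectrum`),
#'   `truth` (list with `times`, `true_percent`, `placebo_au`).
#' @export
synthesize_run <- function(config, params, n_vessels = 6,
                           seed = params$seed,
                           times = ivr_sampling_times(48),
                           grid = default_grid()) {
  stopifnot(inherits(config, "run_config"), inherits(params, "simulation_params"))
  n_vessels <- as.integer(n_vessels)
  if (n_vessels < 1L) stop("need at least one vessel", call. = FALSE)
  grid <- wavelength_grid(grid)
  times <- as.numeric(times)

  drug <- drug_reference_spectrum(grid, params)
  plac <- placebo_spectrum(grid, params)
  truth <- true_release_curve(times, params,
                              temperature = config$temperature,
                              rpm = config$stirring_rate)
  amp <- placebo_amplitude_curve(times, params)
  clean <- outer(truth / 100, drug$absorbance) +
    outer(amp, plac$absorbance)

  # one base seed -> independent, reproducible per-vessel streams
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  vessel_seeds <- sample.int(.Machine$integer.max - 1L, n_vessels)

  std_conc <- full_release_concentration(config$dose_mass, config$medium_volume)
  series <- list()
  standards <- list()
  for (v in seq_len(n_vessels)) {
    set.seed(vessel_seeds[v])
    eps <- matrix(stats::rnorm(length(times) * length(grid),
                               sd = params$noise_sd),
                  nrow = length(times))
    id <- sprintf("vessel_%d", v)
    series[[id]] <- spectral_series(id, times, grid, clean + eps)
    standards[[v]] <- probe_calibration(sprintf("probe_%d", v), drug, std_conc)
  }
  list(series = series, standards = standards,
       medium = spectrum(grid, rep(0, length(grid))),
       truth = list(times = times, true_percent = truth, placebo_au = amp))
}

#' Ground truth as a release profile
#'
#' @param truth The `truth` element returned by [synthesize_run()].
#' @return A `release_profile` with method `"simulated_truth"`.
#' @export
truth_profile <- function(truth) {
  release_profile(truth$times, truth$true_percent, method = "simulated_truth")
}

# Scenario table: each scenario is one or more simulated conditions that
# mirror the sensitivity experiments (temperature, stirring, sample
# volume), the 48 h replicate run and the 72 h placebo-leakage run.
fixture_scenarios <- function() {
  list(
    baseline_48h = list(
      conditions = list(list(name = "baseline", temperature = 37, rpm = 75,
                             dose = 2, sample_volume = 1)),
      n_vessels = 6, max_hours = 48),
    placebo_leakage_72h = list(
      conditions = list(list(name = "leakage", temperature = 37, rpm = 75,
                             dose = 2, sample_volume = 1)),
      n_vessels = 6, max_hours = 72),
    temperature_pair = list(
      conditions = list(
        list(name = "temp25", temperature = 25, rpm = 75, dose = 2, sample_volume = 1),
        list(name = "temp37", temperature = 37, rpm = 75, dose = 2, sample_volume = 1)),
      n_vessels = 3, max_hours = 24),
    rpm_pair = list(
      conditions = list(
        list(name = "rpm50", temperature = 37, rpm = 50, dose = 2, sample_volume = 1),
        list(name = "rpm75", temperature = 37, rpm = 75, dose = 2, sample_volume = 1)),
      n_vessels = 3, max_hours = 24),
    volume_pair = list(
      conditions = list(
        list(name = "vol1.0", temperature = 37, rpm = 75, dose = 2, sample_volume = 1),
        list(name = "vol0.5", temperature = 37, rpm = 75, dose = 1, sample_volume = 0.5)),
      n_vessels = 3, max_hours = 24)
  )
}

#' Write a named simulated scenario to disk
#'
#' Known scenarios: `"baseline_48h"`, `"placebo_leakage_72h"`,
#' `"temperature_pair"`, `"rpm_pair"`, `"volume_pair"`. For each
#' condition in the scenario the generator writes
#' `<condition>_series.csv`, `<condition>_standards.csv`,
#' `<condition>_medium.csv`, `<condition>_truth.csv`
#' (`time_min,true_percent,placebo_au`) and a `config.json` snapshot of
#' all parameters. Output is deterministic given the seed, byte for byte.
#'
#' @param directory Output directory (created if absent).
#' @param scenario_name One of the known scenario names.
#' @param seed Integer seed.
#' @param params Optional `simulation_params` override (its seed is
#'   replaced by `seed`).
#' @return Invisibly, the character vector of files written.
#' @export
make_fixture_dataset <- function(directory, scenario_name, seed,
                                 params = NULL) {
  scenarios <- fixture_scenarios()
  if (!scenario_name %in% names(scenarios)) {
    stop("unknown scenario '", scenario_name, "'; known: ",
         paste(names(scenarios), collapse = ", "), call. = FALSE)
  }
  sc <- scenarios[[scenario_name]]
  if (is.null(params)) params <- simulation_params(seed = seed)
  params$seed <- as.integer(seed)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)

  written <- character()
  cfg_all <- list(scenario = scenario_name, seed = as.integer(seed),
                  params = params[setdiff(names(params), "seed")],
                  conditions = list())
  for (ci in seq_along(sc$conditions)) {
    cond <- sc$conditions[[ci]]
    cfg <- run_config(medium_volume = 500, dose_mass = cond$dose,
                      temperature = cond$temperature,
                      stirring_rate = cond$rpm,
                      sample_volume = cond$sample_volume)
    run <- synthesize_run(cfg, params, n_vessels = sc$n_vessels,
                          seed = params$seed + ci - 1L,
                          times = ivr_sampling_times(sc$max_hours))
    pre <- file.path(directory, cond$name)
    write_spectral_series(run$series, paste0(pre, "_series.csv"))
    std_df <- do.call(rbind, lapply(run$standards, function(s) {
      data.frame(probe_id = s$probe_id,
                 wavelength_nm = s$standard_spectrum$wavelength,
                 absorbance = s$standard_spectrum$absorbance)
    }))
    utils::write.csv(format_num_df(std_df), paste0(pre, "_standards.csv"),
                     row.names = FALSE, quote = FALSE)
    write_spectrum(run$medium, paste0(pre, "_medium.csv"))
    tr_df <- data.frame(time_min = run$truth$times,
                        true_percent = run$truth$true_percent,
                        placebo_au = run$truth$placebo_au)
    utils::write.csv(format_num_df(tr_df), paste0(pre, "_truth.csv"),
                     row.names = FALSE, quote = FALSE)
    written <- c(written, paste0(pre, c("_series.csv", "_standards.csv",
                                        "_medium.csv", "_truth.csv")))
    cfg_all$conditions[[cond$name]] <- c(cond[setdiff(names(cond), "name")],
                                         list(medium_volume = 500,
                                              n_vessels = sc$n_vessels,
                                              standard_concentration =
                                                run$standards[[1]]$standard_concentration))
  }
  cfg_path <- file.path(directory, "config.json")
  jsonlite::write_json(cfg_all, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- c(written, cfg_path)
  invisible(written)
}
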