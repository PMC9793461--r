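#' Two-phase partitioning experiment
#'
#' One shake-flask equilibrium between an oil formulation and an aqueous
#' buffer: the oil solution is prepared at concentration `c_i`, equal
#' volumes (or not) of the two phases are shaken to equilibrium, and the
#' aqueous drug concentration `c_v` is assayed.
#'
#' @param c_i Drug concentration of the prepared oil solution, mg/mL.
#' @param c_v Aqueous-phase drug concentration at equilibrium, mg/mL.
#' @param V_u Oil-phase volume, mL.
#' @param V_v Aqueous-phase volume, mL.
#' @return An object of class `partition_experiment`.
#' @export
partition_experiment <- function(c_i, c_v, V_u, V_v) {
  vals <- c(c_i = c_i, c_v = c_v, V_u = V_u, V_v = V_v)
  if (anyNA(vals) || any(!is.finite(vals)) || any(vals <= 0)) {
    stop("c_i, c_v, V_u, V_v must all be positive and finite", call. = FALSE)
  }
  # mass balance: the aqueous phase cannot hold more drug than was loaded
  if (c_v > c_i * V_u / V_v * (1 + 1e-12)) {
    stop("c_v exceeds the total-mass limit c_i * V_u / V_v; impossible mass balance",
         call. = FALSE)
  }
  structure(as.list(vals), class = "partition_experiment")
}

#' Apparent partition coefficient from mass balance
#'
#' The drug not found in the aqueous phase must still be in the oil phase,
#' so the equilibrium oil-phase concentration is
#' `(c_i * V_u - c_v * V_v) / V_u` and the apparent partition coefficient
#' is that concentration over the measured aqueous concentration:
#'
#' \deqn{P_{app} = \frac{c_i V_u - c_v V_v}{c_v V_u}}
#'
#' A log10 value above 1 is the usual screen for a formulation able to
#' sustain prolonged release.
#'
#' @param exp A `partition_experiment`.
#' @return Dimensionless apparent partition coefficient.
#' @examples
#' apparent_partition_coefficient(partition_experiment(2, 1, 1, 1)) # 1
#' @export
apparent_partition_coefficient <- function(exp) {
  stopifnot(inherits(exp, "partition_experiment"))
  if (exp$c_v == 0) {
    stop("c_v is zero: partitioning is unbounded (all drug in the oil phase)",
         call. = FALSE)
  }
  (exp$c_i * exp$V_u - exp$c_v * exp$V_v) / (exp$c_v * exp$V_u)
}

#' Directly measured oil/aqueous concentration ratio
#'
#' @param c_oil Oil-phase drug concentration, mg/mL.
#' @param c_aq Aqueous-phase drug concentration, mg/mL.
#' @return Dimensionless ratio `c_oil / c_aq`.
#' @export
partition_ratio <- function(c_oil, c_aq) {
  if (!is.finite(c_oil) || c_oil <= 0) stop("c_oil must be positive", call. = FALSE)
  if (!is.finite(c_aq) || c_aq <= 0) stop("c_aq must be positive", call. = FALSE)
  c_oil / c_aq
}

#' Base-10 logarithm of a partition coefficient
#'
#' @param P Dimensionless partition coefficient, > 0.
#' @return log10(P).
#' @examples
#' log_partition(34.7) # 1.5403
#' @export
log_partition <- function(P) {
  if (!is.finite(P) || P <= 0) {
    stop("partition coefficient must be positive for log10", call. = FALSE)
  }
  log10(P)
}

#' Sink-condition specification
#'
#' @param dose_mass Drug mass released into the medium at 100 % release, mg.
#' @param medium_solubility Drug solubility in the release medium, mg/mL.
#' @param sink_factor Multiple of the saturation volume required
#'   (dimensionless, >= 1); 3 is the classical pharmacopoeial convention.
#' @return An object of class `sink_spec`.
#' @export
sink_spec <- function(dose_mass, medium_solubility, sink_factor = 3) {
  vals <- c(dose_mass = dose_mass, medium_solubility = medium_solubility,
            sink_factor = sink_factor)
  if (anyNA(vals) || any(!is.finite(vals)) || any(vals <= 0)) {
    stop("dose mass, solubility and sink factor must be positive", call. = FALSE)
  }
  if (sink_factor < 1) stop("sink_factor must be >= 1", call. = FALSE)
  structure(as.list(vals), class = "sink_spec")
}

#' Minimum medium volume ensuring sink conditions
#'
#' `sink_factor` times the volume that would be exactly saturated by the
#' full dose: `sink_factor * dose_mass / medium_solubility`.
#'
#' @param spec A `sink_spec`.
#' @return Volume in mL.
#' @examples
#' sink_volume(sink_spec(2, 0.17, 3)) # 35.3 mL
#' @export
sink_volume <- function(spec) {
  stopifnot(inherits(spec, "sink_spec"))
  spec$sink_factor * spec$dose_mass / spec$medium_solubility
}

#' Does a medium volume satisfy sink conditions?
#'
#' Closed bound: a volume exactly equal to the sink volume qualifies.
#'
#' @param medium_volume Medium volume, mL.
#' @param spec A `sink_spec`.
#' @return Logical.
#' @export
is_sink <- function(medium_volume, spec) {
  if (!is.finite(medium_volume) || medium_volume <= 0) {
    stop("medium volume must be positive", call. = FALSE)
  }
  medium_volume >= sink_volume(spec)
}
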