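#' First-order release model fit
#'
#' Fits \eqn{F(t) = f_\infty (1 - e^{-k t})} to a percent-released profile
#' by unweighted least squares, the model generally reported for release
#' from oil solutions. The fit is deterministic: the starting value for
#' `k` comes from the log-linear slope of the first half of the points, a
#' small fixed multiplier grid of starts is screened by residual sum of
#' squares, and Levenberg-Marquardt refines the best one. No random
#' restarts.
#'
#' A constant all-zero profile is degenerate: `k` is unidentifiable. The
#' documented behaviour is to return `f_inf = 0`, `k = NA`, `rss = 0` and
#' `identifiable = FALSE` rather than error.
#'
#' @param profile A `release_profile` with at least 4 time points.
#' @return An object of class `first_order_fit`: list with `f_inf` (%),
#'   `k` (1/min), `rss` (squared-percent), `identifiable`, `fitted`.
#' @export
fit_first_order <- function(profile) {
  stopifnot(inherits(profile, "release_profile"))
  t <- profile$times
  y <- profile$percent_released
  if (length(t) < 4L) stop("need at least 4 time points", call. = FALSE)
  if (any(!is.finite(y))) stop("percent values must be finite", call. = FALSE)

  if (all(abs(y) < .Machine$double.eps^0.5)) {
    return(structure(list(f_inf = 0, k = NA_real_, rss = 0,
                          identifiable = FALSE, fitted = rep(0, length(t))),
                     class = "first_order_fit"))
  }

  starts <- first_order_starts(t, y)
  fit <- lm_refine(
    fn = function(par) par[1] * (1 - exp(-par[2] * t)),
    y = y, starts = starts, lower = c(0, 1e-12)
  )
  structure(list(f_inf = fit$par[1], k = fit$par[2], rss = fit$rss,
                 identifiable = TRUE, fitted = fit$fitted),
            class = "first_order_fit")
}

#' @export
print.first_order_fit <- function(x, ...) {
  cat(sprintf("<first_order_fit> f_inf = %.4g %%, k = %.4g /min, rss = %.4g\n",
              x$f_inf, x$k, x$rss))
  invisible(x)
}

# Deterministic initializer: plateau from the max observed percent, rate
# from the log-linear slope of the first half of the points, screened over
# a fixed multiplier grid.
first_order_starts <- function(t, y) {
  f0 <- max(y)
  if (f0 <= 0) f0 <- 1
  half <- seq_len(max(3L, ceiling(length(t) / 2)))
  tt <- t[half]
  yy <- y[half]
  keep <- tt > 0
  frac <- pmin(pmax(1 - yy[keep] / (f0 * 1.0001), 1e-8), 1)
  k0 <- -stats::coef(stats::lm(log(frac) ~ tt[keep]))[[2]]
  if (!is.finite(k0) || k0 <= 0) k0 <- 1 / max(t[t > 0])
  lapply(c(0.3, 1, 3), function(mult) c(f0, k0 * mult))
}

# Screen starts by rss, refine the best with Levenberg-Marquardt under
# bounds. Refinement never increases the objective from its start, so the
# returned rss is <= the best start's rss.
lm_refine <- function(fn, y, starts, lower) {
  rss_of <- function(par) sum((y - fn(par))^2)
  start_rss <- vapply(starts, rss_of, numeric(1))
  best <- starts[[which.min(start_rss)]]
  res <- minpack.lm::nls.lm(
    par = best, lower = lower,
    fn = function(par) y - fn(par),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  if (res$info == 0 || res$info == 9) {
    stop(sprintf(
      "least-squares fit did not converge (info %d) from start [%s]",
      res$info, paste(signif(best, 6), collapse = ", ")), call. = FALSE)
  }
  par <- res$par
  rss <- rss_of(par)
  if (rss > min(start_rss)) { # never worse than the screened starts
    par <- best
    rss <- min(start_rss)
  }
  list(par = par, rss = rss, fitted = fn(par))
}

#' Biphasic release model fit
#'
#' Fits \eqn{F(t) = a (1 - e^{-k_1 t}) + m t}: an exponential fast phase
#' (cosolvent-assisted) plus a linear terminal phase under sink
#' conditions. The slope-change point `t_break` is reported as the time at
#' which the fast phase reaches 95 % of its amplitude,
#' \eqn{-\ln(0.05)/k_1}. The first-order solution (with `m = 0`) is one of
#' the deterministic starting points, so the biphasic residual sum never
#' exceeds the nested first-order one.
#'
#' @param profile A `release_profile` with at least 6 time points.
#' @return An object of class `biphasic_fit`: list with `a` (%), `k1`
#'   (1/min), `m` (%/min), `t_break` (min), `rss`, `fitted`.
#' @export
fit_biphasic <- function(profile) {
  stopifnot(inherits(profile, "release_profile"))
  t <- profile$times
  y <- profile$percent_released
  if (length(t) < 6L) stop("need at least 6 time points", call. = FALSE)
  if (any(!is.finite(y))) stop("percent values must be finite", call. = FALSE)

  # terminal slope estimate from the last third of the profile
  tail_idx <- seq.int(max(1L, length(t) - max(2L, floor(length(t) / 3)) + 1L),
                      length(t))
  m0 <- max(0, stats::coef(stats::lm(y[tail_idx] ~ t[tail_idx]))[[2]])
  y_fast <- y - m0 * t
  fo_starts <- first_order_starts(t, pmax(y_fast, 0))
  starts <- lapply(fo_starts, function(s) c(s, m0))

  fo <- fit_first_order(profile)
  if (fo$identifiable) starts <- c(starts, list(c(fo$f_inf, fo$k, 0)))

  fit <- lm_refine(
    fn = function(par) par[1] * (1 - exp(-par[2] * t)) + par[3] * t,
    y = y, starts = starts, lower = c(0, 1e-12, 0)
  )
  t_break <- -log(0.05) / fit$par[2]
  structure(list(a = fit$par[1], k1 = fit$par[2], m = fit$par[3],
                 t_break = t_break, rss = fit$rss, fitted = fit$fitted),
            class = "biphasic_fit")
}

#' @export
print.biphasic_fit <- function(x, ...) {
  cat(sprintf("<biphasic_fit> a = %.4g %%, k1 = %.4g /min, m = %.4g %%/min, t_break = %.4g min, rss = %.4g\n",
              x$a, x$k1, x$m, x$t_break, x$rss))
  invisible(x)
}

#' f2 similarity factor between two release profiles
#'
#' The standard logarithmic transform of the mean squared percent
#' difference:
#' \deqn{f_2 = 50 \log_{10}\!\left(\frac{100}{\sqrt{1 + \overline{(R_t - T_t)^2}}}\right)}
#' Identical profiles give 100; values >= 50 are conventionally called
#' similar. By default all shared points enter the mean; `regulatory =
#' TRUE` applies the conventional truncation that keeps at most one point
#' after the reference first reaches 85 % released.
#'
#' @param reference,test `release_profile`s on the same time grid with at
#'   least 3 shared points.
#' @param regulatory Apply the one-point-above-85 % truncation rule.
#' @return Dimensionless f2 value.
#' @examples
#' p1 <- release_profile(c(10, 20, 30), c(20, 50, 80), method = "single_point")
#' p2 <- release_profile(c(10, 20, 30), c(30, 60, 90), method = "single_point")
#' f2_similarity(p1, p2) # 49.89
#' @export
f2_similarity <- function(reference, test, regulatory = FALSE) {
  stopifnot(inherits(reference, "release_profile"),
            inherits(test, "release_profile"))
  if (length(reference$times) != length(test$times) ||
      any(reference$times != test$times)) {
    stop("profiles must share an identical time grid", call. = FALSE)
  }
  r <- reference$percent_released
  s <- test$percent_released
  if (regulatory) {
    over <- which(r >= 85)
    if (length(over) > 1L) {
      keep <- seq_len(over[1])
      r <- r[keep]
      s <- s[keep]
    }
  }
  if (length(r) < 3L) stop("need at least 3 shared points", call. = FALSE)
  50 * log10(100 / sqrt(1 + mean((r - s)^2)))
}
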