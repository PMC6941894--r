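# Growth-rate estimation from turbidostat traces and plate-reader curves.

#' Construct a turbidostat OD trace
#'
#' Bundles a time-stamped optical density series with the indices at which a
#' dilution cycle ends (the reading immediately *after* each dilution). Between
#' dilutions the culture grows exponentially; each inter-dilution segment
#' yields one independent growth-rate estimate.
#'
#' @param times Numeric vector of times in hours, strictly increasing.
#' @param od Numeric vector of optical densities, all positive.
#' @param dilution_marks Integer indices of the first reading of each cycle
#'   (the reading right after a dilution). If `NULL`, boundaries are detected
#'   as relative OD drops exceeding `drop_threshold`.
#' @param drop_threshold Relative OD drop (default 0.02) that flags a dilution
#'   when explicit marks are absent.
#' @return An object of class `od_trace`.
#' @export
od_trace <- function(times, od, dilution_marks = NULL, drop_threshold = 0.02) {
  times <- as.numeric(times)
  od <- as.numeric(od)
  if (length(times) != length(od)) stop("times and od must have equal length")
  if (any(!is.finite(times)) || any(!is.finite(od))) stop("non-finite values in trace")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(od <= 0)) stop("od must be positive at every point")
  if (is.null(dilution_marks)) {
    rel <- diff(od) / od[-length(od)]
    dilution_marks <- which(rel < -drop_threshold) + 1L
  } else {
    dilution_marks <- as.integer(dilution_marks)
    if (any(dilution_marks < 1L | dilution_marks > length(od)))
      stop("dilution_marks out of range")
    # small dilution steps can be buried in reading noise, so a mark at a
    # non-drop is suspicious but not fatal
    bad <- dilution_marks[dilution_marks > 1L &
                            od[dilution_marks] >= od[pmax(dilution_marks - 1L, 1L)]]
    if (length(bad))
      warning(length(bad), " dilution mark(s) without an OD drop ",
              "(first at index ", bad[1], ")")
  }
  structure(list(times = times, od = od,
                 dilution_marks = sort(unique(dilution_marks))),
            class = "od_trace")
}

#' Per-cycle specific growth rates
#'
#' For each dilution cycle i the specific growth rate is
#' \deqn{\mu_i = \ln(N_{t1,i}/N_{t0,i}) / (t_{1,i} - t_{0,i})}
#' where \eqn{N_{t0}} is the OD reading right after a dilution and
#' \eqn{N_{t1}} the reading right before the next one. Ratio-based, hence
#' invariant to uniform rescaling of all OD values.
#'
#' @param trace An [od_trace()].
#' @return Numeric vector of rates in h^-1, one per usable cycle, with an
#'   attribute `"rejected"` listing cycles dropped for having < 2 points or
#'   zero duration.
#' @export
per_cycle_rates <- function(trace) {
  stopifnot(inherits(trace, "od_trace"))
  n <- length(trace$od)
  starts <- sort(unique(c(1L, trace$dilution_marks)))
  ends <- c(starts[-1] - 1L, n)
  rates <- numeric(0)
  rejected <- character(0)
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- ends[i]
    if (e - s < 1L) {
      rejected <- c(rejected, sprintf("cycle %d: fewer than 2 points", i))
      next
    }
    dt <- trace$times[e] - trace$times[s]
    if (dt <= 0) {
      rejected <- c(rejected, sprintf("cycle %d: zero duration", i))
      next
    }
    rates <- c(rates, log(trace$od[e] / trace$od[s]) / dt)
  }
  attr(rates, "rejected") <- rejected
  rates
}

#' Summarise a day of per-cycle growth rates
#'
#' Averages the per-cycle rates and converts to generations per day via
#' \eqn{g = 24 \bar\mu / \ln 2} (a doubling takes \eqn{\ln 2/\mu} hours).
#' Optionally excludes outlier cycles whose rate lies beyond `z_cut` standard
#' deviations of the day's distribution.
#'
#' @param rates Numeric vector of per-cycle rates (h^-1).
#' @param z_cut Z-score beyond which a cycle is excluded (default 4); `Inf`
#'   disables filtering.
#' @return A list of class `growth_estimate` with elements `mu_bar`,
#'   `n_cycles`, `generations_per_day`, `per_cycle_rates`, `n_excluded`.
#' @export
summarize_day <- function(rates, z_cut = 4) {
  rates <- as.numeric(rates)
  if (length(rates) == 0) stop("empty rate list")
  kept <- rates
  if (is.finite(z_cut) && length(rates) > 2) {
    z <- (rates - mean(rates)) / stats::sd(rates)
    z[is.na(z)] <- 0
    kept <- rates[abs(z) <= z_cut]
    if (length(kept) == 0) kept <- rates
  }
  mu_bar <- mean(kept)
  structure(list(mu_bar = mu_bar,
                 n_cycles = length(kept),
                 generations_per_day = 24 * mu_bar / log(2),
                 per_cycle_rates = kept,
                 n_excluded = length(rates) - length(kept)),
            class = "growth_estimate")
}

# Zwietering-form modified Gompertz curve.
gompertz_model <- function(t, mu_max, lag, a_max) {
  a_max * exp(-exp(mu_max * exp(1) / a_max * (lag - t) + 1))
}

#' Fit a modified Gompertz growth curve
#'
#' Fits \deqn{y(t) = A \exp\{-\exp[(\mu_{max} e / A)(\lambda - t) + 1]\}}
#' to a baseline-subtracted plate-reader growth curve by nonlinear least
#' squares. The baseline is the mean of the first `baseline_points` readings
#' after a moving-average smoother of width 3. At \eqn{t = \lambda} the fitted
#' curve equals \eqn{A e^{-e}}; as \eqn{t \to \infty} it approaches \eqn{A}.
#'
#' @param times Numeric vector of times (hours).
#' @param od Numeric vector of raw absorbances.
#' @param baseline_points Number of early (smoothed) points averaged to form
#'   the baseline (default 5). Use 0 to skip baseline subtraction.
#' @return A list of class `gompertz_fit` with `mu_max` (h^-1), `lag` (h),
#'   `a_max` (OD), `rss`, `baseline`, and the `fitted` values.
#' @export
fit_gompertz <- function(times, od, baseline_points = 5) {
  times <- as.numeric(times); od <- as.numeric(od)
  if (length(times) != length(od)) stop("times and od must have equal length")
  if (length(times) < 8) stop("need at least 8 points spanning lag and growth")
  baseline <- 0
  if (baseline_points > 0) {
    sm <- stats::filter(od, rep(1 / 3, 3), sides = 2)
    sm[is.na(sm)] <- od[is.na(sm)]
    baseline <- mean(sm[seq_len(min(baseline_points, length(od)))])
  }
  y <- od - baseline

  # initial guesses from the tangent at the inflection: in this
  # parameterisation mu_max is the maximum slope of the curve and lag the
  # intercept of that tangent with the baseline
  sm <- stats::filter(y, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- y[is.na(sm)]
  d <- diff(as.numeric(sm)) / diff(times)
  i <- which.max(d)
  mu0 <- max(d[i], 1e-6)
  t_inf <- (times[i] + times[i + 1]) / 2
  lag0 <- max(t_inf - sm[i] / mu0, times[1])
  a0 <- max(y)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ gompertz_model(times, mu_max, lag, a_max),
      start = list(mu_max = mu0, lag = lag0, a_max = a0),
      lower = c(1e-8, 0, 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("Gompertz fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  est <- stats::coef(fit)
  structure(list(mu_max = unname(est["mu_max"]),
                 lag = unname(est["lag"]),
                 a_max = unname(est["a_max"]),
                 rss = sum(stats::resid(fit)^2),
                 baseline = baseline,
                 fitted = stats::fitted(fit)),
            class = "gompertz_fit")
}
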