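# Burst-phase progress curves, Michaelis-Menten and allosteric-effector fits.

#' Fit a burst-phase progress curve
#'
#' An NADPH-production progress curve from a semialdehyde dehydrogenase assay
#' shows a rapid burst (reduction of the pre-existing free-aldehyde form)
#' followed by a linear phase (limited by dehydration of the hydrate). Two
#' models are supported:
#' \describe{
#'   \item{exponential}{\eqn{f(x) = m x + b(1 - e^{-x})}, fit to the whole
#'     curve. The printed form carries no rate constant on the exponential
#'     (time constant 1 s); set `float_rate = TRUE` to fit
#'     \eqn{b(1 - e^{-kx})} with a free k.}
#'   \item{linear}{\eqn{f(x) = m x + b}, fit only to the post-burst linear
#'     window.}
#' }
#' The burst magnitude b converts to the free-aldehyde fraction via
#' \eqn{(b / (\epsilon \ell)) / [S]_{tot}}.
#'
#' @param time_s Time in seconds, strictly increasing from 0.
#' @param a340 Absorbance at 340 nm.
#' @param model `"exponential"` or `"linear"`.
#' @param linear_window Length-2 numeric `c(from, to)` in seconds delimiting
#'   the linear phase (linear model). `NULL` selects the longest suffix whose
#'   linear fit has R^2 >= 0.995.
#' @param float_rate Fit a free rate constant on the exponential (default
#'   `FALSE`, the fixed unit time constant).
#' @param epsilon NADPH molar extinction coefficient at 340 nm
#'   (M^-1 cm^-1, default 6220).
#' @param pathlength_cm Optical path length (cm, default 1).
#' @param total_substrate Total substrate concentration, aldehyde + hydrate
#'   (+ cyclic form), in M. `NA` skips the fraction.
#' @return A list of class `burst_fit` with `slope_m` (A s^-1), `burst_b`
#'   (A), `model`, `rate_k` (s^-1 or NA), `free_fraction`, `rss`.
#' @export
fit_burst <- function(time_s, a340, model = c("exponential", "linear"),
                      linear_window = NULL, float_rate = FALSE,
                      epsilon = 6220, pathlength_cm = 1,
                      total_substrate = NA) {
  model <- match.arg(model)
  time_s <- as.numeric(time_s); a340 <- as.numeric(a340)
  if (length(time_s) < 6) stop("need >= 6 points")
  if (any(diff(time_s) <= 0)) stop("time must be strictly increasing")
  rate_k <- NA_real_

  if (model == "linear") {
    if (is.null(linear_window)) linear_window <- auto_linear_window(time_s, a340)
    keep <- time_s >= linear_window[1] & time_s <= linear_window[2]
    if (sum(keep) < 3) stop("linear window contains fewer than 3 points")
    fit <- stats::lm(a340[keep] ~ time_s[keep])
    b <- unname(stats::coef(fit)[1]); m <- unname(stats::coef(fit)[2])
    rss <- sum(stats::resid(fit)^2)
  } else if (!float_rate) {
    # fixed unit time constant: linear in (m, b)
    X <- cbind(x = time_s, e = 1 - exp(-time_s))
    fit <- stats::lm(a340 ~ X - 1)
    m <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
    rss <- sum(stats::resid(fit)^2)
  } else {
    start <- list(m = (a340[length(a340)] - a340[1]) / diff(range(time_s)),
                  b = max(a340[time_s <= stats::median(time_s)]), k = 1)
    fit <- minpack.lm::nlsLM(a340 ~ m * time_s + b * (1 - exp(-k * time_s)),
                             start = start, lower = c(-Inf, -Inf, 1e-6))
    cf <- stats::coef(fit)
    m <- unname(cf["m"]); b <- unname(cf["b"]); rate_k <- unname(cf["k"])
    rss <- sum(stats::resid(fit)^2)
  }

  free_fraction <- NA_real_
  if (!is.na(total_substrate)) {
    bb <- b
    if (bb < 0) {
      warning("negative burst magnitude; free fraction clamped to 0")
      bb <- 0
    }
    free_fraction <- (bb / (epsilon * pathlength_cm)) / total_substrate
  }
  structure(list(slope_m = m, burst_b = b, model = model, rate_k = rate_k,
                 free_fraction = free_fraction, rss = rss),
            class = "burst_fit")
}

# Longest suffix of the curve whose straight-line fit has R^2 >= r2_min.
auto_linear_window <- function(time_s, a340, r2_min = 0.995) {
  n <- length(time_s)
  for (s in seq_len(n - 2)) {
    fit <- stats::lm(a340[s:n] ~ time_s[s:n])
    if (summary(fit)$r.squared >= r2_min) return(c(time_s[s], time_s[n]))
  }
  c(time_s[n - 2], time_s[n])
}

#' Fit the Michaelis-Menten model to initial rates
#'
#' Nonlinear least squares of \eqn{v = V_{max} S / (K_M + S)}; replicate
#' points are fit individually, unweighted. \eqn{k_{cat} = V_{max}/[E]_0};
#' standard errors come from the fit covariance (the kcat/Km SE by the delta
#' method, ignoring the Vmax-Km covariance contribution would be wrong, so
#' the full covariance is used).
#'
#' @param S Substrate concentrations (M). When the substrate equilibrates
#'   with an unreactive hydrate, pass free-aldehyde concentrations (total
#'   times the free fraction from [fit_burst()]).
#' @param v Initial rates (same concentration units per second as Vmax).
#' @param enzyme_conc Total enzyme concentration (M).
#' @return A list of class `mm_fit` with `kcat` (s^-1), `km` (M),
#'   `kcat_over_km` (M^-1 s^-1), `vmax`, `se_kcat`, `se_km`,
#'   `se_kcat_over_km`.
#' @export
fit_michaelis_menten <- function(S, v, enzyme_conc) {
  S <- as.numeric(S); v <- as.numeric(v)
  if (length(unique(S)) < 4) stop("need >= 4 substrate levels")
  if (enzyme_conc <= 0) stop("enzyme_conc must be > 0")
  vmax0 <- max(v) * 1.2
  km0 <- S[which.min(abs(v - vmax0 / 2))]
  if (km0 <= 0) km0 <- stats::median(S)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ vmax * S / (km + S),
                      start = list(vmax = vmax0, km = km0),
                      lower = c(1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("Michaelis-Menten fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA, 2, 2))
  vmax <- unname(cf["vmax"]); km <- unname(cf["km"])
  if (km > 10 * max(S))
    warning("extrapolated Km: estimate ", signif(km, 3),
            " exceeds 10x the largest substrate concentration")
  kcat <- vmax / enzyme_conc
  eff <- kcat / km
  # delta method for kcat/Km with gradient (1/(E0 km), -vmax/(E0 km^2))
  g <- c(1 / (enzyme_conc * km), -vmax / (enzyme_conc * km^2))
  se_eff <- sqrt(drop(t(g) %*% vc %*% g))
  structure(list(kcat = kcat, km = km, kcat_over_km = eff, vmax = vmax,
                 se_kcat = sqrt(vc[1, 1]) / enzyme_conc,
                 se_km = sqrt(vc[2, 2]),
                 se_kcat_over_km = se_eff),
            class = "mm_fit")
}

#' Fit a hyperbolic allosteric-effector titration
#'
#' Activity relative to the ligand-free rate follows
#' \deqn{v/v_0 = (a L + K_d) / (L + K_d)}
#' where a is the asymptote at infinite ligand (a < 1: inhibitor, a > 1:
#' activator) and \eqn{K_d} the apparent dissociation constant. At L = 0 the
#' model is exactly 1; at \eqn{L = K_d} it is \eqn{(a+1)/2}. A flat response
#' (no measurable regulation) is returned as a = 1 with `kd = NA` and
#' `determined = FALSE`.
#'
#' @param L Ligand concentrations (M), including 0 or near-zero.
#' @param v_over_v0 Rates relative to the ligand-free rate.
#' @param flat_tol Fitted |a - 1| below which the response is declared flat
#'   (default 0.02).
#' @return A list of class `allosteric_fit` with `kd` (M), `a`, `determined`,
#'   `se_kd`, `se_a`.
#' @export
fit_allosteric <- function(L, v_over_v0, flat_tol = 0.02) {
  L <- as.numeric(L); v_over_v0 <- as.numeric(v_over_v0)
  if (length(unique(L)) < 4) stop("need >= 4 ligand levels")
  a0 <- mean(v_over_v0[L >= stats::quantile(L, 0.75)])
  kd0 <- stats::median(L[L > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(v_over_v0 ~ (a * L + kd) / (L + kd),
                      start = list(a = a0, kd = kd0),
                      lower = c(1e-8, 1e-15),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(kd = NA_real_, a = 1, determined = FALSE,
                          se_kd = NA_real_, se_a = NA_real_),
                     class = "allosteric_fit"))
  cf <- stats::coef(fit)
  if (abs(cf["a"] - 1) < flat_tol)
    return(structure(list(kd = NA_real_, a = 1, determined = FALSE,
                          se_kd = NA_real_, se_a = NA_real_),
                     class = "allosteric_fit"))
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA, 2, 2))
  structure(list(kd = unname(cf["kd"]), a = unname(cf["a"]), determined = TRUE,
                 se_kd = sqrt(vc[2, 2]), se_a = sqrt(vc[1, 1])),
            class = "allosteric_fit")
}

#' Derived comparison statistics
#'
#' Small arithmetic helpers for comparing kinetic parameters between enzyme
#' variants and for the colorimetric citrulline coupling assay.
#'
#' @param x,y Positive scalars (e.g. two catalytic efficiencies).
#' @return `fold_change`: x/y. `percent_change`: 100 (x/y - 1).
#' @export
fold_change <- function(x, y) {
  if (any(y == 0)) stop("division by zero")
  x / y
}

#' @rdname fold_change
#' @export
percent_change <- function(x, y) 100 * (fold_change(x, y) - 1)

#' @rdname fold_change
#' @param a464 Absorbance at 464 nm of the diacetyl-monoxime citrulline adduct.
#' @param epsilon464 Extinction coefficient (M^-1 cm^-1, default 37800).
#' @param pathlength_cm Path length (cm).
#' @return `citrulline_conc`: molar citrulline from A464.
#' @export
citrulline_conc <- function(a464, epsilon464 = 37800, pathlength_cm = 1) {
  a464 / (epsilon464 * pathlength_cm)
}

#' @rdname fold_change
#' @param mol_product Moles of carbamoyl phosphate (measured as citrulline).
#' @param mol_atp Moles of ATP hydrolysed.
#' @return `coupling_ratio`: mol product per mol ATP; a fully coupled
#'   synthetase consuming two ATP per product gives 0.5.
#' @export
coupling_ratio <- function(mol_product, mol_atp) {
  if (mol_atp == 0) stop("division by zero")
  mol_product / mol_atp
}
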