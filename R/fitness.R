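# Competitive fitness from two-colour cell counts.

#' Relative fitness from a two-colour competition assay
#'
#' With R the test/reference count ratio (e.g. YFP/CFP) and t the number of
#' generations elapsed,
#' \deqn{w = \ln(R(t)/R(0)) / t + 1.}
#' Neutrality gives w = 1. A Poisson counting-error standard error is
#' propagated by the delta method (\eqn{\mathrm{var}\,\ln R \approx 1/n_{test}
#' + 1/n_{ref}} at each time point) and reported, not used for filtering.
#'
#' @param counts_test_initial,counts_ref_initial,counts_test_final,counts_ref_final
#'   Positive cell counts for the two channels at the two time points.
#' @param generations_t Number of generations elapsed (> 0); see
#'   [estimate_generations()].
#' @return A list of class `fitness_estimate` with `w_raw`, `se_w`, `ln_ratio`
#'   and the inputs.
#' @export
relative_fitness <- function(counts_test_initial, counts_ref_initial,
                             counts_test_final, counts_ref_final,
                             generations_t) {
  counts <- c(test_initial = counts_test_initial,
              ref_initial = counts_ref_initial,
              test_final = counts_test_final,
              ref_final = counts_ref_final)
  zero <- names(counts)[counts <= 0]
  if (length(zero))
    stop("nonpositive count in channel(s): ", paste(zero, collapse = ", "))
  if (generations_t <= 0) stop("generations_t must be > 0")
  ln_ratio <- log((counts_test_final / counts_ref_final) /
                    (counts_test_initial / counts_ref_initial))
  se <- sqrt(sum(1 / counts)) / generations_t
  structure(list(w_raw = ln_ratio / generations_t + 1,
                 se_w = se, ln_ratio = ln_ratio,
                 generations_t = generations_t, counts = counts),
            class = "fitness_estimate")
}

#' Generations elapsed during a competition
#'
#' Population doublings across all passages:
#' \deqn{t = \log_2(\mathrm{total_{final}} \cdot D / \mathrm{total_{initial}})}
#' where D is the product of all dilution factors applied between the two
#' counts (1 if none).
#'
#' @param total_initial,total_final Total cell counts (both channels).
#' @param dilution_factor_total Combined dilution factor (default 1).
#' @return Number of generations (doublings).
#' @export
estimate_generations <- function(total_initial, total_final,
                                 dilution_factor_total = 1) {
  if (total_initial <= 0 || total_final <= 0 || dilution_factor_total <= 0)
    stop("all inputs must be positive")
  expansion <- total_final * dilution_factor_total / total_initial
  if (expansion < 1) stop("nonpositive net expansion: population shrank")
  log2(expansion)
}

#' Normalise fitness against a label-control competition
#'
#' Divides the raw w by the w of a reference-vs-reference competition that
#' carries only the fluorophore labels, so any label cost cancels and a
#' neutral strain stays at exactly 1.
#'
#' @param w_raw Raw fitness (number or [relative_fitness()] result).
#' @param control_w Fitness of the label-control competition (> 0).
#' @return Normalised fitness w_raw / control_w.
#' @export
normalize_fitness <- function(w_raw, control_w) {
  if (inherits(w_raw, "fitness_estimate")) w_raw <- w_raw$w_raw
  if (inherits(control_w, "fitness_estimate")) control_w <- control_w$w_raw
  if (control_w <= 0) stop("control_w must be > 0")
  w_raw / control_w
}
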