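# Efficiency-corrected qPCR relative quantification.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of threshold cycle (Ct) on log10 template quantity.
#' Primer efficiency is the fold amplification per cycle,
#' \deqn{E = 10^{-1/m}} where m is the slope in cycles per log10 unit. A
#' perfectly doubling primer set has m = -3.3219 and E = 2.
#'
#' @param log_quantity Numeric, log10 of template amount (arbitrary units).
#' @param ct Numeric threshold cycles.
#' @return A list of class `standard_curve` with `slope_m`, `intercept`,
#'   `efficiency_E`, `r_squared`, and the input points.
#' @export
fit_standard_curve <- function(log_quantity, ct) {
  log_quantity <- as.numeric(log_quantity); ct <- as.numeric(ct)
  if (length(unique(log_quantity)) < 3)
    stop("standard curve needs >= 3 distinct quantities")
  fit <- stats::lm(ct ~ log_quantity)
  m <- unname(stats::coef(fit)[2])
  if (!is.finite(m) || m >= 0)
    stop("invalid standard curve: slope must be negative (got ",
         signif(m, 3), ")")
  E <- 10^(-1 / m)
  if (E <= 1 || E > 2.2)
    warning("primer efficiency ", signif(E, 4), " outside (1, 2.2]")
  structure(list(slope_m = m,
                 intercept = unname(stats::coef(fit)[1]),
                 efficiency_E = E,
                 # suppressed: lm warns on exactly collinear (perfect) series
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 log_quantity = log_quantity, ct = ct),
            class = "standard_curve")
}

# Mean Ct for one (sample, primer) cell of a long Ct table; warns when the
# replicate spread exceeds the QC limit.
mean_ct <- function(cts, primer, qc_range = 0.5) {
  cts <- as.numeric(cts)
  if (any(cts <= 0)) stop("Ct values must be positive (primer ", primer, ")")
  if (length(cts) > 1 && diff(range(cts)) > qc_range)
    warning("replicate Ct range ", signif(diff(range(cts)), 3),
            " exceeds QC limit for primer ", primer)
  mean(cts)
}

#' Efficiency-corrected relative quantity against reference genes
#'
#' Computes the copy number (or expression fold-change) of a target gene in a
#' sample relative to a calibrator, normalised by one or more single-copy
#' reference genes:
#' \deqn{n = E_{tgt}^{\Delta Ct,tgt} / C(E_{ref}^{\Delta Ct,ref})}
#' with \eqn{\Delta Ct_x = Ct(\mathrm{calibrator}, x) - Ct(\mathrm{sample}, x)}
#' so that an amplified target (earlier Ct in the sample) gives n > 1.
#' C is the geometric mean of the reference terms by default; `combine =
#' "product"` uses their plain product instead.
#'
#' @param calibrator_cts,sample_cts Data frames with columns `primer_set` and
#'   `ct` (one row per replicate) for the calibrator and sample respectively.
#' @param curves Named list of [fit_standard_curve()] objects (or bare
#'   efficiency numbers), one per primer set.
#' @param target Primer-set name of the target gene.
#' @param references Character vector of reference primer-set names.
#' @param combine `"geomean"` (default) or `"product"`.
#' @param qc_range Replicate-spread QC limit in cycles (default 0.5, warn).
#' @return A list of class `relative_quantity` with `value`, `target_gene`,
#'   `reference_genes`, `method`, and the per-primer `delta_ct` /
#'   `efficiency` used.
#' @export
relative_quantity <- function(calibrator_cts, sample_cts, curves, target,
                              references, combine = c("geomean", "product"),
                              qc_range = 0.5) {
  combine <- match.arg(combine)
  genes <- c(target, references)
  eff <- vapply(genes, function(g) {
    cv <- curves[[g]]
    if (is.null(cv)) stop("no standard curve / efficiency for primer set ", g)
    E <- if (inherits(cv, "standard_curve")) cv$efficiency_E else as.numeric(cv)
    if (E <= 1 || E > 2.2)
      warning("efficiency ", signif(E, 4), " for ", g, " outside (1, 2.2]")
    E
  }, numeric(1))
  dct <- vapply(genes, function(g) {
    cal <- calibrator_cts$ct[calibrator_cts$primer_set == g]
    sam <- sample_cts$ct[sample_cts$primer_set == g]
    if (!length(cal) || !length(sam))
      stop("primer set ", g, " missing from calibrator or sample Ct records")
    mean_ct(cal, g, qc_range) - mean_ct(sam, g, qc_range)
  }, numeric(1))
  ref_terms <- eff[references]^dct[references]
  denom <- switch(combine,
                  geomean = exp(mean(log(ref_terms))),
                  product = prod(ref_terms))
  structure(list(value = unname(eff[target]^dct[target] / denom),
                 target_gene = target, reference_genes = references,
                 method = combine,
                 delta_ct = dct, efficiency = eff),
            class = "relative_quantity")
}
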