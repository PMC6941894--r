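# Synthetic-data generators with known ground truth for every input class.
#
# Noise defaults are plausible bench magnitudes: multiplicative OD noise 1%,
# Ct noise 0.15 cycles, absorbance noise 0.002 A, proportional rate noise 5%,
# count sampling 1e4 events per channel. All are configurable.

#' Simulate a turbidostat OD trace
#'
#' Exponential growth at a true specific rate between dilutions that reset
#' the culture to the target OD, sampled every `sampling_s` seconds with
#' multiplicative lognormal noise. Dilution happens every `cycle_s` seconds.
#'
#' @param mu True specific growth rate (h^-1).
#' @param n_cycles Number of dilution cycles.
#' @param od_target OD right after a dilution.
#' @param cycle_s Dilution period in seconds (default 60).
#' @param sampling_s Sampling period in seconds (default 3).
#' @param noise_sd Standard deviation of the multiplicative lognormal noise
#'   (default 0.01).
#' @param seed Integer seed.
#' @return An [od_trace()] with attribute `truth` (the generating
#'   parameters).
#' @export
sim_od_trace <- function(mu = 0.27, n_cycles = 100, od_target = 0.4,
                         cycle_s = 60, sampling_s = 3, noise_sd = 0.01,
                         seed = 0) {
  set.seed(seed)
  per_cycle <- floor(cycle_s / sampling_s)
  t_within <- (seq_len(per_cycle) - 1) * sampling_s / 3600   # hours
  times <- rep((seq_len(n_cycles) - 1) * cycle_s / 3600, each = per_cycle) +
    rep(t_within, n_cycles)
  od_true <- od_target * exp(mu * rep(t_within, n_cycles))
  noise <- if (noise_sd > 0) exp(stats::rnorm(length(od_true), 0, noise_sd)) else 1
  marks <- ((seq_len(n_cycles) - 1) * per_cycle + 1L)[-1]
  # marks are ground truth here; noise can hide small dilution drops, so the
  # constructor's non-drop warning is expected and muffled
  tr <- withCallingHandlers(
    od_trace(times, od_true * noise, dilution_marks = marks),
    warning = function(w) {
      if (grepl("dilution mark", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  attr(tr, "truth") <- list(mu = mu, n_cycles = n_cycles, noise_sd = noise_sd,
                            seed = seed)
  tr
}

#' Simulate a plate-reader growth curve
#'
#' Modified Gompertz curve plus a flat baseline and additive Gaussian noise.
#'
#' @param mu_max,lag,a_max True Gompertz parameters (h^-1, h, OD).
#' @param baseline Additive baseline absorbance.
#' @param t_max,dt Duration and sampling interval (hours).
#' @param noise_sd Additive noise SD (default 0.002 OD).
#' @param seed Integer seed.
#' @return Data frame `time_h`, `od` with attribute `truth`.
#' @export
sim_growth_curve <- function(mu_max = 0.27, lag = 2, a_max = 0.5,
                             baseline = 0.05, t_max = 24, dt = 1 / 3,
                             noise_sd = 0.002, seed = 0) {
  set.seed(seed)
  t <- seq(0, t_max, by = dt)
  y <- gompertz_model(t, mu_max, lag, a_max) + baseline
  if (noise_sd > 0) y <- y + stats::rnorm(length(t), 0, noise_sd)
  out <- data.frame(time_h = t, od = y)
  attr(out, "truth") <- list(mu_max = mu_max, lag = lag, a_max = a_max,
                             baseline = baseline, noise_sd = noise_sd,
                             seed = seed)
  out
}

#' Simulate a qPCR Ct table from a true copy number
#'
#' Ct values are generated from the amplification model
#' \eqn{Ct = \mathrm{intercept} - \log_E(\mathrm{quantity})} with Gaussian Ct
#' noise. The target quantity in the sample is `copy_number` times the
#' calibrator's; reference genes stay at one copy.
#'
#' @param copy_number True target copy number in the sample.
#' @param efficiencies Named vector of per-primer efficiencies; first name is
#'   the target, the rest references.
#' @param n_replicates Technical replicates per (sample, primer).
#' @param ct_intercept Ct at unit quantity (cycles).
#' @param noise_sd Gaussian Ct noise SD in cycles (default 0.15).
#' @param seed Integer seed.
#' @return List with `calibrator_cts`, `sample_cts` (long data frames
#'   `primer_set`, `ct`) and `truth`.
#' @export
sim_ct_table <- function(copy_number = 7,
                         efficiencies = c(proA = 2, gyrB = 2, icd = 2),
                         n_replicates = 3, ct_intercept = 25,
                         noise_sd = 0.15, seed = 0) {
  set.seed(seed)
  target <- names(efficiencies)[1]
  gen <- function(qty) {
    do.call(rbind, lapply(names(efficiencies), function(g) {
      q <- if (g == target) qty else 1
      ct <- ct_intercept - log(q, base = efficiencies[[g]]) +
        stats::rnorm(n_replicates, 0, noise_sd)
      data.frame(primer_set = g, ct = ct)
    }))
  }
  list(calibrator_cts = gen(1), sample_cts = gen(copy_number),
       truth = list(copy_number = copy_number, efficiencies = efficiencies,
                    noise_sd = noise_sd, seed = seed))
}

#' Simulate a two-colour competition assay
#'
#' Both strains grow deterministically and exponentially (test at
#' `s * mu_ref`); initial and final samples are multinomially counted at
#' `events` cells per sample.
#'
#' @param s Ratio of test to reference growth rate.
#' @param mu_ref Reference growth rate (h^-1).
#' @param hours Competition duration (h).
#' @param events Flow-cytometry events counted per sample (default 1e4 per
#'   channel, i.e. 2e4 total).
#' @param count_noise Multinomial sampling of counts (default `TRUE`;
#'   `FALSE` returns expected counts).
#' @param seed Integer seed.
#' @return List with the four counts, `generations_t` (reference-strain
#'   doublings), and `truth` including the closed-form expected fitness
#'   `w_true = 1 + (s - 1) mu_ref T / t = 1 + (s - 1) ln 2`.
#' @export
sim_competition <- function(s = 1.05, mu_ref = 0.6, hours = 20,
                            events = 2e4, count_noise = TRUE, seed = 0) {
  set.seed(seed)
  n_ref <- exp(mu_ref * hours)
  n_test <- exp(s * mu_ref * hours)
  generations_t <- mu_ref * hours / log(2)   # reference doublings
  draw <- function(p_test) {
    if (count_noise) {
      n <- stats::rmultinom(1, events, c(p_test, 1 - p_test))
      c(test = n[1], ref = n[2])
    } else c(test = events * p_test, ref = events * (1 - p_test))
  }
  init <- draw(0.5)
  fin <- draw(n_test / (n_test + n_ref))
  w_true <- 1 + (s - 1) * mu_ref * hours / generations_t
  list(counts_test_initial = init[["test"]], counts_ref_initial = init[["ref"]],
       counts_test_final = fin[["test"]], counts_ref_final = fin[["ref"]],
       generations_t = generations_t,
       truth = list(s = s, mu_ref = mu_ref, hours = hours, w_true = w_true,
                    seed = seed))
}

#' Simulate a burst-phase progress curve
#'
#' \eqn{f(x) = m x + b (1 - e^{-x})} plus additive absorbance noise.
#'
#' @param m Linear-phase slope (A s^-1).
#' @param b Burst magnitude (A).
#' @param t_max,dt Duration and sampling interval (s).
#' @param noise_sd Additive absorbance noise SD (default 0.002).
#' @param seed Integer seed.
#' @return Data frame `time_s`, `a340` with attribute `truth`.
#' @export
sim_progress_curve <- function(m = 1e-3, b = 0.05, t_max = 60, dt = 0.5,
                               noise_sd = 0.002, seed = 0) {
  set.seed(seed)
  t <- seq(0, t_max, by = dt)
  y <- m * t + b * (1 - exp(-t))
  if (noise_sd > 0) y <- y + stats::rnorm(length(t), 0, noise_sd)
  out <- data.frame(time_s = t, a340 = y)
  attr(out, "truth") <- list(m = m, b = b, noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate Michaelis-Menten initial rates
#'
#' Rates at a geometric ladder of substrate concentrations spanning Km, with
#' proportional Gaussian noise, in triplicate.
#'
#' @param kcat True turnover number (s^-1).
#' @param km True Michaelis constant (M).
#' @param enzyme_conc Enzyme concentration (M).
#' @param n_levels Substrate levels (geometric, Km/8 .. 8 Km).
#' @param n_replicates Replicates per level.
#' @param noise_cv Proportional noise coefficient of variation (default 0.05).
#' @param seed Integer seed.
#' @return Data frame `S`, `v` with attribute `truth`.
#' @export
sim_mm_rates <- function(kcat = 0.046, km = 76e-6, enzyme_conc = 1e-7,
                         n_levels = 8, n_replicates = 3, noise_cv = 0.05,
                         seed = 0) {
  set.seed(seed)
  S <- rep(km * 2^seq(-3, 3, length.out = n_levels), each = n_replicates)
  v <- kcat * enzyme_conc * S / (km + S)
  if (noise_cv > 0) v <- v * (1 + stats::rnorm(length(v), 0, noise_cv))
  out <- data.frame(S = S, v = v)
  attr(out, "truth") <- list(kcat = kcat, km = km, enzyme_conc = enzyme_conc,
                             noise_cv = noise_cv, seed = seed)
  out
}

#' Simulate an allosteric-effector titration
#'
#' \eqn{v/v_0 = (a L + K_d)/(L + K_d)} at a ladder of ligand concentrations
#' including 0, with proportional noise, in triplicate.
#'
#' @param kd True apparent dissociation constant (M).
#' @param a True asymptote at infinite ligand.
#' @param n_levels Nonzero ligand levels (geometric, Kd/16 .. 16 Kd).
#' @param n_replicates Replicates per level.
#' @param noise_cv Proportional noise CV (default 0.05).
#' @param seed Integer seed.
#' @return Data frame `L`, `v_over_v0` with attribute `truth`.
#' @export
sim_allosteric_rates <- function(kd = 0.81e-6, a = 0.27, n_levels = 8,
                                 n_replicates = 3, noise_cv = 0.05,
                                 seed = 0) {
  set.seed(seed)
  L <- rep(c(0, kd * 2^seq(-4, 4, length.out = n_levels)),
           each = n_replicates)
  y <- (a * L + kd) / (L + kd)
  if (noise_cv > 0) y <- y * (1 + stats::rnorm(length(y), 0, noise_cv))
  out <- data.frame(L = L, v_over_v0 = y)
  attr(out, "truth") <- list(kd = kd, a = a, noise_cv = noise_cv, seed = seed)
  out
}

#' Write one deterministic fixture per input class
#'
#' Generates a canonical fixture of every kind at its default true parameters
#' and writes them as TSV files plus a JSON manifest of the generating
#' parameters. Byte-identical across runs for a given seed.
#'
#' @param dir Destination directory (created if absent).
#' @param seed Integer seed shared by all generators.
#' @return Invisibly, the manifest list.
#' @export
fixture_suite <- function(dir, seed = 0) {
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop("cannot create fixture directory ", dir)
  manifest <- list(seed = seed)

  # hour-long cycles so each cycle carries measurable growth above the noise
  tr <- sim_od_trace(n_cycles = 48, cycle_s = 3600, sampling_s = 300,
                     seed = seed)
  write_measurements(data.frame(time_h = tr$times, od = tr$od,
                                dilution = seq_along(tr$od) %in%
                                  tr$dilution_marks),
                     file.path(dir, "trace.tsv"))
  manifest$trace <- attr(tr, "truth")

  gc <- sim_growth_curve(seed = seed)
  write_measurements(gc, file.path(dir, "growth_curve.tsv"))
  manifest$growth_curve <- attr(gc, "truth")

  ct <- sim_ct_table(seed = seed)
  write_measurements(cbind(sample_id = "calibrator", ct$calibrator_cts),
                     file.path(dir, "ct_calibrator.tsv"))
  write_measurements(cbind(sample_id = "sample", ct$sample_cts),
                     file.path(dir, "ct_sample.tsv"))
  manifest$ct_table <- ct$truth

  cp <- sim_competition(seed = seed)
  write_measurements(
    data.frame(channel = c("test", "ref", "test", "ref"),
               timepoint = c("initial", "initial", "final", "final"),
               count = c(cp$counts_test_initial, cp$counts_ref_initial,
                         cp$counts_test_final, cp$counts_ref_final)),
    file.path(dir, "competition.tsv"))
  manifest$competition <- cp$truth

  pc <- sim_progress_curve(seed = seed)
  write_measurements(pc, file.path(dir, "progress_curve.tsv"))
  manifest$progress_curve <- attr(pc, "truth")

  mm <- sim_mm_rates(seed = seed)
  write_measurements(mm, file.path(dir, "mm_rates.tsv"))
  manifest$mm_rates <- attr(mm, "truth")

  al <- sim_allosteric_rates(seed = seed)
  write_measurements(al, file.path(dir, "allosteric_rates.tsv"))
  manifest$allosteric_rates <- attr(al, "truth")

  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
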