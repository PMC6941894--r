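test_that("burst fits recover exact two-phase progress curves", {
  pc <- sim_progress_curve(m = 1e-3, b = 0.05, noise_sd = 0, seed = 1)
  f <- fit_burst(pc$time_s, pc$a340)
  expect_equal(f$slope_m, 1e-3, tolerance = 1e-6)
  expect_equal(f$burst_b, 0.05, tolerance = 1e-6)
  # the model passes through the origin
  expect_equal(1e-3 * 0 + 0.05 * (1 - exp(-0)), 0)
  expect_equal(pc$a340[1], 0)
})

test_that("burst magnitude converts to the free-aldehyde fraction", {
  t <- seq(0, 60, 0.5)
  y <- 1e-3 * t + 0.0056 * (1 - exp(-t))
  f <- fit_burst(t, y, epsilon = 6220, pathlength_cm = 1,
                 total_substrate = 20e-6)
  expect_equal(f$free_fraction, (0.0056 / 6220) / 2e-5, tolerance = 1e-6)
  expect_equal(f$free_fraction, 0.045, tolerance = 1e-3)
})

test_that("linear-window burst fit uses only the post-burst phase", {
  t <- seq(0, 60, 0.5)
  y <- 2e-3 * t + 0.04 * (1 - exp(-t))
  f <- fit_burst(t, y, model = "linear", linear_window = c(10, 60),
                 total_substrate = 2e-5)
  # in the window the exponential is spent: intercept = b, slope = m
  expect_equal(f$slope_m, 2e-3, tolerance = 1e-5)
  expect_equal(f$burst_b, 0.04, tolerance = 1e-4)
  # automatic window lands on the same linear phase
  fa <- fit_burst(t, y, model = "linear")
  expect_equal(fa$slope_m, f$slope_m, tolerance = 0.02)
  expect_error(fit_burst(t, y, model = "linear", linear_window = c(59.4, 60)),
               "fewer than 3")
})

test_that("both burst models agree on the late-time slope", {
  t <- seq(0, 120, 1)
  y <- 1.5e-3 * t + 0.03 * (1 - exp(-t))
  m_exp <- fit_burst(t, y, model = "exponential")$slope_m
  m_lin <- fit_burst(t, y, model = "linear", linear_window = c(20, 120))$slope_m
  expect_equal(m_exp, m_lin, tolerance = 1e-6)
})

test_that("negative bursts clamp the fraction with a warning", {
  t <- seq(0, 60, 2)
  y <- 1e-3 * t - 0.01 * (1 - exp(-t))
  expect_warning(f <- fit_burst(t, y, total_substrate = 2e-5),
                 "clamped")
  expect_equal(f$free_fraction, 0)
})

test_that("floated-rate burst model recovers a non-unit time constant", {
  t <- seq(0, 60, 0.25)
  y <- 1e-3 * t + 0.05 * (1 - exp(-0.35 * t))
  f <- fit_burst(t, y, float_rate = TRUE)
  expect_equal(f$rate_k, 0.35, tolerance = 1e-4)
  expect_equal(f$burst_b, 0.05, tolerance = 1e-4)
})

test_that("Michaelis-Menten fits are exact on noiseless data", {
  # slow neo-activity parameters: kcat 0.21 s^-1, Km 95 uM (free aldehyde)
  mm <- sim_mm_rates(kcat = 0.21, km = 95e-6, enzyme_conc = 2e-7,
                     noise_cv = 0, seed = 1)
  f <- fit_michaelis_menten(mm$S, mm$v, enzyme_conc = 2e-7)
  expect_equal(f$kcat, 0.21, tolerance = 1e-6)
  expect_equal(f$km, 95e-6, tolerance = 1e-6)
  expect_equal(f$kcat_over_km, 0.21 / 95e-6, tolerance = 1e-6)
  expect_equal(signif(f$kcat_over_km, 3), 2210)
  # rate at S = Km is half of kcat * E0
  expect_equal(f$vmax * f$km / (f$km + f$km), f$kcat * 2e-7 / 2)
  # efficiency field is exactly the ratio of the fitted parameters
  expect_identical(f$kcat_over_km, f$kcat / f$km)
})

test_that("Michaelis-Menten fitting commutes with substrate unit change", {
  mm <- sim_mm_rates(kcat = 0.046, km = 76e-6, noise_cv = 0.03, seed = 5)
  f_M <- fit_michaelis_menten(mm$S, mm$v, 1e-7)
  f_mM <- fit_michaelis_menten(mm$S * 1e3, mm$v, 1e-7)
  expect_equal(f_mM$km, f_M$km * 1e3, tolerance = 1e-6)
  expect_equal(f_mM$kcat, f_M$kcat, tolerance = 1e-6)
})

test_that("Michaelis-Menten recovery under proportional noise is tight", {
  res <- vapply(1:200, function(i) {
    mm <- sim_mm_rates(kcat = 0.046, km = 76e-6, noise_cv = 0.05, seed = i)
    f <- fit_michaelis_menten(mm$S, mm$v, 1e-7)
    c(f$kcat / 0.046 - 1, f$km / 76e-6 - 1)
  }, numeric(2))
  expect_lt(stats::median(abs(res[1, ])), 0.02)   # kcat
  expect_lt(stats::median(abs(res[2, ])), 0.08)   # Km
})

test_that("allosteric fits recover inhibitor and activator parameters", {
  # UMP-like inhibition
  al <- sim_allosteric_rates(kd = 0.81e-6, a = 0.27, noise_cv = 0, seed = 1)
  f <- fit_allosteric(al$L, al$v_over_v0)
  expect_true(f$determined)
  expect_equal(f$kd, 0.81e-6, tolerance = 1e-5)
  expect_equal(f$a, 0.27, tolerance = 1e-5)
  expect_lt(f$a, 1)   # inhibitor

  # ornithine-like activation
  al <- sim_allosteric_rates(kd = 130e-6, a = 3.28, noise_cv = 0, seed = 2)
  f <- fit_allosteric(al$L, al$v_over_v0)
  expect_equal(f$kd, 130e-6, tolerance = 1e-5)
  expect_equal(f$a, 3.28, tolerance = 1e-5)
  expect_gt(f$a, 1)   # activator

  # closed form at L = Kd
  expect_equal((0.27 * 0.81 + 0.81) / (0.81 + 0.81), (0.27 + 1) / 2)
})

test_that("allosteric model is monotonic with direction set by a - 1", {
  L <- c(0, 10^seq(-8, -4, length.out = 20))
  inhib <- (0.27 * L + 1e-6) / (L + 1e-6)
  activ <- (3.28 * L + 1e-6) / (L + 1e-6)
  expect_true(all(diff(inhib) < 0))
  expect_true(all(diff(activ) > 0))
  expect_equal(inhib[1], 1)
})

test_that("flat titrations are flagged not-determined", {
  L <- c(0, 10^seq(-7, -4, length.out = 8))
  f <- fit_allosteric(L, rep(1, length(L)))
  expect_false(f$determined)
  expect_equal(f$a, 1)
  expect_true(is.na(f$kd))
})

test_that("derived comparison statistics match hand arithmetic", {
  expect_equal(signif(fold_change(2200, 610), 2), 3.6)
  expect_equal(round(percent_change(21.2e3, 12.9e3)), 64)
  expect_equal(citrulline_conc(0.378), 1e-5)
  expect_equal(coupling_ratio(5e-9, 1e-8), 0.5)
  expect_error(fold_change(1, 0), "zero")
  expect_error(coupling_ratio(1, 0), "zero")
})
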