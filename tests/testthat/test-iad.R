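# Agent-based brute-force simulator: every cell represented explicitly.
# Written independently of the class-based engine; used as a distributional
# oracle on small instances.
agent_wf <- function(k, j, params, n_gens) {
  n <- length(k)
  for (g in seq_len(n_gens)) {
    # selection: resample n offspring with prob proportional to exp(mu dt)
    fit <- array_fitness(k, j, params)
    dt <- log(2) / max(fit)
    idx <- sample.int(n, n, replace = TRUE, prob = exp(fit * dt))
    k <- k[idx]; j <- j[idx]
    # mutation: each wild-type copy mutates independently
    pm <- per_array_mutation_rate(params$mu_gene, pmax(k - j, 1))
    pm[j == k] <- 0
    hit <- stats::runif(n) < pm
    j[hit] <- j[hit] + 1L
    # recombination: per-cell Bernoulli, then hypergeometric redraw of the
    # kept copies from the duplicated pool
    rec <- which(stats::runif(n) < params$rec_rate & k >= 2)
    if (length(rec)) {
      delta <- sample(c(-1L, 0L, 1L), length(rec), replace = TRUE,
                      prob = params$copy_change_probs)
      k2 <- pmin(pmax(k[rec] + delta, 1L), params$k_max)
      j2 <- stats::rhyper(length(rec), m = 2L * j[rec],
                          n = 2L * (k[rec] - j[rec]), k = k2)
      k[rec] <- k2; j[rec] <- j2
    }
  }
  list(k = k, j = j)
}

test_that("per-array mutation frequency scales with copy number", {
  expect_equal(per_array_mutation_rate(1e-6, 10), 1e-5)
  expect_equal(per_array_mutation_rate(1e-7, 10), 1e-6)
  p <- sim_params(mu_nt = 1e-9, gene_length_nt = 1000)
  expect_equal(p$mu_gene, 1e-6)
  # exact form kicks in for large rates
  expect_equal(per_array_mutation_rate(0.01, 10), 1 - 0.99^10)
  expect_error(per_array_mutation_rate(1e-6, 0), "k must be")
})

test_that("the dosage fitness map honours its anchors", {
  p <- sim_params(mu0 = 0.24, s_max = 0.75, cost = 0)
  expect_equal(array_fitness(5, 0, p), 0.24)          # baseline
  expect_equal(array_fitness(7, 7, p), 1.75 * 0.24)   # full sweep: +75%
  expect_equal(array_fitness(7, 1, p), 0.24 * (1 + 0.75 / 7))
  expect_equal(array_fitness(7, 1, p), 0.2657, tolerance = 1e-4)
  # per-copy cost and clamping at zero
  pc <- sim_params(mu0 = 0.24, s_max = 0.75, cost = 0.05)
  expect_equal(array_fitness(7, 7, pc), 1.75 * 0.24 - 0.05 * 6)
  expect_equal(array_fitness(10, 0, pc), 0)   # clamped
  # saturating mode: baseline when A = 0, approaches mu0 (1 + s_max)
  ps <- sim_params(dosage = "saturating", mu0 = 0.24, s_max = 0.75,
                   a_wt = 0, a_mut = 1, k_half = 1)
  expect_equal(array_fitness(7, 0, ps), 0.24)
  expect_gt(array_fitness(7, 7, ps), array_fitness(7, 1, ps))
})

test_that("recombination conserves allele identity", {
  p <- sim_params(seed = 1)
  set.seed(1)
  d0 <- recombine(6, 0, p, n = 500)
  expect_true(all(d0$j == 0))
  dk <- recombine(6, 6, p, n = 500)
  expect_true(all(dk$j == dk$k))
  expect_true(all(d0$k >= 1 & d0$k <= p$k_max))
})

test_that("the homogenization kernel matches hypergeometric enumeration", {
  # k=2, j=1, no copy-number change: drawing 2 from a duplicated pool of
  # 2 mutant + 2 wild-type copies gives j' probabilities {1/6, 4/6, 1/6}
  p <- sim_params(copy_change_probs = c(0, 1, 0), seed = 1)
  set.seed(42)
  d <- recombine(2, 1, p, n = 1e5)
  expect_true(all(d$k == 2))
  probs <- c(1, 4, 1) / 6
  for (jj in 0:2) {
    phat <- mean(d$j == jj)
    se <- sqrt(probs[jj + 1] * (1 - probs[jj + 1]) / 1e5)
    expect_lt(abs(phat - probs[jj + 1]), 3 * se)
  }
})

test_that("population size and copy-number bounds are preserved", {
  p <- sim_params(n_pop = 5000, k_max = 9, seed = 3)
  st <- population_state(p, k = 7, j = 1, count = 50)
  tr <- weaklink:::build_transition(p)
  expect_equal(max(abs(colSums(tr) - 1)), 0, tolerance = 1e-12)
  set.seed(3)
  for (g in 1:20) {
    st <- wf_step(st, p, tr)
    expect_equal(sum(st), 5000)
  }
  tab <- attr(st, "table")
  expect_true(all(tab$k >= 1 & tab$k <= 9 & tab$j >= 0 & tab$j <= tab$k))
})

test_that("neutral dynamics are a martingale", {
  # no mutation, no recombination, flat fitness: allele frequency drifts
  # without bias
  p <- sim_params(mu_gene = 0, rec_rate = 0, s_max = 0, cost = 0,
                  n_pop = 200, k_max = 7, seed = 5)
  tr <- weaklink:::build_transition(p)
  init <- population_state(p, k = c(7, 7), j = c(1, 0), count = c(60, 140),
                           pad_wildtype = NA)
  set.seed(5)
  finals <- vapply(1:1000, function(r) {
    st <- init
    for (g in 1:5) st <- wf_step(st, p, tr)
    weaklink:::state_summary(st)$freq_cell
  }, 0)
  p0 <- 0.3
  # var of the mean after 5 WF generations of drift
  v5 <- p0 * (1 - p0) * (1 - (1 - 1 / 200)^5)
  expect_lt(abs(mean(finals) - p0), 3 * sqrt(v5 / 1000))
})

test_that("deterministic selection follows the haploid logit recursion", {
  # two classes, fitnesses mu1 > mu2, no noise: per generation the log odds
  # of the fitter class increases by exactly (mu1 - mu2) dt
  p <- sim_params(mu_gene = 0, rec_rate = 0, mu0 = 0.24, s_max = 0.75,
                  cost = 0, n_pop = 1e5, k_max = 7, seed = 1)
  tr <- weaklink:::build_transition(p)
  st <- population_state(p, k = c(7, 7), j = c(7, 0), count = c(10, 99990),
                         pad_wildtype = NA)
  mu1 <- array_fitness(7, 7, p); mu2 <- array_fitness(7, 0, p)
  dt <- log(2) / mu1
  s_gen <- exp((mu1 - mu2) * dt) - 1
  tab <- attr(st, "table")
  i1 <- weaklink:::class_index(7L, 7L, 7L)
  i7 <- weaklink:::class_index(7L, 0L, 7L)
  logit <- function(x) log(x[i1] / x[i7])
  l <- logit(st)
  for (g in 1:30) {
    st <- wf_step(st, p, tr, resample = FALSE)
    l2 <- logit(st)
    expect_equal(l2 - l, log(1 + s_gen), tolerance = 1e-12)
    l <- l2
  }
})

test_that("the class engine matches the agent-based oracle in distribution", {
  # small instance: k_max 2, 60 cells, 3 generations, strong rates so all
  # channels act; compare per-class mean counts across replicates
  p <- sim_params(mu_gene = 0.02, rec_rate = 0.3, mu0 = 0.3, s_max = 0.75,
                  cost = 0.01, n_pop = 60, k_max = 2, seed = 9)
  tr <- weaklink:::build_transition(p)
  init_k <- rep(c(1L, 2L, 2L), times = c(20L, 30L, 10L))
  init_j <- rep(c(0L, 0L, 1L), times = c(20L, 30L, 10L))
  n_rep <- 4000
  tab <- weaklink:::class_table(2)
  nc <- nrow(tab)

  set.seed(101)
  cls <- matrix(0, n_rep, nc)
  init <- population_state(p, k = init_k, j = init_j,
                           count = rep(1, length(init_k)), pad_wildtype = NA)
  for (r in 1:n_rep) {
    st <- init
    for (g in 1:3) st <- wf_step(st, p, tr)
    cls[r, ] <- as.numeric(st)
  }

  set.seed(202)
  agt <- matrix(0, n_rep, nc)
  for (r in 1:n_rep) {
    out <- agent_wf(init_k, init_j, p, 3)
    idx <- weaklink:::class_index(out$k, out$j, 2L)
    agt[r, ] <- tabulate(idx, nbins = nc)
  }

  for (c_i in seq_len(nc)) {
    diff_mean <- mean(cls[, c_i]) - mean(agt[, c_i])
    se <- sqrt(stats::var(cls[, c_i]) / n_rep + stats::var(agt[, c_i]) / n_rep)
    expect_lt(abs(diff_mean), 3 * se + 1e-9)
  }
})

test_that("single-lineage homogenization matches the Markov-chain oracle", {
  # (2,1) genotype, recombination prob 0.01/generation, no copy-number
  # change: absorption (j = 0 or 2) happens on each event with prob 1/3,
  # so absorption time is geometric with mean 1 / (0.01 * 1/3) = 300.
  # Transition-matrix oracle: E[T] = (I - Q)^{-1} 1 on the single transient
  # state.
  p <- sim_params(rec_rate = 0.01, copy_change_probs = c(0, 1, 0), seed = 1)
  q_stay <- 1 - 0.01 * (1 - stats::dhyper(1, 2, 2, 2))
  e_oracle <- 1 / (1 - q_stay)
  expect_equal(e_oracle, 300, tolerance = 1e-12)
  set.seed(77)
  times <- vapply(1:2000, function(i) simulate_lineage(2, 1, p), 0L)
  # geometric: sd ~ mean; 3 sigma on the Monte-Carlo mean
  expect_lt(abs(mean(times) - e_oracle), 3 * e_oracle / sqrt(2000))
})

test_that("closed systems preserve heterozygosity forever", {
  p <- sim_params(mu_gene = 0, rec_rate = 0, n_pop = 1000, k_max = 7, seed = 2)
  init <- population_state(p, k = 7, j = 1, count = 1000, pad_wildtype = NA)
  res <- run_iad(p, n_generations = 50, n_replicates = 1, init = init)
  expect_true(all(res$trajectories$heterozygosity == 1))
  expect_true(all(is.na(res$events$loh_generation)))
})

test_that("identical seeds give bit-identical trajectories", {
  p <- sim_params(n_pop = 2000, k_max = 7, seed = 42)
  init <- population_state(p, k = 7, j = 1, count = 5)
  r1 <- run_iad(p, n_generations = 40, n_replicates = 3, init = init)
  r2 <- run_iad(p, n_generations = 40, n_replicates = 3, init = init)
  expect_identical(r1, r2)
  p2 <- sim_params(n_pop = 2000, k_max = 7, seed = 43)
  r3 <- run_iad(p2, n_generations = 40, n_replicates = 3, init = init)
  expect_false(identical(r1$trajectories, r3$trajectories))
})

test_that("arrays homogenize before second within-array mutations matter", {
  # At the default rates, recombination (~1/100 divisions) homogenizes the
  # amplified array long before a second, independent beneficial mutation
  # (1e-6 per copy per division) could arise in a different copy of the
  # array and rise to 1% frequency. The second-mutation oracle is a
  # branching-process companion fed by the recorded trajectories: targets
  # are the wild-type copies inside carrier arrays, a successful event
  # establishes with prob ~2 s (s the per-generation advantage of one extra
  # beneficial copy over its sibling background), then grows at
  # ln(1 + s) per generation towards 1% of the population.
  p <- sim_params(seed = 17)
  res <- run_iad(p, n_generations = 2000, n_replicates = 30,
                 record_every = 1)
  ev <- res$events
  fixed <- which(!is.na(ev$fixed_generation))
  expect_gt(length(fixed), 20)

  set.seed(17)
  ok <- vapply(fixed, function(r) {
    tr <- res$trajectories[res$trajectories$replicate == r, ]
    wt_in_carriers <- pmax(tr$mean_k * p$n_pop *
                             (tr$freq_cell - tr$freq_copy), 0)
    s2 <- exp(p$mu0 * p$s_max / 7 * tr$dt) - 1
    rate <- wt_in_carriers * p$mu_gene * 2 * s2
    u <- stats::runif(1)
    first <- match(TRUE, 1 - exp(-cumsum(rate)) > u)
    t2 <- Inf
    if (!is.na(first)) {
      lsize <- cumsum(c(0, log(1 + s2[-seq_len(first)])))
      hit <- match(TRUE, lsize >= log(0.01 * p$n_pop))
      if (!is.na(hit)) t2 <- tr$generation[first] + hit - 1
    }
    ev$first_full_generation[r] < t2
  }, NA)
  expect_gte(mean(ok), 0.9)
})
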