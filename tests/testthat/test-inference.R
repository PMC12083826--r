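test_that("prior density is uniform in the transformed coordinates", {
  prior <- prior_spec()
  centre <- c(0.05, 70, 0, 1, 10, 30, 30)
  expect_true(is.finite(log_prior(centre, prior)))
  # outside the box
  expect_identical(log_prior(c(0.2, 70, 0, 1, 10, 30, 30), prior), -Inf)
  expect_identical(log_prior(c(0.05, 70, 0, 1, 10, 30, 30000), prior), -Inf)
  expect_identical(log_prior(c(0.05, 70, 2000, 1, 10, 30, 30), prior), -Inf)
  # log-uniform parameters carry a 1/value density on the natural scale
  lp10 <- log_prior(c(0.05, 10, 0, 1, 10, 30, 30), prior)
  lp100 <- log_prior(c(0.05, 100, 0, 1, 10, 30, 30), prior)
  expect_equal(exp(lp10 - lp100), 10)
  # prior_spec validation
  expect_error(prior_spec(lower = c(r1 = 0)), "positive")
  expect_error(prior_spec(lower = c(p_b = 0.2)), "below")
  expect_error(prior_spec(lower = c(nope = 1)), "unknown")
})

test_that("log likelihood is a sum of Gaussian terms over observations", {
  th <- c(0.05, 200, 300, 1, 10, 100, 10)
  expect_identical(log_likelihood(th, NULL, 0.5, 0), 0)
  obs1 <- data.frame(omega_rf_hz = 0, omega1_hz = 0, t_ex_s = 0,
                     intensity = 10)  # reference: model predicts i0 exactly
  expect_equal(log_likelihood(th, obs1, 0.5, 0), -0.5 * log(2 * pi * 0.25))
  obs2 <- rbind(obs1, obs1)
  expect_equal(log_likelihood(th, obs2, 0.5, 0),
               2 * log_likelihood(th, obs1, 0.5, 0))
  expect_error(log_likelihood(th, obs1, 0, 0), "positive")
  # replicate accumulation equals explicit summation at a real condition
  obs3 <- data.frame(omega_rf_hz = c(300, 300, -100), omega1_hz = 25,
                     t_ex_s = 0.6, intensity = c(4.2, 4.5, 7.0))
  byrow <- sum(vapply(seq_len(3), function(i)
    log_likelihood(th, obs3[i, ], 0.5, 0), numeric(1)))
  expect_equal(log_likelihood(th, obs3, 0.5, 0), byrow)
})

test_that("with no data the sampler reproduces the prior marginals", {
  d <- sample_posterior(NULL, sigma = 1, omega_a = 0,
                        settings = mcmc_settings(burnin = 5000,
                                                 steps = 100000, thin = 50),
                        seed = 11)
  dr <- d$draws
  expect_equal(nrow(dr), 2000)
  ks <- suppressWarnings(c(
    stats::ks.test(dr[, "p_b"], "punif", 0, 0.1)$statistic,
    stats::ks.test(log(dr[, "k_ex"]), "punif", log(5), log(1000))$statistic,
    stats::ks.test(dr[, "omega_b"], "punif", -1000, 1000)$statistic,
    stats::ks.test(log(dr[, "r1"]), "punif", log(0.1), log(10))$statistic,
    stats::ks.test(log(dr[, "r2a"] / dr[, "r1"]), "punif", 0, log(100))$statistic,
    stats::ks.test(log(dr[, "r2b"] / dr[, "r1"]), "punif", 0, log(1000))$statistic,
    stats::ks.test(log(dr[, "i0"]), "punif", log(0.1), log(10000))$statistic))
  expect_true(all(ks < 0.05))
})

test_that("retained draws always lie inside the prior box", {
  truth <- generate_virtual_protein(1, seed = 41)
  obs <- simulate_schedule_obs(truth,
                               conventional_schedule(11, -1000, 1000,
                                                     c(10, 50), 0.5, 1))
  d <- sample_posterior(obs, sigma = truth$sigma, omega_a = truth$omega_a,
                        settings = quick_loop(), seed = 42)
  dr <- d$draws
  expect_true(all(dr[, "p_b"] >= 0 & dr[, "p_b"] <= 0.1))
  expect_true(all(dr[, "k_ex"] >= 5 & dr[, "k_ex"] <= 1000))
  expect_true(all(abs(dr[, "omega_b"]) <= 1000))
  expect_true(all(dr[, "r1"] >= 0.1 & dr[, "r1"] <= 10))
  expect_true(all(dr[, "r2a"] / dr[, "r1"] >= 1 - 1e-12 &
                    dr[, "r2a"] / dr[, "r1"] <= 100 + 1e-9))
  expect_true(all(dr[, "r2b"] / dr[, "r1"] >= 1 - 1e-12 &
                    dr[, "r2b"] / dr[, "r1"] <= 1000 + 1e-9))
  expect_true(all(dr[, "i0"] >= 0.1 & dr[, "i0"] <= 10000))
})

test_that("identical seed and inputs give a bit-identical chain", {
  truth <- generate_virtual_protein(1, seed = 7)
  obs <- simulate_schedule_obs(truth,
                               conventional_schedule(5, -500, 500, 25, 0.5, 1))
  d1 <- sample_posterior(obs, sigma = truth$sigma, omega_a = truth$omega_a,
                         settings = quick_loop(), seed = 99)
  d2 <- sample_posterior(obs, sigma = truth$sigma, omega_a = truth$omega_a,
                         settings = quick_loop(), seed = 99)
  expect_identical(d1$draws, d2$draws)
  expect_identical(d1$loglik, d2$loglik)
})

test_that("a dense profile pins every parameter within its 99% interval", {
  truth <- generate_virtual_protein(1, seed = 3)
  sched <- conventional_schedule(51, -1000, 1000, c(10, 50), 0.5, 3)
  set.seed(14)
  obs <- simulate_schedule_obs(truth, sched)
  d <- sample_posterior(obs, sigma = truth$sigma, omega_a = truth$omega_a,
                        settings = mcmc_settings(burnin = 10000,
                                                 steps = 20000, thin = 20),
                        seed = 15)
  qs <- apply(d$draws, 2, stats::quantile, probs = c(0.005, 0.995))
  tv <- as.numeric(truth[1, PAR_NAMES])
  expect_true(all(tv >= qs[1, ] & tv <= qs[2, ]))
})

test_that("posterior summaries report the MAP draw and central intervals", {
  # degenerate draws: MAP is that draw, intervals have zero width
  one <- c(0.05, 100, 300, 1, 10, 100, 10)
  fake <- structure(list(residue_id = "r", omega_a = 0, sigma = 1,
                         draws = matrix(rep(one, each = 200), 200, 7,
                                        dimnames = list(NULL, PAR_NAMES)),
                         loglik = rep(-1, 200),
                         meta = list(acceptance_rate = 0.3)),
                    class = "posterior_draws")
  s <- summarize_posterior(fake)
  expect_equal(s$map, one)
  expect_equal(s$ci_lo, s$ci_hi)

  # uniform draws: the 68.3% interval approaches [0.1585, 0.8415]
  set.seed(2)
  u <- runif(20000)
  fake$draws <- matrix(rep(u, 7), 20000, 7,
                       dimnames = list(NULL, PAR_NAMES))
  fake$loglik <- rep(0, 20000)
  s <- summarize_posterior(fake)
  expect_lt(abs(s$ci_lo[3] - 0.1585), 0.01)
  expect_lt(abs(s$ci_hi[3] - 0.8415), 0.01)

  # interval bounds are invariant to draw order
  perm <- sample.int(20000)
  fake2 <- fake
  fake2$draws <- fake$draws[perm, ]
  fake2$loglik <- fake$loglik[perm]
  s2 <- summarize_posterior(fake2)
  expect_equal(s$ci_lo, s2$ci_lo)
  expect_equal(s$ci_hi, s2$ci_hi)
  expect_error(summarize_posterior(structure(list(draws = fake$draws[1:10, ]),
                                             class = "posterior_draws")),
               "100")
})

test_that("credible intervals are exactly calibrated on single-mode targets", {
  # reference-only data: the posterior factorizes into a unimodal basal
  # intensity posterior times the prior, so a correct sampler must hit
  # the nominal 68.3% coverage exactly
  set.seed(777)
  hits <- 0; tot <- 0
  for (r in 1:300) {
    d <- draw_prior_box(1)
    th <- as.numeric(d[1, 1:7])
    sg <- th[7] / 20
    obs <- data.frame(omega_rf_hz = 0, omega1_hz = 0, t_ex_s = 0,
                      intensity = th[7] + rnorm(1, 0, sg))
    ps <- sample_posterior(obs, sigma = sg, omega_a = d[1, "omega_a"],
                           settings = mcmc_settings(burnin = 3000,
                                                    steps = 6000, thin = 10))
    s <- summarize_posterior(ps)
    hits <- hits + sum(th >= s$ci_lo & th <= s$ci_hi)
    tot <- tot + 7
  }
  expect_lt(abs(hits / tot - 0.683), 3 * sqrt(0.683 * 0.317 / tot))
})

test_that("the minor-state shift posterior contracts as observations accumulate", {
  # contraction presumes a resolvable minor state: when the minor shift
  # sits on top of the major resonance the data can never localize it
  set.seed(19)
  repeat {
    truth <- generate_virtual_protein(1)
    if (abs(truth$omega_b - truth$omega_a) >= 100) break
  }
  grid <- build_candidate_grid(-1000, 1000, 20, c(10, 50), 0.5,
                               include_reference = FALSE)
  width_at <- function(obs, n_obs, seed) {
    # pooled chains give honest widths even while the minor-shift
    # posterior is still multimodal
    d <- sample_posterior(obs[seq_len(n_obs), ], sigma = truth$sigma,
                          omega_a = truth$omega_a, settings = quick_final(),
                          seed = seed, n_chains = 4)
    s <- summarize_posterior(d)
    s$ci_hi[s$parameter == "omega_b"] - s$ci_lo[s$parameter == "omega_b"]
  }
  # average width over replicate measurement orderings: whether the first
  # ten points happen to graze the dip is luck, the average is not
  w10 <- w100 <- numeric(4)
  for (rep in 1:4) {
    set.seed(20 + rep)
    rows <- grid[sample.int(nrow(grid), 100), ]
    obs <- do.call(rbind, lapply(seq_len(100), function(n)
      virtual_observe(truth, rows[n, 1:3], n)))
    w10[rep] <- width_at(obs, 10, 31 + rep)
    w100[rep] <- width_at(obs, 100, 131 + rep)
  }
  expect_lte(mean(w100), mean(w10) * 1.1)  # non-increasing up to noise
})

test_that("mcmc settings presets match the in-loop and detailed analyses", {
  s <- mcmc_settings("loop")
  expect_equal(c(s$burnin, s$steps, s$thin), c(20000, 30000, 50))
  expect_equal(s$steps / s$thin, 600)  # retained draws per chain
  s <- mcmc_settings("long")
  expect_equal(c(s$burnin, s$steps), c(1e5, 1e6))
  expect_error(mcmc_settings(burnin = 10, steps = 5, thin = 10))
})
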