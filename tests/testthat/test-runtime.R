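test_that("the virtual spectrometer adds calibrated Gaussian noise to the exact response", {
  truth <- generate_virtual_protein(2, seed = 61)
  cnd <- irr_condition(truth$omega_b[1], 25, 0.5)
  exact <- vapply(1:2, function(k)
    propagate_exact(.ns$truth_model(truth, k), cnd), numeric(1))

  # noiseless limit
  tr0 <- truth
  tr0$sigma <- rep(1e-12, 2)
  ob <- virtual_observe(tr0, cnd)
  expect_equal(ob$intensity, exact, tolerance = 1e-9)

  # repeated observations: mean and SD follow the noise model
  set.seed(62)
  n <- 4000
  ys <- t(replicate(n, virtual_observe(truth, reference_condition())$intensity))
  for (k in 1:2) {
    expect_lt(abs(mean(ys[, k]) - truth$i0[k]), 3 * truth$sigma[k] / sqrt(n))
    expect_lt(abs(stats::sd(ys[, k]) - truth$sigma[k]), 0.05 * truth$sigma[k])
    # the reference read-out realizes the configured signal-to-noise ratio
    expect_equal(mean(ys[, k]) / stats::sd(ys[, k]), 20, tolerance = 0.1)
  }
})

test_that("a one-iteration run contains the reference observation and one utility table", {
  truth <- generate_virtual_protein(1, seed = 63)
  cands <- build_candidate_grid(-500, 500, 100, c(10, 50), 0.5)
  rec <- run_adaptive(truth, cands, n_iterations = 1, seed = 64,
                      loop_settings = quick_loop(), final_settings = NULL)
  expect_equal(length(rec$iterations), 1)
  expect_true(is_reference(rec$iterations[[1]]$condition))
  expect_equal(nrow(rec$observations), 1)
  expect_equal(rec$observations$t_ex_s, 0)
  expect_equal(nrow(rec$iterations[[1]]$utility), nrow(cands))
  expect_error(run_adaptive(truth, cands[!cands$reference, ],
                            n_iterations = 1, seed = 1,
                            loop_settings = quick_loop()),
               "reference")
})

test_that("every selected condition is the arg-max of the preceding utility table", {
  truth <- generate_virtual_protein(1, seed = 65)
  cands <- build_candidate_grid(-800, 800, 100, c(10, 50), 0.5)
  rec <- run_adaptive(truth, cands, n_iterations = 6, seed = 66,
                      loop_settings = quick_loop(), final_settings = NULL)
  for (n in 2:6) {
    prev <- rec$iterations[[n - 1]]
    cur <- rec$iterations[[n]]$condition
    expect_true(conditions_equal(cur, prev$next_condition))
    u <- prev$utility
    picked <- u$omega_rf_hz == cur$omega_rf_hz &
      u$omega1_hz == cur$omega1_hz & u$t_ex_s == cur$t_ex_s
    expect_equal(u$mi_total_nat[picked], max(u$mi_total_nat))
  }
  # repetition is allowed and accumulates observations, one per iteration
  expect_equal(nrow(rec$observations), 6)
  # realized KL recorded from iteration 2 onwards
  expect_null(rec$iterations[[1]]$realized_kl)
  expect_true(all(vapply(2:6, function(n)
    rec$iterations[[n]]$realized_kl >= 0, logical(1))))
})

test_that("adaptive runs are bit-identical under a fixed seed", {
  truth <- generate_virtual_protein(2, seed = 67)
  cands <- build_candidate_grid(-600, 600, 200, 25, 0.5)
  rec1 <- run_adaptive(truth, cands, n_iterations = 3, seed = 68,
                       loop_settings = quick_loop(),
                       final_settings = quick_final())
  rec2 <- run_adaptive(truth, cands, n_iterations = 3, seed = 68,
                       loop_settings = quick_loop(),
                       final_settings = quick_final())
  expect_identical(rec1$observations, rec2$observations)
  expect_identical(rec1$final$summaries, rec2$final$summaries)
  expect_identical(lapply(rec1$iterations, `[[`, "condition"),
                   lapply(rec2$iterations, `[[`, "condition"))
})

test_that("conventional schedules reproduce the published layout", {
  s <- conventional_schedule(63, -1000, 1000, c(6.3, 13.0, 26.2), 0.5, 3)
  expect_equal(nrow(s), 192)
  offs <- unique(s$omega_rf_hz[s$t_ex_s > 0])
  expect_equal(length(offs), 63)
  expect_equal(diff(sort(offs))[1], 2000 / 62, tolerance = 1e-9)  # 32.3 Hz
  expect_equal(sum(s$t_ex_s == 0), 3)
  expect_true(all(s$t_ex_s[1:3] == 0))  # references first
  s2 <- conventional_schedule(2, -100, 100, 10, 0.5, 0)
  expect_equal(s2$omega_rf_hz, c(-100, 100))
  expect_error(conventional_schedule(1, -100, 100, 10, 0.5, 0), "n_offsets")
})

test_that("conventional runs observe the whole schedule and analyze once", {
  truth <- generate_virtual_protein(3, seed = 71)
  sched <- conventional_schedule(7, -900, 900, c(10, 50), 0.5, 2)
  rec <- run_conventional(truth, sched, seed = 72, settings = quick_final())
  expect_equal(nrow(rec$observations), nrow(sched) * 3)
  expect_equal(length(rec$final$draws), 3)
  rec2 <- run_conventional(truth, sched, seed = 72, settings = quick_final())
  expect_identical(rec$observations, rec2$observations)
  expect_identical(rec$final$summaries, rec2$final$summaries)
  expect_error(run_conventional(truth, sched[0, ], seed = 1), "empty")

  # parameter recovery: the 99% interval covers the truth for almost all
  # (residue, parameter) pairs
  hits <- 0
  for (k in 1:3) {
    qs <- apply(rec$final$draws[[k]]$draws, 2, stats::quantile,
                probs = c(0.005, 0.995))
    tv <- as.numeric(truth[k, PAR_NAMES])
    hits <- hits + sum(tv >= qs[1, ] & tv <= qs[2, ])
  }
  expect_gte(hits, 19)  # out of 21
})

test_that("mid-run utility reweighting refocuses the design on one residue", {
  truth <- generate_virtual_protein(2, seed = 73)
  cands <- build_candidate_grid(-800, 800, 200, c(10, 50), 0.5)
  wfun <- function(n) if (n >= 3) c(1, 0) else c(1, 1)
  rec <- run_adaptive(truth, cands, n_iterations = 4, seed = 74,
                      loop_settings = quick_loop(), final_settings = NULL,
                      weights = wfun)
  u4 <- rec$iterations[[4]]$utility
  col1 <- paste0("mi_residue_", truth$residue_id[1], "_nat")
  expect_equal(u4$mi_total_nat, u4[[col1]])
})

test_that("early iterations explore offsets, late iterations concentrate, and the selected utility decays", {
  cands <- build_candidate_grid(-1000, 1000, 25, c(10, 50), 0.5)
  explore_win <- 1:20
  exploit_win <- 81:100
  votes_explore <- 0
  votes_decay <- 0
  for (seed in 1:3) {
    truth <- generate_virtual_protein(1, seed = 80 + seed)
    rec <- run_adaptive(truth, cands, n_iterations = 100, seed = 90 + seed,
                        loop_settings = quick_loop(), final_settings = NULL)
    offs <- vapply(rec$iterations, function(it) it$condition$omega_rf_hz,
                   numeric(1))
    sel_mi <- vapply(rec$iterations, function(it) max(it$utility$mi_total_nat),
                     numeric(1))
    if (length(unique(offs[explore_win])) > length(unique(offs[exploit_win])))
      votes_explore <- votes_explore + 1
    if (stats::median(sel_mi[exploit_win]) < stats::median(sel_mi[explore_win]))
      votes_decay <- votes_decay + 1
  }
  expect_gte(votes_explore, 2)
  expect_gte(votes_decay, 2)
})

test_that("longer saturation is preferred when the estimated R1rho is small", {
  cands <- build_candidate_grid(-1000, 1000, 50, 25, c(0.5, 0.75, 1.0))
  tex <- numeric(0)
  inv_r1rho <- numeric(0)
  for (seed in 1:2) {
    truth <- generate_virtual_protein(1, seed = 84 + seed)
    rec <- run_adaptive(truth, cands, n_iterations = 30, seed = 94 + seed,
                        loop_settings = quick_loop(), final_settings = NULL)
    for (n in 5:30) {
      it <- rec$iterations[[n]]
      if (it$condition$t_ex_s == 0 || it$condition$omega1_hz == 0) next
      s <- it$summaries[[1]]
      map <- stats::setNames(s$map, s$parameter)
      m <- residue_model(map["p_b"], map["k_ex"], map["omega_b"], map["r1"],
                         map["r2a"], map["r2b"], map["i0"], truth$omega_a,
                         validate = FALSE)
      rr <- r1rho_fast(m, irr_condition(it$condition$omega_rf_hz,
                                        it$condition$omega1_hz, 0.5))
      tex <- c(tex, it$condition$t_ex_s)
      inv_r1rho <- c(inv_r1rho, 1 / rr)
    }
  }
  rho <- stats::cor(tex, pmin(inv_r1rho, 2), method = "spearman")
  expect_gt(rho, 0)
})

test_that("run records persist as a readable directory of text files", {
  truth <- generate_virtual_protein(2, seed = 75)
  cands <- build_candidate_grid(-500, 500, 250, 25, 0.5)
  rec <- run_adaptive(truth, cands, n_iterations = 2, seed = 76,
                      loop_settings = quick_loop(),
                      final_settings = quick_final())
  dir <- tempfile("runrec")
  save_run_record(rec, dir)
  expect_true(file.exists(file.path(dir, "observations.csv")))
  expect_true(file.exists(file.path(dir, "utility_iter001.csv")))
  expect_true(file.exists(file.path(dir, "utility_iter002.csv")))
  expect_true(file.exists(file.path(dir, "summaries.csv")))
  obs <- read_observations(file.path(dir, "observations.csv"))
  expect_equal(obs$intensity, rec$observations$intensity)
  meta <- jsonlite::read_json(file.path(dir, "run_meta.json"))
  expect_equal(meta$seed, 76)
  summ <- utils::read.csv(file.path(dir, "summaries.csv"))
  expect_equal(nrow(summ), 14)  # 2 residues x 7 parameters
})
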