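# constraints derived from deterministic truth for one locus
truth_constraints <- function(maf0, scenario, seed, days = c(2, 6, 10, 14, 22),
                              tolerance = 0.10) {
  sched <- simulate_fitness_schedule(1, length(days), scenario,
                                     seed = seed)[1, , ]
  tr <- propagate_truth(hwe_expected(maf0), sched)
  list(truth = tr,
       constraints = empirical_constraints(days, tr$maf[-1],
                                           tr$survival[-1],
                                           tolerance = tolerance))
}

test_that("constraint checks use absolute MAF and relative survival scales", {
  ec <- empirical_constraints(2, maf = 0.45, survival = 0.52)
  r <- check_constraints(0.30, 0.52, ec, day = 2)
  expect_false(r$ok) # |0.30 - 0.45| = 0.15 > 0.10
  expect_equal(r$reason, "maf")
  r <- check_constraints(0.45, 0.50, ec, day = 2)
  expect_true(r$ok) # relative survival deviation ~0.038
  # both failing reports both
  r <- check_constraints(0.30, 0.10, ec, day = 2)
  expect_equal(r$reason, "maf+survival")
  # a vacuous tolerance accepts everything
  ec1 <- empirical_constraints(2, 0.45, 0.52, tolerance = 1.0)
  expect_true(check_constraints(0.99, 0.01, ec1, day = 2)$ok)
  expect_error(check_constraints(0.3, 0.5, ec, day = 7), "no constraint")
  expect_error(empirical_constraints(c(2, 6), c(0.4, 0.4), c(0.5, 0.6)),
               "non-increasing")
  expect_error(empirical_constraints(2, 0.4, 0), "positive")
})

test_that("a vacuous tolerance accepts every proposal first try", {
  tc <- truth_constraints(0.3, "neutral", seed = 51)
  tr <- tc$truth
  # tolerance 1 on absolute scales cannot reject any proposal
  ec <- empirical_constraints(c(2, 6, 10, 14, 22), tr$maf[-1],
                              tr$survival[-1], tolerance = 1,
                              maf_scale = "absolute",
                              survival_scale = "absolute")
  fc <- forecast_locus(hwe_expected(0.3), ec, n_accept = 10,
                       seed = 1, batch = 1)
  expect_equal(fc$n_accepted, 10L)
  # one proposal per interval per trajectory, no restarts
  expect_equal(fc$diagnostics$n_proposals, 10L * 5L)
  expect_equal(fc$diagnostics$n_restarts, 0L)
})

test_that("the forecaster is deterministic given the seed", {
  tc <- truth_constraints(0.25, "balanced", seed = 52)
  a <- forecast_locus(hwe_expected(0.25), tc$constraints, n_accept = 8,
                      seed = 4)
  b <- forecast_locus(hwe_expected(0.25), tc$constraints, n_accept = 8,
                      seed = 4)
  expect_identical(a$states, b$states)
  expect_identical(a$fitness, b$fitness)
})

test_that("accepted trajectories satisfy all constraints post hoc", {
  tc <- truth_constraints(0.35, "directional", seed = 53)
  fc <- forecast_locus(hwe_expected(0.35), tc$constraints, n_accept = 20,
                       seed = 5)
  ec <- tc$constraints
  for (t in seq_len(fc$n_accepted)) {
    for (j in seq_along(ec$days)) {
      chk <- check_constraints(fc$maf[t, j + 1], fc$survival[t, j + 1],
                               ec, day = ec$days[j])
      expect_true(chk$ok)
    }
    # states stay on the simplex, tracked MAF is consistent
    sums <- apply(fc$states[t, , ], 1, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
    expect_true(all(fc$states[t, , ] >= -1e-12))
    expect_equal(fc$maf[t, ],
                 fc$states[t, , 2] / 2 + fc$states[t, , 3],
                 tolerance = 1e-9)
  }
})

test_that("infeasible constraints return a partial ensemble, not a hang", {
  # demand an impossible MAF jump under a microscopic tolerance
  ec <- empirical_constraints(c(2, 6), maf = c(0.9, 0.05),
                              survival = c(0.9, 0.5), tolerance = 0.001)
  fc <- forecast_locus(hwe_expected(0.05), ec, n_accept = 3,
                       max_attempts_per_interval = 200, max_restarts = 2,
                       seed = 6)
  expect_true(fc$infeasible)
  expect_equal(fc$n_accepted, 0L)
  expect_equal(fc$diagnostics$failed_slots, 3L)
})

test_that("ensemble summaries average correctly and count records", {
  # hand-built ensemble of two trajectories
  ens <- structure(list(
    days = c(0, 2),
    states = array(c(0.3, 0.2, 0.3, 0.2,   # f_AA by (traj, day)
                     0.4, 0.6, 0.4, 0.6,   # f_AB
                     0.3, 0.2, 0.3, 0.2),  # f_BB
                   dim = c(2, 2, 3)),
    fitness = array(0.5, dim = c(2, 1, 3)),
    survival = matrix(c(1, 1, 0.5, 0.5), 2),
    maf = matrix(c(0.5, 0.5, 0.5, 0.5), 2),
    n_accepted = 2L, infeasible = FALSE,
    diagnostics = list(n_proposals = 2, n_restarts = 0, failed_slots = 0)
  ), class = "trajectory_ensemble")
  s <- summarize_ensemble(ens)
  ab2 <- s$genotype[s$genotype$day == 2 & s$genotype$genotype == "AB", ]
  expect_equal(ab2$mean, 0.5) # mean of 0.4 and 0.6
  expect_equal(s$n_records, 4L) # 2 trajectories x 2 time points
  # identical trajectories give zero-width intervals
  ens0 <- ens
  ens0$states[2, , ] <- ens0$states[1, , ]
  s0 <- summarize_ensemble(ens0)
  expect_true(all(s0$genotype$hi - s0$genotype$lo < 1e-12))
  ens1 <- ens
  ens1$n_accepted <- 1L
  expect_error(summarize_ensemble(ens1), "at least two")
})

test_that("bookkeeping counts one record per locus, trajectory and time point", {
  expect_identical(forecast_bookkeeping(473, 50, 6), 141900L)
  expect_identical(forecast_bookkeeping(1, 2, 3), 6L)
})

test_that("neutral data recover no spurious fitness difference between represented genotypes", {
  # On neutral loci the well-represented genotype classes (AA and AB carry
  # >= 3/4 of the cohort at q <= 0.5) must get indistinguishable fitness.
  # The rare minor homozygote is excluded here: with f_BB = q^2 small its
  # acceptance likelihood is nearly flat, so its accepted-fitness mean sits
  # at the uniform-proposal mean rather than at the empirical mean fitness
  # (a documented limitation of the accept/reject scheme).
  set.seed(61)
  n_loci <- 50
  diff_aa_ab <- matrix(NA_real_, n_loci, 5)
  for (i in seq_len(n_loci)) {
    tc <- truth_constraints(runif(1, 0.15, 0.5), "neutral", seed = 600 + i)
    fc <- forecast_locus(hwe_expected(tc$truth$maf[1]), tc$constraints,
                         n_accept = 20, seed = 700 + i)
    s <- summarize_ensemble(fc)
    for (j in 1:5) {
      m <- s$fitness$mean[s$fitness$day_from == fc$days[j]]
      diff_aa_ab[i, j] <- m[1] - m[2]
    }
  }
  expect_true(all(abs(colMeans(diff_aa_ab)) < 0.1))
})

test_that("strong directional selection is recovered with the right ordering", {
  set.seed(62)
  n_loci <- 20
  ok <- logical(n_loci)
  for (i in seq_len(n_loci)) {
    sched <- matrix(rep(c(0.85, 0.55, 0.25), each = 5), 5)
    tr <- propagate_truth(hwe_expected(runif(1, 0.25, 0.5)), sched)
    ec <- empirical_constraints(c(2, 6, 10, 14, 22), tr$maf[-1],
                                tr$survival[-1])
    fc <- forecast_locus(tr$states[1, ], ec, n_accept = 20, seed = 800 + i)
    s <- summarize_ensemble(fc)
    waa <- s$fitness$mean[s$fitness$genotype == "AA"]
    wbb <- s$fitness$mean[s$fitness$genotype == "BB"]
    ok[i] <- all(waa > wbb)
  }
  expect_gte(mean(ok), 0.9)
})
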