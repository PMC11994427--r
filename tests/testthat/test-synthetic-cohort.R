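test_that("cohorts are deterministic under a seed and differ across seeds", {
  a <- generate_cohort(synthetic_spec(seed = 4))
  b <- generate_cohort(synthetic_spec(seed = 4))
  c <- generate_cohort(synthetic_spec(seed = 5))
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$subjects$tsh, c$subjects$tsh))
})

test_that("without assay noise the measured pair recovers the true capacity", {
  sp <- synthetic_spec(n_euthyroid = 150, n_sh = 80,
                       noise_cv_tsh = 0, noise_cv_ft4 = 0, seed = 9)
  co <- generate_cohort(sp)
  gt_est <- compute_gt(co$subjects$tsh, co$subjects$ft4)
  expect_equal(gt_est, co$truth$gt_true_pmol_s, tolerance = 1e-12)
  expect_equal(co$subjects$tsh, co$truth$tsh_true)
  expect_equal(co$subjects$ft4, co$truth$ft4_true)
})

test_that("generated subjects satisfy the group admissibility ranges", {
  co <- generate_cohort(synthetic_spec(seed = 13))
  s <- co$subjects
  expect_true(all(s$tsh > 0 & s$ft4 > 0))
  eu <- s[s$group == "euthyroid", ]
  sh <- s[s$group == "sh", ]
  expect_true(all(eu$tsh > 0.6 & eu$tsh <= 4.5))
  expect_true(all(sh$tsh > 4.5 & sh$tsh <= 15))
  expect_true(all(sh$ft4 >= 10.43 & sh$ft4 <= 24.5))
  expect_true(all(co$truth$gt_true_pmol_s > min_feasible_gt(co$truth$ft4_true)))
})

test_that("FT4 moments converge to the generative parameters at large n", {
  # a capacity distribution far above the feasibility bound and a wide TSH
  # window make rejection negligible, so measured moments must approach the
  # spec'd FT4 Normal (within 2 standard errors at n = 10^4)
  sp <- synthetic_spec(n_euthyroid = 10000, n_sh = 1,
                       gt_meanlog_euthyroid = log(6), gt_sdlog_euthyroid = 0.1,
                       tsh_range_euthyroid = c(1e-4, 1e5),
                       noise_cv_tsh = 0, noise_cv_ft4 = 0, seed = 17)
  eu <- generate_cohort(sp)$subjects
  eu <- eu[eu$group == "euthyroid", ]
  se_mean <- 2.19 / sqrt(10000)
  se_sd <- 2.19 / sqrt(2 * 10000)
  expect_lt(abs(mean(eu$ft4) - 16.3), 2 * se_mean)
  expect_lt(abs(sd(eu$ft4) - 2.19), 2 * se_sd)
})

test_that("a generating median of 2.5 pmol/s is recovered from noisy cohorts", {
  meds <- vapply(1:50, function(r) {
    sp <- synthetic_spec(n_euthyroid = 313, n_sh = 1,
                         gt_meanlog_euthyroid = log(2.5), gt_sdlog_euthyroid = 0.1,
                         seed = 3000 + r)
    s <- generate_cohort(sp)$subjects
    s <- s[s$group == "euthyroid", ]
    median(compute_gt(s$tsh, s$ft4))
  }, 1.0)
  expect_true(all(abs(meds - 2.5) < 0.15))
})

test_that("antibody assignment honours the configured probabilities", {
  none <- default_ab_prob()
  none$prob <- 0
  all_pos <- default_ab_prob()
  all_pos$prob <- 1
  co0 <- generate_cohort(synthetic_spec(n_euthyroid = 50, n_sh = 50,
                                        ab_prob = none, seed = 2))
  co1 <- generate_cohort(synthetic_spec(n_euthyroid = 50, n_sh = 50,
                                        ab_prob = all_pos, seed = 2))
  expect_true(all(!antibody_positive(co0$subjects$tg_ab, co0$subjects$tpo_ab)))
  expect_true(all(antibody_positive(co1$subjects$tg_ab, co1$subjects$tpo_ab)))
})

test_that("an infeasible capacity configuration fails with a diagnostic", {
  sp <- synthetic_spec(n_euthyroid = 50, n_sh = 1,
                       gt_meanlog_euthyroid = log(1.3), gt_sdlog_euthyroid = 0.01,
                       seed = 3)
  expect_error(generate_cohort(sp), "feasible")
})

test_that("recovery is exact in the noiseless limit", {
  sp <- stratified_synthetic_spec(noise_cv_tsh = 0, noise_cv_ft4 = 0, seed = 30)
  rec <- recovery_experiment(sp, n_replicates = 2)
  expect_equal(rec$summary$bias_pct, rep(0, 6), tolerance = 1e-10)
  expect_equal(rec$summary$rmse, rep(0, 6), tolerance = 1e-10)
})

test_that("recovery error grows with TSH assay noise", {
  rmse_at <- vapply(c(0, 0.05, 0.2), function(cv) {
    sp <- stratified_synthetic_spec(noise_cv_tsh = cv, noise_cv_ft4 = 0.05,
                                    seed = 77)
    rec <- recovery_experiment(sp, n_replicates = 10)
    ok <- rec$per_replicate$n > 0
    sqrt(mean(rec$per_replicate$rel_err[ok]^2))
  }, 1.0)
  expect_true(all(diff(rmse_at) > 0))
})
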