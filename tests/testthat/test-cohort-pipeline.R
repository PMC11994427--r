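test_that("thyroid status thresholds follow the clinical definition", {
  got <- classify_thyroid_status(c(0.6, 4.5, 4.51, 9.99, 10, 10.23, 15))
  expect_equal(as.character(got),
               c("euthyroid", "euthyroid", "mild_SH", "mild_SH", "mild_SH",
                 "severe_SH", "severe_SH"))
})

test_that("antibody positivity uses and/or semantics with a strict cut-off", {
  expect_true(antibody_positive(tg_ab = 35, tpo_ab = 1))
  expect_false(antibody_positive(tg_ab = 34, tpo_ab = 34))
  expect_true(antibody_positive(tg_ab = NA, tpo_ab = 100))
  expect_false(antibody_positive(tg_ab = NA, tpo_ab = 12))
  expect_true(is.na(antibody_positive(tg_ab = NA, tpo_ab = NA)))
})

test_that("quartile bins split equally spaced values evenly", {
  qb <- tsh_quartile_bins(seq(0.6, 4.4, length.out = 8))
  expect_equal(qb$table$n, rep(2L, 4))
  expect_equal(as.character(qb$bins), rep(c("Q1", "Q2", "Q3", "Q4"), each = 2))
})

test_that("quartile boundaries of a large uniform sample match closed form", {
  set.seed(11)
  x <- runif(10000, 0.6, 4.47)
  qb <- tsh_quartile_bins(x)
  expect_true(all(abs(qb$breaks - c(1.5675, 2.5350, 3.5025)) < 0.05))
  # partition: every value in exactly one bin, boundary ties to the lower bin
  expect_equal(sum(qb$table$n), length(x))
  expect_false(anyNA(qb$bins))
})

test_that("boundary ties go to the lower bin", {
  x <- c(1, 2, 2, 2, 3, 4, 5, 6)
  qb <- tsh_quartile_bins(x)
  expect_true(all(qb$bins[x == 2] == "Q1")) # 25th percentile is 2
})

test_that("quartile binning refuses degenerate input", {
  expect_error(tsh_quartile_bins(c(1, 2, 3)), "at least 4")
  expect_error(tsh_quartile_bins(rep(2, 10)), "at least 4")
})

test_that("BMI-SDS is the centred, scaled BMI", {
  expect_equal(bmi_sds(17, 17, 1.5), 0)
  expect_equal(bmi_sds(20, 17, 1.5), 2)
  d <- 2.3
  expect_equal(bmi_sds(17 + d, 17, 1.5), -bmi_sds(17 - d, 17, 1.5))
  expect_error(bmi_sds(20, 17, 0), "ref_sd")
})

test_that("strata partition the cohort with ordered, non-overlapping TSH ranges", {
  co <- tiny_cohort()
  aug <- augment_spina(assign_strata(co))
  expect_false(anyNA(aug$stratum))
  expect_equal(sum(aug$status == "euthyroid"),
               sum(aug$stratum %in% c("Q1", "Q2", "Q3", "Q4")))
  s <- summarize_strata(aug)
  expect_equal(as.character(s$stratum), stratum_levels)
  expect_equal(s$n, c(2L, 2L, 2L, 2L, 1L, 1L))
  filled <- s[s$n > 0, ]
  expect_true(all(filled$tsh_min <= filled$tsh_max))
  # consecutive stratum ranges do not overlap
  expect_true(all(utils::head(filled$tsh_max, -1) < utils::tail(filled$tsh_min, -1)))
})

test_that("single-subject stratum aggregates equal the subject's own GT", {
  co <- tiny_cohort()
  s <- summarize_strata(augment_spina(assign_strata(co)))
  mild <- s[s$stratum == "mild_SH", ]
  expect_equal(mild$gt_actual_median, 1.68097545, tolerance = 1e-12)
  expect_equal(mild$gt_actual_median, mild$gt_actual_mean)
  expect_equal(mild$tsh_min, 6.7)
  expect_equal(mild$tsh_max, 6.7)
})

test_that("positivity percentages reproduce printed stratum frequencies", {
  # 20 positives of 171 -> 12% at integer rounding; 6 of 78 -> 7.7% at one decimal
  s171 <- summarize_strata(augment_spina(assign_strata(dplyr::bind_rows(
    tiny_cohort()[1:8, ], positivity_stratum(171, 20)))), pct_digits = 0)
  expect_equal(s171$ab_positive_pct[s171$stratum == "mild_SH"], 12)
  s78 <- summarize_strata(augment_spina(assign_strata(dplyr::bind_rows(
    tiny_cohort()[1:8, ], positivity_stratum(78, 6)))), pct_digits = 1)
  expect_equal(s78$ab_positive_pct[s78$stratum == "mild_SH"], 7.7)
})

test_that("empty strata yield n = 0 rows with absent aggregates", {
  co <- tiny_cohort()[1:8, ] # euthyroid only
  s <- summarize_strata(augment_spina(assign_strata(co)))
  sev <- s[s$stratum == "severe_SH", ]
  expect_equal(sev$n, 0L)
  expect_true(is.na(sev$tsh_min) && is.na(sev$gt_actual_median))
})

test_that("group comparisons delegate to the standard tests", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  tt <- compare_groups(g, "t_test")
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)
  # strongly separated normals are detected with overwhelming evidence
  set.seed(3)
  sep <- compare_groups(list(a = rnorm(50), b = rnorm(50, 5)), "t_test")
  expect_lt(sep$p_value, 1e-10)
  # positivity contrast between SH (22/183) and euthyroid (20/313) groups
  chi <- compare_groups(matrix(c(22, 161, 20, 293), 2, byrow = TRUE), "chi_squared")
  expect_lt(chi$p_value, 0.05)
  expect_false(chi$adjusted)
  expect_error(compare_groups(list(a = c(2, 2), b = c(2, 2)), "anova_tukey"),
               "constant")
})

test_that("Tukey rows carry adjusted p-values for every pair", {
  set.seed(5)
  g <- list(a = rnorm(20, 0), b = rnorm(20, 1), c = rnorm(20, 4))
  res <- compare_groups(g, "anova_tukey")
  expect_equal(res$test, c("anova_F", rep("anova_tukey", 3)))
  expect_true(all(res$adjusted[-1]))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  # the widest separation is the most significant pair
  expect_lt(res$p_value[res$groups == "c-a"], 0.001)
})

test_that("stratum mean GT decreases when strata share an FT4 distribution", {
  sp <- synthetic_spec(ft4_mean_sh = 16.3, ft4_sd_sh = 2.19,
                       ft4_range_sh = c(0.1, Inf),
                       n_euthyroid = 2000, n_sh = 2000, seed = 21)
  fit <- analyze_cohort(generate_cohort(sp)$subjects)
  means <- fit$strata$gt_actual_mean
  expect_true(all(diff(means) <= 0))
})

test_that("full analysis returns strata, comparisons and quartile breaks", {
  co <- generate_cohort(synthetic_spec(seed = 8))
  fit <- analyze_cohort(co$subjects)
  expect_s3_class(fit, "thyro_analysis")
  expect_equal(nrow(fit$strata), 6)
  expect_length(fit$quartile_breaks, 3)
  expect_true(all(c("test", "groups", "statistic", "p_value", "adjusted")
                  %in% names(fit$comparisons)))
  expect_true(any(fit$comparisons$test == "chi_squared"))
  # every SH subject with TSH above the predicted curve sits below predicted GT
  sh <- fit$subjects[fit$subjects$status != "euthyroid", ]
  above <- sh$tsh > sh$tsh_predicted
  expect_true(all(sh$gt_actual_pmol_s[above] < sh$gt_predicted_pmol_s[above]))
})
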