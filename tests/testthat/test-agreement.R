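# ICC(A,1), Bland-Altman, proportional bias, covariate regressions, cohort.

test_that("ICC(A,1) is 1 for identical raters and penalizes a constant offset", {
  clin <- c(80, 95, 102, 88, 91, 84, 99)
  p <- paired_measurements(1:7, clin, clin)
  expect_equal(icc_a1(p)$estimate, 1)

  off <- paired_measurements(1:7, clin, clin + 50)
  expect_lt(icc_a1(off)$estimate, kinemark:::icc_c1(off))
  expect_lt(icc_a1(off)$estimate, 0.2)

  expect_error(paired_measurements(1:2, c(1, 2), c(1, 2)), "at least 3")
  expect_error(icc_a1(paired_measurements(1:3, rep(5, 3), rep(5, 3))),
               "zero total variance")
})

test_that("ICC(A,1) matches the frozen independent reference on the 14-subject table", {
  clin <- c(95.2, 88.1, 102.3, 79.5, 91.0, 84.7, 99.9, 87.2, 93.4, 81.8,
            105.1, 90.6, 76.3, 98.0)
  d <- c(-2.1, 4.3, -6.0, 3.2, 1.1, -4.5, 7.8, -1.9, 2.4, -3.3, 5.6, -7.1,
         2.9, -0.8)
  r <- icc_a1(paired_measurements(1:14, clin, round(clin + d, 1)))
  # reference values computed with an independent ICC implementation
  expect_equal(r$estimate, 0.8935052015430196, tolerance = 1e-12)
  expect_equal(r$f_value, 16.59253087629878, tolerance = 1e-12)
  expect_equal(r$p_value, 5.419333730040959e-06, tolerance = 1e-9)
  expect_equal(round(r$ci_low, 2), 0.70)
  expect_equal(round(r$ci_high, 2), 0.96)
  expect_equal(kinemark:::icc_c1(paired_measurements(1:14, clin,
                                                     round(clin + d, 1))),
               0.886315, tolerance = 1e-6)
  expect_true(r$ci_low <= r$estimate && r$estimate <= r$ci_high)
})

test_that("ICC(A,1) equals the two-way ANOVA mean-squares oracle on random tables", {
  withr::with_seed(101, {
    for (i in 1:100) {
      n <- sample(4:12, 1)
      clin <- rnorm(n, 90, 10)
      alg <- clin * runif(1, 0.8, 1.2) + rnorm(n, runif(1, -5, 5), 4)
      p <- paired_measurements(seq_len(n), clin, alg)
      expect_equal(icc_a1(p)$estimate, icc_a1_aov(clin, alg), tolerance = 1e-9)
    }
  })
})

test_that("ICC(A,1) is invariant to a common affine transform of both raters", {
  withr::with_seed(5, {
    clin <- rnorm(12, 90, 9); alg <- clin + rnorm(12, 1, 3)
    r0 <- icc_a1(paired_measurements(1:12, clin, alg))$estimate
    r1 <- icc_a1(paired_measurements(1:12, 2.5 * clin - 40,
                                     2.5 * alg - 40))$estimate
    expect_equal(r0, r1, tolerance = 1e-9)
    # offset on one rater only strictly decreases the estimate
    r2 <- icc_a1(paired_measurements(1:12, clin, alg + 10))$estimate
    expect_lt(r2, r0)
  })
})

test_that("ICC recovers a known population value at large n", {
  tab <- simulate_two_way_table(200, subject_sd = 9, rater_offset = 0,
                                error_sd = 3, seed = 77)
  expect_equal(attr(tab, "population_icc_a1"), 81 / 90)
  r <- icc_a1(tab)
  expect_lt(abs(r$estimate - 0.9), 0.05)
  expect_true(r$ci_low <= 0.9 && 0.9 <= r$ci_high)
})

test_that("at the study size n=14 the estimator is near-unbiased with honest CIs", {
  n_sims <- 500
  est <- numeric(n_sims); cover <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    tab <- simulate_two_way_table(14, subject_sd = 9, rater_offset = 0,
                                  error_sd = 3, seed = 5000 + i)
    r <- icc_a1(tab)
    est[i] <- r$estimate
    cover[i] <- r$ci_low <= 0.9 && 0.9 <= r$ci_high
  }
  expect_lt(abs(mean(est) - 0.9), 0.03)
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.98)
})

test_that("Bland-Altman reduces to exact values on constructed pairs", {
  p <- paired_measurements(1:3, c(10, 20, 30), c(10, 20, 30))
  ba <- bland_altman(p)
  expect_equal(ba$bias, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(0, 0))

  p2 <- paired_measurements(1:4, c(10, 20, 30, 40), c(12, 22, 32, 42))
  ba2 <- suppressWarnings(bland_altman(p2))
  expect_equal(ba2$bias, 2)
  expect_equal(ba2$sd_diff, 0)
  expect_equal(c(ba2$loa_low, ba2$loa_high), c(2, 2))
  # bias identity and role swap
  expect_equal(ba2$bias, mean(p2$algorithm_deg) - mean(p2$clinical_deg))
  swap <- paired_measurements(1:4, p2$algorithm_deg, p2$clinical_deg)
  bs <- suppressWarnings(bland_altman(swap))
  expect_equal(bs$bias, -ba2$bias)
  expect_equal(c(bs$loa_low, bs$loa_high), -c(ba2$loa_high, ba2$loa_low))
})

test_that("Bland-Altman recovers simulated difference moments", {
  withr::with_seed(404, {
    n <- 10000
    clin <- rnorm(n, 90, 9)
    alg <- clin + rnorm(n, -2, 5)
    ba <- bland_altman(paired_measurements(seq_len(n), clin, alg))
    expect_lt(abs(ba$bias - (-2)), 0.15)
    expect_lt(abs((ba$loa_high - ba$loa_low) - 2 * 1.96 * 5), 0.5)
  })
})

test_that("proportional bias detects perfect linearity and handles the null", {
  m <- c(60, 80, 100, 120, 140)
  # differences = 0.5 * means: algorithm - clinical = 0.5 * (alg + clin) / 2
  clin <- m - 0.25 * m; alg <- m + 0.25 * m
  pb <- suppressWarnings(proportional_bias(paired_measurements(1:5, clin, alg)))
  expect_equal(pb$slope, 0.5, tolerance = 1e-9)
  expect_lt(pb$p_value, 1e-10)

  pb0 <- suppressWarnings(proportional_bias(paired_measurements(1:5, m, m + 2)))
  expect_equal(pb0$slope, 0, tolerance = 1e-12)

  expect_error(proportional_bias(paired_measurements(1:4, rep(10, 4) - 1,
                                                     rep(10, 4) + 1)),
               "no regressor variance")
})

test_that("proportional-bias test holds its nominal size under the null", {
  n_sims <- 1000
  rej <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    tab <- simulate_two_way_table(14, subject_sd = 9, rater_offset = 0,
                                  error_sd = 3, seed = 20000 + i)
    rej[i] <- proportional_bias(tab)$p_value < 0.05
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("error_vs_covariate recovers exact and null relationships", {
  months <- c(1, 2, 3, 5, 8, 12)
  clin <- rep(90, 6)
  alg <- clin + 2 * months                     # absolute error = 2 * months
  p <- do.call(paired_measurements,
               list(subject_id = 1:6, clinical_deg = clin, algorithm_deg = alg,
                    months_since_surgery = months))
  r <- suppressWarnings(error_vs_covariate(p, "months_since_surgery", "absolute"))
  expect_equal(r$beta, 2, tolerance = 1e-9)
  expect_equal(r$r_squared, 1, tolerance = 1e-9)
  expect_equal(r$rho, 1, tolerance = 1e-12)

  withr::with_seed(55, {
    n <- 500
    months <- runif(n, 1, 60)
    clin <- rnorm(n, 90, 9)
    alg <- clin + rnorm(n, 0, 4)               # error independent of months
    p <- do.call(paired_measurements,
                 list(subject_id = seq_len(n), clinical_deg = clin,
                      algorithm_deg = alg, months_since_surgery = months))
    r <- error_vs_covariate(p, "months_since_surgery", "signed")
    expect_lt(abs(r$beta), 0.05)
    expect_lt(abs(r$rho), 0.1)
  })

  p$months_since_surgery[2] <- NA
  expect_error(error_vs_covariate(p, "months_since_surgery"), "subject")
})

test_that("Spearman handles ties by midranks and offers exact enumeration", {
  # two distinct covariate values only: midranks, t-approximation still runs
  months <- c(1, 1, 1, 6, 6, 6)
  err <- c(2, 3, 4, 8, 9, 10)
  p <- do.call(paired_measurements,
               list(subject_id = 1:6, clinical_deg = rep(90, 6),
                    algorithm_deg = rep(90, 6) + err,
                    months_since_surgery = months))
  r <- error_vs_covariate(p, "months_since_surgery", "absolute")
  # hand-ranked: midranks (2,2,2,5,5,5) vs ranks 1..6 -> rho = 0.8783...
  expect_equal(r$rho, cor(c(2, 2, 2, 5, 5, 5), 1:6), tolerance = 1e-12)
  expect_true(r$rho_p > 0 && r$rho_p < 1)

  # exact permutation p at n = 6 for a perfect monotone relation: 2 / 6! of
  # permutations reach |rho| = 1 (identity and full reversal)
  sp <- kinemark:::spearman_midrank(1:6, c(2, 4, 5, 7, 8, 11), exact = TRUE)
  expect_equal(sp$rho, 1)
  expect_equal(sp$p_value, 2 / factorial(6), tolerance = 1e-12)
})

test_that("cohort summary reproduces the pilot-study demographics", {
  cohort <- read_cohort_csv(cohort_path())
  s <- summarize_cohort(cohort)
  expect_equal(s$n, 14L)
  ns <- s$numeric_summary
  months <- ns[ns$variable == "months_since_surgery", ]
  expect_equal(months$mean, 7.14)
  expect_equal(months$min, 1)
  expect_equal(months$max, 60)
  expect_equal(s$n_tha, 9L)     # bilateral hip replacements count once
  expect_equal(s$n_tka, 5L)
})

test_that("surgery labels parse to procedure/side/bilateral; junk is rejected", {
  st <- parse_surgery_type(c("Left THA", "Right TKA", "Left and Right THA"))
  expect_equal(st$procedure, c("THA", "TKA", "THA"))
  expect_equal(st$bilateral, c(FALSE, FALSE, TRUE))
  expect_error(parse_surgery_type("Hip surgery"), "unparseable.*Hip surgery")

  one <- summarize_cohort(data.frame(age_years = 61, weight_kg = 78,
                                     height_m = 1.63,
                                     surgery_type = "Left THA",
                                     months_since_surgery = 60))
  ns <- one$numeric_summary
  expect_equal(ns$mean[ns$variable == "age_years"], 61)
  expect_equal(ns$min, ns$max)
})
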