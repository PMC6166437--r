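test_that("percentile intervals interpolate linearly between order statistics", {
  expect_equal(percentile_interval(1:100),
               c(low = 3.475, high = 97.525))
  expect_identical(percentile_interval(rep(2.5, 40)),
                   c(low = 2.5, high = 2.5))
  expect_identical(percentile_interval(7), c(low = 7, high = 7))
  expect_error(percentile_interval(numeric(0)),
               class = "rr_error_no_replicates")
  expect_equal(percentile_interval(c(NA, 1:100, NA)),
               c(low = 3.475, high = 97.525))
})

test_that("a cohort with unanimous reporting gives a zero-width interval at 1", {
  b <- bootstrap_ratio(unanimous_cohort(25), "abortion", B = 100, seed = 3)
  expect_true(all(b$replicates == 1))
  expect_identical(b$ci_low, 1)
  expect_identical(b$ci_high, 1)
  expect_identical(b$n_undefined, 0L)
})

test_that("the replicate stream is reproducible and the CI brackets the median", {
  sim <- generate_cohort(generator_config(n = 600, seed = 14))
  b1 <- bootstrap_ratio(sim$cohort, "loss", B = 100, seed = 21)
  b2 <- bootstrap_ratio(sim$cohort, "loss", B = 100, seed = 21)
  expect_identical(b1$replicates, b2$replicates)
  expect_identical(b1$ci_low, b2$ci_low)
  med <- stats::median(b1$replicates, na.rm = TRUE)
  expect_true(b1$ci_low <= med && med <= b1$ci_high)
  # chunking is an implementation detail, not a result knob
  b3 <- bootstrap_ratio(sim$cohort, "loss", B = 100, seed = 21, chunk = 7L)
  expect_identical(b1$replicates, b3$replicates)
})

test_that("sparse categories fail loudly rather than returning junk intervals", {
  # one history reporter: many replicates lose the whole denominator
  resp <- demo_respondents()
  co <- cohort(resp, demo_pregnancies(), quiet = TRUE)
  expect_error(bootstrap_ratio(co, "loss", B = 200, seed = 2),
               class = "rr_error_degenerate_bootstrap")
})

test_that("independent difference tests pair replicate streams and test zero exclusion", {
  sim <- generate_cohort(generator_config(n = 800, seed = 44))
  a <- bootstrap_ratio(sim$cohort, "loss", B = 150, seed = 9)
  b <- bootstrap_ratio(sim$cohort, "loss", B = 150, seed = 9)
  d <- difference_test_independent(a, b)
  expect_true(all(d$diff_replicates == 0))
  expect_false(d$significant)

  short <- bootstrap_ratio(sim$cohort, "loss", B = 100, seed = 9)
  expect_error(difference_test_independent(a, short),
               class = "rr_error_incompatible_bootstrap")
})

test_that("well-separated true ratios are declared different across cohorts", {
  # two rounds with closed-form ratios 1.15 and about 1.44
  sim_a <- generate_cohort(one_event_config(10000, seed = 81,
                                            p_acasi = 0.92, p_ftf = 0.80))
  sim_b <- generate_cohort(one_event_config(10000, seed = 82,
                                            p_acasi = 0.92, p_ftf = 0.64))
  a <- bootstrap_ratio(sim_a$cohort, "abortion", B = 500, seed = 7)
  b <- bootstrap_ratio(sim_b$cohort, "abortion", B = 500, seed = 8)
  d <- difference_test_independent(b, a)
  expect_true(d$significant)
  expect_gt(d$pct_low, 0)
})

test_that("joint subgroup contrasts preserve shared-sample resampling", {
  sim <- generate_cohort(generator_config(n = 2000, seed = 52))
  d0 <- difference_test_joint(sim$cohort, "loss", "religiosity",
                              "monthly_plus", "monthly_plus",
                              B = 100, seed = 6)
  expect_true(all(d0$diff_replicates == 0, na.rm = TRUE))
  expect_false(d0$significant)

  cfg <- one_event_config(
    20000, seed = 53, p_acasi = 0.6,
    p_acasi_multipliers = list(religiosity = c(monthly_plus = 1.5))
  )
  sim2 <- generate_cohort(cfg)
  d1 <- difference_test_joint(sim2$cohort, "abortion", "religiosity",
                              "monthly_plus", "lt_monthly",
                              B = 300, seed = 61)
  expect_true(d1$significant)
  expect_gt(d1$estimate, 0)
})

test_that("interval non-overlap is the conservative disjointness check", {
  expect_true(ci_nonoverlap(c(1.36, 1.56), c(1.11, 1.15)))
  expect_false(ci_nonoverlap(c(1.26, 1.39), c(1.37, 1.45)))
  expect_false(ci_nonoverlap(c(1.0, 1.2), c(1.0, 1.2)))
  expect_true(ci_nonoverlap(c(0.1, 0.2), c(0.3, 0.4)))
})

test_that("tidiers summarise bootstrap objects in broom shape", {
  sim <- generate_cohort(generator_config(n = 600, seed = 14))
  b <- bootstrap_ratio(sim$cohort, "loss", B = 100, seed = 21)
  td <- tidy(b)
  expect_named(td, c("category", "estimate", "conf.low", "conf.high"))
  gl <- glance(b)
  expect_identical(gl$B, 100L)
  d <- difference_test_independent(b, b)
  expect_named(tidy(d),
               c("contrast", "estimate", "conf.low", "conf.high",
                 "significant"))
})
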