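test_that("zero event rates give empty histories and all-zero counts", {
  cfg <- generator_config(n = 50, seed = 4,
                          event_rate = c(birth = 0, loss = 0, abortion = 0))
  sim <- generate_cohort(cfg)
  expect_identical(nrow(sim$cohort$pregnancies), 0L)
  expect_true(all(sim$cohort$respondents$acasi_birth == 0L))
  expect_true(all(sim$cohort$respondents$acasi_abortion == 0L))
  expect_identical(nrow(sim$ledger$events), 0L)
})

test_that("a fixed seed reproduces the cohort and ledger exactly", {
  cfg <- generator_config(n = 300, seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort$respondents, b$cohort$respondents)
  expect_identical(a$cohort$pregnancies, b$cohort$pregnancies)
  expect_identical(a$ledger, b$ledger)
  # stage one is independently reproducible too
  expect_identical(generate_true_histories(cfg),
                   generate_true_histories(cfg))
})

test_that("true event counts follow the configured Poisson mean", {
  cfg <- generator_config(n = 10000, seed = 12,
                          event_rate = c(birth = 0.5, loss = 0.2,
                                         abortion = 0.3))
  truth <- generate_true_histories(cfg)
  n_ab <- sum(truth$events$category == "abortion")
  expect_lt(abs(n_ab / 10000 - 0.3), 3 * sqrt(0.3 / 10000))
  n_b <- sum(truth$events$category == "birth")
  expect_lt(abs(n_b / 10000 - 0.5), 3 * sqrt(0.5 / 10000))
})

test_that("faithful history reporting reproduces truth exactly", {
  cfg <- faithful_config(n = 500, seed = 31)
  truth <- generate_true_histories(cfg)
  ftf <- apply_ftf_reporting(truth, cfg)
  expect_true(all(ftf$disclosed_ftf))
  expect_identical(ftf$recorded_cm, ftf$true_cm)
})

test_that("zero history disclosure empties all histories", {
  cfg <- generator_config(n = 200, seed = 32,
                          p_ftf = c(birth = 0, loss = 0, abortion = 0))
  sim <- generate_cohort(cfg)
  expect_identical(nrow(sim$cohort$pregnancies), 0L)
  expect_true(all(!sim$ledger$events$disclosed_ftf))
})

test_that("disclosure fractions calibrate to the configured probabilities", {
  n <- 10000
  sim <- generate_cohort(one_event_config(n, seed = 55))
  # every woman has exactly one true in-window abortion
  a_frac <- mean(sim$cohort$respondents$acasi_abortion >= 1)
  f_frac <- mean(ftf_window_count(sim$cohort, "abortion", "standard")$n >= 1)
  expect_lt(abs(a_frac - 0.92), 3 * sqrt(0.92 * 0.08 / n))
  expect_lt(abs(f_frac - 0.80), 3 * sqrt(0.80 * 0.20 / n))
})

test_that("faithful limit: self-administered counts equal windowed history counts", {
  sim <- generate_cohort(faithful_config(n = 800, seed = 61))
  for (cat in outcome_categories()) {
    acasi <- acasi_count(sim$cohort, cat)$n
    ftf <- ftf_window_count(sim$cohort, cat, "standard")$n
    expect_identical(acasi, ftf)
  }
})

test_that("lifetime confusion reports lifetime counts while the window is empty", {
  cfg <- generator_config(
    n = 150, seed = 91,
    events_fixed = c(birth = 0, loss = 0, abortion = 2),
    event_placement = "prewindow", span_years = 15,
    p_ftf = c(birth = 1, loss = 1, abortion = 1),
    p_acasi = c(birth = 1, loss = 1, abortion = 1),
    misdate_sd_months = 0, telescope_in_prob = 0, confusion_prob = 1
  )
  sim <- generate_cohort(cfg)
  expect_true(all(sim$cohort$respondents$acasi_abortion == 2L))
  expect_true(all(ftf_window_count(sim$cohort, "abortion", "standard")$n == 0L))
  expect_true(all(sim$ledger$respondents$confusion_applied))
})

test_that("misdating spreads recorded dates with roughly the configured SD and clamps at interview", {
  cfg <- generator_config(
    n = 4000, seed = 13,
    events_fixed = c(birth = 1, loss = 0, abortion = 0),
    event_placement = "inwindow",
    p_ftf = c(birth = 1, loss = 1, abortion = 1),
    misdate_sd_months = 4, telescope_in_prob = 0, confusion_prob = 0
  )
  sim <- generate_cohort(cfg)
  led <- sim$ledger$events
  iv <- sim$cohort$respondents$interview_cm[
    match(led$id, sim$cohort$respondents$id)
  ]
  expect_true(all(led$recorded_cm <= iv))
  err <- led$recorded_cm - led$true_cm
  # clamping can only shrink the spread; check it is in a sane band
  expect_gt(stats::sd(err), 2.5)
  expect_lt(stats::sd(err), 5)
  expect_lt(abs(mean(err)), 0.5)
})

test_that("the truth ledger satisfies its invariants", {
  sim <- generate_cohort(generator_config(n = 400, seed = 8))
  led <- sim$ledger$events
  expect_identical(is.na(led$recorded_cm), !led$disclosed_ftf)
  expect_true(all(led$id %in% sim$cohort$respondents$id))
  expect_setequal(sim$ledger$respondents$id, sim$cohort$respondents$id)
  # disclosed events are exactly the history records
  expect_identical(sum(led$disclosed_ftf), nrow(sim$cohort$pregnancies))
})

test_that("woman-level never-disclosure suppresses whole histories", {
  cfg <- generator_config(
    n = 2000, seed = 19,
    events_fixed = c(birth = 2, loss = 0, abortion = 0),
    event_placement = "inwindow",
    p_ftf = c(birth = 1, loss = 1, abortion = 1),
    misdate_sd_months = 0, p_never_discloser = 0.3
  )
  sim <- generate_cohort(cfg)
  n_disc <- ftf_window_count(sim$cohort, "birth", "standard")$n
  # each woman discloses both events or neither
  expect_true(all(n_disc %in% c(0L, 2L)))
  expect_lt(abs(mean(n_disc == 0L) - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(confusion_prob = 1.2),
               class = "rr_error_config")
  expect_error(generator_config(p_ftf = c(birth = 0.5)),
               class = "rr_error_config")
  expect_error(
    generator_config(event_placement = "prewindow", span_years = 5),
    class = "rr_error_config"
  )
})
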