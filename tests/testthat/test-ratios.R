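test_that("the reporter ratio is women-with->=1 over women-with->=1", {
  co <- demo_cohort()
  r <- reporting_ratio(co, "abortion")
  expect_identical(r$n_acasi, 3L)
  expect_identical(r$n_ftf, 1L)
  expect_identical(r$ratio, 3)
  expect_identical(r$n_total, 6L)
  # identical indicators in both modes give exact parity
  expect_identical(reporting_ratio(unanimous_cohort(), "abortion")$ratio, 1)
  expect_identical(reporting_ratio(unanimous_cohort(), "birth")$ratio, 1)
})

test_that("the secondary event-count statistic is labelled and distinct", {
  co <- unanimous_cohort(10)
  # double-count one woman's self-administered abortions
  co$respondents$acasi_abortion[1] <- 2L
  rep_r <- reporting_ratio(co, "abortion", statistic = "reporters")
  ev_r <- reporting_ratio(co, "abortion", statistic = "events")
  expect_identical(rep_r$ratio, 1)
  expect_identical(ev_r$ratio, 1.1)
  expect_identical(ev_r$statistic, "events")
})

test_that("window labels must match the round design", {
  co <- demo_cohort() # 2011-2015
  expect_error(reporting_ratio(co, "abortion", window = "lifetime"),
               class = "rr_error_window")
  sim02 <- generate_cohort(faithful_config(n = 200, seed = 5, round = "2002"))
  expect_error(reporting_ratio(sim02$cohort, "birth", window = "standard"),
               class = "rr_error_window")
  expect_error(expanded_reporting_ratio(sim02$cohort, "birth"),
               class = "rr_error_window")
  # 2002 lifetime comparisons work by default
  expect_identical(reporting_ratio(sim02$cohort, "birth")$ratio, 1)
})

test_that("an empty history-side denominator is an explicit error", {
  resp <- demo_respondents()
  co <- cohort(resp, NULL, quiet = TRUE)
  expect_error(reporting_ratio(co, "abortion"),
               class = "rr_error_undefined_ratio")
})

test_that("expanded ratios widen only the denominator", {
  co <- demo_cohort()
  # widening pulls w2's 2007 abortion into the window: denominator 2
  e <- expanded_reporting_ratio(co, "abortion")
  expect_identical(e$n_acasi, 3L)
  expect_identical(e$n_ftf, 2L)
  expect_identical(e$ratio, 1.5)
  expect_identical(e$ftf_window, "expanded")
  expect_identical(e$acasi_window, "standard")
})

test_that("with all events strictly in-window and exact dates, expanded equals standard", {
  cfg <- one_event_config(2000, seed = 41)
  sim <- generate_cohort(cfg)
  s <- reporting_ratio(sim$cohort, "abortion")
  e <- expanded_reporting_ratio(sim$cohort, "abortion")
  expect_identical(e$ratio, s$ratio)
  expect_identical(e$n_ftf, s$n_ftf)
})

test_that("ratios match an independent brute-force recount on small cohorts", {
  for (s in c(101, 202, 303, 404)) {
    n <- 20 + (s %% 31)
    sim <- generate_cohort(generator_config(
      n = n, seed = s,
      event_rate = c(birth = 1.2, loss = 0.8, abortion = 0.8),
      misdate_sd_months = 3, telescope_in_prob = 0.1, confusion_prob = 0.15
    ))
    for (cat in outcome_categories()) {
      for (lab in c("standard", "expanded", "lifetime")) {
        expect_identical(
          ftf_window_count(sim$cohort, cat, lab)$n,
          oracle_ftf_counts(sim$cohort, cat, lab),
          info = paste(s, cat, lab)
        )
      }
      want <- oracle_ratio_counts(sim$cohort, cat, "standard")
      got <- tryCatch(reporting_ratio(sim$cohort, cat),
                      rr_error_undefined_ratio = function(e) NULL)
      if (is.null(got)) {
        expect_identical(want$n_ftf, 0L, info = paste(s, cat))
      } else {
        expect_identical(got$n_acasi, want$n_acasi)
        expect_identical(got$n_ftf, want$n_ftf)
        expect_identical(got$ratio, want$ratio)
      }
    }
  }
})

test_that("stratified estimates carry reference flags and recombine to the overall counts", {
  sim <- generate_cohort(generator_config(n = 3000, seed = 17))
  overall <- reporting_ratio(sim$cohort, "loss")
  for (ax in c("age_group", "race_ethnicity", "poverty", "marital",
               "religiosity")) {
    st <- stratified_ratios(sim$cohort, "loss", ax)
    expect_identical(sum(st$is_ref), 1L)
    expect_identical(sum(st$n_acasi, na.rm = TRUE), overall$n_acasi)
    expect_identical(sum(st$n_ftf, na.rm = TRUE), overall$n_ftf)
    expect_identical(sum(st$n_total), overall$n_total)
  }
  st <- stratified_ratios(sim$cohort, "loss", "age_group")
  expect_identical(st$level[st$is_ref], "25-34")
})

test_that("a subgroup with boosted self-administered disclosure shows a larger ratio", {
  cfg <- one_event_config(
    30000, seed = 71, p_acasi = 0.75,
    p_acasi_multipliers = list(religiosity = c(monthly_plus = 1.25))
  )
  sim <- generate_cohort(cfg)
  st <- stratified_ratios(sim$cohort, "abortion", "religiosity")
  boosted <- st$ratio[st$level == "monthly_plus"]
  ref <- st$ratio[st$level == "lt_monthly"]
  # closed forms 0.9375/0.8 vs 0.75/0.8; at n=30k the gap is many sigma wide
  expect_gt(boosted, ref)
  expect_lt(abs(ref - 0.75 / 0.80), 0.05)
  expect_lt(abs(boosted - 0.75 * 1.25 / 0.80), 0.05)
})

test_that("an empty stratum is reported as undefined without failing the rest", {
  resp <- demo_respondents()
  resp$age_group <- c("15-24", "15-24", "15-24", "25-34", "25-34", "25-34")
  co <- cohort(resp, demo_pregnancies(), quiet = TRUE)
  st <- stratified_ratios(co, "abortion", "age_group")
  expect_identical(nrow(st), 3L)
  # 35-44 is empty; 25-34 has reporters in one mode only (also undefined)
  expect_true(is.na(st$ratio[st$level == "35-44"]))
  expect_identical(st$note[st$level == "35-44"], "undefined_ratio")
  expect_identical(st$ratio[st$level == "15-24"], 2)
})

test_that("ratio_table stacks overall and expanded rows per category", {
  sim <- generate_cohort(generator_config(n = 1500, seed = 29))
  rt <- ratio_table(sim$cohort)
  expect_identical(nrow(rt), 6L)
  expect_setequal(unique(rt$ftf_window), c("standard", "expanded"))
  expect_true(all(rt$round == "2011-2015"))
  td <- tidy(rt)
  expect_s3_class(td, "tbl_df")
})
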