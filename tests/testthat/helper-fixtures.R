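# Small hand-built cohorts with hand-computable answers.

# Six women interviewed June 2013 (standard window Jan 2008 - Dec 2012).
# Hand tally (reporters, standard window):
#   abortion: ACASI w1,w2,w5 = 3; history-in-window w1 = 1 -> ratio 3
#   birth:    ACASI w3,w4,w6 = 3; history-in-window w3 = 1 -> ratio 3
#   loss:     ACASI w4 = 1;       history-in-window w4 = 1 -> ratio 1
# Discordant abortion: w2, w5 (lifetime match only w2 -> 0.5)
# Discordant birth: w4, w6 (both lifetime-match -> 1.0)
demo_respondents <- function() {
  tibble::tibble(
    id = paste0("w", 1:6),
    round = "2011-2015",
    interview_cm = cm(2013, 6),
    age_group = c("15-24", "25-34", "25-34", "35-44", "15-24", "35-44"),
    race_ethnicity = c("white_nl", "black_nl", "latina", "white_nl",
                       "other_nl", "latina"),
    poverty = c("0-99", "100-299", "300+", "0-99", "100-299", "300+"),
    marital = c("never_married", "never_married", "currently_married",
                "previously_married", "never_married", "currently_married"),
    religiosity = c("lt_monthly", "monthly_plus", "lt_monthly",
                    "monthly_plus", "lt_monthly", "monthly_plus"),
    acasi_birth = c(0L, 0L, 1L, 1L, 0L, 1L),
    acasi_loss = c(0L, 0L, 0L, 1L, 0L, 0L),
    acasi_abortion = c(1L, 1L, 0L, 0L, 1L, 0L)
  )
}

demo_pregnancies <- function() {
  tibble::tibble(
    id = c("w1", "w2", "w3", "w4", "w4", "w6"),
    outcome = c("abortion", "abortion", "live_birth_vaginal", "miscarriage",
                "live_birth_cesarean", "live_birth_vaginal"),
    end_cm = c(cm(2010, 2), cm(2007, 6), cm(2012, 3), cm(2009, 5),
               cm(2013, 5), cm(2005, 11)),
    is_current = FALSE
  )
}

demo_cohort <- function() {
  cohort(demo_respondents(), demo_pregnancies(), quiet = TRUE)
}

# cohort where every woman reports the category in both modes (zero-variance
# bootstrap case)
unanimous_cohort <- function(n = 30) {
  resp <- tibble::tibble(
    id = paste0("u", seq_len(n)),
    round = "2011-2015",
    interview_cm = cm(2014, 3),
    age_group = "25-34", race_ethnicity = "white_nl", poverty = "300+",
    marital = "currently_married", religiosity = "lt_monthly",
    acasi_birth = 1L, acasi_loss = 0L, acasi_abortion = 1L
  )
  preg <- tibble::tibble(
    id = rep(resp$id, each = 2),
    outcome = rep(c("abortion", "live_birth_vaginal"), n),
    end_cm = cm(2011, 7),
    is_current = FALSE
  )
  cohort(resp, preg, quiet = TRUE)
}

# faithful-reporting generator: both modes disclose everything, no
# misdating, telescoping or confusion
faithful_config <- function(n = 2000, seed = 101, round = "2011-2015", ...) {
  generator_config(
    n = n, round = round, seed = seed,
    p_ftf = c(birth = 1, loss = 1, abortion = 1),
    p_acasi = c(birth = 1, loss = 1, abortion = 1),
    misdate_sd_months = 0, telescope_in_prob = 0, confusion_prob = 0,
    ...
  )
}

# one true in-window abortion per woman with known disclosure probabilities:
# closed-form reporter ratio p_acasi / p_ftf
one_event_config <- function(n, seed, p_acasi = 0.92, p_ftf = 0.80, ...) {
  generator_config(
    n = n, seed = seed,
    events_fixed = c(birth = 0, loss = 0, abortion = 1),
    event_placement = "inwindow",
    p_ftf = c(birth = 1, loss = 1, abortion = p_ftf),
    p_acasi = c(birth = 1, loss = 1, abortion = p_acasi),
    misdate_sd_months = 0, telescope_in_prob = 0, confusion_prob = 0,
    ...
  )
}
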