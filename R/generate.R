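# field periods per survey round (start, end) as century months
rr_round_period <- function(round) {
  switch(round,
    "2002"      = c(cm(2002, 3), cm(2003, 2)),
    "2006-2010" = c(cm(2006, 6), cm(2010, 12)),
    "2011-2015" = c(cm(2011, 6), cm(2015, 6))
  )
}

# default demographic mix: the 2011-2015 unweighted sample composition
rr_default_demographic_probs <- list(
  age_group      = c("15-24" = 0.35, "25-34" = 0.37, "35-44" = 0.28),
  race_ethnicity = c(white_nl = 0.47, black_nl = 0.21, other_nl = 0.07,
                     latina = 0.25),
  poverty        = c("0-99" = 0.35, "100-299" = 0.37, "300+" = 0.28),
  marital        = c(currently_married = 0.30, previously_married = 0.13,
                     never_married = 0.57),
  religiosity    = c(lt_monthly = 0.50, monthly_plus = 0.50)
)

#' Configuration for the synthetic paired-mode cohort generator
#'
#' The generator draws true reproductive histories and then passes them
#' through two imperfect reporting channels that emulate the hypothesised
#' response processes:
#'
#' * mode-specific disclosure — each true event is independently disclosed in
#'   the interviewer-administered history with probability `p_ftf[category]`
#'   and kept in the self-administered count with probability
#'   `p_acasi[category]` (optionally scaled per demographic subgroup);
#' * date misdating — disclosed history events get a recorded month equal to
#'   the true month plus a symmetric two-sided geometric error with standard
#'   deviation `misdate_sd_months`, clamped at the interview month;
#' * forward telescoping — each true event outside the five-year window is
#'   pulled into the self-administered count with probability
#'   `telescope_in_prob`;
#' * lifetime-for-window confusion — with probability `confusion_prob` a
#'   respondent answers the five-year count items with her lifetime disclosed
#'   counts.
#'
#' Telescoping and confusion apply only to rounds with five-year items
#' (2006 onward); the 2002 round's self-administered items are lifetime
#' counts by construction.
#'
#' @param n Cohort size (default 11297, the 2011-2015 female sample size).
#' @param round Survey round code.
#' @param seed Integer RNG seed (< 2^31 - 16).
#' @param demographic_probs Named list of category-probability vectors per
#'   demographic axis; defaults to the 2011-2015 unweighted composition.
#' @param event_rate Named vector: mean true events per woman over
#'   `span_years`, per category.
#' @param events_fixed Optional named integer vector: exactly this many true
#'   events per woman per category instead of a Poisson draw (calibration
#'   scenarios).
#' @param span_years Length in years of the simulated reproductive history
#'   ending at the interview month.
#' @param event_placement Where true event months fall: `"span"` (uniform
#'   over the span), `"inwindow"` (uniform inside the standard five-year
#'   window) or `"prewindow"` (uniform before the window start); the latter
#'   two exist for calibration scenarios with known closed-form answers.
#' @param p_ftf,p_acasi Named per-category disclosure probabilities.
#' @param p_ftf_multipliers,p_acasi_multipliers,event_rate_multipliers
#'   Optional nested lists `list(axis = c(level = multiplier))`; products
#'   across axes scale the base parameter, probabilities clamped to `[0, 1]`.
#' @param misdate_sd_months Standard deviation (months) of the history date
#'   error; 0 disables misdating.
#' @param telescope_in_prob Probability an out-of-window true event enters
#'   the five-year self-administered count.
#' @param confusion_prob Probability a respondent answers the five-year items
#'   with lifetime counts.
#' @param p_never_discloser Woman-level probability of never disclosing any
#'   event in the interviewer-administered history (a shared random effect
#'   alternative to purely event-level suppression; default 0).
#' @return A validated `rr_config` list.
#' @export
generator_config <- function(n = 11297,
                             round = "2011-2015",
                             seed = 1L,
                             demographic_probs = rr_default_demographic_probs,
                             event_rate = c(birth = 0.60, loss = 0.25,
                                            abortion = 0.16),
                             events_fixed = NULL,
                             span_years = 15,
                             event_placement = c("span", "inwindow",
                                                 "prewindow"),
                             p_ftf = c(birth = 0.97, loss = 0.70,
                                       abortion = 0.45),
                             p_acasi = c(birth = 0.98, loss = 0.88,
                                         abortion = 0.60),
                             p_ftf_multipliers = NULL,
                             p_acasi_multipliers = NULL,
                             event_rate_multipliers = NULL,
                             misdate_sd_months = 5,
                             telescope_in_prob = 0.02,
                             confusion_prob = 0.04,
                             p_never_discloser = 0) {
  round <- rlang::arg_match(round, rr_rounds)
  event_placement <- rlang::arg_match(event_placement)
  stopifnot(
    n >= 1, span_years >= 1,
    seed == as.integer(seed), abs(seed) < 2^31 - 16
  )
  complete_cat <- function(v, what) {
    if (is.null(names(v)) && length(v) == 1) {
      v <- stats::setNames(rep(v, 3), rr_categories)
    }
    if (!all(rr_categories %in% names(v))) {
      rlang::abort(paste0(what, " must name all of: ",
                          paste(rr_categories, collapse = ", ")),
                   class = "rr_error_config")
    }
    v[rr_categories]
  }
  event_rate <- complete_cat(event_rate, "event_rate")
  p_ftf <- complete_cat(p_ftf, "p_ftf")
  p_acasi <- complete_cat(p_acasi, "p_acasi")
  if (!is.null(events_fixed)) {
    events_fixed <- complete_cat(events_fixed, "events_fixed")
    stopifnot(all(events_fixed >= 0))
  }
  probs01 <- c(p_ftf, p_acasi, telescope_in_prob, confusion_prob,
               p_never_discloser)
  if (any(probs01 < 0 | probs01 > 1)) {
    rlang::abort("All disclosure/telescoping/confusion probabilities must lie in [0, 1].",
                 class = "rr_error_config")
  }
  stopifnot(all(event_rate >= 0), misdate_sd_months >= 0)
  for (ax in names(rr_demographic_levels)) {
    p <- demographic_probs[[ax]]
    if (is.null(p) || !all(rr_demographic_levels[[ax]] %in% names(p))) {
      rlang::abort(paste0("demographic_probs$", ax,
                          " must cover all levels."),
                   class = "rr_error_config")
    }
    demographic_probs[[ax]] <- p[rr_demographic_levels[[ax]]] /
      sum(p[rr_demographic_levels[[ax]]])
  }
  if (event_placement == "prewindow" && round != "2002" && span_years < 8) {
    rlang::abort("prewindow placement needs span_years >= 8.",
                 class = "rr_error_config")
  }
  structure(
    list(
      n = as.integer(n), round = round, seed = as.integer(seed),
      demographic_probs = demographic_probs,
      event_rate = event_rate, events_fixed = events_fixed,
      span_years = span_years, event_placement = event_placement,
      p_ftf = p_ftf, p_acasi = p_acasi,
      p_ftf_multipliers = p_ftf_multipliers,
      p_acasi_multipliers = p_acasi_multipliers,
      event_rate_multipliers = event_rate_multipliers,
      misdate_sd_months = misdate_sd_months,
      telescope_in_prob = telescope_in_prob,
      confusion_prob = confusion_prob,
      p_never_discloser = p_never_discloser
    ),
    class = "rr_config"
  )
}

# per-woman multiplier from a nested list(axis = c(level = mult))
subgroup_multiplier <- function(resp, multipliers) {
  m <- rep(1, nrow(resp))
  if (is.null(multipliers)) return(m)
  for (ax in names(multipliers)) {
    mv <- multipliers[[ax]]
    hit <- match(resp[[ax]], names(mv))
    m <- m * ifelse(is.na(hit), 1, mv[hit])
  }
  m
}

# symmetric two-sided geometric month error with target SD (0 => exact dates)
two_sided_geom_err <- function(n, sd) {
  if (sd == 0 || n == 0) return(integer(n))
  # sign * G, G ~ Geom(p) on {0,1,...}: Var = (1-p)(2-p)/p^2
  f <- function(p) (1 - p) * (2 - p) / p^2 - sd^2
  p <- stats::uniroot(f, c(1e-9, 1 - 1e-9))$root
  mag <- stats::rgeom(n, p)
  sgn <- sample(c(-1L, 1L), n, replace = TRUE)
  as.integer(sgn * mag)
}

raw_outcome_for <- function(category, n) {
  switch(category,
    birth = sample(c("live_birth_vaginal", "live_birth_cesarean"), n,
                   replace = TRUE, prob = c(0.67, 0.33)),
    loss = sample(c("miscarriage", "stillbirth", "ectopic"), n,
                  replace = TRUE, prob = c(0.80, 0.10, 0.10)),
    abortion = rep("abortion", n)
  )
}

#' Draw true reproductive histories and demographics
#'
#' Stage one of the generator: demographics drawn independently from the
#' configured category probabilities, interview months uniform over the
#' round's field period, and per-category true event counts Poisson with the
#' configured mean (or fixed via `events_fixed`), event months placed per
#' `event_placement`.
#'
#' @param config An `rr_config` from [generator_config()].
#' @param .seed Seed the RNG at `config$seed` (set `FALSE` when called inside
#'   [generate_cohort()], which manages one stream for all stages).
#' @return A list with tibbles `respondents` (id, demographics,
#'   `interview_cm`) and `events` (`event_id`, `id`, `category`, `outcome`,
#'   `true_cm`).
#' @export
generate_true_histories <- function(config, .seed = TRUE) {
  stopifnot(inherits(config, "rr_config"))
  run <- function() {
    n <- config$n
    period <- rr_round_period(config$round)
    resp <- tibble::tibble(
      id = sprintf("w%06d", seq_len(n)),
      round = config$round,
      interview_cm = as.integer(
        sample(seq(period[1], period[2]), n, replace = TRUE)
      )
    )
    for (ax in names(rr_demographic_levels)) {
      p <- config$demographic_probs[[ax]]
      resp[[ax]] <- sample(names(p), n, replace = TRUE, prob = p)
    }
    rate_mult <- subgroup_multiplier(resp, config$event_rate_multipliers)

    win <- if (config$round == "2002") {
      build_window(config$round, resp$interview_cm, "lifetime")
    } else {
      build_window(config$round, resp$interview_cm, "standard")
    }
    span_start <- resp$interview_cm - as.integer(config$span_years * 12) + 1L

    ev_list <- lapply(rr_categories, function(cat) {
      k <- if (!is.null(config$events_fixed)) {
        rep(config$events_fixed[[cat]], n)
      } else {
        stats::rpois(n, config$event_rate[[cat]] * rate_mult)
      }
      idx <- rep(seq_len(n), k)
      m <- length(idx)
      if (m == 0) return(NULL)
      lo <- switch(config$event_placement,
        span = span_start[idx],
        inwindow = if (config$round == "2002") span_start[idx]
                   else win$start_cm[idx],
        prewindow = span_start[idx]
      )
      hi <- switch(config$event_placement,
        span = resp$interview_cm[idx],
        inwindow = if (config$round == "2002") resp$interview_cm[idx]
                   else win$end_cm[idx],
        prewindow = if (config$round == "2002") resp$interview_cm[idx]
                    else win$start_cm[idx] - 1L
      )
      if (any(hi < lo)) {
        rlang::abort("Event span too short for the requested placement.",
                     class = "rr_error_config")
      }
      tibble::tibble(
        id = resp$id[idx],
        category = cat,
        outcome = raw_outcome_for(cat, m),
        true_cm = as.integer(lo + floor(stats::runif(m) * (hi - lo + 1L)))
      )
    })
    events <- dplyr::bind_rows(ev_list)
    if (nrow(events) == 0) {
      events <- tibble::tibble(id = character(), category = character(),
                               outcome = character(), true_cm = integer())
    }
    events <- dplyr::arrange(events, .data$id, .data$category, .data$true_cm)
    events$event_id <- seq_len(nrow(events))
    list(respondents = resp,
         events = events[, c("event_id", "id", "category", "outcome",
                             "true_cm")])
  }
  if (.seed) withr::with_seed(config$seed, run()) else run()
}

#' Pass true events through the interviewer-administered channel
#'
#' Stage two: each true event is disclosed independently with probability
#' `p_ftf[category]` (scaled by subgroup multipliers, clamped to `[0, 1]`;
#' women flagged as never-disclosers by `p_never_discloser` disclose
#' nothing); disclosed events receive a recorded month equal to the true
#' month plus a two-sided geometric error, clamped at the interview month.
#'
#' @inheritParams generate_true_histories
#' @param truth Output of [generate_true_histories()].
#' @return The `truth$events` tibble with added columns `disclosed_ftf` and
#'   `recorded_cm` (`NA` when undisclosed).
#' @export
apply_ftf_reporting <- function(truth, config, .seed = TRUE) {
  stopifnot(inherits(config, "rr_config"))
  run <- function() {
    ev <- truth$events
    resp <- truth$respondents
    if (nrow(ev) == 0) {
      ev$disclosed_ftf <- logical(0)
      ev$recorded_cm <- integer(0)
      return(ev)
    }
    mult <- subgroup_multiplier(resp, config$p_ftf_multipliers)
    never <- stats::rbinom(nrow(resp), 1, config$p_never_discloser) == 1
    ridx <- match(ev$id, resp$id)
    p <- pmin(pmax(config$p_ftf[ev$category] * mult[ridx], 0), 1)
    p[never[ridx]] <- 0
    ev$disclosed_ftf <- stats::rbinom(nrow(ev), 1, p) == 1
    err <- two_sided_geom_err(nrow(ev), config$misdate_sd_months)
    rec <- pmin(pmax(ev$true_cm + err, 1L), resp$interview_cm[ridx])
    ev$recorded_cm <- ifelse(ev$disclosed_ftf, as.integer(rec), NA_integer_)
    ev
  }
  if (.seed) withr::with_seed(config$seed + 1L, run()) else run()
}

#' Pass true events through the self-administered channel
#'
#' Stage three: each true event is independently kept with probability
#' `p_acasi[category]` (scaled by subgroup multipliers). For five-year
#' rounds, the base reported count is the kept in-window events plus any
#' out-of-window event telescoped in with probability `telescope_in_prob`;
#' with probability `confusion_prob` the respondent instead reports her
#' lifetime kept counts. For the 2002 round the items are lifetime counts
#' (kept events of any date) and telescoping/confusion do not apply.
#'
#' @inheritParams apply_ftf_reporting
#' @return A list with tibbles `acasi` (per woman: `id`, `acasi_birth`,
#'   `acasi_loss`, `acasi_abortion`, `confusion_applied`) and `events`
#'   (`event_id`, `counted_in_acasi`).
#' @export
apply_acasi_reporting <- function(truth, config, .seed = TRUE) {
  stopifnot(inherits(config, "rr_config"))
  run <- function() {
    ev <- truth$events
    resp <- truth$respondents
    five_year <- config$round != "2002"
    confusion <- if (five_year) {
      stats::rbinom(nrow(resp), 1, config$confusion_prob) == 1
    } else {
      rep(FALSE, nrow(resp))
    }
    if (nrow(ev) > 0) {
      mult <- subgroup_multiplier(resp, config$p_acasi_multipliers)
      ridx <- match(ev$id, resp$id)
      p <- pmin(pmax(config$p_acasi[ev$category] * mult[ridx], 0), 1)
      kept <- stats::rbinom(nrow(ev), 1, p) == 1
      if (five_year) {
        win <- build_window(config$round, resp$interview_cm, "standard")
        in_win <- cm_in_window(ev$true_cm, win$start_cm[ridx],
                               win$end_cm[ridx])
        telescoped <- !in_win &
          stats::rbinom(nrow(ev), 1, config$telescope_in_prob) == 1
        conf_ev <- confusion[ridx]
        counted <- ifelse(conf_ev, kept, (kept & in_win) | telescoped)
      } else {
        counted <- kept
      }
    } else {
      counted <- logical(0)
    }
    counts <- tidyr::pivot_wider(
      dplyr::count(
        dplyr::filter(
          dplyr::mutate(ev, counted = counted), .data$counted
        ),
        .data$id, .data$category
      ),
      names_from = "category", values_from = "n", values_fill = 0L
    )
    for (cat in rr_categories) {
      if (!cat %in% names(counts)) counts[[cat]] <- 0L
    }
    acasi <- tibble::tibble(id = resp$id)
    acasi <- dplyr::left_join(acasi, counts, by = "id")
    for (cat in rr_categories) {
      acasi[[paste0("acasi_", cat)]] <-
        as.integer(dplyr::coalesce(acasi[[cat]], 0L))
      acasi[[cat]] <- NULL
    }
    acasi$confusion_applied <- confusion
    list(
      acasi = acasi,
      events = tibble::tibble(event_id = ev$event_id,
                              counted_in_acasi = counted)
    )
  }
  if (.seed) withr::with_seed(config$seed + 2L, run()) else run()
}

#' Generate a synthetic paired-mode cohort with ground truth
#'
#' Composes [generate_true_histories()], [apply_ftf_reporting()] and
#' [apply_acasi_reporting()] under a single RNG stream seeded at
#' `config$seed`, and assembles a validated [cohort()] plus a truth ledger
#' recording, per event, the true month, history disclosure, recorded month
#' and self-administered counting, and per respondent the confusion flag.
#'
#' @param config An `rr_config`.
#' @return A list with elements `cohort` (an `rr_cohort`) and `ledger` (list
#'   of tibbles `events` and `respondents`).
#' @examples
#' sim <- generate_cohort(generator_config(n = 200, seed = 42))
#' sim$cohort
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "rr_config"))
  withr::with_seed(config$seed, {
    truth <- generate_true_histories(config, .seed = FALSE)
    ftf <- apply_ftf_reporting(truth, config, .seed = FALSE)
    acasi <- apply_acasi_reporting(truth, config, .seed = FALSE)
  })

  resp <- truth$respondents
  resp <- dplyr::left_join(
    resp,
    acasi$acasi[, c("id", "acasi_birth", "acasi_loss", "acasi_abortion")],
    by = "id"
  )
  resp$acasi_period <- if (config$round == "2002") "lifetime" else "five_year"
  resp$acasi_lifetime_total <- NA_integer_
  resp$currently_pregnant <- NA

  preg <- ftf[ftf$disclosed_ftf, c("id", "outcome", "recorded_cm"),
              drop = FALSE]
  names(preg)[names(preg) == "recorded_cm"] <- "end_cm"
  preg$is_current <- FALSE

  ledger_events <- ftf[, c("event_id", "id", "category", "outcome", "true_cm",
                           "disclosed_ftf", "recorded_cm")]
  ledger_events <- dplyr::left_join(ledger_events, acasi$events,
                                    by = "event_id")
  ledger_resp <- acasi$acasi[, c("id", "confusion_applied")]

  list(
    cohort = cohort(resp, preg, quiet = TRUE),
    ledger = list(events = ledger_events, respondents = ledger_resp)
  )
}
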