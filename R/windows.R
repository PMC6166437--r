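#' Century-month date helpers
#'
#' Event and interview dates are carried as century-month codes: months
#' elapsed since January 1900, so `cm(1900, 1) == 1` and `cm(2013, 6) == 1362`.
#' This is the encoding used by US fertility-survey public-use files and keeps
#' all recall-window arithmetic in whole calendar months.
#'
#' @param year Calendar year (vectorised).
#' @param month Calendar month 1-12 (vectorised).
#' @param x A century-month code (vectorised).
#' @return `cm()` returns an integer century-month code; `cm_year()` and
#'   `cm_month()` invert it.
#' @examples
#' cm(2013, 6)
#' cm_year(cm(2013, 6))
#' cm_month(cm(2013, 6))
#' @export
cm <- function(year, month) {
  stopifnot(all(month >= 1 & month <= 12))
  as.integer((year - 1900L) * 12L + month)
}

#' @rdname cm
#' @export
cm_year <- function(x) as.integer(1900L + (x - 1L) %/% 12L)

#' @rdname cm
#' @export
cm_month <- function(x) as.integer((x - 1L) %% 12L + 1L)

# category sets used throughout
rr_outcome_codes <- c(
  "live_birth_cesarean", "live_birth_vaginal", "stillbirth",
  "miscarriage", "ectopic", "abortion"
)
rr_categories <- c("birth", "loss", "abortion")
rr_rounds <- c("2002", "2006-2010", "2011-2015")
rr_window_labels <- c("standard", "expanded", "lifetime")

rr_demographic_levels <- list(
  age_group      = c("15-24", "25-34", "35-44"),
  race_ethnicity = c("white_nl", "black_nl", "other_nl", "latina"),
  poverty        = c("0-99", "100-299", "300+"),
  marital        = c("currently_married", "previously_married", "never_married"),
  religiosity    = c("lt_monthly", "monthly_plus")
)

# reference levels for stratified tables
rr_reference_levels <- c(
  age_group      = "25-34",
  race_ethnicity = "white_nl",
  poverty        = "300+",
  marital        = "currently_married",
  religiosity    = "lt_monthly"
)

#' Map a raw pregnancy-outcome code to a comparable category
#'
#' The interviewer-administered history records six outcome codes; the
#' self-administered module asks one count question per comparable category.
#' Live births (either delivery mode) map to `birth`; miscarriage, stillbirth
#' and ectopic pregnancy are pooled as `loss` (the self-administered item asks
#' for them in a single count); `abortion` maps to itself.
#'
#' @param outcome_raw Character vector of raw codes (see
#'   [outcome_codes()]).
#' @return Character vector over `c("birth", "loss", "abortion")`.
#' @examples
#' harmonize_outcome(c("ectopic", "live_birth_vaginal", "abortion"))
#' @export
harmonize_outcome <- function(outcome_raw) {
  map <- c(
    live_birth_cesarean = "birth",
    live_birth_vaginal  = "birth",
    stillbirth          = "loss",
    miscarriage         = "loss",
    ectopic             = "loss",
    abortion            = "abortion"
  )
  bad <- setdiff(unique(outcome_raw), names(map))
  if (length(bad) > 0) {
    rlang::abort(
      paste0("Unknown pregnancy outcome code(s): ", paste(bad, collapse = ", ")),
      class = "rr_error_outcome"
    )
  }
  unname(map[outcome_raw])
}

#' Outcome codes and comparable categories
#'
#' @return `outcome_codes()` returns the six raw pregnancy-outcome codes;
#'   `outcome_categories()` the three comparable categories.
#' @export
outcome_codes <- function() rr_outcome_codes

#' @rdname outcome_codes
#' @export
outcome_categories <- function() rr_categories

#' Build a recall window for one or more interview dates
#'
#' Three window labels are supported, mirroring the survey instruments:
#' * `standard`: January of (interview year - 5) through December of
#'   (interview year - 1) — the five whole calendar years preceding the
#'   interview year, as the five-year self-administered count items phrase it.
#' * `expanded`: widened one further year back to probe date misdating,
#'   January of (interview year - 6) through the interview month (default) or
#'   through December of (interview year - 1) when
#'   `expanded_end = "dec_prior_year"`.
#' * `lifetime`: open start, ending at the interview month (the 2002 round's
#'   lifetime count items).
#'
#' `standard` and `expanded` windows require a round with dated five-year
#' items (2006 onward); requesting them for the 2002 round is an error.
#'
#' @param round Survey round, one of `"2002"`, `"2006-2010"`, `"2011-2015"`.
#' @param interview_cm Century-month code(s) of the interview date.
#' @param label Window label: `"standard"`, `"expanded"` or `"lifetime"`.
#' @param expanded_end Where the expanded window closes: `"interview"`
#'   (default) or `"dec_prior_year"`.
#' @return A tibble with one row per interview date and columns `start_cm`
#'   (`NA` for the open lifetime start), `end_cm` and `label`. Window
#'   membership is always closed-interval on months.
#' @examples
#' build_window("2011-2015", cm(2013, 6), "standard") # Jan 2008 - Dec 2012
#' build_window("2006-2010", cm(2009, 3), "expanded") # Jan 2003 - Mar 2009
#' @export
build_window <- function(round, interview_cm,
                         label = c("standard", "expanded", "lifetime"),
                         expanded_end = c("interview", "dec_prior_year")) {
  label <- rlang::arg_match(label)
  expanded_end <- rlang::arg_match(expanded_end)
  round <- rlang::arg_match(round, rr_rounds)
  if (round == "2002" && label %in% c("standard", "expanded")) {
    rlang::abort(
      paste0("Window '", label, "' needs dated five-year items; the 2002 ",
             "round has lifetime items only."),
      class = "rr_error_window"
    )
  }
  yr <- cm_year(interview_cm)
  out <- switch(label,
    standard = tibble::tibble(
      start_cm = cm(yr - 5L, 1L),
      end_cm   = cm(yr - 1L, 12L)
    ),
    expanded = tibble::tibble(
      start_cm = cm(yr - 6L, 1L),
      end_cm   = if (expanded_end == "interview") as.integer(interview_cm)
                 else cm(yr - 1L, 12L)
    ),
    lifetime = tibble::tibble(
      start_cm = NA_integer_,
      end_cm   = as.integer(interview_cm)
    )
  )
  out$label <- label
  out
}

# closed-interval membership; NA start = open (lifetime)
cm_in_window <- function(x, start_cm, end_cm) {
  lower <- ifelse(is.na(start_cm), TRUE, x >= start_cm)
  lower & x <= end_cm
}

#' Per-respondent event counts from the interviewer-administered history
#'
#' Counts, for every respondent in the cohort, the non-ongoing pregnancies of
#' a comparable category whose end date falls inside the respondent's recall
#' window (closed interval, both endpoint months included). Each respondent's
#' window is built from her own interview date.
#'
#' @param x A [cohort()] object.
#' @param category One of `"birth"`, `"loss"`, `"abortion"`.
#' @param window Window label passed to [build_window()].
#' @param drop_stillbirth If `TRUE`, stillbirths are excluded from the
#'   history-side count (sensitivity option; the loss category otherwise pools
#'   miscarriage, stillbirth and ectopic in both modes).
#' @param expanded_end Passed to [build_window()].
#' @return A tibble with columns `id` and `n` (one row per respondent,
#'   respondents with no qualifying event included with `n = 0`).
#' @export
ftf_window_count <- function(x, category,
                             window = c("standard", "expanded", "lifetime"),
                             drop_stillbirth = FALSE,
                             expanded_end = c("interview", "dec_prior_year")) {
  stopifnot(inherits(x, "rr_cohort"))
  category <- rlang::arg_match(category, rr_categories)
  window <- rlang::arg_match(window)
  expanded_end <- rlang::arg_match(expanded_end)

  win <- build_window(x$round, x$respondents$interview_cm, window,
                      expanded_end = expanded_end)
  win <- tibble::tibble(
    id = x$respondents$id, win_start = win$start_cm, win_end = win$end_cm
  )

  ev <- x$pregnancies
  ev <- ev[!ev$is_current & !is.na(ev$end_cm), , drop = FALSE]
  if (drop_stillbirth) ev <- ev[ev$outcome != "stillbirth", , drop = FALSE]
  if (nrow(ev) > 0) {
    ev <- ev[harmonize_outcome(ev$outcome) == category, , drop = FALSE]
  }

  counted <- dplyr::inner_join(ev, win, by = "id")
  counted <- counted[
    cm_in_window(counted$end_cm, counted$win_start, counted$win_end), ,
    drop = FALSE
  ]
  tallied <- dplyr::count(counted, .data$id, name = "n")
  out <- dplyr::left_join(
    tibble::tibble(id = x$respondents$id), tallied, by = "id"
  )
  out$n <- as.integer(dplyr::coalesce(out$n, 0L))
  out
}

#' Per-respondent counts from the self-administered module
#'
#' Returns each respondent's reported count for a comparable category from
#' the self-administered (ACASI) module. Respondents with a missing module are
#' excluded at cohort validation, so counts here are always non-missing.
#'
#' @inheritParams ftf_window_count
#' @return A tibble with columns `id` and `n`.
#' @export
acasi_count <- function(x, category) {
  stopifnot(inherits(x, "rr_cohort"))
  category <- rlang::arg_match(category, rr_categories)
  col <- paste0("acasi_", category)
  tibble::tibble(id = x$respondents$id, n = as.integer(x$respondents[[col]]))
}
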