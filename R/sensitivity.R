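#' Respondents discordant between the two modes
#'
#' Identifies respondents who report at least one event of a category in the
#' five-year self-administered module but none in the same standard window of
#' the interviewer-administered history. These are the candidates for
#' telescoping or lifetime-for-window confusion (or pure history-side
#' suppression). Requires dated five-year items, i.e. rounds from 2006
#' onward.
#'
#' @inheritParams reporting_ratio
#' @return Character vector of respondent ids.
#' @export
discordant_reporters <- function(x, category) {
  stopifnot(inherits(x, "rr_cohort"))
  category <- rlang::arg_match(category, rr_categories)
  if (x$round == "2002") {
    rlang::abort(
      "Discordance needs five-year items with dated history (2006 onward).",
      class = "rr_error_round"
    )
  }
  a <- acasi_count(x, category)
  f <- ftf_window_count(x, category, "standard")
  a$id[a$n >= 1L & f$n == 0L]
}

#' Lifetime-match proportion among discordant reporters
#'
#' Among respondents discordant for a category (see
#' [discordant_reporters()]), computes the proportion whose self-administered
#' five-year count exactly equals their lifetime count of that category in
#' the interviewer-administered history (all matching pregnancies regardless
#' of date). A high proportion indicates respondents answering the five-year
#' count question with their lifetime history — the comprehension failure the
#' sensitivity analysis probes. Exact equality is required for a match.
#'
#' The source analysis reports this for births and abortions; the loss
#' category is computed here too but has no published counterpart.
#'
#' @inheritParams reporting_ratio
#' @return A one-row tibble: `category`, `n_discordant`, `n_lifetime_match`,
#'   `proportion`.
#' @export
lifetime_match_proportion <- function(x, category) {
  stopifnot(inherits(x, "rr_cohort"))
  category <- rlang::arg_match(category, rr_categories)
  ids <- discordant_reporters(x, category)
  if (length(ids) == 0) {
    rlang::abort(
      paste0("No discordant reporters for category '", category,
             "'; the proportion is undefined."),
      class = "rr_error_undefined_proportion"
    )
  }
  a <- acasi_count(x, category)
  lifetime <- ftf_window_count(x, category, "lifetime")
  acasi_n <- a$n[match(ids, a$id)]
  life_n <- lifetime$n[match(ids, lifetime$id)]
  n_match <- sum(acasi_n == life_n)
  tibble::tibble(
    category = category,
    n_discordant = length(ids),
    n_lifetime_match = as.integer(n_match),
    proportion = n_match / length(ids)
  )
}
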