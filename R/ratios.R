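rr_default_window <- function(round) {
  if (round == "2002") "lifetime" else "standard"
}

new_ratio_tbl <- function(df) {
  tibble::new_tibble(df, class = "rr_ratio")
}

ratio_row <- function(cohort, category, ftf_window, acasi_window,
                      statistic = "reporters", stratum = NA_character_,
                      level = NA_character_, expanded_end = "interview") {
  a <- acasi_count(cohort, category)$n
  f <- ftf_window_count(cohort, category, ftf_window,
                        expanded_end = expanded_end)$n
  if (statistic == "reporters") {
    num <- sum(a >= 1L)
    den <- sum(f >= 1L)
  } else {
    num <- sum(a)
    den <- sum(f)
  }
  if (den == 0) {
    rlang::abort(
      paste0("Undefined reporting ratio: no history-side reporters for ",
             "category '", category, "'",
             if (!is.na(level)) paste0(" in stratum ", stratum, "=", level),
             "."),
      class = "rr_error_undefined_ratio"
    )
  }
  new_ratio_tbl(tibble::tibble(
    category = category,
    statistic = statistic,
    stratum = stratum,
    level = level,
    is_ref = NA,
    n_acasi = as.integer(num),
    n_ftf = as.integer(den),
    ratio = num / den,
    acasi_window = acasi_window,
    ftf_window = ftf_window,
    n_total = nrow(cohort$respondents)
  ))
}

#' Within-subject reporting ratio for one outcome
#'
#' The headline statistic: the number of respondents reporting at least one
#' event of a comparable category in the self-administered module, divided by
#' the number reporting at least one in the interviewer-administered history
#' over the matching recall window. The same respondents enter both counts
#' (a within-subject design); 1.00 means parity, values above 1.00 mean more
#' respondents disclose in the self-administered mode.
#'
#' For the 2002 round both modes are compared on lifetime reports; for later
#' rounds both use the standard five-year window (January of the interview
#' year minus 5 through December of the interview year minus 1).
#'
#' `statistic = "events"` gives a secondary event-count ratio (total reported
#' events rather than reporting women); it is not the headline statistic and
#' is labelled as such in the output.
#'
#' @param x An [cohort()] object.
#' @param category `"birth"`, `"loss"` or `"abortion"`.
#' @param window History-side window label; defaults to the round's matched
#'   window (`lifetime` for 2002, `standard` otherwise).
#' @param statistic `"reporters"` (respondents with >= 1 event; the headline
#'   statistic) or `"events"` (summed counts).
#' @return A one-row `rr_ratio` tibble with columns `category`, `statistic`,
#'   `stratum`, `level`, `n_acasi`, `n_ftf`, `ratio`, the window labels and
#'   `n_total`. The ratio is carried at full precision; round only for
#'   display (see [render_table()]).
#' @examples
#' sim <- generate_cohort(generator_config(n = 500, seed = 7))
#' reporting_ratio(sim$cohort, "abortion")
#' @export
reporting_ratio <- function(x, category,
                            window = NULL,
                            statistic = c("reporters", "events")) {
  stopifnot(inherits(x, "rr_cohort"))
  category <- rlang::arg_match(category, rr_categories)
  statistic <- rlang::arg_match(statistic)
  if (is.null(window)) window <- rr_default_window(x$round)
  window <- rlang::arg_match(window, c("standard", "lifetime"))
  if (x$round == "2002" && window != "lifetime") {
    rlang::abort("The 2002 round supports lifetime comparisons only.",
                 class = "rr_error_window")
  }
  if (x$round != "2002" && window != "standard") {
    rlang::abort(
      "Five-year rounds compare both modes on the standard window.",
      class = "rr_error_window"
    )
  }
  ratio_row(x, category, ftf_window = window, acasi_window = window,
            statistic = statistic)
}

#' Expanded-window reporting ratio
#'
#' Same numerator as [reporting_ratio()] (five-year self-administered
#' reporters) but the history-side denominator is widened to start six years
#' before the interview year. If part of the excess self-administered
#' reporting comes from events misdated into the five-year window, the
#' expanded ratio falls below the standard one. Only defined for rounds with
#' dated five-year items (2006 onward).
#'
#' @inheritParams reporting_ratio
#' @param expanded_end Where the expanded window closes: `"interview"`
#'   (default) or `"dec_prior_year"`.
#' @return A one-row `rr_ratio` tibble; `ftf_window` is `"expanded"`.
#' @export
expanded_reporting_ratio <- function(x, category,
                                     statistic = c("reporters", "events"),
                                     expanded_end = c("interview",
                                                      "dec_prior_year")) {
  stopifnot(inherits(x, "rr_cohort"))
  category <- rlang::arg_match(category, rr_categories)
  statistic <- rlang::arg_match(statistic)
  expanded_end <- rlang::arg_match(expanded_end)
  if (x$round == "2002") {
    rlang::abort(
      "Expanded windows need dated five-year items (2006 onward).",
      class = "rr_error_window"
    )
  }
  ratio_row(x, category, ftf_window = "expanded", acasi_window = "standard",
            statistic = statistic, expanded_end = expanded_end)
}

#' Reporting ratios stratified by a demographic axis
#'
#' Computes [reporting_ratio()] on the subset of respondents at each level of
#' a recoded demographic axis. The reference level per axis (the one marked
#' "(ref)" in stratified tables) is flagged: ages 25-34, white non-Latina,
#' poverty at or above 300 percent, currently married, less-than-monthly
#' religious attendance. A level whose ratio is undefined (no history-side
#' reporters) is returned with `ratio = NA` and a note instead of failing the
#' other levels.
#'
#' @inheritParams reporting_ratio
#' @param axis One of `"age_group"`, `"race_ethnicity"`, `"poverty"`,
#'   `"marital"`, `"religiosity"`.
#' @return An `rr_ratio` tibble, one row per level, with `is_ref` and `note`
#'   columns.
#' @export
stratified_ratios <- function(x, category, axis, window = NULL) {
  stopifnot(inherits(x, "rr_cohort"))
  category <- rlang::arg_match(category, rr_categories)
  axis <- rlang::arg_match(axis, names(rr_demographic_levels))
  levels <- rr_demographic_levels[[axis]]
  rows <- purrr::map(levels, function(lv) {
    ids <- x$respondents$id[x$respondents[[axis]] == lv]
    row <- tryCatch({
      if (length(ids) == 0) {
        rlang::abort(paste0("Empty stratum ", axis, "=", lv, "."),
                     class = "rr_error_undefined_ratio")
      }
      sub <- cohort_subset(x, ids)
      r <- reporting_ratio(sub, category, window = window)
      r$note <- NA_character_
      r
    },
    rr_error_undefined_ratio = function(e) {
      new_ratio_tbl(tibble::tibble(
        category = category, statistic = "reporters",
        stratum = axis, level = lv, is_ref = NA,
        n_acasi = NA_integer_, n_ftf = NA_integer_, ratio = NA_real_,
        acasi_window = NA_character_, ftf_window = NA_character_,
        n_total = length(ids), note = "undefined_ratio"
      ))
    })
    row$stratum <- axis
    row$level <- lv
    row
  })
  out <- dplyr::bind_rows(rows)
  out$is_ref <- out$level == rr_reference_levels[[axis]]
  new_ratio_tbl(out)
}

#' All reporting ratios for a cohort, table-style
#'
#' Convenience wrapper returning the overall ratio (and, for five-year
#' rounds, the expanded ratio) for every comparable category — one cohort's
#' worth of a round-by-outcome results table.
#'
#' @inheritParams reporting_ratio
#' @param categories Categories to include.
#' @param expanded Also compute expanded-window ratios (five-year rounds).
#' @return An `rr_ratio` tibble.
#' @export
ratio_table <- function(x, categories = rr_categories, expanded = TRUE) {
  stopifnot(inherits(x, "rr_cohort"))
  rows <- purrr::map(categories, function(cat) {
    r <- reporting_ratio(x, cat)
    if (expanded && x$round != "2002") {
      dplyr::bind_rows(r, expanded_reporting_ratio(x, cat))
    } else {
      r
    }
  })
  out <- dplyr::bind_rows(rows)
  out$round <- x$round
  new_ratio_tbl(out)
}

#' @exportS3Method generics::tidy
tidy.rr_ratio <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Forest-style plot of reporting ratios
#'
#' @param object An `rr_ratio` tibble (e.g. from [stratified_ratios()] or
#'   [ratio_table()]), optionally with `ci_low`/`ci_high` columns attached
#'   (e.g. joined from bootstrap results).
#' @param ... Unused.
#' @return A ggplot object: ratios (log scale) by level/category with a
#'   parity line at 1.
#' @exportS3Method ggplot2::autoplot
autoplot.rr_ratio <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- ifelse(is.na(df$level),
                     paste(df$category, df$ftf_window, sep = ", "),
                     df$level)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "reporting ratio (self-administered / interviewer, log scale)",
      y = NULL
    )
  if (all(c("ci_low", "ci_high") %in% names(df))) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    )
  }
  if (!all(is.na(df$category)) && length(unique(df$category)) > 1) {
    p <- p + ggplot2::facet_wrap(~category)
  }
  p
}
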