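format_ratio_ci <- function(ratio, ci_low = NA, ci_high = NA, decimals = 2,
                            sig = "") {
  fmt <- paste0("%.", decimals, "f")
  base <- sprintf(fmt, ratio)
  if (!is.na(sig) && nzchar(sig)) base <- paste0(base, "^", sig)
  if (!is.na(ci_low) && !is.na(ci_high)) {
    base <- paste0(base, " (", sprintf(fmt, ci_low), "–",
                   sprintf(fmt, ci_high), ")")
  }
  base
}

md_table <- function(header, rows) {
  lines <- c(
    paste0("| ", paste(header, collapse = " | "), " |"),
    paste0("|", paste(rep("---", length(header)), collapse = "|"), "|")
  )
  for (r in rows) {
    lines <- c(lines, paste0("| ", paste(r, collapse = " | "), " |"))
  }
  structure(lines, class = "rr_table")
}

#' @export
print.rr_table <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}

#' Render estimates as a publication-shaped markdown table
#'
#' Two layouts are supported. `round_by_outcome` puts survey rounds in rows
#' and outcome categories in columns, each cell `ratio (ci_low-ci_high)`
#' with optional significance letters and an optional expanded-ratio column
#' per category. `stratified_panel` puts demographic levels in rows (with a
#' "(ref)" marker on reference levels) and categories in columns. Ratios are
#' displayed rounded to `decimals` (default 2); the underlying tibbles keep
#' full precision.
#'
#' @param results A tibble. For `round_by_outcome`: columns `round`,
#'   `category`, `ratio`, optionally `ci_low`, `ci_high`, `expanded_ratio`,
#'   `sig` (letter flags). For `stratified_panel`: columns `stratum`,
#'   `level`, `is_ref`, `category`, `ratio`, optionally `ci_low`, `ci_high`,
#'   `sig`. At most one row per cell; duplicates are an error.
#' @param style Table layout.
#' @param decimals Display decimals.
#' @return Character lines of a markdown table (class `rr_table`).
#' @examples
#' render_table(
#'   tibble::tibble(round = "2011-2015", category = "abortion",
#'                  ratio = 1.4567, ci_low = 1.361, ci_high = 1.557),
#'   style = "round_by_outcome"
#' )
#' @export
render_table <- function(results,
                         style = c("round_by_outcome", "stratified_panel"),
                         decimals = 2) {
  style <- rlang::arg_match(style)
  results <- tibble::as_tibble(results)
  for (col in c("ci_low", "ci_high")) {
    if (!col %in% names(results)) results[[col]] <- NA_real_
  }
  if (!"sig" %in% names(results)) results$sig <- ""
  if (nrow(results) == 0) {
    return(md_table(c("", rr_categories), list()))
  }
  cell <- function(df) {
    if (nrow(df) == 0) return("")
    format_ratio_ci(df$ratio[1], df$ci_low[1], df$ci_high[1], decimals,
                    df$sig[1])
  }

  if (style == "round_by_outcome") {
    need <- c("round", "category", "ratio")
    if (!all(need %in% names(results))) {
      rlang::abort("round_by_outcome needs columns round, category, ratio.",
                   class = "rr_error_render")
    }
    if (anyDuplicated(results[, c("round", "category")])) {
      rlang::abort(
        "More than one estimate per round and category in one row.",
        class = "rr_error_render"
      )
    }
    has_exp <- "expanded_ratio" %in% names(results)
    cats <- intersect(rr_categories, unique(results$category))
    header <- c("Survey period", unlist(lapply(cats, function(ct) {
      c(ct, if (has_exp) paste0(ct, " (expanded)"))
    })))
    rows <- lapply(unique(results$round), function(rd) {
      vals <- unlist(lapply(cats, function(ct) {
        df <- results[results$round == rd & results$category == ct, ]
        c(cell(df),
          if (has_exp) {
            if (nrow(df) == 0 || is.na(df$expanded_ratio[1])) "" else
              sprintf(paste0("%.", decimals, "f"), df$expanded_ratio[1])
          })
      }))
      c(rd, vals)
    })
    return(md_table(header, rows))
  }

  need <- c("stratum", "level", "category", "ratio")
  if (!all(need %in% names(results))) {
    rlang::abort(
      "stratified_panel needs columns stratum, level, category, ratio.",
      class = "rr_error_render"
    )
  }
  if (!"is_ref" %in% names(results)) results$is_ref <- FALSE
  cats <- intersect(rr_categories, unique(results$category))
  header <- c("Characteristic", cats)
  key <- unique(results[, c("stratum", "level", "is_ref")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    lab <- paste0(key$level[i], if (isTRUE(key$is_ref[i])) " (ref)" else "")
    vals <- vapply(cats, function(ct) {
      cell(results[results$stratum == key$stratum[i] &
                     results$level == key$level[i] &
                     results$category == ct, ])
    }, character(1))
    c(lab, vals)
  })
  md_table(header, rows)
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  config
}

#' Run the full paired-mode analysis pipeline
#'
#' Orchestrates cohort acquisition (read from files or simulate), the
#' reporting-ratio analyses, bootstrap inference and the misdating
#' sensitivity analysis, writing a bundle of CSV/markdown outputs and a
#' machine-readable manifest.
#'
#' `config` is a list (or path to a YAML/JSON file) with fields:
#' * exactly one of `input` (list with `respondents`, optional `pregnancies`,
#'   optional `schema` path) or `simulate` (arguments to
#'   [generator_config()]);
#' * `analyses`: subset of `"ratios"`, `"bootstrap"`, `"sensitivity"`
#'   (default all applicable);
#' * `axes`: demographic axes for stratified panels (default none);
#' * `B`, `alpha`, `seed`, `decimals`, `out_dir`.
#'
#' Outputs in `out_dir`: `cohort_summary.csv`, `ratios.csv` + `ratios.md`,
#' `stratified.csv` + `stratified.md` (if `axes`), `bootstrap.csv`,
#' `sensitivity.csv` (five-year rounds), and `manifest.json` recording the
#' seed, parameters, package version and exclusion counts. A failing stage
#' aborts with the stage named and removes the partial outputs.
#'
#' @param config List or path; see Details.
#' @return Invisibly, a list with the cohort and all result tibbles.
#' @export
run_pipeline <- function(config) {
  config <- read_run_config(config)
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim) {
    rlang::abort("Provide exactly one of 'input' or 'simulate'.",
                 class = "rr_error_config")
  }
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  B <- as.integer(config$B %||% 5000L)
  alpha <- config$alpha %||% 0.05
  seed <- as.integer(config$seed %||% 1L)
  decimals <- config$decimals %||% 2
  analyses <- config$analyses %||% c("ratios", "bootstrap", "sensitivity")

  written <- character()
  emit_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(df, path, progress = FALSE)
    written <<- c(written, path)
  }
  emit_text <- function(lines, name) {
    path <- file.path(out_dir, name)
    writeLines(lines, path)
    written <<- c(written, path)
  }
  stage <- "setup"
  bundle <- list()

  result <- tryCatch({
    stage <- "cohort"
    if (has_sim) {
      gc_args <- config$simulate
      if (!is.null(seed) && is.null(gc_args$seed)) gc_args$seed <- seed
      cfg <- do.call(generator_config, gc_args)
      sim <- generate_cohort(cfg)
      coh <- sim$cohort
      bundle$ledger <- sim$ledger
    } else {
      coh <- read_cohort(config$input$respondents,
                         config$input$pregnancies %||% NULL,
                         schema = config$input$schema %||% default_schema(),
                         quiet = TRUE)
    }
    bundle$cohort <- coh
    emit_csv(cohort_summary(coh), "cohort_summary.csv")

    if ("ratios" %in% analyses) {
      stage <- "ratios"
      rt <- ratio_table(coh)
      bundle$ratios <- rt
      emit_csv(tibble::as_tibble(rt), "ratios.csv")
      wide <- tidyr::pivot_wider(
        tibble::as_tibble(rt)[, c("round", "category", "ftf_window", "ratio")],
        names_from = "ftf_window", values_from = "ratio"
      )
      std <- wide
      names(std)[names(std) %in% c("standard", "lifetime")] <- "ratio"
      if ("expanded" %in% names(std)) {
        names(std)[names(std) == "expanded"] <- "expanded_ratio"
      }
      emit_text(render_table(std, "round_by_outcome", decimals), "ratios.md")

      axes <- config$axes %||% character()
      if (length(axes) > 0) {
        strat <- dplyr::bind_rows(lapply(axes, function(ax) {
          dplyr::bind_rows(lapply(rr_categories, function(ct) {
            tibble::as_tibble(stratified_ratios(coh, ct, ax))
          }))
        }))
        bundle$stratified <- strat
        emit_csv(strat, "stratified.csv")
        emit_text(render_table(strat, "stratified_panel", decimals),
                  "stratified.md")
      }
    }

    if ("bootstrap" %in% analyses) {
      stage <- "bootstrap"
      boots <- lapply(rr_categories, function(ct) {
        bootstrap_ratio(coh, ct, B = B, seed = seed, alpha = alpha)
      })
      bundle$bootstrap <- boots
      emit_csv(
        dplyr::bind_rows(lapply(boots, function(b) {
          cbind(tidy(b), glance(b))
        })),
        "bootstrap.csv"
      )
    }

    if ("sensitivity" %in% analyses && coh$round != "2002") {
      stage <- "sensitivity"
      sens <- dplyr::bind_rows(lapply(rr_categories, function(ct) {
        tryCatch(lifetime_match_proportion(coh, ct),
                 rr_error_undefined_proportion = function(e) {
                   tibble::tibble(category = ct, n_discordant = 0L,
                                  n_lifetime_match = 0L,
                                  proportion = NA_real_)
                 })
      }))
      bundle$sensitivity <- sens
      emit_csv(sens, "sensitivity.csv")
    }

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("reportratio")),
      seed = seed, B = B, alpha = alpha, decimals = decimals,
      round = coh$round,
      n_respondents = nrow(coh$respondents),
      n_excluded = nrow(coh$exclusions),
      analyses = analyses,
      source = if (has_sim) "simulate" else "input",
      config = config[setdiff(names(config), "out_dir")]
    )
    path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    written <- c(written, path)
    bundle$manifest <- manifest
    bundle
  },
  error = function(e) {
    unlink(written)
    rlang::abort(paste0("Pipeline stage '", stage, "' failed: ",
                        conditionMessage(e)),
                 class = "rr_error_stage", parent = e)
  })
  invisible(result)
}
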