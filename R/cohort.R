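#' Assemble and validate a paired-mode cohort
#'
#' A cohort bundles one survey round's respondent table (demographics,
#' interview date, self-administered outcome counts) with its event-level
#' pregnancy table (one row per pregnancy from the interviewer-administered
#' history). Validation enforces the domain invariants and excludes
#' respondents who fail them, keeping a per-respondent exclusion report:
#'
#' * self-administered counts present and non-negative (a refused or
#'   not-ascertained module, coded `NA` or a negative sentinel, excludes the
#'   respondent — she has only one mode and cannot enter a within-subject
#'   ratio);
#' * demographics inside their category sets;
#' * every pregnancy end date at or before the interview month;
#' * `end_cm` present exactly when the pregnancy is not ongoing.
#'
#' Pregnancy rows whose `id` matches no respondent are an error (orphan
#' records), as is mixing survey rounds in one cohort.
#'
#' @param respondents Data frame with columns `id`, `round`, `interview_cm`,
#'   `age_group`, `race_ethnicity`, `poverty`, `marital`, `religiosity`,
#'   `acasi_birth`, `acasi_loss`, `acasi_abortion`, and optionally
#'   `acasi_period`, `acasi_lifetime_total`, `currently_pregnant`.
#' @param pregnancies Data frame with columns `id`, `outcome` (one of
#'   [outcome_codes()]), `end_cm`, `is_current`. May be empty.
#' @param quiet Suppress the exclusion-count message.
#' @return An object of class `rr_cohort`: a list with tibbles `respondents`
#'   and `pregnancies`, the `round`, and an `exclusions` tibble
#'   (`id`, `reason`).
#' @examples
#' resp <- tibble::tibble(
#'   id = "w1", round = "2011-2015", interview_cm = cm(2013, 6),
#'   age_group = "25-34", race_ethnicity = "latina", poverty = "0-99",
#'   marital = "never_married", religiosity = "lt_monthly",
#'   acasi_birth = 1L, acasi_loss = 0L, acasi_abortion = 1L
#' )
#' preg <- tibble::tibble(
#'   id = "w1", outcome = "abortion", end_cm = cm(2010, 2), is_current = FALSE
#' )
#' cohort(resp, preg)
#' @export
cohort <- function(respondents, pregnancies = NULL, quiet = FALSE) {
  respondents <- tibble::as_tibble(respondents)
  if (is.null(pregnancies)) {
    pregnancies <- tibble::tibble(
      id = character(), outcome = character(),
      end_cm = integer(), is_current = logical()
    )
  }
  pregnancies <- tibble::as_tibble(pregnancies)

  req_resp <- c("id", "round", "interview_cm", "age_group", "race_ethnicity",
                "poverty", "marital", "religiosity",
                "acasi_birth", "acasi_loss", "acasi_abortion")
  miss <- setdiff(req_resp, names(respondents))
  if (length(miss) > 0) {
    rlang::abort(
      paste0("Respondent table lacks column(s): ", paste(miss, collapse = ", ")),
      class = "rr_error_schema"
    )
  }
  req_preg <- c("id", "outcome", "end_cm", "is_current")
  miss <- setdiff(req_preg, names(pregnancies))
  if (length(miss) > 0) {
    rlang::abort(
      paste0("Pregnancy table lacks column(s): ", paste(miss, collapse = ", ")),
      class = "rr_error_schema"
    )
  }

  if (anyDuplicated(respondents$id)) {
    rlang::abort("Duplicated respondent ids.", class = "rr_error_schema")
  }
  rounds <- unique(respondents$round)
  if (length(rounds) != 1) {
    rlang::abort(
      paste0("A cohort holds exactly one survey round; got: ",
             paste(rounds, collapse = ", ")),
      class = "rr_error_cohort"
    )
  }
  round <- rlang::arg_match0(as.character(rounds), rr_rounds)

  orphans <- setdiff(pregnancies$id, respondents$id)
  if (length(orphans) > 0) {
    rlang::abort(
      paste0("Pregnancy rows reference unknown respondent id(s): ",
             paste(utils::head(orphans, 5), collapse = ", ")),
      class = "rr_error_orphan"
    )
  }

  respondents$id <- as.character(respondents$id)
  pregnancies$id <- as.character(pregnancies$id)
  respondents$interview_cm <- as.integer(respondents$interview_cm)
  for (col in c("acasi_birth", "acasi_loss", "acasi_abortion")) {
    respondents[[col]] <- suppressWarnings(as.integer(respondents[[col]]))
  }
  if (!"acasi_period" %in% names(respondents)) {
    respondents$acasi_period <-
      if (round == "2002") "lifetime" else "five_year"
  }
  if (!"acasi_lifetime_total" %in% names(respondents)) {
    respondents$acasi_lifetime_total <- NA_integer_
  }
  if (!"currently_pregnant" %in% names(respondents)) {
    respondents$currently_pregnant <- NA
  }
  respondents$acasi_lifetime_total <-
    suppressWarnings(as.integer(respondents$acasi_lifetime_total))
  respondents$currently_pregnant <-
    as.logical(respondents$currently_pregnant)
  pregnancies$end_cm <- suppressWarnings(as.integer(pregnancies$end_cm))
  pregnancies$is_current <- as.logical(pregnancies$is_current)

  # ---- per-respondent invariant checks -> exclusions ----
  reasons <- rep(NA_character_, nrow(respondents))
  mark <- function(bad, why) {
    reasons[bad & is.na(reasons)] <<- why
  }

  acasi_bad <- is.na(respondents$acasi_birth) | respondents$acasi_birth < 0 |
    is.na(respondents$acasi_loss) | respondents$acasi_loss < 0 |
    is.na(respondents$acasi_abortion) | respondents$acasi_abortion < 0
  mark(acasi_bad, "missing_acasi_module")

  if (round == "2002" && any(respondents$acasi_period != "lifetime")) {
    rlang::abort("2002 self-administered items are lifetime counts.",
                 class = "rr_error_schema")
  }

  for (ax in names(rr_demographic_levels)) {
    bad <- !(respondents[[ax]] %in% rr_demographic_levels[[ax]])
    mark(bad, paste0("invalid_", ax))
  }
  mark(is.na(respondents$interview_cm), "missing_interview_date")

  # event-level invariants roll up to the owning respondent
  ev_bad_date <- (!pregnancies$is_current & is.na(pregnancies$end_cm)) |
    (pregnancies$is_current & !is.na(pregnancies$end_cm))
  ev_bad_code <- !(pregnancies$outcome %in% rr_outcome_codes)
  iv <- respondents$interview_cm[match(pregnancies$id, respondents$id)]
  ev_future <- !is.na(pregnancies$end_cm) & !is.na(iv) & pregnancies$end_cm > iv
  bad_ids <- unique(pregnancies$id[ev_bad_date | ev_bad_code | ev_future])
  mark(respondents$id %in% bad_ids, "invalid_pregnancy_record")

  excl <- tibble::tibble(
    id = respondents$id[!is.na(reasons)],
    reason = reasons[!is.na(reasons)]
  )
  keep <- is.na(reasons)
  respondents <- respondents[keep, , drop = FALSE]
  pregnancies <- pregnancies[pregnancies$id %in% respondents$id, , drop = FALSE]
  if (!quiet && nrow(excl) > 0) {
    rlang::inform(paste0(
      "cohort(): excluded ", nrow(excl), " respondent(s) failing validation (",
      paste(sprintf("%s: %d", names(table(excl$reason)), table(excl$reason)),
            collapse = "; "), ")."
    ))
  }
  if (nrow(respondents) == 0) {
    rlang::abort("No respondents left after validation.",
                 class = "rr_error_cohort")
  }

  structure(
    list(
      respondents = respondents,
      pregnancies = pregnancies,
      round = round,
      exclusions = excl
    ),
    class = "rr_cohort"
  )
}

#' @export
print.rr_cohort <- function(x, ...) {
  cat("<rr_cohort> round ", x$round, ": ", nrow(x$respondents),
      " respondents, ", nrow(x$pregnancies),
      " pregnancy records (", nrow(x$exclusions), " excluded)\n", sep = "")
  invisible(x)
}

# subset a cohort to a set of respondent ids (keeps validation state)
cohort_subset <- function(x, ids) {
  keep_r <- x$respondents$id %in% ids
  out <- x
  out$respondents <- x$respondents[keep_r, , drop = FALSE]
  out$pregnancies <- x$pregnancies[x$pregnancies$id %in% ids, , drop = FALSE]
  out
}

#' Column schemas for reading cohorts from delimited text
#'
#' `default_schema()` maps file columns named exactly like the native fields.
#' `nsfg_schema()` maps the variable names used by the NCHS public-use female
#' respondent and pregnancy files onto the native fields; values must already
#' be recoded to the package's category sets (see the methods vignette for
#' the recode conventions).
#'
#' @return A list with character vectors `respondents` and `pregnancies`;
#'   names are native fields, values the file column names.
#' @export
default_schema <- function() {
  list(
    respondents = c(
      id = "id", round = "round", interview_cm = "interview_cm",
      age_group = "age_group", race_ethnicity = "race_ethnicity",
      poverty = "poverty", marital = "marital", religiosity = "religiosity",
      acasi_birth = "acasi_birth", acasi_loss = "acasi_loss",
      acasi_abortion = "acasi_abortion",
      acasi_period = "acasi_period",
      acasi_lifetime_total = "acasi_lifetime_total",
      currently_pregnant = "currently_pregnant"
    ),
    pregnancies = c(
      id = "id", outcome = "outcome", end_cm = "end_cm",
      is_current = "is_current"
    )
  )
}

#' @rdname default_schema
#' @export
nsfg_schema <- function() {
  list(
    respondents = c(
      id = "CASEID", round = "round", interview_cm = "CMINTVW",
      age_group = "age_group", race_ethnicity = "race_ethnicity",
      poverty = "poverty", marital = "marital", religiosity = "religiosity",
      acasi_birth = "JB_BIRTH", acasi_loss = "JB_LOSS",
      acasi_abortion = "JB_ABORT",
      acasi_period = "acasi_period",
      acasi_lifetime_total = "JB_TOTAL",
      currently_pregnant = "JB_PREGNOW"
    ),
    pregnancies = c(
      id = "CASEID", outcome = "OUTCOME", end_cm = "DATEND",
      is_current = "CURRPREG"
    )
  )
}

apply_schema <- function(df, map, what) {
  required <- switch(what,
    respondents = c("id", "round", "interview_cm", "age_group",
                    "race_ethnicity", "poverty", "marital", "religiosity",
                    "acasi_birth", "acasi_loss", "acasi_abortion"),
    pregnancies = c("id", "outcome", "end_cm", "is_current")
  )
  miss <- setdiff(map[required], names(df))
  if (length(miss) > 0) {
    rlang::abort(
      paste0("Input file lacks mandatory column(s): ",
             paste(miss, collapse = ", ")),
      class = "rr_error_schema"
    )
  }
  present <- map[map %in% names(df)]
  out <- df[, unname(present), drop = FALSE]
  names(out) <- names(present)
  out
}

#' Read a cohort from delimited text files
#'
#' Reads a respondent table and a companion pregnancy-event table (CSV or
#' TSV, sniffed from the extension), applies a column schema, and validates
#' the result with [cohort()]. A schema may be supplied as a list (see
#' [default_schema()]) or as a path to a YAML/JSON file with `respondents`
#' and `pregnancies` mappings.
#'
#' @param respondents_path Path to the respondent-level file.
#' @param pregnancies_path Path to the pregnancy-level file, or `NULL` for a
#'   cohort with no recorded pregnancies.
#' @param schema A schema list or a path to a YAML/JSON schema file.
#' @param quiet Passed to [cohort()].
#' @return An `rr_cohort`.
#' @export
read_cohort <- function(respondents_path, pregnancies_path = NULL,
                        schema = default_schema(), quiet = FALSE) {
  if (is.character(schema) && length(schema) == 1) {
    schema <- if (grepl("\\.json$", schema, ignore.case = TRUE)) {
      jsonlite::read_json(schema, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(schema)
    }
    schema <- lapply(schema, function(m) unlist(m))
  }
  read_one <- function(path) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    readr::read_delim(path, delim = delim, show_col_types = FALSE,
                      progress = FALSE)
  }
  resp <- apply_schema(read_one(respondents_path), schema$respondents,
                       "respondents")
  preg <- if (is.null(pregnancies_path)) NULL else {
    apply_schema(read_one(pregnancies_path), schema$pregnancies, "pregnancies")
  }
  cohort(resp, preg, quiet = quiet)
}

#' Write a cohort to delimited text files
#'
#' Writes `respondents.csv` and `pregnancies.csv` into `dir` using the native
#' column names, so that [read_cohort()] with the default schema round-trips.
#'
#' @param x An `rr_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "rr_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rp <- file.path(dir, "respondents.csv")
  pp <- file.path(dir, "pregnancies.csv")
  readr::write_csv(x$respondents, rp, progress = FALSE)
  readr::write_csv(x$pregnancies, pp, progress = FALSE)
  invisible(c(respondents = rp, pregnancies = pp))
}

#' Cohort composition summary
#'
#' Tabulates the cohort by each recoded demographic axis — the shape of a
#' sample-characteristics table (unweighted N and percent per category).
#'
#' @param x An `rr_cohort`.
#' @return A tibble with columns `axis`, `level`, `n`, `pct`.
#' @export
cohort_summary <- function(x) {
  stopifnot(inherits(x, "rr_cohort"))
  n_tot <- nrow(x$respondents)
  rows <- purrr::map_dfr(names(rr_demographic_levels), function(ax) {
    lv <- rr_demographic_levels[[ax]]
    counts <- table(factor(x$respondents[[ax]], levels = lv))
    tibble::tibble(
      axis = ax, level = lv,
      n = as.integer(counts),
      pct = round(100 * as.integer(counts) / n_tot, 1)
    )
  })
  dplyr::bind_rows(
    tibble::tibble(axis = "total", level = "total", n = n_tot, pct = 100),
    rows
  )
}
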