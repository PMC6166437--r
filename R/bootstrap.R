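#' Percentile interval of bootstrap replicates
#'
#' Empirical quantiles at `alpha/2` and `1 - alpha/2`, with linear
#' interpolation between the closest order statistics
#' ([stats::quantile()] type 7) so results are bit-reproducible across
#' implementations. `NA` replicates (undefined ratios) are excluded.
#'
#' @param replicates Numeric vector of replicate statistics.
#' @param alpha Total tail mass (default 0.05 for a 95 percent interval).
#' @return Named numeric vector `c(low, high)`.
#' @examples
#' percentile_interval(1:100) # 3.475, 97.525
#' @export
percentile_interval <- function(replicates, alpha = 0.05) {
  replicates <- replicates[!is.na(replicates)]
  if (length(replicates) == 0) {
    rlang::abort("No defined replicates to take percentiles of.",
                 class = "rr_error_no_replicates")
  }
  q <- stats::quantile(replicates, c(alpha / 2, 1 - alpha / 2),
                       type = 7, names = FALSE)
  c(low = q[1], high = q[2])
}

# paired per-woman indicators for a category/window on a cohort
mode_indicators <- function(x, category, window) {
  a <- acasi_count(x, category)$n >= 1L
  f <- ftf_window_count(x, category, window)$n >= 1L
  list(a = as.numeric(a), f = as.numeric(f))
}

# chunked with-replacement resampling of respondents; returns replicate
# ratios (NA when a replicate denominator is zero)
boot_ratio_reps <- function(num_w, den_w, B, chunk = 500L) {
  n <- length(num_w)
  reps <- numeric(B)
  done <- 0L
  while (done < B) {
    b <- min(chunk, B - done)
    idx <- sample.int(n, n * b, replace = TRUE)
    dim(idx) <- c(n, b)
    num <- .colSums(num_w[idx], n, b)
    den <- .colSums(den_w[idx], n, b)
    reps[(done + 1L):(done + b)] <- ifelse(den == 0, NA_real_, num / den)
    done <- done + b
  }
  reps
}

check_degenerate <- function(n_undefined, B) {
  if (n_undefined > 0.01 * B) {
    rlang::abort(
      paste0(n_undefined, " of ", B, " bootstrap replicates had an empty ",
             "denominator; the cohort is too sparse for this category."),
      class = "rr_error_degenerate_bootstrap"
    )
  }
}

#' Percentile-bootstrap confidence interval for a reporting ratio
#'
#' Resamples respondents with replacement — the respondent is the resampling
#' unit, preserving the within-subject pairing of her two mode responses —
#' and recomputes the reporting ratio on each of `B` replicates (default
#' 5000). The confidence interval is the percentile interval of the
#' replicate ratios. Replicates whose history-side denominator is empty are
#' excluded from the percentiles; more than 1 percent of them is an error
#' (the category is too sparse for a meaningful bootstrap).
#'
#' @inheritParams reporting_ratio
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed; the replicate stream is fully reproducible.
#' @param alpha Total tail mass of the interval.
#' @param chunk Internal vectorisation chunk (replicates per block); does not
#'   affect results.
#' @return An `rr_boot` object: point estimate (`rr_ratio` row), `replicates`,
#'   `ci_low`, `ci_high`, `n_undefined`, `B`, `alpha`, `seed`.
#' @examples
#' sim <- generate_cohort(generator_config(n = 400, seed = 3))
#' bootstrap_ratio(sim$cohort, "loss", B = 200, seed = 9)
#' @export
bootstrap_ratio <- function(x, category, window = NULL, B = 5000L,
                            seed = 1L, alpha = 0.05, chunk = 500L) {
  stopifnot(inherits(x, "rr_cohort"), B >= 1)
  category <- rlang::arg_match(category, rr_categories)
  point <- reporting_ratio(x, category, window = window)
  ind <- mode_indicators(x, category, point$ftf_window)
  reps <- withr::with_seed(seed, boot_ratio_reps(ind$a, ind$f, B, chunk))
  n_undef <- sum(is.na(reps))
  check_degenerate(n_undef, B)
  ci <- percentile_interval(reps, alpha)
  structure(
    list(
      point = point, replicates = reps,
      ci_low = unname(ci[1]), ci_high = unname(ci[2]),
      n_undefined = n_undef, B = as.integer(B),
      alpha = alpha, seed = as.integer(seed)
    ),
    class = "rr_boot"
  )
}

#' @export
print.rr_boot <- function(x, ...) {
  cat(sprintf(
    "<rr_boot> %s (%s window): ratio %.3f, %d%% CI [%.3f, %.3f] (B = %d%s)\n",
    x$point$category, x$point$ftf_window, x$point$ratio,
    round(100 * (1 - x$alpha)), x$ci_low, x$ci_high, x$B,
    if (x$n_undefined > 0) paste0(", ", x$n_undefined, " undefined") else ""
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rr_boot <- function(x, ...) {
  tibble::tibble(
    category = x$point$category,
    estimate = x$point$ratio,
    conf.low = x$ci_low,
    conf.high = x$ci_high
  )
}

#' @exportS3Method generics::glance
glance.rr_boot <- function(x, ...) {
  tibble::tibble(
    B = x$B, n_undefined = x$n_undefined, alpha = x$alpha,
    seed = x$seed, n_total = x$point$n_total
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.rr_boot <- function(object, ...) {
  df <- tibble::tibble(ratio = object$replicates[!is.na(object$replicates)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = NA) +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        linetype = 2) +
    ggplot2::geom_vline(xintercept = object$point$ratio) +
    ggplot2::labs(x = "replicate reporting ratio", y = "replicates")
}

new_difftest <- function(diffs, alpha, estimate, label_a, label_b,
                         n_undefined = sum(is.na(diffs))) {
  pct <- percentile_interval(diffs, alpha)
  structure(
    list(
      diff_replicates = diffs,
      pct_low = unname(pct[1]), pct_high = unname(pct[2]),
      significant = unname(pct[1] > 0 || pct[2] < 0),
      estimate = estimate,
      label_a = label_a, label_b = label_b,
      alpha = alpha, n_undefined = n_undefined
    ),
    class = "rr_difftest"
  )
}

#' Bootstrap difference test between two independent cohorts
#'
#' For ratios from disjoint cohorts (e.g. two survey rounds), forms the
#' replicate-wise differences of the two bootstrap distributions (replicate
#' b of A minus replicate b of B; under independence any pairing is valid
#' and the fixed pairing keeps results reproducible) and declares the
#' difference significant when the central percentile interval of the
#' differences excludes zero.
#'
#' @param boot_a,boot_b `rr_boot` objects with equal `B`.
#' @return An `rr_difftest`: `diff_replicates`, the percentile bounds
#'   `pct_low`/`pct_high`, and `significant`.
#' @export
difference_test_independent <- function(boot_a, boot_b) {
  stopifnot(inherits(boot_a, "rr_boot"), inherits(boot_b, "rr_boot"))
  if (boot_a$B != boot_b$B) {
    rlang::abort("Bootstrap results have different replicate counts.",
                 class = "rr_error_incompatible_bootstrap")
  }
  diffs <- boot_a$replicates - boot_b$replicates
  new_difftest(
    diffs, alpha = boot_a$alpha,
    estimate = boot_a$point$ratio - boot_b$point$ratio,
    label_a = boot_a$point$category, label_b = boot_b$point$category
  )
}

#' Joint bootstrap difference test between two strata of one cohort
#'
#' Contrasts the reporting ratios of two levels of a demographic axis within
#' a single cohort. Each replicate resamples the full cohort with
#' replacement and recomputes both stratum ratios on the replicate before
#' differencing, so the between-stratum dependence induced by shared
#' sampling is preserved. Replicates where either stratum has an empty
#' denominator (or is empty altogether) are excluded, capped at 1 percent.
#'
#' @inheritParams bootstrap_ratio
#' @param axis Demographic axis name.
#' @param level_a,level_b Levels to contrast (`level_a` minus `level_b`).
#' @return An `rr_difftest`.
#' @export
difference_test_joint <- function(x, category, axis, level_a, level_b,
                                  window = NULL, B = 5000L, seed = 1L,
                                  alpha = 0.05, chunk = 500L) {
  stopifnot(inherits(x, "rr_cohort"), B >= 1)
  category <- rlang::arg_match(category, rr_categories)
  axis <- rlang::arg_match(axis, names(rr_demographic_levels))
  level_a <- rlang::arg_match(level_a, rr_demographic_levels[[axis]])
  level_b <- rlang::arg_match(level_b, rr_demographic_levels[[axis]])
  if (is.null(window)) window <- rr_default_window(x$round)

  ind <- mode_indicators(x, category, window)
  ga <- as.numeric(x$respondents[[axis]] == level_a)
  gb <- as.numeric(x$respondents[[axis]] == level_b)
  na_w <- ind$a * ga; da_w <- ind$f * ga
  nb_w <- ind$a * gb; db_w <- ind$f * gb
  n <- length(ga)

  diffs <- withr::with_seed(seed, {
    out <- numeric(B)
    done <- 0L
    while (done < B) {
      b <- min(chunk, B - done)
      idx <- sample.int(n, n * b, replace = TRUE)
      dim(idx) <- c(n, b)
      ra <- .colSums(na_w[idx], n, b) / .colSums(da_w[idx], n, b)
      rb <- .colSums(nb_w[idx], n, b) / .colSums(db_w[idx], n, b)
      d <- ra - rb
      d[!is.finite(d)] <- NA_real_
      out[(done + 1L):(done + b)] <- d
      done <- done + b
    }
    out
  })
  n_undef <- sum(is.na(diffs))
  check_degenerate(n_undef, B)
  est <- tryCatch({
    pa <- reporting_ratio(cohort_subset(x, x$respondents$id[ga == 1]),
                          category, window = window)$ratio
    pb <- reporting_ratio(cohort_subset(x, x$respondents$id[gb == 1]),
                          category, window = window)$ratio
    pa - pb
  }, rr_error_undefined_ratio = function(e) NA_real_)
  new_difftest(diffs, alpha = alpha, estimate = est,
               label_a = paste0(axis, "=", level_a),
               label_b = paste0(axis, "=", level_b),
               n_undefined = n_undef)
}

#' @export
print.rr_difftest <- function(x, ...) {
  cat(sprintf(
    "<rr_difftest> %s - %s: estimate %.3f, %d%% percentile interval [%.3f, %.3f] -> %s\n",
    x$label_a, x$label_b, x$estimate, round(100 * (1 - x$alpha)),
    x$pct_low, x$pct_high,
    if (x$significant) "significant" else "not significant"
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rr_difftest <- function(x, ...) {
  tibble::tibble(
    contrast = paste(x$label_a, "-", x$label_b),
    estimate = x$estimate,
    conf.low = x$pct_low,
    conf.high = x$pct_high,
    significant = x$significant
  )
}

#' @exportS3Method generics::glance
glance.rr_difftest <- function(x, ...) {
  tibble::tibble(
    B = length(x$diff_replicates), n_undefined = x$n_undefined,
    alpha = x$alpha
  )
}

#' Do two confidence intervals fail to overlap?
#'
#' The conservative across-outcome comparison: two interval estimates are
#' declared different when their intervals do not overlap at all.
#'
#' @param interval_a,interval_b Numeric length-2 vectors `(low, high)`.
#' @return `TRUE` iff the intervals are disjoint.
#' @examples
#' ci_nonoverlap(c(1.36, 1.56), c(1.11, 1.15)) # TRUE
#' @export
ci_nonoverlap <- function(interval_a, interval_b) {
  stopifnot(length(interval_a) == 2, length(interval_b) == 2,
            interval_a[1] <= interval_a[2], interval_b[1] <= interval_b[2])
  unname(interval_a[2] < interval_b[1] || interval_b[2] < interval_a[1])
}
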