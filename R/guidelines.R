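#' Average daily screen time from weekday and weekend reports
#'
#' The survey asks for a typical weekday's and a typical weekend day's
#' total screen minutes; daily screen time is their plain average.
#' Missing propagates: if either report is missing the average is missing.
#'
#' @param weekday_min,weekend_min non-negative minutes (vectors allowed).
#' @return `(weekday_min + weekend_min) / 2`, `NA` where either is `NA`.
#' @export
screen_time_avg <- function(weekday_min, weekend_min) {
  if (any(weekday_min < 0, na.rm = TRUE) || any(weekend_min < 0, na.rm = TRUE))
    stop("screen-time minutes cannot be negative", call. = FALSE)
  (weekday_min + weekend_min) / 2
}

#' Classify children against the 24-h Movement Guidelines
#'
#' Applies the guideline thresholds for 5-13-year-olds: at least 60 min/day
#' of MVPA ("60+" read inclusively), less than 2 h/day of screen time
#' (strict), and 9-11 h of sleep (both bounds inclusive). The combined
#' status is the conjunction of the three and is missing whenever the
#' screen status is missing.
#'
#' @param cohort a [build_cohort()] result (columns `mvpa`, `sleep`,
#'   `screen_weekday_min`, `screen_weekend_min`), or any data frame with
#'   those columns.
#' @param mvpa_min MVPA threshold, minutes (default 60, inclusive).
#' @param screen_max screen-time threshold, minutes (default 120, strict).
#' @param sleep_range inclusive sleep bounds, minutes (default 540-660).
#' @return Data frame: `child_id`, `meets_mvpa`, `meets_screen`,
#'   `meets_sleep`, `meets_combined`.
#' @export
classify_guidelines <- function(cohort, mvpa_min = 60, screen_max = 120,
                                sleep_range = c(540, 660)) {
  d <- as.data.frame(cohort)
  need <- c("child_id", "mvpa", "sleep", "screen_weekday_min",
            "screen_weekend_min")
  if (!all(need %in% names(d)))
    stop("cohort lacks column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  screen <- screen_time_avg(d$screen_weekday_min, d$screen_weekend_min)
  out <- data.frame(
    child_id = d$child_id,
    meets_mvpa = d$mvpa >= mvpa_min,
    meets_screen = screen < screen_max,
    meets_sleep = d$sleep >= sleep_range[1] & d$sleep <= sleep_range[2]
  )
  out$meets_combined <- out$meets_mvpa & out$meets_screen & out$meets_sleep
  out$meets_combined[is.na(out$meets_screen)] <- NA
  out
}

#' Adherence counts and percentages by factor level
#'
#' Met / not-met counts per level with percentages over the explicitly
#' reported non-missing denominator. An empty level reports `NA`
#' percentages, never 0%.
#'
#' @param statuses a [classify_guidelines()] result.
#' @param factor_values factor level per child (same order as `statuses`),
#'   or `NULL` for the total row only.
#' @param outcome which guideline: `"mvpa"`, `"screen"`, `"sleep"` or
#'   `"combined"`.
#' @return Data frame: `level`, `n_met`, `n_not_met`, `denominator`,
#'   `pct_met`, `pct_not_met`.
#' @export
adherence_table <- function(statuses, factor_values = NULL,
                            outcome = c("mvpa", "screen", "sleep", "combined")) {
  outcome <- match.arg(outcome)
  met <- statuses[[paste0("meets_", outcome)]]
  lev_of <- function(keep, name) {
    m <- met[keep]
    n1 <- sum(m, na.rm = TRUE)
    n0 <- sum(!m, na.rm = TRUE)
    den <- n1 + n0
    data.frame(level = name, n_met = n1, n_not_met = n0, denominator = den,
               pct_met = if (den > 0) 100 * n1 / den else NA_real_,
               pct_not_met = if (den > 0) 100 * n0 / den else NA_real_)
  }
  rows <- list(lev_of(rep(TRUE, length(met)), "total"))
  if (!is.null(factor_values)) {
    stopifnot(length(factor_values) == length(met))
    for (lv in sort(unique(stats::na.omit(factor_values))))
      rows[[length(rows) + 1L]] <- lev_of(!is.na(factor_values) &
                                            factor_values == lv, lv)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cramér's V from a contingency table
#'
#' Effect size `sqrt(chi2 / (n * (min(r, c) - 1)))` computed from the
#' Pearson statistic without continuity correction. For a 2x2 table this
#' is the absolute phi coefficient.
#'
#' @param tab matrix of non-negative counts.
#' @return Cramér's V in \[0, 1\].
#' @export
cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
  sqrt(unname(chi2) / (sum(tab) * (min(dim(tab)) - 1)))
}

#' Association between guideline adherence and a sociodemographic factor
#'
#' Builds the level x (met / not met) contingency table (listwise deletion
#' of missing outcomes or levels) and tests independence with a Pearson
#' chi-square without continuity correction. When any expected cell count
#' is below 5 the p-value comes from Fisher's exact test instead; Cramér's
#' V is always derived from the Pearson statistic.
#'
#' @param statuses a [classify_guidelines()] result.
#' @param factor_values factor level per child (same order).
#' @param outcome which guideline (see [adherence_table()]).
#' @return List of class `association_result`: `outcome`, `table`,
#'   `test_used`, `statistic`, `p_value`, `cramers_v`, `min_expected`.
#' @export
association_test <- function(statuses, factor_values,
                             outcome = c("mvpa", "screen", "sleep", "combined")) {
  outcome <- match.arg(outcome)
  met <- statuses[[paste0("meets_", outcome)]]
  keep <- !is.na(met) & !is.na(factor_values)
  tab <- table(level = factor_values[keep],
               status = base::factor(ifelse(met[keep], "met", "not_met"),
                                     levels = c("met", "not_met")))
  if (nrow(tab) < 2 || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate contingency table for outcome '", outcome, "'",
         call. = FALSE)
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  min_exp <- min(chi$expected)
  if (min_exp < 5) {
    p <- tryCatch(stats::fisher.test(tab, workspace = 2e7)$p.value,
                  error = function(e)
                    stats::fisher.test(tab, simulate.p.value = TRUE,
                                       B = 1e5)$p.value)
    test_used <- "fisher-exact"
  } else {
    p <- chi$p.value
    test_used <- "pearson-chi-square"
  }
  structure(list(outcome = outcome, table = tab, test_used = test_used,
                 statistic = unname(chi$statistic), p_value = p,
                 cramers_v = cramers_v(tab), min_expected = min_exp),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat("Guideline association (", x$outcome, "), ", x$test_used, "\n", sep = "")
  print(x$table)
  cat(sprintf("chi2 = %.3f, p = %.4g, Cramer's V = %.3f\n",
              x$statistic, x$p_value, x$cramers_v))
  invisible(x)
}
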