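#' Keep valid wear days and children with at least one valid day
#'
#' A valid day is 24 h of concurrent wear; children contribute to the
#' analysis with one or more valid days. Counts of dropped days and
#' children are attached as attributes and reported via `message()`.
#'
#' @param records data frame with columns `child_id`, `valid` and part
#'   minutes (as written by [write_cohort()]).
#' @param quiet suppress the message.
#' @return Filtered records; attributes `n_days_dropped`,
#'   `n_children_dropped`.
#' @export
filter_valid <- function(records, quiet = FALSE) {
  stopifnot(all(c("child_id", "valid") %in% names(records)))
  valid <- as.logical(records$valid)
  kept <- records[valid, , drop = FALSE]
  if (nrow(kept) == 0) stop("no valid days remain: empty cohort", call. = FALSE)
  all_children <- unique(records$child_id)
  kept_children <- unique(kept$child_id)
  n_child_drop <- length(all_children) - length(kept_children)
  if (!quiet)
    message("dropped ", sum(!valid), " invalid day(s) and ",
            n_child_drop, " child(ren) with no valid days")
  attr(kept, "n_days_dropped") <- sum(!valid)
  attr(kept, "n_children_dropped") <- n_child_drop
  kept
}

#' Average daily minutes over each child's valid days
#'
#' Per-part arithmetic mean of minutes across a child's valid days, then
#' closure to `kappa`. Plain averaging over valid days — no
#' weekday/weekend reweighting.
#'
#' @param records valid day records (see [filter_valid()]).
#' @param parts character vector of part columns to average.
#' @param kappa closure constant.
#' @return Data frame: `child_id`, `n_valid_days`, `n_weekend_days`, one
#'   column per part (closed to `kappa`).
#' @export
average_days <- function(records, parts, kappa = 1440) {
  stopifnot(all(parts %in% names(records)))
  ids <- unique(records$child_id)
  idx <- factor(match(records$child_id, ids), levels = seq_along(ids))
  m <- sapply(parts, function(p) as.numeric(tapply(records[[p]], idx, mean)))
  m <- closure(matrix(m, ncol = length(parts),
                      dimnames = list(NULL, parts)), kappa)
  wk <- if ("is_weekend" %in% names(records))
    as.integer(tapply(as.logical(records$is_weekend), idx, sum))
  else rep(NA_integer_, length(ids))
  out <- data.frame(child_id = ids,
                    n_valid_days = as.integer(tabulate(idx, length(ids))),
                    n_weekend_days = wk)
  cbind(out, as.data.frame(m))
}

#' Express a closed composition as percent of the day
#'
#' @param x composition vector or matrix closed to `kappa`.
#' @param kappa closure constant.
#' @param digits optional rounding for presentation (e.g. 1); default no
#'   rounding — statistics are always computed at full precision.
#' @return `100 * x / kappa`, optionally rounded.
#' @export
percent_of_day <- function(x, kappa = 1440, digits = NULL) {
  p <- 100 * x / kappa
  if (!is.null(digits)) p <- round(p, digits)
  p
}

#' Assemble the analysis-ready per-child cohort table
#'
#' Filters valid days, averages each child's daily minutes, imputes
#' rounded zeros by [lr_em_impute()], and joins the sociodemographic
#' profile and screen-time columns. Activity-intensity and activity-type
#' compositions are processed as two independent tables (their child sets
#' may differ) and stored side by side.
#'
#' @param profiles per-child profile data frame.
#' @param intensity_days,type_days daily records for the two composition
#'   families.
#' @param intensity_parts,type_parts part column names (defaults match the
#'   generator).
#' @param kappa closure constant.
#' @param impute impute zeros/missing in the averaged compositions
#'   (default TRUE).
#' @param detection_limit passed to [lr_em_impute()].
#' @param quiet passed to [filter_valid()].
#' @return A data frame of class `cohort_table` with attributes
#'   `intensity_parts`, `type_parts`, `kappa`.
#' @export
build_cohort <- function(profiles, intensity_days, type_days,
                         intensity_parts = c("sedentary", "lpa", "mvpa", "sleep"),
                         type_parts = c("sitting", "standing", "walking",
                                        "running", "lying"),
                         kappa = 1440, impute = TRUE,
                         detection_limit = 1 / 12, quiet = TRUE) {
  avg_one <- function(days, parts) {
    av <- average_days(filter_valid(days, quiet = quiet), parts, kappa)
    if (impute) {
      m <- as.matrix(av[, parts, drop = FALSE])
      if (any(m == 0, na.rm = TRUE) || anyNA(m))
        av[, parts] <- lr_em_impute(m, detection_limit, kappa)
    }
    av
  }
  ai <- avg_one(intensity_days, intensity_parts)
  at <- avg_one(type_days, type_parts)
  base <- merge(ai, at[, c("child_id", type_parts)], by = "child_id",
                all = TRUE, sort = TRUE)
  out <- merge(profiles, base, by = "child_id", all.y = TRUE, sort = TRUE)
  structure(out, class = c("cohort_table", "data.frame"),
            intensity_parts = intensity_parts, type_parts = type_parts,
            kappa = kappa)
}

#' Extract one composition family from a cohort table
#'
#' @param cohort a [build_cohort()] result.
#' @param family `"intensity"` or `"type"`.
#' @param drop_na drop children without this family's composition.
#' @return Numeric matrix of compositions with `child_id` rownames.
#' @export
composition_matrix <- function(cohort, family = c("intensity", "type"),
                               drop_na = TRUE) {
  family <- match.arg(family)
  parts <- attr(cohort, paste0(family, "_parts"))
  if (is.null(parts)) stop("`cohort` lacks the ", family, " parts attribute",
                           call. = FALSE)
  m <- as.matrix(as.data.frame(cohort)[, parts, drop = FALSE])
  rownames(m) <- cohort$child_id
  if (drop_na) m <- m[stats::complete.cases(m), , drop = FALSE]
  m
}

#' Compositional descriptive table (minutes per level)
#'
#' Closed geometric-mean compositions for the whole cohort and, when a
#' factor is given, per factor level — the descriptive table of a
#' compositional time-use analysis. Values are minutes at full precision;
#' round only for presentation.
#'
#' @param cohort a [build_cohort()] result (already imputed).
#' @param factor optional name of a sociodemographic column.
#' @param family `"intensity"` or `"type"`.
#' @return Data frame: `level` ("total" plus factor levels), `n`, one
#'   column per part. Levels with fewer than 2 children are flagged in the
#'   `small_level` column (their mean is still computed).
#' @export
descriptive_table <- function(cohort, factor = NULL,
                              family = c("intensity", "type")) {
  family <- match.arg(family)
  kappa <- attr(cohort, "kappa")
  m <- composition_matrix(cohort, family)
  rows <- list(data.frame(level = "total", n = nrow(m), small_level = FALSE,
                          t(compositional_mean(m, kappa))))
  if (!is.null(factor)) {
    if (!factor %in% names(cohort))
      stop("factor '", factor, "' not found in cohort", call. = FALSE)
    g <- as.data.frame(cohort)[match(rownames(m), cohort$child_id), factor]
    for (lev in sort(unique(g))) {
      mi <- m[g == lev, , drop = FALSE]
      mu <- if (nrow(mi) >= 2) compositional_mean(mi, kappa) else
        closure(mi[1, ], kappa)
      rows[[length(rows) + 1L]] <-
        data.frame(level = lev, n = nrow(mi), small_level = nrow(mi) < 2,
                   t(mu))
    }
  }
  do.call(rbind, rows)
}
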