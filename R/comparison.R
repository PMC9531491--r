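## shared: ilr coordinates + grouping for one composition family
.ilr_and_group <- function(cohort, factor, family, basis) {
  m <- composition_matrix(cohort, family)
  if (any(m <= 0)) stop("compositions contain zeros; impute first", call. = FALSE)
  if (is.null(basis)) basis <- pivot_basis(ncol(m), colnames(m))
  g <- as.data.frame(cohort)[match(rownames(m), cohort$child_id), factor]
  keep <- !is.na(g)
  list(Y = ilr_transform(m[keep, , drop = FALSE], basis),
       g = droplevels(base::factor(g[keep])), basis = basis)
}

#' Compositional MANOVA for one sociodemographic factor
#'
#' Fits the one-factor multivariate linear model on ilr coordinates of a
#' composition family and reports Pillai's trace with its F approximation,
#' hypothesis/error degrees of freedom, p-value, and partial eta squared.
#' All reported statistics are invariant to the choice of orthonormal ilr
#' basis. Partial eta squared is defined as Pillai/s with
#' s = min(groups - 1, D - 1); for a two-level factor it equals Pillai's
#' trace.
#'
#' @param cohort a [build_cohort()] result (imputed).
#' @param factor name of a sociodemographic column.
#' @param family `"intensity"` or `"type"`.
#' @param basis optional [ilr_basis()]; default pivot basis.
#' @return A one-row data frame of class `manova_result`: `factor`,
#'   `family`, `pillai`, `f_stat`, `df_effect`, `df_error`, `p_value`,
#'   `eta_p2`.
#' @export
compositional_manova <- function(cohort, factor,
                                 family = c("intensity", "type"),
                                 basis = NULL) {
  family <- match.arg(family)
  d <- .ilr_and_group(cohort, factor, family, basis)
  p <- ncol(d$Y)
  tab <- table(d$g)
  if (length(tab) < 2) stop("factor '", factor, "' has fewer than 2 levels",
                            call. = FALSE)
  if (any(tab < p + 1))
    stop("level(s) ", paste(names(tab)[tab < p + 1], collapse = ", "),
         " have too few children for a ", p, "-coordinate model",
         call. = FALSE)
  fit <- stats::manova(d$Y ~ d$g)
  sm <- summary(fit, test = "Pillai")$stats
  pillai <- sm[1, "Pillai"]
  s <- min(length(tab) - 1, p)
  out <- data.frame(factor = factor, family = family,
                    pillai = unname(pillai),
                    f_stat = unname(sm[1, "approx F"]),
                    df_effect = unname(sm[1, "num Df"]),
                    df_error = unname(sm[1, "den Df"]),
                    p_value = unname(sm[1, "Pr(>F)"]),
                    eta_p2 = unname(pillai / s))
  class(out) <- c("manova_result", "data.frame")
  out
}

#' Pairwise Hotelling's T-squared post-hoc tests with Holm adjustment
#'
#' For a factor with more than two levels, tests every unordered pair of
#' levels on ilr coordinates with the classical two-sample Hotelling T²
#' (pooled covariance, F-transformed) and applies the Holm step-down
#' adjustment across the pairs of that factor. Pairs are ordered by raw
#' p-value with ties broken by pair name, so the adjustment is
#' deterministic.
#'
#' @inheritParams compositional_manova
#' @return Data frame, one row per level pair: `level_a`, `level_b`, `n_a`,
#'   `n_b`, `t2`, `f_stat`, `df1`, `df2`, `p_raw`, `p_adjusted`.
#' @export
pairwise_hotelling <- function(cohort, factor,
                               family = c("intensity", "type"),
                               basis = NULL) {
  family <- match.arg(family)
  d <- .ilr_and_group(cohort, factor, family, basis)
  p <- ncol(d$Y)
  levs <- levels(d$g)
  if (length(levs) < 2) stop("need at least 2 levels", call. = FALSE)
  rows <- list()
  for (i in seq_len(length(levs) - 1)) for (j in (i + 1):length(levs)) {
    Ya <- d$Y[d$g == levs[i], , drop = FALSE]
    Yb <- d$Y[d$g == levs[j], , drop = FALSE]
    n1 <- nrow(Ya); n2 <- nrow(Yb)
    if (n1 <= p || n2 <= p) {
      warning("pair ", levs[i], " vs ", levs[j],
              " skipped: too few observations for ", p, " coordinates",
              call. = FALSE)
      next
    }
    dm <- colMeans(Ya) - colMeans(Yb)
    Sp <- ((n1 - 1) * stats::cov(Ya) + (n2 - 1) * stats::cov(Yb)) / (n1 + n2 - 2)
    t2 <- (n1 * n2 / (n1 + n2)) * drop(t(dm) %*% solve(Sp, dm))
    f <- (n1 + n2 - p - 1) / ((n1 + n2 - 2) * p) * t2
    rows[[length(rows) + 1L]] <- data.frame(
      level_a = levs[i], level_b = levs[j], n_a = n1, n_b = n2,
      t2 = t2, f_stat = f, df1 = p, df2 = n1 + n2 - p - 1,
      p_raw = stats::pf(f, p, n1 + n2 - p - 1, lower.tail = FALSE))
  }
  out <- do.call(rbind, rows)
  ord <- order(out$p_raw, paste(out$level_a, out$level_b))
  out <- out[ord, , drop = FALSE]
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = "holm")
  rownames(out) <- NULL
  out
}

#' Back-transform a log-ratio difference to a percentage difference
#'
#' `(exp(d) - 1) * 100`: a log-ratio difference of ln 2 between two group
#' shares is a +100% relative difference.
#'
#' @param d finite log-ratio difference(s).
#' @return Percentage difference(s).
#' @export
back_transform_pct <- function(d) {
  if (any(!is.finite(d))) stop("`d` must be finite", call. = FALSE)
  (exp(d) - 1) * 100
}

#' Per-part between-group log-ratio contrasts with bootstrap CIs
#'
#' For each part, the point estimate is the log-ratio of the comparison
#' level's closed compositional-mean share to the reference level's:
#' positive values mean the comparison group devotes a larger share of the
#' day to that part. Confidence intervals are percentile bootstrap,
#' resampling children with replacement within each level. Percentages are
#' the exact back-transformation `(exp(d) - 1) * 100`.
#'
#' @inheritParams compositional_manova
#' @param reference_level,comparison_level factor levels to contrast
#'   (reference is the figure-caption baseline, e.g. boys).
#' @param n_boot bootstrap replicates (default 2000; < 100 warns).
#' @param ci_level confidence level (default 0.95).
#' @param seed integer seed for the bootstrap; required for
#'   reproducibility.
#' @return Data frame, one row per part: `part`, `reference`, `comparison`,
#'   `logratio_diff`, `ci_low`, `ci_high`, `pct_diff`, `pct_low`,
#'   `pct_high`.
#' @export
per_part_contrast <- function(cohort, factor, reference_level,
                              comparison_level,
                              family = c("intensity", "type"),
                              n_boot = 2000, ci_level = 0.95, seed = 1L) {
  family <- match.arg(family)
  if (n_boot < 100) warning("n_boot < 100 gives unstable intervals", call. = FALSE)
  m <- composition_matrix(cohort, family)
  if (any(m <= 0)) stop("compositions contain zeros; impute first", call. = FALSE)
  g <- as.data.frame(cohort)[match(rownames(m), cohort$child_id), factor]
  a <- m[!is.na(g) & g == reference_level, , drop = FALSE]
  b <- m[!is.na(g) & g == comparison_level, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("both contrast levels must be present in the cohort", call. = FALSE)

  ## scale-free statistic: difference of centred log geometric means
  lrd <- function(xa, xb) {
    ca <- log(compositional_mean(xa, 1))
    cb <- log(compositional_mean(xb, 1))
    cb - ca
  }
  est <- lrd(a, b)
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, ncol(m))
  la <- log(a); lb <- log(b)
  for (r in seq_len(n_boot)) {
    ia <- sample.int(nrow(a), replace = TRUE)
    ib <- sample.int(nrow(b), replace = TRUE)
    ga <- closure(exp(colMeans(la[ia, , drop = FALSE])), 1)
    gb <- closure(exp(colMeans(lb[ib, , drop = FALSE])), 1)
    boot[r, ] <- log(gb) - log(ga)
  }
  alpha <- (1 - ci_level) / 2
  ci <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha))
  data.frame(part = colnames(m),
             reference = reference_level, comparison = comparison_level,
             logratio_diff = unname(est),
             ci_low = unname(ci[1, ]), ci_high = unname(ci[2, ]),
             pct_diff = back_transform_pct(unname(est)),
             pct_low = back_transform_pct(unname(ci[1, ])),
             pct_high = back_transform_pct(unname(ci[2, ])),
             row.names = NULL)
}
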