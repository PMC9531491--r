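# build a status table + factor vector from met/not-met counts per level
statuses_from_counts <- function(counts, outcome = "mvpa") {
  lev <- rep(names(counts), vapply(counts, sum, 0))
  met <- unlist(lapply(counts, function(x) rep(c(TRUE, FALSE), x)))
  st <- data.frame(child_id = seq_along(met))
  st[[paste0("meets_", outcome)]] <- met
  list(statuses = st, factor_values = lev)
}

test_that("screen time averages weekday and weekend reports", {
  expect_equal(screen_time_avg(120, 180), 150)
  expect_equal(screen_time_avg(0, 0), 0)
  expect_true(is.na(screen_time_avg(100, NA)))
  expect_equal(screen_time_avg(c(100, NA), c(200, 50)), c(150, NA))
  expect_error(screen_time_avg(-5, 100), "negative")
})

test_that("guideline boundaries follow the stated conventions", {
  d <- data.frame(
    child_id = 1:6,
    mvpa = c(60, 59.99, 80, 80, 80, 80),        # "60+" is inclusive
    sleep = c(600, 600, 540, 660, 539.9, 660.1), # 9-11 h inclusive bounds
    screen_weekday_min = c(120, 60, 60, 119.9, 60, NA),
    screen_weekend_min = c(120, 60, 60, 120.1, 60, 100))
  st <- classify_guidelines(d)
  expect_equal(st$meets_mvpa, c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE))
  # screen < 120 strict: child 1 averages exactly 120 -> not met
  expect_equal(st$meets_screen[1:5], c(FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_true(is.na(st$meets_screen[6]))
  expect_equal(st$meets_sleep, c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  # combined = AND of the three, missing when screen is missing
  expect_equal(st$meets_combined[1:5], c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_true(is.na(st$meets_combined[6]))
})

test_that("classification is monotone in MVPA and screen time", {
  mvpa_grid <- seq(0, 180, by = 5)
  d <- data.frame(child_id = seq_along(mvpa_grid), mvpa = mvpa_grid,
                  sleep = 600, screen_weekday_min = rev(mvpa_grid) * 2,
                  screen_weekend_min = rev(mvpa_grid) * 2)
  st <- classify_guidelines(d)
  expect_true(!is.unsorted(st$meets_mvpa))        # FALSE block then TRUE
  expect_true(!is.unsorted(st$meets_screen))      # screen decreasing in grid
})

test_that("adherence percentages reproduce the published proportions", {
  g <- statuses_from_counts(list(boy = c(279, 20), girl = c(278, 43)))
  tab <- adherence_table(g$statuses, g$factor_values, "mvpa")
  expect_equal(round(tab$pct_met[tab$level == "boy"], 1), 93.3)
  expect_equal(round(tab$pct_met[tab$level == "girl"], 1), 86.6)
  expect_equal(tab$n_met + tab$n_not_met, tab$denominator)

  comb <- statuses_from_counts(list(all = c(50, 420)), "combined")
  ct <- adherence_table(comb$statuses, NULL, "combined")
  expect_equal(round(ct$pct_met[ct$level == "total"], 1), 10.6)

  # an empty level reports NA, never 0%
  st <- data.frame(child_id = 1:2, meets_mvpa = c(TRUE, NA))
  et <- adherence_table(st, c("u", "u"), "mvpa")
  expect_equal(et$denominator[et$level == "u"], 1)
  miss <- adherence_table(data.frame(child_id = 1, meets_mvpa = NA),
                          NULL, "mvpa")
  expect_true(is.na(miss$pct_met))
})

test_that("gender x MVPA association reproduces the published effect size", {
  g <- statuses_from_counts(list(boy = c(279, 20), girl = c(278, 43)))
  res <- association_test(g$statuses, g$factor_values, "mvpa")
  expect_equal(res$test_used, "pearson-chi-square")
  expect_equal(round(res$cramers_v, 2), 0.11)
  expect_equal(round(res$p_value, 3), 0.006)
})

test_that("independence gives chi-square 0 and V 0; V is |phi| for 2x2", {
  prop <- statuses_from_counts(list(a = c(40, 10), b = c(80, 20)))
  res <- association_test(prop$statuses, prop$factor_values, "mvpa")
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$cramers_v, 0, tolerance = 1e-9)

  tab <- matrix(c(30, 10, 12, 25), 2)
  phi <- (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1]) /
    sqrt(prod(rowSums(tab)) * prod(colSums(tab)))
  expect_equal(cramers_v(tab), abs(phi), tolerance = 1e-12)
  # invariant to swapping rows / columns
  expect_equal(cramers_v(tab[2:1, ]), cramers_v(tab))
  expect_equal(cramers_v(tab[, 2:1]), cramers_v(tab))
})

test_that("Fisher's exact test replaces chi-square at low expected counts", {
  # expected count for (b, met) = 9 * 14 / 30 = 4.2 < 5
  g <- statuses_from_counts(list(a = c(10, 11), b = c(4, 5)))
  tab <- table(g$factor_values,
               base::factor(ifelse(g$statuses$meets_mvpa, "met", "not_met")))
  expect_lt(min(outer(rowSums(tab), colSums(tab)) / sum(tab)), 5)
  res <- association_test(g$statuses, g$factor_values, "mvpa")
  expect_equal(res$test_used, "fisher-exact")
  expect_equal(res$p_value, fisher.test(res$table)$p.value, tolerance = 1e-9)
  expect_equal(res$cramers_v, cramers_v(res$table))  # V stays Pearson-based

  expect_error(association_test(
    data.frame(child_id = 1:3, meets_mvpa = c(TRUE, TRUE, TRUE)),
    c("a", "a", "b"), "mvpa"), "degenerate")
})
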