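# Independent Pillai oracle: between/within cross-product matrices and
# the classical F approximation, computed from first principles.
pillai_oracle <- function(Y, g) {
  g <- base::factor(g)
  N <- nrow(Y); p <- ncol(Y); k <- nlevels(g)
  gm <- colMeans(Y)
  H <- matrix(0, p, p); E <- matrix(0, p, p)
  for (lev in levels(g)) {
    Yi <- Y[g == lev, , drop = FALSE]
    d <- colMeans(Yi) - gm
    H <- H + nrow(Yi) * tcrossprod(d)
    R <- sweep(Yi, 2, colMeans(Yi))
    E <- E + crossprod(R)
  }
  pillai <- sum(diag(H %*% solve(H + E)))
  h <- k - 1
  s <- min(h, p)
  m <- (abs(h - p) - 1) / 2
  nn <- (N - k - p - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nn + s + 1)
  f <- (df2 / df1) * pillai / (s - pillai)
  list(pillai = pillai, f = f, df1 = df1, df2 = df2,
       p_value = pf(f, df1, df2, lower.tail = FALSE))
}

test_that("compositional MANOVA matches the H(H+E)^-1 eigen oracle", {
  set.seed(10)
  D <- 4
  base_tab <- random_comp_table(120, D, seed = 10)
  colnames(base_tab) <- c("sedentary", "lpa", "mvpa", "sleep")
  shift <- c(1.15, 0.9, 1.1, 0.95)
  tab <- rbind(base_tab[1:60, ], perturb(base_tab[61:120, ], shift))
  g <- rep(c("a", "b"), each = 60)
  co <- cohort_from_matrix(tab, g)
  res <- compositional_manova(co, "group")
  want <- pillai_oracle(ilr_transform(tab, pivot_basis(D)), g)
  expect_equal(res$pillai, want$pillai, tolerance = 1e-9)
  expect_equal(res$f_stat, want$f, tolerance = 1e-9)
  expect_equal(res$df_effect, want$df1)
  expect_equal(res$df_error, want$df2)
  expect_equal(res$p_value, want$p_value, tolerance = 1e-9)
})

test_that("MANOVA statistics are invariant to the ilr basis", {
  co <- make_cohort(n = 150, seed = 2)
  D <- length(attr(co, "intensity_parts"))
  r1 <- compositional_manova(co, "gender", basis = pivot_basis(D))
  r2 <- compositional_manova(co, "gender",
                             basis = random_orthonormal_basis(D, seed = 77))
  for (col in c("pillai", "f_stat", "p_value", "eta_p2"))
    expect_equal(r1[[col]], r2[[col]], tolerance = 1e-9)
})

test_that("two-level factors give eta_p2 equal to Pillai's trace", {
  co <- make_cohort(n = 120, seed = 6)
  r <- compositional_manova(co, "gender")
  expect_identical(r$eta_p2, r$pillai)
  expect_gte(r$pillai, 0)
  expect_lte(r$eta_p2, 1)
})

test_that("an exact null (duplicated groups) gives Pillai 0 and p 1", {
  tab <- random_comp_table(40, 4, seed = 3)
  colnames(tab) <- c("sedentary", "lpa", "mvpa", "sleep")
  co <- cohort_from_matrix(rbind(tab, tab), rep(c("x", "y"), each = 40))
  r <- compositional_manova(co, "group")
  expect_equal(r$pillai, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-9)
})

test_that("pairwise Hotelling matches the pooled-covariance formula", {
  set.seed(4)
  tab <- random_comp_table(45, 4, seed = 4)
  colnames(tab) <- c("sedentary", "lpa", "mvpa", "sleep")
  g <- rep(c("a", "b", "c"), each = 15)
  co <- cohort_from_matrix(tab, g)
  res <- pairwise_hotelling(co, "group")
  expect_equal(nrow(res), 3)

  Y <- ilr_transform(tab)
  Ya <- Y[g == "a", ]; Yb <- Y[g == "b", ]
  n1 <- 15; n2 <- 15; p <- 3
  dm <- colMeans(Ya) - colMeans(Yb)
  Sp <- ((n1 - 1) * cov(Ya) + (n2 - 1) * cov(Yb)) / (n1 + n2 - 2)
  t2 <- n1 * n2 / (n1 + n2) * drop(t(dm) %*% solve(Sp) %*% dm)
  f <- (n1 + n2 - p - 1) / ((n1 + n2 - 2) * p) * t2
  row <- res[res$level_a == "a" & res$level_b == "b", ]
  expect_equal(row$t2, t2, tolerance = 1e-9)
  expect_equal(row$f_stat, f, tolerance = 1e-9)
  expect_equal(row$p_raw, pf(f, p, n1 + n2 - p - 1, lower.tail = FALSE),
               tolerance = 1e-12)

  # Holm: never decreases, preserves ordering, smallest p multiplied by
  # the number of pairs (capped at 1)
  expect_true(all(res$p_adjusted >= res$p_raw))
  expect_true(!is.unsorted(res$p_adjusted))
  expect_equal(res$p_adjusted[1], min(1, 3 * res$p_raw[1]))
})

test_that("identical duplicated groups give T2 = 0 and adjusted p = 1", {
  tab <- random_comp_table(20, 4, seed = 9)
  colnames(tab) <- c("sedentary", "lpa", "mvpa", "sleep")
  co <- cohort_from_matrix(rbind(tab, tab, tab),
                           rep(c("a", "b", "c"), each = 20))
  res <- pairwise_hotelling(co, "group")
  expect_equal(res$t2, rep(0, 3), tolerance = 1e-12)
  expect_equal(res$p_adjusted, rep(1, 3))
})

test_that("back_transform_pct applies the exact exp formula", {
  expect_equal(back_transform_pct(0), 0)
  expect_equal(back_transform_pct(log(2)), 100)
  expect_equal(back_transform_pct(log(0.82)), -18)
  d <- 0.37
  p1 <- back_transform_pct(d); p2 <- back_transform_pct(-d)
  expect_equal((1 + p1 / 100) * (1 + p2 / 100), 1, tolerance = 1e-12)
  expect_error(back_transform_pct(Inf), "finite")
})

test_that("per-part contrasts: identity, invariance and CI behaviour", {
  tab <- random_comp_table(60, 4, seed = 13)
  colnames(tab) <- c("sedentary", "lpa", "mvpa", "sleep")
  co <- cohort_from_matrix(rbind(tab, tab), rep(c("r", "s"), each = 60))
  same <- per_part_contrast(co, "group", "r", "s", n_boot = 200, seed = 1)
  expect_equal(same$logratio_diff, rep(0, 4), tolerance = 1e-12)
  expect_equal(same$pct_diff, rep(0, 4), tolerance = 1e-12)

  # point estimates invariant to row-wise rescaling of the input
  set.seed(2)
  g2 <- rep(c("r", "s"), each = 30)
  t2 <- random_comp_table(60, 4, seed = 21)
  colnames(t2) <- colnames(tab)
  co_a <- cohort_from_matrix(t2, g2)
  co_b <- cohort_from_matrix(t2 * runif(60, 0.5, 2), g2)
  ca <- per_part_contrast(co_a, "group", "r", "s", n_boot = 100, seed = 3)
  cb <- per_part_contrast(co_b, "group", "r", "s", n_boot = 100, seed = 3)
  expect_equal(ca$logratio_diff, cb$logratio_diff, tolerance = 1e-10)

  # bootstrap CIs bracket the point estimate and narrow with n
  width <- function(n) {
    ch <- make_cohort(n = n, seed = 7)
    cc <- per_part_contrast(ch, "gender", "boy", "girl", n_boot = 300,
                            seed = 11)
    expect_true(all(cc$ci_low <= cc$logratio_diff + 1e-12) &&
                  all(cc$ci_high >= cc$logratio_diff - 1e-12))
    mean(cc$ci_high - cc$ci_low)
  }
  expect_lt(width(800), width(100))
})

test_that("contrast percentages match a planted single-part shift", {
  # one group's mvpa share multiplied by 1.25 (before re-closure)
  ref <- c(sedentary = 448, lpa = 321, mvpa = 98, sleep = 573)
  pert <- c(1, 1, 1.25, 1)
  set.seed(5)
  grp1 <- t(replicate(400, drop(closure(ref * exp(rnorm(4, sd = 0.1))))))
  grp2 <- t(replicate(400, drop(closure(ref * pert * exp(rnorm(4, sd = 0.1))))))
  colnames(grp1) <- colnames(grp2) <- names(ref)
  co <- cohort_from_matrix(rbind(grp1, grp2), rep(c("r", "s"), each = 400))
  cc <- per_part_contrast(co, "group", "r", "s", n_boot = 400, seed = 2)
  truth <- log(closure(ref * pert)) - log(closure(ref))
  expect_equal(cc$logratio_diff[cc$part == "mvpa"],
               unname(truth["mvpa"]), tolerance = 0.03)
  expect_equal(cc$pct_diff[cc$part == "mvpa"],
               back_transform_pct(unname(truth["mvpa"])), tolerance = 2)
})
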