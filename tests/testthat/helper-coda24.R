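# Shared fixtures and independent oracles.

# random strictly positive composition table, rows closed to kappa
random_comp_table <- function(n, D, kappa = 1440, seed = 1) {
  set.seed(seed)
  closure(matrix(exp(rnorm(n * D)), n, D,
                 dimnames = list(NULL, paste0("p", seq_len(D)))), kappa)
}

# random orthonormal ilr basis: pivot basis rotated by a random
# orthogonal matrix (columns stay orthonormal and zero-sum)
random_orthonormal_basis <- function(D, seed = 1) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm((D - 1)^2), D - 1)))
  ilr_basis(pivot_basis(D)$psi %*% Q)
}

# minimal cohort_table around a single composition matrix + one factor
cohort_from_matrix <- function(m, g = NULL, family = "intensity",
                               kappa = 1440) {
  d <- data.frame(child_id = sprintf("c%04d", seq_len(nrow(m))))
  if (!is.null(g)) d$group <- g
  d <- cbind(d, as.data.frame(m))
  structure(d, class = c("cohort_table", "data.frame"),
            intensity_parts = if (family == "intensity") colnames(m) else character(0),
            type_parts = if (family == "type") colnames(m) else character(0),
            kappa = kappa)
}

# full synthetic cohort -> analysis-ready cohort table
make_cohort <- function(n = 200, seed = 1, ...) {
  ch <- generate_cohort(cohort_spec(n_children = n, seed = seed, ...))
  split_records(ch)
}

split_records <- function(ch) {
  ip <- names(ch$spec$intensity_ref)
  tp <- names(ch$spec$type_ref)
  meta <- c("child_id", "day_index", "is_weekend", "valid")
  build_cohort(ch$profiles, ch$records[, c(meta, ip)],
               ch$records[, c(meta, tp)], intensity_parts = ip,
               type_parts = tp, kappa = ch$spec$kappa)
}

# Independent log-ratio EM oracle: alr-regression E-step (conditional
# normal expectation; truncated-above for censored cells) and
# mean/covariance M-step, written directly from the formulas. `ref` is
# the alr reference column; `dl` the per-part detection limits.
lrem_oracle <- function(x, ref, dl, max_iter = 500, tol = 1e-6) {
  n <- nrow(x); D <- ncol(x)
  cen <- is.finite(x) & x == 0
  mis <- !is.finite(x)
  xw <- x
  for (j in seq_len(D)) {
    if (any(cen[, j])) xw[cen[, j], j] <- 0.65 * dl[j]
    if (any(mis[, j])) {
      ob <- is.finite(x[, j]) & x[, j] > 0
      xw[mis[, j], j] <- exp(mean(log(x[ob, j])))
    }
  }
  keep <- setdiff(seq_len(D), ref)
  Y <- log(xw[, keep, drop = FALSE] / xw[, ref])
  impY <- (cen | mis)[, keep, drop = FALSE]
  cenY <- cen[, keep, drop = FALSE]
  lim <- log(outer(1 / x[, ref], dl[keep]))
  for (it in seq_len(max_iter)) {
    mu <- colMeans(Y); S <- cov(Y)
    Yn <- Y
    for (i in which(rowSums(impY) > 0)) {
      ci <- which(impY[i, ]); oi <- which(!impY[i, ])
      if (length(oi)) {
        B <- S[ci, oi, drop = FALSE] %*% solve(S[oi, oi, drop = FALSE])
        m <- mu[ci] + drop(B %*% (Y[i, oi] - mu[oi]))
        v <- pmax(diag(S)[ci] - rowSums(B * S[ci, oi, drop = FALSE]), 1e-12)
      } else {
        m <- mu[ci]; v <- diag(S)[ci]
      }
      for (k in seq_along(ci)) {
        j <- ci[k]
        if (cenY[i, j]) {
          s <- sqrt(v[k]); a <- (lim[i, j] - m[k]) / s
          Yn[i, j] <- m[k] - s * dnorm(a) / pnorm(a)
        } else Yn[i, j] <- m[k]
      }
    }
    if (max(abs(Yn[impY] - Y[impY])) < tol) { Y <- Yn; break }
    Y <- Yn
  }
  out <- x
  for (i in seq_len(n)) for (k in seq_along(keep)) {
    j <- keep[k]
    if (impY[i, k]) out[i, j] <- x[i, ref] * exp(Y[i, k])
  }
  out
}
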