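#' Close a vector (or the rows of a matrix) to a constant sum
#'
#' Rescales non-negative parts so that they sum to the closure constant
#' `kappa` (1440 minutes for a 24-h day). Zero entries are preserved as
#' zeros; they carry no relative information and are handled later by
#' [lr_em_impute()]. `NA` entries are preserved and excluded from the sum.
#'
#' @param x numeric vector, or matrix / data frame with one composition per
#'   row.
#' @param kappa closure constant (default 1440, minutes in a day).
#' @return An object of the same shape as `x` whose (row) sums equal
#'   `kappa`.
#' @examples
#' closure(c(100, 100, 100, 100))          # -> 360 360 360 360
#' closure(c(479, 155, 106, 7, 694))       # re-close a row summing to 1441
#' @export
closure <- function(x, kappa = 1440) {
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) || kappa <= 0)
    stop("`kappa` must be a single positive number", call. = FALSE)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    if (any(x < 0, na.rm = TRUE))
      stop("negative part values are not a composition", call. = FALSE)
    s <- rowSums(x, na.rm = TRUE)
    if (any(s <= 0))
      stop("row(s) ", paste(which(s <= 0), collapse = ", "),
           " have no positive parts", call. = FALSE)
    return(x * (kappa / s))
  }
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  if (any(x < 0, na.rm = TRUE))
    stop("negative part values are not a composition", call. = FALSE)
  s <- sum(x, na.rm = TRUE)
  if (s <= 0) stop("all-zero vector cannot be closed", call. = FALSE)
  x * (kappa / s)
}

#' Compositional (closed geometric) mean
#'
#' The centre of a compositional sample: the vector of per-part geometric
#' means across rows, re-closed to `kappa`. All entries must be strictly
#' positive; impute zeros first.
#'
#' @param x matrix or data frame, one strictly positive composition per row.
#' @param kappa closure constant of the result.
#' @return Named numeric vector summing to `kappa`.
#' @export
compositional_mean <- function(x, kappa = 1440) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  bad <- which(!is.finite(x) | x < .Machine$double.eps, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("zero/missing entries in rows ",
         paste(sort(unique(bad[, 1])), collapse = ", "),
         "; run lr_em_impute() first", call. = FALSE)
  closure(exp(colMeans(log(x))), kappa)
}

## minimum value allowed inside a log; below this we refuse rather than clamp
.log_floor <- 1e-12

.check_positive <- function(x, what = "composition") {
  if (any(!is.finite(x)) || any(x < .log_floor))
    stop(what, " must be strictly positive (no zeros/missing); ",
         "impute first", call. = FALSE)
  invisible(x)
}

#' Pivot (balance) ilr basis
#'
#' Builds the standard pivot sequential-binary-partition basis for `D`
#' parts: coordinate k contrasts part k against parts k+1..D. The returned
#' contrast matrix `psi` is D x (D-1) with orthonormal columns lying in the
#' clr plane (columns sum to zero).
#'
#' @param D number of parts (>= 2).
#' @param parts optional part names attached to the basis.
#' @return An object of class `ilr_basis` with elements `psi` and `parts`.
#' @export
pivot_basis <- function(D, parts = NULL) {
  if (length(D) != 1L || D < 2 || D != round(D))
    stop("`D` must be an integer >= 2", call. = FALSE)
  D <- as.integer(D)
  psi <- matrix(0, D, D - 1L)
  for (k in seq_len(D - 1L)) {
    r <- D - k                       # number of parts in the denominator
    psi[k, k] <- sqrt(r / (r + 1))
    psi[(k + 1):D, k] <- -1 / sqrt(r * (r + 1))
  }
  ilr_basis(psi, parts)
}

#' Construct an ilr basis from a contrast matrix
#'
#' @param psi D x (D-1) matrix with orthonormal, zero-sum columns.
#' @param parts optional character vector of part names (length D).
#' @return An object of class `ilr_basis`.
#' @export
ilr_basis <- function(psi, parts = NULL) {
  psi <- as.matrix(psi)
  D <- nrow(psi)
  if (ncol(psi) != D - 1L)
    stop("contrast matrix must be D x (D-1)", call. = FALSE)
  if (max(abs(crossprod(psi) - diag(D - 1L))) > 1e-8)
    stop("columns of `psi` are not orthonormal", call. = FALSE)
  if (max(abs(colSums(psi))) > 1e-8)
    stop("columns of `psi` must sum to zero (clr plane)", call. = FALSE)
  if (!is.null(parts) && length(parts) != D)
    stop("`parts` must have one name per row of `psi`", call. = FALSE)
  structure(list(psi = psi, parts = parts, D = D), class = "ilr_basis")
}

#' Centred log-ratio transform
#' @param x strictly positive vector or matrix (rows = compositions).
#' @return clr coordinates, same shape as `x`, rows summing to zero.
#' @export
clr_transform <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    .check_positive(x)
    lx <- log(x)
    return(lx - rowMeans(lx))
  }
  .check_positive(x)
  log(x) - mean(log(x))
}

#' Isometric log-ratio transform
#'
#' Maps strictly positive compositions to D-1 orthonormal real coordinates,
#' `psi' clr(x)`. Invariant to the closure constant.
#'
#' @param x strictly positive vector or matrix (rows = compositions).
#' @param basis an [ilr_basis()]; default pivot basis for the part count.
#' @return numeric vector (or matrix with rows) of length D-1.
#' @export
ilr_transform <- function(x, basis = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  D <- if (is.matrix(x)) ncol(x) else length(x)
  if (is.null(basis)) basis <- pivot_basis(D)
  if (basis$D != D) stop("basis dimension does not match composition", call. = FALSE)
  z <- clr_transform(x)
  if (is.matrix(z)) z %*% basis$psi else drop(crossprod(basis$psi, z))
}

#' Inverse isometric log-ratio transform
#'
#' @param z numeric vector of length D-1, or matrix with such rows.
#' @param basis an [ilr_basis()].
#' @param kappa closure constant of the reconstructed composition.
#' @return Composition (vector or matrix) closed to `kappa`.
#' @export
ilr_inverse <- function(z, basis, kappa = 1440) {
  if (is.matrix(z)) {
    if (ncol(z) != basis$D - 1L) stop("coordinate dimension mismatch", call. = FALSE)
    y <- exp(z %*% t(basis$psi))
    y <- closure(y, kappa)
    if (!is.null(basis$parts)) colnames(y) <- basis$parts
    return(y)
  }
  if (length(z) != basis$D - 1L) stop("coordinate dimension mismatch", call. = FALSE)
  y <- closure(exp(drop(basis$psi %*% z)), kappa)
  if (!is.null(basis$parts)) names(y) <- basis$parts
  y
}

#' Variation array of a compositional sample
#'
#' For every pair of parts (i, j) computes the mean (`xi`) and the sample
#' variance (`tau`, denominator n-1) of the pairwise log-ratio
#' ln(x_i / x_j) over rows. `tau` is the classical compositional dispersion
#' summary: small entries mean the two parts are nearly proportional across
#' children.
#'
#' @param x matrix or data frame of strictly positive compositions (>= 2 rows).
#' @return List of class `variation_array` with matrices `tau` (symmetric,
#'   zero diagonal) and `xi` (antisymmetric).
#' @export
variation_array <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows for a variation array", call. = FALSE)
  .check_positive(x)
  lx <- log(x)
  D <- ncol(x)
  nm <- colnames(x)
  tau <- matrix(0, D, D, dimnames = list(nm, nm))
  xi <- matrix(0, D, D, dimnames = list(nm, nm))
  for (i in seq_len(D)) for (j in seq_len(D)) {
    if (i == j) next
    lr <- lx[, i] - lx[, j]
    tau[i, j] <- stats::var(lr)
    xi[i, j] <- mean(lr)
  }
  structure(list(tau = tau, xi = xi, parts = nm), class = "variation_array")
}

#' @export
print.variation_array <- function(x, digits = 3, ...) {
  cat("Variation array (", length(x$parts), " parts)\n", sep = "")
  cat("tau  (variance of ln(x_i/x_j)):\n")
  print(round(x$tau, digits))
  cat("xi (mean of ln(x_i/x_j)):\n")
  print(round(x$xi, digits))
  invisible(x)
}

#' Perturbation (Aitchison addition) of compositions
#'
#' Component-wise product followed by closure; the simplex analogue of
#' translation.
#'
#' @param x,p strictly positive compositions of equal length (or a matrix
#'   `x` perturbed row-wise by `p`).
#' @param kappa closure constant of the result.
#' @return Perturbed composition(s).
#' @export
perturb <- function(x, p, kappa = 1440) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    return(closure(sweep(x, 2, p, `*`), kappa))
  }
  closure(x * p, kappa)
}
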