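#' Validate a mass-isotopomer distribution
#'
#' A MID is a vector of mass-shift fractions M+0..M+n for a metabolite with n
#' carbons: entries in [0,1] summing to 1 within 1e-6 (tiny negative values
#' down to -1e-12 are tolerated as numerical noise).
#' @param mid Numeric vector of length n+1.
#' @param n_carbons Expected carbon count (optional).
#' @return `mid`, invisibly; errors if invalid.
#' @export
check_mid <- function(mid, n_carbons = NULL) {
  if (!is.numeric(mid) || length(mid) < 1L) stop("MID must be numeric")
  if (!is.null(n_carbons) && length(mid) != n_carbons + 1L) {
    stop("MID has length ", length(mid), ", expected ", n_carbons + 1L)
  }
  if (any(mid < -1e-12)) stop("MID has negative entries")
  if (abs(sum(mid) - 1) > 1e-6) {
    stop("MID entries sum to ", format(sum(mid)), ", not 1")
  }
  invisible(mid)
}

#' Clip tiny negatives and renormalize a MID
#' @param mid Numeric vector.
#' @return Valid MID summing to exactly 1.
#' @export
normalize_mid <- function(mid) {
  mid <- pmax(mid, 0)
  s <- sum(mid)
  if (s <= 0) stop("cannot normalize an all-zero MID")
  mid / s
}

#' Convolve two MIDs
#'
#' The mass distribution of a fragment assembled from two independent parts is
#' the convolution of their MIDs.
#' @param a,b Numeric MID vectors.
#' @return MID of length `length(a) + length(b) - 1`.
#' @export
convolve_mids <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# MID of a size-s carbon subset of a metabolite with n carbons whose full MID
# is `mid`, under the exchangeable-positions convention used for externally
# fixed sources: conditional on k of n carbons labeled, the labeled positions
# are uniform, so the subset label count is hypergeometric.
subset_mid <- function(mid, n, s) {
  stopifnot(length(mid) == n + 1L, s >= 1L, s <= n)
  out <- numeric(s + 1L)
  for (k in 0:n) {
    if (mid[k + 1L] == 0) next
    j <- 0:s
    out <- out + mid[k + 1L] * stats::dhyper(j, k, n - k, s)
  }
  out
}

# Positional-isotopomer distribution (length 2^n, bit i of the index = carbon
# i labeled) of an exchangeable source with the given MID.
exchangeable_isotopomers <- function(mid, n) {
  stopifnot(length(mid) == n + 1L)
  idx <- 0:(2^n - 1L)
  nlab <- vapply(idx, function(i) sum(bitwAnd(i, bitwShiftL(1L, 0:(n - 1L))) > 0),
                 numeric(1))
  mid[nlab + 1L] / choose(n, nlab)
}

#' Correct a measured MID for natural isotope abundance
#'
#' Removes the mass-shift contribution of naturally occurring 13C in the
#' unlabeled carbons: the observed mass shift of a molecule with i
#' tracer-labeled carbons is i plus a Binomial(n - i, p13) natural shift.
#' The correction multiplies by the inverse of that convolution matrix,
#' clips negatives, and renormalizes.
#'
#' @param raw Measured MID (length n+1).
#' @param n_carbons Carbon count n (must be <= 20).
#' @param p13 Natural 13C abundance, in [0, 0.05]; default 0.0107.
#' @return Corrected MID.
#' @export
correct_natural_abundance <- function(raw, n_carbons, p13 = 0.0107) {
  if (p13 < 0 || p13 > 0.05) stop("p13 must be in [0, 0.05]")
  if (n_carbons > 20L) stop("natural-abundance correction matrix is ",
                            "ill-conditioned for n_carbons > 20")
  check_mid(raw, n_carbons)
  Cmat <- natural_abundance_matrix(n_carbons, p13)
  out <- solve(Cmat, raw)
  normalize_mid(out)
}

#' Forward natural-abundance convolution matrix
#'
#' `observed = M %*% true` for the binomial natural-abundance model of
#' [correct_natural_abundance()].
#' @param n_carbons Carbon count.
#' @param p13 Natural 13C abundance.
#' @return (n+1) x (n+1) lower-triangular matrix.
#' @export
natural_abundance_matrix <- function(n_carbons, p13 = 0.0107) {
  n <- n_carbons
  M <- matrix(0, n + 1L, n + 1L)
  for (i in 0:n) {
    j <- 0:(n - i)
    M[i + j + 1L, i + 1L] <- dbinom(j, n - i, p13)
  }
  M
}

#' Fractional carbon enrichment of a MID
#'
#' Mean mass shift divided by the carbon count: 0 for unlabeled, 1 for fully
#' labeled material.
#' @param mid MID vector (length n+1).
#' @return Scalar in [0,1].
#' @export
mid_enrichment <- function(mid) {
  n <- length(mid) - 1L
  sum((0:n) * mid) / n
}
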