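#' Build the mixing matrix mapping bin signals to population averages
#'
#' Row r holds the (division-weighted) population mass per position bin at
#' release time `t_r`: a population-averaged measurement at that release time
#' is the row-weighted combination of bin-specific signals.
#'
#' @param params A [population_params()].
#' @param release_times Release times (hours, >= 0).
#' @param B Number of position bins.
#' @return Row-stochastic matrix (length(release_times) x B).
#' @export
build_mixing_matrix <- function(params, release_times, B) {
  stopifnot(all(release_times >= 0))
  W <- t(vapply(release_times, function(t) {
    evolve_density(params, t, B)$mass
  }, numeric(B)))
  rownames(W) <- sprintf("t%g", release_times)
  W
}

circular_diff_matrix <- function(B) {
  if (B < 2L) return(matrix(0, 0, B))
  D <- matrix(0, B, B)
  for (i in seq_len(B)) {
    D[i, i] <- -1
    D[i, if (i == B) 1L else i + 1L] <- 1
  }
  D
}

# Non-negative least squares with a tiny-ridge fallback: exactly collinear
# columns (e.g. identical bin signals) can make the active-set iteration
# cycle, in which case an escalating ridge breaks the degeneracy at a level
# far below measurement precision.
.nnls <- function(A, b) {
  fit <- tryCatch(pracma::lsqnonneg(A, b), error = function(e) NULL)
  if (!is.null(fit)) return(fit$x)
  scale <- max(abs(A))
  for (ridge in c(1e-8, 1e-6, 1e-4)) {
    Aa <- rbind(A, sqrt(ridge) * scale * diag(ncol(A)))
    ba <- c(b, numeric(ncol(A)))
    fit <- tryCatch(pracma::lsqnonneg(Aa, ba), error = function(e) NULL)
    if (!is.null(fit)) return(fit$x)
  }
  stop("non-negative least squares failed to converge")
}

# Solve min ||A x - b||^2 + lambda ||Dc x||^2 s.t. x >= 0 by stacking the
# smoothing rows and calling non-negative least squares.
nnls_smooth <- function(A, b, Dc, lambda) {
  Aa <- rbind(A, sqrt(lambda) * Dc)
  ba <- c(b, numeric(nrow(Dc)))
  .nnls(Aa, ba)
}

# Stein's unbiased risk estimate for the smoothing weight: with the data
# rows scaled to unit noise sd, SURE(lambda) = resid^2(lambda) +
# 2 * edof(lambda) - n estimates the prediction risk up to a constant;
# its minimizer balances inversion variance against smoothing bias without
# the instability the discrepancy principle shows when the parameter count
# is a large fraction of the data count.
select_lambda_sure <- function(resid2_fn, edof_fn,
                               lambdas = 10^seq(-4, 6, by = 0.5)) {
  risk <- vapply(lambdas, function(l) resid2_fn(l) + 2 * edof_fn(l),
                 numeric(1))
  lambdas[which.min(risk)]
}

# Discrete L-curve corner: maximum curvature of log(residual) vs
# log(roughness) over a lambda grid.
select_lambda_lcurve <- function(solve_fn, lambdas = 10^seq(-4, 2, by = 0.5)) {
  pts <- t(vapply(lambdas, function(l) solve_fn(l), numeric(2)))
  rho <- log10(pmax(pts[, 1], 1e-300))
  eta <- log10(pmax(pts[, 2], 1e-300))
  n <- length(lambdas)
  if (n < 3L) return(lambdas[1])
  curv <- rep(-Inf, n)
  for (i in 2:(n - 1L)) {
    d1 <- c(rho[i + 1] - rho[i - 1], eta[i + 1] - eta[i - 1]) / 2
    d2 <- c(rho[i + 1] - 2 * rho[i] + rho[i - 1],
            eta[i + 1] - 2 * eta[i] + eta[i - 1])
    den <- (d1[1]^2 + d1[2]^2)^1.5
    if (den > 0) curv[i] <- (d1[1] * d2[2] - d2[1] * d1[2]) / den
  }
  lambdas[which.max(curv)]
}

#' Deconvolve per-bin pool sizes from population-averaged measurements
#'
#' Solves the non-negative regularized least-squares problem
#' `min sum_r ((meas_r - sum_b W_rb P_b) / sd_r)^2 + lambda * sum_b (P_b+1 - P_b)^2`
#' (circular second difference index) for the position-bin pool sizes `P_b`.
#'
#' @param meas Population pool sizes, one per release time (row of `W`).
#' @param sd Measurement standard deviations (> 0), recycled.
#' @param W Mixing matrix from [build_mixing_matrix()].
#' @param lambda Smoothing weight on the scale-normalized pools; `NULL`
#'   (default) selects it automatically by `method`.
#' @param method Automatic selection rule when `lambda` is `NULL`:
#'   `"sure"` (default; minimizes Stein's unbiased risk estimate, using the
#'   known measurement sds) or `"lcurve"` (maximum-curvature corner over
#'   `lambdas`).
#' @param lambdas Candidate grid for the L-curve.
#' @return List with `pools` (length B), `lambda`, `residual_norm`
#'   (weighted), and `flagged` (bins with no mixing-matrix support, filled by
#'   neighbor interpolation).
#' @export
deconvolve_pools <- function(meas, sd, W, lambda = NULL,
                             method = c("sure", "lcurve"),
                             lambdas = 10^seq(-4, 2, by = 0.5)) {
  method <- match.arg(method)
  stopifnot(length(meas) == nrow(W), all(sd > 0))
  sd <- rep_len(sd, length(meas))
  B <- ncol(W)
  dead <- which(colSums(W) < 1e-12)
  if (length(dead) && (!is.null(lambda) && lambda == 0)) {
    stop("bins ", paste(dead, collapse = ", "),
         " have no mixing-matrix support and lambda = 0: unidentifiable")
  }
  scale <- mean(abs(meas))
  if (scale <= 0) scale <- 1
  A <- W / sd * scale     # variables are pools / scale
  b <- meas / sd
  Dc <- circular_diff_matrix(B)
  if (is.null(lambda)) {
    if (method == "sure") {
      edof_fn <- function(l) {
        HtH <- crossprod(A) + l * crossprod(Dc)
        diag(HtH) <- diag(HtH) + 1e-10 * max(diag(HtH))
        sum(A * t(solve(HtH, t(A))))
      }
      lambda <- select_lambda_sure(function(l) {
        x <- nnls_smooth(A, b, Dc, l)
        sum((A %*% x - b)^2)
      }, edof_fn)
    } else {
      lambda <- select_lambda_lcurve(function(l) {
        x <- nnls_smooth(A, b, Dc, l)
        c(sqrt(sum((A %*% x - b)^2)), sqrt(sum((Dc %*% x)^2)))
      }, lambdas)
    }
  }
  x <- nnls_smooth(A, b, Dc, lambda)
  pools <- x * scale
  flagged <- integer(0)
  if (length(dead)) {
    flagged <- dead
    pools[dead] <- NA_real_
    pools <- .interp_circular(pools)
  }
  list(pools = pools, lambda = lambda,
       residual_norm = sqrt(sum((A %*% (pools / scale) - b)^2)),
       flagged = flagged)
}

.interp_circular <- function(x) {
  B <- length(x)
  bad <- which(is.na(x))
  if (!length(bad)) return(x)
  good <- which(!is.na(x))
  if (!length(good)) stop("no identifiable bins to interpolate from")
  for (i in bad) {
    d <- pmin(abs(good - i), B - abs(good - i))
    w <- 1 / pmax(d, 0.5)
    x[i] <- sum(x[good] * w) / sum(w)
  }
  x
}

#' Deconvolve per-bin MID time courses from population-averaged MIDs
#'
#' The population-averaged MID at release time r is the pool-abundance
#' weighted mixture `meas_r(tau) = sum_b W_rb P_b M_b(tau) / sum_b W_rb P_b`.
#' For each chase time this solves, jointly over mass channels, the weighted
#' non-negative least-squares problem with circular smoothing `lambda`
#' across bins and a per-bin unit-sum (simplex) constraint, then projects
#' each recovered bin MID exactly onto the simplex.
#'
#' @param mids Numeric array `releases x chase times x channels` of measured
#'   population MIDs for one metabolite (chase grids aligned across release
#'   times).
#' @param W Mixing matrix (`releases x B`).
#' @param pools Per-bin pool sizes (length B), typically from
#'   [deconvolve_pools()].
#' @param sd MID channel standard deviation(s) (> 0), recycled per channel.
#' @param lambda Smoothing weight; `NULL` selects it automatically (by
#'   `method`) on the most informative chase time and reuses it for all
#'   times.
#' @param method `"sure"` (default) or `"lcurve"`, as in
#'   [deconvolve_pools()].
#' @param lambdas Candidate grid for the L-curve.
#' @return List with `mids` (array `B x chase times x channels`), `lambda`,
#'   `flagged` (bins with negligible abundance weight, neighbor-filled).
#' @export
deconvolve_mids <- function(mids, W, pools, sd = 0.01, lambda = NULL,
                            method = c("sure", "lcurve"),
                            lambdas = 10^seq(-4, 2, by = 0.5)) {
  method <- match.arg(method)
  stopifnot(length(dim(mids)) == 3L, dim(mids)[1] == nrow(W),
            length(pools) == ncol(W), all(sd > 0))
  R <- dim(mids)[1]; Tt <- dim(mids)[2]; K <- dim(mids)[3]
  B <- ncol(W)
  sd <- rep_len(sd, K)

  wp <- W * rep(pools, each = R)
  rs <- rowSums(wp)
  if (any(rs <= 0)) stop("a mixing row has zero total abundance")
  A <- wp / rs                      # row-stochastic abundance weights
  colmass <- colSums(A)
  flagged <- which(colmass < 1e-10)

  Dc <- circular_diff_matrix(B)
  mu <- 1e3                          # weight of the per-bin unit-sum rows

  solve_tau <- function(ti, l) {
    # variables: M[b, k], column-major blocks by channel
    Arows <- .mid_system_matrix(A, sd, Dc, l, mu, B, K)
    brhs <- numeric(nrow(Arows))
    for (k in seq_len(K)) {
      brhs[(k - 1L) * R + seq_len(R)] <- mids[, ti, k] / sd[k]
    }
    brhs[R * K + nrow(Dc) * K + seq_len(B)] <- mu
    x <- .nnls(Arows, brhs)
    M <- matrix(x, B, K)
    resid <- sqrt(sum((Arows[seq_len(R * K), ] %*% x -
                         brhs[seq_len(R * K)])^2))
    rough <- if (B > 1L) sqrt(sum((M[c(2:B, 1), ] - M)^2)) else 0
    list(M = M, resid = resid, rough = rough)
  }

  if (is.null(lambda)) {
    # pick the chase time with the most inter-release contrast to set lambda
    contrast <- vapply(seq_len(Tt), function(ti) {
      sum(apply(mids[, ti, , drop = FALSE], 3, stats::var))
    }, numeric(1))
    ti0 <- which.max(contrast)
    if (method == "sure") {
      edof_fn <- function(l) {
        H <- .mid_system_matrix(A, sd, Dc, l, mu, B, K)
        Hd <- H[seq_len(R * K), , drop = FALSE]
        HtH <- crossprod(H)
        diag(HtH) <- diag(HtH) + 1e-10 * max(diag(HtH))
        sum(Hd * t(solve(HtH, t(Hd))))
      }
      lambda <- select_lambda_sure(function(l) {
        solve_tau(ti0, l)$resid^2
      }, edof_fn)
    } else {
      lambda <- select_lambda_lcurve(function(l) {
        s <- solve_tau(ti0, l)
        c(s$resid, s$rough)
      }, lambdas)
    }
  }

  out <- array(NA_real_, dim = c(B, Tt, K))
  for (ti in seq_len(Tt)) {
    M <- solve_tau(ti, lambda)$M
    if (length(flagged)) {
      M[flagged, ] <- NA_real_
      for (k in seq_len(K)) M[, k] <- .interp_circular(M[, k])
    }
    out[, ti, ] <- t(apply(M, 1, normalize_mid))
  }

  # linear error propagation through the regularized (unconstrained) solve:
  # the data rows are scaled to unit sd, so cov(x) = G_data G_data' with
  # G = (H'H)^-1 H'. Gives per-bin, per-channel sds of the recovered MIDs.
  H <- .mid_system_matrix(A, sd, Dc, lambda, mu, B, K)
  HtH <- crossprod(H)
  diag(HtH) <- diag(HtH) + 1e-10 * max(diag(HtH))
  G <- solve(HtH, t(H[seq_len(R * K), , drop = FALSE]))
  sds <- matrix(sqrt(rowSums(G^2)), B, K)

  list(mids = out, lambda = lambda, flagged = flagged, sds = sds)
}

# Stacked system matrix of the per-chase-time MID deconvolution (data rows,
# smoothing rows, per-bin unit-sum rows), variables M[b, k] channel-blocked.
.mid_system_matrix <- function(A, sd, Dc, lambda, mu, B, K) {
  R <- nrow(A)
  H <- matrix(0, R * K + nrow(Dc) * K + B, B * K)
  for (k in seq_len(K)) {
    rr <- (k - 1L) * R + seq_len(R)
    cc <- (k - 1L) * B + seq_len(B)
    H[rr, cc] <- A / sd[k]
    sr <- R * K + (k - 1L) * nrow(Dc) + seq_len(nrow(Dc))
    H[sr, cc] <- sqrt(lambda) * Dc
  }
  for (b in seq_len(B)) {
    H[R * K + nrow(Dc) * K + b, b + B * (seq_len(K) - 1L)] <- mu
  }
  H
}
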