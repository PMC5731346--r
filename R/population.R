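#' Define cell-cycle phases as intervals of cycle position
#'
#' Cycle position theta lives on the unit circle \[0,1); phases are ordered
#' half-open intervals partitioning it.
#'
#' @param breaks Increasing break points starting at 0 and ending at 1;
#'   default `c(0, 0.4, 0.75, 1)`.
#' @param labels Phase labels, default `c("G1", "S", "G2M")`.
#' @return A `phase_definition` (data frame with `phase`, `lo`, `hi`).
#' @export
phase_definition <- function(breaks = c(0, 0.4, 0.75, 1),
                             labels = c("G1", "S", "G2M")) {
  stopifnot(length(breaks) == length(labels) + 1L,
            breaks[1] == 0, breaks[length(breaks)] == 1,
            all(diff(breaks) > 0))
  structure(data.frame(phase = labels, lo = breaks[-length(breaks)],
                       hi = breaks[-1], stringsAsFactors = FALSE),
            class = c("phase_definition", "data.frame"))
}

#' Population desynchronization parameters
#'
#' Wrapped-Gaussian advection-diffusion model of a synchronized population:
#' at clock time t after release the unwrapped position is Gaussian with mean
#' `theta0 + t/T` and variance `s0^2 + 2*D*t`.
#'
#' @param T_cycle Cell-cycle length (hours, > 0).
#' @param theta0 Initial mean position in \[0,1).
#' @param s0 Initial spread (position units, >= 0).
#' @param D Dispersion rate (position^2 per hour, >= 0).
#' @param division_weighting If `TRUE` (default), lineage mass doubles at
#'   each wrap past division, so measured population signals weight divided
#'   lineages twice.
#' @return A `population_params` list.
#' @export
population_params <- function(T_cycle, theta0 = 0, s0 = 0, D = 0,
                              division_weighting = TRUE) {
  stopifnot(T_cycle > 0, s0 >= 0, D >= 0, theta0 >= 0, theta0 < 1)
  structure(list(T_cycle = T_cycle, theta0 = theta0, s0 = s0, D = D,
                 division_weighting = division_weighting),
            class = "population_params")
}

#' Evolve the population density over cycle position
#'
#' Bin-integrated wrapped-Gaussian density at clock time `t`: mean position
#' advects by `t/T`, variance grows as `s0^2 + 2*D*t`. With division
#' weighting, mass that has wrapped k times past division carries weight
#' 2^k before renormalization.
#'
#' @param params A [population_params()].
#' @param t Clock time since release (hours, >= 0).
#' @param B Number of uniform position bins (>= 10 for analysis; smaller
#'   values are allowed for degenerate tests).
#' @return A `population_density`: list with `theta` (bin centers), `mass`
#'   (non-negative, sums to 1), `B`, `t`.
#' @export
evolve_density <- function(params, t, B) {
  stopifnot(t >= 0, B >= 1)
  mu <- params$theta0 + t / params$T_cycle
  sd <- sqrt(params$s0^2 + 2 * params$D * t)
  edges <- seq(0, 1, length.out = B + 1L)
  if (sd < 1e-12) {
    theta <- mu %% 1
    mass <- numeric(B)
    mass[min(B, findInterval(theta, edges, rightmost.closed = TRUE))] <- 1
  } else {
    # wrap range wide enough for the division-weighted tail 2^k exp(-k^2/2sd^2)
    k_lo <- floor(mu - 8 * sd - 1)
    k_hi <- ceiling(mu + 8 * sd + sd^2 * log(2) + 1)
    mass <- numeric(B)
    for (k in k_lo:k_hi) {
      seg <- pnorm(edges + k, mean = mu, sd = sd)
      w <- if (params$division_weighting) 2^k else 1
      mass <- mass + w * diff(seg)
    }
    mass <- mass / sum(mass)
  }
  structure(list(theta = (edges[-1] + edges[-(B + 1L)]) / 2, mass = mass,
                 B = B, t = t), class = "population_density")
}

#' Phase fractions of a population density
#'
#' Sums bin mass over each phase interval; bins straddling a boundary are
#' split in proportion to overlap.
#'
#' @param density A `population_density`.
#' @param phases A [phase_definition()].
#' @return Named numeric vector of fractions (sums to 1).
#' @export
phase_fractions <- function(density, phases) {
  B <- density$B
  lo <- (seq_len(B) - 1) / B
  hi <- seq_len(B) / B
  out <- setNames(numeric(nrow(phases)), phases$phase)
  for (i in seq_len(nrow(phases))) {
    ov <- pmax(0, pmin(hi, phases$hi[i]) - pmax(lo, phases$lo[i]))
    out[i] <- sum(density$mass * ov * B)
  }
  out
}

#' Phase label of each position bin
#'
#' Assigns each of B uniform bins to the phase containing its center.
#' @param B Number of bins.
#' @param phases A [phase_definition()].
#' @return Character vector of length B.
#' @export
bin_phases <- function(B, phases) {
  centers <- (seq_len(B) - 0.5) / B
  idx <- vapply(centers, function(th) {
    which(th >= phases$lo & th < phases$hi)[1]
  }, integer(1))
  phases$phase[idx]
}

#' Fit desynchronization parameters to observed phase fractions
#'
#' Least-squares calibration of the wrapped-Gaussian model
#' (theta0, s0, D, and optionally T) to flow-cytometry-style phase-fraction
#' time courses, by bounded multistart optimization.
#'
#' @param observed Data frame with column `t_release_h` and one column per
#'   phase label (fractions; each row sums to 1 within 1e-3). At least 4
#'   observation times are required.
#' @param phases A [phase_definition()].
#' @param T_cycle If supplied, the cycle length is fixed at this value;
#'   otherwise it is fitted.
#' @param B Bin count used to evaluate the model (default 240).
#' @param n_starts Multistart count (default 20).
#' @param division_weighting Passed to the density model.
#' @param seed Seed for the multistart draws.
#' @return List with `params` ([population_params()]), `ssr`, and
#'   `n_converged`.
#' @export
fit_population_params <- function(observed, phases = phase_definition(),
                                  T_cycle = NULL, B = 240L, n_starts = 20L,
                                  division_weighting = TRUE, seed = 1L) {
  stopifnot(is.data.frame(observed), "t_release_h" %in% names(observed))
  if (nrow(observed) < 4L) {
    stop("need at least 4 observation times to fit population parameters")
  }
  fr <- as.matrix(observed[, phases$phase, drop = FALSE])
  if (any(abs(rowSums(fr) - 1) > 1e-3)) {
    stop("phase fractions must sum to 1 within 1e-3 in every row")
  }
  tr <- observed$t_release_h
  fit_T <- is.null(T_cycle)

  obj <- function(p) {
    Tc <- if (fit_T) p[4] else T_cycle
    pp <- population_params(Tc, theta0 = p[1] %% 1, s0 = p[2], D = p[3],
                            division_weighting = division_weighting)
    pred <- t(vapply(tr, function(t) {
      phase_fractions(evolve_density(pp, t, B), phases)
    }, numeric(nrow(phases))))
    sum((pred - fr)^2)
  }

  span <- max(tr) - min(tr)
  lower <- c(0, 1e-4, 0)
  upper <- c(1, 0.35, 0.05)
  pscale <- c(0.1, 0.05, 0.002)
  if (fit_T) {
    lower <- c(lower, max(span / 4, 1))
    upper <- c(upper, span * 4 + 10)
    pscale <- c(pscale, 5)
  }
  set.seed(seed)
  starts <- matrix(runif(n_starts * length(lower), lower, upper),
                   nrow = n_starts, byrow = TRUE)
  best <- NULL; n_conv <- 0L; diags <- character(0)
  for (i in seq_len(n_starts)) {
    o <- tryCatch(
      optim(starts[i, ], obj, method = "L-BFGS-B", lower = lower,
            upper = upper,
            control = list(maxit = 400, parscale = pscale,
                           factr = 1e3)),
      error = function(e) e)
    if (inherits(o, "error")) {
      diags <- c(diags, sprintf("start %d: %s", i, conditionMessage(o)))
      next
    }
    n_conv <- n_conv + 1L
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) {
    stop("population-parameter fit failed for every start:\n",
         paste(diags, collapse = "\n"))
  }
  # polish the best optimum with a derivative-free pass
  pol <- tryCatch(
    optim(best$par, function(p) {
      if (any(p < lower) || any(p > upper)) return(1e6)
      obj(p)
    }, method = "Nelder-Mead",
    control = list(maxit = 1000, parscale = pscale, reltol = 1e-12)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value < best$value) best <- pol
  p <- best$par
  Tc <- if (fit_T) p[4] else T_cycle
  list(params = population_params(Tc, theta0 = p[1] %% 1, s0 = p[2],
                                  D = p[3],
                                  division_weighting = division_weighting),
       ssr = best$value, n_converged = n_conv)
}
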