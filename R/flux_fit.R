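#' Free-flux parameterization of the stoichiometric null space
#'
#' Partitions reactions into free and dependent sets by QR with column
#' pivoting on the balanced stoichiometric matrix, so that any assignment of
#' the free net fluxes determines all dependent net fluxes and every
#' resulting flux map satisfies stoichiometric steady state by construction.
#'
#' @param net A `flux_network`.
#' @return A `flux_parameterization`: list with `free_ids`, `dep_ids`,
#'   `rev_ids` (reversible reactions, which get exchange parameters), and
#'   `to_fluxmap(v_free, exch)` returning a `flux_map` (dependent fluxes may
#'   be negative for infeasible free combinations; the fitter penalizes
#'   those).
#' @export
flux_parameterization <- function(net) {
  S <- stoichiometric_matrix(net)
  qrS <- qr(S, LAPACK = TRUE)
  r <- sum(abs(diag(qr.R(qrS))) > 1e-10 * max(abs(diag(qr.R(qrS))), 1e-300))
  piv <- qrS$pivot
  dep_ids <- colnames(S)[piv[seq_len(r)]]
  free_ids <- colnames(S)[piv[-seq_len(r)]]
  Sd <- S[, dep_ids, drop = FALSE]
  Sf <- S[, free_ids, drop = FALSE]
  Sd_qr <- qr(Sd)
  rev_ids <- names(Filter(function(x) x$reversible, net$reactions))
  to_fluxmap <- function(v_free, exch = numeric(0)) {
    stopifnot(length(v_free) == length(free_ids))
    v_dep <- qr.coef(Sd_qr, -Sf %*% v_free)[, 1]
    nets <- setNames(c(v_free, v_dep), c(free_ids, dep_ids))
    if (length(rev_ids)) {
      ex <- setNames(numeric(length(rev_ids)), rev_ids)
      if (length(exch)) ex[names(exch)] <- exch
      flux_map(nets, ex)
    } else {
      flux_map(nets)
    }
  }
  structure(list(free_ids = free_ids, dep_ids = dep_ids, rev_ids = rev_ids,
                 to_fluxmap = to_fluxmap, S = S),
            class = "flux_parameterization")
}

#' Default fitting configuration
#'
#' @param n_starts Multistart count (default 20).
#' @param seed Root seed for start draws.
#' @param rtol,atol Labeling-ODE tolerances during fitting.
#' @param flux_ub Upper bound for free net fluxes.
#' @param exch_ub Upper bound for exchange fluxes; default `100 * flux_ub`.
#' @param penalty Weight of the negativity penalty on dependent fluxes.
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @return Config list for [fit_fluxes()].
#' @export
fit_config <- function(n_starts = 20L, seed = 1L, rtol = 1e-7, atol = 1e-9,
                       flux_ub = 10, exch_ub = NULL, penalty = 1e4,
                       maxiter = 150L) {
  list(n_starts = n_starts, seed = seed, rtol = rtol, atol = atol,
       flux_ub = flux_ub, exch_ub = if (is.null(exch_ub)) 100 * flux_ub
                          else exch_ub,
       penalty = penalty, maxiter = maxiter)
}

#' Bundle one tracer's observed labeling time courses for fitting
#'
#' @param tracer A `tracer_spec`.
#' @param tau Chase times (ascending).
#' @param mids Named list of `length(tau) x (n+1)` observed MID matrices.
#' @param sd Measurement standard deviation: scalar or named list of
#'   matrices matching `mids`.
#' @param pools Optional named vector of pool sizes specific to this
#'   observation (e.g. one cell-cycle position bin's pools when several bins
#'   are fitted jointly); overrides the network/fit-level pools.
#' @return A `flux_observation`.
#' @export
flux_observation <- function(tracer, tau, mids, sd = 0.01, pools = NULL) {
  stopifnot(inherits(tracer, "tracer_spec"), is.list(mids),
            !is.null(names(mids)))
  structure(list(tracer = tracer, tau = tau, mids = mids, sd = sd,
                 pools = pools),
            class = "flux_observation")
}

# Stacked weighted residual vector for a candidate parameter vector.
# Chase time 0 rows carry no flux information (initial condition) and are
# excluded.
.fit_machinery <- function(net, observations, param, config) {
  nets <- lapply(observations, function(ob) {
    bad <- setdiff(names(ob$mids), names(net$metabolites))
    if (length(bad)) {
      stop("observed metabolites not in the network: ",
           paste(bad, collapse = ", "))
    }
    nb <- net
    if (!is.null(ob$pools)) {
      for (nm in names(ob$pools)) {
        if (is.null(nb$metabolites[[nm]])) stop("unknown metabolite: ", nm)
        nb$metabolites[[nm]]$pool_size <- ob$pools[[nm]]
      }
    }
    nb
  })
  emus <- lapply(observations, function(ob) {
    emu_decompose(net, names(ob$mids))
  })
  nf <- length(param$free_ids)
  nx <- length(param$rev_ids)

  resid_fn <- function(p) {
    v_free <- p[seq_len(nf)]
    exch <- if (nx) setNames(10^p[nf + seq_len(nx)], param$rev_ids)
            else numeric(0)
    fm <- param$to_fluxmap(v_free, exch)
    pen <- sqrt(config$penalty) * pmin(fm$net, 0)
    fm$net <- pmax(fm$net, 0)
    res <- numeric(0)
    for (oi in seq_along(observations)) {
      ob <- observations[[oi]]
      sim <- simulate_labeling(nets[[oi]], fm, ob$tracer, ob$tau,
                               engine = "rk45", rtol = config$rtol,
                               atol = config$atol, emu = emus[[oi]])
      keep <- ob$tau > 0
      for (m in names(ob$mids)) {
        sdm <- if (is.list(ob$sd)) ob$sd[[m]] else ob$sd
        res <- c(res, ((sim$mids[[m]] - ob$mids[[m]]) / sdm)[keep, ])
      }
    }
    c(res, pen)
  }
  list(resid_fn = resid_fn, nf = nf, nx = nx, n_pen = length(param$free_ids) +
         length(param$dep_ids))
}

#' Fit phase-specific fluxes by isotopically non-stationary MFA
#'
#' Minimizes the weighted sum of squared residuals
#' `SSR = sum(((sim - meas) / sd)^2)` over the free net fluxes (and
#' log10-scaled exchange fluxes of reversible reactions) by multistart
#' bounded Levenberg-Marquardt, simultaneously across all supplied tracers.
#' Every candidate satisfies stoichiometric steady state structurally via
#' [flux_parameterization()]; negative dependent fluxes are penalized.
#'
#' @param net A `flux_network` whose pool sizes are the (fixed) pools to use;
#'   override per-metabolite values with `pools`.
#' @param observations List of [flux_observation()] (one per tracer).
#' @param pools Optional named vector overriding metabolite pool sizes.
#' @param config See [fit_config()].
#' @param phase Optional phase label carried into the result.
#' @return A `flux_fit_result`: `fluxmap`, `par` (free vector), `free_ids`,
#'   `ssr`, `converged`, `start_diagnostics`, `param`
#'   (the parameterization), plus the inputs needed to profile
#'   (`observations`, `net`, `config`).
#' @export
fit_fluxes <- function(net, observations, pools = NULL, config = fit_config(),
                       phase = NA_character_) {
  if (inherits(observations, "flux_observation")) {
    observations <- list(observations)
  }
  if (!is.null(pools)) {
    for (nm in names(pools)) {
      if (is.null(net$metabolites[[nm]])) stop("unknown metabolite: ", nm)
      net$metabolites[[nm]]$pool_size <- pools[[nm]]
    }
  }
  param <- flux_parameterization(net)
  mach <- .fit_machinery(net, observations, param, config)
  nf <- mach$nf; nx <- mach$nx

  lower <- c(numeric(nf), rep(-6, nx))
  upper <- c(rep(config$flux_ub, nf), rep(log10(config$exch_ub), nx))
  set.seed(config$seed)
  starts <- matrix(runif(config$n_starts * (nf + nx),
                         rep(c(0.01 * config$flux_ub, -4), c(nf, nx)),
                         rep(c(0.8 * config$flux_ub,
                               log10(config$exch_ub) - 1), c(nf, nx))),
                   nrow = config$n_starts, byrow = TRUE)

  best <- NULL
  diags <- vector("list", config$n_starts)
  for (i in seq_len(config$n_starts)) {
    o <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                         fn = mach$resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = config$maxiter, ftol = 1e-12,
                           ptol = 1e-10)),
      error = function(e) e)
    if (inherits(o, "error")) {
      diags[[i]] <- list(ok = FALSE, message = conditionMessage(o))
      next
    }
    ssr <- o$deviance
    diags[[i]] <- list(ok = TRUE, ssr = ssr, info = o$info,
                       message = o$message)
    if (is.null(best) || ssr < best$deviance) best <- o
  }
  if (is.null(best)) {
    stop("no start converged; per-start diagnostics:\n",
         paste(vapply(diags, function(d) d$message, character(1)),
               collapse = "\n"))
  }
  p <- best$par
  exch <- if (nx) setNames(10^p[nf + seq_len(nx)], param$rev_ids)
          else numeric(0)
  fm <- param$to_fluxmap(p[seq_len(nf)], exch)
  fm$net <- pmax(fm$net, 0)
  structure(list(fluxmap = fm, par = p,
                 free_ids = param$free_ids, rev_ids = param$rev_ids,
                 ssr = best$deviance, converged = best$info %in% 1:4,
                 start_diagnostics = diags, param = param,
                 observations = observations, net = net, config = config,
                 phase = phase),
            class = "flux_fit_result")
}

#' @export
print.flux_fit_result <- function(x, ...) {
  cat("Flux fit", if (!is.na(x$phase)) paste0("(phase ", x$phase, ")"),
      "- SSR:", format(x$ssr, digits = 6),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("free fluxes:\n")
  print(setNames(x$par[seq_along(x$free_ids)], x$free_ids))
  invisible(x)
}

#' Profile-likelihood confidence interval for one fitted flux
#'
#' Walks the named net flux away from its optimum in both directions,
#' re-optimizing all other parameters at each value (the profiled flux is
#' held by a stiff linear constraint penalty, so any reaction's net flux can
#' be profiled, free or dependent), until the re-optimized SSR crosses
#' `SSR_min + qchisq(level, 1)` (3.841 at 0.95); the crossing is then
#' refined by bisection to a tolerance of `1e-3 * |fitted|`. A direction
#' whose profile never crosses the threshold before the bound is reported as
#' open; a failed re-optimization flags the interval unreliable rather than
#' silently widening it.
#'
#' @param fit A `flux_fit_result` (converged).
#' @param flux_id A reaction id from the fitted network.
#' @param level Confidence level (default 0.95).
#' @param max_steps Walk step cap per direction.
#' @return List with `lo`, `hi`, `open_lo`, `open_hi`, `reliable`, `level`.
#' @export
profile_likelihood_ci <- function(fit, flux_id, level = 0.95,
                                  max_steps = 40L) {
  if (!fit$converged) stop("fit did not converge; cannot profile")
  if (!flux_id %in% names(fit$fluxmap$net)) {
    stop(flux_id, " is not a reaction in the fitted network")
  }
  mach <- .fit_machinery(fit$net, fit$observations, fit$param, fit$config)
  npar <- length(fit$par)
  nf <- mach$nf
  thresh <- fit$ssr + qchisq(level, df = 1)
  vhat <- unname(fit$fluxmap$net[flux_id])
  tol <- 1e-3 * max(abs(vhat), 1e-3)
  reliable <- TRUE

  lower <- c(numeric(nf), rep(-6, mach$nx))
  upper <- c(rep(fit$config$flux_ub, nf),
             rep(log10(fit$config$exch_ub), mach$nx))

  # net flux of flux_id as a (linear) function of the free vector
  net_of <- function(p) {
    exch <- if (mach$nx) setNames(10^p[nf + seq_len(mach$nx)],
                                  fit$param$rev_ids) else numeric(0)
    unname(fit$param$to_fluxmap(p[seq_len(nf)], exch)$net[flux_id])
  }
  wcon <- 1e4 / max(abs(vhat), 0.1)   # constraint penalty weight

  prof_ssr <- function(value, start) {
    fn <- function(p) {
      c(mach$resid_fn(p), wcon * (net_of(p) - value))
    }
    o <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper, fn = fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = fit$config$maxiter, ftol = 1e-12)),
      error = function(e) e)
    if (inherits(o, "error")) {
      reliable <<- FALSE
      return(list(ssr = Inf, par = start))
    }
    # report the data SSR (constraint penalty excluded)
    ssr <- o$deviance - (wcon * (net_of(o$par) - value))^2
    list(ssr = ssr, par = o$par)
  }

  walk <- function(dir) {
    bound <- if (dir > 0) fit$config$flux_ub else 0
    step <- max(0.05 * max(abs(vhat), 0.1), tol)
    v_in <- vhat; s_in <- unname(fit$par)
    for (i in seq_len(max_steps)) {
      v_out <- v_in + dir * step
      hit_bound <- (dir > 0 && v_out >= bound) || (dir < 0 && v_out <= bound)
      if (hit_bound) v_out <- bound
      pr <- prof_ssr(v_out, s_in)
      if (pr$ssr > thresh) {
        # bisection between v_in (below) and v_out (above)
        lo <- v_in; hi <- v_out; s <- s_in
        while (abs(hi - lo) > tol) {
          mid <- (lo + hi) / 2
          pm <- prof_ssr(mid, s)
          if (pm$ssr > thresh) hi <- mid else { lo <- mid; s <- pm$par }
        }
        return(list(value = (lo + hi) / 2, open = FALSE))
      }
      if (hit_bound) {
        return(list(value = bound, open = dir > 0))
      }
      v_in <- v_out; s_in <- pr$par
      step <- step * 1.6
    }
    list(value = v_in, open = TRUE)
  }

  up <- walk(+1)
  dn <- walk(-1)
  list(lo = dn$value, hi = up$value, open_lo = dn$open, open_hi = up$open,
       reliable = reliable, level = level)
}
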