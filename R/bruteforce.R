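# Brute-force positional-isotopomer simulator.
#
# Integrates the full 2^n isotopomer ODE system for every balanced metabolite
# directly from the atom maps, with no EMU reduction. It is deliberately an
# independent code path from the EMU engine (different state space, different
# integrator) and serves as its validation oracle on small networks.

popcount_bits <- function(n) {
  idx <- 0:(2^n - 1L)
  vapply(idx, function(i) sum(bitwAnd(i, bitwShiftL(1L, 0:(n - 1L))) > 0L),
         integer(1))
}

#' Simulate labeling by full positional-isotopomer integration
#'
#' Direct integration of the complete 2^n positional-isotopomer ODE system
#' (one state per labeling pattern of every balanced metabolite), used as the
#' independent oracle for [simulate_labeling()]. The total state count is
#' capped at 1e5.
#'
#' @inheritParams simulate_labeling
#' @param rtol,atol [deSolve::lsoda()] tolerances.
#' @return A `labeling_set` (marginal mass distributions).
#' @export
simulate_labeling_bruteforce <- function(net, fluxmap, tracer, times,
                                         targets = NULL,
                                         rtol = 1e-10, atol = 1e-12) {
  balanced <- names(Filter(function(m) !m$is_source, net$metabolites))
  if (is.null(targets)) targets <- balanced
  stopifnot(all(targets %in% names(net$metabolites)))

  nc <- vapply(balanced, function(m) net$metabolites[[m]]$n_carbons,
               integer(1))
  sizes <- 2L^nc
  if (sum(sizes) > 1e5) {
    stop("positional-isotopomer state count ", sum(sizes),
         " exceeds the 1e5 cap")
  }
  offset <- setNames(c(0L, cumsum(sizes))[seq_along(balanced)], balanced)
  n_state <- sum(sizes)

  smids <- source_mid_table(net, tracer)
  sdist <- lapply(names(smids), function(nm) {
    exchangeable_isotopomers(smids[[nm]], net$metabolites[[nm]]$n_carbons)
  })
  names(sdist) <- names(smids)

  variants <- expand_reaction_variants(net)
  vflux <- variant_fluxes(variants, fluxmap)
  turn <- metabolite_turnover(net, variants, vflux)

  # Precompute per-variant transfer machinery.
  terms <- list()
  for (vi in seq_along(variants)) {
    v <- variants[[vi]]
    if (vflux[vi] == 0) next
    bal_prods <- Filter(function(p) p$name %in% balanced, v$products)
    if (length(bal_prods) == 0L) next
    ns <- vapply(v$substrates, function(e) length(e$map), integer(1))
    grids <- lapply(ns, function(k) 0:(2L^k - 1L))
    joint <- do.call(expand.grid, grids)
    njoint <- nrow(joint)
    sub_idx <- lapply(seq_along(v$substrates), function(si) joint[[si]] + 1L)
    # letter -> (substrate, position)
    letter_src <- list()
    for (si in seq_along(v$substrates)) {
      mp <- v$substrates[[si]]$map
      for (q in seq_along(mp)) letter_src[[mp[q]]] <- c(si, q)
    }
    prod_mats <- lapply(bal_prods, function(p) {
      np <- length(p$map)
      pidx <- integer(njoint)
      for (j in seq_along(p$map)) {
        src <- letter_src[[p$map[j]]]
        bit <- bitwAnd(joint[[src[1]]], bitwShiftL(1L, src[2] - 1L)) > 0L
        pidx <- pidx + bit * bitwShiftL(1L, j - 1L)
      }
      Matrix::sparseMatrix(i = pidx + 1L, j = seq_len(njoint), x = 1,
                           dims = c(2L^np, njoint))
    })
    terms[[length(terms) + 1L]] <- list(
      flux = vflux[vi],
      subs = v$substrates, sub_idx = sub_idx,
      prods = vapply(bal_prods, `[[`, character(1), "name"),
      prod_mats = prod_mats)
  }

  e0_influx <- function() {
    inf <- setNames(vector("list", length(balanced)), balanced)
    for (m in balanced) inf[[m]] <- numeric(sizes[m])
    inf
  }

  deriv <- function(t, y, parms) {
    inf <- e0_influx()
    for (tm in terms) {
      prob <- rep(tm$flux, length(tm$sub_idx[[1]]))
      for (si in seq_along(tm$subs)) {
        nm <- tm$subs[[si]]$name
        d <- if (nm %in% balanced) {
          y[offset[nm] + seq_len(sizes[nm])]
        } else {
          sdist[[nm]]
        }
        prob <- prob * d[tm$sub_idx[[si]]]
      }
      for (pi in seq_along(tm$prods)) {
        nm <- tm$prods[pi]
        inf[[nm]] <- inf[[nm]] + as.numeric(tm$prod_mats[[pi]] %*% prob)
      }
    }
    ydot <- numeric(n_state)
    for (m in balanced) {
      mm <- net$metabolites[[m]]
      idx <- offset[m] + seq_len(sizes[m])
      influx <- inf[[m]]
      tot_in <- sum(influx)
      dil <- mm$dilution_fraction
      contrib <- (1 - dil) * influx
      contrib[1] <- contrib[1] + dil * tot_in
      ydot[idx] <- (contrib - turn$efflux[m] * y[idx]) / mm$pool_size
    }
    list(ydot)
  }

  y0 <- numeric(n_state)
  y0[offset + 1L] <- 1
  tt <- if (times[1] > 0) c(0, times) else times
  o <- deSolve::lsoda(y0, tt, deriv, parms = NULL, rtol = rtol, atol = atol,
                      maxsteps = 50000)
  if (attr(o, "istate")[1] < 0) {
    stop("brute-force integration failed at t=", max(o[, 1]))
  }
  sol <- unname(o[match(times, tt), -1, drop = FALSE])

  mids <- list()
  for (m in targets) {
    if (m %in% balanced) {
      nl <- popcount_bits(nc[m])
      mm <- t(apply(sol[, offset[m] + seq_len(sizes[m]), drop = FALSE], 1,
                    function(row) {
                      normalize_mid(vapply(0:nc[m], function(k) {
                        sum(row[nl == k])
                      }, numeric(1)))
                    }))
    } else {
      sm <- smids[[m]]
      mm <- matrix(rep(sm, each = length(times)), nrow = length(times))
    }
    colnames(mm) <- paste0("M", seq_len(ncol(mm)) - 1L)
    mids[[m]] <- mm
  }
  structure(list(tau = times, mids = mids), class = "labeling_set")
}
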