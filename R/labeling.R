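#' Specify a tracer (externally fixed source labeling)
#'
#' @param source_mids Named list mapping source metabolite names to their
#'   fixed MIDs. Sources not named are unlabeled. Labeled positions are
#'   treated as exchangeable, which is exact for the uniformly labeled
#'   (\[U-13C\]) tracers modeled here.
#' @param name Optional label for reporting.
#' @return A `tracer_spec`.
#' @export
tracer_spec <- function(source_mids, name = NULL) {
  stopifnot(is.list(source_mids), !is.null(names(source_mids)))
  for (m in source_mids) check_mid(m)
  structure(list(source_mids = source_mids, name = name),
            class = "tracer_spec")
}

#' Fully labeled tracer for one source metabolite
#' @param source Source metabolite name.
#' @param n_carbons Its carbon count.
#' @param purity Fraction fully labeled (remainder unlabeled); default 1.
#' @param name Optional label.
#' @return A `tracer_spec`.
#' @export
uniform_tracer <- function(source, n_carbons, purity = 1, name = source) {
  mid <- numeric(n_carbons + 1L)
  mid[1] <- 1 - purity
  mid[n_carbons + 1L] <- purity
  tracer_spec(setNames(list(mid), source), name = name)
}

# Resolve the MID of every source metabolite under a tracer spec.
source_mid_table <- function(net, tracer) {
  out <- list()
  for (m in net$metabolites) {
    if (!m$is_source) next
    mid <- tracer$source_mids[[m$name]]
    if (is.null(mid)) {
      mid <- c(1, numeric(m$n_carbons))
    } else {
      check_mid(mid, m$n_carbons)
    }
    out[[m$name]] <- mid
  }
  out
}

# Assemble the flat arrays driving the EMU ODE/steady-state solvers for one
# (fluxmap, tracer) pair. Offsets are 0-based for the C++ side.
emu_assemble <- function(comp, fluxmap, tracer, initial = NULL) {
  net <- comp$net; sys <- comp$sys
  nodes <- sys$nodes
  vflux <- variant_fluxes(sys$variants, fluxmap)
  turn <- metabolite_turnover(net, sys$variants, vflux)

  state_nodes <- comp$state_nodes
  nsn <- length(state_nodes)
  state_pos <- match(seq_along(nodes), state_nodes)  # node -> state node rank

  node_start <- integer(nsn); node_len <- integer(nsn)
  node_efflux <- numeric(nsn); node_inv_pool <- numeric(nsn)
  node_dil <- numeric(nsn)
  for (k in seq_len(nsn)) {
    ni <- state_nodes[k]
    nd <- nodes[[ni]]
    m <- net$metabolites[[nd$metabolite]]
    node_start[k] <- comp$offset[ni]
    node_len[k] <- nd$size + 1L
    node_efflux[k] <- turn$efflux[nd$metabolite]
    node_inv_pool[k] <- 1 / m$pool_size
    node_dil[k] <- m$dilution_fraction
  }

  smids <- source_mid_table(net, tracer)
  const_data <- numeric(0)
  edge_target <- integer(0); edge_val_raw <- numeric(0)
  ops_ptr <- 0L; op_is_state <- integer(0)
  op_start <- integer(0); op_len <- integer(0)

  for (e in sys$edges) {
    tk <- state_pos[e$target]
    if (is.na(tk)) next  # edges never target source nodes, but be safe
    edge_target <- c(edge_target, tk - 1L)
    edge_val_raw <- c(edge_val_raw, vflux[e$variant])
    for (o in e$operands) {
      nd <- nodes[[o]]
      if (nd$is_source) {
        cv <- subset_mid(smids[[nd$metabolite]],
                         net$metabolites[[nd$metabolite]]$n_carbons, nd$size)
        op_is_state <- c(op_is_state, 0L)
        op_start <- c(op_start, length(const_data))
        const_data <- c(const_data, cv)
      } else {
        op_is_state <- c(op_is_state, 1L)
        op_start <- c(op_start, comp$offset[o])
      }
      op_len <- c(op_len, nd$size + 1L)
    }
    ops_ptr <- c(ops_ptr, length(op_is_state))
  }

  # dilution: influx into a node's metabolite partially replaced by unlabeled
  node_dil_influx <- numeric(nsn)
  edge_val <- numeric(0)
  if (length(edge_val_raw)) {
    edge_influx <- rowsum(edge_val_raw, edge_target)
    node_dil_influx[as.integer(rownames(edge_influx)) + 1L] <-
      node_dil[as.integer(rownames(edge_influx)) + 1L] * edge_influx[, 1]
    edge_val <- edge_val_raw * (1 - node_dil[edge_target + 1L])
  }

  y0 <- numeric(comp$n_state)
  for (k in seq_len(nsn)) {
    ni <- state_nodes[k]
    nd <- nodes[[ni]]
    if (!is.null(initial) && !is.null(initial[[nd$metabolite]])) {
      full <- initial[[nd$metabolite]]
      check_mid(full, net$metabolites[[nd$metabolite]]$n_carbons)
      y0[node_start[k] + seq_len(node_len[k])] <-
        subset_mid(full, net$metabolites[[nd$metabolite]]$n_carbons, nd$size)
    } else {
      y0[node_start[k] + 1L] <- 1
    }
  }

  list(n_state = comp$n_state, y0 = y0,
       node_start = node_start, node_len = node_len,
       node_efflux = node_efflux, node_dil_influx = node_dil_influx,
       node_inv_pool = node_inv_pool,
       edge_target = edge_target, edge_val = edge_val,
       ops_ptr = ops_ptr, op_is_state = op_is_state,
       op_start = op_start, op_len = op_len, const_data = const_data)
}

# R-side evaluation of the same right-hand side (used by the lsoda reference
# engine and the steady-state solver's residual checks).
emu_deriv_r <- function(y, a) {
  ydot <- numeric(a$n_state)
  for (e in seq_along(a$edge_target)) {
    buf <- a$edge_val[e]
    for (k in (a$ops_ptr[e] + 1L):a$ops_ptr[e + 1L]) {
      src <- if (a$op_is_state[k] == 1L) {
        y[a$op_start[k] + seq_len(a$op_len[k])]
      } else {
        a$const_data[a$op_start[k] + seq_len(a$op_len[k])]
      }
      buf <- convolve_mids(buf, src)
    }
    idx <- a$node_start[a$edge_target[e] + 1L] + seq_along(buf)
    ydot[idx] <- ydot[idx] + buf
  }
  for (i in seq_along(a$node_start)) {
    idx <- a$node_start[i] + seq_len(a$node_len[i])
    ydot[idx[1]] <- ydot[idx[1]] + a$node_dil_influx[i]
    ydot[idx] <- (ydot[idx] - a$node_efflux[i] * y[idx]) * a$node_inv_pool[i]
  }
  ydot
}

#' Simulate isotopically non-stationary labeling time courses
#'
#' Integrates the EMU labeling ODE system
#' `d(pool * X)/dt = sum_in v_in * X_in - (sum_out v_out) * X`
#' at fixed fluxes and pool sizes (metabolic steady state, isotopic
#' non-stationarity), with convolution inputs for condensation EMUs and the
#' per-metabolite `dilution_fraction` mixing unlabeled material into the
#' influx. The default engine is an adaptive Dormand-Prince RK45 in compiled
#' code; `engine = "lsoda"` integrates the identical system with
#' [deSolve::lsoda()] (stiff-capable reference path).
#'
#' @param net A `flux_network`.
#' @param fluxmap A `flux_map` satisfying [validate_steady_state()].
#' @param tracer A `tracer_spec`.
#' @param times Ascending chase times (hours, >= 0).
#' @param targets Metabolites whose full-carbon MIDs to return; default all
#'   balanced metabolites.
#' @param engine `"rk45"` (default) or `"lsoda"`.
#' @param rtol,atol Integration tolerances.
#' @param initial Optional named list of initial full MIDs per metabolite
#'   (default unlabeled).
#' @param emu Optional precomputed [emu_decompose()] system for `targets`
#'   (reused across calls during fitting).
#' @return A `labeling_set`: list with `tau` (times) and `mids`, a named list
#'   of `length(times) x (n+1)` MID matrices.
#' @export
simulate_labeling <- function(net, fluxmap, tracer, times,
                              targets = NULL, engine = c("rk45", "lsoda"),
                              rtol = 1e-8, atol = 1e-10, initial = NULL,
                              emu = NULL) {
  engine <- match.arg(engine)
  stopifnot(all(diff(times) > 0) || length(times) == 1L, all(times >= 0))
  if (!is.null(emu)) {
    emu_targets <- vapply(emu$targets, function(i) {
      emu$nodes[[i]]$metabolite
    }, character(1))
    if (is.null(targets)) targets <- emu_targets
    else stopifnot(identical(targets, emu_targets))
  }
  if (is.null(targets)) {
    targets <- names(Filter(function(m) !m$is_source, net$metabolites))
  }
  if (is.null(emu)) emu <- emu_decompose(net, targets)
  comp <- emu_compile(net, emu)
  a <- emu_assemble(comp, fluxmap, tracer, initial = initial)

  tt <- if (times[1] > 0) c(0, times) else times
  if (a$n_state == 0L) {
    sol <- matrix(numeric(0), length(tt), 0)
  } else if (engine == "rk45" && length(tt) > 1L) {
    sol <- emu_integrate_cpp(a$n_state, a$y0, tt,
                             a$node_start, a$node_len, a$node_efflux,
                             a$node_dil_influx, a$node_inv_pool,
                             a$edge_target, a$edge_val, a$ops_ptr,
                             a$op_is_state, a$op_start, a$op_len,
                             a$const_data, rtol, atol)
  } else if (length(tt) == 1L) {
    sol <- matrix(a$y0, 1L, a$n_state)
  } else {
    fn <- function(t, y, parms) list(emu_deriv_r(y, a))
    o <- deSolve::lsoda(a$y0, tt, fn, parms = NULL, rtol = rtol, atol = atol)
    if (attr(o, "istate")[1] < 0) {
      stop("labeling ODE integration failed (lsoda) at t=",
           max(o[, 1]))
    }
    sol <- unname(o[, -1, drop = FALSE])
  }
  keep <- match(times, tt)

  mids <- list()
  for (ti in seq_along(emu$targets)) {
    ni <- emu$targets[ti]
    nd <- emu$nodes[[ni]]
    if (nd$is_source) {
      sm <- source_mid_table(net, tracer)[[nd$metabolite]]
      mm <- matrix(rep(subset_mid(sm, length(sm) - 1L, nd$size),
                       each = length(times)),
                   nrow = length(times))
    } else {
      idx <- comp$offset[ni] + seq_len(nd$size + 1L)
      mm <- sol[keep, idx, drop = FALSE]
      mm <- t(apply(mm, 1, normalize_mid))
      if (nd$size == 0L) mm <- t(mm)
    }
    colnames(mm) <- paste0("M", 0:nd$size)
    mids[[targets[ti]]] <- mm
  }
  structure(list(tau = times, mids = mids), class = "labeling_set")
}

#' Isotopic steady state of the labeling system
#'
#' Solves the algebraic fixed point of the EMU labeling system (the t -> Inf
#' limit of [simulate_labeling()]) size class by size class; each class is a
#' linear system because convolution inputs involve strictly smaller EMUs.
#'
#' @inheritParams simulate_labeling
#' @return Named list of steady-state MIDs for `targets`.
#' @export
steady_state_mids <- function(net, fluxmap, tracer, targets = NULL,
                              emu = NULL) {
  if (!is.null(emu)) {
    emu_targets <- vapply(emu$targets, function(i) {
      emu$nodes[[i]]$metabolite
    }, character(1))
    if (is.null(targets)) targets <- emu_targets
    else stopifnot(identical(targets, emu_targets))
  }
  if (is.null(targets)) {
    targets <- names(Filter(function(m) !m$is_source, net$metabolites))
  }
  if (is.null(emu)) emu <- emu_decompose(net, targets)
  comp <- emu_compile(net, emu)
  a <- emu_assemble(comp, fluxmap, tracer)
  nodes <- emu$nodes
  state_nodes <- comp$state_nodes

  x <- numeric(a$n_state)
  sizes <- vapply(nodes, `[[`, numeric(1), "size")
  for (s in sort(unique(sizes[state_nodes]))) {
    cls <- state_nodes[sizes[state_nodes] == s]
    dim_cls <- length(cls) * (s + 1L)
    loc <- setNames(seq_along(cls), cls)  # node index -> class rank
    A <- matrix(0, dim_cls, dim_cls)
    rhs <- numeric(dim_cls)
    for (k in seq_along(cls)) {
      ni <- cls[k]
      sk <- match(ni, state_nodes)
      rows <- (k - 1L) * (s + 1L) + seq_len(s + 1L)
      if (a$node_efflux[sk] <= 0) {
        stop("zero-turnover pool for metabolite ",
             nodes[[ni]]$metabolite, ": no isotopic steady state")
      }
      A[cbind(rows, rows)] <- a$node_efflux[sk]
      rhs[rows[1]] <- rhs[rows[1]] + a$node_dil_influx[sk]
    }
    for (e in seq_along(a$edge_target)) {
      tgt_node <- state_nodes[a$edge_target[e] + 1L]
      if (!(tgt_node %in% cls)) next
      k <- loc[[as.character(tgt_node)]]
      rows <- (k - 1L) * (s + 1L) + seq_len(s + 1L)
      ops <- (a$ops_ptr[e] + 1L):a$ops_ptr[e + 1L]
      state_ops <- ops[a$op_is_state[ops] == 1L]
      same_class <- state_ops[a$op_len[state_ops] == s + 1L &
                                a$op_start[state_ops] %in%
                                  comp$offset[cls]]
      if (length(ops) == 1L && length(same_class) == 1L) {
        src_node <- cls[match(a$op_start[same_class], comp$offset[cls])]
        kk <- loc[[as.character(src_node)]]
        cols <- (kk - 1L) * (s + 1L) + seq_len(s + 1L)
        A[cbind(rows, cols)] <- A[cbind(rows, cols)] - a$edge_val[e]
      } else {
        buf <- a$edge_val[e]
        for (o in ops) {
          src <- if (a$op_is_state[o] == 1L) {
            x[a$op_start[o] + seq_len(a$op_len[o])]
          } else {
            a$const_data[a$op_start[o] + seq_len(a$op_len[o])]
          }
          buf <- convolve_mids(buf, src)
        }
        rhs[rows] <- rhs[rows] + buf
      }
    }
    sol <- solve(A, rhs)
    for (k in seq_along(cls)) {
      idx <- comp$offset[cls[k]] + seq_len(s + 1L)
      x[idx] <- sol[(k - 1L) * (s + 1L) + seq_len(s + 1L)]
    }
  }

  out <- list()
  smt <- source_mid_table(net, tracer)
  for (ti in seq_along(emu$targets)) {
    ni <- emu$targets[ti]
    nd <- nodes[[ni]]
    mid <- if (nd$is_source) {
      subset_mid(smt[[nd$metabolite]],
                 net$metabolites[[nd$metabolite]]$n_carbons, nd$size)
    } else {
      normalize_mid(x[comp$offset[ni] + seq_len(nd$size + 1L)])
    }
    names(mid) <- paste0("M", 0:nd$size)
    out[[targets[ti]]] <- mid
  }
  out
}
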