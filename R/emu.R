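emu_key <- function(name, idx) paste0(name, "{", paste(idx, collapse = ","), "}")

#' Decompose a network into the minimal EMU system for a set of targets
#'
#' An EMU (elementary metabolite unit) is a subset of a metabolite's carbons.
#' Backward-tracing atom maps from the target EMUs yields the minimal set of
#' EMUs (and the reaction edges connecting them) whose mass distributions
#' determine the target MIDs. Condensation reactions, whose product carbons
#' draw on more than one substrate entry, produce convolution edges joining
#' smaller EMUs. Symmetric-metabolite scrambling and reversible reactions are
#' handled through the expanded reaction variants, so an EMU may receive flux
#' from several variants of one reaction.
#'
#' @param net A `flux_network`.
#' @param targets List of targets, each `list(metabolite =, indices =)`;
#'   `indices` defaults to the full carbon set. A character vector of
#'   metabolite names is also accepted (full-carbon EMUs).
#' @return An `emu_system`: list with `nodes` (each: `metabolite`, `indices`,
#'   `size`, `is_source`, `key`), `edges` (each: `target` node index,
#'   `variant` index into `variants`, `operands` integer vector of node
#'   indices), `variants` (see `expand_reaction_variants`), and `targets`
#'   (node indices). Nodes are ordered by increasing size, topologically
#'   within each size class where the dependency graph is acyclic.
#' @export
emu_decompose <- function(net, targets) {
  if (is.character(targets)) {
    targets <- lapply(targets, function(m) list(metabolite = m))
  }
  targets <- lapply(targets, function(tg) {
    m <- net$metabolites[[tg$metabolite]]
    if (is.null(m)) stop("unknown target metabolite: ", tg$metabolite)
    if (is.null(tg$indices)) tg$indices <- seq_len(m$n_carbons)
    tg$indices <- sort(unique(as.integer(tg$indices)))
    if (any(tg$indices < 1L) || any(tg$indices > m$n_carbons)) {
      stop("target indices out of range for ", tg$metabolite)
    }
    tg
  })

  variants <- expand_reaction_variants(net)
  # producing variants indexed by metabolite
  producers <- list()
  for (vi in seq_along(variants)) {
    for (pi in seq_along(variants[[vi]]$products)) {
      nm <- variants[[vi]]$products[[pi]]$name
      producers[[nm]] <- c(producers[[nm]], list(c(vi, pi)))
    }
  }

  nodes <- list()
  node_id <- function(name, idx) {
    key <- emu_key(name, idx)
    for (i in seq_along(nodes)) if (nodes[[i]]$key == key) return(i)
    m <- net$metabolites[[name]]
    nodes[[length(nodes) + 1L]] <<- list(
      metabolite = name, indices = idx, size = length(idx),
      is_source = m$is_source, key = key)
    length(nodes)
  }

  edges <- list()
  queue <- integer(0)
  target_ids <- vapply(targets, function(tg) {
    node_id(tg$metabolite, tg$indices)
  }, integer(1))
  queue <- target_ids
  seen <- logical(0)

  while (length(queue)) {
    ni <- queue[1]; queue <- queue[-1]
    if (length(seen) >= ni && isTRUE(seen[ni])) next
    seen[ni] <- TRUE
    node <- nodes[[ni]]
    if (node$is_source) next
    prods <- producers[[node$metabolite]]
    if (is.null(prods)) {
      stop("EMU ", node$key, " has no producing reaction; ", node$metabolite,
           " is balanced but never produced")
    }
    for (pp in prods) {
      v <- variants[[pp[1]]]
      pentry <- v$products[[pp[2]]]
      letters_needed <- pentry$map[node$indices]
      ops <- integer(0)
      for (se in v$substrates) {
        hit <- which(se$map %in% letters_needed)
        if (length(hit)) {
          ops <- c(ops, node_id(se$name, sort(hit)))
        }
      }
      stopifnot(sum(vapply(ops, function(o) nodes[[o]]$size, numeric(1))) ==
                  node$size)
      edges[[length(edges) + 1L]] <- list(target = ni, variant = pp[1],
                                          operands = ops)
      for (o in ops) {
        if (length(seen) < o || !isTRUE(seen[o])) queue <- c(queue, o)
      }
    }
  }

  ord <- emu_order(nodes, edges)
  remap <- integer(length(nodes)); remap[ord] <- seq_along(nodes)
  nodes <- nodes[ord]
  edges <- lapply(edges, function(e) {
    e$target <- remap[e$target]
    e$operands <- remap[e$operands]
    e
  })
  structure(list(nodes = nodes, edges = edges, variants = variants,
                 targets = remap[target_ids]),
            class = "emu_system")
}

# Order nodes by size, then topologically within a size class where possible
# (cyclic dependencies within a class are permitted and left in place).
emu_order <- function(nodes, edges) {
  n <- length(nodes)
  sizes <- vapply(nodes, `[[`, numeric(1), "size")
  deps <- vector("list", n)  # same-size single-operand dependencies
  for (e in edges) {
    if (length(e$operands) == 1L &&
        sizes[e$operands] == sizes[e$target] &&
        e$operands != e$target) {
      deps[[e$target]] <- union(deps[[e$target]], e$operands)
    }
  }
  ord <- integer(0)
  for (s in sort(unique(sizes))) {
    cls <- which(sizes == s)
    placed <- logical(length(cls))
    repeat {
      prog <- FALSE
      for (i in seq_along(cls)) {
        if (placed[i]) next
        pend <- setdiff(deps[[cls[i]]], ord)
        if (length(intersect(pend, cls[!placed])) == 0L) {
          ord <- c(ord, cls[i]); placed[i] <- TRUE; prog <- TRUE
        }
      }
      if (all(placed)) break
      if (!prog) {  # cycle: append remaining as-is
        ord <- c(ord, cls[!placed])
        break
      }
    }
  }
  ord
}

#' @export
print.emu_system <- function(x, ...) {
  sizes <- vapply(x$nodes, `[[`, numeric(1), "size")
  cat("EMU system:", length(x$nodes), "nodes,", length(x$edges),
      "edges; size classes:",
      paste(sprintf("%d (n=%d)", sort(unique(sizes)),
                    tabulate(factor(sizes))[order(unique(sizes))]),
            collapse = ", "), "\n")
  invisible(x)
}

# Compile an EMU system into the flat arrays consumed by the integrators.
# State = concatenated MIDs of non-source nodes; source nodes become constant
# vectors once tracer MIDs are known (at simulate time).
emu_compile <- function(net, emu_sys) {
  nodes <- emu_sys$nodes
  n <- length(nodes)
  state_nodes <- which(!vapply(nodes, `[[`, logical(1), "is_source"))
  offset <- setNames(rep(NA_integer_, n), seq_len(n))
  pos <- 0L
  for (i in state_nodes) {
    offset[i] <- pos
    pos <- pos + nodes[[i]]$size + 1L
  }
  mets <- vapply(nodes, `[[`, character(1), "metabolite")
  list(net = net, sys = emu_sys, state_nodes = state_nodes,
       offset = offset, n_state = pos, node_met = mets)
}
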