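# Toy networks used across tests (built in code, no fixtures on disk).

two_pool_chain <- function(pool_b = 1) {
  parse_network(c(
    "met: S, 2, 1.0, source, 0.0",
    sprintf("met: B, 2, %g, balanced, 0.0", pool_b),
    "met: B.snk, 2, 1.0, source, 0.0",
    "R1: S (ab) -> B (ab)",
    "R2: B (ab) -> B.snk (ab)"))
}

linear_chain3 <- function() {
  parse_network(c(
    "met: S, 2, 1.0, source, 0.0",
    "met: A, 2, 0.5, balanced, 0.0",
    "met: B, 2, 1.0, balanced, 0.0",
    "met: C, 2, 2.0, balanced, 0.0",
    "met: C.snk, 2, 1.0, source, 0.0",
    "R1: S (ab) -> A (ab)",
    "R2: A (ab) -> B (ab)",
    "R3: B (ab) -> C (ab)",
    "R4: C (ab) -> C.snk (ab)"))
}

# branched toy with an extra disconnected branch whose flux cannot be
# observed from A/B MIDs (used for flat-profile CI tests)
branched_toy <- function(extra_branch = FALSE) {
  lines <- c(
    "met: S, 2, 1.0, source, 0.0",
    "met: A, 2, 0.6, balanced, 0.0",
    "met: B, 2, 1.5, balanced, 0.0",
    "met: A.snk, 2, 1.0, source, 0.0",
    "met: B.snk, 2, 1.0, source, 0.0",
    "R1: S (ab) -> A (ab)",
    "R2: A (ab) -> B (ab)",
    "R3: B (ab) -> B.snk (ab)",
    "R4: A (ab) -> A.snk (ab)")
  if (extra_branch) {
    lines <- c(lines,
               "met: S2, 1, 1.0, source, 0.0",
               "met: C, 1, 0.5, balanced, 0.0",
               "met: C.snk, 1, 1.0, source, 0.0",
               "R5: S2 (a) -> C (a)",
               "R6: C (a) -> C.snk (a)")
  }
  parse_network(lines)
}

branched_toy_fluxmap <- function(extra_branch = FALSE) {
  v <- c(R1 = 1.0, R2 = 0.7, R3 = 0.7, R4 = 0.3)
  if (extra_branch) v <- c(v, R5 = 0.4, R6 = 0.4)
  flux_map(v)
}

symmetric_fumarate_toy <- function() {
  # source feeds a 4-carbon pool consumed through a symmetric intermediate
  parse_network(c(
    "met: S, 4, 1.0, source, 0.0",
    "met: F, 4, 0.5, balanced, 0.0, symmetric",
    "met: M, 4, 0.8, balanced, 0.0",
    "met: M.snk, 4, 1.0, source, 0.0",
    "R1: S (abcd) -> F (abcd)",
    "R2: F (abcd) -> M (abcd)",
    "R3: M (abcd) -> M.snk (abcd)"))
}

default_tca_fluxmap <- function() {
  flux_map(c(PYRt = 1.5, PDH = 1.0, PC = 0.5, CS = 1.1, IDH = 0.85,
             RC = 0.15, AKGDH = 1.3, GLS = 0.8, GDH = 0.6, SDH = 1.3,
             FH = 1.3, MDH = 1.3, ACL = 0.1, CITout = 0.3, GLUout = 0.2,
             OAAout = 0.8))
}

tca_observed <- function() c("Pyr", "Cit", "AKG", "Suc", "Fum", "Mal",
                             "OAA", "Glu")

# Random small acyclic network with a fully labeled source, random
# permutation atom maps, random Dirichlet-split fluxes (balanced by
# construction), optionally a symmetric metabolite and a diluted pool.
random_toy_network <- function(seed) {
  set.seed(seed)
  nc <- sample(2:3, 1)
  k <- sample(3:4, 1)
  mets <- paste0("M", seq_len(k))
  lines <- c(sprintf("met: S, %d, 1.0, source, 0.0", nc))
  dil_on <- sample(c(0, 0.3), 1)
  sym_idx <- if (nc >= 2 && runif(1) < 0.5) sample(k, 1) else 0
  for (i in seq_len(k)) {
    lines <- c(lines, sprintf(
      "met: %s, %d, %.3f, balanced, %.1f%s", mets[i], nc,
      runif(1, 0.2, 2), if (i == 1) dil_on else 0,
      if (i == sym_idx) ", symmetric" else ""))
    lines <- c(lines, sprintf("met: %s.snk, %d, 1.0, source, 0.0",
                              mets[i], nc))
  }
  pmap <- function() paste(letters[sample(nc)], collapse = "")
  rxn <- character(0)
  fl <- numeric(0)
  rxn <- c(rxn, sprintf("Rin: S (%s) -> M1 (%s)",
                        paste(letters[1:nc], collapse = ""), pmap()))
  fl["Rin"] <- 1
  influx <- setNames(numeric(k), mets)
  influx["M1"] <- 1
  rid <- 0L
  for (i in seq_len(k)) {
    # always feed the next node (so every pool is produced), plus at most
    # one random skip edge
    targets <- if (i < k) i + 1L else integer(0)
    if (i + 2L <= k && runif(1) < 0.5) {
      extra <- seq(i + 2L, k)
      targets <- c(targets, extra[sample.int(length(extra), 1L)])
    }
    w <- as.numeric(stats::rgamma(length(targets) + 1L, 1)) # last = sink
    w <- w / sum(w)
    for (j in seq_along(targets)) {
      rid <- rid + 1L
      id <- paste0("R", rid)
      rxn <- c(rxn, sprintf("%s: %s (%s) -> %s (%s)", id, mets[i],
                            paste(letters[1:nc], collapse = ""),
                            mets[targets[j]], pmap()))
      fl[id] <- influx[mets[i]] * w[j]
      influx[mets[targets[j]]] <- influx[mets[targets[j]]] + fl[id]
    }
    rid <- rid + 1L
    id <- paste0("R", rid)
    rxn <- c(rxn, sprintf("%s: %s (%s) -> %s.snk (%s)", id, mets[i],
                          paste(letters[1:nc], collapse = ""), mets[i],
                          pmap()))
    fl[id] <- influx[mets[i]] * w[length(w)]
  }
  net <- parse_network(c(lines, rxn))
  fm <- flux_map(fl)
  stopifnot(nrow(validate_steady_state(fm, net)) == 0)
  list(net = net, fluxmap = fm, tracer = uniform_tracer("S", nc))
}

max_mid_dev <- function(a, b) {
  max(vapply(names(a$mids), function(m) {
    max(abs(a$mids[[m]] - b$mids[[m]]))
  }, numeric(1)))
}
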