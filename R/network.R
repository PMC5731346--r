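#' @useDynLib tempoflux, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dbinom optim pnorm qchisq rnorm runif rlnorm setNames
#' @importFrom utils read.csv write.csv head tail
NULL

#' Parse an atom-mapped metabolic network definition
#'
#' Reads the plain-text network format used throughout the package. Each
#' non-comment line is either a metabolite declaration
#'
#' ```
#' met: <name>, <n_carbons>, <pool_size>, source|balanced, <dilution_fraction>[, symmetric]
#' ```
#'
#' or a reaction with per-entry lowercase atom maps
#'
#' ```
#' <id>: S1 (ab) + S2 (c) -> P1 (acb) [rev]
#' ```
#'
#' Every carbon letter must appear exactly once on each side of a reaction.
#' Stoichiometric coefficients are expressed by repeating an entry with its
#' own map. Metabolites flagged `symmetric` (two-fold rotational symmetry,
#' e.g. succinate, fumarate) are scrambled on consumption: every reaction
#' consuming them is expanded internally into half-weighted variants with the
#' carbon order of that substrate reversed.
#'
#' @param text Character scalar (whole document) or character vector of lines.
#' @return A `flux_network` object: list with `metabolites` (named list of
#'   records with `name`, `n_carbons`, `pool_size`, `is_source`,
#'   `dilution_fraction`, `symmetric`) and `reactions` (named list of records
#'   with `id`, `substrates`, `products` (each a list of `list(name, map)`),
#'   `reversible`).
#' @seealso [read_network()], [serialize_network()], [validate_steady_state()]
#' @export
parse_network <- function(text) {
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  lines <- sub("#.*$", "", text)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  mets <- list()
  rxns <- list()
  for (ln in lines) {
    if (grepl("^met\\s*:", ln)) {
      m <- .parse_met_line(ln)
      if (!is.null(mets[[m$name]])) {
        stop("duplicate metabolite declaration: ", m$name)
      }
      mets[[m$name]] <- m
    } else {
      r <- .parse_reaction_line(ln)
      if (!is.null(rxns[[r$id]])) {
        stop("duplicate reaction id: ", r$id)
      }
      rxns[[r$id]] <- r
    }
  }

  net <- structure(list(metabolites = mets, reactions = rxns),
                   class = "flux_network")
  .validate_network(net)
  net
}

#' Read a network definition from a file
#' @param path Path to a network definition file.
#' @return A `flux_network` (see [parse_network()]).
#' @export
read_network <- function(path) {
  parse_network(readLines(path, warn = FALSE))
}

#' Path to the default TCA-cycle network shipped with the package
#'
#' A single-compartment TCA network with a glycolytic pyruvate source, PDH,
#' pyruvate carboxylase, citrate synthase, oxidative citrate -> alpha-KG ->
#' succinate flow, reductive carboxylation (alpha-KG + CO2 -> citrate),
#' glutamine -> glutamate -> alpha-KG anaplerosis, the succinate -> fumarate ->
#' malate -> OAA arm with symmetric succinate/fumarate, an ATP-citrate-lyase
#' style citrate cleavage, and efflux reactions to biosynthetic sinks.
#' @return File path (character).
#' @export
default_network_path <- function() {
  system.file("extdata", "tca_network.txt", package = "tempoflux",
              mustWork = TRUE)
}

.parse_met_line <- function(ln) {
  body <- sub("^met\\s*:\\s*", "", ln)
  parts <- trimws(strsplit(body, ",", fixed = TRUE)[[1]])
  if (length(parts) < 4L) {
    stop("malformed metabolite line: ", ln)
  }
  kind <- parts[4]
  if (!kind %in% c("source", "balanced")) {
    stop("metabolite kind must be 'source' or 'balanced': ", ln)
  }
  nc <- as.integer(parts[2])
  pool <- as.numeric(parts[3])
  dil <- if (length(parts) >= 5L && nzchar(parts[5]) && parts[5] != "symmetric") {
    as.numeric(parts[5])
  } else 0
  sym <- any(parts[-(1:4)] == "symmetric")
  if (is.na(nc) || nc < 1L) stop("n_carbons must be >= 1: ", ln)
  if (is.na(pool) || (kind == "balanced" && pool <= 0)) {
    stop("pool_size must be > 0 for balanced metabolites: ", ln)
  }
  if (is.na(dil) || dil < 0 || dil > 1) {
    stop("dilution_fraction must be in [0,1]: ", ln)
  }
  list(name = parts[1], n_carbons = nc, pool_size = pool,
       is_source = (kind == "source"), dilution_fraction = dil,
       symmetric = sym)
}

.parse_side <- function(side, rxn_id) {
  entries <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  out <- list()
  for (e in entries) {
    m <- regmatches(e, regexec("^(?:([0-9.]+)\\s+)?([A-Za-z0-9_.]+)\\s*\\(([a-z]+)\\)$", e))[[1]]
    if (length(m) == 0L) {
      stop("reaction ", rxn_id, ": cannot parse entry '", e, "'")
    }
    if (nzchar(m[2]) && as.numeric(m[2]) != 1) {
      stop("reaction ", rxn_id, ": stoichiometric coefficients != 1 are not ",
           "supported; repeat the entry with its own atom map instead")
    }
    out[[length(out) + 1L]] <- list(name = m[3],
                                    map = strsplit(m[4], "")[[1]])
  }
  out
}

.parse_reaction_line <- function(ln) {
  m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1]]
  if (length(m) == 0L) stop("malformed reaction line: ", ln)
  id <- m[2]
  body <- m[3]
  rev <- FALSE
  if (grepl("\\brev\\b\\s*$", body)) {
    rev <- TRUE
    body <- sub("\\brev\\b\\s*$", "", body)
  }
  sides <- strsplit(body, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L) stop("reaction ", id, ": expected one '->'")
  list(id = id,
       substrates = .parse_side(sides[1], id),
       products   = .parse_side(sides[2], id),
       reversible = rev)
}

.validate_network <- function(net) {
  for (r in net$reactions) {
    for (entry in c(r$substrates, r$products)) {
      if (is.null(net$metabolites[[entry$name]])) {
        stop("reaction ", r$id, ": unknown metabolite '", entry$name, "'")
      }
      nc <- net$metabolites[[entry$name]]$n_carbons
      if (length(entry$map) != nc) {
        stop("reaction ", r$id, ": atom map for ", entry$name, " has ",
             length(entry$map), " carbons, expected ", nc)
      }
    }
    sub_letters <- unlist(lapply(r$substrates, `[[`, "map"))
    prod_letters <- unlist(lapply(r$products, `[[`, "map"))
    if (anyDuplicated(sub_letters) || anyDuplicated(prod_letters)) {
      stop("reaction ", r$id, ": a carbon letter appears more than once on ",
           "one side")
    }
    if (length(sub_letters) != length(prod_letters) ||
        !setequal(sub_letters, prod_letters)) {
      stop("reaction ", r$id, ": unbalanced carbons (substrate letters ",
           paste(sort(sub_letters), collapse = ""), ", product letters ",
           paste(sort(prod_letters), collapse = ""), ")")
    }
  }
  invisible(net)
}

#' Serialize a network back to its text format
#'
#' Output is canonical (metabolites first, in declaration order; one reaction
#' per line) so that `parse_network(serialize_network(net))` round-trips.
#' @param net A `flux_network`.
#' @return Character vector of lines.
#' @export
serialize_network <- function(net) {
  met_lines <- vapply(net$metabolites, function(m) {
    sprintf("met: %s, %d, %.12g, %s, %.12g%s", m$name, m$n_carbons,
            m$pool_size, if (m$is_source) "source" else "balanced",
            m$dilution_fraction, if (m$symmetric) ", symmetric" else "")
  }, character(1))
  side_txt <- function(entries) {
    paste(vapply(entries, function(e) {
      sprintf("%s (%s)", e$name, paste(e$map, collapse = ""))
    }, character(1)), collapse = " + ")
  }
  rxn_lines <- vapply(net$reactions, function(r) {
    sprintf("%s: %s -> %s%s", r$id, side_txt(r$substrates),
            side_txt(r$products), if (r$reversible) " rev" else "")
  }, character(1))
  c("# metabolites", unname(met_lines), "# reactions", unname(rxn_lines))
}

#' Construct a flux map
#'
#' @param net_flux Named numeric vector of net fluxes, one per reaction id,
#'   non-negative in the written direction.
#' @param exchange_flux Named non-negative numeric vector of exchange fluxes
#'   for reversible reactions. Reversible reactions not named here get
#'   exchange 0.
#' @return A `flux_map` object (list with `net`, `exch`).
#' @export
flux_map <- function(net_flux, exchange_flux = numeric(0)) {
  stopifnot(!is.null(names(net_flux)))
  if (length(exchange_flux) && is.null(names(exchange_flux))) {
    stop("exchange_flux must be named")
  }
  structure(list(net = net_flux, exch = exchange_flux), class = "flux_map")
}

#' Balanced-metabolite stoichiometric matrix
#'
#' Rows are balanced (non-source) metabolites, columns are reactions; entries
#' count net production of the metabolite per unit net flux.
#' @param net A `flux_network`.
#' @return Numeric matrix with dimnames.
#' @export
stoichiometric_matrix <- function(net) {
  balanced <- names(Filter(function(m) !m$is_source, net$metabolites))
  rids <- names(net$reactions)
  S <- matrix(0, length(balanced), length(rids),
              dimnames = list(balanced, rids))
  for (r in net$reactions) {
    for (e in r$substrates) {
      if (e$name %in% balanced) S[e$name, r$id] <- S[e$name, r$id] - 1
    }
    for (e in r$products) {
      if (e$name %in% balanced) S[e$name, r$id] <- S[e$name, r$id] + 1
    }
  }
  S
}

#' Check stoichiometric steady state of a flux map
#'
#' @param fluxmap A `flux_map`.
#' @param net A `flux_network`.
#' @return A data frame of violations (`metabolite`, `imbalance`), zero rows
#'   if every balanced metabolite's influx equals its efflux within
#'   `1e-9 * max(|flux|)`.
#' @export
validate_steady_state <- function(fluxmap, net) {
  unknown <- setdiff(names(fluxmap$net), names(net$reactions))
  if (length(unknown)) {
    stop("flux map references unknown reactions: ",
         paste(unknown, collapse = ", "))
  }
  S <- stoichiometric_matrix(net)
  v <- setNames(numeric(ncol(S)), colnames(S))
  v[names(fluxmap$net)] <- fluxmap$net
  imb <- drop(S %*% v)
  tol <- 1e-9 * max(abs(v), 1e-300)
  bad <- abs(imb) > tol
  data.frame(metabolite = names(imb)[bad], imbalance = unname(imb[bad]),
             stringsAsFactors = FALSE)
}

# Expand reactions into irreversible, symmetry-scrambled variants used by the
# simulators. Reversible reactions become a forward variant (flux net + exch)
# and a backward variant (flux exch, sides swapped, map unchanged letters).
# Each reaction consuming k symmetric metabolite entries becomes 2^k variants
# of weight 2^-k, with the symmetric substrate's map reversed in half of them.
expand_reaction_variants <- function(net) {
  variants <- list()
  add_variant <- function(base_id, subs, prods, role, weight) {
    variants[[length(variants) + 1L]] <<- list(
      base_id = base_id, substrates = subs, products = prods,
      role = role, weight = weight)
  }
  for (r in net$reactions) {
    dirs <- list(list(subs = r$substrates, prods = r$products, role = "fwd"))
    if (r$reversible) {
      dirs[[2]] <- list(subs = r$products, prods = r$substrates, role = "bwd")
    }
    for (d in dirs) {
      sym_idx <- which(vapply(d$subs, function(e) {
        isTRUE(net$metabolites[[e$name]]$symmetric)
      }, logical(1)))
      if (length(sym_idx) == 0L) {
        add_variant(r$id, d$subs, d$prods, d$role, 1)
      } else {
        flips <- expand.grid(rep(list(c(FALSE, TRUE)), length(sym_idx)))
        w <- 1 / nrow(flips)
        for (i in seq_len(nrow(flips))) {
          subs <- d$subs
          for (j in seq_along(sym_idx)) {
            if (flips[i, j]) {
              k <- sym_idx[j]
              subs[[k]]$map <- rev(subs[[k]]$map)
            }
          }
          add_variant(r$id, subs, d$prods, d$role, w)
        }
      }
    }
  }
  variants
}

# Numeric flux of each variant under a flux map: fwd = net + exch, bwd = exch.
variant_fluxes <- function(variants, fluxmap) {
  vapply(variants, function(v) {
    net <- fluxmap$net[[v$base_id]]
    if (is.null(net) || is.na(net)) {
      stop("flux map missing net flux for reaction ", v$base_id)
    }
    exch <- fluxmap$exch[v$base_id]
    exch <- if (is.null(exch) || is.na(exch)) 0 else unname(exch)
    v$weight * (if (v$role == "fwd") net + exch else exch)
  }, numeric(1))
}

# Total consumption (out-flux) per metabolite, and total production, from the
# expanded variants (exchange included on both sides; it cancels in the net
# balance but both directions turn the pool over).
metabolite_turnover <- function(net, variants, vflux) {
  mets <- names(net$metabolites)
  influx <- setNames(numeric(length(mets)), mets)
  efflux <- influx
  for (i in seq_along(variants)) {
    v <- variants[[i]]
    for (e in v$substrates) efflux[e$name] <- efflux[e$name] + vflux[i]
    for (e in v$products) influx[e$name] <- influx[e$name] + vflux[i]
  }
  list(influx = influx, efflux = efflux)
}
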