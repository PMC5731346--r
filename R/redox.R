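#' Load a redox accounting table
#'
#' The accounting table assigns per-reaction yields of reducing equivalents:
#' columns `reaction`, `nadh`, `fadh2`, `nadph`. The default table (shipped
#' as YAML and editable) covers the default TCA network: PDH, IDH, AKGDH and
#' MDH produce NAD(P)H, SDH produces FADH2, and reductive carboxylation
#' consumes NADPH.
#'
#' @param path YAML file; default the shipped table.
#' @return Data frame with columns `reaction`, `nadh`, `fadh2`, `nadph`.
#' @export
read_redox_accounting <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "redox_accounting.yaml",
                        package = "tempoflux", mustWork = TRUE)
  }
  y <- yaml::read_yaml(path)
  out <- do.call(rbind, lapply(y, function(e) {
    data.frame(reaction = e$reaction,
               nadh = if (is.null(e$nadh)) 0 else e$nadh,
               fadh2 = if (is.null(e$fadh2)) 0 else e$fadh2,
               nadph = if (is.null(e$nadph)) 0 else e$nadph,
               stringsAsFactors = FALSE)
  }))
  out
}

#' Redox and oxidative-phosphorylation production rates of a flux map
#'
#' Linear accounting of reducing-equivalent production:
#' `NADH = sum(yield_nadh_i * v_i)`, `FADH2 = sum(yield_fadh2_i * v_i)`, and
#' the oxygen-equivalent OxPhos rate `(NADH + FADH2) / 2` (each NADH or
#' FADH2 reduces half an O2). By default NADPH yields are merged into the
#' NADH total (`merge_nadph = TRUE`); set it `FALSE` to keep NADPH separate
#' and exclude it from the OxPhos rate.
#'
#' @param fluxmap A `flux_map`.
#' @param accounting Accounting table (see [read_redox_accounting()]).
#' @param merge_nadph Merge NADPH into the NADH total (default `TRUE`).
#' @return A `redox_summary` list: `nadh`, `fadh2`, `o2`, and `nadph` (only
#'   when not merged).
#' @export
compute_redox_oxphos <- function(fluxmap, accounting = read_redox_accounting(),
                                 merge_nadph = TRUE) {
  miss <- setdiff(accounting$reaction, names(fluxmap$net))
  if (length(miss)) {
    stop("accounting references fluxes absent from the flux map: ",
         paste(miss, collapse = ", "))
  }
  v <- fluxmap$net[accounting$reaction]
  nadh <- sum(accounting$nadh * v)
  fadh2 <- sum(accounting$fadh2 * v)
  nadph <- sum(accounting$nadph * v)
  if (merge_nadph) {
    nadh <- nadh + nadph
    nadph <- NULL
  }
  o2 <- (nadh + fadh2) / 2
  if (nadh < -1e-9 || fadh2 < -1e-9 || o2 < -1e-9) {
    stop("negative reducing-equivalent production rate (nadh=",
         format(nadh), ", fadh2=", format(fadh2),
         "): accounting/flux inconsistency")
  }
  structure(list(nadh = nadh, fadh2 = fadh2, o2 = o2, nadph = nadph),
            class = "redox_summary")
}

#' Oscillation summary of per-phase values
#'
#' Relative amplitude `(max - min) / mean` and the peak phase (ties broken
#' toward the earliest phase in cycle order).
#'
#' @param values Named numeric vector of per-phase values, in cycle order.
#' @return List with `amplitude` and `peak` (phase name).
#' @export
oscillation_summary <- function(values) {
  stopifnot(length(values) >= 2L, all(is.finite(values)),
            !is.null(names(values)))
  m <- mean(values)
  if (m <= 0) stop("mean of per-phase values is not positive")
  list(amplitude = (max(values) - min(values)) / m,
       peak = names(values)[which.max(values)])
}
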