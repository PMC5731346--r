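test_that("reaction parsing handles transfers, condensations, and errors", {
  net <- parse_network(c(
    "met: A, 2, 1.0, source, 0.0",
    "met: B, 2, 1.0, balanced, 0.0",
    "R1: A (ab) -> B (ab)"))
  expect_identical(net$reactions$R1$substrates[[1]]$map, c("a", "b"))
  expect_identical(net$reactions$R1$products[[1]]$name, "B")

  cs <- parse_network(c(
    "met: OAA, 4, 1.0, source, 0.0",
    "met: AcCoA, 2, 1.0, source, 0.0",
    "met: Cit, 6, 1.0, balanced, 0.0",
    "CS: OAA (abcd) + AcCoA (ef) -> Cit (dcbfea)"))
  expect_length(cs$reactions$CS$products[[1]]$map, 6L)

  expect_error(parse_network(c(
    "met: A, 2, 1.0, source, 0.0",
    "met: B, 1, 1.0, balanced, 0.0",
    "R1: A (ab) -> B (a)")), "unbalanced carbons|has 1 carbons")
  expect_error(parse_network(c(
    "met: A, 2, 1.0, source, 0.0",
    "met: B, 2, 1.0, balanced, 0.0",
    "R1: A (ab) -> B (ab)",
    "R1: A (ab) -> B (ba)")), "duplicate reaction id")
  expect_error(parse_network(c(
    "met: A, 2, 1.0, source, 0.0",
    "R1: A (ab) -> Z (ab)")), "unknown metabolite")
  expect_error(parse_network(c(
    "met: A, 2, 1.0, source, 0.0",
    "met: B, 2, 1.0, balanced, 0.0",
    "R1: 2 A (ab) -> B (ab)")), "coefficients != 1")
})

test_that("serialize -> parse round-trips the default TCA network", {
  net <- read_network(default_network_path())
  txt <- serialize_network(net)
  net2 <- parse_network(txt)
  expect_identical(serialize_network(net2), txt)
  expect_identical(names(net2$reactions), names(net$reactions))
  expect_identical(net2$metabolites$Fum$symmetric, TRUE)
})

test_that("steady-state validation reports imbalances exactly", {
  net <- linear_chain3()
  ok <- flux_map(c(R1 = 1, R2 = 1, R3 = 1, R4 = 1))
  expect_identical(nrow(validate_steady_state(ok, net)), 0L)

  bad <- flux_map(c(R1 = 1, R2 = 2, R3 = 2, R4 = 2))
  v <- validate_steady_state(bad, net)
  expect_identical(v$metabolite, "A")
  expect_equal(v$imbalance, -1.0)

  empty <- parse_network("met: X, 1, 1.0, source, 0.0")
  expect_identical(nrow(validate_steady_state(flux_map(setNames(
    numeric(0), character(0))), empty)), 0L)
})

test_that("any 1% single-flux perturbation of a balanced map is detected", {
  net <- read_network(default_network_path())
  fm <- default_tca_fluxmap()
  expect_identical(nrow(validate_steady_state(fm, net)), 0L)
  S <- stoichiometric_matrix(net)
  for (r in names(fm$net)) {
    fm2 <- fm
    fm2$net[r] <- fm2$net[r] * 1.01
    touches_balanced <- any(S[, r] != 0)
    expect_identical(nrow(validate_steady_state(fm2, net)) > 0,
                     touches_balanced, info = r)
  }
})

test_that("symmetric metabolites expand consumers into half-weight variants", {
  net <- symmetric_fumarate_toy()
  variants <- tempoflux:::expand_reaction_variants(net)
  r2 <- Filter(function(v) v$base_id == "R2", variants)
  expect_length(r2, 2L)
  expect_equal(vapply(r2, `[[`, numeric(1), "weight"), c(0.5, 0.5))
  maps <- lapply(r2, function(v) v$substrates[[1]]$map)
  expect_identical(maps[[2]], rev(maps[[1]]))
  # producers of the symmetric pool are not expanded
  r1 <- Filter(function(v) v$base_id == "R1", variants)
  expect_length(r1, 1L)
})

test_that("reversible reactions yield forward and backward variants", {
  net <- parse_network(c(
    "met: A, 2, 1.0, source, 0.0",
    "met: B, 2, 1.0, balanced, 0.0",
    "met: C, 2, 1.0, balanced, 0.0",
    "met: C.snk, 2, 1.0, source, 0.0",
    "R1: A (ab) -> B (ab)",
    "R2: B (ab) -> C (ba) rev",
    "R3: C (ab) -> C.snk (ab)"))
  variants <- tempoflux:::expand_reaction_variants(net)
  r2 <- Filter(function(v) v$base_id == "R2", variants)
  expect_identical(sort(vapply(r2, `[[`, character(1), "role")),
                   c("bwd", "fwd"))
  fm <- flux_map(c(R1 = 1, R2 = 1, R3 = 1), c(R2 = 0.5))
  vf <- tempoflux:::variant_fluxes(variants, fm)
  roles <- vapply(variants, `[[`, character(1), "role")
  base <- vapply(variants, `[[`, character(1), "base_id")
  expect_equal(vf[base == "R2" & roles == "fwd"], 1.5)
  expect_equal(vf[base == "R2" & roles == "bwd"], 0.5)
})
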