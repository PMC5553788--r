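entry <- function(id, eq) pathcascade:::new_reaction_entry(id, eq)

test_that("reversibility follows the 15 kJ/mol threshold rule", {
  e <- entry("R1", c(A = -1, B = 1))
  # strongly exergonic: irreversible forward
  r <- assign_reversibility(e, dg = -20, threshold = 15)
  expect_length(r, 1)
  expect_equal(r[[1]]$direction, "forward")
  expect_equal(r[[1]]$dg, -20)
  # near equilibrium: reverse pair with negated energy
  r2 <- assign_reversibility(e, dg = 5, threshold = 15)
  expect_length(r2, 2)
  expect_equal(r2[[2]]$dg, -5)
  expect_equal(r2[[1]]$reverse_of, r2[[2]]$id)
  expect_equal(r2[[2]]$equation, -r2[[1]]$equation)
  # no data: irreversible in the written direction
  r3 <- assign_reversibility(e, dg = NA)
  expect_length(r3, 1)
  expect_equal(r3[[1]]$direction, "forward")
  expect_true(is.na(r3[[1]]$dg))
  # strongly endergonic as written: flipped
  r4 <- assign_reversibility(e, dg = 20, threshold = 15)
  expect_length(r4, 1)
  expect_equal(r4[[1]]$direction, "backward")
  expect_equal(r4[[1]]$equation[["A"]], 1)
  expect_equal(r4[[1]]$dg, -20)
  expect_error(assign_reversibility(e, dg = Inf), "non-finite")
})

test_that("threshold boundaries are sharp", {
  e <- entry("R1", c(A = -1, B = 1))
  expect_length(assign_reversibility(e, dg = -14.999), 2)
  expect_length(assign_reversibility(e, dg = -15), 1)
  expect_length(assign_reversibility(e, dg = 15), 1)
})

test_that("arc construction respects categories and banned endpoints", {
  e1 <- entry("R1", c(GLC = -1, ATP = -1, G6P = 1, ADP = 1))
  rx <- assign_reversibility(e1, dg = -17)
  pairs <- data.frame(
    reaction_id = c("R1", "R1", "R1"),
    substrate_id = c("GLC", "ATP", "GLC"),
    product_id = c("G6P", "ADP", "ADP"),
    category = c("main", "cofac", "main"),
    stringsAsFactors = FALSE)
  arcs <- build_arcs(pairs, rx, cofactors = c("ATP", "ADP"))
  # cofac pair dropped by category, third pair dropped by endpoint
  expect_equal(nrow(arcs), 1)
  expect_equal(arcs$substrate, "GLC")
  expect_equal(arcs$product, "G6P")
  expect_error(
    build_arcs(data.frame(reaction_id = "RX", substrate_id = "A",
                          product_id = "B", category = "main",
                          stringsAsFactors = FALSE), rx),
    "unknown reaction")
})

test_that("reversible reactions mirror their arcs on the backward copy", {
  e <- entry("R1", c(A = -1, B = 1))
  rx <- assign_reversibility(e, dg = 3)
  pairs <- data.frame(reaction_id = "R1", substrate_id = "A",
                      product_id = "B", category = "main",
                      stringsAsFactors = FALSE)
  arcs <- build_arcs(pairs, rx)
  expect_equal(nrow(arcs), 2)
  fwd <- arcs[arcs$reaction == "R1", ]
  bwd <- arcs[arcs$reaction == "R1_r", ]
  expect_equal(fwd$substrate, bwd$product)
  expect_equal(fwd$product, bwd$substrate)
})

test_that("metabolite categories follow the mass window and basis list", {
  arcs <- data.frame(substrate = c("GLC", "SUC"), product = c("G6P", "GLC"),
                     reaction = c("R1", "R2"), category = "main",
                     stringsAsFactors = FALSE)
  mets <- c("GLC", "G6P", "SUC", "ORPHAN")
  masses <- c(GLC = 180.16, G6P = 260.14, SUC = 342.3)
  cats <- categorize_metabolites(mets, arcs, masses)
  expect_setequal(cats$start, c("GLC", "G6P"))
  # sucrose: above the mass window until curated into the basis set
  expect_false("SUC" %in% cats$start)
  cats2 <- categorize_metabolites(mets, arcs, masses, basis = "SUC")
  expect_true("SUC" %in% cats2$start)
  expect_true("SUC" %in% cats2$basis)
  # a metabolite on no arc is external even with admissible mass
  cats3 <- categorize_metabolites(mets, arcs, c(masses, ORPHAN = 100))
  expect_true("ORPHAN" %in% cats3$external)
  # half-open window: mass exactly at the upper bound is a start
  cats4 <- categorize_metabolites(mets, arcs, c(GLC = 300, G6P = 0.0))
  expect_true("GLC" %in% cats4$start)
  expect_false("G6P" %in% cats4$start)
  expect_error(categorize_metabolites(mets, arcs, masses, basis = "NOPE"),
               "absent from network")
  # partition: pool and external cover everything, start contains basis
  expect_setequal(c(cats2$pool, cats2$external), mets)
  expect_length(intersect(cats2$pool, cats2$external), 0)
  expect_true(all(cats2$basis %in% cats2$start))
})

test_that("stoichiometric matrix columns reproduce the equations", {
  e1 <- entry("R1", c(A = -2, B = 1))
  e2 <- entry("R2", c(B = -1, C = 1))
  rx <- c(assign_reversibility(e1, dg = NA), assign_reversibility(e2, dg = 2))
  S <- build_stoichiometric_matrix(rx, c("A", "B", "C"))
  expect_equal(dim(S), c(3, 3))
  expect_equal(as.numeric(S[, "R1"]), c(-2, 1, 0))
  expect_equal(as.numeric(S[, "R2"]), c(0, -1, 1))
  # reverse-pair columns are elementwise negations
  expect_equal(as.numeric(S[, "R2_r"]), -as.numeric(S[, "R2"]))
})

test_that("every arc of a reconstructed network is stoichiometrically sound", {
  net <- make_fig3_network()
  for (i in seq_len(nrow(net$arcs))) {
    a <- net$arcs[i, ]
    expect_lt(net$stoich[a$substrate, a$reaction], 0)
    expect_gt(net$stoich[a$product, a$reaction], 0)
  }
  # reverse pairs are antisymmetric in the full network too
  rp <- net$reverse_pairs
  for (q in seq_len(nrow(rp))) {
    expect_equal(as.numeric(net$stoich[, rp$fwd[q]]),
                 -as.numeric(net$stoich[, rp$bwd[q]]))
  }
})

test_that("network JSON serialization round-trips exactly", {
  net <- make_fig3_network()
  js <- write_network_json(net)
  net2 <- read_network_json(js, text = TRUE)
  expect_identical(write_network_json(net2), js)
  expect_equal(net2$metabolites, net$metabolites)
  expect_equal(net2$reaction_ids, net$reaction_ids)
  expect_equal(net2$delta_g, net$delta_g)
  expect_equal(unclass(net2$categories), unclass(net$categories))
})
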