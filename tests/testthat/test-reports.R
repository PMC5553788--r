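test_that("thermodynamic profile accumulates and carries over unknowns", {
  net <- chain_network(dg = c(-5, -10))
  s <- enumerate_pathways(net, "P", 1)[[1]]
  prof <- thermodynamic_profile(s, net)
  expect_equal(prof$cumulative_dg, c(-5, -15))
  expect_true(all(prof$dg_known))

  net2 <- chain_network(dg = c(4, NA, -6))
  s2 <- enumerate_pathways(net2, "P", 1)[[1]]
  prof2 <- thermodynamic_profile(s2, net2)
  expect_equal(prof2$cumulative_dg, c(4, 4, -2))
  expect_equal(prof2$dg_known, c(TRUE, FALSE, TRUE))
  expect_equal(prof2$step, 1:3)
})

test_that("reactant balance splits pool, externals and target correctly", {
  net <- chain_network(dg = c(-20, -20))  # X1 -> X2 -> P, unit fluxes
  s <- enumerate_pathways(net, "P", 1)[[1]]
  bal <- reactant_balance(s, net)
  b <- stats::setNames(bal$balance, bal$metabolite)
  expect_equal(b[["X1"]], -1)
  expect_equal(b[["X2"]], 0)
  expect_equal(b[["P"]], 1)
  expect_equal(bal$role[bal$metabolite == "X1"], "pool_consumed")
  expect_equal(bal$role[bal$metabolite == "P"], "target")

  # supplied external stays non-negative, target at >= 1
  net3 <- make_fig3_network()
  s3 <- enumerate_pathways(net3, "P", 1)[[1]]
  bal3 <- reactant_balance(s3, net3)
  b3 <- stats::setNames(bal3$balance, bal3$metabolite)
  expect_gte(b3[["M4"]], 0)
  expect_gte(b3[["P"]], 1)
  ext <- bal3$metabolite[bal3$role %in% c("external", "external_produced")]
  expect_true(all(b3[ext] >= -1e-9))
})

test_that("side reactions list host consumers of pathway metabolites only", {
  net <- make_fig3_network()
  s <- enumerate_pathways(net, "P", 1)[[1]]
  # R2's backward copy consumes the intermediate M3; R7 consumes the
  # decoy D3 which is not on the pathway; R4 is active
  sr <- side_reactions(s, net, host_reactions = c("R2", "R7", "R4"))
  expect_equal(sr$reaction, "R2")
  expect_match(sr$metabolites, "M3")
  # a host reaction consuming a non-pathway metabolite is not listed
  sr2 <- side_reactions(s, net, host_reactions = "R5")
  expect_equal(nrow(sr2), 0)
  expect_equal(nrow(side_reactions(s, net, character(0))), 0)
})

test_that("host reactions touching only pool cofactors are not side reactions", {
  equations <- list(R1 = c(A = -1, ATP = -1, P = 1, ADP = 1),
                    R2 = c(ATP = -1, ADP = 1))
  pairs <- data.frame(reaction_id = c("R1", "R2"),
                      substrate_id = c("A", "ATP"),
                      product_id = c("P", "ADP"),
                      category = c("main", "cofac"), stringsAsFactors = FALSE)
  entries <- lapply(names(equations), function(id)
    pathcascade:::new_reaction_entry(id, equations[[id]]))
  net <- reconstruct_network(entries, pairs,
                             delta_g = c(R1 = -20, R2 = -20),
                             masses = c(A = 100, P = 400),
                             cofactors = c("ATP", "ADP"))
  s <- enumerate_pathways(net, "P", 1)[[1]]
  # R2 consumes only the cofactor ATP: not a pathway carbon intermediate
  expect_equal(nrow(side_reactions(s, net, host_reactions = c("R2"))), 0)
})

test_that("SBML export is structurally valid and round-trips stoichiometry", {
  net <- chain_network(dg = c(-20, -20))
  s <- enumerate_pathways(net, "P", 1)[[1]]
  txt <- export_sbml(s, net)
  doc <- xml2::read_xml(txt)  # well-formed
  expect_equal(xml2::xml_name(doc), "sbml")
  expect_equal(xml2::xml_attr(doc, "level"), "3")
  expect_equal(xml2::xml_attr(doc, "version"), "1")
  pb <- read_sbml_pathway(txt)
  expect_equal(nrow(pb$species), 3)
  expect_length(pb$reactions, 2)
  for (r in names(pb$reactions)) {
    eq <- pathcascade:::get_reaction(net, r)$equation
    expect_equal(pb$reactions[[r]][sort(names(eq))], eq[sort(names(eq))])
  }
  # pool species are boundary species
  expect_true(pb$species$boundary[pb$species$id == "X1"])
  expect_false(pb$species$boundary[pb$species$id == "P"])

  # supplying reactions and their metabolites are included
  net3 <- make_fig3_network()
  s3 <- enumerate_pathways(net3, "P", 1)[[1]]
  pb3 <- read_sbml_pathway(export_sbml(s3, net3))
  expect_true("R4" %in% names(pb3$reactions))
  expect_true("M4" %in% pb3$species$id)
})

test_that("identifier sanitisation is reversible", {
  ids <- c("C00031", "R08_r", "2-oxoglutarate", "a b(c)", "_x", "9cis")
  san <- pathcascade:::sanitize_sid(ids)
  expect_true(all(grepl("^[A-Za-z_][A-Za-z0-9_]*$", san)))
  expect_equal(pathcascade:::unsanitize_sid(san), ids)
})

test_that("the report bundle is written completely", {
  net <- make_fig3_network()
  sols <- enumerate_pathways(net, "P", 3)
  res <- cmd_rank(net, sols, host = c("R1", "R2"), out = td <- tempfile())
  files <- list.files(td)
  expect_true("ranked.tsv" %in% files)
  n <- length(res$ranked)
  for (i in seq_len(n)) {
    expect_true(all(sprintf(c("profile_%d.tsv", "balance_%d.tsv",
                              "side_%d.tsv", "candidate_%d.sbml"), i)
                    %in% files))
  }
  tab <- read_tsv_table(file.path(td, "ranked.tsv"))
  expect_equal(tab$rank, seq_len(n))
  expect_true(all(diff(tab$n_active_reactions) >= 0))
})
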