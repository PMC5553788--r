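test_that("start-feasibility accepts pool-executable candidates", {
  net <- make_fig3_network()
  sols <- enumerate_pathways(net, "P", max_solutions = 5)
  # chain + supplier: the supplier's substrate M5 is in the pool, so an
  # execution order exists (R4 before R3)
  expect_true(filter_start_feasible(sols[[1]], net))
  expect_true(all(vapply(sols, filter_start_feasible, logical(1),
                         network = net)))
})

test_that("cyclically dependent supplying reactions fail the filter", {
  # Rc1 and Rc2 feed each other (X from W, W from X); no pool input can
  # bootstrap either, so no producer-before-consumer order exists.
  equations <- list(
    R1 = c(A = -1, X = -1, P = 1),
    Rc1 = c(W = -1, X = 1),
    Rc2 = c(X = -1, W = 1))
  pairs <- data.frame(reaction_id = c("R1", "Rc1", "Rc2"),
                      substrate_id = c("A", "W", "X"),
                      product_id = c("P", "X", "W"),
                      category = "main", stringsAsFactors = FALSE)
  entries <- lapply(names(equations), function(id)
    pathcascade:::new_reaction_entry(id, equations[[id]]))
  net <- reconstruct_network(entries, pairs,
                             delta_g = c(R1 = -20, Rc1 = -20, Rc2 = -20),
                             masses = c(A = 100, P = 400, X = 400, W = 400))
  cand <- structure(list(
    linear_path = data.frame(substrate = "A", product = "P",
                             stringsAsFactors = FALSE),
    active_reactions = c("R1", "Rc1", "Rc2"),
    path_reactions = "R1",
    supplying_reactions = c("Rc1", "Rc2"),
    fluxes = c(R1 = 1, Rc1 = 1, Rc2 = 1),
    start_metabolite = "A", objective = NA_real_),
    class = "pathway_solution")
  expect_false(filter_start_feasible(cand, net))
})

test_that("criterion values follow their defining formulas", {
  net <- chain_network(dg = c(-5, -10), basis = "X1")
  s <- enumerate_pathways(net, "P", 1)[[1]]
  rv <- score_candidate(s, net)
  expect_equal(rv$n_active_reactions, 2)
  expect_true(rv$starts_with_basis)
  expect_equal(rv$n_reactions_missing_dg, 0)
  expect_equal(rv$kinetic_trap_score, 0)   # all energies negative
  expect_equal(rv$total_dg, -15)
  # all heterologous without a host; none with a full host set
  expect_equal(rv$n_heterologous, 2)
  rv_host <- score_candidate(s, net, host_reactions = c("R1", "R2"))
  expect_equal(rv_host$n_heterologous, 0)

  # an endergonic step is charged twice its energy
  net2 <- chain_network(dg = c(4, -10))
  s2 <- enumerate_pathways(net2, "P", 1)[[1]]
  rv2 <- score_candidate(s2, net2)
  expect_equal(rv2$kinetic_trap_score, 8)  # (4+|4|) + (-10+10)
  expect_equal(rv2$total_dg, -6)

  # unknown energies count toward criterion 3, not the sums
  net3 <- chain_network(dg = c(NA, -10))
  s3 <- enumerate_pathways(net3, "P", 1)[[1]]
  rv3 <- score_candidate(s3, net3)
  expect_equal(rv3$n_reactions_missing_dg, 1)
  expect_equal(rv3$total_dg, -10)
})

test_that("kinetic-trap score is zero exactly when no known step is endergonic", {
  withr::with_seed(99, {
    for (i in 1:40) {
      dgs <- stats::runif(sample(2:5, 1), -30, 30)
      dgs[stats::runif(length(dgs)) < 0.2] <- NA
      known <- dgs[!is.na(dgs)]
      trap <- sum(known + abs(known))
      expect_equal(trap == 0, all(known <= 0))
      expect_gte(trap, 0)
    }
  })
})

test_that("lexicographic ranking matches an independent comparator", {
  withr::with_seed(42, {
    vectors <- replicate(300, random_rank_vector(), simplify = FALSE)
    scored <- lapply(vectors, function(v)
      list(candidate = list(start_metabolite = "X",
                            linear_path = data.frame(substrate = "X",
                                                     product = "P")),
           rank = v))
    ranked <- rank_candidates(scored)
    expect_equal(lapply(ranked, `[[`, "rank"),
                 vectors[insertion_order(vectors)])
  })
})

test_that("shorter pathways outrank basis starts, and ties keep input order", {
  v_short <- random_rank_vector()
  v_short$n_active_reactions <- 4; v_short$starts_with_basis <- FALSE
  v_long <- v_short
  v_long$n_active_reactions <- 5; v_long$starts_with_basis <- TRUE
  mk <- function(v, tag) list(candidate = list(start_metabolite = tag,
                                               linear_path = data.frame(
                                                 substrate = tag, product = "P")),
                              rank = v)
  ranked <- rank_candidates(list(mk(v_long, "a"), mk(v_short, "b")))
  expect_equal(ranked[[1]]$candidate$start_metabolite, "b")
  # full tie: stable
  ranked2 <- rank_candidates(list(mk(v_short, "first"), mk(v_short, "second")))
  expect_equal(vapply(ranked2, function(s) s$candidate$start_metabolite,
                      character(1)), c("first", "second"))
})

test_that("ranking is invariant under input permutation (total preorder)", {
  withr::with_seed(7, {
    vectors <- replicate(40, random_rank_vector(), simplify = FALSE)
    mk <- function(v, i) list(candidate = list(start_metabolite = paste0("c", i),
                                               linear_path = data.frame(
                                                 substrate = "X", product = "P")),
                              rank = v)
    scored <- Map(mk, vectors, seq_along(vectors))
    r1 <- rank_candidates(scored)
    perm <- sample(seq_along(scored))
    r2 <- rank_candidates(scored[perm])
    key <- function(r) vapply(r, function(s)
      paste(unlist(s$rank), collapse = "|"), character(1))
    expect_equal(key(r1), key(r2))
  })
})
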