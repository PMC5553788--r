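# Shared miniature networks built in code.

# Linear chain X1 -> X2 -> ... -> P with one unary reaction per step.
# dg values are per source reaction (NA = no thermodynamic data).
chain_network <- function(dg = c(-20, -20), basis = character(0)) {
  n <- length(dg)
  mets <- c(sprintf("X%d", seq_len(n)), "P")
  equations <- list()
  pairs <- list()
  dgv <- numeric(0)
  for (i in seq_len(n)) {
    id <- sprintf("R%d", i)
    equations[[id]] <- stats::setNames(c(-1, 1), mets[c(i, i + 1)])
    pairs[[i]] <- data.frame(reaction_id = id, substrate_id = mets[i],
                             product_id = mets[i + 1], category = "main",
                             stringsAsFactors = FALSE)
    if (!is.na(dg[i])) dgv[id] <- dg[i]
  }
  masses <- stats::setNames(rep(400, n + 1), mets)
  masses["X1"] <- 120
  entries <- lapply(names(equations), function(id)
    pathcascade:::new_reaction_entry(id, equations[[id]]))
  net <- reconstruct_network(entries, do.call(rbind, pairs), delta_g = dgv,
                             masses = masses, basis = basis)
  attr(net, "target") <- "P"
  net
}

# The seeded fixture family used by the validation suites.
acceptance_fixture <- function(seed) {
  generate_random_network(fixture_spec(
    n_metabolites = 8 + (seed %% 3) * 2,
    n_reactions = 9, seed = seed))
}

# Independent pairwise comparator over the seven ranking criteria,
# written as a chain of explicit comparisons (no shared code with
# rank_candidates' order() keys).
compare_rank_vectors <- function(a, b) {
  step <- function(x, y) if (x < y) -1L else if (x > y) 1L else 0L
  for (v in list(step(a$n_active_reactions, b$n_active_reactions),
                 step(!a$starts_with_basis, !b$starts_with_basis),
                 step(a$n_reactions_missing_dg, b$n_reactions_missing_dg),
                 step(a$kinetic_trap_score, b$kinetic_trap_score),
                 step(a$total_dg, b$total_dg),
                 step(a$n_heterologous, b$n_heterologous),
                 step(a$n_cofactor_species, b$n_cofactor_species))) {
    if (v != 0L) return(v)
  }
  0L
}

# stable insertion sort on the comparator
insertion_order <- function(vectors) {
  ord <- seq_along(vectors)
  for (i in seq_along(ord)[-1]) {
    j <- i
    while (j > 1 &&
           compare_rank_vectors(vectors[[ord[j - 1]]],
                                vectors[[ord[j]]]) > 0L) {
      tmp <- ord[j - 1]; ord[j - 1] <- ord[j]; ord[j] <- tmp
      j <- j - 1
    }
  }
  ord
}

random_rank_vector <- function() {
  structure(list(
    n_active_reactions = sample(2:6, 1),
    starts_with_basis = sample(c(TRUE, FALSE), 1),
    n_reactions_missing_dg = sample(0:2, 1),
    kinetic_trap_score = sample(c(0, 4, 8), 1),
    total_dg = sample(c(-30, -10, 5), 1),
    n_heterologous = sample(0:3, 1),
    n_cofactor_species = sample(0:2, 1)), class = "rank_vector")
}
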