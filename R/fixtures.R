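## Deterministic synthetic networks and a brute-force pathway oracle.
## These exist to exercise and validate the reconstruction, search and
## ranking code without any external database; they make no attempt to
## mimic the degree distribution of real metabolic networks.

# run code under a local RNG seed without disturbing the caller's RNG
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# internal: assemble a network from compact tables
build_toy_network <- function(equations, pairs, dg = numeric(0),
                              masses = numeric(0), basis = character(0),
                              cofactors = character(0),
                              excluded = character(0),
                              generic = character(0),
                              dg_threshold = 15) {
  entries <- lapply(names(equations), function(id) {
    new_reaction_entry(id, equations[[id]])
  })
  reconstruct_network(entries, pairs, delta_g = dg, masses = masses,
                      basis = basis, cofactors = cofactors,
                      excluded = excluded, generic = generic,
                      dg_threshold = dg_threshold)
}

#' Small worked-example network with a supplying reaction
#'
#' A hand-built network with a three-step linear chain from the start
#' metabolite M1 to the product P.  The final chain reaction consumes
#' the external metabolite M4, which must be supplied by reaction R4
#' from the pool metabolite M5; two decoy start metabolites are planted
#' at a longer distance so the optimum is unique: the M1 chain plus
#' supplying reaction R4.
#'
#' @return a \code{metabolic_network} with attribute \code{"target"}
#'   set to \code{"P"}.
#' @export
make_fig3_network <- function() {
  equations <- list(
    R1 = c(M1 = -1, ATP = -1, M2 = 1, ADP = 1),
    R2 = c(M2 = -1, M3 = 1),
    R3 = c(M3 = -1, M4 = -1, P = 1),
    R4 = c(M5 = -1, M4 = 1),
    R5 = c(D1 = -1, D2 = 1),
    R6 = c(D2 = -1, D3 = 1),
    R7 = c(D3 = -1, M3 = 1))
  pairs <- data.frame(
    reaction_id = c("R1", "R2", "R3", "R4", "R5", "R6", "R7"),
    substrate_id = c("M1", "M2", "M3", "M5", "D1", "D2", "D3"),
    product_id = c("M2", "M3", "P", "M4", "D2", "D3", "M3"),
    category = "main", stringsAsFactors = FALSE)
  dg <- c(R1 = -20, R2 = -5, R3 = -25, R5 = -18, R6 = -18, R7 = -18)
  masses <- c(M1 = 180.16, M5 = 100.1, D1 = 120.1,
              M2 = 510.3, M3 = 520.4, M4 = 480.2,
              D2 = 530.1, D3 = 540.7, P = 410.5,
              ATP = 507.2, ADP = 427.2)
  net <- build_toy_network(equations, pairs, dg = dg, masses = masses,
                           basis = "M1", cofactors = c("ATP", "ADP"))
  attr(net, "target") <- "P"
  net
}

#' Two reactions realising the same arc
#'
#' Minimal network in which the single arc into the product is realised
#' by two different reactions, so enumeration must return the same
#' metabolite path twice with different path-reaction sets Z'.
#' @return a \code{metabolic_network} with attribute \code{"target"}.
#' @export
make_parallel_arc_network <- function() {
  equations <- list(
    R1 = c(A = -1, P = 1),
    R2 = c(A = -1, P = 1, W = 1))
  pairs <- data.frame(reaction_id = c("R1", "R2"),
                      substrate_id = c("A", "A"),
                      product_id = c("P", "P"),
                      category = "main", stringsAsFactors = FALSE)
  net <- build_toy_network(equations, pairs,
                           dg = c(R1 = -20, R2 = -22),
                           masses = c(A = 120.2, P = 420.1, W = 350.5))
  attr(net, "target") <- "P"
  net
}

#' A path that strictly extends a shorter optimal path
#'
#' The optimum is the one-arc path B -> P; a second solution extends it
#' upstream through an arc into B (A -> B -> P), exercising the
#' extension case of the path-exclusion constraints.
#' @return a \code{metabolic_network} with attribute \code{"target"}.
#' @export
make_extension_network <- function() {
  equations <- list(
    R1 = c(B = -1, P = 1),
    R2 = c(A = -1, B = 1))
  pairs <- data.frame(reaction_id = c("R1", "R2"),
                      substrate_id = c("B", "A"),
                      product_id = c("P", "B"),
                      category = "main", stringsAsFactors = FALSE)
  net <- build_toy_network(equations, pairs,
                           dg = c(R1 = -20, R2 = -20),
                           masses = c(A = 100.1, B = 140.1, P = 330.3))
  attr(net, "target") <- "P"
  net
}

#' Specification for a random synthetic network
#'
#' @param n_metabolites total number of core metabolites.
#' @param n_reactions approximate number of source reactions (at least
#'   the planted path length).
#' @param arc_density probability that an extra random reaction
#'   duplicates an existing arc (creating parallel realisers) rather
#'   than connecting a fresh metabolite pair.
#' @param fraction_start fraction of metabolites given a molecular mass
#'   inside the start window (0, 300].
#' @param fraction_pool probability that a non-start metabolite is
#'   added to the freely available (excluded) list; 1 puts every
#'   non-target metabolite in the pool.
#' @param planted_path_length arc count of the guaranteed feasible path
#'   to the target.
#' @param seed RNG seed; all output is reproducible from it.
#' @return a \code{fixture_spec} list.
#' @export
fixture_spec <- function(n_metabolites = 10, n_reactions = 8,
                         arc_density = 0.25, fraction_start = 0.4,
                         fraction_pool = 0.2, planted_path_length = 3,
                         seed = 1) {
  spec <- list(n_metabolites = n_metabolites, n_reactions = n_reactions,
               arc_density = arc_density, fraction_start = fraction_start,
               fraction_pool = fraction_pool,
               planted_path_length = planted_path_length, seed = seed)
  if (planted_path_length < 1 || planted_path_length >= n_metabolites)
    stop("planted_path_length must be in [1, n_metabolites)")
  if (n_reactions < planted_path_length)
    stop("n_reactions must cover at least the planted path")
  fr <- c(arc_density, fraction_start, fraction_pool)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  structure(spec, class = "fixture_spec")
}

#' Generate a random metabolic network with a planted feasible pathway
#'
#' A simple path of \code{planted_path_length} arcs to the designated
#' target is planted first (side substrates drawn from the pool with
#' probability 0.7, otherwise from externals backed by a planted
#' supplying reaction), then random decoy reactions are added.  The
#' result is fully reproducible from the spec's seed.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @return a \code{metabolic_network} with attribute \code{"target"}.
#' @export
generate_random_network <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_local_seed(spec$seed, {
    nM <- spec$n_metabolites
    mets <- sprintf("M%02d", seq_len(nM))
    target <- mets[nM]
    core <- setdiff(mets, target)

    n_start <- max(1L, round(spec$fraction_start * nM))
    start_mets <- sample(core, min(n_start, length(core)))
    masses <- stats::setNames(round(stats::runif(nM, 320, 600), 2), mets)
    masses[start_mets] <- round(stats::runif(length(start_mets), 60, 290), 2)

    L <- spec$planted_path_length
    s0 <- sample(start_mets, 1)
    inter_pool <- setdiff(core, s0)
    intermediates <- if (L > 1) sample(inter_pool, L - 1) else character(0)
    path_nodes <- c(s0, intermediates, target)

    excluded <- character(0)
    non_start <- setdiff(core, c(start_mets, path_nodes))
    if (length(non_start) && spec$fraction_pool > 0) {
      pick <- stats::runif(length(non_start)) < spec$fraction_pool
      excluded <- non_start[pick]
    }
    if (spec$fraction_pool >= 1) excluded <- setdiff(core, start_mets)

    equations <- list()
    pairs <- list()
    dg <- numeric(0)
    aux_n <- 0L
    rid <- function() sprintf("R%02d", length(equations) + 1L)

    add_reaction <- function(eq, sub, prod, g) {
      id <- rid()
      equations[[id]] <<- eq
      pairs[[length(pairs) + 1L]] <<-
        data.frame(reaction_id = id, substrate_id = sub, product_id = prod,
                   category = "main", stringsAsFactors = FALSE)
      if (!is.na(g)) dg[id] <<- g
      id
    }

    ext_side <- character(0)
    pool_side <- character(0)
    for (i in seq_len(L)) {
      a <- path_nodes[i]; b <- path_nodes[i + 1L]
      eq <- stats::setNames(c(-1, 1), c(a, b))
      if (stats::runif(1) < 0.4) {  # side substrate
        if (stats::runif(1) < 0.7) {
          cand <- setdiff(c(start_mets, excluded), c(a, b))
          if (length(cand)) {
            side <- sample(cand, 1)
            pool_side <- c(pool_side, side)
            eq <- c(eq, stats::setNames(-1, side))
          }
        } else {
          aux_n <- aux_n + 1L
          side <- sprintf("E%02d", aux_n)
          masses[side] <- NA  # external helper, no mass record
          eq <- c(eq, stats::setNames(-1, side))
          ext_side <- c(ext_side, side)
        }
      }
      if (stats::runif(1) < 0.3) {  # byproduct
        aux_n <- aux_n + 1L
        bp <- sprintf("W%02d", aux_n)
        eq <- c(eq, stats::setNames(1, bp))
      }
      g <- if (stats::runif(1) < 0.25) NA_real_ else round(stats::runif(1, -40, -16), 1)
      add_reaction(eq, a, b, g)
    }
    for (side in ext_side) {
      src <- sample(start_mets, 1)
      g <- round(stats::runif(1, -35, -16), 1)
      add_reaction(stats::setNames(c(-1, 1), c(src, side)), src, side, g)
    }

    n_extra <- max(0L, spec$n_reactions - length(equations))
    existing_pairs <- function() do.call(rbind, pairs)
    for (k in seq_len(n_extra)) {
      if (stats::runif(1) < spec$arc_density && length(pairs)) {
        # duplicate an existing arc with a new reaction
        ep <- existing_pairs()
        row <- ep[sample(nrow(ep), 1), ]
        a <- row$substrate_id; b <- row$product_id
      } else {
        a <- sample(core, 1)
        b <- sample(setdiff(mets, a), 1)
      }
      eq <- stats::setNames(c(-1, 1), c(a, b))
      if (stats::runif(1) < 0.25) {
        aux_n <- aux_n + 1L
        bp <- sprintf("W%02d", aux_n)
        eq <- c(eq, stats::setNames(1, bp))
      }
      g <- if (stats::runif(1) < 0.3) NA_real_
           else round(stats::runif(1, -40, 20), 1)
      add_reaction(eq, a, b, g)
    }

    basis <- if (stats::runif(1) < 0.5) s0 else character(0)
    # a mass-eligible metabolite only joins the start set if it sits on
    # an arc; pool-intended side substrates that missed the arc network
    # are declared freely available instead so the planted path stays
    # executable from the pool
    arc_members <- unique(unlist(lapply(pairs, function(p)
      c(p$substrate_id, p$product_id))))
    stranded <- setdiff(pool_side, c(arc_members, excluded))
    excluded <- unique(c(excluded, stranded))
    masses_clean <- masses[!is.na(masses)]
    net <- build_toy_network(equations, do.call(rbind, pairs), dg = dg,
                             masses = masses_clean, basis = basis,
                             excluded = excluded)
    attr(net, "target") <- target
    attr(net, "spec") <- spec
    net
  })
}

#' Brute-force enumeration of pathway candidates (oracle)
#'
#' Exhaustive depth-first search over simple arc paths from any start
#' metabolite to the target, honouring the path rules (no arc may enter
#' a basis metabolite; non-start metabolites cannot begin a path), then
#' enumeration of every arc-covering reaction subset Z' and, for each,
#' the minimal supplying-reaction sets that make the flux balance
#' feasible (externals never taken up, at least one unit of target).
#' Objectives are compared in exact integer arithmetic:
#' \code{arcs * (|R|+1) + active reactions}.
#'
#' @param network a \code{metabolic_network} with at most 25 metabolites.
#' @param target target metabolite id.
#' @param max_len maximum path length in arcs.
#' @param max_supply maximum supplying-set size searched per candidate.
#' @param flux_cap flux upper bound Max.
#' @return list with \code{candidates} (every feasible (path, Z')
#'   record) and \code{optimal} (the minimum-objective subset); each
#'   record has \code{path} (node vector), \code{path_reactions},
#'   \code{min_supplying} (count), \code{supplying_sets},
#'   \code{objective_int} and \code{objective}.
#' @export
brute_force_pathways <- function(network, target, max_len = 6,
                                 max_supply = 3, flux_cap = 1000) {
  if (length(network$metabolites) > 25)
    stop("oracle guard: network has more than 25 metabolites")
  arcs <- network$arcs
  nR <- length(network$reaction_ids)
  cats <- network$categories
  keys <- arc_pair_key(arcs$substrate, arcs$product)
  realisers <- split(arcs$reaction, keys)
  adj <- split(arcs$product, arcs$substrate)
  adj <- lapply(adj, unique)

  paths <- list()
  dfs <- function(node, visited) {
    if (length(visited) - 1L > max_len) return()
    if (node == target) {
      paths[[length(paths) + 1L]] <<- visited
      return()
    }
    if (length(visited) - 1L == max_len) return()
    for (nb in sort(adj[[node]])) {
      if (nb %in% visited) next
      if (nb %in% cats$basis) next            # no arc may enter a basis met
      if (nb != target && !length(adj[[nb]])) next  # dead end
      dfs(nb, c(visited, nb))
    }
  }
  for (s in sort(intersect(cats$start, names(adj)))) dfs(s, s)

  rev_conflict <- function(ids) {
    rp <- network$reverse_pairs
    nrow(rp) && any(rp$fwd %in% ids & rp$bwd %in% ids)
  }

  S <- network$stoich
  feasible_active <- function(active) {
    if (rev_conflict(active)) return(FALSE)
    cols <- match(active, network$reaction_ids)
    na <- length(cols)
    Ssub <- S[, cols, drop = FALSE]
    ext <- setdiff(cats$external, target)
    rows <- list(); sense <- character(0); rhs <- numeric(0)
    for (m in ext) {
      coefs <- as.numeric(Ssub[m, ])
      if (all(coefs == 0)) next
      rows[[length(rows) + 1L]] <- coefs; sense <- c(sense, ">="); rhs <- c(rhs, 0)
    }
    rows[[length(rows) + 1L]] <- as.numeric(Ssub[target, ])
    sense <- c(sense, ">="); rhs <- c(rhs, 1)
    for (i in seq_len(na)) {
      e <- numeric(na); e[i] <- 1
      rows[[length(rows) + 1L]] <- e; sense <- c(sense, ">="); rhs <- c(rhs, 1)
      rows[[length(rows) + 1L]] <- e; sense <- c(sense, "<="); rhs <- c(rhs, flux_cap)
    }
    A <- do.call(rbind, rows)
    simplex_lp(numeric(na), A, sense, rhs)$status == "optimal"
  }

  # transitive closure of candidate supplying reactions for an active set
  supply_pool <- function(base_active, path_realisers) {
    pool <- character(0)
    frontier <- base_active
    repeat {
      cols <- match(unique(c(frontier, pool, base_active)),
                    network$reaction_ids)
      consumed <- rownames(S)[Matrix::rowSums(S[, cols, drop = FALSE] < 0) > 0]
      needed <- setdiff(intersect(consumed, cats$external), target)
      if (!length(needed)) break
      producers <- network$reaction_ids[
        Matrix::colSums(S[needed, , drop = FALSE] > 0) > 0]
      producers <- setdiff(producers, c(path_realisers, pool, base_active))
      if (!length(producers)) break
      pool <- c(pool, producers)
      frontier <- producers
    }
    sort(pool)
  }

  records <- list()
  for (pn in paths) {
    pkeys <- arc_pair_key(pn[-length(pn)], pn[-1L])
    rls <- lapply(pkeys, function(k) unique(realisers[[k]]))
    RU <- sort(unique(unlist(rls)))
    if (length(RU) > 14) {
      warning("oracle skip: too many realisers for path ",
              paste(pn, collapse = "->"))
      next
    }
    nRU <- length(RU)
    for (mask in seq_len(2^nRU) - 1L) {
      sel <- RU[bitwAnd(mask, 2^(seq_len(nRU) - 1L)) > 0]
      if (!length(sel)) next
      covers <- all(vapply(rls, function(r) any(r %in% sel), logical(1)))
      if (!covers) next
      if (rev_conflict(sel)) next
      cs <- supply_pool(sel, RU)
      found_m <- NA_integer_
      supply_sets <- list()
      for (k in 0:max_supply) {
        if (k > length(cs)) break
        combos <- if (k == 0) list(character(0))
                  else apply(utils::combn(cs, k), 2, identity, simplify = FALSE)
        for (sp in combos) {
          if (feasible_active(c(sel, sp))) {
            found_m <- k
            supply_sets[[length(supply_sets) + 1L]] <- sp
          }
        }
        if (!is.na(found_m)) break
      }
      if (is.na(found_m)) next
      obj_int <- (length(pn) - 1L) * (nR + 1L) + length(sel) + found_m
      records[[length(records) + 1L]] <-
        list(path = pn, path_reactions = sort(sel),
             min_supplying = found_m, supplying_sets = supply_sets,
             objective_int = obj_int, objective = obj_int / (nR + 1))
    }
  }
  if (!length(records)) {
    return(list(candidates = list(), optimal = list(),
                objective_scale = nR + 1))
  }
  objs <- vapply(records, `[[`, numeric(1), "objective_int")
  list(candidates = records,
       optimal = records[objs == min(objs)],
       objective_scale = nR + 1)
}

#' Canonical (path, Z') key of an oracle record or pathway solution
#'
#' Used to compare enumeration output with the brute-force oracle as
#' sets.
#' @param x an oracle record (list with \code{path},
#'   \code{path_reactions}) or a \code{pathway_solution}.
#' @return character scalar.
#' @export
candidate_key <- function(x) {
  if (inherits(x, "pathway_solution")) {
    nodes <- c(x$linear_path$substrate,
               x$linear_path$product[nrow(x$linear_path)])
    zr <- x$path_reactions
  } else {
    nodes <- x$path
    zr <- x$path_reactions
  }
  paste(paste(nodes, collapse = ">"),
        paste(sort(zr), collapse = ","), sep = " || ")
}

#' Write a network as a KEGG-style fixture bundle
#'
#' Emits flat-file reactions, reaction-pair/thermodynamics/compound
#' tables and curated id lists into a directory such that running the
#' reconstruction on the bundle reproduces an equivalent network.
#' Optionally appends one synthetic record per exclusion rule (generic
#' comment, incomplete comment, symbolic coefficient, glycan compound),
#' all of which the reconstruction filters must reject.
#'
#' @param network a \code{metabolic_network}.
#' @param dir output directory (created if needed).
#' @param include_rejected append the four reject-rule records.
#' @return invisibly, the named vector of written file paths.
#' @export
write_kegg_fixture <- function(network, dir, include_rejected = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # one record per source reaction: forward copies, plus flipped
  # (backward-only) singletons written in their runnable direction
  fwd <- Filter(function(r) r$direction == "forward" || is.na(r$reverse_of),
                network$reactions)
  entries <- lapply(fwd, function(r) new_reaction_entry(r$source_id, r$equation))
  txt <- serialize_reaction_entries(entries)
  if (include_rejected) {
    rej <- paste(
      "ENTRY       RX901                Reaction",
      "EQUATION    C90001 <=> C90002",
      "COMMENT     generic reaction",
      "///",
      "ENTRY       RX902                Reaction",
      "EQUATION    C90003 <=> C90004",
      "COMMENT     incomplete reaction",
      "///",
      "ENTRY       RX903                Reaction",
      "EQUATION    n C90005 <=> n C90006",
      "///",
      "ENTRY       RX904                Reaction",
      "EQUATION    G90001 <=> C90007",
      "///", sep = "\n")
    txt <- paste0(txt, rej, "\n")
  }
  src_ids <- vapply(fwd, function(r) r$source_id, character(1))
  fwd_ids <- vapply(fwd, function(r) r$id, character(1))
  paths <- c(reactions = file.path(dir, "reactions.keg"),
             pairs = file.path(dir, "pairs.tsv"),
             thermo = file.path(dir, "thermo.tsv"),
             compounds = file.path(dir, "compounds.tsv"),
             basis = file.path(dir, "basis.txt"),
             cofactors = file.path(dir, "cofactors.txt"),
             excluded = file.path(dir, "excluded.txt"),
             host = file.path(dir, "host.txt"))
  writeLines(txt, paths["reactions"], sep = "")

  fa <- network$arcs[network$arcs$reaction %in% fwd_ids, , drop = FALSE]
  fa$reaction_id <- src_ids[match(fa$reaction, fwd_ids)]
  pairs_tab <- data.frame(reaction_id = fa$reaction_id,
                          substrate_id = fa$substrate,
                          product_id = fa$product,
                          category = fa$category, stringsAsFactors = FALSE)
  utils::write.table(pairs_tab, paths["pairs"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  dg <- network$delta_g[fwd_ids]
  thermo <- data.frame(reaction_id = src_ids,
                       drG_m_kJ_mol = ifelse(is.na(dg), "", as.character(dg)),
                       stringsAsFactors = FALSE)
  utils::write.table(thermo, paths["thermo"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ms <- network$masses
  comp <- data.frame(id = names(ms), name = names(ms), mass = unname(ms),
                     stringsAsFactors = FALSE)
  utils::write.table(comp, paths["compounds"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  writeLines(network$categories$basis, paths["basis"])
  writeLines(network$categories$cofactors, paths["cofactors"])
  writeLines(network$categories$excluded, paths["excluded"])
  writeLines(sort(unique(src_ids))[seq(1, length(unique(src_ids)), by = 2)],
             paths["host"])
  invisible(paths)
}
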