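## Pathway-search MILP.
##
## The model couples a graph path (binary arc-use variables u_ij over
## the curated arc network) with reaction stoichiometry (continuous
## fluxes v_r in [1, Max] when active, binary activity indicators z_r):
## a simple path from an arbitrary start metabolite to the target plus a
## minimal set of supplying reactions producing every non-pool
## substrate consumed along the way.  The objective minimises the arc
## count, with the active-reaction count as a strictly dominated
## tie-breaker (weight 1/(|R|+1)).  Already-returned solutions --
## identified by (metabolite path, path-realising reaction set Z') --
## are cut off by dedicated exclusion constraints so repeated solving
## streams distinct candidates in nondecreasing objective order.

arc_pair_key <- function(i, j) paste(i, j, sep = " -> ")

#' Build the pathway-search MILP for a target metabolite
#'
#' @param network a \code{metabolic_network}.
#' @param target metabolite id to synthesise; must be in the network
#'   and outside the freely available metabolite pool.
#' @param flux_cap upper bound Max for active-reaction fluxes
#'   (default 1000; any value >= 1 is valid).
#' @return an object of class \code{milp_problem} (mutable environment)
#'   holding the model and the solution-exclusion state.
#' @export
build_milp <- function(network, target, flux_cap = 1000) {
  stopifnot(flux_cap >= 1)
  M <- network$metabolites
  if (!target %in% M) stop("target metabolite not in network: ", target)
  cats <- network$categories
  if (target %in% cats$pool)
    stop("configuration error: target ", target,
         " is in the metabolite pool (freely available; nothing to search)")
  R_ids <- network$reaction_ids
  nR <- length(R_ids)
  arcs <- network$arcs

  # distinct (i, j) endpoint pairs with at least one arc
  pk <- arc_pair_key(arcs$substrate, arcs$product)
  upairs <- unique(data.frame(i = arcs$substrate, j = arcs$product,
                              key = pk, stringsAsFactors = FALSE))
  if (!any(arcs$product == target))
    warning("target ", target, " has no incoming arc; the model is infeasible")

  model <- milp_model()
  uvar <- stats::setNames(integer(nrow(upairs)), upairs$key)
  for (p in seq_len(nrow(upairs)))
    uvar[p] <- milp_add_var(model, paste0("u[", upairs$key[p], "]"), "B", 1)
  vvar <- stats::setNames(integer(nR), R_ids)
  zvar <- stats::setNames(integer(nR), R_ids)
  for (r in seq_len(nR)) {
    vvar[r] <- milp_add_var(model, paste0("v[", R_ids[r], "]"), "C", 0)
    zvar[r] <- milp_add_var(model, paste0("z[", R_ids[r], "]"), "B",
                            1 / (nR + 1))
  }

  into <- function(node) uvar[upairs$j == node]
  outof <- function(node) uvar[upairs$i == node]

  # one arc ends in the target; none leaves it
  milp_add_constraint(model, into(target), rep(1, length(into(target))),
                      "==", 1, "one-arc-into-target")
  op <- outof(target)
  if (length(op))
    milp_add_constraint(model, op, rep(1, length(op)), "==", 0,
                        "no-arc-out-of-target")

  pair_nodes <- unique(c(upairs$i, upairs$j))
  for (l in setdiff(intersect(cats$start, pair_nodes), target)) {
    iv <- into(l); ov <- outof(l)
    if (!length(iv)) next  # 0 <= sum(out) always holds
    milp_add_constraint(model, c(iv, ov), c(rep(1, length(iv)),
                                            rep(-1, length(ov))),
                        "<=", 0, paste0("start-degree[", l, "]"))
  }
  for (l in setdiff(intersect(cats$basis, pair_nodes), target)) {
    iv <- into(l)
    if (!length(iv)) next
    milp_add_constraint(model, iv, rep(1, length(iv)), "==", 0,
                        paste0("basis-no-entry[", l, "]"))
  }
  for (k in setdiff(setdiff(pair_nodes, cats$start), target)) {
    iv <- into(k); ov <- outof(k)
    milp_add_constraint(model, c(iv, ov), c(rep(1, length(iv)),
                                            rep(-1, length(ov))),
                        "==", 0, paste0("flow[", k, "]"))
  }
  for (k in pair_nodes) {
    iv <- into(k)
    if (length(iv) >= 2L)
      milp_add_constraint(model, iv, rep(1, length(iv)), "<=", 1,
                          paste0("simple[", k, "]"))
  }

  # stoichiometric feasibility
  S <- network$stoich
  for (m in setdiff(cats$external, target)) {
    row <- S[m, ]
    nz <- which(row != 0)
    if (!length(nz)) next
    milp_add_constraint(model, vvar[nz], as.numeric(row[nz]), ">=", 0,
                        paste0("no-uptake[", m, "]"))
  }
  rowP <- S[target, ]
  nzP <- which(rowP != 0)
  milp_add_constraint(model, vvar[nzP], as.numeric(rowP[nzP]), ">=", 1,
                      "produce-target")
  for (r in seq_len(nR)) {
    milp_add_constraint(model, c(zvar[r], vvar[r]), c(1, -1), "<=", 0,
                        paste0("flux-lb[", R_ids[r], "]"))
    milp_add_constraint(model, c(vvar[r], zvar[r]), c(1, -flux_cap), "<=", 0,
                        paste0("flux-ub[", R_ids[r], "]"))
  }
  if (nrow(network$reverse_pairs)) {
    for (q in seq_len(nrow(network$reverse_pairs))) {
      milp_add_constraint(model,
                          zvar[c(network$reverse_pairs$fwd[q],
                                 network$reverse_pairs$bwd[q])],
                          c(1, 1), "<=", 1,
                          paste0("no-trivial-cycle[",
                                 network$reverse_pairs$fwd[q], "]"))
    }
  }
  # link path arcs to realising reactions
  realisers <- split(arcs$reaction, arc_pair_key(arcs$substrate, arcs$product))
  for (p in seq_len(nrow(upairs))) {
    rs <- unique(realisers[[upairs$key[p]]])
    milp_add_constraint(model, c(zvar[rs], uvar[p]),
                        c(rep(1, length(rs)), -1), ">=", 0,
                        paste0("realise[", upairs$key[p], "]"))
  }

  e <- new.env(parent = emptyenv())
  e$model <- model
  e$network <- network
  e$target <- target
  e$flux_cap <- flux_cap
  e$upairs <- upairs
  e$uvar <- uvar
  e$vvar <- vvar
  e$zvar <- zvar
  e$realisers <- realisers
  e$paths <- list()        # per distinct metabolite path: key, arcs, alpha, svar
  e$seen <- character(0)   # "pathkey || Z' key" strings already returned
  e$n_solutions <- 0L
  e$exhausted <- FALSE
  class(e) <- "milp_problem"
  e
}

#' @export
print.milp_problem <- function(x, ...) {
  cat("<milp_problem> target", x$target, "-",
      length(x$model$var_names), "variables,",
      length(x$model$cons), "constraints,",
      x$n_solutions, "solutions returned\n")
  invisible(x)
}

#' Extract a structured pathway solution from variable values
#'
#' Orders the active arcs into the linear path from its unique start
#' node to the target, splits the active reactions into the
#' path-realising set Z' and the supplying reactions, and records the
#' fluxes.  A variable assignment that does not encode a simple
#' connected path raises a consistency error.
#'
#' @param x named solver solution vector.
#' @param problem the \code{milp_problem}.
#' @param objective solver objective value.
#' @return object of class \code{pathway_solution}.
#' @export
extract_solution <- function(x, problem, objective = NA_real_) {
  int_tol <- 1e-6
  up <- problem$upairs
  uval <- x[paste0("u[", up$key, "]")]
  on <- which(uval > 0.5)
  if (!length(on)) stop("solution consistency error: empty path")
  pa <- up[on, , drop = FALSE]
  # unique start: path node with an outgoing but no incoming path arc
  starts <- setdiff(pa$i, pa$j)
  if (length(starts) != 1L)
    stop("solution consistency error: path is not a single simple chain")
  if (anyDuplicated(pa$i) || anyDuplicated(pa$j))
    stop("solution consistency error: repeated path node")
  nxt <- stats::setNames(pa$j, pa$i)
  ordered <- character(0)
  node <- starts
  for (step in seq_len(nrow(pa))) {
    ordered <- c(ordered, node)
    node <- nxt[[node]]
    if (is.null(node)) stop("solution consistency error: broken chain")
  }
  if (node != problem$target)
    stop("solution consistency error: path does not end in target")
  if (length(unique(c(ordered, node))) != nrow(pa) + 1L)
    stop("solution consistency error: path revisits a node")
  lp <- data.frame(substrate = ordered,
                   product = c(ordered[-1L], node),
                   stringsAsFactors = FALSE)

  zval <- x[paste0("z[", names(problem$zvar), "]")]
  active <- names(problem$zvar)[zval > 0.5]
  vval <- x[paste0("v[", names(problem$vvar), "]")]
  fluxes <- stats::setNames(as.numeric(vval), names(problem$vvar))
  fluxes[fluxes < int_tol] <- 0
  path_keys <- arc_pair_key(lp$substrate, lp$product)
  zp <- unique(unlist(problem$realisers[path_keys], use.names = FALSE))
  path_rx <- intersect(active, zp)
  structure(list(linear_path = lp,
                 active_reactions = active,
                 path_reactions = sort(path_rx),
                 supplying_reactions = sort(setdiff(active, path_rx)),
                 fluxes = fluxes,
                 start_metabolite = starts,
                 objective = objective),
            class = "pathway_solution")
}

#' @export
print.pathway_solution <- function(x, ...) {
  cat("<pathway_solution>",
      paste(c(x$linear_path$substrate,
              x$linear_path$product[nrow(x$linear_path)]),
            collapse = " -> "), "\n")
  cat("  path reactions:", paste(x$path_reactions, collapse = ", "), "\n")
  if (length(x$supplying_reactions))
    cat("  supplying:", paste(x$supplying_reactions, collapse = ", "), "\n")
  cat("  objective:", format(x$objective), "\n")
  invisible(x)
}

path_key <- function(solution) {
  paste(sort(arc_pair_key(solution$linear_path$substrate,
                          solution$linear_path$product)), collapse = " | ")
}

solution_key <- function(solution) {
  paste(path_key(solution), paste(sort(solution$path_reactions),
                                  collapse = ","), sep = " || ")
}

# Append the exclusion constraints for a freshly returned solution.
add_exclusion <- function(problem, solution) {
  model <- problem$model
  pkey <- path_key(solution)
  keys <- arc_pair_key(solution$linear_path$substrate,
                       solution$linear_path$product)
  known <- vapply(problem$paths, `[[`, character(1), "key")
  k <- match(pkey, known)
  if (is.na(k)) {
    # new metabolite path: fresh s_k and the three path-identity
    # constraints (s_k = 1 forces exactly this arc set; an extension of
    # the path through its start node remains admissible)
    svar <- milp_add_var(model, paste0("s[", length(problem$paths) + 1L, "]"),
                         "B", 0)
    u_in <- problem$uvar[keys]
    u_out <- problem$uvar[setdiff(problem$upairs$key, keys)]
    nM2 <- length(problem$network$metabolites)^2
    milp_add_constraint(model, c(svar, u_in),
                        c(length(u_in), rep(-1, length(u_in))),
                        "<=", 0, "excl-arcs-active")
    if (length(u_out))
      milp_add_constraint(model, c(u_out, svar),
                          c(rep(1, length(u_out)), nM2),
                          "<=", nM2, "excl-no-extra-arc")
    alpha <- solution$start_metabolite
    u_alpha <- problem$uvar[problem$upairs$key[problem$upairs$j == alpha]]
    milp_add_constraint(model, c(u_in, u_alpha, svar),
                        c(rep(1, length(u_in)), rep(-1, length(u_alpha)), -1),
                        "<=", length(u_in) - 1, "excl-same-or-extend")
    problem$paths[[length(problem$paths) + 1L]] <-
      list(key = pkey, arcs = keys, alpha = alpha, svar = svar)
    k <- length(problem$paths)
  }
  svar <- problem$paths[[k]]$svar
  zp <- problem$zvar[solution$path_reactions]
  nR <- length(problem$network$reaction_ids)
  m_l <- length(zp)
  milp_add_constraint(model, c(zp, svar), c(rep(1, m_l), nR),
                      "<=", m_l - 1 + nR, "excl-same-reactions")
  problem$seen <- c(problem$seen, solution_key(solution))
  invisible(problem)
}

# Secondary LP: with all binaries fixed at their solved values,
# minimise total flux so the reported v_r are the smallest scaling that
# satisfies the balances (deterministic, instead of an arbitrary vertex
# anywhere in [1, Max]).
polish_fluxes <- function(problem, x) {
  rl <- milp_realise(problem$model)
  bins <- rl$bin
  fix <- matrix(0, length(bins), rl$n)
  fix[cbind(seq_along(bins), bins)] <- 1
  obj2 <- numeric(rl$n)
  obj2[problem$vvar] <- 1
  sol <- simplex_lp(obj2, rbind(rl$A, fix),
                    c(rl$sense, rep("==", length(bins))),
                    c(rl$b, round(x[bins])))
  if (sol$status == "optimal") x[problem$vvar] <- sol$x[problem$vvar]
  x
}

#' Return the next distinct pathway solution
#'
#' Solves the current model to optimality, extracts the pathway, and
#' appends the exclusion constraints so the same (metabolite path, Z')
#' combination can never be returned again.
#'
#' @param problem a \code{milp_problem}.
#' @return a \code{pathway_solution}, or the string \code{"exhausted"}
#'   once the model has become infeasible.
#' @export
solve_next <- function(problem) {
  if (problem$exhausted) return("exhausted")
  res <- milp_solve(problem$model)
  if (res$status == "infeasible") {
    problem$exhausted <- TRUE
    return("exhausted")
  }
  if (res$status != "optimal") stop("solver failure: status ", res$status)
  sol <- extract_solution(polish_fluxes(problem, res$x), problem,
                          res$objective)
  if (solution_key(sol) %in% problem$seen)
    stop("internal error: exclusion constraints failed to cut previous solution")
  add_exclusion(problem, sol)
  problem$n_solutions <- problem$n_solutions + 1L
  sol
}

#' Enumerate pathway candidates to a target metabolite
#'
#' Driver looping \code{\link{solve_next}}: returns up to
#' \code{max_solutions} distinct (path, Z') candidates in nondecreasing
#' objective order, stopping early when the model is exhausted.
#'
#' @param network a \code{metabolic_network}.
#' @param target target metabolite id.
#' @param max_solutions maximum number of candidates (>= 1).
#' @param flux_cap flux upper bound Max.
#' @param quiet suppress per-solution progress messages.
#' @return list of \code{pathway_solution}.
#' @export
enumerate_pathways <- function(network, target, max_solutions = 10,
                               flux_cap = 1000, quiet = TRUE) {
  stopifnot(max_solutions >= 1)
  problem <- build_milp(network, target, flux_cap)
  out <- list()
  last_obj <- -Inf
  while (length(out) < max_solutions) {
    sol <- tryCatch(solve_next(problem), error = function(e) {
      if (grepl("consistency error", conditionMessage(e))) {
        # exclusion pressure can push the model into degenerate
        # assignments once every genuine simple path is spent
        "exhausted"
      } else {
        stop(e)
      }
    })
    if (identical(sol, "exhausted")) break
    if (sol$objective < last_obj - 1e-6 * (1 + abs(sol$objective)))
      stop("internal error: objective decreased across enumeration")
    last_obj <- sol$objective
    if (!quiet)
      message(sprintf("solution %d: %s (objective %.6f)",
                      length(out) + 1L,
                      paste(c(sol$linear_path$substrate,
                              target), collapse = " -> "),
                      sol$objective))
    out[[length(out) + 1L]] <- sol
  }
  out
}

#' Independently re-check a pathway solution against the model rules
#'
#' Re-evaluates every structural and stoichiometric requirement of the
#' pathway model -- path shape (degree, start/basis/flow/simplicity
#' rules), non-uptake of externals, target production, flux/activity
#' coupling, reverse-pair exclusivity and arc-reaction linkage --
#' directly from the network data, without reference to the solver or
#' the constraint matrix.
#'
#' @param solution a \code{pathway_solution}.
#' @param network the \code{metabolic_network} it was found in.
#' @param target target metabolite id.
#' @param flux_cap flux cap used for the search.
#' @param tol numeric tolerance.
#' @return \code{TRUE} if valid, otherwise a character vector naming
#'   the violated rules.
#' @export
validate_solution <- function(solution, network, target, flux_cap = 1000,
                              tol = 1e-6) {
  bad <- character(0)
  lp <- solution$linear_path
  cats <- network$categories
  nodes <- c(lp$substrate, lp$product[nrow(lp)])
  u_in <- table(factor(lp$product, levels = network$metabolites))
  u_out <- table(factor(lp$substrate, levels = network$metabolites))

  if (u_in[[target]] != 1) bad <- c(bad, "one arc must enter the target")
  if (u_out[[target]] != 0) bad <- c(bad, "no arc may leave the target")
  for (l in setdiff(cats$start, target))
    if (u_in[[l]] > u_out[[l]]) bad <- c(bad, paste0("start-degree at ", l))
  for (l in setdiff(cats$basis, target))
    if (u_in[[l]] != 0) bad <- c(bad, paste0("basis metabolite entered: ", l))
  for (k in setdiff(network$metabolites, c(cats$start, target)))
    if (u_in[[k]] != u_out[[k]]) bad <- c(bad, paste0("flow violated at ", k))
  if (any(u_in > 1)) bad <- c(bad, "node entered more than once")
  if (anyDuplicated(nodes)) bad <- c(bad, "path not simple")
  if (!nodes[1] %in% cats$start) bad <- c(bad, "path does not start in S")

  # arcs must exist and each must be realised by an active reaction
  akeys <- arc_pair_key(network$arcs$substrate, network$arcs$product)
  for (i in seq_len(nrow(lp))) {
    key <- arc_pair_key(lp$substrate[i], lp$product[i])
    rs <- unique(network$arcs$reaction[akeys == key])
    if (!length(rs)) {
      bad <- c(bad, paste0("no arc exists for ", key))
    } else if (!any(rs %in% solution$active_reactions)) {
      bad <- c(bad, paste0("path arc not realised by an active reaction: ", key))
    }
  }

  v <- solution$fluxes[network$reaction_ids]
  v[is.na(v)] <- 0
  active <- network$reaction_ids %in% solution$active_reactions
  if (any(v[!active] > tol)) bad <- c(bad, "inactive reaction carries flux")
  if (any(v[active] < 1 - tol)) bad <- c(bad, "active reaction below unit flux")
  if (any(v[active] > flux_cap + tol)) bad <- c(bad, "flux exceeds cap")

  balance <- as.numeric(network$stoich %*% v)
  names(balance) <- network$metabolites
  for (m in setdiff(cats$external, target))
    if (balance[[m]] < -tol) bad <- c(bad, paste0("external taken up: ", m))
  if (balance[[target]] < 1 - tol) bad <- c(bad, "target production below 1")

  if (nrow(network$reverse_pairs)) {
    both <- network$reverse_pairs$fwd %in% solution$active_reactions &
      network$reverse_pairs$bwd %in% solution$active_reactions
    if (any(both)) bad <- c(bad, "reverse pair simultaneously active")
  }

  if (length(bad)) bad else TRUE
}
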