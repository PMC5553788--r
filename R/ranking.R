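## Candidate filtering and lexicographic ranking.
##
## Candidates surviving the start-feasibility filter are ordered by
## seven criteria applied in sequence: (1) fewer active reactions,
## (2) start metabolite in the curated basis set, (3) fewer path
## reactions lacking Gibbs energy data, (4) lower kinetic-trap score
## sum(dG + |dG|), (5) lower total path dG, (6) fewer heterologous
## reactions, (7) fewer distinct cofactor species.  Ties after all
## seven keep input (enumeration) order.

#' Check that a pathway candidate can be executed from the pool
#'
#' The global search guarantees stoichiometric feasibility but not that
#' the first reaction -- or the supply chain feeding it -- can start
#' from freely available metabolites alone.  This filter checks
#' constructively that the active reactions admit an execution order in
#' which every non-pool substrate has been produced by an earlier
#' reaction, with pool metabolites free throughout.
#'
#' @param candidate a \code{pathway_solution}.
#' @param network the \code{metabolic_network}.
#' @return \code{TRUE} if an execution order exists, else \code{FALSE}.
#' @export
filter_start_feasible <- function(candidate, network) {
  pool <- network$categories$pool
  avail <- pool
  todo <- candidate$active_reactions
  while (length(todo)) {
    runnable <- vapply(todo, function(r) {
      eq <- get_reaction(network, r)$equation
      subs <- names(eq)[eq < 0]
      all(subs %in% avail)
    }, logical(1))
    if (!any(runnable)) return(FALSE)
    for (r in todo[runnable]) {
      eq <- get_reaction(network, r)$equation
      avail <- unique(c(avail, names(eq)[eq > 0]))
    }
    todo <- todo[!runnable]
  }
  TRUE
}

#' Score a pathway candidate on the seven ranking criteria
#'
#' Criteria 3-5 (missing Gibbs data, kinetic-trap score, total Gibbs
#' energy) are computed over the linear-path reactions Z'; criteria 1,
#' 6 and 7 over all active reactions.  With no host reaction set every
#' active reaction counts as heterologous.
#'
#' @param candidate a \code{pathway_solution}.
#' @param network the \code{metabolic_network}.
#' @param host_reactions character vector of host-organism reaction ids
#'   (source, pre-split ids accepted), or \code{NULL}.
#' @param cofactor_set cofactor metabolite ids; defaults to the
#'   network's curated cofactor list.
#' @return object of class \code{rank_vector}: named list of the seven
#'   criteria.
#' @export
score_candidate <- function(candidate, network, host_reactions = NULL,
                            cofactor_set = NULL) {
  if (is.null(cofactor_set)) cofactor_set <- network$categories$cofactors
  active <- candidate$active_reactions
  path_rx <- candidate$path_reactions
  dg <- vapply(path_rx, function(r) get_reaction(network, r)$dg, numeric(1))
  known <- dg[!is.na(dg)]
  host_directed <- character(0)
  if (!is.null(host_reactions) && length(host_reactions)) {
    src <- vapply(network$reactions, `[[`, character(1), "source_id")
    host_directed <- network$reaction_ids[src %in% host_reactions |
                                            network$reaction_ids %in%
                                              host_reactions]
  }
  cof <- unique(unlist(lapply(active, function(r) {
    intersect(names(get_reaction(network, r)$equation), cofactor_set)
  })))
  structure(list(
    n_active_reactions = length(active),
    starts_with_basis = candidate$start_metabolite %in%
      network$categories$basis,
    n_reactions_missing_dg = sum(is.na(dg)),
    kinetic_trap_score = sum(known + abs(known)),
    total_dg = sum(known),
    n_heterologous = length(setdiff(active, host_directed)),
    n_cofactor_species = length(cof)),
    class = "rank_vector")
}

#' @export
print.rank_vector <- function(x, ...) {
  cat(sprintf(paste0("<rank_vector> reactions=%d basis_start=%s ",
                     "missing_dG=%d trap=%.3g total_dG=%.3g ",
                     "heterologous=%d cofactors=%d\n"),
              x$n_active_reactions, x$starts_with_basis,
              x$n_reactions_missing_dg, x$kinetic_trap_score,
              x$total_dg, x$n_heterologous, x$n_cofactor_species))
  invisible(x)
}

#' Rank scored candidates lexicographically
#'
#' Stable sort by the seven criteria in their order of application;
#' candidates with identical vectors keep their input order.
#'
#' @param scored list of elements each containing \code{candidate} (a
#'   \code{pathway_solution}) and \code{rank} (a \code{rank_vector}).
#' @return the same list, reordered, with a \code{rank_position} field
#'   added to each element.
#' @export
rank_candidates <- function(scored) {
  if (!length(scored)) return(scored)
  key <- function(field) vapply(scored, function(s) {
    v <- s$rank[[field]]
    if (is.logical(v)) as.numeric(!v) else as.numeric(v)
  }, numeric(1))
  ord <- order(key("n_active_reactions"), key("starts_with_basis"),
               key("n_reactions_missing_dg"), key("kinetic_trap_score"),
               key("total_dg"), key("n_heterologous"),
               key("n_cofactor_species"))  # order() is stable
  out <- scored[ord]
  for (i in seq_along(out)) out[[i]]$rank_position <- i
  out
}

#' Tabulate ranked candidates
#' @param ranked output of \code{\link{rank_candidates}}.
#' @return data.frame with one row per candidate: rank, start, path,
#'   and the seven criteria.
#' @export
ranking_table <- function(ranked) {
  do.call(rbind, lapply(ranked, function(s) {
    r <- s$rank
    lp <- s$candidate$linear_path
    data.frame(rank = s$rank_position,
               start = s$candidate$start_metabolite,
               path = paste(c(lp$substrate, lp$product[nrow(lp)]),
                            collapse = ">"),
               n_active_reactions = r$n_active_reactions,
               starts_with_basis = r$starts_with_basis,
               n_reactions_missing_dg = r$n_reactions_missing_dg,
               kinetic_trap_score = r$kinetic_trap_score,
               total_dg = r$total_dg,
               n_heterologous = r$n_heterologous,
               n_cofactor_species = r$n_cofactor_species,
               stringsAsFactors = FALSE)
  }))
}
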