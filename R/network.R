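## Directed-network assembly: thermodynamic reversibility assignment,
## arc construction from curated reaction pairs, metabolite
## categorisation and the stoichiometric matrix.

#' Assign reaction directionality from transformed Gibbs energy
#'
#' Reactions are split by the standard threshold rule: a reaction whose
#' transformed Gibbs energy of reaction (1 mM reactants, pH 7, 25 degC)
#' lies within \code{threshold} of zero is treated as reversible and
#' split into a forward/backward pair of directed reactions with
#' negated stoichiometry; strongly exergonic reactions stay forward
#' only; strongly endergonic reactions are flipped to run in the
#' exergonic direction.  Reactions without thermodynamic data are kept
#' irreversible in the direction written.
#'
#' @param entry a \code{reaction_entry}.
#' @param dg transformed reaction Gibbs energy in kJ/mol, or \code{NA}.
#' @param threshold positive reversibility threshold in kJ/mol
#'   (default 15).
#' @return list of one or two directed-reaction objects, each a list
#'   with \code{id}, \code{source_id}, \code{direction}
#'   (\code{"forward"}/\code{"backward"}), \code{equation} (signed named
#'   coefficients), \code{dg}, and \code{reverse_of} (partner directed
#'   id or \code{NA}).
#' @export
assign_reversibility <- function(entry, dg = NA_real_, threshold = 15) {
  stopifnot(threshold > 0)
  if (!is.na(dg) && !is.finite(dg)) stop("non-finite delta G for ", entry$id)
  fwd <- list(id = entry$id, source_id = entry$id, direction = "forward",
              equation = entry$equation, dg = dg, reverse_of = NA_character_)
  if (is.na(dg)) {
    fwd$dg <- NA_real_
    return(list(fwd))
  }
  if (abs(dg) < threshold) {
    bid <- paste0(entry$id, "_r")
    bwd <- list(id = bid, source_id = entry$id, direction = "backward",
                equation = -entry$equation, dg = -dg, reverse_of = entry$id)
    fwd$reverse_of <- bid
    return(list(fwd, bwd))
  }
  if (dg <= -threshold) return(list(fwd))
  # strongly endergonic as written: run it backwards only
  list(list(id = paste0(entry$id, "_r"), source_id = entry$id,
            direction = "backward", equation = -entry$equation,
            dg = -dg, reverse_of = NA_character_))
}

#' Build the arc set from a reaction-pair table
#'
#' Arcs are directed substrate-to-product edges taken from curated
#' reaction pairs.  Only admitted pair categories (by default main and
#' trans pairs) are used, and arcs touching cofactors, excluded or
#' generic metabolites are dropped to prevent biologically meaningless
#' shortcuts.  For reversible (split) reactions each admitted arc also
#' exists reversed on the backward copy.
#'
#' @param pair_table data.frame with columns \code{reaction_id},
#'   \code{substrate_id}, \code{product_id}, \code{category}.
#' @param reactions list of directed reactions (from
#'   \code{\link{assign_reversibility}}).
#' @param admitted_categories pair categories to keep.
#' @param cofactors,excluded,generic metabolite id vectors whose
#'   members may not be arc endpoints.
#' @return data.frame of arcs: \code{substrate}, \code{product},
#'   \code{reaction} (directed id), \code{category}; one row per
#'   distinct (substrate, product, reaction) triple.
#' @export
build_arcs <- function(pair_table, reactions,
                       admitted_categories = c("main", "trans"),
                       cofactors = character(0),
                       excluded = character(0),
                       generic = character(0)) {
  need <- c("reaction_id", "substrate_id", "product_id", "category")
  if (!all(need %in% names(pair_table)))
    stop("pair table must have columns: ", paste(need, collapse = ", "))
  src_ids <- vapply(reactions, `[[`, character(1), "source_id")
  banned <- unique(c(cofactors, excluded, generic))
  out <- list()
  for (i in seq_len(nrow(pair_table))) {
    row <- pair_table[i, ]
    ks <- which(src_ids == row$reaction_id)
    if (!length(ks))
      stop("reaction pair references unknown reaction: ", row$reaction_id)
    if (!row$category %in% admitted_categories) next
    if (row$substrate_id %in% banned || row$product_id %in% banned) next
    for (k in ks) {
      rx <- reactions[[k]]
      if (rx$direction == "forward") {
        s <- row$substrate_id; p <- row$product_id
      } else {
        s <- row$product_id; p <- row$substrate_id
      }
      cs <- rx$equation[s]
      cp <- rx$equation[p]
      if (is.na(cs) || is.na(cp) || cs >= 0 || cp <= 0)
        stop("pair (", row$substrate_id, ", ", row$product_id,
             ") inconsistent with equation of ", rx$id)
      out[[length(out) + 1L]] <-
        data.frame(substrate = s, product = p, reaction = rx$id,
                   category = row$category, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(substrate = character(0), product = character(0),
                      reaction = character(0), category = character(0),
                      stringsAsFactors = FALSE))
  }
  arcs <- do.call(rbind, out)
  arcs[!duplicated(arcs[, c("substrate", "product", "reaction")]), ,
       drop = FALSE]
}

#' Categorise the metabolites of a network
#'
#' Derives the metabolite sets used by the pathway search: start
#' metabolites (arc members with molecular mass in the configured
#' bounds, plus the curated basis list), the basis subset, cofactors,
#' excluded (freely available) metabolites, the resulting metabolite
#' pool, and the remaining external metabolites which must be produced
#' and can never be taken up.
#'
#' @param metabolites character vector of all metabolite ids M.
#' @param arcs arc data.frame from \code{\link{build_arcs}}.
#' @param masses named numeric vector of molecular masses (may omit
#'   metabolites; those are conservatively never start metabolites).
#' @param basis,cofactors,excluded,generic curated id lists.
#' @param mass_bounds numeric length-2, half-open interval
#'   \code{(lower, upper]} for start-metabolite mass (default (0, 300]).
#' @return object of class \code{metabolite_categories}: list of sets
#'   \code{start}, \code{basis}, \code{cofactors}, \code{excluded},
#'   \code{pool}, \code{external}, \code{generic}.
#' @export
categorize_metabolites <- function(metabolites, arcs, masses = numeric(0),
                                   basis = character(0),
                                   cofactors = character(0),
                                   excluded = character(0),
                                   generic = character(0),
                                   mass_bounds = c(0, 300)) {
  stopifnot(length(mass_bounds) == 2, mass_bounds[1] < mass_bounds[2])
  missing_basis <- setdiff(basis, metabolites)
  if (length(missing_basis))
    stop("basis metabolite(s) absent from network: ",
         paste(missing_basis, collapse = ", "))
  in_arc <- unique(c(arcs$substrate, arcs$product))
  has_mass <- in_arc[in_arc %in% names(masses)]
  mass_ok <- has_mass[!is.na(masses[has_mass]) &
                        masses[has_mass] > mass_bounds[1] &
                        masses[has_mass] <= mass_bounds[2]]
  start <- sort(unique(c(mass_ok, basis)))
  cofactors <- intersect(sort(unique(cofactors)), metabolites)
  excluded <- intersect(sort(unique(excluded)), metabolites)
  generic <- intersect(sort(unique(generic)), metabolites)
  pool <- sort(unique(c(start, basis, cofactors, excluded)))
  external <- sort(setdiff(metabolites, pool))
  structure(list(start = start, basis = sort(unique(basis)),
                 cofactors = cofactors, excluded = excluded,
                 pool = pool, external = external, generic = generic),
            class = "metabolite_categories")
}

#' Build the sparse stoichiometric matrix of a directed-reaction set
#'
#' @param reactions list of directed reactions.
#' @param metabolites ordered metabolite ids (matrix rows).
#' @return sparse |M| x |R| \code{Matrix}; negative entries are
#'   reactants, positive are products; column r reproduces reaction r's
#'   equation.
#' @export
build_stoichiometric_matrix <- function(reactions, metabolites) {
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(reactions)) {
    eq <- reactions[[j]]$equation
    rows <- match(names(eq), metabolites)
    if (anyNA(rows))
      stop("reaction ", reactions[[j]]$id,
           " references metabolite outside the network")
    ii <- c(ii, rows); jj <- c(jj, rep.int(j, length(eq)))
    xx <- c(xx, unname(eq))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(metabolites), length(reactions)),
                       dimnames = list(metabolites,
                                       vapply(reactions, `[[`,
                                              character(1), "id")))
}

#' Assemble a metabolic network from parsed inputs
#'
#' Orchestrates the reconstruction: filters raw reaction entries,
#' assigns reversibility from the thermodynamics table, builds the arc
#' set from reaction pairs, categorises metabolites and computes the
#' stoichiometric matrix.
#'
#' @param entries list of \code{reaction_entry} (unfiltered).
#' @param pair_table reaction-pair data.frame (see
#'   \code{\link{build_arcs}}).
#' @param delta_g named numeric of source-reaction Gibbs energies
#'   (kJ/mol); reactions absent from it are irreversible forward.
#' @param masses named numeric of molecular masses.
#' @param basis,cofactors,excluded,generic curated id lists.
#' @param admitted_categories pair categories used for arcs.
#' @param dg_threshold reversibility threshold, kJ/mol.
#' @param mass_bounds start-metabolite mass interval (lower, upper].
#' @return object of class \code{metabolic_network}.
#' @export
reconstruct_network <- function(entries, pair_table,
                                delta_g = numeric(0),
                                masses = numeric(0),
                                basis = character(0),
                                cofactors = character(0),
                                excluded = character(0),
                                generic = character(0),
                                admitted_categories = c("main", "trans"),
                                dg_threshold = 15,
                                mass_bounds = c(0, 300)) {
  flt <- filter_reactions(entries)
  reactions <- list()
  for (e in flt$kept) {
    dg <- if (e$id %in% names(delta_g)) delta_g[[e$id]] else NA_real_
    reactions <- c(reactions, assign_reversibility(e, dg, dg_threshold))
  }
  kept_ids <- vapply(flt$kept, `[[`, character(1), "id")
  pair_table <- pair_table[pair_table$reaction_id %in% kept_ids |
                             !pair_table$reaction_id %in%
                               vapply(entries, `[[`, character(1), "id"), ,
                           drop = FALSE]
  arcs <- build_arcs(pair_table, reactions, admitted_categories,
                     cofactors, excluded, generic)
  metabolites <- sort(unique(unlist(lapply(reactions,
                                           function(r) names(r$equation)))))
  categories <- categorize_metabolites(metabolites, arcs, masses, basis,
                                       cofactors, excluded, generic,
                                       mass_bounds)
  new_metabolic_network(metabolites, reactions, arcs, categories,
                       masses, filter_log = flt$reasons)
}

new_metabolic_network <- function(metabolites, reactions, arcs, categories,
                                  masses = numeric(0),
                                  filter_log = NULL) {
  ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate directed reaction ids")
  stoich <- build_stoichiometric_matrix(reactions, metabolites)
  rev_of <- vapply(reactions, `[[`, character(1), "reverse_of")
  pairs <- which(!is.na(rev_of) & ids < rev_of)
  reverse_pairs <- data.frame(fwd = ids[pairs],
                              bwd = rev_of[pairs],
                              stringsAsFactors = FALSE)
  dg <- stats::setNames(vapply(reactions, function(r) {
    if (is.null(r$dg) || is.na(r$dg)) NA_real_ else r$dg
  }, numeric(1)), ids)
  bad <- !(arcs$reaction %in% ids)
  if (any(bad))
    stop("arc references unknown reaction: ",
         paste(unique(arcs$reaction[bad]), collapse = ", "))
  structure(list(metabolites = metabolites,
                 reactions = reactions,
                 reaction_ids = ids,
                 stoich = stoich,
                 arcs = arcs,
                 categories = categories,
                 delta_g = dg,
                 reverse_pairs = reverse_pairs,
                 masses = masses,
                 filter_log = filter_log),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network>", length(x$metabolites), "metabolites,",
      length(x$reactions), "directed reactions,", nrow(x$arcs), "arcs\n")
  cat("  pool:", length(x$categories$pool),
      " external:", length(x$categories$external),
      " start:", length(x$categories$start),
      " basis:", length(x$categories$basis), "\n")
  invisible(x)
}

# look up a directed reaction by id
get_reaction <- function(network, id) {
  k <- match(id, network$reaction_ids)
  if (is.na(k)) stop("unknown reaction id: ", id)
  network$reactions[[k]]
}
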