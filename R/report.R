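## Per-candidate reports: thermodynamic profile, overall reactant
## balance, potential side reactions in a host organism, and SBML
## export for visualisation.

#' Thermodynamic profile of a candidate's linear path
#'
#' Cumulative transformed Gibbs energy along the path steps.  Steps
#' whose reaction lacks thermodynamic data are flagged and contribute
#' nothing: the cumulative value carries forward.
#'
#' @param candidate a \code{pathway_solution}.
#' @param network the \code{metabolic_network}.
#' @return data.frame with columns \code{step}, \code{reaction},
#'   \code{substrate}, \code{product}, \code{dg} (NA when unknown),
#'   \code{dg_known}, \code{cumulative_dg}.
#' @export
thermodynamic_profile <- function(candidate, network) {
  lp <- candidate$linear_path
  if (!nrow(lp)) {
    return(data.frame(step = integer(0), reaction = character(0),
                      substrate = character(0), product = character(0),
                      dg = numeric(0), dg_known = logical(0),
                      cumulative_dg = numeric(0), stringsAsFactors = FALSE))
  }
  akeys <- arc_pair_key(network$arcs$substrate, network$arcs$product)
  cum <- 0
  rows <- lapply(seq_len(nrow(lp)), function(i) {
    key <- arc_pair_key(lp$substrate[i], lp$product[i])
    rs <- sort(intersect(unique(network$arcs$reaction[akeys == key]),
                         candidate$path_reactions))
    r <- rs[1L]
    dg <- get_reaction(network, r)$dg
    data.frame(step = i, reaction = r, substrate = lp$substrate[i],
               product = lp$product[i], dg = dg, dg_known = !is.na(dg),
               stringsAsFactors = FALSE)
  })
  prof <- do.call(rbind, rows)
  dgs <- ifelse(is.na(prof$dg), 0, prof$dg)
  prof$cumulative_dg <- cumsum(dgs)
  prof
}

#' Overall reactant balance of a pathway candidate
#'
#' Net production of every metabolite under the candidate's fluxes,
#' \code{sum_r S_mr v_r} over the active reactions.  Pool members may
#' be net-consumed; externals must come out non-negative and the
#' target at one unit or more.
#'
#' @param candidate a \code{pathway_solution}.
#' @param network the \code{metabolic_network}.
#' @param target target metabolite id (defaults to the last path node).
#' @return data.frame with columns \code{metabolite}, \code{balance},
#'   \code{role} (one of \code{"pool_consumed"}, \code{"pool"},
#'   \code{"external_produced"}, \code{"external"}, \code{"target"}),
#'   restricted to metabolites touched by active reactions.
#' @export
reactant_balance <- function(candidate, network, target = NULL) {
  if (is.null(target))
    target <- candidate$linear_path$product[nrow(candidate$linear_path)]
  v <- stats::setNames(numeric(length(network$reaction_ids)),
                       network$reaction_ids)
  v[names(candidate$fluxes)] <- candidate$fluxes
  v[!names(v) %in% candidate$active_reactions] <- 0
  bal <- as.numeric(network$stoich %*% v)
  names(bal) <- network$metabolites
  touched <- unique(unlist(lapply(candidate$active_reactions, function(r)
    names(get_reaction(network, r)$equation))))
  pool <- network$categories$pool
  rows <- lapply(sort(touched), function(m) {
    role <- if (m == target) "target"
    else if (m %in% pool) {
      if (bal[[m]] < 0) "pool_consumed" else "pool"
    } else {
      if (bal[[m]] > 0) "external_produced" else "external"
    }
    data.frame(metabolite = m, balance = bal[[m]], role = role,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Potential side reactions of a candidate in a host organism
#'
#' Lists every host reaction outside the candidate's active set that
#' consumes a pathway metabolite: a linear-path node (start,
#' intermediates), the target, or a product of a supplying reaction.
#' Cofactors and other freely available metabolites are not treated as
#' pathway carbon intermediates and do not trigger a listing.
#'
#' @param candidate a \code{pathway_solution}.
#' @param network the \code{metabolic_network}.
#' @param host_reactions host reaction ids (source, pre-split ids
#'   accepted).
#' @return data.frame with columns \code{reaction} (source id) and
#'   \code{metabolites} (comma-joined shared metabolites), one row per
#'   host reaction, sorted by reaction id.
#' @export
side_reactions <- function(candidate, network, host_reactions) {
  empty <- data.frame(reaction = character(0), metabolites = character(0),
                      stringsAsFactors = FALSE)
  if (!length(host_reactions)) return(empty)
  lp <- candidate$linear_path
  supplied <- unlist(lapply(candidate$supplying_reactions, function(r) {
    eq <- get_reaction(network, r)$equation
    names(eq)[eq > 0]
  }))
  relevant <- unique(c(lp$substrate, lp$product, supplied))
  relevant <- setdiff(relevant, c(network$categories$cofactors,
                                  network$categories$excluded))
  src <- vapply(network$reactions, `[[`, character(1), "source_id")
  in_host <- src %in% host_reactions | network$reaction_ids %in% host_reactions
  hits <- list()
  for (k in which(in_host)) {
    rid <- network$reaction_ids[k]
    if (rid %in% candidate$active_reactions) next
    eq <- network$reactions[[k]]$equation
    shared <- intersect(names(eq)[eq < 0], relevant)
    if (!length(shared)) next
    sid <- src[k]
    hits[[sid]] <- sort(unique(c(hits[[sid]], shared)))
  }
  if (!length(hits)) return(empty)
  out <- data.frame(reaction = names(hits),
                    metabolites = vapply(hits, paste, character(1),
                                         collapse = ","),
                    stringsAsFactors = FALSE)
  out <- out[order(out$reaction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# SBML SIds must match [A-Za-z_][A-Za-z0-9_]*; anything else is hex-
# escaped reversibly as _xHH_ (and "_x" itself is escaped first).
sanitize_sid <- function(x) {
  vapply(x, function(s) {
    s <- gsub("_x", "_x5fx", s, fixed = TRUE)
    chars <- vapply(strsplit(s, "")[[1]], function(ch) {
      if (grepl("[A-Za-z0-9_]", ch)) ch
      else sprintf("_x%02x_", utf8ToInt(ch))
    }, character(1))
    out <- paste(chars, collapse = "")
    if (grepl("^[0-9]", out)) out <- paste0("_", out)
    out
  }, character(1), USE.NAMES = FALSE)
}

unsanitize_sid <- function(x) {
  vapply(x, function(s) {
    s <- sub("^_([0-9])", "\\1", s)
    while (grepl("_x[0-9a-f]{2}_", s)) {
      hit <- regmatches(s, regexpr("_x[0-9a-f]{2}_", s))
      ch <- intToUtf8(strtoi(substr(hit, 3, 4), 16L))
      s <- sub(hit, ch, s, fixed = TRUE)
    }
    gsub("_x5fx", "_x", s, fixed = TRUE)
  }, character(1), USE.NAMES = FALSE)
}

#' Export a pathway candidate as an SBML Level 3 Version 1 document
#'
#' One species per metabolite appearing in the candidate's active
#' reactions (pool members marked as boundary species), one reaction
#' element per active reaction with its stoichiometry.  Identifiers
#' outside the SBML SId grammar are escaped reversibly.
#'
#' @param candidate a \code{pathway_solution}.
#' @param network the \code{metabolic_network}.
#' @param path optional output file; when \code{NULL} the document
#'   string is returned.
#' @return the SBML document as a character scalar (invisibly when
#'   written to a file).
#' @export
export_sbml <- function(candidate, network, path = NULL) {
  pool <- network$categories$pool
  mets <- sort(unique(unlist(lapply(candidate$active_reactions, function(r)
    names(get_reaction(network, r)$equation)))))
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1")
  model <- xml2::xml_add_child(doc, "model", id = "pathway_candidate")
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "c", constant = "true")
  los <- xml2::xml_add_child(model, "listOfSpecies")
  for (m in mets) {
    xml2::xml_add_child(los, "species",
                        id = sanitize_sid(m), name = m, compartment = "c",
                        boundaryCondition = tolower(m %in% pool),
                        hasOnlySubstanceUnits = "false", constant = "false")
  }
  lor <- xml2::xml_add_child(model, "listOfReactions")
  for (r in sort(candidate$active_reactions)) {
    eq <- get_reaction(network, r)$equation
    rx <- xml2::xml_add_child(lor, "reaction", id = sanitize_sid(r),
                              name = r, reversible = "false",
                              fast = "false")
    subs <- eq[eq < 0]
    prods <- eq[eq > 0]
    if (length(subs)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (i in seq_along(subs))
        xml2::xml_add_child(lr, "speciesReference",
                            species = sanitize_sid(names(subs)[i]),
                            stoichiometry = format(abs(subs[[i]])),
                            constant = "true")
    }
    if (length(prods)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (i in seq_along(prods))
        xml2::xml_add_child(lp, "speciesReference",
                            species = sanitize_sid(names(prods)[i]),
                            stoichiometry = format(prods[[i]]),
                            constant = "true")
    }
  }
  txt <- as.character(doc)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Parse an SBML document written by \code{\link{export_sbml}}
#'
#' @param text SBML document string or file path.
#' @return list with \code{species} (data.frame id, boundary) and
#'   \code{reactions} (named list of signed stoichiometry vectors,
#'   ids unescaped).
#' @export
read_sbml_pathway <- function(text) {
  doc <- xml2::read_xml(text)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core")
  sp <- xml2::xml_find_all(doc, ".//s:species", ns)
  species <- data.frame(
    id = unsanitize_sid(xml2::xml_attr(sp, "id")),
    boundary = xml2::xml_attr(sp, "boundaryCondition") == "true",
    stringsAsFactors = FALSE)
  rxn <- xml2::xml_find_all(doc, ".//s:reaction", ns)
  reactions <- stats::setNames(lapply(rxn, function(r) {
    subs <- xml2::xml_find_all(r, ".//s:listOfReactants/s:speciesReference", ns)
    prods <- xml2::xml_find_all(r, ".//s:listOfProducts/s:speciesReference", ns)
    eq <- c(stats::setNames(-as.numeric(xml2::xml_attr(subs, "stoichiometry")),
                            unsanitize_sid(xml2::xml_attr(subs, "species"))),
            stats::setNames(as.numeric(xml2::xml_attr(prods, "stoichiometry")),
                            unsanitize_sid(xml2::xml_attr(prods, "species"))))
    eq
  }), unsanitize_sid(xml2::xml_attr(rxn, "id")))
  list(species = species, reactions = reactions)
}

#' Write the full report bundle for ranked candidates
#'
#' Emits \code{ranked.tsv} plus, per candidate i in rank order,
#' \code{profile_i.tsv}, \code{balance_i.tsv}, \code{side_i.tsv} and
#' \code{candidate_i.sbml}.
#'
#' @param ranked output of \code{\link{rank_candidates}}.
#' @param network the \code{metabolic_network}.
#' @param dir output directory.
#' @param host_reactions host reaction id vector (may be empty).
#' @return invisibly, the path of \code{ranked.tsv}.
#' @export
write_candidate_reports <- function(ranked, network, dir,
                                    host_reactions = character(0)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- ranking_table(ranked)
  out <- file.path(dir, "ranked.tsv")
  utils::write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in ranked) {
    i <- s$rank_position
    utils::write.table(thermodynamic_profile(s$candidate, network),
                       file.path(dir, sprintf("profile_%d.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(reactant_balance(s$candidate, network),
                       file.path(dir, sprintf("balance_%d.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(side_reactions(s$candidate, network, host_reactions),
                       file.path(dir, sprintf("side_%d.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    export_sbml(s$candidate, network,
                file.path(dir, sprintf("candidate_%d.sbml", i)))
  }
  invisible(out)
}
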