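## Canonical JSON serialization of networks and pathway solutions, plus
## readers for the small tabular input formats (TSV tables, one-id-per-
## line lists).

#' Write a metabolic network to canonical JSON
#'
#' The interchange format consumed by the path-finding and ranking
#' steps: metabolites, directed reactions with coefficient maps,
#' arcs, category sets and Gibbs energies.  Output is deterministic
#' (fixed key order, no float rounding) so identical networks produce
#' byte-identical files.
#'
#' @param network a \code{metabolic_network}.
#' @param path output file path; if \code{NULL} the JSON string is
#'   returned instead.
#' @export
write_network_json <- function(network, path = NULL) {
  rx <- lapply(network$reactions, function(r) {
    list(id = r$id, source_id = r$source_id, direction = r$direction,
         metabolites = as.list(r$equation),
         dg = if (is.na(r$dg)) NULL else r$dg,
         reverse_of = if (is.na(r$reverse_of)) NULL else r$reverse_of)
  })
  obj <- list(
    metabolites = as.list(network$metabolites),
    reactions = rx,
    arcs = lapply(seq_len(nrow(network$arcs)), function(i) {
      as.list(network$arcs[i, c("substrate", "product",
                                "reaction", "category")])
    }),
    categories = lapply(unclass(network$categories), as.list),
    masses = as.list(network$masses)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = FALSE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Read a metabolic network from its canonical JSON form
#'
#' @param path file path, or a JSON string when \code{text = TRUE}.
#' @param text treat \code{path} as JSON text.
#' @return a \code{metabolic_network}.
#' @export
read_network_json <- function(path, text = FALSE) {
  obj <- jsonlite::fromJSON(if (text) path else paste(readLines(path, warn = FALSE),
                                                      collapse = "\n"),
                            simplifyVector = FALSE)
  reactions <- lapply(obj$reactions, function(r) {
    list(id = r$id, source_id = r$source_id, direction = r$direction,
         equation = unlist(r$metabolites),
         dg = if (is.null(r$dg)) NA_real_ else as.numeric(r$dg),
         reverse_of = if (is.null(r$reverse_of)) NA_character_ else r$reverse_of)
  })
  arcs <- if (length(obj$arcs)) {
    do.call(rbind, lapply(obj$arcs, function(a) {
      data.frame(substrate = a$substrate, product = a$product,
                 reaction = a$reaction, category = a$category,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(substrate = character(0), product = character(0),
               reaction = character(0), category = character(0),
               stringsAsFactors = FALSE)
  }
  cats <- lapply(obj$categories, function(v) as.character(unlist(v)))
  categories <- structure(cats, class = "metabolite_categories")
  masses <- unlist(obj$masses)
  if (is.null(masses)) masses <- numeric(0)
  new_metabolic_network(as.character(unlist(obj$metabolites)), reactions,
                       arcs, categories, masses)
}

#' Serialize pathway solutions to JSON
#'
#' @param solutions list of \code{pathway_solution}.
#' @param target target metabolite id.
#' @param path output path or \code{NULL} for a string.
#' @export
write_solutions_json <- function(solutions, target, path = NULL) {
  obj <- list(target = target,
              solutions = lapply(solutions, function(s) {
                list(start = s$start_metabolite,
                     path = lapply(seq_len(nrow(s$linear_path)), function(i) {
                       as.list(s$linear_path[i, c("substrate", "product")])
                     }),
                     path_reactions = as.list(s$path_reactions),
                     supplying_reactions = as.list(s$supplying_reactions),
                     active_reactions = as.list(s$active_reactions),
                     fluxes = as.list(s$fluxes[s$active_reactions]),
                     objective = s$objective)
              }))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Read pathway solutions written by \code{write_solutions_json}
#' @param path file path.
#' @return list with \code{target} and \code{solutions} (each a
#'   \code{pathway_solution}).
#' @export
read_solutions_json <- function(path) {
  obj <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE),
                                  collapse = "\n"), simplifyVector = FALSE)
  sols <- lapply(obj$solutions, function(s) {
    lp <- if (length(s$path)) {
      do.call(rbind, lapply(s$path, function(a) {
        data.frame(substrate = a$substrate, product = a$product,
                   stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(substrate = character(0), product = character(0),
                 stringsAsFactors = FALSE)
    }
    structure(list(linear_path = lp,
                   active_reactions = as.character(unlist(s$active_reactions)),
                   path_reactions = as.character(unlist(s$path_reactions)),
                   supplying_reactions = as.character(unlist(s$supplying_reactions)),
                   fluxes = unlist(s$fluxes),
                   start_metabolite = s$start,
                   objective = as.numeric(s$objective)),
              class = "pathway_solution")
  })
  list(target = obj$target, solutions = sols)
}

#' Read a simple TSV table
#' @param path file path.
#' @return data.frame with character columns as-is.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a one-id-per-line metabolite or reaction list
#'
#' Blank lines and lines starting with \code{#} are ignored.
#' @param path file path.
#' @return character vector of ids.
#' @export
read_id_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a thermodynamics table (reaction_id, drG_m_kJ_mol)
#'
#' Empty or NA energies are treated as missing.
#' @param path file path.
#' @return named numeric vector, possibly with NA entries dropped.
#' @export
read_thermo_table <- function(path) {
  tb <- read_tsv_table(path)
  need <- c("reaction_id", "drG_m_kJ_mol")
  if (!all(need %in% names(tb)))
    stop("thermodynamics table must have columns: ",
         paste(need, collapse = ", "))
  vals <- suppressWarnings(as.numeric(tb$drG_m_kJ_mol))
  keep <- !is.na(vals)
  stats::setNames(vals[keep], tb$reaction_id[keep])
}

#' Read a compound attribute table (id, name, mass)
#' @param path file path.
#' @return list with \code{masses} (named numeric) and \code{names}
#'   (named character).
#' @export
read_compound_table <- function(path) {
  tb <- read_tsv_table(path)
  if (!all(c("id", "mass") %in% names(tb)))
    stop("compound table must have columns: id, mass")
  mass <- suppressWarnings(as.numeric(tb$mass))
  keep <- !is.na(mass)
  list(masses = stats::setNames(mass[keep], tb$id[keep]),
       names = if ("name" %in% names(tb))
         stats::setNames(tb$name, tb$id) else character(0))
}
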