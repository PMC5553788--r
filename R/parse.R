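## Parsing of KEGG-flat-file-style REACTION records and a TSV dialect.
##
## Supported flat-file subset: records separated by "///", fields ENTRY,
## EQUATION and COMMENT starting in column 1, continuation lines
## indented.  The TSV dialect has a header line "id<TAB>equation<TAB>comment".
## Equation grammar (both dialects):
##   side ::= term (" + " term)*
##   term ::= [coefficient " "] compound_id
##   equation ::= side " <=> " side
## Integer coefficients are numeric; any non-integer coefficient token
## (e.g. "n", "n+1", "2n") marks the record as symbolic.

new_reaction_entry <- function(id, equation, comment_flags = character(0),
                               has_symbolic_coefficient = FALSE,
                               involves_glycan = FALSE) {
  stopifnot(length(equation) > 0, all(equation != 0))
  structure(
    list(id = id,
         equation = equation,
         comment_flags = comment_flags,
         has_symbolic_coefficient = has_symbolic_coefficient,
         involves_glycan = involves_glycan),
    class = "reaction_entry")
}

#' @export
print.reaction_entry <- function(x, ...) {
  subs <- names(x$equation)[x$equation < 0]
  prods <- names(x$equation)[x$equation > 0]
  cat("<reaction_entry>", x$id, ":",
      paste(subs, collapse = " + "), "<=>",
      paste(prods, collapse = " + "), "\n")
  invisible(x)
}

# Parse one equation string into a signed named coefficient vector plus
# symbolic/glycan flags.  Errors mention `id` so malformed records can
# be located in large files.
parse_equation <- function(eq, id) {
  sides <- strsplit(eq, "<=>", fixed = TRUE)[[1]]
  if (length(sides) != 2L)
    stop("malformed equation in record ", id, ": expected one '<=>'")
  symbolic <- FALSE
  glycan <- FALSE
  parse_side <- function(side, sign) {
    terms <- strsplit(side, " + ", fixed = TRUE)[[1]]
    terms <- trimws(terms)
    terms <- terms[nzchar(terms)]
    if (!length(terms))
      stop("malformed equation in record ", id, ": empty reaction side")
    coefs <- numeric(0)
    for (tm in terms) {
      toks <- strsplit(tm, "\\s+")[[1]]
      if (length(toks) == 1L) {
        cf <- 1
        met <- toks
      } else if (length(toks) == 2L) {
        if (grepl("^[0-9]+$", toks[1L])) {
          cf <- as.numeric(toks[1L])
        } else {
          symbolic <<- TRUE
          cf <- 1
        }
        met <- toks[2L]
      } else {
        stop("malformed equation in record ", id, ": term '", tm, "'")
      }
      if (!grepl("^[A-Za-z]", met))
        stop("malformed equation in record ", id, ": compound '", met, "'")
      if (startsWith(met, "G")) glycan <<- TRUE
      coefs[met] <- if (met %in% names(coefs)) coefs[[met]] + sign * cf else sign * cf
    }
    coefs
  }
  lhs <- parse_side(sides[1L], -1)
  rhs <- parse_side(sides[2L], +1)
  both <- intersect(names(lhs), names(rhs))
  if (length(both))
    stop("malformed equation in record ", id,
         ": metabolite on both sides: ", paste(both, collapse = ", "))
  list(equation = c(lhs, rhs), symbolic = symbolic, glycan = glycan)
}

#' Parse reaction records from KEGG-style flat-file text or TSV
#'
#' @param text character scalar (whole file) or vector of lines; or a
#'   file path when \code{is_path = TRUE}.
#' @param format \code{"auto"} (detect: a leading ENTRY field means
#'   flat-file), \code{"kegg"} or \code{"tsv"}.
#' @param is_path read \code{text} from disk first.
#'
#' @return a list of \code{reaction_entry} objects, one per record, with
#'   equations parsed into signed stoichiometric coefficient vectors
#'   (negative = substrate), lowercased comment keywords, and flags for
#'   symbolic coefficients ("n") and glycan ("G" number) participation.
#' @export
parse_reaction_file <- function(text, format = c("auto", "kegg", "tsv"),
                                is_path = FALSE) {
  format <- match.arg(format)
  if (is_path) text <- readLines(text, warn = FALSE)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  if (format == "auto") {
    first <- lines[nzchar(trimws(lines))][1]
    format <- if (!is.na(first) && grepl("^ENTRY", first)) "kegg" else "tsv"
  }
  if (format == "kegg") parse_kegg_flat(lines) else parse_reaction_tsv(lines)
}

parse_kegg_flat <- function(lines) {
  entries <- list()
  fields <- list()
  cur <- NULL
  flush_record <- function(fields) {
    if (!length(fields)) return(NULL)
    id <- trimws(strsplit(trimws(fields$ENTRY %||% ""), "\\s+")[[1]][1])
    if (!nzchar(id) || is.na(id)) stop("record without ENTRY field")
    if (is.null(fields$EQUATION))
      stop("malformed record ", id, ": missing EQUATION")
    pq <- parse_equation(trimws(fields$EQUATION), id)
    flags <- character(0)
    if (!is.null(fields$COMMENT)) {
      words <- strsplit(tolower(fields$COMMENT), "[^a-z]+")[[1]]
      flags <- unique(words[nzchar(words)])
    }
    new_reaction_entry(id, pq$equation, flags, pq$symbolic, pq$glycan)
  }
  for (ln in lines) {
    if (grepl("^///", ln)) {
      ent <- flush_record(fields)
      if (!is.null(ent)) entries[[length(entries) + 1L]] <- ent
      fields <- list()
      cur <- NULL
    } else if (grepl("^[A-Z][A-Z_]*(\\s|$)", ln)) {
      key <- sub("^([A-Z_]+).*$", "\\1", ln)
      val <- trimws(sub("^[A-Z_]+\\s*", "", ln))
      fields[[key]] <- if (is.null(fields[[key]])) val else paste(fields[[key]], val)
      cur <- key
    } else if (grepl("^\\s+\\S", ln) && !is.null(cur)) {
      fields[[cur]] <- paste(fields[[cur]], trimws(ln))
    }
  }
  ent <- flush_record(fields)
  if (!is.null(ent)) entries[[length(entries) + 1L]] <- ent
  entries
}

parse_reaction_tsv <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(list())
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
  need <- c("id", "equation")
  if (!all(need %in% header))
    stop("reaction TSV must have 'id' and 'equation' columns")
  entries <- list()
  for (ln in lines[-1L]) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    rec <- stats::setNames(as.list(parts), header[seq_along(parts)])
    id <- rec$id
    pq <- parse_equation(rec$equation, id)
    flags <- character(0)
    if (!is.null(rec$comment) && nzchar(rec$comment)) {
      words <- strsplit(tolower(rec$comment), "[^a-z]+")[[1]]
      flags <- unique(words[nzchar(words)])
    }
    entries[[length(entries) + 1L]] <-
      new_reaction_entry(id, pq$equation, flags, pq$symbolic, pq$glycan)
  }
  entries
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize reaction entries back to KEGG-style flat-file text
#'
#' Inverse of \code{\link{parse_reaction_file}} up to whitespace; used
#' for fixture generation and round-trip testing.
#'
#' @param entries list of \code{reaction_entry}.
#' @return character scalar of flat-file text.
#' @export
serialize_reaction_entries <- function(entries) {
  fmt_side <- function(eq, neg) {
    part <- eq[if (neg) eq < 0 else eq > 0]
    paste(vapply(seq_along(part), function(i) {
      cf <- abs(part[[i]])
      if (cf == 1) names(part)[i] else paste(cf, names(part)[i])
    }, character(1)), collapse = " + ")
  }
  blocks <- vapply(entries, function(e) {
    eqn <- paste(fmt_side(e$equation, TRUE), "<=>", fmt_side(e$equation, FALSE))
    lines <- c(sprintf("ENTRY       %-20s Reaction", e$id),
               paste0("EQUATION    ", eqn))
    if (length(e$comment_flags))
      lines <- c(lines, paste0("COMMENT     ",
                               paste(e$comment_flags, collapse = " ")))
    paste(c(lines, "///"), collapse = "\n")
  }, character(1))
  paste0(paste(blocks, collapse = "\n"), "\n")
}

#' Apply curated exclusion filters to parsed reactions
#'
#' Rejects reactions flagged in their comments as generic or incomplete,
#' reactions with symbolic ("n") stoichiometric coefficients, and
#' reactions involving glycans (G-number compounds).  Each rejected
#' record carries exactly one reason code with fixed precedence
#' comment > symbolic > glycan.
#'
#' @param entries list of \code{reaction_entry}.
#' @return list with \code{kept} (list of entries), \code{rejected}
#'   (list of entries) and \code{reasons} (data.frame id, reason).
#' @export
filter_reactions <- function(entries) {
  kept <- list()
  rejected <- list()
  ids <- character(0)
  reasons <- character(0)
  for (e in entries) {
    reason <- NA_character_
    if (any(c("generic", "incomplete") %in% e$comment_flags)) {
      reason <- "comment"
    } else if (isTRUE(e$has_symbolic_coefficient)) {
      reason <- "symbolic"
    } else if (isTRUE(e$involves_glycan)) {
      reason <- "glycan"
    }
    if (is.na(reason)) {
      kept[[length(kept) + 1L]] <- e
    } else {
      rejected[[length(rejected) + 1L]] <- e
      ids <- c(ids, e$id)
      reasons <- c(reasons, reason)
    }
  }
  list(kept = kept, rejected = rejected,
       reasons = data.frame(id = ids, reason = reasons,
                            stringsAsFactors = FALSE))
}
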