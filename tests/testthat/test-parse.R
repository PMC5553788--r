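test_that("flat-file records parse into signed coefficient pairs", {
  txt <- paste(
    "ENTRY       R00200              Reaction",
    "EQUATION    C00031 + C00002 <=> C00092 + C00008",
    "COMMENT     glycolysis step",
    "///", sep = "\n")
  entries <- parse_reaction_file(txt)
  expect_length(entries, 1)
  e <- entries[[1]]
  expect_equal(e$id, "R00200")
  expect_equal(sort(names(e$equation)),
               c("C00002", "C00008", "C00031", "C00092"))
  expect_equal(unname(e$equation[c("C00031", "C00002", "C00092", "C00008")]),
               c(-1, -1, 1, 1))
  expect_true("glycolysis" %in% e$comment_flags)
  expect_false(e$has_symbolic_coefficient)
  expect_false(e$involves_glycan)
})

test_that("symbolic coefficients, glycans and integer coefficients are flagged", {
  txt <- paste(
    "ENTRY       R00001              Reaction",
    "EQUATION    n C00031 <=> n C00092",
    "///",
    "ENTRY       R00002              Reaction",
    "EQUATION    G00001 + C00001 <=> C00002",
    "///",
    "ENTRY       R00003              Reaction",
    "EQUATION    2 C00031 <=> C00092",
    "///", sep = "\n")
  entries <- parse_reaction_file(txt)
  expect_true(entries[[1]]$has_symbolic_coefficient)
  expect_true(entries[[2]]$involves_glycan)
  expect_false(entries[[3]]$has_symbolic_coefficient)
  expect_equal(entries[[3]]$equation[["C00031"]], -2)
})

test_that("TSV dialect parses equivalently to the flat file", {
  tsv <- paste("id\tequation\tcomment",
               "R10\tC00001 + 2 C00002 <=> C00003\tgeneric something",
               sep = "\n")
  kegg <- paste("ENTRY       R10                 Reaction",
                "EQUATION    C00001 + 2 C00002 <=> C00003",
                "COMMENT     generic something",
                "///", sep = "\n")
  a <- parse_reaction_file(tsv)[[1]]
  b <- parse_reaction_file(kegg)[[1]]
  expect_equal(a$equation, b$equation)
  expect_equal(a$comment_flags, b$comment_flags)
  expect_true("generic" %in% a$comment_flags)
})

test_that("malformed equations raise errors naming the record", {
  txt <- paste("ENTRY       RBAD                Reaction",
               "EQUATION    C00001 + C00002", "///", sep = "\n")
  expect_error(parse_reaction_file(txt), "RBAD")
  txt2 <- paste("ENTRY       RBOTH               Reaction",
                "EQUATION    C00001 <=> C00001 + C00002", "///", sep = "\n")
  expect_error(parse_reaction_file(txt2), "RBOTH")
})

test_that("parse -> serialize -> parse is the identity on entry fields", {
  txt <- paste(
    "ENTRY       R00200              Reaction",
    "EQUATION    C00031 + 2 C00002 <=> C00092 + C00008",
    "///",
    "ENTRY       R00300              Reaction",
    "EQUATION    C00001 <=> 3 C00009",
    "COMMENT     incomplete",
    "///", sep = "\n")
  e1 <- parse_reaction_file(txt)
  e2 <- parse_reaction_file(serialize_reaction_entries(e1))
  expect_equal(length(e1), length(e2))
  for (i in seq_along(e1)) {
    expect_equal(e1[[i]]$id, e2[[i]]$id)
    expect_equal(sort(names(e1[[i]]$equation)), sort(names(e2[[i]]$equation)))
    expect_equal(e1[[i]]$equation[sort(names(e1[[i]]$equation))],
                 e2[[i]]$equation[sort(names(e2[[i]]$equation))])
    expect_equal(e1[[i]]$comment_flags, e2[[i]]$comment_flags)
  }
})

test_that("exclusion filters reject with single reason codes by precedence", {
  mk <- function(id, flags = character(0), sym = FALSE, gly = FALSE)
    pathcascade:::new_reaction_entry(id, c(A = -1, B = 1), flags, sym, gly)
  entries <- list(
    mk("R1", flags = "incomplete"),
    mk("R2", flags = "generic"),
    mk("R3", sym = TRUE),
    mk("R4", gly = TRUE),
    mk("R5"),
    mk("R6", flags = "generic", sym = TRUE, gly = TRUE))
  res <- filter_reactions(entries)
  expect_equal(vapply(res$kept, `[[`, character(1), "id"), "R5")
  expect_equal(res$reasons$reason,
               c("comment", "comment", "symbolic", "glycan", "comment"))
  # completeness and disjointness
  all_ids <- vapply(entries, `[[`, character(1), "id")
  expect_setequal(c(vapply(res$kept, `[[`, character(1), "id"),
                    res$reasons$id), all_ids)
  expect_length(intersect(vapply(res$kept, `[[`, character(1), "id"),
                          res$reasons$id), 0)
  # precedence: symbolic beats glycan when both apply
  both <- filter_reactions(list(mk("R7", sym = TRUE, gly = TRUE)))
  expect_equal(both$reasons$reason, "symbolic")
})
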