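## Exact small-scale linear and mixed-integer linear programming.
##
## The pathway-search models solved here are small (tens of binaries,
## tens of continuous fluxes, a few hundred constraints), so the package
## ships its own exact solver: a dense two-phase primal simplex with an
## anti-cycling (Bland) fallback, wrapped in a depth-first
## branch-and-bound over the binary variables.  All variables are
## non-negative; upper bounds are expressed as constraint rows.

#' Solve a linear program with the two-phase primal simplex method
#'
#' Minimises \code{obj \%*\% x} subject to \code{A x (sense) b} and
#' \code{x >= 0}.  Intended for the small dense programs produced by the
#' pathway MILP; sizes beyond a few hundred rows/columns will be slow.
#'
#' @param obj numeric objective coefficient vector (length n).
#' @param A dense constraint matrix (m x n).
#' @param sense character vector of length m, each \code{"<="},
#'   \code{">="} or \code{"=="}.
#' @param b numeric right-hand side (length m).
#' @param tol feasibility/reduced-cost tolerance.
#' @param piv_tol minimum admissible pivot magnitude (larger than
#'   \code{tol} to keep the tableau well conditioned).
#' @param max_iter iteration cap across both phases.
#'
#' @return a list with \code{status} (\code{"optimal"},
#'   \code{"infeasible"} or \code{"unbounded"}), \code{x} (primal
#'   solution, length n) and \code{objective}.
#' @keywords internal
simplex_lp <- function(obj, A, sense, b, tol = 1e-9, piv_tol = 1e-7,
                       max_iter = 20000L) {
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(sense) == m)
  if (m == 0L) {
    # unconstrained except x >= 0: bounded iff obj >= 0
    if (any(obj < -tol)) return(list(status = "unbounded", x = NULL, objective = -Inf))
    return(list(status = "optimal", x = numeric(n), objective = 0))
  }

  # equilibrate rows: unit max-norm improves pivot conditioning when
  # constraint magnitudes differ widely (e.g. big-M flux caps)
  rmax <- apply(abs(A), 1, max)
  rmax[rmax == 0] <- 1
  A <- A / rmax
  b <- b / rmax

  # normalise to b >= 0
  flip <- b < 0
  if (any(flip)) {
    A[flip, , drop = FALSE] -> Af
    A[flip, ] <- -Af
    b[flip] <- -b[flip]
    sense[flip] <- c("<=" = ">=", ">=" = "<=", "==" = "==")[sense[flip]]
  }

  n_slack <- sum(sense != "==")
  # artificials for ">=" and "==" rows
  art_rows <- which(sense != "<=")
  n_art <- length(art_rows)

  ncol_tot <- n + n_slack + n_art
  Tb <- matrix(0, m, ncol_tot + 1L)
  Tb[, seq_len(n)] <- A
  Tb[, ncol_tot + 1L] <- b

  basis <- integer(m)
  sj <- 0L
  for (i in seq_len(m)) {
    if (sense[i] == "<=") {
      sj <- sj + 1L
      Tb[i, n + sj] <- 1
      basis[i] <- n + sj
    } else if (sense[i] == ">=") {
      sj <- sj + 1L
      Tb[i, n + sj] <- -1
    }
  }
  aj <- 0L
  for (i in art_rows) {
    aj <- aj + 1L
    Tb[i, n + n_slack + aj] <- 1
    basis[i] <- n + n_slack + aj
  }
  art_cols <- if (n_art > 0L) (n + n_slack + 1L):ncol_tot else integer(0)

  pivot <- function(Tb, cost, pr, pc) {
    piv <- Tb[pr, pc]
    Tb[pr, ] <- Tb[pr, ] / piv
    fac <- Tb[, pc]
    fac[pr] <- 0
    nz <- which(abs(fac) > 0)
    if (length(nz))
      Tb[nz, ] <- Tb[nz, , drop = FALSE] - outer(fac[nz], Tb[pr, ])
    cfac <- cost[pc]
    if (abs(cfac) > 0) cost <- cost - cfac * Tb[pr, ]
    list(Tb = Tb, cost = cost)
  }

  run_phase <- function(Tb, basis, cost, active_cols, iter_left) {
    it <- 0L
    bland_after <- 3L * (m + length(active_cols))
    repeat {
      it <- it + 1L
      if (it > iter_left) stop("simplex iteration limit exceeded")
      red <- cost[active_cols]
      cand <- which(red < -tol)
      if (!length(cand)) {
        return(list(Tb = Tb, basis = basis, cost = cost, status = "optimal",
                    iters = it))
      }
      bland <- it > bland_after
      pc <- if (bland) active_cols[cand[1L]]
            else active_cols[cand[which.min(red[cand])]]
      col <- Tb[, pc]
      pos <- which(col > piv_tol)
      if (!length(pos)) {
        return(list(Tb = Tb, basis = basis, cost = cost, status = "unbounded",
                    iters = it))
      }
      ratios <- pmax(Tb[pos, ncol_tot + 1L], 0) / col[pos]
      rmin <- min(ratios)
      tied <- pos[ratios <= rmin + tol]
      # prefer the numerically largest pivot among tied rows; fall back
      # to Bland's least-index rule in the anti-cycling regime
      pr <- if (bland) tied[which.min(basis[tied])]
            else tied[which.max(col[tied])]
      res <- pivot(Tb, cost, pr, pc)
      Tb <- res$Tb
      cost <- res$cost
      basis[pr] <- pc
    }
  }

  reduce_cost <- function(Tb, basis, raw_cost) {
    cost <- c(raw_cost, 0)
    for (i in seq_len(m)) {
      cb <- cost[basis[i]]
      if (abs(cb) > 0) cost <- cost - cb * Tb[i, ]
    }
    cost
  }

  iters_used <- 0L
  if (n_art > 0L) {
    raw1 <- numeric(ncol_tot)
    raw1[art_cols] <- 1
    cost1 <- reduce_cost(Tb, basis, raw1)
    ph1 <- run_phase(Tb, basis, cost1, seq_len(ncol_tot), max_iter)
    if (ph1$status != "optimal") stop("phase-1 simplex did not converge")
    iters_used <- ph1$iters
    Tb <- ph1$Tb; basis <- ph1$basis
    ph1_obj <- -ph1$cost[ncol_tot + 1L]
    if (ph1_obj > 1e-7) {
      return(list(status = "infeasible", x = NULL, objective = NA_real_))
    }
    # drive remaining artificials out of the basis
    drop_rows <- integer(0)
    for (i in seq_len(m)) {
      if (basis[i] %in% art_cols) {
        row <- Tb[i, seq_len(n + n_slack)]
        nz <- which(abs(row) > piv_tol)
        if (length(nz)) {
          res <- pivot(Tb, ph1$cost, i, nz[1L])
          Tb <- res$Tb
          basis[i] <- nz[1L]
        } else {
          drop_rows <- c(drop_rows, i)  # redundant row
        }
      }
    }
    if (length(drop_rows)) {
      Tb <- Tb[-drop_rows, , drop = FALSE]
      basis <- basis[-drop_rows]
      m <- nrow(Tb)
    }
  }

  # phase 2 on structural + slack columns only
  keep <- c(seq_len(n + n_slack), ncol_tot + 1L)
  Tb2 <- Tb[, keep, drop = FALSE]
  ncol_tot <- n + n_slack  # run_phase closes over ncol_tot
  raw2 <- c(obj, numeric(n_slack))
  cost2 <- {
    cost <- c(raw2, 0)
    for (i in seq_len(m)) {
      cb <- cost[basis[i]]
      if (abs(cb) > 0) cost <- cost - cb * Tb2[i, ]
    }
    cost
  }
  ph2 <- run_phase(Tb2, basis, cost2, seq_len(ncol_tot), max_iter - iters_used)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, objective = -Inf))
  }
  Tb2 <- ph2$Tb; basis <- ph2$basis
  x <- numeric(n + n_slack)
  x[basis] <- Tb2[, ncol_tot + 1L]
  xs <- x[seq_len(n)]
  list(status = "optimal", x = xs, objective = sum(obj * xs))
}

#' Construct an empty mixed-integer linear model
#'
#' The model is an ordered collection of named variables (continuous or
#' binary, all with lower bound 0) plus linear constraints, minimised.
#' Binary upper bounds are materialised as constraint rows when solving.
#'
#' @return an object of class \code{milp_model} (an environment).
#' @export
milp_model <- function() {
  e <- new.env(parent = emptyenv())
  e$var_names <- character(0)
  e$vtype <- character(0)      # "C" or "B"
  e$obj <- numeric(0)
  e$cons <- list()             # list(idx, coef, sense, rhs, label)
  class(e) <- "milp_model"
  e
}

#' Add a variable to a model
#' @param model a \code{milp_model}.
#' @param name unique variable name.
#' @param type \code{"C"} (continuous, >= 0) or \code{"B"} (binary).
#' @param obj objective coefficient.
#' @return the (1-based) column index of the new variable, invisibly.
#' @export
milp_add_var <- function(model, name, type = c("C", "B"), obj = 0) {
  type <- match.arg(type)
  if (name %in% model$var_names) stop("duplicate variable name: ", name)
  model$var_names <- c(model$var_names, name)
  model$vtype <- c(model$vtype, type)
  model$obj <- c(model$obj, obj)
  invisible(length(model$var_names))
}

#' Add a linear constraint to a model
#' @param model a \code{milp_model}.
#' @param idx integer column indices (or variable names).
#' @param coef coefficients, same length as \code{idx}.
#' @param sense one of \code{"<="}, \code{">="}, \code{"=="}.
#' @param rhs right-hand side scalar.
#' @param label optional human-readable tag used in diagnostics.
#' @export
milp_add_constraint <- function(model, idx, coef, sense, rhs, label = "") {
  if (is.character(idx)) idx <- match(idx, model$var_names)
  if (anyNA(idx)) stop("constraint references unknown variable")
  stopifnot(length(idx) == length(coef), sense %in% c("<=", ">=", "=="))
  model$cons[[length(model$cons) + 1L]] <-
    list(idx = as.integer(idx), coef = as.numeric(coef), sense = sense,
         rhs = as.numeric(rhs), label = label)
  invisible(length(model$cons))
}

# Dense matrix realisation of the model; binaries get an x <= 1 row.
milp_realise <- function(model) {
  n <- length(model$var_names)
  bin <- which(model$vtype == "B")
  m <- length(model$cons) + length(bin)
  A <- matrix(0, m, n)
  sense <- character(m)
  b <- numeric(m)
  for (i in seq_along(model$cons)) {
    cn <- model$cons[[i]]
    A[i, cn$idx] <- A[i, cn$idx] + cn$coef
    sense[i] <- cn$sense
    b[i] <- cn$rhs
  }
  off <- length(model$cons)
  for (k in seq_along(bin)) {
    A[off + k, bin[k]] <- 1
    sense[off + k] <- "<="
    b[off + k] <- 1
  }
  list(A = A, sense = sense, b = b, bin = bin, n = n)
}

#' Solve a mixed-integer linear model by branch-and-bound
#'
#' Depth-first branch-and-bound over the binary variables with LP
#' relaxations solved by \code{\link{simplex_lp}}.  Deterministic:
#' branching selects the most fractional binary (lowest index on ties)
#' and explores the rounded value first.
#'
#' @param model a \code{milp_model}.
#' @param int_tol integrality tolerance for reading binaries.
#' @param gap_tol pruning tolerance on objective bounds.
#' @return list with \code{status} (\code{"optimal"} or
#'   \code{"infeasible"}), \code{x} (named vector) and \code{objective}.
#' @export
milp_solve <- function(model, int_tol = 1e-6, gap_tol = 1e-7) {
  rl <- milp_realise(model)
  n <- rl$n
  best_obj <- Inf
  best_x <- NULL

  # node = list of (var index, fixed value) pairs
  solve_node <- function(fixes) {
    extra <- length(fixes)
    if (extra) {
      Afix <- matrix(0, extra, n)
      bfix <- numeric(extra)
      for (k in seq_len(extra)) {
        Afix[k, fixes[[k]][1L]] <- 1
        bfix[k] <- fixes[[k]][2L]
      }
      A <- rbind(rl$A, Afix)
      sense <- c(rl$sense, rep("==", extra))
      b <- c(rl$b, bfix)
    } else {
      A <- rl$A; sense <- rl$sense; b <- rl$b
    }
    simplex_lp(model$obj, A, sense, b)
  }

  stack <- list(list())
  while (length(stack)) {
    fixes <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    sol <- solve_node(fixes)
    if (sol$status != "optimal") next
    if (sol$objective >= best_obj - gap_tol) next
    xb <- sol$x[rl$bin]
    frac <- abs(xb - round(xb))
    if (all(frac <= int_tol)) {
      x <- sol$x
      x[rl$bin] <- round(xb)
      best_obj <- sol$objective
      best_x <- x
      next
    }
    j <- rl$bin[which.max(frac)]
    v0 <- round(sol$x[j])
    # push far branch first so near branch is explored next (LIFO)
    stack[[length(stack) + 1L]] <- c(fixes, list(c(j, 1 - v0)))
    stack[[length(stack) + 1L]] <- c(fixes, list(c(j, v0)))
  }

  if (is.null(best_x)) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  names(best_x) <- model$var_names
  list(status = "optimal", x = best_x, objective = best_obj)
}
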