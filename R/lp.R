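# Dense two-phase primal simplex used by the flux-balance routines and the
# branch-and-bound solver.  Written for robustness at desk scale rather
# than speed: rows are rescaled, the pivot rule falls back from Dantzig to
# Bland's rule (which cannot cycle) after a fixed number of iterations, and
# degenerate ties in the ratio test are broken toward the smallest basis
# index.

LP_TOL <- 1e-8

#' @title Dense linear-programming kernel
#' @description Solves `min/max objective'x` over `x >= 0` subject to
#'   `A_le x <= b_le`, `A_ge x >= b_ge`, `A_eq x == b_eq` with a two-phase
#'   primal simplex.  All variables are implicitly non-negative; upper
#'   bounds must be supplied as `<=` rows.
#' @param objective numeric objective coefficients.
#' @param A_le,b_le inequality block `A_le %*% x <= b_le` (may be `NULL`).
#' @param A_ge,b_ge inequality block `A_ge %*% x >= b_ge` (may be `NULL`).
#' @param A_eq,b_eq equality block `A_eq %*% x == b_eq` (may be `NULL`).
#' @param maximize maximize instead of minimize.
#' @return list with `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `value` (objective at the optimum) and `x`.
#' @keywords internal
lp_solve <- function(objective, A_le = NULL, b_le = NULL,
                     A_ge = NULL, b_ge = NULL,
                     A_eq = NULL, b_eq = NULL, maximize = FALSE) {
  n <- length(objective)
  blocks <- list(list(A = A_le, b = b_le, sense = "<="),
                 list(A = A_ge, b = b_ge, sense = ">="),
                 list(A = A_eq, b = b_eq, sense = "=="))
  A <- NULL; b <- numeric(0); sense <- character(0)
  for (blk in blocks) {
    if (is.null(blk$A)) next
    Ab <- as.matrix(blk$A)
    storage.mode(Ab) <- "double"
    A <- rbind(A, Ab)
    b <- c(b, as.numeric(blk$b))
    sense <- c(sense, rep(blk$sense, nrow(Ab)))
  }
  m <- length(b)
  obj <- if (maximize) -objective else objective
  # normalize: non-negative right-hand sides, scaled rows
  for (i in seq_len(m)) {
    if (b[i] < 0) {
      A[i, ] <- -A[i, ]; b[i] <- -b[i]
      sense[i] <- switch(sense[i], "<=" = ">=", ">=" = "<=", "==" = "==")
    }
    sc <- max(abs(A[i, ]), abs(b[i]), 1)
    A[i, ] <- A[i, ] / sc; b[i] <- b[i] / sc
  }
  n_slack <- sum(sense == "<=")
  n_surp <- sum(sense == ">=")
  n_art <- sum(sense != "<=")
  ncols <- n + n_slack + n_surp + n_art
  Tb <- matrix(0, m, ncols + 1L)
  Tb[, seq_len(n)] <- A
  Tb[, ncols + 1L] <- b
  basis <- integer(m)
  si <- n; ui <- n + n_slack; ai <- n + n_slack + n_surp
  art_cols <- integer(0)
  for (i in seq_len(m)) {
    if (sense[i] == "<=") {
      si <- si + 1L; Tb[i, si] <- 1; basis[i] <- si
    } else {
      if (sense[i] == ">=") { ui <- ui + 1L; Tb[i, ui] <- -1 }
      ai <- ai + 1L; Tb[i, ai] <- 1; basis[i] <- ai
      art_cols <- c(art_cols, ai)
    }
  }
  # phase 1: minimize the artificial sum
  if (length(art_cols)) {
    c1 <- numeric(ncols); c1[art_cols] <- 1
    ph1 <- simplex_iterate(Tb, basis, c1, ncols)
    if (ph1$status == "unbounded") return(list(status = "infeasible",
                                               value = NA_real_, x = NULL))
    Tb <- ph1$T; basis <- ph1$basis
    if (ph1$value > 1e-7) {
      return(list(status = "infeasible", value = NA_real_, x = NULL))
    }
    # pivot residual artificials out of the basis where possible
    for (i in which(basis %in% art_cols)) {
      piv <- which(abs(Tb[i, seq_len(n + n_slack + n_surp)]) > LP_TOL)
      if (length(piv)) {
        pc <- piv[1]
        Tb[i, ] <- Tb[i, ] / Tb[i, pc]
        for (r in seq_len(nrow(Tb))[-i]) {
          if (abs(Tb[r, pc]) > 0) Tb[r, ] <- Tb[r, ] - Tb[r, pc] * Tb[i, ]
        }
        basis[i] <- pc
      }
    }
    Tb[, art_cols] <- 0  # artificials may never re-enter
  }
  c2 <- c(obj, numeric(ncols - n))
  ph2 <- simplex_iterate(Tb, basis, c2, ncols)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", value = NA_real_, x = NULL))
  }
  x <- numeric(ncols)
  x[ph2$basis] <- ph2$T[, ncols + 1L]
  value <- sum(c2 * x)
  list(status = "optimal", value = if (maximize) -value else value,
       x = x[seq_len(n)])
}

simplex_iterate <- function(Tb, basis, costs, ncols,
                            bland_after = 500L, max_iter = 20000L) {
  m <- nrow(Tb)
  red <- costs - as.numeric(costs[basis] %*% Tb[, seq_len(ncols), drop = FALSE])
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) stop("simplex iteration limit exceeded")
    candidates <- which(red < -LP_TOL)
    if (!length(candidates)) break
    pc <- if (iter <= bland_after) candidates[which.min(red[candidates])]
          else candidates[1L]                       # Bland's rule
    col <- Tb[, pc]
    pos <- which(col > LP_TOL)
    if (!length(pos)) {
      return(list(status = "unbounded", T = Tb, basis = basis,
                  value = NA_real_))
    }
    ratios <- Tb[pos, ncols + 1L] / col[pos]
    best <- min(ratios)
    tied <- pos[ratios <= best + LP_TOL * (1 + abs(best))]
    pr <- tied[which.min(basis[tied])]
    pivot <- Tb[pr, pc]
    Tb[pr, ] <- Tb[pr, ] / pivot
    prow <- Tb[pr, ]
    upd <- which(abs(Tb[, pc]) > 0); upd <- upd[upd != pr]
    if (length(upd)) Tb[upd, ] <- Tb[upd, ] - outer(Tb[upd, pc], prow)
    red <- red - red[pc] * prow[seq_len(ncols)]
    basis[pr] <- pc
    Tb[, pc] <- 0; Tb[pr, pc] <- 1; red[pc] <- 0  # squash drift
  }
  value <- sum(costs[basis] * Tb[, ncols + 1L])
  list(status = "optimal", T = Tb, basis = basis, value = value)
}

#' Maximize the flux through one reaction by flux balance analysis
#'
#' Solves `max v_j` subject to the steady-state constraint `S v = 0` and the
#' model's flux bounds.  The model must already be in non-negative form (all
#' lower bounds zero, see [split_reversible()]); strictly positive lower
#' bounds are rejected.
#'
#' @param model a `minea_model`.
#' @param reaction_id id of the reaction whose flux is maximized.
#' @param extra_ge optional list with `A` and `b` for additional `>=` rows
#'   over the flux variables (used internally for yield floors).
#' @param zero_out character vector of reaction ids forced to zero flux.
#' @return list with `status`, `value` (the optimum) and named flux vector
#'   `fluxes`.
#' @export
fba_max <- function(model, reaction_id, extra_ge = NULL, zero_out = NULL) {
  stopifnot(inherits(model, "minea_model"))
  rid <- model$reactions$id
  if (!reaction_id %in% rid) {
    stop("unknown reaction id: ", reaction_id)
  }
  if (any(model$reactions$lb < 0)) {
    stop("model has negative lower bounds; call split_reversible() first")
  }
  if (any(model$reactions$lb > 1e-12)) {
    stop("strictly positive lower bounds are not supported")
  }
  n <- length(rid)
  ub <- model$reactions$ub
  if (!is.null(zero_out)) {
    ub[match(zero_out, rid)] <- 0
  }
  S <- as.matrix(model$stoich)
  obj <- numeric(n)
  obj[match(reaction_id, rid)] <- 1
  A_ge <- NULL; b_ge <- NULL
  if (!is.null(extra_ge)) {
    A_ge <- extra_ge$A; b_ge <- extra_ge$b
  }
  res <- lp_solve(obj,
                  A_le = diag(n), b_le = ub,
                  A_ge = A_ge, b_ge = b_ge,
                  A_eq = S, b_eq = numeric(nrow(S)),
                  maximize = TRUE)
  if (res$status == "optimal") {
    fl <- res$x[seq_len(n)]
    names(fl) <- rid
    list(status = "optimal", value = res$value, fluxes = fl)
  } else {
    list(status = res$status, value = NA_real_, fluxes = NULL)
  }
}
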