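# Exact branch-and-bound for the minimal-active-network MILP.
#
#   minimize   sum_i a_i                 (a_i binary activity indicators)
#   subject to S v = 0
#              0 <= v_i <= u_i * a_i     (u_i: FVA-tightened capacity)
#              v_MT >= c * V_MT,max
#              a_fwd + a_rev <= 1        (per split pair)
#              sum_{i in A} a_i <= |A|-1 (one integer cut per found network)
#
# The LP relaxation (a_i in [0,1]) is solved at every node; branching is on
# the most fractional indicator.  With FVA-tightened capacities the
# relaxation bound ceil(obj) is sharp enough that trees stay small at the
# problem sizes this solver targets.

MILP_INT_TOL <- 1e-6     # integrality tolerance on indicators
MILP_ACT_TOL <- 1e-6     # activity threshold on witness fluxes
MILP_FEAS_TOL <- 1e-6    # slack allowed on the yield floor when verifying

#' @keywords internal
milp_problem <- function(model, demand_id, yield_floor) {
  rid <- model$reactions$id
  n <- length(rid)
  dem <- match(demand_id, rid)
  if (is.na(dem)) stop("demand reaction not in model: ", demand_id)
  yield_row <- list(A = matrix(as.numeric(seq_len(n) == dem), nrow = 1),
                    b = yield_floor)
  # FVA under the yield floor: tight capacities; blocked reactions drop out
  u <- numeric(n)
  for (j in seq_len(n)) {
    if (model$reactions$ub[j] <= MILP_ACT_TOL) { u[j] <- 0; next }
    res <- fba_max(model, rid[j], extra_ge = yield_row)
    if (res$status != "optimal") stop("FVA LP failed for ", rid[j])
    u[j] <- min(res$value, model$reactions$ub[j])
  }
  keep <- which(u > MILP_ACT_TOL)
  if (!(dem %in% keep)) stop("task infeasible: demand cannot carry flux")
  K <- length(keep)
  S <- as.matrix(model$stoich)[, keep, drop = FALSE]
  S <- S[rowSums(S != 0) > 0, , drop = FALSE]
  parent <- model$reactions$parent_id[keep]
  uK <- u[keep]
  demK <- match(dem, keep)
  cost <- as.numeric(seq_len(K) != demK)
  # pair rows: both split directions of a parent never active together
  pair_parents <- names(which(table(parent) == 2L))
  list(model = model, keep = keep, ids = rid[keep], parent = parent,
       u = uK, dem = demK, S = S, cost = cost,
       pair_parents = pair_parents, yield_floor = yield_floor)
}

#' @keywords internal
milp_node_lp <- function(prob, cuts, a_lo, a_up) {
  K <- length(prob$u)
  nv <- 2L * K           # x = c(v, a)
  obj <- c(numeric(K), prob$cost)
  # coupling v_j - u_j a_j <= 0
  A_cpl <- cbind(diag(K), diag(-prob$u))
  # a_j <= a_up_j
  A_aub <- cbind(matrix(0, K, K), diag(K))
  le_rows <- list(A_cpl, A_aub)
  b_le <- c(numeric(K), a_up)
  for (pp in prob$pair_parents) {
    r <- numeric(nv); r[K + which(prob$parent == pp)] <- 1
    le_rows <- c(le_rows, list(matrix(r, nrow = 1)))
    b_le <- c(b_le, 1)
  }
  for (cut in cuts) {
    r <- numeric(nv); r[K + which(prob$parent %in% cut)] <- 1
    le_rows <- c(le_rows, list(matrix(r, nrow = 1)))
    b_le <- c(b_le, length(cut) - 1)
  }
  A_le <- do.call(rbind, le_rows)
  # demand floor plus fixed-on indicators
  ge_rows <- list()
  b_ge <- numeric(0)
  r <- numeric(nv); r[prob$dem] <- 1
  ge_rows <- c(ge_rows, list(r)); b_ge <- c(b_ge, prob$yield_floor)
  for (j in which(a_lo > 0)) {
    r <- numeric(nv); r[K + j] <- 1
    ge_rows <- c(ge_rows, list(r)); b_ge <- c(b_ge, a_lo[j])
  }
  A_ge <- do.call(rbind, ge_rows)
  res <- lp_solve(obj, A_le = A_le, b_le = b_le, A_ge = A_ge, b_ge = b_ge,
                  A_eq = cbind(prob$S, matrix(0, nrow(prob$S), K)),
                  b_eq = numeric(nrow(prob$S)))
  if (res$status != "optimal") return(list(status = res$status))
  list(status = "optimal", value = res$value,
       v = res$x[seq_len(K)], a = res$x[K + seq_len(K)])
}

#' @keywords internal
milp_branch_and_bound <- function(prob, cuts = list(), limit = Inf,
                                  max_nodes = 200000L) {
  K <- length(prob$u)
  best <- list(obj = Inf, a = NULL)
  root <- list(a_lo = numeric(K), a_up = rep(1, K))
  root$a_lo[prob$dem] <- 1
  stack <- list(root)
  nodes <- 0L
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    if (nodes > max_nodes) stop("branch-and-bound node limit exceeded")
    lp <- milp_node_lp(prob, cuts, node$a_lo, node$a_up)
    if (lp$status != "optimal") next
    bound <- ceiling(lp$value - 1e-6)
    if (bound > limit || bound >= best$obj) next
    frac <- pmin(lp$a, 1 - lp$a)
    frac[lp$a < node$a_lo - 1e-9] <- 0   # guard: respect fixings
    j <- which.max(frac)
    if (frac[j] <= MILP_INT_TOL) {
      obj <- round(lp$value)
      if (obj < best$obj) best <- list(obj = obj, a = round(lp$a))
      next
    }
    off <- node; off$a_up[j] <- 0
    on <- node; on$a_lo[j] <- 1
    stack <- c(stack, list(off), list(on))  # explore 'on' child first
  }
  if (!is.finite(best$obj)) return(list(status = "infeasible"))
  list(status = "optimal", obj = best$obj,
       active = which(best$a > 0.5), nodes = nodes)
}

#' @keywords internal
milp_verify_witness <- function(prob, active_idx) {
  model <- prob$model
  ids <- prob$ids
  off <- setdiff(model$reactions$id, ids[active_idx])
  res <- fba_max(model, ids[prob$dem], zero_out = off)
  if (res$status != "optimal" ||
      res$value < prob$yield_floor - MILP_FEAS_TOL) {
    stop("internal error: witness LP does not meet the yield floor for {",
         paste(ids[active_idx], collapse = ", "), "}")
  }
  res$fluxes
}
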