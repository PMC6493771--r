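#' Solve the minimal active network problem for one task
#'
#' Finds a provably minimum-cardinality set of reactions that can jointly
#' carry a steady-state flux synthesizing the task target at a rate of at
#' least `c` times the maximum yield.  Sizes are counted over parent
#' reaction ids (split directions collapsed) and the task's demand reaction
#' is excluded from the count.
#'
#' @param model a split `minea_model` (all lower bounds zero).
#' @param task a prepared `minea_task` (see [prepare_task()]); its
#'   `v_mt_max` must be positive.
#' @return a `minea_min_network`: list with `task`, `active_reactions`
#'   (sorted parent ids), `size`, `flux_witness` (named flux vector over
#'   reaction ids, zero off the active set) and `objective_rank` (0).
#' @export
solve_min_network <- function(model, task) {
  stopifnot(inherits(model, "minea_model"), inherits(task, "minea_task"))
  if (is.na(task$v_mt_max)) stop("task not prepared; call prepare_task()")
  if (task$v_mt_max <= 0) {
    stop("task '", task$name, "' is infeasible: maximum yield is 0")
  }
  prob <- milp_problem(model, task$demand_id, task$c * task$v_mt_max)
  sol <- milp_branch_and_bound(prob)
  if (sol$status != "optimal") {
    stop("task '", task$name, "' is infeasible under the yield floor")
  }
  as_min_network(prob, sol$active, task, msize = sol$obj)
}

as_min_network <- function(prob, active_idx, task, msize) {
  witness <- milp_verify_witness(prob, active_idx)
  carrying <- names(witness)[abs(witness) > MILP_ACT_TOL]
  parents <- prob$model$reactions$parent_id[
    match(carrying, prob$model$reactions$id)]
  active <- sort(setdiff(unique(parents), task$demand_id))
  structure(list(task = task$name, active_reactions = active,
                 size = length(active), flux_witness = witness,
                 objective_rank = length(active) - msize),
            class = "minea_min_network")
}

#' @export
print.minea_min_network <- function(x, ...) {
  cat(sprintf("minea_min_network for task '%s': %d reactions (rank %d)\n",
              x$task, x$size, x$objective_rank))
  cat("  ", paste(x$active_reactions, collapse = ", "), "\n")
  invisible(x)
}

#' Enumerate all alternative minimal networks of a task
#'
#' Repeatedly re-solves the minimal-network MILP, each time excluding the
#' previously found active sets with an integer cut
#' (`sum_{i in A} a_i <= |A| - 1` over the parent-level set), until the
#' optimum exceeds `msize + max_rank` or `cap` networks have been found.
#' Reactions present in every alternative are the task's high-frequency
#' reactions (HFRs).
#'
#' @param model a split `minea_model`.
#' @param task a prepared `minea_task` with positive yield.
#' @param max_rank enumerate networks up to size `msize + max_rank`
#'   (default 0: strict minimum size only).
#' @param cap safety cap on the number of enumerated networks; if reached
#'   the result is flagged truncated and the HFRs are only valid for the
#'   enumerated subset.
#' @return a `minea_altset`: list with `task`, `networks` (list of
#'   `minea_min_network`, sorted lexicographically by active set), `msize`,
#'   `hfrs`, `hfr_fraction` (percent of `msize`), `truncated`.
#' @export
enumerate_alternatives <- function(model, task, max_rank = 0L, cap = 10000L) {
  stopifnot(inherits(model, "minea_model"), inherits(task, "minea_task"))
  if (is.na(task$v_mt_max)) stop("task not prepared; call prepare_task()")
  if (task$v_mt_max <= 0) {
    stop("task '", task$name, "' is infeasible: maximum yield is 0")
  }
  prob <- milp_problem(model, task$demand_id, task$c * task$v_mt_max)
  sol0 <- milp_branch_and_bound(prob)
  if (sol0$status != "optimal") {
    stop("task '", task$name, "' is infeasible under the yield floor")
  }
  first <- as_min_network(prob, sol0$active, task, msize = sol0$obj)
  msize <- first$size
  networks <- list(first)
  cuts <- list(first$active_reactions)
  truncated <- FALSE
  repeat {
    if (length(networks) >= cap) {
      truncated <- TRUE
      warning("enumeration cap reached for task '", task$name,
              "'; HFRs are only valid for the enumerated subset")
      break
    }
    sol <- milp_branch_and_bound(prob, cuts = cuts,
                                 limit = msize + max_rank)
    if (sol$status != "optimal" || sol$obj > msize + max_rank) break
    net <- as_min_network(prob, sol$active, task, msize = msize)
    key <- paste(net$active_reactions, collapse = "\r")
    seen <- vapply(networks, function(x)
      paste(x$active_reactions, collapse = "\r"), character(1))
    if (!key %in% seen) networks <- c(networks, list(net))
    cuts <- c(cuts, list(net$active_reactions))
  }
  ord <- order(vapply(networks, function(x)
    paste(x$active_reactions, collapse = "\r"), character(1)))
  networks <- networks[ord]
  hfrs <- sort(Reduce(intersect,
                      lapply(networks, function(x) x$active_reactions)))
  structure(list(task = task, networks = networks, msize = msize,
                 hfrs = hfrs, hfr_fraction = 100 * length(hfrs) / msize,
                 truncated = truncated),
            class = "minea_altset")
}

#' @export
print.minea_altset <- function(x, ...) {
  cat(sprintf(
    "minea_altset task '%s': msize %d, %d alternatives, %d HFRs (%.0f%%)%s\n",
    x$task$name, x$msize, length(x$networks), length(x$hfrs),
    x$hfr_fraction, if (x$truncated) " [truncated]" else ""))
  invisible(x)
}

#' High-frequency reactions shared across a phenotype
#'
#' The intersection of the active sets over every alternative network of
#' every task in a phenotype group.
#'
#' @param alt_sets non-empty list of `minea_altset` objects.
#' @return sorted character vector of reaction (parent) ids; carries the
#'   attribute `approximate = TRUE` (with a warning) if any input was
#'   truncated.
#' @export
phenotypic_hfrs <- function(alt_sets) {
  if (length(alt_sets) == 0L) stop("empty list of alternative sets")
  stopifnot(all(vapply(alt_sets, inherits, logical(1), "minea_altset")))
  approx <- any(vapply(alt_sets, function(x) isTRUE(x$truncated), logical(1)))
  if (approx) {
    warning("phenotypic HFRs computed from truncated enumerations; ",
            "result is approximate")
  }
  nets <- unlist(lapply(alt_sets, function(x)
    lapply(x$networks, function(n) n$active_reactions)), recursive = FALSE)
  out <- sort(Reduce(intersect, nets))
  if (approx) attr(out, "approximate") <- TRUE
  out
}

#' Per-subsystem activity summary of a reaction set
#'
#' Counts, per subsystem annotation, how many of its (parent-level) member
#' reactions are in the given active set, alongside the subsystem's total
#' membership.  Unlabeled reactions are grouped under `"unassigned"`.
#'
#' @param active character vector of parent reaction ids, or a
#'   `minea_min_network`.
#' @param model the `minea_model` carrying subsystem labels.
#' @return data frame with columns `subsystem`, `active`, `total`.
#' @export
subsystem_summary <- function(active, model) {
  stopifnot(inherits(model, "minea_model"))
  if (inherits(active, "minea_min_network")) active <- active$active_reactions
  rxn <- model$reactions
  parents <- rxn[!duplicated(rxn$parent_id), c("parent_id", "subsystem")]
  parents$subsystem[!nzchar(parents$subsystem)] <- "unassigned"
  agg <- stats::aggregate(
    cbind(total = rep(1L, nrow(parents)),
          active = as.integer(parents$parent_id %in% active)) ~ subsystem,
    data = parents, FUN = sum)
  agg[order(-agg$active, agg$subsystem), c("subsystem", "active", "total")]
}
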