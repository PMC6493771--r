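# Synthetic fixtures with known ground truth, plus brute-force oracles.
# The generator builds source -> backbone -> target models in which each
# backbone stage offers several stoichiometrically interchangeable parallel
# branches, so the family of minimal networks is known by construction
# (one branch per stage; the alternative count is the product of the
# per-stage branch counts).

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a parallel-route toy metabolic model with known minimal networks
#'
#' Builds a linear backbone from a source to a target metabolite.  Each
#' stage of the backbone is bridged by `branches_per_stage[s]`
#' interchangeable parallel branches of `branch_length` reactions with unit
#' stoichiometry.  Optional decoy reactions drain backbone intermediates:
#' they can carry flux (the 80\% yield floor leaves slack) but never lie on
#' a minimal route.  Stages listed in `cofactor_stages` couple their
#' branches to a shared cofactor pair whose recharge reaction is then part
#' of every minimal network, exercising the cofactor balancing that
#' annotation-based pathway enrichment cannot capture.  Every reaction gets
#' a synthetic GPR rule over its own private genes.
#'
#' @param branches_per_stage integer vector, branches per backbone stage;
#'   `integer(0)` gives the degenerate single-source chain.
#' @param branch_length reactions per branch.
#' @param n_decoys number of decoy drain reactions.
#' @param genes_per_reaction integer range `c(lo, hi)` of genes per rule.
#' @param cofactor_stages indices of cofactor-coupled stages.
#' @param seed RNG seed (the global RNG state is left untouched).
#' @param vmax flux cap for all reactions.
#' @return list with `model` (a `minea_model`, all reactions irreversible),
#'   `task` (a `minea_task` for the target metabolite), and `truth`: list
#'   with `msize`, `n_alternatives`, `alternatives` (each a sorted id set),
#'   and `hfrs`.
#' @export
make_parallel_gem <- function(branches_per_stage = c(2L),
                              branch_length = 1L,
                              n_decoys = 0L,
                              genes_per_reaction = c(2L, 3L),
                              cofactor_stages = integer(0),
                              seed = 1L, vmax = MINEA_VMAX) {
  stopifnot(branch_length >= 1L, n_decoys >= 0L,
            all(branches_per_stage >= 1L),
            all(cofactor_stages %in% seq_along(branches_per_stage)))
  n_stages <- length(branches_per_stage)
  backbone <- paste0("M", 0:n_stages)
  mets <- data.frame(id = backbone, compartment = "c",
                     stringsAsFactors = FALSE)
  rxn <- data.frame(id = "SRC", lb = 0, ub = vmax, subsystem = "source",
                    stringsAsFactors = FALSE)
  trip <- list(data.frame(metabolite = "M0", reaction = "SRC",
                          coefficient = 1, stringsAsFactors = FALSE))
  branch_rxns <- list()  # [[stage]][[branch]] -> reaction ids
  use_cofactor <- length(cofactor_stages) > 0L
  if (use_cofactor) {
    mets <- rbind(mets, data.frame(id = c("atp", "adp"), compartment = "c",
                                   stringsAsFactors = FALSE))
    rxn <- rbind(rxn, data.frame(id = "COF_RECHARGE", lb = 0, ub = vmax,
                                 subsystem = "cofactor",
                                 stringsAsFactors = FALSE))
    trip[[length(trip) + 1L]] <- data.frame(
      metabolite = c("adp", "atp"), reaction = "COF_RECHARGE",
      coefficient = c(-1, 1), stringsAsFactors = FALSE)
  }
  for (s in seq_len(n_stages)) {
    branch_rxns[[s]] <- vector("list", branches_per_stage[s])
    for (b in seq_len(branches_per_stage[s])) {
      chain_mets <- c(backbone[s],
                      if (branch_length > 1L) {
                        paste0("m_s", s, "b", b, "i", seq_len(branch_length - 1L))
                      },
                      backbone[s + 1L])
      inner <- setdiff(chain_mets, backbone)
      if (length(inner)) {
        mets <- rbind(mets, data.frame(id = inner, compartment = "c",
                                       stringsAsFactors = FALSE))
      }
      ids <- paste0("S", s, "B", b, "R", seq_len(branch_length))
      branch_rxns[[s]][[b]] <- ids
      for (r in seq_len(branch_length)) {
        rxn <- rbind(rxn, data.frame(
          id = ids[r], lb = 0, ub = vmax,
          subsystem = paste0("stage_", s), stringsAsFactors = FALSE))
        tr <- data.frame(metabolite = c(chain_mets[r], chain_mets[r + 1L]),
                         reaction = ids[r], coefficient = c(-1, 1),
                         stringsAsFactors = FALSE)
        if (r == 1L && s %in% cofactor_stages) {
          tr <- rbind(tr, data.frame(metabolite = c("atp", "adp"),
                                     reaction = ids[r],
                                     coefficient = c(-1, 1),
                                     stringsAsFactors = FALSE))
        }
        trip[[length(trip) + 1L]] <- tr
      }
    }
  }
  if (n_decoys > 0L) {
    drain_from <- backbone[((seq_len(n_decoys) - 1L) %% max(n_stages, 1L)) + 1L]
    for (k in seq_len(n_decoys)) {
      id <- paste0("DECOY", k)
      rxn <- rbind(rxn, data.frame(id = id, lb = 0, ub = vmax,
                                   subsystem = "decoy",
                                   stringsAsFactors = FALSE))
      trip[[length(trip) + 1L]] <- data.frame(
        metabolite = drain_from[k], reaction = id, coefficient = -1,
        stringsAsFactors = FALSE)
    }
  }
  gprs <- with_local_seed(seed, {
    out <- list()
    for (id in rxn$id) {
      ng <- sample(seq.int(genes_per_reaction[1], genes_per_reaction[2]), 1L)
      genes <- paste0("g_", id, "_", seq_len(ng))
      rule <- paste(genes, collapse = paste0(" ", sample(c("and", "or"), 1L), " "))
      out[[id]] <- parse_gpr(rule)
    }
    out
  })
  model <- minea_model(paste0("parallel_gem_seed", seed), mets, rxn,
                       do.call(rbind, c(trip, list(make.row.names = FALSE))),
                       gprs)
  task <- minea_task("TARGET", backbone[n_stages + 1L],
                     phenotype = "synthetic", c = 0.8)
  choice_sets <- if (n_stages == 0L) list(character(0)) else {
    grids <- lapply(branch_rxns, function(stage) seq_along(stage))
    combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
    lapply(seq_len(nrow(combos)), function(i) {
      unlist(lapply(seq_len(n_stages), function(s)
        branch_rxns[[s]][[combos[i, s]]]), use.names = FALSE)
    })
  }
  core <- c("SRC", if (use_cofactor) "COF_RECHARGE")
  alternatives <- lapply(choice_sets, function(ch) sort(c(core, ch)))
  shared_chains <- unlist(lapply(seq_len(n_stages), function(s)
    if (branches_per_stage[s] == 1L) branch_rxns[[s]][[1L]]), use.names = FALSE)
  truth <- list(
    msize = length(core) + n_stages * branch_length,
    n_alternatives = prod(branches_per_stage),
    alternatives = alternatives[order(vapply(alternatives, paste,
                                             character(1), collapse = "\r"))],
    hfrs = sort(c(core, shared_chains)))
  list(model = model, task = task, truth = truth)
}

#' Plant a regulation pattern on a fixture
#'
#' Calls every gene of every listed reaction in the given direction, and
#' calls each remaining model gene with probability `background_rate`
#' (direction then uniform up/down).  Deterministic under `seed`.
#'
#' @param model a `minea_model`.
#' @param target_reactions reaction ids whose genes are planted.
#' @param direction `"up"` or `"down"`.
#' @param background_rate per-gene call probability outside the target.
#' @param seed RNG seed.
#' @return named character vector of `"up"`/`"down"` calls.
#' @export
plant_regulation <- function(model, target_reactions, direction = "up",
                             background_rate = 0, seed = 1L) {
  stopifnot(direction %in% c("up", "down"),
            background_rate >= 0, background_rate <= 1)
  missing <- setdiff(target_reactions, model$reactions$id)
  if (length(missing)) stop("unknown reactions: ",
                            paste(missing, collapse = ", "))
  planted <- unique(unlist(lapply(target_reactions, genes_of, model = model),
                           use.names = FALSE))
  background <- setdiff(model$genes, planted)
  with_local_seed(seed, {
    called <- background[stats::runif(length(background)) < background_rate]
    dirs <- sample(c("up", "down"), length(called), replace = TRUE)
    c(stats::setNames(rep(direction, length(planted)), planted),
      stats::setNames(dirs, called))
  })
}

#' Exhaustive minimal-network oracle
#'
#' Enumerates every subset of (parent) reactions in increasing cardinality
#' and tests by linear programming whether the subset alone can satisfy the
#' task's yield floor; the complete family of minimum-cardinality feasible
#' subsets is returned.  Independent of the branch-and-bound solver; used
#' to validate it on small models.
#'
#' @param model a `minea_model` (reversible reactions are split internally).
#' @param task a `minea_task`.
#' @param max_reactions refusal threshold on the number of candidate parent
#'   reactions (default 14).
#' @return list with `msize` (`NA` for an infeasible task),
#'   `alternatives` (list of sorted parent-id sets) and `hfrs`.
#' @export
oracle_enumerate <- function(model, task, max_reactions = 14L) {
  stopifnot(inherits(model, "minea_model"), inherits(task, "minea_task"))
  model <- split_reversible(model)
  prep <- prepare_task(model, task)
  model <- prep$model; task <- prep$task
  parents <- setdiff(unique(model$reactions$parent_id), task$demand_id)
  if (length(parents) > max_reactions) {
    stop("oracle refuses models with more than ", max_reactions,
         " candidate reactions (got ", length(parents), ")")
  }
  if (task$v_mt_max <= 0) {
    return(list(msize = NA_integer_, alternatives = list(), hfrs = character(0)))
  }
  floor_v <- task$c * task$v_mt_max
  feasible_subset <- function(subset) {
    if (!oracle_reachable(model, subset, task)) return(FALSE)
    off <- model$reactions$id[!(model$reactions$parent_id %in%
                                  c(subset, task$demand_id))]
    res <- fba_max(model, task$demand_id, zero_out = off)
    res$status == "optimal" && res$value >= floor_v - 1e-6
  }
  for (s in seq_along(parents)) {
    hits <- list()
    sets <- utils::combn(parents, s, simplify = FALSE)
    for (subset in sets) {
      if (feasible_subset(subset)) hits[[length(hits) + 1L]] <- sort(subset)
    }
    if (length(hits)) {
      hits <- hits[order(vapply(hits, paste, character(1), collapse = "\r"))]
      return(list(msize = s, alternatives = hits,
                  hfrs = sort(Reduce(intersect, hits))))
    }
  }
  list(msize = NA_integer_, alternatives = list(), hfrs = character(0))
}

# cheap necessary conditions for subset feasibility (cycle-safe, so cofactor
# loops are never pruned): the subset must contain a producer of the target,
# and -- because summing all mass balances gives sum_j colsum_j v_j = 0 while
# the demand has negative column sum -- at least one net-source reaction.
oracle_reachable <- function(model, subset, task) {
  rxn_ids <- model$reactions$id[model$reactions$parent_id %in% subset]
  S <- model$stoich
  sub <- S[, rxn_ids, drop = FALSE]
  if (all(sub[task$metabolite, ] <= 0)) return(FALSE)
  any(Matrix::colSums(sub) > 0)
}

#' Exhaustive multivariate hypergeometric tail oracle
#'
#' Computes the joint tail probability of [up_pvalue()] / [down_pvalue()]
#' by enumerating all `choose(R, T)` reaction subsets of a labelled model
#' census and counting the qualifying outcomes.  Refuses `R > 15`.
#'
#' @param census model census `(R, R_up, R_down, R_no)`.
#' @param min_census network census `(T, T_up, T_down)`.
#' @param mode `"up"` or `"down"`.
#' @return exact tail probability.
#' @export
oracle_multivariate_tail <- function(census, min_census,
                                     mode = c("up", "down")) {
  mode <- match.arg(mode)
  census <- as.numeric(census); min_census <- as.numeric(min_census)
  if (census[1] > 15) stop("oracle refuses censuses with R > 15")
  stopifnot(census[1] == sum(census[2:4]), min_census[1] <= census[1])
  states <- rep(c("up", "down", "no"), times = census[2:4])
  T_tot <- min_census[1]
  if (T_tot == 0) return(1)
  a <- if (mode == "up") "up" else "down"
  b <- if (mode == "up") "down" else "up"
  T_a <- if (mode == "up") min_census[2] else min_census[3]
  T_b <- if (mode == "up") min_census[3] else min_census[2]
  subsets <- utils::combn(length(states), T_tot, simplify = FALSE)
  hits <- vapply(subsets, function(idx) {
    sum(states[idx] == a) >= T_a && sum(states[idx] == b) <= T_b
  }, logical(1))
  sum(hits) / length(subsets)
}
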