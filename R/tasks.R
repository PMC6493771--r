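#' Construct a metabolic task
#'
#' A metabolic task (MT) requires the network to synthesize a target
#' metabolite at a rate of at least `c` times the maximum achievable rate.
#' The task is realized through a demand reaction added by
#' [prepare_task()] / [add_demand()].
#'
#' @param name short task code (e.g. `"H2O2"`).
#' @param metabolite target metabolite id as present in the model.
#' @param phenotype free-text phenotype label grouping tasks.
#' @param c yield fraction in `(0, 1]`; the default 0.8 demands at least
#'   80\% of the maximum yield.
#' @return an object of class `minea_task`.
#' @export
minea_task <- function(name, metabolite, phenotype = "", c = 0.8) {
  if (!(is.numeric(c) && length(c) == 1L && c > 0 && c <= 1)) {
    stop("c must be a single number in (0, 1]")
  }
  structure(list(name = name, metabolite = metabolite, phenotype = phenotype,
                 c = c, v_mt_max = NA_real_, demand_id = NA_character_),
            class = "minea_task")
}

#' @export
print.minea_task <- function(x, ...) {
  cat(sprintf("minea_task '%s': synthesize %s (phenotype '%s', c = %g)\n",
              x$name, x$metabolite, x$phenotype, x$c))
  if (!is.na(x$v_mt_max)) {
    cat(sprintf("  demand %s, maximum yield %g\n", x$demand_id, x$v_mt_max))
  }
  invisible(x)
}

#' Append a demand reaction for a metabolite
#'
#' Adds an irreversible reaction consuming one unit of the target with
#' bounds `[0, vmax]`.  Idempotent: if a demand for the target already
#' exists it is reused.
#'
#' @param model a `minea_model`.
#' @param metabolite target metabolite id.
#' @param vmax upper bound of the demand reaction.
#' @return list with the (possibly extended) `model` and `demand_id`.
#' @export
add_demand <- function(model, metabolite, vmax = MINEA_VMAX) {
  stopifnot(inherits(model, "minea_model"))
  if (!metabolite %in% model$metabolites$id) {
    stop("unknown metabolite: ", metabolite)
  }
  demand_id <- paste0("DM_", metabolite)
  if (demand_id %in% model$reactions$id) {
    return(list(model = model, demand_id = demand_id))
  }
  rxn <- rbind(model$reactions,
               data.frame(id = demand_id, lb = 0, ub = vmax,
                          subsystem = "demand", parent_id = demand_id,
                          stringsAsFactors = FALSE))
  S <- model$stoich
  trip <- Matrix::summary(S)
  stoich <- data.frame(metabolite = rownames(S)[trip$i],
                       reaction = colnames(S)[trip$j],
                       coefficient = trip$x, stringsAsFactors = FALSE)
  stoich <- rbind(stoich,
                  data.frame(metabolite = metabolite, reaction = demand_id,
                             coefficient = -1, stringsAsFactors = FALSE))
  out <- minea_model(model$id, model$metabolites, rxn, stoich, model$gprs,
                     model$genes)
  list(model = out, demand_id = demand_id)
}

#' Maximum yield of a demand reaction
#'
#' The LP optimum of maximizing the demand flux subject to steady state and
#' the flux bounds; `v = 0` is always feasible, so the value is `>= 0`.
#'
#' @param model a split `minea_model` containing the demand reaction.
#' @param demand_id the demand reaction id.
#' @return maximum demand flux (model units).
#' @export
compute_max_yield <- function(model, demand_id) {
  res <- fba_max(model, demand_id)
  if (res$status != "optimal") {
    stop("internal error: yield LP did not solve (", res$status, ")")
  }
  max(res$value, 0)
}

#' Prepare a task against a model
#'
#' Adds (or reuses) the demand reaction and computes the task's maximum
#' yield.  A task is usable downstream only if the yield is positive.
#'
#' @param model a split `minea_model`.
#' @param task a `minea_task`.
#' @return list with `model` (extended) and `task` (with `demand_id` and
#'   `v_mt_max` filled in).
#' @export
prepare_task <- function(model, task) {
  stopifnot(inherits(task, "minea_task"))
  dm <- add_demand(model, task$metabolite)
  task$demand_id <- dm$demand_id
  task$v_mt_max <- compute_max_yield(dm$model, dm$demand_id)
  list(model = dm$model, task = task)
}

#' Load a task table
#'
#' Reads a headered TSV with columns `task_name`, `metabolite_id`,
#' `compartment`, `phenotype`.  The target metabolite must resolve in the
#' model, either as `metabolite_id` directly (with a matching compartment
#' annotation) or as `metabolite_id` suffixed with `_<compartment>`.
#' The compartment is always explicit; no default compartment is guessed.
#'
#' @param path path to the task TSV.
#' @param model a `minea_model` used to resolve metabolite ids.
#' @param c yield fraction applied to every task.
#' @return list of `minea_task` objects.
#' @export
load_tasks <- function(path, model, c = 0.8) {
  if (!file.exists(path)) stop("task file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) return(list())
  need <- c("task_name", "metabolite_id", "compartment", "phenotype")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("task table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$task_name)) {
    stop("duplicate task names: ",
         paste(unique(tab$task_name[duplicated(tab$task_name)]), collapse = ", "))
  }
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    met <- resolve_metabolite(model, row$metabolite_id, row$compartment)
    if (is.na(met)) {
      stop("task '", row$task_name, "' (row ", i, "): metabolite '",
           row$metabolite_id, "' in compartment '", row$compartment,
           "' not found in model")
    }
    minea_task(row$task_name, met, row$phenotype, c = c)
  })
}

resolve_metabolite <- function(model, metabolite_id, compartment) {
  met <- model$metabolites
  hit <- met$id == metabolite_id & met$compartment == compartment
  if (any(hit)) return(met$id[which(hit)[1]])
  suffixed <- paste0(metabolite_id, "_", compartment)
  if (suffixed %in% met$id) return(suffixed)
  NA_character_
}
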