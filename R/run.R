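#' Build a pipeline configuration
#'
#' Collects the inputs and tuning parameters of a full analysis run.  Every
#' field mirrors a key of the TOML configuration file accepted by
#' [read_config()] and a flag of the command-line wrapper.
#'
#' @param model path to the model file (or a `minea_model`).
#' @param model_format `"auto"`, `"cobra-json"` or `"sbml"`.
#' @param tasks path to the task TSV (see [load_tasks()]).
#' @param deg named character vector of DEG table paths; names label the
#'   condition pairs (`"NS_vs_N"` style, treatment first).
#' @param directionality optional path to a directionality TSV.
#' @param c yield fraction (default 0.8).
#' @param max_rank enumerate up to `msize + max_rank` (default 0).
#' @param cap per-task cap on enumerated alternatives.
#' @param alpha_gene gene-mode significance threshold (default 0.05).
#' @param alpha_rxn reaction-mode significance threshold (default 0.005).
#' @param vmax flux cap for unbounded reactions.
#' @param seed integer seed recorded in the manifest (the pipeline itself
#'   is deterministic; the seed feeds fixture generation when used).
#' @param out_dir output directory.
#' @return a `minea_config` list.
#' @export
minea_config <- function(model = NULL, model_format = "auto", tasks = NULL,
                         deg = character(0), directionality = NULL,
                         c = 0.8, max_rank = 0L, cap = 10000L,
                         alpha_gene = 0.05, alpha_rxn = 0.005,
                         vmax = MINEA_VMAX, seed = 1L, out_dir = ".") {
  structure(list(model = model, model_format = model_format, tasks = tasks,
                 deg = deg, directionality = directionality, c = c,
                 max_rank = max_rank, cap = cap, alpha_gene = alpha_gene,
                 alpha_rxn = alpha_rxn, vmax = vmax, seed = seed,
                 out_dir = out_dir),
            class = "minea_config")
}

#' Read a TOML configuration file
#'
#' Keys match the arguments of [minea_config()]; the `deg` key is a table
#' of condition label to path.
#'
#' @param path path to the TOML file.
#' @return a `minea_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- RcppTOML::parseTOML(path)
  cfg <- minea_config()
  for (key in intersect(names(raw), names(cfg))) {
    val <- raw[[key]]
    if (key == "deg" && is.list(val)) val <- unlist(val)
    cfg[[key]] <- val
  }
  cfg
}

#' Validate a configuration
#'
#' @param config a `minea_config`.
#' @return character vector of problems; empty iff a run could start.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  if (!(is.numeric(config$c) && config$c > 0 && config$c <= 1)) {
    add("c must be in (0,1]")
  }
  for (key in c("alpha_gene", "alpha_rxn")) {
    v <- config[[key]]
    if (!(is.numeric(v) && v > 0 && v < 1)) {
      add(paste0(key, " must be in (0,1)"))
    }
  }
  if (!(is.numeric(config$max_rank) && config$max_rank >= 0)) {
    add("max_rank must be a non-negative integer")
  }
  if (!(is.numeric(config$cap) && config$cap >= 1)) add("cap must be >= 1")
  if (!(is.numeric(config$vmax) && config$vmax > 0)) add("vmax must be > 0")
  if (is.null(config$model)) {
    add("model is required")
  } else if (is.character(config$model) && !file.exists(config$model)) {
    add(paste0("model file not found: ", config$model))
  }
  if (is.null(config$tasks)) {
    add("tasks table is required")
  } else if (is.character(config$tasks) && !file.exists(config$tasks)) {
    add(paste0("task file not found: ", config$tasks))
  }
  for (i in seq_along(config$deg)) {
    if (!file.exists(config$deg[[i]])) {
      add(paste0("DEG table not found: ", config$deg[[i]]))
    }
  }
  if (!is.null(config$directionality) &&
      is.character(config$directionality) &&
      !file.exists(config$directionality)) {
    add(paste0("directionality table not found: ", config$directionality))
  }
  problems
}

run_load_inputs <- function(config) {
  model <- if (inherits(config$model, "minea_model")) config$model
           else load_model(config$model, config$model_format,
                           vmax = config$vmax)
  model <- split_reversible(model, vmax = config$vmax)
  if (!is.null(config$directionality)) {
    model <- apply_directionality(model, config$directionality)
  }
  tasks <- if (is.character(config$tasks)) {
    load_tasks(config$tasks, model, c = config$c)
  } else config$tasks
  list(model = model, tasks = tasks)
}

#' Enumerate minimal networks for every task of a configuration
#'
#' Runs the enumeration half of the pipeline (model normalization, task
#' preparation, minimal-network enumeration) and writes one JSON document
#' per task plus a summary TSV to the output directory.
#'
#' @param config a valid `minea_config`.
#' @return invisibly, a list with the split `model`, the `alt_sets`, and
#'   the skipped (zero-yield) task names.
#' @export
run_enumerate <- function(config) {
  problems <- validate_config(config)
  if (length(problems)) stop("invalid configuration:\n  ",
                             paste(problems, collapse = "\n  "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- run_load_inputs(config)
  alt_sets <- list(); skipped <- character(0)
  for (task in inputs$tasks) {
    prep <- prepare_task(inputs$model, task)
    if (prep$task$v_mt_max <= 0) {
      message("task '", task$name, "' has zero maximum yield; skipped")
      skipped <- c(skipped, task$name)
      next
    }
    aset <- enumerate_alternatives(prep$model, prep$task,
                                   max_rank = config$max_rank,
                                   cap = config$cap)
    alt_sets[[task$name]] <- aset
    write_altset_json(aset,
                      file.path(config$out_dir,
                                paste0("alternatives_", task$name, ".json")))
  }
  summary <- altset_summary(alt_sets)
  write_tsv(summary, file.path(config$out_dir, "minea_summary.tsv"))
  invisible(list(model = inputs$model, alt_sets = alt_sets,
                 skipped = skipped, summary = summary))
}

altset_summary <- function(alt_sets) {
  if (length(alt_sets) == 0L) {
    return(data.frame(task = character(0), phenotype = character(0),
                      msize = integer(0), n_alternatives = integer(0),
                      n_hfrs = integer(0), pct_hfrs = numeric(0),
                      n_phenotypic_hfrs = integer(0)))
  }
  phen <- vapply(alt_sets, function(a) a$task$phenotype, character(1))
  phen_hfrs <- vapply(names(alt_sets), function(nm) {
    group <- alt_sets[phen == phen[[nm]]]
    length(suppressWarnings(phenotypic_hfrs(group)))
  }, integer(1))
  data.frame(
    task = vapply(alt_sets, function(a) a$task$name, character(1)),
    phenotype = phen,
    msize = vapply(alt_sets, function(a) a$msize, numeric(1)),
    n_alternatives = vapply(alt_sets, function(a) length(a$networks),
                            numeric(1)),
    n_hfrs = vapply(alt_sets, function(a) length(a$hfrs), numeric(1)),
    pct_hfrs = round(vapply(alt_sets, function(a) a$hfr_fraction,
                            numeric(1)), 1),
    n_phenotypic_hfrs = phen_hfrs,
    row.names = NULL, stringsAsFactors = FALSE)
}

write_altset_json <- function(aset, path) {
  doc <- list(
    task = aset$task$name, phenotype = aset$task$phenotype,
    metabolite = aset$task$metabolite, c = aset$task$c,
    v_mt_max = aset$task$v_mt_max, msize = aset$msize,
    truncated = aset$truncated, hfrs = as.list(aset$hfrs),
    networks = lapply(aset$networks, function(n) {
      w <- n$flux_witness[abs(n$flux_witness) > MILP_ACT_TOL]
      list(active_reactions = as.list(n$active_reactions), size = n$size,
           objective_rank = n$objective_rank, flux_witness = as.list(w))
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Reload saved enumerations
#'
#' Reads the per-task JSON documents written by [run_enumerate()] so the
#' enrichment half can be re-run without re-solving the MILPs.
#'
#' @param paths character vector of `alternatives_*.json` paths.
#' @return named list of `minea_altset` objects.
#' @export
load_alternatives <- function(paths) {
  out <- list()
  for (path in paths) {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    task <- minea_task(doc$task, doc$metabolite, doc$phenotype, c = doc$c)
    task$v_mt_max <- doc$v_mt_max
    task$demand_id <- paste0("DM_", doc$metabolite)
    networks <- lapply(doc$networks, function(n) {
      structure(list(task = doc$task,
                     active_reactions = unlist(n$active_reactions),
                     size = n$size,
                     flux_witness = unlist(n$flux_witness),
                     objective_rank = n$objective_rank),
                class = "minea_min_network")
    })
    out[[doc$task]] <- structure(
      list(task = task, networks = networks, msize = doc$msize,
           hfrs = unlist(doc$hfrs, use.names = FALSE),
           hfr_fraction = 100 * length(doc$hfrs) / doc$msize,
           truncated = isTRUE(doc$truncated)),
      class = "minea_altset")
  }
  out
}

#' Score saved enumerations against DEG tables
#'
#' Runs the enrichment half of the pipeline on existing alternative sets
#' and writes the per-network, AMiNF and HFR-regulation TSVs.
#'
#' @param config a `minea_config` (its `deg` tables are used).
#' @param model the split `minea_model` the enumerations refer to.
#' @param alt_sets named list of `minea_altset` objects.
#' @return invisibly, the report list of [build_report()].
#' @export
run_enrich <- function(config, model, alt_sets) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (length(config$deg) == 0L) stop("no DEG tables configured")
  labels <- names(config$deg)
  if (is.null(labels)) labels <- paste0("condition", seq_along(config$deg))
  regulations <- lapply(seq_along(config$deg), function(i) {
    calls <- load_deg_table(config$deg[[i]])
    assign_regulation(model, calls, condition = labels[i])
  })
  report <- build_report(alt_sets, model, regulations,
                         alpha_gene = config$alpha_gene,
                         alpha_rxn = config$alpha_rxn)
  write_tsv(report$networks, file.path(config$out_dir, "minea_networks.tsv"))
  write_tsv(report$aminf, file.path(config$out_dir, "minea_aminf.tsv"))
  write_tsv(report$hfr_regulation,
            file.path(config$out_dir, "minea_hfr_regulation.tsv"))
  invisible(report)
}

#' Run the full pipeline
#'
#' Model normalization, task preparation, minimal-network enumeration,
#' regulation assignment and enrichment scoring, with all artifacts
#' written to `config$out_dir`:
#' `alternatives_<task>.json`, `minea_summary.tsv`, `minea_networks.tsv`,
#' `minea_aminf.tsv`, `minea_hfr_regulation.tsv` and `run_manifest.json`.
#' Re-running with an identical configuration reproduces the TSV outputs
#' byte for byte.
#'
#' @param config a valid `minea_config`.
#' @return invisibly, list with `alt_sets`, `report`, `summary`, `skipped`.
#' @export
run_minea <- function(config) {
  enum <- run_enumerate(config)
  report <- if (length(config$deg)) {
    run_enrich(config, enum$model, enum$alt_sets)
  } else NULL
  manifest <- list(
    package = "minea",
    version = as.character(utils::packageVersion("minea")),
    config = config[setdiff(names(config), "model")],
    model_id = enum$model$id,
    n_tasks = length(enum$alt_sets),
    skipped_tasks = as.list(enum$skipped),
    solver = list(kernel = "boot::simplex branch-and-bound",
                  integrality_tol = MILP_INT_TOL,
                  activity_tol = MILP_ACT_TOL,
                  relative_gap = 0))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(alt_sets = enum$alt_sets, report = report,
                 summary = enum$summary, skipped = enum$skipped))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
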