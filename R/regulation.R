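#' Load a differential-expression call table
#'
#' Reads a headered TSV with either a `direction` column (`"up"`/`"down"`)
#' or a signed `logFC` column (direction inferred from the sign), plus an
#' optional `fdr` column filtered at `fdr_threshold`.  Upstream
#' differential-expression calling is out of scope: the table is consumed
#' as given.
#'
#' @param path path to the TSV (column `gene_id` required).
#' @param fdr_threshold keep rows with `fdr <= fdr_threshold` when an `fdr`
#'   column is present (default 0.05).
#' @return named character vector mapping gene id to `"up"`/`"down"`.
#' @export
load_deg_table <- function(path, fdr_threshold = 0.05) {
  if (!file.exists(path)) stop("DEG table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) return(stats::setNames(character(0), character(0)))
  if (!"gene_id" %in% names(tab)) stop("DEG table lacks a gene_id column")
  if ("fdr" %in% names(tab)) {
    tab <- tab[!is.na(tab$fdr) & tab$fdr <= fdr_threshold, , drop = FALSE]
  }
  if ("direction" %in% names(tab)) {
    dir <- tolower(tab$direction)
    bad <- setdiff(unique(dir), c("up", "down"))
    if (length(bad)) stop("unknown direction value(s): ",
                          paste(bad, collapse = ", "))
  } else if ("logFC" %in% names(tab)) {
    tab <- tab[!is.na(tab$logFC) & tab$logFC != 0, , drop = FALSE]
    dir <- ifelse(tab$logFC > 0, "up", "down")
  } else {
    stop("DEG table needs a 'direction' or a 'logFC' column")
  }
  calls <- stats::setNames(dir, tab$gene_id)
  dup <- unique(names(calls)[duplicated(names(calls))])
  for (g in dup) {
    if (length(unique(calls[names(calls) == g])) > 1L) {
      stop("gene '", g, "' is listed as both up- and downregulated")
    }
  }
  calls[!duplicated(names(calls))]
}

#' Regulation state of one reaction
#'
#' A reaction is upregulated if all of its differentially expressed
#' associated genes are upregulated, downregulated if all are
#' downregulated, and unregulated if the associated calls are mixed or if
#' no associated gene is called (including reactions without a GPR).
#' Association is set membership in the GPR (see [genes_of()]).
#'
#' @param model a `minea_model`.
#' @param reaction_id reaction id.
#' @param gene_calls named vector from [load_deg_table()].
#' @return one of `"up"`, `"down"`, `"unregulated"`.
#' @export
reaction_state <- function(model, reaction_id, gene_calls) {
  genes <- genes_of(model, reaction_id)
  called <- gene_calls[intersect(genes, names(gene_calls))]
  if (length(called) == 0L) return("unregulated")
  dirs <- unique(unname(called))
  if (identical(dirs, "up")) "up"
  else if (identical(dirs, "down")) "down"
  else "unregulated"
}

#' Assign regulation states across a model
#'
#' Computes per-reaction regulation states at the parent-reaction level
#' (both split directions inherit the parent's state) and the census
#' `(R, R_up, R_down, R_no)` over parent reactions, which always satisfies
#' `R = R_up + R_down + R_no`.
#'
#' @param model a `minea_model`.
#' @param gene_calls named vector of `"up"`/`"down"` calls.
#' @param condition label for the condition pair (e.g. `"NS_vs_N"`).
#' @return a `minea_regulation`: list with `condition`, `gene_calls`
#'   (restricted to model genes; the unmatched ones kept in attribute
#'   `"unmatched"`), `reaction_states` (named, parent level) and `census`.
#' @export
assign_regulation <- function(model, gene_calls, condition = "condition") {
  stopifnot(inherits(model, "minea_model"))
  unmatched <- setdiff(names(gene_calls), model$genes)
  model_calls <- gene_calls[setdiff(names(gene_calls), unmatched)]
  rxn <- model$reactions
  parents <- rxn$id[!duplicated(rxn$parent_id)]
  states <- vapply(parents, function(id)
    reaction_state(model, id, model_calls), character(1))
  names(states) <- rxn$parent_id[!duplicated(rxn$parent_id)]
  cen <- regulation_census(states)
  out <- structure(list(condition = condition, gene_calls = model_calls,
                        reaction_states = states, census = cen),
                   class = "minea_regulation")
  attr(out$gene_calls, "unmatched") <- unmatched
  out
}

#' Census of reaction regulation states
#'
#' @param states named character vector of `"up"`/`"down"`/`"unregulated"`.
#' @return named integer vector `(R, R_up, R_down, R_no)` with
#'   `R = R_up + R_down + R_no`.
#' @export
regulation_census <- function(states) {
  out <- c(R = length(states),
           R_up = sum(states == "up"),
           R_down = sum(states == "down"),
           R_no = sum(states == "unregulated"))
  stopifnot(out[["R"]] == out[["R_up"]] + out[["R_down"]] + out[["R_no"]])
  out
}

#' @export
print.minea_regulation <- function(x, ...) {
  cen <- x$census
  cat(sprintf(
    "minea_regulation '%s': %d gene calls; reactions: %d up, %d down, %d unregulated of %d\n",
    x$condition, length(x$gene_calls), cen[["R_up"]], cen[["R_down"]],
    cen[["R_no"]], cen[["R"]]))
  invisible(x)
}
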