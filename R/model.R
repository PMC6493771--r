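#' Construct a metabolic model object
#'
#' The container used throughout the package: a stoichiometric matrix with
#' per-reaction flux bounds, subsystem labels and parsed GPR rules.  It is a
#' deliberately small S3 analogue of the COBRA model structure.
#'
#' @param id model identifier.
#' @param metabolites data frame with columns `id`, `compartment`.
#' @param reactions data frame with columns `id`, `lb`, `ub`, `subsystem`,
#'   `parent_id` (equal to `id` for unsplit reactions).
#' @param stoich data frame of triplets with columns `metabolite`,
#'   `reaction`, `coefficient` (negative = consumed).
#' @param gprs named list of GPR trees (names = reaction ids); reactions
#'   without an entry have no gene association.
#' @param genes character vector of gene ids; defaults to the union of the
#'   GPR leaf sets.
#' @return an object of class `minea_model`.
#' @export
minea_model <- function(id, metabolites, reactions, stoich, gprs = list(),
                        genes = NULL) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  stoich <- as.data.frame(stoich, stringsAsFactors = FALSE)
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  if (is.null(reactions$parent_id)) reactions$parent_id <- reactions$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- ""
  gpr_leaves <- unique(unlist(lapply(gprs, gpr_genes), use.names = FALSE))
  if (is.null(genes)) genes <- gpr_leaves
  genes <- sort(unique(c(genes, gpr_leaves)))
  S <- Matrix::sparseMatrix(
    i = match(stoich$metabolite, metabolites$id),
    j = match(stoich$reaction, reactions$id),
    x = as.numeric(stoich$coefficient),
    dims = c(nrow(metabolites), nrow(reactions)),
    dimnames = list(metabolites$id, reactions$id))
  model <- structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         stoich = S, gprs = gprs, genes = genes),
    class = "minea_model")
  validate_model(model)
}

#' Validate a metabolic model
#'
#' Checks referential integrity of the stoichiometry, uniqueness of ids, and
#' the bound conventions; called by every constructor and loader.
#'
#' @param model a `minea_model`.
#' @return the model, invisibly unchanged, or an error.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "minea_model"))
  rxn <- model$reactions
  met <- model$metabolites
  if (anyDuplicated(rxn$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", "))
  }
  if (anyDuplicated(met$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(met$id[duplicated(met$id)]), collapse = ", "))
  }
  if (!identical(dim(model$stoich), c(nrow(met), nrow(rxn)))) {
    stop("stoichiometric matrix dimensions do not match metabolite/reaction tables")
  }
  if (any(rxn$ub < rxn$lb)) {
    stop("reaction with upper bound below lower bound: ",
         paste(rxn$id[rxn$ub < rxn$lb], collapse = ", "))
  }
  bad_gpr <- setdiff(names(model$gprs), rxn$id)
  if (length(bad_gpr)) {
    stop("GPR rules for unknown reactions: ", paste(bad_gpr, collapse = ", "))
  }
  leaves <- unique(unlist(lapply(model$gprs, gpr_genes), use.names = FALSE))
  missing_genes <- setdiff(leaves, model$genes)
  if (length(missing_genes)) {
    stop("GPR genes missing from gene set: ",
         paste(missing_genes, collapse = ", "))
  }
  invisible(model)
}

#' @export
print.minea_model <- function(x, ...) {
  cat(sprintf("minea_model '%s': %d metabolites, %d reactions, %d genes\n",
              x$id, nrow(x$metabolites), nrow(x$reactions), length(x$genes)))
  n_rev <- sum(x$reactions$lb < 0)
  if (n_rev) cat(sprintf("  %d reversible reactions (not yet split)\n", n_rev))
  invisible(x)
}

#' Default flux capacity used for unbounded reactions
#'
#' Any absent, infinite or over-large bound is clipped to this value when a
#' model is loaded, following the usual COBRA convention; it also serves as
#' the big-M constant coupling fluxes to activity indicators in the MILP.
#' @export
MINEA_VMAX <- 1000

#' Load a genome-scale metabolic model
#'
#' Reads a COBRA-style JSON model or an SBML Level 3 file (with the `fbc`
#' package for bounds and gene associations).  GPR strings are parsed into
#' trees; rules that fail to parse are recorded as empty with a warning.
#'
#' @param path path to the model file.
#' @param format `"auto"` (by file extension), `"cobra-json"`, or `"sbml"`.
#' @param vmax flux cap replacing infinite or missing bounds.
#' @return a validated `minea_model`.
#' @export
load_model <- function(path, format = c("auto", "cobra-json", "sbml"),
                       vmax = MINEA_VMAX) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "cobra-json"
              else "sbml"
  }
  switch(format,
         "cobra-json" = load_model_json(path, vmax),
         "sbml" = load_model_sbml(path, vmax))
}

clip_bound <- function(x, vmax) {
  x <- as.numeric(x)
  x[!is.finite(x) & x > 0] <- vmax
  x[!is.finite(x) & x < 0] <- -vmax
  pmax(pmin(x, vmax), -vmax)
}

parse_gpr_safely <- function(text, rxn_id) {
  tryCatch(parse_gpr(text), error = function(e) {
    warning("unparseable GPR for reaction ", rxn_id, " ('", text,
            "'): recorded as empty", call. = FALSE)
    NULL
  })
}

load_model_json <- function(path, vmax) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed JSON model '", path,
                                           "': ", conditionMessage(e)))
  for (field in c("metabolites", "reactions")) {
    if (is.null(doc[[field]])) stop("malformed model: missing '", field, "'")
  }
  met <- data.frame(
    id = vapply(doc$metabolites, function(m) as.character(m$id), character(1)),
    compartment = vapply(doc$metabolites, function(m) {
      if (!is.null(m$compartment)) as.character(m$compartment)
      else sub("^.*_", "", as.character(m$id))
    }, character(1)),
    stringsAsFactors = FALSE)
  trip <- list()
  gprs <- list()
  rxn <- data.frame(
    id = character(0), lb = numeric(0), ub = numeric(0),
    subsystem = character(0), stringsAsFactors = FALSE)
  for (r in doc$reactions) {
    rid <- as.character(r$id)
    if (is.null(r$metabolites) || length(r$metabolites) == 0L) {
      stop("reaction '", rid, "' has no stoichiometry")
    }
    lb <- if (is.null(r$lower_bound)) -vmax else r$lower_bound
    ub <- if (is.null(r$upper_bound)) vmax else r$upper_bound
    rxn <- rbind(rxn, data.frame(
      id = rid, lb = clip_bound(lb, vmax), ub = clip_bound(ub, vmax),
      subsystem = if (is.null(r$subsystem)) "" else as.character(r$subsystem),
      stringsAsFactors = FALSE))
    trip[[rid]] <- data.frame(
      metabolite = names(r$metabolites), reaction = rid,
      coefficient = as.numeric(unlist(r$metabolites)),
      stringsAsFactors = FALSE)
    rule <- r$gene_reaction_rule
    if (!is.null(rule) && nzchar(trimws(rule))) {
      tree <- parse_gpr_safely(rule, rid)
      if (!is.null(tree)) gprs[[rid]] <- tree
    }
  }
  stoich <- do.call(rbind, c(trip, list(make.row.names = FALSE)))
  unknown <- setdiff(stoich$metabolite, met$id)
  if (length(unknown)) {
    stop("stoichiometry references unknown metabolites: ",
         paste(unknown, collapse = ", "))
  }
  genes <- if (!is.null(doc$genes)) {
    vapply(doc$genes, function(g) as.character(g$id), character(1))
  } else NULL
  mid <- if (!is.null(doc$id)) as.character(doc$id) else basename(path)
  minea_model(mid, met, rxn, stoich, gprs, genes)
}

sbml_local_name <- function(nodes) vapply(nodes, xml2::xml_name, character(1))

load_model_sbml <- function(path, vmax) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML model '", path,
                                           "': ", conditionMessage(e)))
  ns <- c(s = xml2::xml_ns(doc)[[1]])
  model_node <- xml2::xml_find_first(doc, "./*[local-name() = 'model']")
  if (inherits(model_node, "xml_missing")) stop("malformed SBML: no <model>")
  mid <- xml2::xml_attr(model_node, "id")
  if (is.na(mid)) mid <- basename(path)

  params <- xml2::xml_find_all(model_node,
    ".//*[local-name() = 'listOfParameters']/*[local-name() = 'parameter']")
  param_val <- stats::setNames(
    as.numeric(xml2::xml_attr(params, "value")),
    xml2::xml_attr(params, "id"))

  sp <- xml2::xml_find_all(model_node,
    ".//*[local-name() = 'listOfSpecies']/*[local-name() = 'species']")
  if (length(sp) == 0L) stop("malformed SBML: no species")
  met <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    compartment = ifelse(is.na(xml2::xml_attr(sp, "compartment")), "",
                         xml2::xml_attr(sp, "compartment")),
    boundary = xml2::xml_attr(sp, "boundaryCondition") %in% "true",
    stringsAsFactors = FALSE)

  rx_nodes <- xml2::xml_find_all(model_node,
    ".//*[local-name() = 'listOfReactions']/*[local-name() = 'reaction']")
  if (length(rx_nodes) == 0L) stop("malformed SBML: no reactions")
  rxn <- data.frame(id = character(0), lb = numeric(0), ub = numeric(0),
                    subsystem = character(0), stringsAsFactors = FALSE)
  trip <- list(); gprs <- list()
  for (node in rx_nodes) {
    rid <- xml2::xml_attr(node, "id")
    reversible <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(param_val)) param_val[[lb_ref]]
          else if (reversible) -vmax else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(param_val)) param_val[[ub_ref]]
          else vmax
    subsystem <- ""
    notes <- xml2::xml_find_first(node, ".//*[local-name() = 'notes']")
    if (!inherits(notes, "xml_missing")) {
      txt <- xml2::xml_text(notes)
      m <- regmatches(txt, regexpr("SUBSYSTEM:[^<\n]*", txt))
      if (length(m)) subsystem <- trimws(sub("SUBSYSTEM:", "", m))
    }
    reac <- xml2::xml_find_all(node,
      ".//*[local-name() = 'listOfReactants']/*[local-name() = 'speciesReference']")
    prod <- xml2::xml_find_all(node,
      ".//*[local-name() = 'listOfProducts']/*[local-name() = 'speciesReference']")
    if (length(reac) + length(prod) == 0L) {
      stop("reaction '", rid, "' has no stoichiometry")
    }
    coef_of <- function(nodes, sign) {
      if (length(nodes) == 0L) return(NULL)
      st <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
      st[is.na(st)] <- 1
      data.frame(metabolite = xml2::xml_attr(nodes, "species"), reaction = rid,
                 coefficient = sign * st, stringsAsFactors = FALSE)
    }
    trip[[rid]] <- rbind(coef_of(reac, -1), coef_of(prod, +1))
    rxn <- rbind(rxn, data.frame(
      id = rid, lb = clip_bound(lb, vmax), ub = clip_bound(ub, vmax),
      subsystem = subsystem, stringsAsFactors = FALSE))
    gpa <- xml2::xml_find_first(node,
      ".//*[local-name() = 'geneProductAssociation']")
    if (!inherits(gpa, "xml_missing")) {
      tree <- sbml_gpa_tree(xml2::xml_children(gpa)[[1]])
      if (!is.null(tree)) gprs[[rid]] <- tree
    }
  }
  # boundary-condition species are sinks/sources: drop their mass-balance rows
  stoich <- do.call(rbind, c(trip, list(make.row.names = FALSE)))
  keep <- !met$boundary
  stoich <- stoich[stoich$metabolite %in% met$id[keep], , drop = FALSE]
  met <- met[keep, c("id", "compartment")]

  gp_nodes <- xml2::xml_find_all(model_node,
    ".//*[local-name() = 'listOfGeneProducts']/*[local-name() = 'geneProduct']")
  genes <- if (length(gp_nodes)) xml2::xml_attr(gp_nodes, "label") else NULL
  if (!is.null(genes) && all(is.na(genes))) genes <- xml2::xml_attr(gp_nodes, "id")
  minea_model(mid, met, rxn, stoich, gprs, genes)
}

sbml_gpa_tree <- function(node) {
  name <- xml2::xml_name(node)
  if (name == "geneProductRef") {
    g <- xml2::xml_attr(node, "label")
    if (is.na(g)) g <- xml2::xml_attr(node, "geneProduct")
    return(list(op = "gene", gene = g))
  }
  if (name %in% c("and", "or")) {
    return(list(op = name,
                args = lapply(xml2::xml_children(node), sbml_gpa_tree)))
  }
  NULL
}

#' Write a model as COBRA-style JSON
#'
#' Inverse of [load_model()] for the JSON dialect; used for fixture
#' round-trips and to export synthetic models.
#'
#' @param model a `minea_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "minea_model"))
  S <- model$stoich
  rx <- lapply(seq_len(nrow(model$reactions)), function(j) {
    r <- model$reactions[j, ]
    col <- S[, j]
    nz <- which(col != 0)
    mets <- as.list(col[nz])
    names(mets) <- rownames(S)[nz]
    tree <- model$gprs[[r$id]]
    list(id = r$id, metabolites = mets,
         lower_bound = r$lb, upper_bound = r$ub,
         subsystem = r$subsystem,
         gene_reaction_rule = gpr_to_string(tree))
  })
  doc <- list(
    id = model$id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      list(id = model$metabolites$id[i],
           compartment = model$metabolites$compartment[i])
    }),
    reactions = rx,
    genes = lapply(model$genes, function(g) list(id = g)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Split reversible reactions into irreversible forward pairs
#'
#' Every reaction with a negative lower bound is replaced by a forward copy
#' (`<id>_fwd`, bounds `[0, ub]`) and a reverse copy (`<id>_rev`, bounds
#' `[0, -lb]`, negated stoichiometry); both carry the original id in
#' `parent_id` and share its GPR and subsystem.  Irreversible reactions keep
#' their id, with the lower bound clipped to zero.  The transformation
#' preserves the net feasible flux cone and is idempotent.
#'
#' @param model a `minea_model`.
#' @param vmax cap replacing non-positive forward capacity of a reversible
#'   reaction whose `ub` is 0 (so the forward copy is inert, not invalid).
#' @return the split `minea_model`.
#' @export
split_reversible <- function(model, vmax = MINEA_VMAX) {
  stopifnot(inherits(model, "minea_model"))
  S <- model$stoich
  rows <- list(); trip <- list(); gprs <- list()
  for (j in seq_len(nrow(model$reactions))) {
    r <- model$reactions[j, ]
    col <- S[, j]
    nz <- which(col != 0)
    base_trip <- data.frame(metabolite = rownames(S)[nz], reaction = r$id,
                            coefficient = as.numeric(col[nz]),
                            stringsAsFactors = FALSE)
    tree <- model$gprs[[r$id]]
    if (r$lb < 0) {
      fid <- paste0(r$parent_id, "_fwd"); rid <- paste0(r$parent_id, "_rev")
      rows[[length(rows) + 1L]] <- data.frame(
        id = fid, lb = 0, ub = max(r$ub, 0), subsystem = r$subsystem,
        parent_id = r$parent_id, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        id = rid, lb = 0, ub = -r$lb, subsystem = r$subsystem,
        parent_id = r$parent_id, stringsAsFactors = FALSE)
      tf <- base_trip; tf$reaction <- fid
      tr <- base_trip; tr$reaction <- rid; tr$coefficient <- -tr$coefficient
      trip[[length(trip) + 1L]] <- tf
      trip[[length(trip) + 1L]] <- tr
      if (!is.null(tree)) { gprs[[fid]] <- tree; gprs[[rid]] <- tree }
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        id = r$id, lb = 0, ub = r$ub, subsystem = r$subsystem,
        parent_id = r$parent_id, stringsAsFactors = FALSE)
      trip[[length(trip) + 1L]] <- base_trip
      if (!is.null(tree)) gprs[[r$id]] <- tree
    }
  }
  minea_model(model$id, model$metabolites,
              do.call(rbind, c(rows, list(make.row.names = FALSE))),
              do.call(rbind, c(trip, list(make.row.names = FALSE))),
              gprs, model$genes)
}

#' Restrict reaction directionalities
#'
#' Applies an externally supplied directionality table (for example derived
#' from thermodynamic curation) by silencing the forbidden direction of each
#' listed reaction: its upper bound is set to zero.  On a split model the
#' table names parent ids and the corresponding `_fwd`/`_rev` copy is
#' silenced; on an unsplit model bounds are tightened directly.
#'
#' @param model a `minea_model`.
#' @param restrictions data frame with columns `reaction_id` and `direction`
#'   (one of `"forward"`, `"reverse"`, `"both"`), or a path to a headered
#'   TSV with those columns.
#' @return the restricted `minea_model`.
#' @export
apply_directionality <- function(model, restrictions) {
  stopifnot(inherits(model, "minea_model"))
  if (is.character(restrictions)) {
    restrictions <- utils::read.delim(restrictions, stringsAsFactors = FALSE)
  }
  restrictions <- as.data.frame(restrictions, stringsAsFactors = FALSE)
  if (nrow(restrictions) == 0L) return(model)
  stopifnot(all(c("reaction_id", "direction") %in% names(restrictions)))
  bad_dir <- setdiff(restrictions$direction, c("forward", "reverse", "both"))
  if (length(bad_dir)) stop("unknown direction value(s): ",
                            paste(bad_dir, collapse = ", "))
  known <- unique(c(model$reactions$id, model$reactions$parent_id))
  unknown <- setdiff(restrictions$reaction_id, known)
  if (length(unknown)) {
    stop("directionality table lists unknown reactions: ",
         paste(unknown, collapse = ", "))
  }
  rxn <- model$reactions
  for (i in seq_len(nrow(restrictions))) {
    id <- restrictions$reaction_id[i]
    dir <- restrictions$direction[i]
    if (dir == "both") next
    hit <- rxn$id == id | rxn$parent_id == id
    for (j in which(hit)) {
      split_pair <- sum(rxn$parent_id == rxn$parent_id[j]) > 1L
      if (split_pair) {
        is_rev <- grepl("_rev$", rxn$id[j])
        if ((dir == "forward" && is_rev) || (dir == "reverse" && !is_rev)) {
          rxn$ub[j] <- 0
        }
      } else {
        if (dir == "forward") rxn$lb[j] <- max(rxn$lb[j], 0)
        if (dir == "reverse") rxn$ub[j] <- min(rxn$ub[j], 0)
      }
    }
  }
  model$reactions <- rxn
  validate_model(model)
  model
}

#' Genes associated with a reaction
#'
#' Set-membership association: all genes appearing anywhere in the
#' reaction's GPR rule, deduplicated; the boolean structure is ignored, as
#' in the enrichment statistics.
#'
#' @param model a `minea_model`.
#' @param reaction_id a reaction id present in the model.
#' @return character vector of gene ids (possibly empty).
#' @export
genes_of <- function(model, reaction_id) {
  stopifnot(inherits(model, "minea_model"))
  if (!reaction_id %in% model$reactions$id) {
    stop("unknown reaction id: ", reaction_id)
  }
  gpr_genes(model$gprs[[reaction_id]])
}
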