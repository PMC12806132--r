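#' @useDynLib fluxomix, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct a metabolic model
#'
#' A `metabolic_model` is a light container for a stoichiometric network:
#' metabolites (rows of the stoichiometric matrix S), reactions (columns,
#' each with bounds, a subsystem/pathway label and an optional GPR rule),
#' and a designated objective reaction (typically growth/biomass).
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions Named list of reactions, each a list with fields
#'   `id`, `stoichiometry` (named numeric, metabolite id -> signed
#'   coefficient), `lower_bound`, `upper_bound`, `subsystem` (character or
#'   `NA`), `gpr` (a `gpr` object or `NULL`).
#' @param objective_id Reaction id whose flux is maximised by default.
#' @param id Optional model identifier string.
#' @return A validated `metabolic_model` object.
#' @export
metabolic_model <- function(metabolites, reactions, objective_id, id = "model") {
  names(reactions) <- vapply(reactions, function(r) r$id, "")
  m <- structure(list(
    id = id,
    metabolites = metabolites,
    reactions = reactions,
    objective_id = objective_id
  ), class = "metabolic_model")
  validate_model(m)
  m
}

#' Validate a metabolic model's structural invariants
#'
#' Checks id uniqueness, bound ordering, resolvable stoichiometry keys
#' and the existence of the objective reaction. Called by all
#' constructors/readers; exported so hand-built models can be checked.
#'
#' @param model A `metabolic_model`.
#' @return The model, invisibly; errors name the offending element.
#' @export
validate_model <- function(model) {
  met_ids <- model$metabolites$id
  if (anyDuplicated(met_ids)) {
    stop("duplicate metabolite id: ",
         met_ids[duplicated(met_ids)][1], call. = FALSE)
  }
  if (any(!nzchar(met_ids))) stop("empty metabolite id", call. = FALSE)
  rxn_ids <- vapply(model$reactions, function(r) r$id, "")
  if (anyDuplicated(rxn_ids)) {
    stop("duplicate reaction id: ",
         rxn_ids[duplicated(rxn_ids)][1], call. = FALSE)
  }
  for (r in model$reactions) {
    if (!is.numeric(r$lower_bound) || !is.numeric(r$upper_bound) ||
        r$lower_bound > r$upper_bound) {
      stop("reaction '", r$id, "': lower_bound must be <= upper_bound",
           call. = FALSE)
    }
    unknown <- setdiff(names(r$stoichiometry), met_ids)
    if (length(unknown)) {
      stop("reaction '", r$id, "' references unknown metabolite: ",
           unknown[1], call. = FALSE)
    }
  }
  if (!model$objective_id %in% rxn_ids) {
    stop("objective reaction '", model$objective_id,
         "' not present in model", call. = FALSE)
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model '%s'>\n", x$id))
  cat(sprintf("  metabolites: %d\n", nrow(x$metabolites)))
  cat(sprintf("  reactions:   %d\n", length(x$reactions)))
  cat(sprintf("  genes:       %d\n", length(model_genes(x))))
  cat(sprintf("  objective:   %s\n", x$objective_id))
  invisible(x)
}

#' Reaction ids of a model
#' @param model A `metabolic_model`.
#' @return Character vector in model order.
#' @export
reaction_ids <- function(model) {
  vapply(model$reactions, function(r) r$id, "")
}

#' All genes referenced by the model's GPR rules
#' @param model A `metabolic_model`.
#' @return Character vector of unique gene ids.
#' @export
model_genes <- function(model) {
  unique(unlist(lapply(model$reactions, function(r) gpr_genes(r$gpr))))
}

#' Dense stoichiometric matrix S (metabolites x reactions)
#' @param model A `metabolic_model`.
#' @return Numeric matrix with metabolite ids as rows, reaction ids as
#'   columns.
#' @export
stoich_matrix <- function(model) {
  met_ids <- model$metabolites$id
  rxns <- model$reactions
  S <- matrix(0, nrow = length(met_ids), ncol = length(rxns),
              dimnames = list(met_ids, names(rxns)))
  for (j in seq_along(rxns)) {
    st <- rxns[[j]]$stoichiometry
    if (length(st)) S[names(st), j] <- unname(st)
  }
  S
}

#' Map subsystem labels to reaction-id sets
#'
#' @param model A `metabolic_model`.
#' @return Named list, one character vector of reaction ids per
#'   subsystem; reactions without a label are omitted.
#' @export
subsystem_index <- function(model) {
  subs <- vapply(model$reactions, function(r) {
    s <- r$subsystem
    if (is.null(s) || length(s) == 0 || is.na(s)) NA_character_ else s
  }, "")
  ids <- reaction_ids(model)
  keep <- !is.na(subs) & nzchar(subs)
  split(ids[keep], subs[keep])
}

#' Exchange reactions of a model
#'
#' Exchange/sink reactions are recognised structurally: exactly one
#' metabolite in the stoichiometry.
#'
#' @param model A `metabolic_model`.
#' @return Character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  ids <- reaction_ids(model)
  ids[vapply(model$reactions, function(r) length(r$stoichiometry) == 1L,
             logical(1))]
}

#' Read a metabolic model from file
#'
#' Supports the COBRA-style JSON interchange format and SBML Level 3 with
#' the flux-balance-constraints (fbc) package. GPR rule strings are parsed
#' into ASTs at read time; default bounds follow the constraint-based
#' modelling convention of `[0, 1000]` (irreversible) and `[-1000, 1000]`
#' (reversible) when a file omits them.
#'
#' @param path Path to the model file.
#' @param format `"json"`, `"sbml"`, or `"auto"` (by file extension).
#' @return A validated `metabolic_model`.
#' @export
read_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  if (format == "json") read_model_json(path) else read_model_sbml(path)
}

read_model_json <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed model JSON (", path, "): ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(doc$metabolites) || is.null(doc$reactions)) {
    stop("malformed model JSON: missing 'metabolites' or 'reactions' array",
         call. = FALSE)
  }
  mets <- data.frame(
    id = vapply(doc$metabolites, function(m) m$id %||% "", ""),
    name = vapply(doc$metabolites, function(m) m$name %||% "", ""),
    compartment = vapply(doc$metabolites, function(m) m$compartment %||% "", ""),
    stringsAsFactors = FALSE
  )
  obj_id <- NULL
  rxns <- lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("malformed model JSON: reaction without id",
                            call. = FALSE)
    st <- unlist(r$metabolites %||% list())
    lb <- r$lower_bound
    ub <- r$upper_bound
    rev <- isTRUE(r$reversible)
    if (is.null(lb)) lb <- if (rev) -1000 else 0
    if (is.null(ub)) ub <- 1000
    if (!is.null(r$objective_coefficient) && r$objective_coefficient != 0) {
      obj_id <<- r$id
    }
    list(
      id = r$id,
      stoichiometry = if (length(st)) st else stats::setNames(numeric(0), character(0)),
      lower_bound = as.numeric(lb),
      upper_bound = as.numeric(ub),
      subsystem = r$subsystem %||% NA_character_,
      gpr = parse_gpr(r$gene_reaction_rule %||% "")
    )
  })
  if (!is.null(doc$objective_id)) obj_id <- doc$objective_id
  if (is.null(obj_id)) {
    stop("model file defines no objective reaction ",
         "(no nonzero objective_coefficient)", call. = FALSE)
  }
  metabolic_model(mets, rxns, obj_id, id = doc$id %||% basename(path))
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML (", path, "): ",
                                           conditionMessage(e), call. = FALSE))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")), "",
                  xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE
  )
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  gp <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  glabel <- stats::setNames(xml2::xml_attr(gp, "label"), xml2::xml_attr(gp, "id"))
  parse_assoc <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- xml2::xml_attr(node, "geneProduct")
      lab <- if (ref %in% names(glabel)) unname(glabel[[ref]]) else ref
      return(structure(list(kind = "gene", gene = lab), class = "gpr"))
    }
    kids <- lapply(xml2::xml_children(node), parse_assoc)
    kids <- Filter(Negate(is.null), kids)
    if (length(kids) == 0) return(NULL)
    if (length(kids) == 1) return(kids[[1]])
    kind <- if (nm == "and") "and" else if (nm == "or") "or" else
      stop("malformed SBML fbc gene association node: ", nm, call. = FALSE)
    structure(list(kind = kind, children = kids), class = "gpr")
  }
  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rx_nodes, function(rn) {
    rid <- xml2::xml_attr(rn, "id")
    rev <- identical(xml2::xml_attr(rn, "reversible"), "true")
    reac <- xml2::xml_find_all(rn, "./s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(rn, "./s:listOfProducts/s:speciesReference", ns)
    coef <- function(nodes, sign) {
      if (length(nodes) == 0) return(stats::setNames(numeric(0), character(0)))
      sto <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
      sto[is.na(sto)] <- 1
      stats::setNames(sign * sto, xml2::xml_attr(nodes, "species"))
    }
    st <- c(coef(reac, -1), coef(prod, +1))
    st <- tapply(st, names(st), sum)  # merge duplicated species refs
    st <- stats::setNames(as.numeric(st), names(st))
    lb_ref <- xml2::xml_attr(rn, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rn, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pval)) pval[[lb_ref]]
          else if (rev) -1000 else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pval)) pval[[ub_ref]] else 1000
    ga <- xml2::xml_find_first(rn, "./fbc:geneProductAssociation", ns)
    gpr <- if (inherits(ga, "xml_node")) {
      kids <- xml2::xml_children(ga)
      if (length(kids)) parse_assoc(kids[[1]]) else NULL
    } else NULL
    list(id = rid, stoichiometry = st, lower_bound = lb, upper_bound = ub,
         subsystem = NA_character_, gpr = gpr)
  })
  fo <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives//fbc:fluxObjective", ns)
  if (!inherits(fo, "xml_node")) {
    stop("SBML model defines no fbc objective", call. = FALSE)
  }
  obj_id <- xml2::xml_attr(fo, "reaction")
  mid <- xml2::xml_attr(xml2::xml_find_first(doc, ".//s:model", ns), "id")
  metabolic_model(mets, rxns, obj_id,
                  id = if (is.na(mid)) basename(path) else mid)
}

#' Write a metabolic model as COBRA-style JSON
#'
#' @param model A `metabolic_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  genes <- model_genes(model)
  doc <- list(
    id = model$id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      list(id = model$metabolites$id[i],
           name = model$metabolites$name[i],
           compartment = model$metabolites$compartment[i])
    }),
    reactions = lapply(model$reactions, function(r) {
      list(
        id = r$id,
        metabolites = as.list(r$stoichiometry),
        lower_bound = r$lower_bound,
        upper_bound = r$upper_bound,
        subsystem = if (is.na(r$subsystem)) "" else r$subsystem,
        gene_reaction_rule = gpr_to_string(r$gpr),
        objective_coefficient = if (r$id == model$objective_id) 1 else 0
      )
    }),
    genes = lapply(genes, function(g) list(id = g))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Split reversible reactions into irreversible forward/backward pairs
#'
#' Expression-capped flux bounds require an all-irreversible network:
#' every reversible reaction (`lower_bound < 0 < upper_bound`) is split
#' into a forward copy (suffix `_f`, bounds `[0, ub]`) and a backward
#' copy (suffix `_b`, negated stoichiometry, bounds `[0, -lb]`), both
#' inheriting subsystem and GPR. Reactions that only run backwards are
#' flipped in place (suffix `_b`). Split copies stay adjacent in the
#' original reaction order so downstream flux matrices are reproducible.
#'
#' @param model A `metabolic_model`.
#' @return List with `model` (the irreversible `metabolic_model`) and
#'   `split_map` (named list: original id -> character vector of
#'   derived ids).
#' @export
make_irreversible <- function(model) {
  out <- list()
  split_map <- list()
  for (r in model$reactions) {
    if (r$lower_bound >= 0) {
      out <- c(out, list(r))
      split_map[[r$id]] <- r$id
    } else if (r$upper_bound <= 0) {
      rb <- r
      rb$id <- paste0(r$id, "_b")
      rb$stoichiometry <- -r$stoichiometry
      rb$lower_bound <- -r$upper_bound
      rb$upper_bound <- -r$lower_bound
      out <- c(out, list(rb))
      split_map[[r$id]] <- rb$id
    } else {
      rf <- r; rb <- r
      rf$id <- paste0(r$id, "_f")
      rf$lower_bound <- 0
      rb$id <- paste0(r$id, "_b")
      rb$stoichiometry <- -r$stoichiometry
      rb$lower_bound <- 0
      rb$upper_bound <- -r$lower_bound
      out <- c(out, list(rf), list(rb))
      split_map[[r$id]] <- c(rf$id, rb$id)
    }
  }
  obj <- model$objective_id
  if (!obj %in% vapply(out, function(r) r$id, "")) {
    obj <- split_map[[obj]][1]
  }
  m2 <- metabolic_model(model$metabolites, out, obj,
                        id = paste0(model$id, "_irrev"))
  list(model = m2, split_map = split_map)
}

#' Collapse split reaction ids back to their parent id
#'
#' Strips the `_f`/`_b` suffixes introduced by [make_irreversible()],
#' so forward/backward copies of one reaction count once (used e.g. when
#' building the enrichment universe).
#'
#' @param ids Character vector of reaction ids.
#' @param split_map Optional split map from [make_irreversible()]; when
#'   supplied, only ids actually produced by splitting are collapsed.
#' @return Character vector of parent ids (same length as `ids`).
#' @export
collapse_split_ids <- function(ids, split_map = NULL) {
  if (!is.null(split_map)) {
    rev_map <- stats::setNames(
      rep(names(split_map), lengths(split_map)),
      unlist(split_map))
    mapped <- unname(rev_map[ids])
    return(ifelse(is.na(mapped), ids, mapped))
  }
  sub("_(f|b)$", "", ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
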