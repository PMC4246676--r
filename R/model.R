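#' Construct a stoichiometric model
#'
#' A `stoich_model` bundles metabolites, reactions (with bounds, gene
#' associations and pathway/compartment labels) and a biomass-style objective
#' reaction, in the conventional constraint-based-modeling form: the feasible
#' flux space is \eqn{\{v : S v = 0,\ lb \le v \le ub\}}.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions list of reactions; each a list with elements `id`, `name`,
#'   `stoichiometry` (named numeric, negative = consumed), `lower_bound`,
#'   `upper_bound` (flux, umol/h), `pathway`, `compartment`, `genes`
#'   (character vector, any-gene-suffices semantics), `exchange` (logical).
#' @param objective id of the reaction whose flux is maximized.
#' @param flux_ratios optional data.frame of flux-ratio constraints with
#'   columns `numerator`, `denominator`, `ratio`; each encodes the linear
#'   equality \eqn{v_{num} - r\, v_{den} = 0}.
#' @return object of class `stoich_model`.
#' @export
stoich_model <- function(metabolites, reactions, objective, flux_ratios = NULL) {
  model <- structure(
    list(metabolites = metabolites, reactions = reactions,
         objective = objective, flux_ratios = flux_ratios),
    class = "stoich_model")
  validate_model(model)
  model
}

#' @export
print.stoich_model <- function(x, ...) {
  cat(sprintf("stoich_model: %d metabolites, %d reactions, objective '%s'\n",
              nrow(x$metabolites), length(x$reactions), x$objective))
  if (!is.null(x$flux_ratios) && nrow(x$flux_ratios) > 0)
    cat(sprintf("  %d flux-ratio constraint(s)\n", nrow(x$flux_ratios)))
  invisible(x)
}

#' Reaction ids of a model
#' @param model a `stoich_model`.
#' @return character vector.
#' @export
reaction_ids <- function(model) {
  vapply(model$reactions, function(r) r$id, character(1))
}

#' Stoichiometric matrix (metabolites x reactions)
#' @param model a `stoich_model`.
#' @return dense numeric matrix with metabolite ids as rownames and reaction
#'   ids as colnames.
#' @export
stoich_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- reaction_ids(model)
  S <- matrix(0, nrow = length(mets), ncol = length(rxns),
              dimnames = list(mets, rxns))
  for (r in model$reactions) {
    st <- r$stoichiometry
    if (length(st)) S[names(st), r$id] <- unlist(st)
  }
  S
}

#' Flux bounds of a model
#' @param model a `stoich_model`.
#' @return data.frame with `reaction_id`, `lower_bound`, `upper_bound`.
#' @export
model_bounds <- function(model) {
  data.frame(
    reaction_id = reaction_ids(model),
    lower_bound = vapply(model$reactions, function(r) r$lower_bound, numeric(1)),
    upper_bound = vapply(model$reactions, function(r) r$upper_bound, numeric(1)),
    stringsAsFactors = FALSE)
}

#' Validate a stoichiometric model
#'
#' Checks every structural invariant and reports all violations at once:
#' unique metabolite ids, every stoichiometry key resolves to a metabolite,
#' `lower_bound <= upper_bound`, non-empty stoichiometry unless flagged as an
#' exchange, and an existing objective reaction.
#'
#' @param model a `stoich_model`.
#' @return the model, invisibly; stops with an informative message listing
#'   every violation otherwise.
#' @export
validate_model <- function(model) {
  errs <- character(0)
  mets <- model$metabolites$id
  if (anyDuplicated(mets))
    errs <- c(errs, sprintf("duplicate metabolite id(s): %s",
                            paste(unique(mets[duplicated(mets)]), collapse = ", ")))
  rids <- vapply(model$reactions, function(r) r$id, character(1))
  if (anyDuplicated(rids))
    errs <- c(errs, sprintf("duplicate reaction id(s): %s",
                            paste(unique(rids[duplicated(rids)]), collapse = ", ")))
  for (r in model$reactions) {
    unknown <- setdiff(names(r$stoichiometry), mets)
    if (length(unknown))
      errs <- c(errs, sprintf("reaction '%s' references unknown metabolite(s): %s",
                              r$id, paste(unknown, collapse = ", ")))
    if (r$lower_bound > r$upper_bound)
      errs <- c(errs, sprintf("reaction '%s': lower_bound (%g) > upper_bound (%g)",
                              r$id, r$lower_bound, r$upper_bound))
    if (length(r$stoichiometry) == 0 && !isTRUE(r$exchange))
      errs <- c(errs, sprintf("reaction '%s': empty stoichiometry but not an exchange",
                              r$id))
  }
  if (!model$objective %in% rids)
    errs <- c(errs, sprintf("objective reaction '%s' not in model", model$objective))
  fr <- model$flux_ratios
  if (!is.null(fr) && nrow(fr) > 0) {
    bad <- setdiff(unique(c(fr$numerator, fr$denominator)), rids)
    if (length(bad))
      errs <- c(errs, sprintf("flux-ratio constraint references unknown reaction(s): %s",
                              paste(bad, collapse = ", ")))
  }
  if (length(errs))
    stop("invalid model:\n  - ", paste(errs, collapse = "\n  - "), call. = FALSE)
  invisible(model)
}

# normalize one reaction record coming from JSON / constructors
.as_reaction <- function(r) {
  st <- r$stoichiometry
  st <- if (is.null(st)) numeric(0) else {
    v <- unlist(st)
    stats::setNames(as.numeric(v), names(v))
  }
  list(id = as.character(r$id),
       name = as.character(if (is.null(r$name)) r$id else r$name),
       stoichiometry = st,
       lower_bound = as.numeric(r$lower_bound),
       upper_bound = as.numeric(r$upper_bound),
       pathway = as.character(if (is.null(r$pathway)) "unassigned" else r$pathway),
       compartment = as.character(if (is.null(r$compartment)) "c" else r$compartment),
       genes = as.character(unlist(r$genes)),
       exchange = isTRUE(r$exchange))
}

#' Read a stoichiometric model from JSON
#'
#' The JSON schema mirrors the `stoich_model` constructor: top-level keys
#' `metabolites` (array of id/name/compartment), `reactions` (array with
#' stoichiometry as a metabolite->coefficient object), `objective`, and an
#' optional `flux_ratios` array of numerator/denominator/ratio records.
#'
#' @param path path to a model JSON file.
#' @return a validated `stoich_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  mets <- do.call(rbind, lapply(j$metabolites, function(m)
    data.frame(id = m$id, name = if (is.null(m$name)) m$id else m$name,
               compartment = m$compartment, stringsAsFactors = FALSE)))
  rxns <- lapply(j$reactions, .as_reaction)
  fr <- NULL
  if (!is.null(j$flux_ratios) && length(j$flux_ratios))
    fr <- do.call(rbind, lapply(j$flux_ratios, function(q)
      data.frame(numerator = q$numerator, denominator = q$denominator,
                 ratio = as.numeric(q$ratio), stringsAsFactors = FALSE)))
  stoich_model(mets, rxns, j$objective, fr)
}

#' Write a stoichiometric model to JSON
#' @param model a `stoich_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  j <- list(
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i)
      as.list(model$metabolites[i, c("id", "name", "compartment")])),
    reactions = lapply(model$reactions, function(r) {
      list(id = r$id, name = r$name, stoichiometry = as.list(r$stoichiometry),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           pathway = r$pathway, compartment = r$compartment,
           genes = as.list(r$genes), exchange = r$exchange)
    }),
    objective = model$objective)
  if (!is.null(model$flux_ratios) && nrow(model$flux_ratios) > 0)
    j$flux_ratios <- lapply(seq_len(nrow(model$flux_ratios)), function(i)
      as.list(model$flux_ratios[i, ]))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a stoichiometric model from SBML (Level 3 core + fbc subset)
#'
#' Minimal importer for SBML Level-3 files using the `fbc` package for flux
#' bounds and objective: species, reactions with stoichiometry and
#' reversibility, fbc bound parameters and the active fbc objective, and fbc
#' gene-product associations (flattened to a plain gene set per reaction).
#'
#' @param path path to an SBML file.
#' @return a validated `stoich_model`.
#' @export
read_sbml_model <- function(path) {
  if (!file.exists(path)) stop("SBML file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  pars <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- lapply(rx, function(node) {
    id <- xml2::xml_attr(node, "id")
    rea <- xml2::xml_find_all(node, "./listOfReactants/speciesReference")
    pro <- xml2::xml_find_all(node, "./listOfProducts/speciesReference")
    st <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(rea, "stoichiometry")),
                      xml2::xml_attr(rea, "species")),
      stats::setNames(as.numeric(xml2::xml_attr(pro, "stoichiometry")),
                      xml2::xml_attr(pro, "species")))
    lbp <- xml2::xml_attr(node, "lowerFluxBound")
    ubp <- xml2::xml_attr(node, "upperFluxBound")
    lb <- if (!is.na(lbp) && lbp %in% names(parval)) parval[[lbp]] else
      if (identical(xml2::xml_attr(node, "reversible"), "true")) -1000 else 0
    ub <- if (!is.na(ubp) && ubp %in% names(parval)) parval[[ubp]] else 1000
    gp <- xml2::xml_find_all(node, ".//*[local-name()='geneProductRef']")
    genes <- xml2::xml_attr(gp, "geneProduct")
    .as_reaction(list(id = id, name = xml2::xml_attr(node, "name"),
                      stoichiometry = st, lower_bound = lb, upper_bound = ub,
                      genes = genes,
                      exchange = length(st) < 2 && grepl("^EX_", id)))
  })
  obj <- xml2::xml_attr(
    xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']"),
    "reaction")
  if (is.na(obj)) stop("SBML file has no fbc flux objective", call. = FALSE)
  stoich_model(mets, rxns, obj)
}
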