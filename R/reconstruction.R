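## Toy genome-scale reconstructions: a minimal JSON schema (with an
## SBML-subset reader) sufficient to exercise community construction and
## flux variability analysis.  Metabolites are referenced in stoichiometry
## maps as "id[compartment]"; exchange reactions are single-metabolite
## reactions over the extracellular compartment [e] whose positive
## direction is secretion out of the microbe.

#' Construct a metabolic reconstruction
#'
#' @param id species (or strain) label.
#' @param metabolites data.frame with columns \code{id} and
#'   \code{compartment} ("c" cytosol, "e" extracellular).
#' @param reactions list of reactions, each a list with \code{id},
#'   \code{stoichiometry} (named numeric, names "met[comp]"),
#'   \code{lower}, \code{upper}.
#' @param biomass_reaction id of the biomass reaction.
#' @param exchange_reactions ids of the exchange reactions (community
#'   construction rewires these into lumen transporters).
#' @return validated object of class \code{reconstruction}.
#' @export
reconstruction <- function(id, metabolites, reactions, biomass_reaction,
                           exchange_reactions = character()) {
  obj <- structure(list(id = id,
                        metabolites = metabolites,
                        reactions = reactions,
                        biomass_reaction = biomass_reaction,
                        exchange_reactions = exchange_reactions),
                   class = "reconstruction")
  validate_reconstruction(obj)
}

met_key <- function(metabolites)
  paste0(metabolites$id, "[", metabolites$compartment, "]")

#' @rdname reconstruction
#' @param x object to validate.
#' @export
validate_reconstruction <- function(x) {
  stopifnot(inherits(x, "reconstruction"))
  missing <- setdiff(c("id", "metabolites", "reactions", "biomass_reaction"),
                     names(x)[!vapply(x, is.null, logical(1))])
  if (length(missing))
    stop("reconstruction is missing fields: ", paste(missing, collapse = ", "))
  rxn_ids <- vapply(x$reactions, `[[`, "", "id")
  if (anyDuplicated(rxn_ids))
    stop("duplicate reaction ids: ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  names(x$reactions) <- rxn_ids
  if (!x$biomass_reaction %in% rxn_ids)
    stop("biomass reaction '", x$biomass_reaction,
         "' not found among the reactions")
  if (length(bad <- setdiff(x$exchange_reactions, rxn_ids)))
    stop("exchange reactions not found: ", paste(bad, collapse = ", "))
  keys <- met_key(x$metabolites)
  for (r in x$reactions) {
    if (is.null(r$lower) || is.null(r$upper) || r$lower > r$upper)
      stop("reaction '", r$id, "' has invalid bounds")
    if (length(unres <- setdiff(names(r$stoichiometry), keys)))
      stop("reaction '", r$id, "' references unknown metabolites: ",
           paste(unres, collapse = ", "))
  }
  x
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf("Reconstruction '%s': %d metabolites, %d reactions (%d exchanges)\n",
              x$id, nrow(x$metabolites), length(x$reactions),
              length(x$exchange_reactions)))
  invisible(x)
}

#' Read / write a reconstruction as JSON
#'
#' The schema mirrors the \code{\link{reconstruction}} constructor; the
#' write-read round trip is the identity.
#'
#' @param path file path.
#' @return for the reader, a validated \code{reconstruction}.
#' @export
read_reconstruction <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  mets <- do.call(rbind, lapply(x$metabolites, function(m)
    data.frame(id = m$id, compartment = m$compartment,
               stringsAsFactors = FALSE)))
  rxns <- lapply(x$reactions, function(r) {
    sto <- unlist(r$stoichiometry)
    list(id = r$id,
         stoichiometry = stats::setNames(as.numeric(sto), names(sto)),
         lower = as.numeric(r$lower), upper = as.numeric(r$upper))
  })
  reconstruction(id = x$id, metabolites = mets, reactions = rxns,
                 biomass_reaction = x$biomass_reaction,
                 exchange_reactions = as.character(unlist(x$exchange_reactions)))
}

#' @rdname read_reconstruction
#' @param model a \code{reconstruction}.
#' @export
write_reconstruction <- function(model, path) {
  out <- list(
    id = model$id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i)
      list(id = model$metabolites$id[i],
           compartment = model$metabolites$compartment[i])),
    reactions = lapply(unname(model$reactions), function(r)
      list(id = r$id, stoichiometry = as.list(r$stoichiometry),
           lower = r$lower, upper = r$upper)),
    biomass_reaction = model$biomass_reaction,
    exchange_reactions = as.list(model$exchange_reactions))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an SBML-subset reconstruction
#'
#' Parses the minimal SBML (level 3, fbc) structure needed here: species
#' with compartments, reactions with stoichiometry and fbc flux bounds.
#' Exchange reactions are recognised by id prefix \code{EX_}; the biomass
#' reaction by the \code{fbc:objective} or, failing that, an id starting
#' with \code{bm}.
#'
#' @param path SBML file path.
#' @return validated \code{reconstruction}.
#' @export
read_reconstruction_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  id <- xml2::xml_attr(model, "id")

  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sp_id <- xml2::xml_attr(sp, "id")
  sp_comp <- xml2::xml_attr(sp, "compartment")
  ## SBML species ids carry a "_<compartment>" suffix (glc_c, glc_e);
  ## strip it so the same metabolite shares one id across compartments
  base_id <- ifelse(endsWith(sp_id, paste0("_", sp_comp)),
                    substr(sp_id, 1L, nchar(sp_id) - nchar(sp_comp) - 1L),
                    sp_id)
  mets <- data.frame(id = base_id, compartment = sp_comp,
                     stringsAsFactors = FALSE)

  par <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(par, "value")),
                          xml2::xml_attr(par, "id"))

  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rx, function(r) {
    rid <- xml2::xml_attr(r, "id")
    sto <- c()
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(r, paste0("./s:", side, "/s:speciesReference"),
                                 ns)
      if (length(refs)) {
        coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
        if (side == "listOfReactants") coef <- -coef
        idx <- match(xml2::xml_attr(refs, "species"), sp_id)
        sto <- c(sto, stats::setNames(coef, paste0(base_id[idx], "[",
                                                   sp_comp[idx], "]")))
      }
    }
    at <- xml2::xml_attrs(r)
    lb <- unname(at[endsWith(names(at), "lowerFluxBound")][1L])
    ub <- unname(at[endsWith(names(at), "upperFluxBound")][1L])
    list(id = rid, stoichiometry = sto,
         lower = unname(pval[lb]), upper = unname(pval[ub]))
  })
  rxn_ids <- vapply(rxns, `[[`, "", "id")

  obj <- xml2::xml_find_first(doc, ".//fbc:fluxObjective", ns)
  biomass <- if (!inherits(obj, "xml_missing")) {
    at <- xml2::xml_attrs(obj)
    unname(at[endsWith(names(at), "reaction")][1L])
  } else rxn_ids[startsWith(rxn_ids, "bm")][1L]
  reconstruction(id = id, metabolites = mets, reactions = rxns,
                 biomass_reaction = biomass,
                 exchange_reactions = rxn_ids[startsWith(rxn_ids, "EX_")])
}

#' Merge strain reconstructions into a species pan-model
#'
#' Takes the union of the member reactions (identical ids merged, keeping
#' the widest bounds; differing stoichiometry under one id is an error)
#' and replaces the member biomass reactions by their arithmetic mean:
#' each metabolite coefficient is the sum of its coefficients over all
#' members divided by the number of members.
#'
#' @param members non-empty list of \code{reconstruction} objects of the
#'   same species.
#' @param id label of the pan-model (defaults to the first member's id).
#' @return a \code{reconstruction}.
#' @export
build_pan_model <- function(members, id = members[[1L]]$id) {
  stopifnot(length(members) >= 1L)
  for (m in members) stopifnot(inherits(m, "reconstruction"))

  mets <- unique(do.call(rbind, lapply(members, `[[`, "metabolites")))
  nm <- length(members)

  rxns <- list()
  bm_sto <- c()        # running sum of biomass stoichiometries
  bm_lb <- Inf; bm_ub <- -Inf
  exch <- character()
  for (m in members) {
    for (r in m$reactions) {
      if (r$id == m$biomass_reaction) {
        all_keys <- union(names(bm_sto), names(r$stoichiometry))
        s <- stats::setNames(numeric(length(all_keys)), all_keys)
        s[names(bm_sto)] <- bm_sto
        s[names(r$stoichiometry)] <- s[names(r$stoichiometry)] +
          r$stoichiometry
        bm_sto <- s
        bm_lb <- min(bm_lb, r$lower); bm_ub <- max(bm_ub, r$upper)
        next
      }
      if (is.null(rxns[[r$id]])) {
        rxns[[r$id]] <- r
      } else {
        prev <- rxns[[r$id]]
        same <- identical(sort(names(prev$stoichiometry)),
                          sort(names(r$stoichiometry))) &&
          all(abs(prev$stoichiometry[names(r$stoichiometry)] -
                    r$stoichiometry) < 1e-12)
        if (!same)
          stop("conflicting stoichiometry for reaction id '", r$id,
               "' across pan-model members")
        rxns[[r$id]]$lower <- min(prev$lower, r$lower)
        rxns[[r$id]]$upper <- max(prev$upper, r$upper)
      }
    }
    exch <- union(exch, m$exchange_reactions)
  }
  bm_id <- members[[1L]]$biomass_reaction
  rxns[[bm_id]] <- list(id = bm_id, stoichiometry = bm_sto / nm,
                        lower = bm_lb, upper = bm_ub)
  reconstruction(id = id, metabolites = mets, reactions = rxns,
                 biomass_reaction = bm_id, exchange_reactions = exch)
}
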