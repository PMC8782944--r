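.COMPARTMENTS <- c("extracellular", "cytosol", "mitochondria",
                   "microsome", "lysosome")

#' Construct and validate a metabolic network
#'
#' @param metabolites data.frame with columns id, name, compartment
#'   (compartment from the closed five-set: extracellular, cytosol,
#'   mitochondria, microsome, lysosome).
#' @param reactions list; each element a list with fields id, stoich
#'   (named numeric, metabolite id -> signed coefficient), reversible,
#'   lb, ub, subsystem, tags (character vector, subset of
#'   `exchange`, `ros_producing`, `atp_demand`), exchange_metabolite
#'   (name of the transported species for exchange reactions, else NA).
#' @return object of class "metabolic_network".
#' @export
metabolic_network <- function(metabolites, reactions) {
  stopifnot(is.data.frame(metabolites),
            all(c("id", "name", "compartment") %in% names(metabolites)))
  bad_comp <- setdiff(unique(metabolites$compartment), .COMPARTMENTS)
  if (length(bad_comp))
    stop("unknown compartment(s): ", paste(bad_comp, collapse = ", "))
  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite id(s)")
  ids <- metabolites$id
  rxn_ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rxn_ids)) stop("duplicate reaction id(s)")
  n_demand <- 0L
  for (r in reactions) {
    dangling <- setdiff(names(r$stoich), ids)
    if (length(dangling))
      stop(sprintf("reaction '%s' references absent metabolite(s): %s",
                   r$id, paste(dangling, collapse = ", ")))
    if (is.null(r$lb) || is.null(r$ub) || r$lb > r$ub)
      stop(sprintf("reaction '%s': bounds must satisfy lb <= ub", r$id))
    if (!isTRUE(r$reversible) && r$lb < 0)
      stop(sprintf("reaction '%s': irreversible but lb < 0", r$id))
    if ("atp_demand" %in% r$tags) n_demand <- n_demand + 1L
  }
  if (n_demand != 1L)
    stop("exactly one reaction must be tagged 'atp_demand'; found ",
         n_demand)
  structure(list(metabolites = metabolites, reactions = reactions),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network> %d metabolites, %d reactions, %d subsystems\n",
              nrow(x$metabolites), length(x$reactions),
              length(unique(subsystems(x)))))
  invisible(x)
}

#' Reaction ids / subsystem labels / tag lookup
#' @param network a metabolic_network.
#' @return character vector.
#' @export
reaction_ids <- function(network) {
  vapply(network$reactions, `[[`, "", "id")
}

#' @rdname reaction_ids
#' @export
subsystems <- function(network) {
  vapply(network$reactions, function(r)
    if (is.null(r$subsystem)) "unassigned" else r$subsystem, "")
}

#' @rdname reaction_ids
#' @param tag tag to select on.
#' @export
reactions_with_tag <- function(network, tag) {
  reaction_ids(network)[vapply(network$reactions,
                               function(r) tag %in% r$tags, TRUE)]
}

#' Stoichiometric matrix
#'
#' @param network a metabolic_network.
#' @return metabolites x reactions numeric matrix with dimnames.
#' @export
stoich_matrix <- function(network) {
  mets <- network$metabolites$id
  rids <- reaction_ids(network)
  S <- matrix(0, length(mets), length(rids),
              dimnames = list(mets, rids))
  for (j in seq_along(network$reactions)) {
    st <- network$reactions[[j]]$stoich
    S[names(st), j] <- as.numeric(st)
  }
  S
}

## ---- JSON schema -----------------------------------------------------

#' Load a metabolic network from JSON
#'
#' Schema: `{metabolites: [{id, name, compartment}], reactions: [{id,
#' stoich: {met: coef}, reversible, lb, ub, subsystem, tags, exchange_metabolite}]}`.
#' All invariants are enforced on load.
#'
#' @param path path to a JSON network file.
#' @return metabolic_network.
#' @export
load_network <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$metabolites) || is.null(j$reactions))
    stop("network file must contain 'metabolites' and 'reactions'")
  mets <- do.call(rbind, lapply(j$metabolites, function(m)
    data.frame(id = m$id, name = m$name, compartment = m$compartment)))
  rxns <- lapply(j$reactions, function(r) {
    list(id = r$id,
         stoich = unlist(r$stoich),
         reversible = isTRUE(r$reversible),
         lb = as.numeric(r$lb), ub = as.numeric(r$ub),
         subsystem = if (is.null(r$subsystem)) "unassigned" else r$subsystem,
         tags = as.character(unlist(r$tags)),
         exchange_metabolite = if (is.null(r$exchange_metabolite))
           NA_character_ else r$exchange_metabolite)
  })
  metabolic_network(mets, rxns)
}

#' @rdname load_network
#' @param network metabolic_network to serialize.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "metabolic_network"))
  j <- list(
    metabolites = lapply(seq_len(nrow(network$metabolites)), function(i)
      as.list(network$metabolites[i, c("id", "name", "compartment")])),
    reactions = lapply(network$reactions, function(r)
      list(id = r$id, stoich = as.list(r$stoich),
           reversible = r$reversible, lb = r$lb, ub = r$ub,
           subsystem = r$subsystem, tags = as.list(r$tags),
           exchange_metabolite = r$exchange_metabolite)))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' The bundled reduced cardiomyocyte network
#'
#' A hand-curated ~45-reaction stand-in for a genome-scale cardiomyocyte
#' reconstruction: glucose uptake and lumped glycolysis, glycogen
#' turnover, lactate exchange, pyruvate oxidation, a lumped TCA cycle,
#' beta-oxidation of four phospholipid-derived acyl-CoA species
#' (palmitoyl-, hexadecenoyl-, stearoyl-, oleoyl-CoA), lumped oxidative
#' phosphorylation with ROS by-production, the creatine kinase shuttle
#' and an ATP-demand objective, spread over the five compartments.
#'
#' @return metabolic_network.
#' @export
cardiomyocyte_network <- function() {
  load_network(system.file("extdata", "cardionet_reduced.json",
                           package = "cardiomet", mustWork = TRUE))
}

## ---- toy fixtures ----------------------------------------------------

#' Generate a toy metabolic network
#'
#' Three fixtures for optimizer oracle tests: `chain` (uptake ->
#' conversion yielding 2 ATP -> ATP demand), `branched` (two routes with
#' ATP yields 2 and 1), `blocked` (ATP demand with no producing path).
#'
#' @param kind one of "chain", "branched", "blocked".
#' @return metabolic_network.
#' @export
generate_toy_network <- function(kind = c("chain", "branched", "blocked")) {
  kind <- match.arg(kind)
  mets <- data.frame(id = c("sub_c", "atp_c"),
                     name = c("substrate", "ATP"),
                     compartment = "cytosol")
  rx <- function(id, stoich, lb, ub, subsystem, tags = character(0),
                 exch = NA_character_, reversible = FALSE)
    list(id = id, stoich = stoich, reversible = reversible, lb = lb,
         ub = ub, subsystem = subsystem, tags = tags,
         exchange_metabolite = exch)
  demand <- rx("ATP_DEMAND", c(atp_c = -1), 0, 1000,
               "Energy maintenance", "atp_demand")
  rxns <- switch(kind,
    chain = list(
      rx("UPT", c(sub_c = 1), 0, 10, "Exchange", "exchange", "substrate"),
      rx("CONV", c(sub_c = -1, atp_c = 2), 0, 1000, "Conversion"),
      demand),
    branched = list(
      rx("UPT", c(sub_c = 1), 0, 10, "Exchange", "exchange", "substrate"),
      rx("HIGH", c(sub_c = -1, atp_c = 2), 0, 1000, "Conversion"),
      rx("LOW", c(sub_c = -1, atp_c = 1), 0, 1000, "Conversion"),
      demand),
    blocked = list(
      rx("UPT", c(sub_c = 1), 0, 10, "Exchange", "exchange", "substrate"),
      demand))
  metabolic_network(mets, rxns)
}

## ---- SBML subset -----------------------------------------------------

.SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"
.CM_NS <- "https://cardiomet.invalid/sbml-annotations"

#' Export / import the network as an SBML Level 3 core subset
#'
#' Compartments, species and reactions (with stoichiometry and the
#' reversible flag) use plain SBML Level 3 core; bounds, subsystem, tags
#' and the exchanged metabolite travel in a package annotation element,
#' so the JSON and SBML representations carry identical content.
#'
#' @param network metabolic_network.
#' @param path file path.
#' @export
write_network_sbml <- function(network, path) {
  stopifnot(inherits(network, "metabolic_network"))
  doc <- xml2::xml_new_root("sbml", xmlns = .SBML_NS,
                            "xmlns:cardiomet" = .CM_NS, level = "3",
                            version = "2")
  model <- xml2::xml_add_child(doc, "model", id = "cardiomet_model")
  lc <- xml2::xml_add_child(model, "listOfCompartments")
  for (cp in unique(network$metabolites$compartment))
    xml2::xml_add_child(lc, "compartment", id = cp, constant = "true")
  ls <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(network$metabolites)))
    xml2::xml_add_child(ls, "species",
                        id = network$metabolites$id[i],
                        name = network$metabolites$name[i],
                        compartment = network$metabolites$compartment[i],
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  lr <- xml2::xml_add_child(model, "listOfReactions")
  for (r in network$reactions) {
    rn <- xml2::xml_add_child(lr, "reaction", id = r$id,
                              reversible = tolower(as.character(r$reversible)))
    ann <- xml2::xml_add_child(rn, "annotation")
    xml2::xml_add_child(ann, "cardiomet:info",
                        lb = format(r$lb, digits = 17),
                        ub = format(r$ub, digits = 17),
                        subsystem = r$subsystem,
                        tags = paste(r$tags, collapse = " "),
                        exchangeMetabolite =
                          if (is.na(r$exchange_metabolite)) ""
                          else r$exchange_metabolite)
    reac <- r$stoich[r$stoich < 0]
    prod <- r$stoich[r$stoich > 0]
    if (length(reac)) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (m in names(reac))
        xml2::xml_add_child(lre, "speciesReference", species = m,
                            stoichiometry = format(-reac[[m]], digits = 17),
                            constant = "true")
    }
    if (length(prod)) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (m in names(prod))
        xml2::xml_add_child(lpr, "speciesReference", species = m,
                            stoichiometry = format(prod[[m]], digits = 17),
                            constant = "true")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_network_sbml
#' @export
read_network_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = .SBML_NS, cm = .CM_NS)
  sp <- xml2::xml_find_all(doc, ".//s:species", ns)
  mets <- data.frame(id = xml2::xml_attr(sp, "id"),
                     name = xml2::xml_attr(sp, "name"),
                     compartment = xml2::xml_attr(sp, "compartment"))
  rxn_nodes <- xml2::xml_find_all(doc, ".//s:reaction", ns)
  rxns <- lapply(rxn_nodes, function(rn) {
    info <- xml2::xml_find_first(rn, ".//cm:info", ns)
    sr <- function(which, sign) {
      refs <- xml2::xml_find_all(
        rn, sprintf("./s:%s/s:speciesReference", which), ns)
      stats::setNames(sign * as.numeric(xml2::xml_attr(refs,
                                                       "stoichiometry")),
                      xml2::xml_attr(refs, "species"))
    }
    st <- c(sr("listOfReactants", -1), sr("listOfProducts", 1))
    tags <- strsplit(xml2::xml_attr(info, "tags"), " ")[[1]]
    exch <- xml2::xml_attr(info, "exchangeMetabolite")
    list(id = xml2::xml_attr(rn, "id"), stoich = st,
         reversible = identical(xml2::xml_attr(rn, "reversible"), "true"),
         lb = as.numeric(xml2::xml_attr(info, "lb")),
         ub = as.numeric(xml2::xml_attr(info, "ub")),
         subsystem = xml2::xml_attr(info, "subsystem"),
         tags = tags[nzchar(tags)],
         exchange_metabolite = if (is.na(exch) || !nzchar(exch))
           NA_character_ else exch)
  })
  metabolic_network(mets, rxns)
}
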