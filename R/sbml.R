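#' Read an SBML Level 2/3 model
#'
#' Extracts what the topological method needs: species ids, compartments and
#' boundary flags; reaction ids, reversibility and reactant/product species
#' references; and, when the fbc extension is present, gene-product
#' associations flattened to boolean `and`/`or` rules. Stoichiometric
#' coefficients, kinetic laws and flux bounds are ignored. Legacy
#' notes-embedded `GENE_ASSOCIATION` strings are not parsed.
#'
#' @param path SBML file path.
#' @inheritParams metabolic_model
#' @return a [metabolic_model()].
#' @export
read_model_sbml <- function(path, id = NULL, extracellular_suffix = "_e$") {
  doc <- xml2::read_xml(path)
  sbml_ns <- xml2::xml_ns(doc)
  model_node <- xml2::xml_find_first(doc, ".//*[local-name() = 'model']")
  if (inherits(model_node, "xml_missing")) abort(paste0(path, ": no <model> element"))
  if (is.null(id)) {
    id <- xml2::xml_attr(model_node, "id")
    if (is.na(id)) id <- tools::file_path_sans_ext(basename(path))
  }
  level <- as.integer(xml2::xml_attr(xml2::xml_root(doc), "level"))
  if (is.na(level)) level <- 3L

  species_nodes <- xml2::xml_find_all(
    model_node, "./*[local-name() = 'listOfSpecies']/*[local-name() = 'species']")
  metabolites <- tibble(
    id = xml2::xml_attr(species_nodes, "id"),
    compartment = xml2::xml_attr(species_nodes, "compartment"),
    boundary = xml2::xml_attr(species_nodes, "boundaryCondition") %in% "true"
  )

  rxn_nodes <- xml2::xml_find_all(
    model_node, "./*[local-name() = 'listOfReactions']/*[local-name() = 'reaction']")
  if (length(rxn_nodes) == 0) abort(paste0(path, ": model has no reactions"))
  side <- function(node, which) {
    refs <- xml2::xml_find_all(
      node, paste0("./*[local-name() = '", which,
                   "']/*[local-name() = 'speciesReference']"))
    unique(xml2::xml_attr(refs, "species"))
  }
  rev_attr <- xml2::xml_attr(rxn_nodes, "reversible")
  # SBML Level 2 defaults reversible to true when the attribute is absent;
  # Level 3 makes it mandatory, but tolerate absence the same way.
  reversible <- ifelse(is.na(rev_attr), level <= 2, rev_attr == "true")

  reactions <- tibble(
    id = xml2::xml_attr(rxn_nodes, "id"),
    reversible = reversible,
    reactants = lapply(rxn_nodes, side, which = "listOfReactants"),
    products = lapply(rxn_nodes, side, which = "listOfProducts"),
    gpr = vapply(rxn_nodes, sbml_gpr, character(1))
  )
  metabolic_model(reactions, metabolites = metabolites, id = id,
                  extracellular_suffix = extracellular_suffix)
}

# Flatten an fbc geneProductAssociation subtree into an "and"/"or" rule string.
sbml_gpr <- function(rxn_node) {
  assoc <- xml2::xml_find_first(
    rxn_node, "./*[local-name() = 'geneProductAssociation']")
  if (inherits(assoc, "xml_missing")) return(NA_character_)
  kids <- xml2::xml_children(assoc)
  if (length(kids) == 0) return(NA_character_)
  flatten_gpr_node(kids[[1]])
}

flatten_gpr_node <- function(node) {
  name <- xml2::xml_name(node)
  if (name == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    return(ref)
  }
  op <- switch(name, "and" = " and ", "or" = " or ", NA_character_)
  if (is.na(op)) return(NA_character_)
  parts <- vapply(xml2::xml_children(node), flatten_gpr_node, character(1))
  parts <- parts[!is.na(parts)]
  if (length(parts) == 0) return(NA_character_)
  paste0("(", paste(parts, collapse = op), ")")
}
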