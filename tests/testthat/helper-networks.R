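# Small builders shared across tests. Networks are written r: A + B -> C.

mk_model <- function(ids, ins, outs, reversible = FALSE, gpr = NA_character_,
                     metabolites = NULL) {
  metabolic_model(
    tibble::tibble(id = ids, reversible = reversible,
                   reactants = ins, products = outs, gpr = gpr),
    metabolites = metabolites
  )
}

mk_graph <- function(ids, ins, outs, reversible = FALSE) {
  build_graph(mk_model(ids, ins, outs, reversible))
}

# Canonical string keys for a list of reaction sets, for set-of-sets equality.
set_keys <- function(sets) {
  sort(vapply(sets, function(s) paste(sort(s), collapse = "|"), character(1)))
}

# Naive scope oracle: fire every fireable reaction until nothing changes.
# Intentionally ignorant of the package's queue/counter machinery.
naive_scope <- function(graph, seeds) {
  avail <- unique(seeds)
  fired <- character(0)
  rx <- graph$reactions
  repeat {
    can <- vapply(seq_len(nrow(rx)), function(i) {
      !(rx$id[i] %in% fired) && all(rx$inputs[[i]] %in% avail)
    }, logical(1))
    if (!any(can)) break
    fired <- c(fired, rx$id[can])
    avail <- unique(c(avail, unlist(rx$outputs[can])))
  }
  list(scope = sort(avail), visited = sort(fired))
}

# Shuffle a model's reaction row order and the order inside each side's
# id list; graph semantics must be unaffected.
shuffle_model <- function(model, seed) {
  withr::with_seed(seed, {
    rx <- model$reactions[sample(nrow(model$reactions)), ]
    rx$reactants <- lapply(rx$reactants, function(v) v[sample(length(v))])
    rx$products <- lapply(rx$products, function(v) v[sample(length(v))])
    metabolic_model(rx, metabolites = model$metabolites[sample(nrow(model$metabolites)), ],
                    id = model$id)
  })
}

sbml_fixture <- function(path) {
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy_sbml">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
      <compartment id="e" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="glc_e" compartment="e" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
      <species id="glc_c" compartment="c" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
      <species id="pyr_c" compartment="c" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="GLCt" reversible="true" fast="false">
        <listOfReactants><speciesReference species="glc_e" stoichiometry="1" constant="true"/></listOfReactants>
        <listOfProducts><speciesReference species="glc_c" stoichiometry="1" constant="true"/></listOfProducts>
      </reaction>
      <reaction id="GLY" reversible="false" fast="false">
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:and>
              <fbc:geneProductRef fbc:geneProduct="g1"/>
              <fbc:geneProductRef fbc:geneProduct="g2"/>
            </fbc:and>
            <fbc:geneProductRef fbc:geneProduct="g3"/>
          </fbc:or>
        </fbc:geneProductAssociation>
        <listOfReactants><speciesReference species="glc_c" stoichiometry="1" constant="true"/></listOfReactants>
        <listOfProducts><speciesReference species="pyr_c" stoichiometry="2" constant="true"/></listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>', path)
  path
}
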