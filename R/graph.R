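#' Build the directed bipartite metabolite-reaction graph
#'
#' Every reaction becomes a reaction node with directed edges from each
#' reactant metabolite into the node and from the node out to each product
#' metabolite. Reversible reactions are split into two separate reaction
#' nodes: the forward half keeps the model id, the reverse half appends
#' `"_rev"` and swaps inputs and outputs; the halves reference each other
#' through `pair_id`. All model metabolites are kept as nodes even when no
#' reaction touches them.
#'
#' @param model a [metabolic_model()].
#' @param exchange_prefix reaction-id prefix marking exchange reactions, in
#'   addition to any reaction touching an extracellular or boundary
#'   metabolite.
#' @return an object of class `bipartite_graph` with tibbles `metabolites`
#'   (`id`, `organism`, `is_extracellular`) and `reactions` (`id`,
#'   `direction_role`, `pair_id`, `is_exchange`, list-columns `inputs` and
#'   `outputs`).
#' @export
build_graph <- function(model, exchange_prefix = "EX_") {
  stopifnot(inherits(model, "metabolic_model"))
  rx <- model$reactions
  is_ex <- detect_exchange(model, exchange_prefix)

  fwd <- tibble(
    id = rx$id,
    direction_role = ifelse(rx$reversible, "forward_of_pair", "irreversible"),
    pair_id = ifelse(rx$reversible, paste0(rx$id, "_rev"), ""),
    is_exchange = is_ex,
    inputs = rx$reactants,
    outputs = rx$products
  )
  rev_rows <- rx$reversible
  rev <- tibble(
    id = paste0(rx$id[rev_rows], "_rev"),
    direction_role = "reverse_of_pair",
    pair_id = rx$id[rev_rows],
    is_exchange = is_ex[rev_rows],
    inputs = rx$products[rev_rows],
    outputs = rx$reactants[rev_rows]
  )
  clash <- intersect(rev$id, fwd$id)
  if (length(clash) > 0) {
    abort(paste0("reverse-half id collision with existing reaction id(s): ",
                 paste(clash, collapse = ", ")))
  }
  reactions <- dplyr::arrange(dplyr::bind_rows(fwd, rev), .data$id)

  metabolites <- tibble(
    id = model$metabolites$id,
    organism = "",
    is_extracellular = model$metabolites$is_extracellular
  )
  metabolites <- dplyr::arrange(metabolites, .data$id)
  new_bipartite_graph(metabolites, reactions)
}

# exchange reactions: touch an extracellular/boundary metabolite, have an
# empty side (pure boundary reactions), or match the configured id prefix
detect_exchange <- function(model, exchange_prefix = "EX_") {
  ex_mets <- model$metabolites$id[model$metabolites$is_extracellular]
  vapply(seq_len(nrow(model$reactions)), function(i) {
    ins <- model$reactions$reactants[[i]]
    outs <- model$reactions$products[[i]]
    any(c(ins, outs) %in% ex_mets) ||
      length(ins) == 0 || length(outs) == 0 ||
      any(startsWith(model$reactions$id[i], exchange_prefix))
  }, logical(1))
}

new_bipartite_graph <- function(metabolites, reactions, organisms = NULL,
                                shared_extracellular_ids = NULL) {
  dup <- intersect(metabolites$id, reactions$id)
  if (length(dup) > 0) {
    abort(paste0("node id(s) used for both a metabolite and a reaction: ",
                 paste(dup, collapse = ", ")))
  }
  producers <- new.env(parent = emptyenv())
  consumers <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(reactions))) {
    rid <- reactions$id[i]
    for (m in reactions$outputs[[i]]) producers[[m]] <- c(producers[[m]], rid)
    for (m in reactions$inputs[[i]]) consumers[[m]] <- c(consumers[[m]], rid)
  }
  stray <- setdiff(c(unlist(reactions$inputs), unlist(reactions$outputs)),
                   metabolites$id)
  if (length(stray) > 0) {
    abort(paste0("reaction(s) reference metabolite(s) absent from the node set: ",
                 paste(head(stray, 5), collapse = ", ")))
  }
  g <- list(
    metabolites = metabolites,
    reactions = reactions,
    producers = producers,
    consumers = consumers,
    organisms = organisms,
    shared_extracellular_ids = shared_extracellular_ids
  )
  cls <- c(if (!is.null(organisms)) "community_graph", "bipartite_graph")
  structure(g, class = cls)
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat("<", class(x)[1], "> ", nrow(x$metabolites), " metabolites + ",
      nrow(x$reactions), " reactions, ", n_edges(x), " edges\n", sep = "")
  if (!is.null(x$organisms)) {
    cat("  organisms: ", paste(x$organisms, collapse = ", "),
        "; shared extracellular metabolites: ",
        length(x$shared_extracellular_ids), "\n", sep = "")
  }
  invisible(x)
}

#' Edge list of a bipartite graph
#'
#' @param graph a `bipartite_graph`.
#' @return tibble with columns `from`, `to`; metabolite -> reaction edges are
#'   reactant roles, reaction -> metabolite edges product roles.
#' @export
graph_edges <- function(graph) {
  stopifnot(inherits(graph, "bipartite_graph"))
  rx <- graph$reactions
  tibble(
    from = c(unlist(rx$inputs),
             rep(rx$id, lengths(rx$outputs))),
    to = c(rep(rx$id, lengths(rx$inputs)),
           unlist(rx$outputs))
  )
}

n_edges <- function(graph) {
  sum(lengths(graph$reactions$inputs)) + sum(lengths(graph$reactions$outputs))
}

#' Join models into a community bipartite graph
#'
#' Each organism's graph is built separately, every non-shared node id is
#' prefixed with its organism label (`"org1:"`, ...), and extracellular
#' metabolites that occur in the exchange reactions of at least two organisms
#' are merged into a single shared, untagged node — the common extracellular
#' medium through which cross-feeding can happen. Extracellular metabolites
#' unique to one organism's exchange reactions stay attached only to that
#' organism's boundary.
#'
#' @param models list of [metabolic_model()] objects (length >= 2 for a true
#'   community; a single model is allowed and simply gets tagged).
#' @param labels organism labels, default `org1`, `org2`, ...; must be unique.
#' @inheritParams build_graph
#' @return a `community_graph` (subclass of `bipartite_graph`) with fields
#'   `organisms` and `shared_extracellular_ids`.
#' @export
build_community_graph <- function(models, labels = NULL, exchange_prefix = "EX_") {
  stopifnot(length(models) >= 1)
  if (is.null(labels)) labels <- paste0("org", seq_along(models))
  if (anyDuplicated(labels)) abort("duplicate organism labels")
  if (length(labels) != length(models)) abort("one label per model required")

  # extracellular metabolites seen in each model's exchange reactions
  ex_mets_per_model <- lapply(models, function(m) {
    is_ex <- detect_exchange(m, exchange_prefix)
    if (!any(is_ex)) {
      warn(paste0("model '", m$id, "' has no detectable exchange reactions; ",
                  "it will share no metabolites with the community"))
      return(character(0))
    }
    touched <- unique(unlist(c(m$reactions$reactants[is_ex],
                               m$reactions$products[is_ex])))
    intersect(touched, m$metabolites$id[m$metabolites$is_extracellular])
  })
  counts <- table(unlist(ex_mets_per_model))
  shared <- sort(names(counts)[counts >= 2])

  graphs <- purrr::map2(models, labels, function(m, lab) {
    g <- build_graph(m, exchange_prefix = exchange_prefix)
    tag <- function(ids) ifelse(ids %in% shared, ids, paste0(lab, ":", ids))
    g$metabolites$organism <- ifelse(g$metabolites$id %in% shared, "", lab)
    g$metabolites$id <- tag(g$metabolites$id)
    g$reactions$id <- paste0(lab, ":", g$reactions$id)
    g$reactions$pair_id <- ifelse(nzchar(g$reactions$pair_id),
                                  paste0(lab, ":", g$reactions$pair_id), "")
    g$reactions$inputs <- lapply(g$reactions$inputs, tag)
    g$reactions$outputs <- lapply(g$reactions$outputs, tag)
    g
  })
  metabolites <- dplyr::distinct(
    dplyr::arrange(dplyr::bind_rows(lapply(graphs, `[[`, "metabolites")), .data$id),
    .data$id, .keep_all = TRUE)
  reactions <- dplyr::arrange(dplyr::bind_rows(lapply(graphs, `[[`, "reactions")),
                              .data$id)
  new_bipartite_graph(metabolites, reactions, organisms = labels,
                      shared_extracellular_ids = shared)
}

#' Organism tag of community node ids
#'
#' @param ids character vector of node ids.
#' @return character vector: the `"org:"` prefix of each id, or `""` for
#'   shared (untagged) nodes.
#' @export
organism_of <- function(ids) {
  ifelse(grepl(":", ids, fixed = TRUE), sub(":.*$", "", ids), "")
}

#' Convert to an igraph object
#'
#' Vertices carry a `bipartite` attribute (`"metabolite"` or `"reaction"`)
#' and, for community graphs, an `organism` attribute.
#'
#' @param graph a `bipartite_graph`.
#' @return an [igraph::graph] (directed).
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "bipartite_graph"))
  verts <- dplyr::bind_rows(
    tibble(name = graph$metabolites$id, bipartite = "metabolite",
           organism = graph$metabolites$organism),
    tibble(name = graph$reactions$id, bipartite = "reaction",
           organism = organism_of(graph$reactions$id))
  )
  igraph::graph_from_data_frame(graph_edges(graph), directed = TRUE,
                                vertices = verts)
}

#' Export a graph to GraphML or DOT
#'
#' @param graph a `bipartite_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_dot <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "dot")
  invisible(path)
}
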