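#' Generate toy metabolic networks with known pathway inventories
#'
#' Deterministic generator of small networks for testing, teaching and
#' benchmarking. Structured kinds carry their exact expected pathway sets by
#' construction; the `random` kind computes ground truth with the
#' independent reference enumerator ([derive_pathways()]), and is therefore
#' limited to 12 reactions. Generation is a pure function of the arguments:
#' identical calls give identical networks.
#'
#' Kinds:
#' * `linear_chain`: `r_i: m_{i-1} -> m_i`; one pathway of size n to `m_n`.
#' * `parallel_routes`: n reactions `m0 -> p`; n pathways of size 1.
#' * `branched_join`: n - 1 branches `m0 -> b_i` joined by one reaction
#'   consuming all of them; one branched pathway of size n.
#' * `cycle`: `m0 -> c1 -> ... -> m0`; one cyclic pathway of size n
#'   regenerating the seed, reported once.
#' * `community_pair`: two one-organism models cross-feeding through a
#'   shared extracellular metabolite `x_e`.
#' * `random`: connected-by-construction random network — each new reaction
#'   consumes at least one already-producible metabolite with probability
#'   0.7 (otherwise a fresh orphan metabolite, exercising stuck-reaction
#'   paths), so both branches of the guided BFS get coverage.
#'
#' @param kind one of `"linear_chain"`, `"parallel_routes"`,
#'   `"branched_join"`, `"cycle"`, `"community_pair"`, `"random"`.
#' @param n_reactions number of reactions (at least 1; at least 3 for
#'   `branched_join`, 2 for `cycle`; at most 12 for `random`).
#' @param seed RNG seed (only the `random` kind draws random numbers).
#' @param reversible_fraction fraction of reactions made reversible
#'   (`random` kind only).
#' @param beta size cut-off used when computing `random` ground truth.
#' @return list of class `toy_network` with elements `model` (or `models`
#'   for `community_pair`), `graph`, `seeds`, `targets`, and `ground_truth`
#'   (per target, the expected list of reaction-id sets).
#' @export
toy_network <- function(kind = c("linear_chain", "parallel_routes",
                                 "branched_join", "cycle", "community_pair",
                                 "random"),
                        n_reactions = 3, seed = 1,
                        reversible_fraction = 0, beta = 6) {
  kind <- match.arg(kind)
  stopifnot(n_reactions >= 1)
  n <- as.integer(n_reactions)
  out <- switch(
    kind,
    linear_chain = toy_linear_chain(n),
    parallel_routes = toy_parallel_routes(n),
    branched_join = toy_branched_join(n),
    cycle = toy_cycle(n),
    community_pair = toy_community_pair(),
    random = toy_random(n, seed, reversible_fraction, beta)
  )
  structure(c(out, list(kind = kind)), class = "toy_network")
}

#' @export
print.toy_network <- function(x, ...) {
  cat("<toy_network> kind = ", x$kind, "\n", sep = "")
  print(x$graph)
  invisible(x)
}

rxn_tbl <- function(ids, reactants, products, reversible = FALSE) {
  tibble(id = ids, reversible = reversible,
         reactants = reactants, products = products)
}

toy_linear_chain <- function(n) {
  ids <- sprintf("r%d", seq_len(n))
  mets <- sprintf("m%d", 0:n)
  model <- metabolic_model(rxn_tbl(
    ids,
    as.list(mets[seq_len(n)]),
    as.list(mets[seq_len(n) + 1])
  ), id = "linear_chain")
  tgt <- mets[n + 1]
  list(model = model, graph = build_graph(model), seeds = "m0",
       targets = tgt,
       ground_truth = setNames(list(list(sort(ids))), tgt))
}

toy_parallel_routes <- function(n) {
  ids <- sprintf("r%d", seq_len(n))
  model <- metabolic_model(rxn_tbl(
    ids, rep(list("m0"), n), rep(list("p"), n)
  ), id = "parallel_routes")
  list(model = model, graph = build_graph(model), seeds = "m0",
       targets = "p",
       ground_truth = list(p = lapply(ids, identity)))
}

toy_branched_join <- function(n) {
  stopifnot(n >= 3)
  nb <- n - 1L
  branch_ids <- sprintf("r%d", seq_len(nb))
  bmets <- sprintf("b%d", seq_len(nb))
  model <- metabolic_model(dplyr::bind_rows(
    rxn_tbl(branch_ids, rep(list("m0"), nb), as.list(bmets)),
    rxn_tbl("rjoin", list(bmets), list("t"))
  ), id = "branched_join")
  list(model = model, graph = build_graph(model), seeds = "m0",
       targets = "t",
       ground_truth = list(t = list(sort(c(branch_ids, "rjoin")))))
}

toy_cycle <- function(n) {
  stopifnot(n >= 2)
  ids <- sprintf("r%d", seq_len(n))
  mets <- c("m0", sprintf("c%d", seq_len(n - 1)), "m0")
  model <- metabolic_model(rxn_tbl(
    ids, as.list(mets[seq_len(n)]), as.list(mets[seq_len(n) + 1])
  ), id = "cycle")
  list(model = model, graph = build_graph(model), seeds = "m0",
       targets = "m0",
       ground_truth = setNames(list(list(sort(ids))), "m0"))
}

toy_community_pair <- function() {
  m1 <- metabolic_model(rxn_tbl(
    c("uptake1", "sec1"),
    list("glc_e", "a"),
    list("a", "x_e")
  ), id = "donor")
  m2 <- metabolic_model(rxn_tbl(
    c("uptake2", "conv2"),
    list("x_e", "b"),
    list("b", "prod")
  ), id = "recipient")
  graph <- build_community_graph(list(m1, m2))
  tgt <- "org2:prod"
  list(models = list(m1, m2), graph = graph, seeds = "org1:glc_e",
       targets = tgt,
       ground_truth = setNames(
         list(list(sort(c("org1:uptake1", "org1:sec1",
                          "org2:uptake2", "org2:conv2")))), tgt))
}

toy_random <- function(n, seed, reversible_fraction, beta) {
  if (n > 12) abort("random toy networks are limited to 12 reactions (ground truth via the reference enumerator)")
  withr::with_seed(seed, {
    producible <- c("s1", "s2")
    seeds <- c("s1", "s2")
    all_mets <- seeds
    rows <- vector("list", n)
    fresh <- 0L
    for (i in seq_len(n)) {
      if (stats::runif(1) < 0.7 || length(all_mets) == length(producible)) {
        ins <- sample(producible, min(length(producible), sample(1:2, 1)))
      } else {
        fresh <- fresh + 1L
        orphan <- sprintf("o%d", fresh)
        all_mets <- c(all_mets, orphan)
        ins <- unique(c(orphan, sample(all_mets, 1)))
      }
      n_new <- sample(1:2, 1)
      new_ids <- sprintf("x%d_%d", i, seq_len(n_new))
      outs <- unique(c(new_ids[stats::runif(n_new) < 0.8],
                       if (stats::runif(1) < 0.3) sample(all_mets, 1)))
      if (length(outs) == 0) outs <- new_ids[1]
      outs <- setdiff(outs, ins)
      if (length(outs) == 0) outs <- sprintf("x%d_f", i)
      all_mets <- unique(c(all_mets, outs))
      producible <- unique(c(producible, outs))
      rows[[i]] <- tibble(id = sprintf("r%02d", i),
                          reversible = stats::runif(1) < reversible_fraction,
                          reactants = list(ins), products = list(outs))
    }
    model <- metabolic_model(dplyr::bind_rows(rows),
                             metabolites = tibble(id = sort(unique(c(
                               all_mets,
                               unlist(lapply(rows, function(r) c(r$reactants[[1]],
                                                                 r$products[[1]]))))))),
                             id = "random")
    graph <- build_graph(model)
    sc <- guided_bfs(graph, seeds)
    targets <- setdiff(sc$scope, seeds)
    if (length(targets) > 3) targets <- sort(sample(targets, 3))
    gt <- lapply(targets, function(tg) derive_pathways(graph, seeds, tg, beta))
    list(model = model, graph = graph, seeds = seeds, targets = targets,
         ground_truth = setNames(gt, targets), beta = beta)
  })
}

#' Write a toy network (or any model) as fixture files
#'
#' Emits the tabular reaction-list dialect plus a seed file; reading the TSV
#' back with [read_model_tsv()] and rebuilding the graph reproduces the
#' original node and edge sets exactly.
#'
#' @param x a `toy_network`, `metabolic_model`, or `bipartite_graph`.
#' @param path_prefix path prefix; writes `<prefix>_reactions.tsv` and
#'   `<prefix>_seeds.txt`.
#' @param seeds seed ids (taken from a `toy_network` automatically).
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(x, path_prefix, seeds = NULL) {
  if (inherits(x, "toy_network")) {
    seeds <- seeds %||% x$seeds
    model <- x$model %||% NULL
    if (is.null(model)) abort("community toy networks: write each member model separately")
  } else if (inherits(x, "metabolic_model")) {
    model <- x
  } else if (inherits(x, "bipartite_graph")) {
    model <- graph_to_model(x)
  } else {
    abort("cannot write this object as a fixture")
  }
  paths <- c(reactions = paste0(path_prefix, "_reactions.tsv"),
             seeds = paste0(path_prefix, "_seeds.txt"))
  write_model_tsv(model, paths[["reactions"]])
  write_seeds(seeds %||% character(0), paths[["seeds"]])
  invisible(paths)
}

# Collapse a bipartite graph back to a model: reverse halves fold into their
# forward partner's reversible flag.
graph_to_model <- function(graph) {
  rx <- graph$reactions
  keep <- rx$direction_role != "reverse_of_pair"
  metabolic_model(tibble(
    id = rx$id[keep],
    reversible = rx$direction_role[keep] == "forward_of_pair",
    reactants = rx$inputs[keep],
    products = rx$outputs[keep]
  ), metabolites = tibble(id = graph$metabolites$id), id = "from_graph")
}
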