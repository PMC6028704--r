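#' Precursor-guided breadth-first scope expansion
#'
#' Starting from a seed set of freely and inexhaustibly available
#' metabolites, repeatedly fires every reaction whose input metabolites are
#' all available, adding its products to the available pool, until no further
#' reaction can fire. The result is the *scope* of the seed set: every
#' producible metabolite, the set of *visited* reactions (all inputs
#' producible), the *stuck* reactions (examined during the traversal — i.e.
#' at least one input is in scope — but still missing a precursor at the
#' fixpoint), and minimum step counts.
#'
#' A reaction that is stuck when first examined is triggered automatically if
#' its missing precursors are produced at any later stage: each metabolite
#' keeps the list of reactions waiting on it and decrements their
#' missing-precursor counters as it enters scope, so total work is linear in
#' the number of edges.
#'
#' Step counts are shortest-path distances in graph *edges* from the seed
#' frontier: seeds have `steps = 0`; a reaction fires at
#' `1 + max(steps of its inputs)` (its inputs must all exist before it can
#' fire, so reaction layers are odd); a non-seed metabolite gets
#' `1 + min(steps of its visited producers)`. These counts do not equal the
#' number of reactions needed and are used downstream only to prune the
#' enumeration.
#'
#' @param graph a `bipartite_graph` from [build_graph()] or
#'   [build_community_graph()].
#' @param seeds character vector of seed metabolite ids (all must exist in
#'   the graph).
#' @return an object of class `scope_result`: list with `scope`,
#'   `visited_reactions`, `stuck_reactions`, `untouched_reactions` (character
#'   vectors, sorted), `steps_metabolite` and `steps_reaction` (named numeric)
#'   and `seeds`.
#' @export
guided_bfs <- function(graph, seeds) {
  stopifnot(inherits(graph, "bipartite_graph"))
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0) abort("seed set must be non-empty")
  missing_seeds <- setdiff(seeds, graph$metabolites$id)
  if (length(missing_seeds) > 0) {
    abort(paste0("seed metabolite(s) absent from the graph: ",
                 paste(missing_seeds, collapse = ", ")))
  }

  rx <- graph$reactions
  nr <- nrow(rx)
  rid <- rx$id
  ins <- rx$inputs
  outs <- rx$outputs

  steps_m <- new.env(parent = emptyenv())
  for (s in seeds) steps_m[[s]] <- 0
  in_scope <- new.env(parent = emptyenv())
  for (s in seeds) in_scope[[s]] <- TRUE

  n_missing <- integer(nr)
  for (i in seq_len(nr)) {
    n_missing[i] <- sum(!(ins[[i]] %in% seeds))
  }
  visited <- logical(nr)
  cand <- rep(NA_real_, nr)   # firing layer, known once all inputs in scope
  lr <- rep(NA_real_, nr)
  fire_layer <- function(i) {
    if (length(ins[[i]]) == 0) return(1)
    1 + max(vapply(ins[[i]], function(m) steps_m[[m]], numeric(1)))
  }
  for (i in which(n_missing == 0)) cand[i] <- fire_layer(i)

  # reactions waiting on each metabolite (index into rx)
  waiting <- new.env(parent = emptyenv())
  for (i in seq_len(nr)) {
    for (m in setdiff(ins[[i]], seeds)) waiting[[m]] <- c(waiting[[m]], i)
  }

  repeat {
    ready <- which(!visited & !is.na(cand))
    if (length(ready) == 0) break
    layer <- min(cand[ready])
    batch <- ready[cand[ready] == layer]
    visited[batch] <- TRUE
    lr[batch] <- layer
    new_mets <- character(0)
    for (i in batch) {
      for (m in outs[[i]]) {
        if (is.null(in_scope[[m]])) {
          in_scope[[m]] <- TRUE
          steps_m[[m]] <- layer + 1
          new_mets <- c(new_mets, m)
        }
      }
    }
    for (m in new_mets) {
      for (i in waiting[[m]]) {
        n_missing[i] <- n_missing[i] - 1L
        if (n_missing[i] == 0L) cand[i] <- fire_layer(i)
      }
    }
  }

  scope <- sort(ls(in_scope))
  # stuck: not visited but examined, i.e. at least one input already in scope
  touched <- vapply(seq_len(nr), function(i) {
    length(ins[[i]]) > 0 && any(vapply(ins[[i]], function(m)
      !is.null(in_scope[[m]]), logical(1)))
  }, logical(1))
  stuck <- sort(rid[!visited & touched])
  untouched <- sort(rid[!visited & !touched])

  sm <- vapply(scope, function(m) steps_m[[m]], numeric(1))
  vis <- sort(rid[visited])
  sr <- setNames(lr[visited][order(rid[visited])], vis)

  structure(
    list(scope = scope,
         visited_reactions = vis,
         stuck_reactions = stuck,
         untouched_reactions = untouched,
         steps_metabolite = sm,
         steps_reaction = sr,
         seeds = sort(seeds)),
    class = "scope_result"
  )
}

#' @export
print.scope_result <- function(x, ...) {
  cat("<scope_result>\n")
  cat("  seeds:   ", length(x$seeds), "\n", sep = "")
  cat("  scope:   ", length(x$scope), " metabolites\n", sep = "")
  cat("  visited: ", length(x$visited_reactions), " reactions; stuck: ",
      length(x$stuck_reactions), "; untouched: ",
      length(x$untouched_reactions), "\n", sep = "")
  invisible(x)
}

#' @describeIn guided_bfs one row per graph node with its traversal status.
#' @param x a `scope_result`.
#' @param ... unused.
#' @export
tidy.scope_result <- function(x, ...) {
  dplyr::bind_rows(
    tibble(node = names(x$steps_metabolite), type = "metabolite",
           status = ifelse(names(x$steps_metabolite) %in% x$seeds,
                           "seed", "in_scope"),
           steps = unname(x$steps_metabolite)),
    tibble(node = x$visited_reactions, type = "reaction", status = "visited",
           steps = unname(x$steps_reaction[x$visited_reactions])),
    tibble(node = x$stuck_reactions, type = "reaction", status = "stuck",
           steps = NA_real_),
    tibble(node = x$untouched_reactions, type = "reaction",
           status = "untouched", steps = NA_real_)
  )
}

#' @describeIn guided_bfs summary counts of the traversal.
#' @export
glance.scope_result <- function(x, ...) {
  tibble(
    n_seeds = length(x$seeds),
    n_scope = length(x$scope),
    n_visited = length(x$visited_reactions),
    n_stuck = length(x$stuck_reactions),
    n_untouched = length(x$untouched_reactions)
  )
}

#' Which targets are reachable from the seed set?
#'
#' A target is reachable exactly when it lies in the scope. For unreachable
#' targets the nearest blockers are reported: the stuck reactions that would
#' produce the target if their missing precursors became available.
#'
#' @param scope_result result of [guided_bfs()].
#' @param targets character vector of metabolite ids.
#' @param graph the graph the scope was computed on (needed to locate stuck
#'   producers; optional).
#' @return tibble with columns `target`, `reachable`, `steps`, and
#'   `stuck_producers` (list of reaction ids).
#' @export
reachable_targets <- function(scope_result, targets, graph = NULL) {
  stopifnot(inherits(scope_result, "scope_result"))
  targets <- unique(as.character(targets))
  reachable <- targets %in% scope_result$scope
  known <- if (!is.null(graph)) targets %in% graph$metabolites$id else rep(TRUE, length(targets))
  if (any(!known)) {
    warn(paste0("unknown target metabolite id(s): ",
                paste(targets[!known], collapse = ", ")))
  }
  stuck_producers <- lapply(targets, function(tg) {
    if (is.null(graph) || tg %in% scope_result$scope) return(character(0))
    prods <- graph$producers[[tg]] %||% character(0)
    sort(intersect(prods, scope_result$stuck_reactions))
  })
  tibble(
    target = targets,
    reachable = reachable,
    steps = ifelse(reachable, unname(scope_result$steps_metabolite[targets]), NA_real_),
    stuck_producers = stuck_producers
  )
}

#' Write a scope report as TSV
#'
#' One row per node: `node`, `type` (`metabolite`/`reaction`), `status`
#' (`seed`, `in_scope`, `visited`, `stuck`, `untouched`) and `steps`.
#'
#' @param scope_result result of [guided_bfs()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scope_report <- function(scope_result, path) {
  readr::write_tsv(tidy(scope_result), path, progress = FALSE)
  invisible(path)
}
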