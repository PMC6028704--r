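#' Enumerate all pathways of bounded size by memoised dynamic programming
#'
#' Fills a table with one row per scoped metabolite and one column per
#' pathway size: `Table[m][k]` holds every distinct reaction set of size
#' exactly `k` that produces `m` and is *complete* (every input of every
#' member reaction is a seed or an output of another member reaction).
#' `Table[m][0]` holds the empty pathway exactly for seed metabolites; a
#' missing cell is the bottom sentinel, meaning no pathway of exactly that
#' size exists.
#'
#' Column 1 is seeded with the single reactions whose inputs are all seed
#' metabolites. Later columns combine, for every visited reaction `r` with
#' `n` inputs, sub-pathways drawn from earlier columns according to ordered
#' integer partitions ([generate_partitions()]): for each partition the cross
#' product of the input cells is merged by set union together with `r`, and
#' the result is stored at the column equal to its *actual* cardinality —
#' shared reactions deduplicate, so the merged size can be smaller than the
#' partition sum plus one. Cells beyond the requested `beta` written during
#' the sweep (overflow columns) are retained in the object but excluded from
#' [pathways()].
#'
#' The column sweep runs `k = 2 .. beta + 1` and is repeated until no new
#' entry at columns `<= beta` appears. The extra column and the repetition
#' close the table under cyclic pathways whose sub-derivations are recorded
#' late; a sub-pathway of a size-`<= beta` pathway never exceeds `beta`
#' itself (a union is at least as large as each part), so this fixpoint is
#' exhaustive for all sizes up to `beta`.
#'
#' @param graph a `bipartite_graph`.
#' @param seeds character vector of seed metabolite ids (ignored when
#'   `scope` is supplied, which carries its own seeds).
#' @param beta integer size cut-off (>= 1).
#' @param scope optional precomputed [guided_bfs()] result for `graph`.
#' @param prune skip reaction `r` at column `k` when `ceiling(l_r / 2) > k`,
#'   i.e. when the minimum number of reaction layers needed to fire `r`
#'   already exceeds the size budget. Output-neutral; only saves work.
#' @param max_pathways hard cap on the total number of stored pathway
#'   entries; exceeding it is an error (exhaustive enumeration is worst-case
#'   exponential, so fail loudly rather than thrash).
#' @return an object of class `pathway_table`; query it with [pathways()],
#'   [tidy()] or [glance()].
#' @export
enumerate_pathways <- function(graph, seeds = NULL, beta, scope = NULL,
                               prune = TRUE, max_pathways = 1e7) {
  stopifnot(inherits(graph, "bipartite_graph"))
  if (!is.numeric(beta) || length(beta) != 1 || is.na(beta) || beta < 1) {
    abort("beta must be a single integer >= 1")
  }
  beta <- as.integer(beta)
  if (is.null(scope)) {
    if (is.null(seeds)) abort("supply either seeds or a precomputed scope")
    scope <- guided_bfs(graph, seeds)
  }
  stopifnot(inherits(scope, "scope_result"))
  seeds <- scope$seeds
  rv <- scope$visited_reactions
  rxi <- match(rv, graph$reactions$id)
  ins <- graph$reactions$inputs[rxi]
  outs <- graph$reactions$outputs[rxi]
  lr <- unname(scope$steps_reaction[rv])

  cells <- new.env(parent = emptyenv())   # "m\x1ek" -> named list of pathways
  filled <- new.env(parent = emptyenv())  # m -> sorted integer columns
  n_stored <- 0L
  beta_max <- 0L
  added_low <- FALSE                      # any addition at column <= beta

  ckey <- function(m, k) paste(m, k, sep = "\x1e")
  add <- function(m, j, u_sorted, key) {
    ck <- ckey(m, j)
    cell <- cells[[ck]]
    if (!is.null(cell[[key]])) return(invisible(FALSE))
    cell[[key]] <- u_sorted
    cells[[ck]] <- cell
    n_stored <<- n_stored + 1L
    if (n_stored > max_pathways) {
      abort(paste0("pathway store exceeded max_pathways = ", max_pathways,
                   " while filling Table[", m, "][", j, "]"))
    }
    f <- filled[[m]]
    if (!(j %in% f)) filled[[m]] <- sort(c(f, j))
    if (j <= beta) added_low <<- TRUE
    if (j > beta_max) beta_max <<- j
    invisible(TRUE)
  }

  for (s in seeds) add(s, 0L, character(0), "")
  for (i in seq_along(rv)) {
    if (all(ins[[i]] %in% seeds)) {
      u <- rv[i]
      for (y in outs[[i]]) add(y, 1L, u, u)
    }
  }

  if (beta >= 1) {
    repeat {
      added_low <- FALSE
      for (k in seq.int(2L, beta + 1L)) {
        for (i in seq_along(rv)) {
          if (prune && ceiling(lr[i] / 2) > k) next
          in_r <- ins[[i]]
          n <- length(in_r)
          if (n == 0) next
          feas <- lapply(in_r, function(m) {
            f <- filled[[m]]
            f[f <= k - 1L]
          })
          if (any(lengths(feas) == 0)) next
          size_cap <- if (k == beta + 1L) beta else Inf
          rid <- rv[i]
          outs_r <- outs[[i]]
          walk_partitions(feas, k, function(p) {
            cell_lists <- lapply(seq_len(n), function(q) cells[[ckey(in_r[q], p[q])]])
            merge_cross(cell_lists, rid, size_cap, function(u_sorted) {
              key <- paste(u_sorted, collapse = "\x1f")
              j <- length(u_sorted)
              for (y in outs_r) add(y, j, u_sorted, key)
            })
          })
        }
      }
      if (!added_low) break
    }
  }

  # freeze into plain lists, each cell sorted for determinism
  cells_list <- list()
  for (ck in sort(ls(cells))) {
    parts <- strsplit(ck, "\x1e", fixed = TRUE)[[1]]
    m <- parts[1]; k <- parts[2]
    cell <- cells[[ck]]
    cell <- cell[order(names(cell))]
    if (is.null(cells_list[[m]])) cells_list[[m]] <- list()
    cells_list[[m]][[k]] <- unname(cell)
  }

  structure(
    list(cells = cells_list, beta = beta, beta_max = beta_max,
         seeds = seeds, scope = scope$scope, visited = rv,
         graph = graph, n_pathways = n_stored, prune = prune),
    class = "pathway_table"
  )
}

# Stream the cross product of pathway cells merged with reaction `rid`.
# Each element passed to `fun` is a sorted unique character vector.
merge_cross <- function(cell_lists, rid, size_cap, fun) {
  n <- length(cell_lists)
  rec <- function(i, acc) {
    if (length(acc) > size_cap) return(invisible(NULL))
    if (i > n) {
      fun(sort(acc))
      return(invisible(NULL))
    }
    for (pw in cell_lists[[i]]) {
      u <- unique(c(acc, pw))
      if (length(u) > size_cap) next
      rec(i + 1L, u)
    }
  }
  rec(1L, rid)
  invisible(NULL)
}

#' @export
print.pathway_table <- function(x, ...) {
  cat("<pathway_table> beta = ", x$beta,
      " (columns materialised up to ", x$beta_max, ")\n", sep = "")
  cat("  scope: ", length(x$scope), " metabolites; visited reactions: ",
      length(x$visited), "\n", sep = "")
  cat("  stored pathway entries: ", x$n_pathways, "\n", sep = "")
  invisible(x)
}

#' Fetch one table cell
#'
#' @param table a `pathway_table`.
#' @param metabolite metabolite id.
#' @param k column (pathway size).
#' @return list of pathways (character vectors of reaction ids), or `NULL`
#'   for the bottom sentinel (no pathway of exactly this size).
#' @export
table_cell <- function(table, metabolite, k) {
  stopifnot(inherits(table, "pathway_table"))
  table$cells[[metabolite]][[as.character(k)]]
}

#' Merge input sub-pathways through one reaction and partition
#'
#' The elementary table-filling step of the dynamic programme, exposed for
#' inspection: given a reaction `r` with inputs `m1..mn` and a partition
#' `(p1, ..., pn)`, takes the cross product of the cells `Table[mi][pi]`,
#' merges each combination by set union together with `r`, and stores every
#' result in the cells of `r`'s outputs at the column equal to the merged
#' cardinality. Because the union deduplicates reactions shared between
#' sub-pathways, the stored size may be smaller than `1 + sum(p)`.
#'
#' @param table a `pathway_table`.
#' @param reaction a reaction id present in the table's graph.
#' @param partition integer vector, one sub-pathway size per input of
#'   `reaction`; every `Table[mi][pi]` must be non-bottom.
#' @return the updated `pathway_table` (a modified copy).
#' @export
populate_table <- function(table, reaction, partition) {
  stopifnot(inherits(table, "pathway_table"))
  ri <- match(reaction, table$graph$reactions$id)
  if (is.na(ri)) abort(paste0("unknown reaction id: ", reaction))
  in_r <- table$graph$reactions$inputs[[ri]]
  outs_r <- table$graph$reactions$outputs[[ri]]
  if (length(partition) != length(in_r)) {
    abort(paste0("partition length ", length(partition),
                 " does not match the ", length(in_r),
                 " inputs of reaction ", reaction))
  }
  cell_lists <- lapply(seq_along(in_r), function(i) {
    cell <- table_cell(table, in_r[i], partition[i])
    if (is.null(cell)) {
      abort(paste0("Table[", in_r[i], "][", partition[i],
                   "] is bottom; partition infeasible"))
    }
    cell
  })
  merge_cross(cell_lists, reaction, Inf, function(u_sorted) {
    j <- as.character(length(u_sorted))
    for (y in outs_r) {
      cell <- table$cells[[y]][[j]]
      keys <- vapply(cell, paste, character(1), collapse = "\x1f")
      key <- paste(u_sorted, collapse = "\x1f")
      if (!(key %in% keys)) {
        cell[[length(cell) + 1]] <- u_sorted
        ord <- order(vapply(cell, paste, character(1), collapse = "\x1f"))
        table$cells[[y]][[j]] <<- cell[ord]
        table$n_pathways <<- table$n_pathways + 1L
        if (length(u_sorted) > table$beta_max) table$beta_max <<- length(u_sorted)
      }
    }
  })
  table
}

#' Query enumerated pathways for a target metabolite
#'
#' Collects the pathways of size 1 to `max_size` producing `target`,
#' annotated with their size, cyclicity (Definition: some metabolite the
#' pathway produces participates, through member reactions, in its own
#' production) and whether both halves of a reversible reaction pair
#' co-occur. For a seed target the trivial empty pathway is excluded, but
#' nontrivial cyclic pathways regenerating the seed are listed.
#'
#' @param table a `pathway_table`.
#' @param target metabolite id.
#' @param max_size largest size to report, capped at the table's `beta`.
#' @return tibble with columns `target`, `size`, `reactions` (list of sorted
#'   reaction-id vectors), `is_cyclic`, `contains_reversible_pair`, ordered
#'   by size then lexicographically by reaction ids.
#' @export
pathways <- function(table, target, max_size = table$beta) {
  stopifnot(inherits(table, "pathway_table"))
  max_size <- min(max_size, table$beta)
  empty <- tibble(target = character(0), size = integer(0),
                  reactions = list(), is_cyclic = logical(0),
                  contains_reversible_pair = logical(0))
  if (!target %in% table$scope) {
    warn(paste0("target '", target, "' is not in the scope of the seed set"))
    return(empty)
  }
  cols <- table$cells[[target]]
  if (is.null(cols)) return(empty)
  ks <- as.integer(names(cols))
  ks <- sort(ks[ks >= 1 & ks <= max_size])
  if (length(ks) == 0) return(empty)
  rows <- purrr::map(ks, function(k) {
    pws <- cols[[as.character(k)]]
    tibble(target = target, size = k, reactions = pws)
  })
  out <- dplyr::bind_rows(rows)
  pair_of <- setNames(table$graph$reactions$pair_id, table$graph$reactions$id)
  out$is_cyclic <- vapply(out$reactions, classify_cyclic, logical(1),
                          graph = table$graph, seeds = table$seeds)
  out$contains_reversible_pair <- vapply(out$reactions, function(rs) {
    p <- pair_of[rs]
    any(nzchar(p) & p %in% rs)
  }, logical(1))
  key <- vapply(out$reactions, paste, character(1), collapse = "\x1f")
  out[order(out$size, key), ]
}

#' Is a pathway cyclic?
#'
#' A pathway is cyclic when a metabolite it produces is used, through the
#' pathway's own reactions, in its own production: equivalently, the
#' bipartite digraph restricted to the member reactions and their
#' metabolites contains a directed cycle. (Any metabolite on such a cycle
#' necessarily has a producing member reaction, and seed-regenerating loops
#' count as cyclic.)
#'
#' @param reactions character vector of reaction ids forming a complete
#'   pathway.
#' @param graph the `bipartite_graph` the pathway lives in.
#' @param seeds unused; kept so the signature mirrors the completeness
#'   contract (cyclicity does not depend on the seed set).
#' @return logical.
#' @export
classify_cyclic <- function(reactions, graph, seeds = NULL) {
  stopifnot(inherits(graph, "bipartite_graph"))
  ri <- match(reactions, graph$reactions$id)
  if (anyNA(ri)) abort("pathway references reactions absent from the graph")
  ins <- graph$reactions$inputs[ri]
  outs <- graph$reactions$outputs[ri]
  from <- c(unlist(ins), rep(reactions, lengths(outs)))
  to <- c(rep(reactions, lengths(ins)), unlist(outs))
  if (length(from) == 0) return(FALSE)
  g <- igraph::graph_from_data_frame(data.frame(from = from, to = to),
                                     directed = TRUE)
  !igraph::is_dag(g)
}

#' @describeIn enumerate_pathways one row per non-bottom cell at columns up
#'   to `beta`: `metabolite`, `size`, `n_pathways`.
#' @param x a `pathway_table`.
#' @param ... unused.
#' @export
tidy.pathway_table <- function(x, ...) {
  rows <- purrr::imap(x$cells, function(cols, m) {
    ks <- as.integer(names(cols))
    keep <- ks <= x$beta
    tibble(metabolite = m, size = ks[keep],
           n_pathways = unname(lengths(cols)[keep]))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$metabolite, .data$size)
}

#' @describeIn enumerate_pathways summary of the table.
#' @export
glance.pathway_table <- function(x, ...) {
  td <- tidy(x)
  tibble(
    beta = x$beta,
    beta_max = x$beta_max,
    n_scope = length(x$scope),
    n_visited = length(x$visited),
    n_cells = nrow(td),
    n_pathways = sum(td$n_pathways[td$size >= 1])
  )
}

#' Write pathways as JSON lines
#'
#' One JSON object per pathway: `target`, `size`, `reactions`, `is_cyclic`,
#' `contains_reversible_pair`.
#'
#' @param pathway_tbl tibble from [pathways()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pathways_jsonl <- function(pathway_tbl, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(pathway_tbl))) {
    rec <- list(
      target = pathway_tbl$target[i],
      size = pathway_tbl$size[i],
      reactions = pathway_tbl$reactions[[i]],
      is_cyclic = pathway_tbl$is_cyclic[i],
      contains_reversible_pair = pathway_tbl$contains_reversible_pair[i]
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Export one pathway as a DOT bipartite subgraph
#'
#' Reactions render as boxes, metabolites as circles; seed metabolites are
#' marked with a doubled border.
#'
#' @param reactions character vector of reaction ids.
#' @param graph the `bipartite_graph`.
#' @param path output DOT file.
#' @param seeds optional seed ids to highlight.
#' @return `path`, invisibly.
#' @export
write_pathway_dot <- function(reactions, graph, path, seeds = character(0)) {
  ri <- match(reactions, graph$reactions$id)
  if (anyNA(ri)) abort("pathway references reactions absent from the graph")
  ins <- graph$reactions$inputs[ri]
  outs <- graph$reactions$outputs[ri]
  mets <- sort(unique(c(unlist(ins), unlist(outs))))
  q <- function(x) paste0("\"", gsub("\"", "\\\\\"", x), "\"")
  lines <- c(
    "digraph pathway {",
    "  rankdir=LR;",
    paste0("  ", q(reactions), " [shape=box, style=filled, fillcolor=gray70];"),
    paste0("  ", q(mets), " [shape=circle",
           ifelse(mets %in% seeds, ", peripheries=2", ""), "];"),
    unlist(purrr::map(seq_along(reactions), function(i) {
      c(paste0("  ", q(ins[[i]]), " -> ", q(reactions[i]), ";"),
        paste0("  ", q(reactions[i]), " -> ", q(outs[[i]]), ";"))
    })),
    "}"
  )
  writeLines(lines, path)
  invisible(path)
}
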