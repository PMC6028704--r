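#' Jaccard index of two pathways
#'
#' `|A intersect B| / |A union B|` over the reaction-id sets; defined as 1
#' when both sets are empty.
#'
#' @param a,b character vectors of reaction ids (or single rows' `reactions`
#'   entries from [pathways()]).
#' @return numeric in \[0, 1\].
#' @export
jaccard_index <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

as_pathway_list <- function(pathways) {
  if (is.data.frame(pathways)) {
    stopifnot("reactions" %in% names(pathways))
    pathways <- pathways$reactions
  }
  lapply(pathways, function(p) unique(as.character(p)))
}

# Sparse pathway x reaction incidence matrix; pairwise intersection counts
# are then inner products, computed in column blocks so the full N x N
# similarity matrix is never materialised.
pathway_incidence <- function(plist) {
  universe <- sort(unique(unlist(plist)))
  i <- unlist(lapply(plist, function(p) match(p, universe)))
  j <- rep(seq_along(plist), lengths(plist))
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(max(length(universe), 1L), length(plist)))
}

#' Pairwise Jaccard similarity spectrum of a pathway set
#'
#' Scores every unordered pair of pathways and bins the Jaccard values.
#' Pairs are processed in blocks against the sparse reaction-incidence
#' matrix, so memory stays linear in the number of pathways. Default bins
#' are closed on the left and open on the right, `[lo, hi)`, with the final
#' bin closed; reproduction-style inclusive bins are available via
#' `closed = "both"`.
#'
#' @param pathways a tibble from [pathways()] or a list of reaction-id
#'   vectors (>= 2 pathways).
#' @param bins data frame with columns `lo`, `hi`, or a numeric vector of
#'   break points (default `seq(0, 1, 0.05)`).
#' @param closed `"left"` for `[lo, hi)` (final bin closed), `"both"` for
#'   `[lo, hi]` on every bin (bins may then overlap; each pair counts in
#'   every bin containing it).
#' @param block pathways per processing block.
#' @return tibble of class `similarity_spectrum` with columns `lo`, `hi`,
#'   `count`, and attribute `total_pairs = N (N - 1) / 2`.
#' @export
similarity_spectrum <- function(pathways, bins = seq(0, 1, 0.05),
                                closed = c("left", "both"), block = 256L) {
  closed <- match.arg(closed)
  plist <- as_pathway_list(pathways)
  n <- length(plist)
  if (n < 2) abort("need at least two pathways")
  if (is.data.frame(bins)) {
    stopifnot(all(c("lo", "hi") %in% names(bins)))
    bins <- tibble(lo = bins$lo, hi = bins$hi)
  } else {
    bins <- tibble(lo = bins[-length(bins)], hi = bins[-1])
  }
  counts <- numeric(nrow(bins))
  total <- 0
  for (jac in stream_jaccard_blocks(plist, block)) {
    total <- total + length(jac)
    for (b in seq_len(nrow(bins))) {
      if (closed == "both") {
        counts[b] <- counts[b] + sum(jac >= bins$lo[b] & jac <= bins$hi[b])
      } else {
        top <- b == nrow(bins)
        counts[b] <- counts[b] +
          sum(jac >= bins$lo[b] & (jac < bins$hi[b] | (top & jac == bins$hi[b])))
      }
    }
  }
  out <- tibble(lo = bins$lo, hi = bins$hi, count = counts)
  attr(out, "total_pairs") <- total
  class(out) <- c("similarity_spectrum", class(out))
  out
}

# All pairwise Jaccard values, yielded as a list of numeric chunks
# (block of columns vs all earlier pathways).
stream_jaccard_blocks <- function(plist, block = 256L) {
  n <- length(plist)
  inc <- pathway_incidence(plist)
  sizes <- lengths(plist)
  starts <- seq(2L, n, by = block)
  lapply(starts, function(s) {
    e <- min(s + block - 1L, n)
    inter <- as.matrix(Matrix::crossprod(inc[, 1:(e - 1L), drop = FALSE],
                                         inc[, s:e, drop = FALSE]))
    vals <- numeric(0)
    for (col in seq_len(ncol(inter))) {
      j <- s + col - 1L
      i <- seq_len(j - 1L)
      un <- sizes[i] + sizes[j] - inter[i, col]
      v <- ifelse(un == 0, 1, inter[i, col] / un)
      vals <- c(vals, v)
    }
    vals
  })
}

#' @export
print.similarity_spectrum <- function(x, ...) {
  cat("<similarity_spectrum> ", attr(x, "total_pairs"),
      " pathway pairs\n", sep = "")
  NextMethod()
}

#' @describeIn similarity_spectrum histogram of pair counts per Jaccard bin.
#' @param object a `similarity_spectrum`.
#' @param ... unused.
#' @export
autoplot.similarity_spectrum <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$lo + .data$hi) / 2,
                                   y = .data$count)) +
    ggplot2::geom_col(width = (df$hi - df$lo) * 0.9, fill = "grey35") +
    ggplot2::labs(x = "Jaccard index", y = "pathway pairs",
                  title = paste0("Pairwise pathway similarity (",
                                 attr(object, "total_pairs"), " pairs)")) +
    ggplot2::theme_minimal()
}

#' The most different pair of pathways
#'
#' Returns the pair minimising the Jaccard index; ties are broken by the
#' smallest combined size, then lexicographically by reaction ids, so the
#' result is deterministic.
#'
#' @inheritParams similarity_spectrum
#' @return one-row tibble with list-columns `pathway_a`, `pathway_b` and
#'   columns `jaccard`, `index_a`, `index_b`.
#' @export
most_different_pair <- function(pathways) {
  plist <- as_pathway_list(pathways)
  n <- length(plist)
  if (n < 2) abort("need at least two pathways")
  plist <- lapply(plist, sort)
  sizes <- lengths(plist)
  keys <- vapply(plist, paste, character(1), collapse = "\x1f")
  best <- NULL
  for (j in 2:n) {
    for (i in 1:(j - 1)) {
      jac <- jaccard_index(plist[[i]], plist[[j]])
      cand <- list(i = i, j = j, jac = jac,
                   combined = sizes[i] + sizes[j],
                   key = paste(sort(c(keys[i], keys[j])), collapse = "\x1f\x1f"))
      if (is.null(best) ||
          jac < best$jac ||
          (jac == best$jac && cand$combined < best$combined) ||
          (jac == best$jac && cand$combined == best$combined &&
           cand$key < best$key)) {
        best <- cand
      }
    }
  }
  tibble(index_a = best$i, index_b = best$j,
         pathway_a = list(plist[[best$i]]), pathway_b = list(plist[[best$j]]),
         jaccard = best$jac)
}

#' Metabolites exchanged between community members
#'
#' Scans pathways enumerated on a community graph for cross-feeding: within
#' a single pathway spanning at least two organisms, a shared extracellular
#' metabolite produced by one organism's reactions and consumed by
#' another's is a candidate exchange. Reports are aggregated per
#' (metabolite, donor, recipient) with the witnessing pathways.
#'
#' With `check_load_bearing = TRUE`, each report is verified to be
#' load-bearing: the recipient's portion of a witnessing pathway must fail
#' the completeness check when the donor's exported metabolite is withheld
#' from the recipient's seed, i.e. the recipient genuinely depends on the
#' exchange. Reports with no load-bearing witness are dropped.
#'
#' @param community_graph a `community_graph` from [build_community_graph()].
#' @param pathway_tbl tibble from [pathways()] (possibly row-bound over many
#'   targets).
#' @param seeds the seed set used for enumeration (required for
#'   `check_load_bearing`).
#' @param check_load_bearing re-run the completeness check per report
#'   (slower).
#' @return tibble with columns `metabolite`, `donor`, `recipient`,
#'   `n_witnessing_pathways`, `witnesses` (list of row indices into
#'   `pathway_tbl`), `example_pathway` (list of reaction ids), ordered by
#'   metabolite, donor, recipient.
#' @export
find_exchanges <- function(community_graph, pathway_tbl, seeds = NULL,
                           check_load_bearing = FALSE) {
  if (!inherits(community_graph, "community_graph")) {
    abort("find_exchanges needs a community_graph (organism-tagged nodes)")
  }
  shared <- community_graph$shared_extracellular_ids
  rx <- community_graph$reactions
  ridx <- setNames(seq_len(nrow(rx)), rx$id)
  plist <- as_pathway_list(pathway_tbl)

  recs <- list()
  for (pi in seq_along(plist)) {
    rs <- plist[[pi]]
    orgs <- unique(organism_of(rs))
    orgs <- orgs[nzchar(orgs)]
    if (length(orgs) < 2) next
    ii <- ridx[rs]
    ins <- rx$inputs[ii]
    outs <- rx$outputs[ii]
    mets <- intersect(unique(c(unlist(ins), unlist(outs))), shared)
    for (m in mets) {
      donors <- unique(organism_of(rs[vapply(outs, function(o) m %in% o, logical(1))]))
      recips <- unique(organism_of(rs[vapply(ins, function(o) m %in% o, logical(1))]))
      donors <- donors[nzchar(donors)]
      recips <- recips[nzchar(recips)]
      for (d in donors) {
        for (r in setdiff(recips, d)) {
          recs[[length(recs) + 1]] <-
            tibble(metabolite = m, donor = d, recipient = r, witness = pi)
        }
      }
    }
  }
  if (length(recs) == 0) {
    return(tibble(metabolite = character(0), donor = character(0),
                  recipient = character(0), n_witnessing_pathways = integer(0),
                  witnesses = list(), example_pathway = list()))
  }
  long <- dplyr::bind_rows(recs)
  out <- long |>
    dplyr::group_by(.data$metabolite, .data$donor, .data$recipient) |>
    dplyr::summarise(n_witnessing_pathways = dplyr::n(),
                     witnesses = list(sort(.data$witness)), .groups = "drop") |>
    dplyr::arrange(.data$metabolite, .data$donor, .data$recipient)
  out$example_pathway <- lapply(out$witnesses, function(w) sort(plist[[w[1]]]))

  if (check_load_bearing) {
    if (is.null(seeds)) abort("seeds are required for check_load_bearing")
    keep <- vapply(seq_len(nrow(out)), function(i) {
      any(vapply(out$witnesses[[i]], function(w) {
        exchange_is_load_bearing(community_graph, plist[[w]],
                                 out$metabolite[i], out$recipient[i], seeds)
      }, logical(1)))
    }, logical(1))
    out <- out[keep, ]
  }
  out
}

# The exchange is load-bearing when the recipient's reactions in the pathway
# cannot all fire from the original seeds alone (donor withheld), but can
# once the exchanged metabolite is added as a seed.
exchange_is_load_bearing <- function(community_graph, pathway, metabolite,
                                     recipient, seeds) {
  rec_rxns <- pathway[organism_of(pathway) == recipient]
  if (length(rec_rxns) == 0) return(FALSE)
  sub <- induced_pathway_graph(community_graph, rec_rxns)
  seeds_in <- intersect(seeds, sub$metabolites$id)
  fire_all <- function(s) {
    if (length(s) == 0) return(FALSE)
    sc <- guided_bfs(sub, s)
    all(rec_rxns %in% sc$visited_reactions)
  }
  without <- fire_all(setdiff(seeds_in, metabolite))
  with_m <- fire_all(unique(c(seeds_in, metabolite)))
  !without && with_m
}

# Subgraph induced by a reaction set: those reactions plus every metabolite
# they touch.
induced_pathway_graph <- function(graph, reactions) {
  ri <- match(reactions, graph$reactions$id)
  stopifnot(!anyNA(ri))
  rx <- graph$reactions[ri, , drop = FALSE]
  mets <- sort(unique(c(unlist(rx$inputs), unlist(rx$outputs))))
  mt <- graph$metabolites[match(mets, graph$metabolites$id), , drop = FALSE]
  new_bipartite_graph(mt, rx, organisms = graph$organisms,
                      shared_extracellular_ids = graph$shared_extracellular_ids)
}

#' Completeness check for an emitted pathway
#'
#' Re-runs the guided BFS on the subgraph induced by the pathway's reactions
#' with the original seeds; the pathway is complete exactly when every
#' member reaction is visited.
#'
#' @param reactions character vector of reaction ids.
#' @param graph the `bipartite_graph`.
#' @param seeds seed metabolite ids.
#' @return logical.
#' @export
is_complete_pathway <- function(reactions, graph, seeds) {
  sub <- induced_pathway_graph(graph, reactions)
  seeds_in <- intersect(seeds, sub$metabolites$id)
  if (length(seeds_in) == 0) return(FALSE)
  sc <- guided_bfs(sub, seeds_in)
  all(reactions %in% sc$visited_reactions)
}

#' Write a similarity spectrum or exchange report as TSV
#'
#' @param x a `similarity_spectrum` or the tibble from [find_exchanges()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(x, path) {
  flat <- as_tibble(x)
  for (col in names(flat)) {
    if (is.list(flat[[col]])) {
      flat[[col]] <- vapply(flat[[col]], paste, character(1), collapse = ";")
    }
  }
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
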