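#' Reference pathway enumerator by naive derivation closure
#'
#' Enumerates the same objects as [enumerate_pathways()] by direct
#' application of the derivation rule, with none of the dynamic programme's
#' machinery (no size-indexed table, no integer partitions, no column
#' schedule): the derivations of a metabolite `m` are the empty set when `m`
#' is a seed, plus, for every reaction `r` producing `m`, every union of one
#' derivation per input of `r` together with `r` itself. The rule is applied
#' bottom-up to all metabolites simultaneously and repeated until the family
#' of derivable reaction sets stops growing. Intermediate sets larger than
#' `beta` are discarded, which is sound because a union is at least as large
#' as each of its parts.
#'
#' Iterating to the fixpoint (rather than recursing to a fixed depth) is
#' essential for cyclic pathways: unfolding a size-`s` cyclic pathway can
#' require revisiting a reaction, so its derivation depth may exceed `s`.
#'
#' This enumerator is exponentially slower than the dynamic programme and
#' exists as an independent correctness reference for small networks and
#' for ground-truth generation in [toy_network()].
#'
#' @param graph a `bipartite_graph`.
#' @param seeds character vector of seed metabolite ids.
#' @param target metabolite id (or `NULL` to return the whole family).
#' @param beta size cut-off.
#' @return for a single `target`, a list of sorted character vectors
#'   (distinct reaction sets of size 1..beta) ordered by size then
#'   lexicographically; with `target = NULL`, a named list of such lists
#'   over every metabolite with at least one derivation.
#' @export
derive_pathways <- function(graph, seeds, target = NULL, beta) {
  stopifnot(inherits(graph, "bipartite_graph"), beta >= 1)
  seeds <- unique(as.character(seeds))
  rx <- graph$reactions
  nr <- nrow(rx)
  ins <- rx$inputs
  outs <- rx$outputs
  rid <- rx$id

  fam <- list()        # metabolite -> named list(key -> set)
  for (s in seeds) fam[[s]] <- list(`_` = character(0))
  key_of <- function(s) if (length(s) == 0) "_" else paste(s, collapse = "\x1f")

  repeat {
    grew <- FALSE
    nxt <- fam
    for (i in seq_len(nr)) {
      in_r <- ins[[i]]
      per <- lapply(in_r, function(m) fam[[m]])
      if (any(vapply(per, is.null, logical(1)))) next
      combos <- Reduce(function(acc, opts) {
        out <- list()
        for (a in acc) {
          for (o in opts) {
            u <- unique(c(a, o))
            if (length(u) <= beta) out[[length(out) + 1]] <- u
          }
        }
        if (length(out) > 1) {
          k <- vapply(out, function(s) paste(sort(s), collapse = "\x1f"),
                      character(1))
          out <- out[!duplicated(k)]
        }
        out
      }, per, list(character(0)))
      for (cmb in combos) {
        u <- sort(unique(c(cmb, rid[i])))
        if (length(u) > beta) next
        k <- key_of(u)
        for (y in outs[[i]]) {
          if (is.null(nxt[[y]][[k]])) {
            nxt[[y]][[k]] <- u
            grew <- TRUE
          }
        }
      }
    }
    fam <- nxt
    if (!grew) break
  }

  tidy_one <- function(sets) {
    sets <- unname(sets[names(sets) != "_"])
    keys <- vapply(sets, paste, character(1), collapse = "\x1f")
    sets[order(lengths(sets), keys)]
  }
  if (!is.null(target)) {
    return(tidy_one(fam[[target]] %||% list()))
  }
  out <- lapply(fam, tidy_one)
  out[order(names(out))]
}
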