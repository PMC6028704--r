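#' Ordered integer partitions of pathway-size budgets
#'
#' For a reaction with `n` input metabolites considered at table column `k`,
#' a *partition* is an ordered n-tuple `(p1, ..., pn)` assigning a
#' sub-pathway size to each input. Entries are bounded by `k - 1` (only
#' earlier columns are fully known when column `k` is processed) and the sum
#' ranges over the whole interval `[k - 1, n * (k - 1)]`: sums larger than
#' `k - 1` are required because merging sub-pathways that share reactions
#' deduplicates the union, so a partition summing above the budget can still
#' yield a pathway of size `k`.
#'
#' @param n number of inputs (>= 1).
#' @param k current column (>= 2).
#' @param feasible_sizes optional list of `n` integer vectors: the column
#'   indices (each `<= k - 1`) at which a sub-pathway actually exists for each
#'   input. Defaults to `0:(k-1)` for every input. An input with no feasible
#'   size yields no partitions.
#' @return list of integer n-tuples in lexicographic order (first position
#'   ascending fastest last).
#' @examples
#' generate_partitions(2, 3)  # sums 2..4 over entries 0..2
#' @export
generate_partitions <- function(n, k, feasible_sizes = NULL) {
  stopifnot(n >= 1, k >= 2)
  if (is.null(feasible_sizes)) {
    feasible_sizes <- rep(list(0:(k - 1)), n)
  }
  stopifnot(length(feasible_sizes) == n)
  feasible_sizes <- lapply(feasible_sizes, function(f) {
    sort(unique(as.integer(f[f <= k - 1 & f >= 0])))
  })
  out <- list()
  walk_partitions(feasible_sizes, k, function(p) out[[length(out) + 1]] <<- p)
  out
}

# Stream every admissible partition to `fun` without materialising the set.
# feasible: list of sorted integer vectors (already clipped to [0, k-1]).
walk_partitions <- function(feasible, k, fun,
                            lo = k - 1L, hi = length(feasible) * (k - 1L)) {
  n <- length(feasible)
  if (any(lengths(feasible) == 0)) return(invisible(NULL))
  min_rest <- rev(cumsum(rev(vapply(feasible, min, numeric(1)))))
  max_rest <- rev(cumsum(rev(vapply(feasible, max, numeric(1)))))
  p <- integer(n)
  rec <- function(i, s) {
    if (i > n) {
      if (s >= lo && s <= hi) fun(p)
      return(invisible(NULL))
    }
    for (v in feasible[[i]]) {
      s2 <- s + v
      rest_min <- if (i < n) min_rest[i + 1] else 0
      rest_max <- if (i < n) max_rest[i + 1] else 0
      if (s2 + rest_max < lo) next      # cannot reach the floor any more
      if (s2 + rest_min > hi) break     # sums only grow from here
      p[i] <<- v
      rec(i + 1L, s2)
    }
  }
  rec(1L, 0L)
  invisible(NULL)
}
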