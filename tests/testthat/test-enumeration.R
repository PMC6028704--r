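test_that("seed initialisation: empty pathway at column 0, bottom elsewhere", {
  g <- mk_graph(c("r1", "r2"), list("A", "B"), list("B", "C"))
  pt <- enumerate_pathways(g, "A", beta = 2)
  expect_equal(table_cell(pt, "A", 0), list(character(0)))
  expect_null(table_cell(pt, "B", 0))
  expect_null(table_cell(pt, "C", 1))                 # bottom: no size-1 route
  expect_equal(table_cell(pt, "C", 2), list(c("r1", "r2")))
})

test_that("parallel routes give two distinct singleton pathways", {
  toy <- toy_network("parallel_routes", 2)
  pt <- enumerate_pathways(toy$graph, toy$seeds, beta = 1)
  expect_equal(table_cell(pt, "p", 1), list("r1", "r2"))
  pw <- pathways(pt, "p")
  expect_equal(nrow(pw), 2)
  expect_equal(pw$size, c(1L, 1L))
})

test_that("branched join yields exactly one pathway covering both branches", {
  g <- mk_graph(c("r1", "r2", "r3"),
                list("A", "A", c("B", "C")),
                list("B", "C", "D"))
  pt <- enumerate_pathways(g, "A", beta = 3)
  pw <- pathways(pt, "D")
  expect_equal(nrow(pw), 1)
  expect_equal(pw$reactions[[1]], c("r1", "r2", "r3"))
  expect_false(pw$is_cyclic[1])
})

test_that("union merge dedupes shared reactions: {r', r} has size 2, not 3", {
  # r' makes both inputs of r from seeds; the (1,1) partition sums to 2
  # but the merged pathway contains two reactions only
  g <- mk_graph(c("rp", "r"),
                list("s", c("m1", "m2")),
                list(c("m1", "m2"), "t"))
  pt <- enumerate_pathways(g, "s", beta = 1)
  expect_equal(table_cell(pt, "m1", 1), list("rp"))
  expect_equal(table_cell(pt, "m2", 1), list("rp"))
  pt2 <- populate_table(pt, "r", c(1, 1))
  expect_equal(table_cell(pt2, "t", 2), list(c("r", "rp")))
  expect_null(table_cell(pt2, "t", 3))
  # and the full enumeration agrees on the placement
  pt3 <- enumerate_pathways(g, "s", beta = 3)
  expect_equal(table_cell(pt3, "t", 2), list(c("r", "rp")))
  expect_null(table_cell(pt3, "t", 3))
})

test_that("disjoint sub-pathways merge additively", {
  # sizes 1 and 2 through r: 1 + 2 + 1 = 4
  g <- mk_graph(c("ra", "rb1", "rb2", "r"),
                list("s", "s", "x", c("a", "b")),
                list("a", "x", "b", "t"))
  pt <- enumerate_pathways(g, "s", beta = 4)
  expect_equal(table_cell(pt, "t", 4), list(c("r", "ra", "rb1", "rb2")))
  pw <- pathways(pt, "t")
  expect_equal(pw$size, 4L)
})

test_that("cyclic pathways are found, classified, and reported once", {
  toy <- toy_network("cycle", 4)  # four-reaction loop regenerating the seed
  pt <- enumerate_pathways(toy$graph, toy$seeds, beta = 5)
  pw <- pathways(pt, "m0")
  expect_equal(nrow(pw), 1)      # first occurrence only, no duplicates
  expect_equal(pw$reactions[[1]], sort(sprintf("r%d", 1:4)))
  expect_true(pw$is_cyclic[1])
  # two-reaction seed-regenerating loop
  g <- mk_graph(c("r1", "r2"), list("A", "B"), list("B", "A"))
  pt2 <- enumerate_pathways(g, "A", beta = 3)
  pw2 <- pathways(pt2, "A")
  expect_true(all(pw2$is_cyclic))
  expect_true(classify_cyclic(c("r1", "r2"), g))
  expect_false(classify_cyclic("r1", g))
})

test_that("cyclic closure: late-written sub-derivations are still combined", {
  # {r1, r2, r3} produces B with only 3 reactions, but its derivation
  # unfolds through a cycle; a single plain column sweep would miss it
  g <- mk_graph(c("r1", "r2", "r3"), list("A", "B", "C"), list("B", "A", "A"))
  pt <- enumerate_pathways(g, "C", beta = 3)
  expect_equal(set_keys(pathways(pt, "B")$reactions),
               set_keys(derive_pathways(g, "C", "B", 3)))
  expect_equal(set_keys(table_cell(pt, "B", 3)), "r1|r2|r3")
})

test_that("every stored cell holds sets of exactly its column size, deduped", {
  for (s in 1:10) {
    toy <- toy_network("random", n_reactions = 9, seed = s,
                       reversible_fraction = 0.3)
    pt <- enumerate_pathways(toy$graph, toy$seeds, beta = 5)
    for (m in names(pt$cells)) {
      for (k in names(pt$cells[[m]])) {
        cell <- pt$cells[[m]][[k]]
        expect_true(all(lengths(cell) == as.integer(k)))
        keys <- vapply(cell, paste, character(1), collapse = "|")
        expect_equal(anyDuplicated(keys), 0)
      }
    }
  }
})

test_that("tables are monotone in beta and invariant to step-count pruning", {
  for (s in 1:8) {
    toy <- toy_network("random", n_reactions = 8, seed = s,
                       reversible_fraction = 0.25)
    lo <- enumerate_pathways(toy$graph, toy$seeds, beta = 3)
    hi <- enumerate_pathways(toy$graph, toy$seeds, beta = 5)
    noprune <- enumerate_pathways(toy$graph, toy$seeds, beta = 3, prune = FALSE)
    for (m in union(names(hi$cells), names(lo$cells))) {
      for (k in 0:3) {
        a <- table_cell(lo, m, k)
        b <- table_cell(hi, m, k)
        cc <- table_cell(noprune, m, k)
        expect_equal(is.null(a), is.null(b))
        if (!is.null(a)) expect_equal(set_keys(a), set_keys(b))
        expect_equal(is.null(a), is.null(cc))
        if (!is.null(a)) expect_equal(set_keys(a), set_keys(cc))
      }
    }
  }
})

test_that("enumeration output is invariant to input row order", {
  toy <- toy_network("random", n_reactions = 9, seed = 3,
                     reversible_fraction = 0.3)
  pt <- enumerate_pathways(toy$graph, toy$seeds, beta = 4)
  shuf <- build_graph(shuffle_model(toy$model, seed = 99))
  pt2 <- enumerate_pathways(shuf, toy$seeds, beta = 4)
  for (tg in toy$targets) {
    a <- suppressWarnings(pathways(pt, tg))
    b <- suppressWarnings(pathways(pt2, tg))
    expect_identical(a$reactions, b$reactions)
    expect_identical(a$size, b$size)
  }
})

test_that("querying a seed target lists only nontrivial pathways", {
  g <- mk_graph(c("r1", "r2"), list("A", "B"), list("B", "A"))
  pt <- enumerate_pathways(g, "A", beta = 2)
  pw <- pathways(pt, "A")
  expect_true(all(pw$size >= 1))
  expect_true(all(vapply(pw$reactions, length, integer(1)) >= 1))
})

test_that("out-of-scope targets warn and return an empty tibble", {
  g <- mk_graph("r1", list(c("A", "B")), list("C"))
  pt <- enumerate_pathways(g, "A", beta = 2)
  expect_warning(pw <- pathways(pt, "C"), "not in the scope")
  expect_equal(nrow(pw), 0)
})

test_that("both halves of a reversible pair may co-occur and are flagged", {
  m <- mk_model(c("ra", "rb"), list("A", c("B", "A")), list("B", "C"),
                reversible = c(TRUE, FALSE))
  g <- build_graph(m)
  pt <- enumerate_pathways(g, "A", beta = 4)
  pw <- pathways(pt, "A")  # A regenerated through ra then ra_rev
  flagged <- pw[pw$contains_reversible_pair, ]
  expect_gte(nrow(flagged), 1)
  expect_true(any(vapply(flagged$reactions,
                         function(r) all(c("ra", "ra_rev") %in% r), logical(1))))
})

test_that("the memory guard trips loudly", {
  toy <- toy_network("parallel_routes", 4)
  expect_error(enumerate_pathways(toy$graph, toy$seeds, beta = 1,
                                  max_pathways = 2),
               "max_pathways")
})

test_that("beta is validated", {
  g <- mk_graph("r1", list("A"), list("B"))
  expect_error(enumerate_pathways(g, "A", beta = 0), "beta")
})

test_that("tidy and glance summarise the table", {
  toy <- toy_network("linear_chain", 3)
  pt <- enumerate_pathways(toy$graph, toy$seeds, beta = 3)
  td <- tidy(pt)
  expect_equal(td$n_pathways[td$metabolite == "m3" & td$size == 3], 1)
  gl <- glance(pt)
  expect_equal(gl$beta, 3)
  expect_equal(gl$n_pathways, 3)  # one per chain prefix
})

test_that("pathway JSONL output round-trips", {
  toy <- toy_network("branched_join", 3)
  pt <- enumerate_pathways(toy$graph, toy$seeds, beta = 3)
  pw <- pathways(pt, "t")
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_pathways_jsonl(pw, path)
  rec <- jsonlite::fromJSON(readLines(path)[1])
  expect_equal(rec$target, "t")
  expect_equal(sort(rec$reactions), pw$reactions[[1]])
  expect_false(rec$is_cyclic)
})

test_that("single pathways export as DOT subgraphs", {
  toy <- toy_network("branched_join", 3)
  pt <- enumerate_pathways(toy$graph, toy$seeds, beta = 3)
  pw <- pathways(pt, "t")
  path <- withr::local_tempfile(fileext = ".dot")
  write_pathway_dot(pw$reactions[[1]], toy$graph, path, seeds = toy$seeds)
  txt <- readLines(path)
  expect_true(any(grepl("shape=box", txt)))
  expect_true(any(grepl("\"m0\" -> \"r1\"", txt)))
})
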