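test_that("jaccard index basics", {
  expect_equal(jaccard_index(c("r1", "r2"), c("r2", "r1")), 1)
  expect_equal(jaccard_index("r1", "r2"), 0)
  expect_equal(jaccard_index(c("r1", "r2"), c("r2", "r3")), 1 / 3)
  expect_equal(jaccard_index(character(0), character(0)), 1)
})

test_that("jaccard is symmetric, bounded, and its distance is a metric", {
  withr::with_seed(7, {
    universe <- sprintf("r%02d", 1:12)
    for (rep in 1:50) {
      tri <- lapply(1:3, function(i) sample(universe, sample(0:6, 1)))
      j12 <- jaccard_index(tri[[1]], tri[[2]])
      j13 <- jaccard_index(tri[[1]], tri[[3]])
      j23 <- jaccard_index(tri[[2]], tri[[3]])
      expect_equal(j12, jaccard_index(tri[[2]], tri[[1]]))
      expect_true(all(c(j12, j13, j23) >= 0 & c(j12, j13, j23) <= 1))
      # Jaccard distance satisfies the triangle inequality
      expect_lte(1 - j13, (1 - j12) + (1 - j23) + 1e-12)
    }
  })
})

test_that("spectrum counts all unordered pairs exactly once", {
  same <- list(c("r1", "r2"), c("r1", "r2"), c("r1", "r2"))
  sp <- similarity_spectrum(same, bins = c(0, 0.5, 1))
  expect_equal(attr(sp, "total_pairs"), 3)
  expect_equal(sp$count[sp$lo == 0.5], 3)   # all three pairs at jaccard 1

  withr::with_seed(11, {
    plist <- lapply(1:17, function(i) sample(sprintf("r%02d", 1:10), sample(1:5, 1)))
    sp2 <- similarity_spectrum(plist, bins = seq(0, 1, 0.1), block = 5)
    expect_equal(sum(sp2$count), choose(17, 2))
    expect_equal(attr(sp2, "total_pairs"), choose(17, 2))
    # blocked streaming equals the direct double loop
    direct <- unlist(lapply(2:17, function(j) {
      vapply(1:(j - 1), function(i) jaccard_index(plist[[i]], plist[[j]]),
             numeric(1))
    }))
    for (b in seq_len(nrow(sp2))) {
      top <- b == nrow(sp2)
      expect_equal(sp2$count[b],
                   sum(direct >= sp2$lo[b] &
                       (direct < sp2$hi[b] | (top & direct == sp2$hi[b]))))
    }
  })
})

test_that("inclusive bins support reproduction-style closed intervals", {
  plist <- list(c("r1", "r2", "r3"), c("r1", "r2", "r4"))  # jaccard 0.5
  sp <- similarity_spectrum(plist, bins = tibble::tibble(lo = 0.5, hi = 0.6),
                            closed = "both")
  expect_equal(sp$count, 1)
  sp2 <- similarity_spectrum(plist, bins = tibble::tibble(lo = 0.4, hi = 0.5),
                             closed = "both")
  expect_equal(sp2$count, 1)
})

test_that("most different pair minimises jaccard deterministically", {
  out <- most_different_pair(list(c("r1"), c("r1"), c("r2")))
  expect_equal(out$jaccard, 0)
  expect_setequal(c(out$pathway_a[[1]], out$pathway_b[[1]]), c("r1", "r2"))
  same <- most_different_pair(list(c("r1", "r2"), c("r1", "r2")))
  expect_equal(same$jaccard, 1)
  # ties break to the smallest combined size
  tie <- most_different_pair(list(c("a1", "a2", "a3"), c("b1", "b2", "b3"),
                                  c("a1"), c("b1")))
  expect_equal(tie$jaccard, 0)
  expect_equal(sort(c(tie$pathway_a[[1]], tie$pathway_b[[1]])), c("a1", "b1"))
  expect_error(most_different_pair(list(c("r1"))), "at least two")
})

test_that("community cross-feeding is detected from enumerated pathways", {
  toy <- toy_network("community_pair")
  pt <- enumerate_pathways(toy$graph, toy$seeds, beta = 5)
  pw <- pathways(pt, toy$targets)
  expect_gte(nrow(pw), 1)
  ex <- find_exchanges(toy$graph, pw, seeds = toy$seeds)
  expect_equal(nrow(ex), 1)
  expect_equal(ex$metabolite, "x_e")
  expect_equal(ex$donor, "org1")
  expect_equal(ex$recipient, "org2")
  expect_equal(ex$n_witnessing_pathways, 1L)
  # the exchange is load-bearing: withholding x_e starves the recipient
  ex2 <- find_exchanges(toy$graph, pw, seeds = toy$seeds,
                        check_load_bearing = TRUE)
  expect_equal(nrow(ex2), 1)
})

test_that("pathways confined to one organism produce no exchange report", {
  toy <- toy_network("community_pair")
  pw <- tibble::tibble(target = "org1:a", size = 1L,
                       reactions = list("org1:uptake1"),
                       is_cyclic = FALSE, contains_reversible_pair = FALSE)
  ex <- find_exchanges(toy$graph, pw)
  expect_equal(nrow(ex), 0)
})

test_that("exchange analysis refuses untagged graphs", {
  g <- toy_network("linear_chain", 3)$graph
  expect_error(find_exchanges(g, tibble::tibble(reactions = list("r1"))),
               "community_graph")
})

test_that("completeness checker accepts emitted pathways and rejects fragments", {
  toy <- toy_network("branched_join", 4)
  pt <- enumerate_pathways(toy$graph, toy$seeds, beta = 4)
  pw <- pathways(pt, "t")
  expect_true(all(vapply(pw$reactions, is_complete_pathway, logical(1),
                         graph = toy$graph, seeds = toy$seeds)))
  # dropping a branch breaks completeness
  frag <- setdiff(pw$reactions[[1]], "r1")
  expect_false(is_complete_pathway(frag, toy$graph, toy$seeds))
})

test_that("reports render to TSV and spectra to ggplot", {
  toy <- toy_network("parallel_routes", 3)
  pt <- enumerate_pathways(toy$graph, toy$seeds, beta = 1)
  pw <- pathways(pt, "p")
  sp <- similarity_spectrum(pw, bins = c(0, 0.5, 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report_tsv(sp, path)
  expect_equal(nrow(readr::read_tsv(path, show_col_types = FALSE)), 2)
  expect_s3_class(autoplot(sp), "ggplot")
  expect_s3_class(autoplot(pt), "ggplot")
  expect_s3_class(autoplot(toy$graph, highlight = "r1"), "ggplot")
})
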