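test_that("a reaction missing a precursor is stuck, not visited", {
  g <- mk_graph("r1", list(c("A", "B")), list("C"))
  sc <- guided_bfs(g, "A")
  expect_equal(sc$scope, "A")
  expect_length(sc$visited_reactions, 0)
  expect_equal(sc$stuck_reactions, "r1")
})

test_that("step counts are edge distances honouring precursor availability", {
  g <- mk_graph(c("r1", "r2"), list("A", c("B", "A")), list("B", "C"))
  sc <- guided_bfs(g, "A")
  expect_setequal(sc$scope, c("A", "B", "C"))
  expect_setequal(sc$visited_reactions, c("r1", "r2"))
  expect_equal(unname(sc$steps_metabolite[c("A", "B", "C")]), c(0, 2, 4))
  expect_equal(unname(sc$steps_reaction[c("r1", "r2")]), c(1, 3))
})

test_that("stuck reactions trigger once late precursors appear", {
  g <- mk_graph(c("r1", "r2"), list(c("A", "X"), "A"), list("B", "X"))
  sc <- guided_bfs(g, "A")
  expect_setequal(sc$visited_reactions, c("r1", "r2"))
  expect_setequal(sc$scope, c("A", "X", "B"))
  expect_length(sc$stuck_reactions, 0)
})

test_that("scope equals the naive fire-until-stable oracle", {
  cases <- c(
    lapply(c("linear_chain", "parallel_routes", "branched_join", "cycle"),
           function(k) toy_network(k, 4)),
    lapply(1:20, function(s) toy_network("random", n_reactions = 9, seed = s,
                                         reversible_fraction = 0.3))
  )
  for (toy in cases) {
    sc <- guided_bfs(toy$graph, toy$seeds)
    ora <- naive_scope(toy$graph, toy$seeds)
    expect_identical(sc$scope, ora$scope)
    expect_identical(sc$visited_reactions, ora$visited)
  }
})

test_that("scope result invariants hold on random networks", {
  for (s in 1:15) {
    toy <- toy_network("random", n_reactions = 10, seed = s,
                       reversible_fraction = 0.25)
    g <- toy$graph
    sc <- guided_bfs(g, toy$seeds)
    expect_true(all(toy$seeds %in% sc$scope))
    expect_equal(unname(sc$steps_metabolite[toy$seeds]), rep(0, length(toy$seeds)))
    expect_length(intersect(sc$visited_reactions, sc$stuck_reactions), 0)
    ri <- match(sc$visited_reactions, g$reactions$id)
    for (k in seq_along(ri)) {
      ins <- g$reactions$inputs[[ri[k]]]
      outs <- g$reactions$outputs[[ri[k]]]
      expect_true(all(ins %in% sc$scope))     # all inputs producible
      expect_true(all(outs %in% sc$scope))    # all outputs produced
      # l_r >= 1 + min over inputs needing production
      need <- setdiff(ins, toy$seeds)
      if (length(need) > 0) {
        expect_gte(sc$steps_reaction[[sc$visited_reactions[k]]],
                   1 + min(sc$steps_metabolite[need]))
      }
      # reaction layers sit at odd edge distances
      expect_equal(sc$steps_reaction[[sc$visited_reactions[k]]] %% 2, 1)
    }
    # fixpoint: nothing outside visited can fire
    unvisited <- setdiff(g$reactions$id, sc$visited_reactions)
    for (r in unvisited) {
      ins <- g$reactions$inputs[[match(r, g$reactions$id)]]
      expect_false(all(ins %in% sc$scope))
    }
    # non-seed scoped metabolites: l_m = 1 + min over visited producers
    for (m in setdiff(sc$scope, toy$seeds)) {
      prods <- intersect(g$producers[[m]], sc$visited_reactions)
      expect_equal(sc$steps_metabolite[[m]], 1 + min(sc$steps_reaction[prods]))
    }
  }
})

test_that("scope is monotone in the seed set", {
  for (s in 1:20) {
    toy <- toy_network("random", n_reactions = 9, seed = s,
                       reversible_fraction = 0.2)
    g <- toy$graph
    s2 <- unique(c(toy$seeds,
                   sample(g$metabolites$id, min(2, nrow(g$metabolites)))))
    sc1 <- guided_bfs(g, toy$seeds)
    sc2 <- guided_bfs(g, s2)
    expect_true(all(sc1$scope %in% sc2$scope))
    expect_true(all(sc1$visited_reactions %in% sc2$visited_reactions))
  }
})

test_that("traversal is independent of adjacency ordering", {
  for (s in 1:8) {
    toy <- toy_network("random", n_reactions = 9, seed = s,
                       reversible_fraction = 0.3)
    sc <- guided_bfs(toy$graph, toy$seeds)
    shuf <- build_graph(shuffle_model(toy$model, seed = s + 100))
    sc2 <- guided_bfs(shuf, toy$seeds)
    expect_identical(sc$scope, sc2$scope)
    expect_identical(sc$visited_reactions, sc2$visited_reactions)
    expect_identical(sc$steps_metabolite, sc2$steps_metabolite)
    expect_identical(sc$steps_reaction, sc2$steps_reaction)
  }
})

test_that("unknown seeds error, listing the offenders", {
  g <- mk_graph("r1", list("A"), list("B"))
  expect_error(guided_bfs(g, c("A", "ghost1", "ghost2")), "ghost1, ghost2")
})

test_that("reachability gatekeeper reports stuck producers for misses", {
  g <- mk_graph(c("r1", "r2"), list("A", c("A", "X")), list("B", "C"))
  sc <- guided_bfs(g, "A")
  out <- reachable_targets(sc, c("A", "B", "C"), g)
  expect_equal(out$reachable, c(TRUE, TRUE, FALSE))
  expect_equal(out$steps[1:2], c(0, 2))
  expect_equal(out$stuck_producers[[3]], "r2")
  expect_warning(reachable_targets(sc, "nope", g), "unknown target")
})

test_that("scope reports are tidy and written as TSV", {
  toy <- toy_network("branched_join", 3)
  sc <- guided_bfs(toy$graph, toy$seeds)
  td <- tidy(sc)
  expect_setequal(unique(td$status), c("seed", "in_scope", "visited"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scope_report(sc, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(td))
  gl <- glance(sc)
  expect_equal(gl$n_visited, 3)
})
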