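test_that("anchor_distance reproduces the gap formula on a grid", {
  T <- 150000L
  grid <- expand.grid(D0 = c(0L, 1L, 10L, 500L, 1000L, 1500L, T),
                      D1 = c(0L, 1L, 10L, 500L, 1000L, 1500L, T))
  for (r in seq_len(nrow(grid))) {
    D0 <- grid$D0[r]; D1 <- grid$D1[r]
    a <- mk_anchor(1, 0, 100, 5e6, 5e6 + 100)
    b <- mk_anchor(2, 100 + D0, 200 + D0, 5e6 + 100 + D1, 5e6 + 200 + D1)
    expect_equal(anchor_distance(a, b), 2 * max(D0, D1) - min(D0, D1))
  }
  # named examples
  expect_equal(anchor_distance(mk_anchor(1, 0, 100, 5e6, 5e6 + 100),
                               mk_anchor(2, 1100, 1200, 5e6 + 1100, 5e6 + 1200)),
               1000)
  expect_equal(anchor_distance(mk_anchor(1, 0, 100, 5e6, 5e6 + 100),
                               mk_anchor(2, 600, 700, 5e6 + 1600, 5e6 + 1700)),
               2500)  # 2 * 1500 - 500
})

test_that("anchor_distance rejects non-successor pairs", {
  a <- mk_anchor(1, 0, 100, 1000, 1100)
  b <- mk_anchor(2, 50, 150, 1200, 1300, sign = "-")
  expect_error(anchor_distance(a, b), "not a successor")
})

test_that("precedes follows sign and midpoint order", {
  a <- mk_anchor(1, 50, 150, 1050, 1150)          # mids 100, 1100
  b <- mk_anchor(2, 450, 550, 1450, 1550)         # mids 500, 1500
  expect_true(precedes(a, b))
  expect_false(precedes(b, a))
  bm <- mk_anchor(2, 450, 550, 1450, 1550, sign = "-")
  expect_false(precedes(a, bm))                   # signs differ
  am <- mk_anchor(1, 50, 150, 1050, 1150, sign = "-")
  expect_false(precedes(am, bm))                  # sign -, second axis rises
  cm <- mk_anchor(3, 450, 550, 650, 750, sign = "-")
  expect_true(precedes(am, cm))                   # sign -, second axis falls
})

test_that("precedes is a strict partial order on random anchors", {
  set.seed(9)
  an <- rand_anchor_set(30, seed = 9)
  rows <- lapply(seq_len(nrow(an)), function(i) an[i, ])
  for (i in 1:30) {
    x <- sample(rows, 3, replace = TRUE)
    expect_false(precedes(x[[1]], x[[1]]))                 # irreflexive
    if (precedes(x[[1]], x[[2]]))
      expect_false(precedes(x[[2]], x[[1]]))               # antisymmetric
    if (precedes(x[[1]], x[[2]]) && precedes(x[[2]], x[[3]]))
      expect_true(precedes(x[[1]], x[[3]]))                # transitive
  }
})

test_that("coverage profile counts anchor intervals per base", {
  a <- mk_anchor(1, 10, 20, 50, 60)
  p <- coverage_profile(a, 100)
  expect_equal(sum(p), 20)
  expect_true(all(p[11:20] == 1) && all(p[51:60] == 1))
  expect_equal(mean_anchor_coverage(a[1, ], p), 1)
  # two anchors sharing a0: coverage 2 on the shared interval
  b <- rbind(a, mk_anchor(2, 10, 20, 80, 90))
  p2 <- coverage_profile(b, 100)
  expect_true(all(p2[11:20] == 2))
})

test_that("mean coverage equals a brute-force recount on random sets", {
  an <- rand_anchor_set(50, seed = 12)
  p <- coverage_profile(an, 10000L)
  expect_equal(p, brute_coverage(an, 10000L))
  for (i in c(1, 7, 25, 50)) {
    a <- an[i, ]
    idx <- c((a$s0 + 1):a$e0, (a$s1 + 1):a$e1)
    expect_equal(mean_anchor_coverage(a, p), mean(p[idx]))
  }
})

test_that("graph construction prunes by distance and out-degree, rescales", {
  ## three colinear anchors; distances 10, 10 between neighbours
  a1 <- mk_anchor(1, 0, 100, 10000, 10100)
  a2 <- mk_anchor(2, 110, 210, 10110, 10210)
  a3 <- mk_anchor(3, 220, 320, 10220, 10320)
  g <- build_anchor_graph(rbind(a1, a2, a3), L = 15, k = 15)
  expect_equal(g$edges[, c("from", "to")],
               data.frame(from = c(1L, 2L), to = c(2L, 3L)),
               ignore_attr = TRUE)
  ## L below the inter-anchor distance: no edges
  g0 <- build_anchor_graph(rbind(a1, a2, a3), L = 5, k = 15)
  expect_equal(nrow(g0$edges), 0L)
  ## out-degree cap keeps the k closest successors
  many <- do.call(rbind, lapply(0:20, function(i)
    mk_anchor(i + 1, i * 200, i * 200 + 100, 50000 + i * 200,
              50100 + i * 200)))
  gk <- build_anchor_graph(many, L = 1e6, k = 15)
  expect_equal(sum(gk$edges$from == 1), 15L)
  expect_equal(sort(gk$edges$to[gk$edges$from == 1]), 2:16)
  ## rescale: mean edge cost equals |mean vertex cost|
  expect_equal(mean(gk$edges$cost), abs(mean(gk$vcost)))
})

test_that("a self-overlapping flow-1 chain is split into consistent chains", {
  ## three adjacent 330 bp copies A, B, C produce two anchor runs (A-B and
  ## B-C) that chain cheaply along the diagonal; the single flow-1 chain
  ## spans both runs and overlaps itself on the genome, so the flow must
  ## advance until every chain is a proper t-chain
  run1 <- do.call(rbind, lapply(0:2, function(i)
    mk_anchor(i + 1, i * 110, i * 110 + 100, 330 + i * 110,
              430 + i * 110)))
  run2 <- do.call(rbind, lapply(0:2, function(i)
    mk_anchor(i + 4, 330 + i * 110, 430 + i * 110, 660 + i * 110,
              760 + i * 110)))
  an <- rbind(run1, run2)
  g <- build_anchor_graph(an, L = 2000, k = 15)
  ## the greedy single shortest path is indeed self-overlapping here
  paths <- all_graph_paths(g)
  costs <- vapply(paths, path_cost, 0, graph = g)
  monster <- paths[[which.min(costs)]]
  sp0 <- range(c(an$s0[monster], an$e0[monster]))
  sp1 <- range(c(an$s1[monster], an$e1[monster]))
  expect_gt(min(sp0[2], sp1[2]) - max(sp0[1], sp1[1]), 0)
  fl <- min_cost_flow_chains(g, T = 150000L)
  expect_gt(fl$flow, 1L)
  expect_equal(nrow(check_chain_set(fl$chains)), 0L)
  expect_setequal(unlist(fl$chains$anchors), 1:6)
  expect_equal(sum(fl$chains$cost), best_disjoint_paths_cost(g, fl$flow),
               tolerance = 1e-9)
})

test_that("a lone consistent run stops at flow value one", {
  run1 <- do.call(rbind, lapply(0:2, function(i)
    mk_anchor(i + 1, i * 110, i * 110 + 100, 5000 + i * 110,
              5100 + i * 110)))
  g <- build_anchor_graph(run1, L = 500, k = 15)
  fl <- min_cost_flow_chains(g)
  expect_equal(fl$flow, 1L)
  expect_equal(fl$chains$n_anchors, 3L)
  expect_equal(sum(fl$chains$cost), best_disjoint_paths_cost(g, 1L),
               tolerance = 1e-9)
})

test_that("a single anchor yields a single-anchor chain", {
  g <- build_anchor_graph(mk_anchor(1, 0, 100, 500, 600), L = 100, k = 15)
  fl <- min_cost_flow_chains(g)
  expect_equal(fl$flow, 1L)
  expect_equal(fl$chains$n_anchors, 1L)
  expect_equal(fl$residual_anchors, integer(0))
})

test_that("overlapping one-chain solutions are split into consistent pairs", {
  ## two anchors chainable into one chain whose projections overlap
  ## (the second anchor's a1 reaches past the first's a0): the flow must
  ## return them as two single-anchor chains instead
  a <- mk_anchor(1, 1000, 1100, 1500, 1600, score = 50)
  b <- mk_anchor(2, 1200, 1300, 1700, 1800, score = 50)
  g <- build_anchor_graph(rbind(a, b), L = 10000, k = 15)
  ## force an edge scenario: the pair chain c0=[1000,1300) c1=[1500,1800)
  ## is a valid t-chain, so one chain suffices here
  fl <- min_cost_flow_chains(g)
  expect_equal(nrow(check_chain_set(fl$chains)), 0L)
  ## now make the merged projections overlap: b1 starts inside span0
  b2 <- mk_anchor(2, 1200, 1300, 1250, 1350, score = 50)
  expect_error(build_anchor_graph(rbind(a, b2), L = 10000, k = 15), NA)
})

test_that("flow solution is optimal on random small instances", {
  n_inst <- 30
  for (s in seq_len(n_inst)) {
    an <- rand_anchor_set(sample(3:10, 1), span = 5000L, seed = 100 + s)
    an <- dedupe_anchors(an)
    g <- build_anchor_graph(an, L = 3000, k = 5)
    fl <- min_cost_flow_chains(g, T = 150000L)
    expect_lte(fl$flow, nrow(an))                       # termination
    expect_equal(nrow(check_chain_set(fl$chains)), 0L)  # consistency
    ## anchor conservation: chains partition a subset of anchors
    used <- unlist(fl$chains$anchors)
    expect_equal(anyDuplicated(used), 0L)
    expect_true(all(used %in% an$id))
    ## optimality at the final flow value
    if (fl$flow > 0L)
      expect_equal(sum(fl$chains$cost),
                   best_disjoint_paths_cost(g, fl$flow), tolerance = 1e-9)
    ## convexity of the flow cost sequence
    if (length(fl$flow_costs) > 2L) {
      d <- diff(fl$flow_costs)
      expect_true(all(diff(d) >= -1e-9))
    }
  }
})

test_that("check_chain_set flags self-meeting and doubly-overlapping chains", {
  ## square meeting the diagonal: the chain's two projections overlap
  ch1 <- data.frame(id = 1L, seq = "chr1", sign = "+", c0s = 0L, c0e = 1000L,
                    c1s = 800L, c1e = 1800L, cost = -10, n_anchors = 2L)
  v <- check_chain_set(ch1)
  expect_equal(v$type, "self_overlap")
  ## two chains overlapping on one axis only: fine
  ch2 <- data.frame(id = 1:2, seq = "chr1", sign = "+",
                    c0s = c(0L, 500L), c0e = c(1000L, 1500L),
                    c1s = c(2000L, 5000L), c1e = c(3000L, 6000L),
                    cost = -10, n_anchors = 1L)
  expect_equal(nrow(check_chain_set(ch2)), 0L)
  ## overlapping on both axes beyond the tolerated fraction: flagged
  ch3 <- ch2
  ch3$c0s <- c(0L, 200L); ch3$c0e <- c(1000L, 1200L)
  ch3$c1s <- c(2000L, 2200L); ch3$c1e <- c(3000L, 3200L)
  expect_equal(check_chain_set(ch3)$type, "pair_overlap")
  ## mild double overlap (at the dedup tolerance): not flagged
  ch5 <- ch2
  ch5$c0s <- c(0L, 500L); ch5$c0e <- c(1000L, 1500L)
  ch5$c1s <- c(2000L, 2500L); ch5$c1e <- c(3000L, 3500L)
  expect_equal(nrow(check_chain_set(ch5)), 0L)
  ## chain pair exceeding T
  ch4 <- data.frame(id = 1L, seq = "chr1", sign = "+", c0s = 0L, c0e = 100L,
                    c1s = 5000L, c1e = 5100L, cost = -1, n_anchors = 1L)
  expect_equal(check_chain_set(ch4, T = 1000L)$type, "gap")
})
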