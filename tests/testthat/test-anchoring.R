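sch <- scoring_scheme()

test_that("a planted exact copy yields a forward anchor covering it", {
  bg <- rand_seq(20000, seed = 42)
  block <- substr(bg, 5001, 6000)
  g <- plant_genome(bg, block, 9000)        # copy at [9000, 10000), gap 3 kb
  a <- find_anchors(g, sch, T = 150000L)
  expect_gt(nrow(a), 0)
  cov0 <- max(overlap_len(a$s0, a$e0, 5000L, 6000L)) / 1000
  cov1 <- max(overlap_len(a$s1, a$e1, 9000L, 10000L)) / 1000
  expect_gte(cov0, 0.95)
  expect_gte(cov1, 0.95)
  expect_true(any(a$sign == "+"))
})

test_that("a reverse-complemented copy yields a minus anchor", {
  bg <- rand_seq(20000, seed = 43)
  block <- substr(bg, 5001, 6000)
  g <- plant_genome(bg, block, 9000, revcomp = TRUE)
  a <- find_anchors(g, sch, T = 150000L)
  am <- a[a$sign == "-", , drop = FALSE]
  expect_gt(nrow(am), 0)
  expect_gte(max(overlap_len(am$s0, am$e0, 5000L, 6000L)) / 1000, 0.95)
  expect_gte(max(overlap_len(am$s1, am$e1, 9000L, 10000L)) / 1000, 0.95)
})

test_that("a sequence without long repeats yields no anchors", {
  expect_equal(nrow(find_anchors(rand_seq(2000, seed = 44), sch)), 0L)
})

test_that("anchor invariants hold on self-alignment output", {
  sim <- simulate_genome(sim_params(genome_length = 100000L, n_arrays = 3L,
                                    seed = 5))
  a <- find_anchors(sim$genome[[1]], sch, T = 150000L)
  expect_gt(nrow(a), 0)
  expect_true(all(a$s0 < a$s1))
  expect_true(all(a$e0 <= a$s1))
  expect_true(all(a$s1 - a$e0 <= 150000L))
  expect_true(all(a$score > 0))
})

test_that("anchors reflect when the genome is reverse-complemented", {
  bg <- rand_seq(15000, seed = 45)
  block <- substr(bg, 2001, 3000)
  g <- plant_genome(bg, block, 7000)
  n <- nchar(g)
  a <- find_anchors(g, sch)
  b <- find_anchors(tandemscan:::revcomp_chr(g), sch)
  expect_gt(nrow(a), 0)
  expect_equal(nrow(a), nrow(b))
  ## reflection maps [s, e) to [n-e, n-s) and swaps the two copies
  for (i in which(a$score >= 100)) {
    rs0 <- n - a$e1[i]; re0 <- n - a$s1[i]
    rs1 <- n - a$e0[i]; re1 <- n - a$s0[i]
    j <- which.max(overlap_len(b$s0, b$e0, rs0, re0) +
                   overlap_len(b$s1, b$e1, rs1, re1))
    jac <- (overlap_len(b$s0[j], b$e0[j], rs0, re0) +
            overlap_len(b$s1[j], b$e1[j], rs1, re1)) /
           ((re0 - rs0) + (re1 - rs1))
    expect_gte(jac, 0.9)
    expect_equal(b$sign[j], a$sign[i])
  }
})

test_that("diverged planted copies are still covered by anchors", {
  # 10% substitutions, 1% indels on a 1 kb copy
  set.seed(46)
  bg <- rand_seq(20000)
  block <- substr(bg, 5001, 6000)
  x <- strsplit(block, "")[[1]]
  nsub <- rbinom(1, 1000, 0.10)
  pos <- sample.int(1000, nsub)
  for (p in pos) x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1)
  nind <- rbinom(1, 1000, 0.01)
  for (p in sort(sample.int(length(x), nind), decreasing = TRUE)) {
    if (runif(1) < 0.5) x <- x[-p]
    else x <- append(x, sample(c("A", "C", "G", "T"), 1), after = p)
  }
  mut <- paste(x, collapse = "")
  g <- paste0(substr(bg, 1, 9000), mut, substr(bg, 9001 + nchar(mut), 20000))
  a <- find_anchors(g, sch)
  expect_gt(nrow(a), 0)
  cov0 <- tandemscan:::union_length(a$s0, a$e0)
  src_cov <- sum(sapply(seq_len(nrow(a)), function(i)
    overlap_len(a$s0[i], a$e0[i], 5000L, 6000L)))
  expect_gte(src_cov / 1000, 0.8)
})

test_that("X-drop extension scores match optimal local alignment", {
  ## Biostrings::pairwiseAlignment as independent oracle; gapOpening = 3,
  ## gapExtension = 2 reproduces the scheme where the first gap character
  ## costs 5 and each further one 2
  set.seed(47)
  for (i in 1:5) {
    a <- rand_seq(500)
    b <- a
    # light mutation so the optimum is one clean local alignment
    x <- strsplit(b, "")[[1]]
    for (p in sample.int(500, 10)) x[p] <- sample(c("A", "C", "G", "T"), 1)
    x <- x[-sample.int(480, 2)] # two deletions
    b <- paste(x, collapse = "")
    g <- paste0(a, rand_seq(100), b)
    an <- find_anchors(g, sch)
    expect_gt(nrow(an), 0)
    best <- max(an$score)
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -3,
                                                    baseOnly = TRUE)
    pa <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 3, gapExtension = 2)
    expect_equal(best, Biostrings::score(pa))
  }
})

test_that("tandem filtering enforces both anchor conditions at the boundary", {
  T <- 1000L
  at_T <- mk_anchor(1, 0, 100, 1100, 1200)      # gap exactly T
  over_T <- mk_anchor(2, 0, 100, 1101, 1201)    # gap T + 1
  selfov <- mk_anchor(3, 0, 100, 50, 200)       # overlaps itself
  out <- filter_tandem_anchors(rbind(at_T, over_T, selfov), T)
  expect_equal(out$id, 1L)
  expect_equal(attr(out, "n_dropped"), 2L)
  empty <- filter_tandem_anchors(tandemscan:::empty_anchors(), T)
  expect_equal(nrow(empty), 0L)
})

test_that("dedupe keeps the best of mutually redundant anchors", {
  a <- mk_anchor(1, 0, 100, 200, 300, score = 50)
  b <- mk_anchor(2, 0, 100, 200, 300, score = 40)
  expect_equal(dedupe_anchors(rbind(a, b))$id, 1L)
  ## overlap on one axis only: both kept
  c2 <- mk_anchor(2, 0, 100, 400, 500, score = 40)
  expect_equal(dedupe_anchors(rbind(a, c2))$id, c(1L, 2L))
})

test_that("dedupe resolves conflict chains greedily by score", {
  ## a conflicts with b and c; b conflicts with c: only a survives
  a <- mk_anchor(1, 0, 100, 200, 300, score = 60)
  b <- mk_anchor(2, 10, 110, 210, 310, score = 50)
  c3 <- mk_anchor(3, 20, 120, 220, 320, score = 40)
  expect_equal(dedupe_anchors(rbind(a, b, c3))$id, 1L)
  ## c conflicts only with b: a and c survive
  c4 <- mk_anchor(3, 55, 155, 255, 355, score = 40)
  expect_equal(dedupe_anchors(rbind(a, b, c4))$id, c(1L, 3L))
})
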