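mk_gene <- function(id, start, end, seq = "chr1")
  data.frame(gene_id = id, seq = seq, start = start, end = end,
             stringsAsFactors = FALSE)

mk_hit <- function(q, s, evalue = 1e-6, qcov = 0.8, scov = 0.9)
  data.frame(query = q, subject = s, evalue = evalue, qcov = qcov,
             scov = scov, stringsAsFactors = FALSE)

test_that("TGA construction applies all linkage thresholds", {
  g <- rbind(mk_gene("a", 0, 2000), mk_gene("b", 102000, 104000))
  ## 100 kb apart, good hit: one TGA of two
  tg <- build_reference_tgas(g, mk_hit("a", "b"), T = 150000L)
  expect_equal(nrow(tg), 1L)
  expect_equal(tg$n_genes, 2L)
  expect_equal(tg$start, 0L); expect_equal(tg$end, 104000L)
  ## same genes 160 kb apart: no TGA
  g2 <- rbind(mk_gene("a", 0, 2000), mk_gene("b", 162000, 164000))
  expect_equal(nrow(build_reference_tgas(g2, mk_hit("a", "b"))), 0L)
  ## weak e-value or low coverage: no TGA
  expect_equal(nrow(build_reference_tgas(g, mk_hit("a", "b", evalue = 1e-4))),
               0L)
  expect_equal(nrow(build_reference_tgas(g, mk_hit("a", "b", qcov = 0.6))),
               0L)
  ## connectivity: only adjacent pairs hit, still one TGA of three
  g3 <- rbind(mk_gene("g1", 0, 2000), mk_gene("g2", 50000, 52000),
              mk_gene("g3", 100000, 102000))
  tg3 <- build_reference_tgas(g3, rbind(mk_hit("g1", "g2"),
                                        mk_hit("g2", "g3")))
  expect_equal(tg3$n_genes, 3L)
  ## unknown gene ids in hits are an error
  expect_error(build_reference_tgas(g, mk_hit("a", "zz")), "zz")
})

test_that("gene gap is measured between intervals, strictly below T", {
  ## genes exactly T apart fail the strict criterion
  g <- rbind(mk_gene("a", 0, 2000), mk_gene("b", 152000, 154000))
  expect_equal(nrow(build_reference_tgas(g, mk_hit("a", "b"), T = 150000L)),
               0L)
  g2 <- rbind(mk_gene("a", 0, 2000), mk_gene("b", 151999, 154000))
  expect_equal(nrow(build_reference_tgas(g2, mk_hit("a", "b"), T = 150000L)),
               1L)
})

test_that("detection thresholds are exact at 70%", {
  g <- rbind(mk_gene("a", 0, 1000), mk_gene("b", 2000, 3000))
  tgas <- build_reference_tgas(g, mk_hit("a", "b"))
  arrays <- data.frame(array_id = "ta1", seq = "chr1", start = 0L,
                       end = 3000L, stringsAsFactors = FALSE)
  ## single TU covering exactly 70% of gene a: detected (>=)
  units <- data.frame(tu_id = "tu1", array_id = "ta1", seq = "chr1",
                      start = 300L, end = 1000L, stringsAsFactors = FALSE)
  sc <- score_detection(tgas, g, arrays, units)
  expect_true(sc$tgu_detected[["a"]])
  expect_false(sc$tgu_detected[["b"]])
  ## TGA: span covered fully here, one TGU detected
  expect_true(sc$tga_detected)
  ## union of two TUs reaching 70% but each below: not detected
  units2 <- data.frame(tu_id = c("tu1", "tu2"), array_id = "ta1",
                       seq = "chr1", start = c(0L, 400L), end = c(350L, 700L),
                       stringsAsFactors = FALSE)
  sc2 <- score_detection(tgas, g, arrays, units2)
  expect_false(sc2$tgu_detected[["a"]])
  ## TA covering exactly 70% of the TGA span: NOT detected (strict >)
  arrays3 <- data.frame(array_id = "ta1", seq = "chr1", start = 0L,
                        end = 2100L, stringsAsFactors = FALSE) # span 3000
  units3 <- data.frame(tu_id = "tu1", array_id = "ta1", seq = "chr1",
                       start = 0L, end = 1000L, stringsAsFactors = FALSE)
  sc3 <- score_detection(tgas, g, arrays3, units3)
  expect_true(sc3$tgu_detected[["a"]])
  expect_false(sc3$tga_detected)
  ## one base more: detected
  arrays4 <- arrays3; arrays4$end <- 2101L
  expect_true(score_detection(tgas, g, arrays4, units3)$tga_detected)
  ## percentages recompute from integer columns
  expect_equal(sc$summary$pct,
               round(100 * sc$summary$detected / sc$summary$total, 1))
})

test_that("detection counts are monotone in the unit set", {
  g <- rbind(mk_gene("a", 0, 1000), mk_gene("b", 2000, 3000))
  tgas <- build_reference_tgas(g, mk_hit("a", "b"))
  arrays <- data.frame(array_id = "ta1", seq = "chr1", start = 0L,
                       end = 3000L, stringsAsFactors = FALSE)
  u1 <- data.frame(tu_id = "tu1", array_id = "ta1", seq = "chr1",
                   start = 0L, end = 1000L, stringsAsFactors = FALSE)
  u2 <- rbind(u1, data.frame(tu_id = "tu2", array_id = "ta1", seq = "chr1",
                             start = 2000L, end = 3000L,
                             stringsAsFactors = FALSE))
  s1 <- score_detection(tgas, g, arrays, u1)$summary
  s2 <- score_detection(tgas, g, arrays, u2)$summary
  expect_true(all(s2$detected >= s1$detected))
})

test_that("annotation overlap report counts per class at 70%", {
  f <- data.frame(class = c(rep("pseudogene", 10), "pre-tRNA"),
                  seq = "chr1",
                  start = seq(0L, 10000L, by = 1000L),
                  end = seq(500L, 10500L, by = 1000L),
                  stringsAsFactors = FALSE)
  ## cover 3 pseudogenes fully, one at exactly 70%
  units <- data.frame(tu_id = c("tu1", "tu2", "tu3", "tu4"),
                      array_id = "ta1", seq = "chr1",
                      start = c(0L, 1000L, 2000L, 3150L),
                      end = c(500L, 1500L, 2500L, 3500L),
                      stringsAsFactors = FALSE)
  r <- annotation_overlap_report(units, f)
  pg <- r[r$class == "pseudogene", ]
  expect_equal(pg$total, 10L)
  expect_equal(pg$detected, 4L) # the exact-70% feature counts
  expect_equal(pg$pct, 40.0)
  expect_equal(r[r$class == "pre-tRNA", "detected"], 0L)
  ## no units: zero everywhere
  r0 <- annotation_overlap_report(units[0, ], f)
  expect_true(all(r0$detected == 0L))
})

test_that("orphan statistics follow the not-a-single-unit rule", {
  arrays <- data.frame(array_id = c("ta1", "ta2", "ta3"), seq = "chr1",
                       start = c(0L, 10000L, 20000L),
                       end = c(5000L, 15000L, 25000L),
                       stringsAsFactors = FALSE)
  units <- data.frame(tu_id = c("tu1", "tu2", "tu3"),
                      array_id = c("ta1", "ta2", "ta2"), seq = "chr1",
                      start = c(1000L, 11000L, 13000L),
                      end = c(2000L, 12000L, 14000L),
                      stringsAsFactors = FALSE)
  feats <- data.frame(class = "gene", seq = "chr1", start = 1100L,
                      end = 1900L, stringsAsFactors = FALSE)
  ## ta1's unit covers the gene -> other; ta2 all orphan; ta3 unitless orphan
  st <- orphan_stats(arrays, units, feats)
  expect_equal(st$n_tas[st$group == "orphan"], 2L)
  expect_equal(st$n_tas[st$group == "other"], 1L)
  expect_equal(st$n_tus[st$group == "orphan"], 2L)
  ## a mixed array with one non-orphan unit is "other"
  units2 <- rbind(units, data.frame(tu_id = "tu4", array_id = "ta2",
                                    seq = "chr1", start = 14100L,
                                    end = 14900L, stringsAsFactors = FALSE))
  feats2 <- rbind(feats, data.frame(class = "gene", seq = "chr1",
                                    start = 14100L, end = 14900L,
                                    stringsAsFactors = FALSE))
  st2 <- orphan_stats(arrays, units2, feats2)
  expect_equal(st2$n_tas[st2$group == "orphan"], 1L)
})

test_that("simulated annotation recovers the planted arrays as TGAs", {
  p <- sim_params(genome_length = 120000L, n_arrays = 3L, seed = 61)
  sim <- simulate_genome(p)
  ann <- simulate_annotation(sim, p)
  tgas <- build_reference_tgas(ann$genes, ann$hits)
  expect_equal(nrow(tgas), 3L)
  expect_equal(sort(vapply(tgas$gene_ids, length, 0L)),
               sort(as.vector(table(sim$truth$array_id))))
  ## decoys never end up in a TGA
  expect_false(any(grepl("decoy", unlist(tgas$gene_ids))))
})
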