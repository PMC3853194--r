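# Junction filtering, motif typing, known/novel classification, AS event
# detection against the brute-force oracle, breadth, intron sizes.

test_that("junction support is thresholded per tissue with no pooling", {
  jx <- toy_junctions(c(10L, 40L, 70L), c(30L, 60L, 90L),
                      support = matrix(c(3, 2, 5,
                                         0, 2, 1), 3))
  f <- filter_junctions(jx, min_support = 3)
  expect_equal(nrow(f), 2L)           # {2,2} detected nowhere, dropped
  expect_equal(f$breadth, c(1, 1))
  expect_true(f$det_root[f$start == 10])
  expect_false(f$det_leaf[f$start == 70]) # support 1 < 3 in leaf
})

test_that("motifs are typed on the splicing strand", {
  genome <- Biostrings::DNAStringSet(c(chrV = paste0(
    "CCCC", "GT", strrep("C", 14), "AG",   # [4,22) plus GT-AG
    "CC", "CT", strrep("C", 14), "AC",     # [24,42) minus (CT..AC)
    "CC", "GC", strrep("C", 14), "AG",     # [44,62) GC-AG plus
    "CC", "AA", strrep("C", 14), "TT",     # [64,82) non-canonical
    "CC")))
  jx <- data.frame(chrom = "chrV", start = c(4L, 24L, 44L, 64L),
                   end = c(22L, 42L, 62L, 82L), strand = ".",
                   support_root = 5, stringsAsFactors = FALSE)
  m <- junction_motif(jx, genome)
  expect_equal(m$motif, c("GT-AG", "GT-AG", "GC-AG", "AA-TT"))
  expect_equal(m$inferred_strand, c("+", "-", "+", "."))
  short <- data.frame(chrom = "chrV", start = 4L, end = 7L, strand = ".",
                      support_root = 5)
  expect_error(junction_motif(short, genome), "shorter than 4")
})

test_that("known junctions are exact annotated introns; the rest novel", {
  gm <- toy_gene()  # introns [100,200) [300,400)
  jx <- toy_junctions(c(100L, 100L, 700L), c(200L, 220L, 800L), support = 5)
  cl <- classify_junctions(jx, gm)
  expect_equal(cl$known, c(TRUE, FALSE, FALSE))
  expect_equal(sum(cl$known) + sum(!cl$known), nrow(jx))
  none <- classify_junctions(jx, gm[0, ])
  expect_false(any(none$known))
})

test_that("toy locus events are typed as ES, A3SS and IR", {
  gm <- toy_gene()  # + strand; exons [0,100) [200,300) [400,500)
  jx <- toy_junctions(c(100L, 300L, 100L, 100L),
                      c(200L, 400L, 400L, 220L), support = 5)
  tx <- rbind(toy_tx("ref", c(0L, 200L, 400L), c(100L, 300L, 500L)),
              toy_tx("ret", c(0L, 400L), c(300L, 500L))) # retains intron 1
  f <- filter_junctions(jx)
  res <- detect_as_events(f, tx, gm)
  ev <- res$events
  es <- ev[ev$event_type == "ES", ]
  expect_equal(c(es$start, es$end), c(200L, 300L))  # skipped exon
  a3 <- ev[ev$event_type == "A3SS", ]
  expect_equal(c(a3$start, a3$end), c(100L, 220L))
  ir <- ev[ev$event_type == "IR", ]
  # the annotated intron is retained; the alt-acceptor variant intron is
  # itself spanned by the retention exon and is typed IR as well
  expect_true(any(ir$start == 100L & ir$end == 200L))
  expect_setequal(ir$end, c(200L, 220L))
  expect_equal(nrow(ev), 4L)
})

test_that("a locus whose junctions are exactly its introns has no events", {
  gm <- toy_gene()
  jx <- toy_junctions(c(100L, 300L), c(200L, 400L), support = 5)
  tx <- toy_tx("ref", c(0L, 200L, 400L), c(100L, 300L, 500L))
  res <- detect_as_events(filter_junctions(jx), tx, gm)
  expect_equal(nrow(res$events), 0L)
  expect_equal(nrow(res$orphans), 0L)
})

test_that("donor/acceptor roles follow the coding strand", {
  gm <- toy_gene(strand = "-")
  # shares genomic start with intron 1, shifted genomic end: on minus the
  # genomic end is the donor, so this is an alternative 5' site
  jx <- toy_junctions(100L, 190L, support = 5)
  tx <- toy_tx("ref", c(0L, 200L, 400L), c(100L, 300L, 500L), strand = "-")
  res <- detect_as_events(filter_junctions(jx), tx, gm)
  expect_equal(res$events$event_type, "A5SS")
})

test_that("junctions at no locus are reported as orphans", {
  gm <- toy_gene()
  jx <- toy_junctions(c(100L, 5000L), c(200L, 5100L), support = 5)
  tx <- toy_tx("ref", c(0L, 200L, 400L), c(100L, 300L, 500L))
  res <- detect_as_events(filter_junctions(jx), tx, gm)
  expect_equal(nrow(res$orphans), 1L)
  expect_equal(res$orphans$start, 5000L)
})

test_that("detector equals exhaustive enumeration on random small loci", {
  for (seed in 1:40) {
    loc <- random_locus(seed)
    f <- filter_junctions(loc$junctions)
    got <- detect_as_events(f, loc$transcripts, loc$gene)$events
    want <- oracle_as_events(f, loc$transcripts, loc$gene)
    expect_equal(as_key_sorted(got), as_key_sorted(want),
                 label = paste("locus seed", seed))
  }
})

test_that("planted events are recovered exactly at zero noise", {
  run <- small_run()
  tr <- run$truth$as_events
  ev <- run$tables$events
  expect_setequal(event_key(ev), event_key(tr))
  m <- merge(tr, ev, by = c("gene_id", "event_type", "start", "end"))
  expect_equal(m$tissues.x, m$tissues.y) # tissue-detection vectors too
})

test_that("planted events stay recoverable under junction noise", {
  cfg <- small_config(seed = 21, noise_rate = 0.05)
  run <- run_pipeline(cfg)
  recall <- mean(event_key(run$truth$as_events) %in%
                   event_key(run$tables$events))
  expect_gte(recall, 0.9)
})

test_that("breadth summaries conserve the item count", {
  b <- c(1, 1, 2, 3, 5, 6)
  s <- breadth_summary(b, k = 2)
  expect_equal(s$n, 6)
  expect_equal(s$n_ge_k, 4)
  expect_equal(s$n_gt_k, 3)
  expect_equal(sum(s$histogram), s$n)
})

test_that("intron size statistics compare retained against all introns", {
  gm <- rbind(toy_gene("g1", starts = c(0L, 200L), ends = c(100L, 300L)),
              toy_gene("g2", starts = c(1000L, 1400L),
                       ends = c(1100L, 1500L)))
  # introns: 100 bp and 300 bp
  ir_short <- data.frame(start = 100L, end = 200L)
  st <- intron_size_stats(ir_short, gm)
  expect_equal(st$mean_retained, 100)
  expect_equal(st$mean_all, 200)
  same <- data.frame(start = c(100L, 1100L), end = c(200L, 1400L))
  st2 <- intron_size_stats(same, gm)
  expect_equal(st2$mean_retained, st2$mean_all)
  expect_equal(st2$p_value, 1)
  expect_error(intron_size_stats(ir_short[0, ], gm), "retained")
})

test_that("IR is planted in short introns, shifting the size contrast", {
  cfg <- sim_config(n_genes = 200L, as_events = c(IR = 40L, ES = 0L,
                                                  A5SS = 0L, A3SS = 0L),
                    n_ntr = 0L, n_uorf = 0L, seed = 31L)
  run <- run_pipeline(cfg)
  gm <- generate_annotation(cfg)$gene_models
  st <- intron_size_stats(
    run$tables$events[run$tables$events$event_type == "IR", ], gm)
  expect_lt(st$mean_retained, st$mean_all)
  expect_lt(st$p_value, 0.05)
})
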