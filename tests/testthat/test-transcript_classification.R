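# Merging, overlap labeling, longest-ORF scan.

test_that("identical intron chains merge with terminal-exon union", {
  tx <- rbind(
    toy_tx("a@root", c(0L, 200L), c(100L, 500L), tissues = "root"),
    toy_tx("a@leaf", c(20L, 200L), c(100L, 520L), tissues = "leaf"))
  m <- merge_transcripts(tx)
  expect_equal(length(unique(m$transcript_id)), 1L)
  expect_equal(m$start, c(0L, 200L))
  expect_equal(m$end, c(100L, 520L))
  expect_equal(m$tissues[[1]], "leaf,root")
})

test_that("overlapping mono-exon transcripts merge to their union", {
  tx <- rbind(toy_tx("a", 0L, 100L, tissues = "root"),
              toy_tx("b", 50L, 150L, tissues = "stem"),
              toy_tx("c", 300L, 400L, tissues = "root"),     # disjoint
              toy_tx("d", 90L, 120L, strand = "-", tissues = "leaf"))
  m <- merge_transcripts(tx)
  expect_equal(nrow(m), 3L)
  u <- m[m$start == 0L, ]
  expect_equal(u$end, 150L)
  expect_equal(u$tissues, "root,stem")
  expect_true(any(m$strand == "-" & m$start == 90L)) # other strand kept
})

test_that("merging is idempotent and preserves empty input", {
  sim <- plant_features(generate_annotation(small_config()), small_config())
  m1 <- merge_transcripts(sim$transcripts)
  m2 <- merge_transcripts(m1)
  expect_equal(m1[c("chrom", "strand", "start", "end", "tissues")],
               m2[c("chrom", "strand", "start", "end", "tissues")])
  empty <- sim$transcripts[0, ]
  expect_equal(nrow(merge_transcripts(empty)), 0L)
})

test_that("overlap labels partition transcripts on a toy locus", {
  gm <- toy_gene()  # exons [0,100) [200,300) [400,500)
  tx <- rbind(
    toy_tx("full", c(0L, 200L, 400L), c(100L, 300L, 600L)),  # exact + 3' ext
    toy_tx("two_exons", c(150L, 400L), c(300L, 500L)),       # partial cover
    toy_tx("far", 10000L, 10400L),                           # novel
    toy_tx("anti", c(0L, 200L, 400L), c(100L, 300L, 500L), strand = "-"))
  lab <- classify_transcripts(tx, gm)
  lab <- setNames(lab$label, lab$transcript_id)
  expect_equal(lab[["full"]], "complete")
  expect_equal(lab[["two_exons"]], "partial")
  expect_equal(lab[["far"]], "novel")
  expect_equal(lab[["anti"]], "partial") # antisense overlap is not novel
  expect_equal(sum(lab == "complete") + sum(lab == "partial") +
                 sum(lab == "novel"), length(lab))
})

test_that("complete requires intron-chain agreement inside the CDS span", {
  gm <- toy_gene()
  # covers all CDS bases but retains intron 1 -> partial
  ret <- toy_tx("ret", c(0L, 400L), c(300L, 500L))
  lab <- classify_transcripts(ret, gm)
  expect_equal(lab$label, "partial")
  expect_equal(lab$gene_id, "g1")
})

test_that("find_longest_orf matches constructed ORFs and the threshold", {
  set.seed(42)
  codons <- c("GCT", "GGA", "CTT", "CGA", "ACC")
  mk <- function(n_codons) {
    paste0(paste(rand_flank(10), collapse = ""), "ATG",
           paste(sample(codons, n_codons - 1, replace = TRUE), collapse = ""),
           "TAA", paste(rand_flank(10), collapse = ""))
  }
  rand_flank <- function(n) sample(c("C", "T"), n, replace = TRUE)
  long <- mk(120)
  res <- find_longest_orf(long)
  expect_equal(res$aa, 120L)
  expect_true(res$coding)
  short <- mk(99)
  res <- find_longest_orf(short)
  expect_equal(res$aa, 99L)
  expect_false(res$coding)
  expect_equal(find_longest_orf("CCCCCCCC")$aa, 0L)
})

test_that("find_longest_orf equals six-frame brute force on random input", {
  set.seed(99)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    expect_equal(find_longest_orf(s)$aa, oracle_longest_orf_aa(s),
                 label = paste("seq", i))
  }
})

test_that("the longest ORF is reported from the minus strand when longer", {
  plus_orf <- paste0("ATG", strrep("GCT", 10), "TAA")           # 11 aa
  minus_orf <- revcomp(paste0("ATG", strrep("GGA", 30), "TGA")) # 31 aa
  s <- paste0("CCTTCC", plus_orf, "CCTTCC", minus_orf, "CCTTCC")
  res <- find_longest_orf(s)
  expect_equal(res$aa, 31L)
  expect_equal(res$strand, "-")
})

test_that("planted NTRs are labeled novel and annotated loci are not", {
  run <- small_run()
  lab <- run$tables$labels
  merged <- run$tables$merged
  novel <- merged[merged$transcript_id %in%
                    lab$transcript_id[lab$label == "novel"], ]
  nk <- paste(novel$chrom, novel$start, novel$end, novel$strand)
  tr <- run$truth$ntr
  tk <- paste(tr$chrom, tr$start, tr$end, tr$strand)
  expect_setequal(nk, tk)
  # planted coding NTRs carry their ORF
  coding <- tr[!is.na(tr$orf_aa), ]
  ntr_tab <- run$tables$ntr
  ck <- novel$transcript_id[match(paste(coding$chrom, coding$start,
                                        coding$end, coding$strand), nk)]
  expect_true(all(ntr_tab$coding_flag[ntr_tab$transcript_id %in% ck]))
  expect_true(all(ntr_tab$longest_orf_aa[ntr_tab$transcript_id %in% ck] >=
                    coding$orf_aa))
})
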