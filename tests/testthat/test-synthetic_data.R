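# Generator contracts: determinism, conservation, planted-motif purity,
# and configuration errors.

test_that("identical config gives byte-identical output files", {
  cfg <- sim_config(n_genes = 12L, as_events = c(IR = 2L, ES = 1L,
                                                 A5SS = 1L, A3SS = 1L),
                    n_ntr = 3L, n_uorf = 4L, seed = 7L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_transcriptome(cfg, d1)
  simulate_transcriptome(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("requested feature counts are conserved in the truth table", {
  cfg <- small_config()
  ann <- generate_annotation(cfg)
  expect_equal(length(unique(ann$gene_models$gene_id)), cfg$n_genes)
  pf <- plant_features(ann, cfg)
  expect_equal(unclass(table(pf$truth$as_events$event_type))[
    names(cfg$as_events)[cfg$as_events > 0]],
    cfg$as_events[cfg$as_events > 0], ignore_attr = TRUE)
  expect_equal(nrow(pf$truth$as_events), sum(cfg$as_events))
  expect_equal(nrow(pf$truth$ntr), cfg$n_ntr)
  expect_equal(nrow(pf$truth$uorfs), cfg$n_uorf)
  # classes partition the gene set
  expect_setequal(pf$truth$expression_class$gene_id,
                  unique(ann$gene_models$gene_id))
  expect_false(anyDuplicated(pf$truth$expression_class$gene_id) > 0)
})

test_that("all emitted junction motifs are canonical GT-AG at zero noise", {
  cfg <- small_config()
  ann <- generate_annotation(cfg)
  pf <- plant_features(ann, cfg)
  jm <- junction_motif(pf$junctions, pf$genome)
  expect_true(all(jm$motif == "GT-AG"))
  # inferred strand agrees with the host gene for annotated introns
  ai <- txomeatlas:::annotated_introns(ann$gene_models)
  m <- merge(jm, ai, by = c("chrom", "start", "end"))
  expect_true(all(m$inferred_strand == m$strand.y))
})

test_that("zero requested events leave only annotated-intron junctions", {
  cfg <- sim_config(n_genes = 15L, as_events = c(IR = 0L, ES = 0L,
                                                 A5SS = 0L, A3SS = 0L),
                    n_ntr = 0L, n_uorf = 0L, seed = 3L)
  ann <- generate_annotation(cfg)
  pf <- plant_features(ann, cfg)
  ai <- txomeatlas:::annotated_introns(ann$gene_models)
  expect_setequal(sprintf("%s:%d-%d", pf$junctions$chrom,
                          pf$junctions$start, pf$junctions$end),
                  sprintf("%s:%d-%d", ai$chrom, ai$start, ai$end))
  flt <- filter_junctions(pf$junctions)
  res <- detect_as_events(flt, merge_transcripts(pf$transcripts),
                          ann$gene_models)
  expect_equal(nrow(res$events), 0L)
})

test_that("invalid configurations are refused", {
  expect_error(sim_config(intron_length = c(3L, 10L)), "intron range")
  expect_error(sim_config(tissues = "root"), "2 tissues")
  expect_error(sim_config(n_ntr = -1L), "non-negative")
  expect_error(sim_config(class_props = c(housekeeping = 1, silent = 0.5)),
               "sum to 1")
})

test_that("an ES request on two-exon genes is a generation error", {
  cfg <- sim_config(n_genes = 6L, exons_per_gene = c(2L, 2L),
                    as_events = c(IR = 0L, ES = 1L, A5SS = 0L, A3SS = 0L),
                    n_ntr = 0L, n_uorf = 0L, seed = 2L)
  ann <- generate_annotation(cfg)
  expect_error(plant_features(ann, cfg), "ES")
})

test_that("gene models are CDS-only with codons written into the genome", {
  cfg <- small_config()
  ann <- generate_annotation(cfg)
  pf <- plant_features(ann, cfg)
  gm <- ann$gene_models
  for (gid in sample(unique(gm$gene_id), 8)) {
    ex <- gm[gm$gene_id == gid, ]
    cds <- mature_sequence(ex, pf$genome)
    expect_equal(nchar(cds) %% 3, 0)
    expect_equal(substr(cds, 1, 3), "ATG")
    expect_true(substr(cds, nchar(cds) - 2, nchar(cds)) %in%
                  c("TAA", "TAG", "TGA"))
    # exons sorted and non-overlapping
    expect_true(all(diff(ex$start) > 0))
    expect_true(all(ex$start[-1] >= ex$end[-nrow(ex)]))
  }
})

test_that("simulated expression matches its class contract", {
  cfg <- small_config()
  ann <- generate_annotation(cfg)
  pf <- plant_features(ann, cfg)
  expr <- simulate_expression(ann, pf$truth, cfg)
  m <- fpkm_matrix(expr[expr$gene_id %in% ann$gene_models$gene_id, ])
  lo <- fpkm_matrix(expr[expr$gene_id %in% ann$gene_models$gene_id, ],
                    "ci_lo")
  cls <- pf$truth$expression_class
  hk <- cls$gene_id[cls$class == "housekeeping"]
  expect_true(all(m[hk, ] > 50))
  ts <- cls[cls$class == "tissue_specific", ]
  for (i in seq_len(nrow(ts))) {
    v <- m[ts$gene_id[[i]], ]
    expect_equal(sum(v > 0), 1L)
    expect_equal(names(which(v > 0)), ts$tissue[[i]])
    expect_equal(compute_tau(v)$tau, 1)
  }
  sil <- cls$gene_id[cls$class == "silent"]
  expect_true(all(lo[sil, ] == 0))
  # identical seed, identical table
  expect_identical(expr, simulate_expression(ann, pf$truth, cfg))
})

test_that("a YAML config round-trips into sim_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_genes: 9", "seed: 4",
               "as_events: {IR: 1, ES: 0, A5SS: 0, A3SS: 0}",
               "n_ntr: 2", "n_uorf: 1"), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_genes, 9L)
  expect_equal(cfg$as_events[["IR"]], 1L)
})
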