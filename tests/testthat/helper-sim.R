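# Shared small synthetic dataset, generated once per test run.

.sim_cache <- new.env(parent = emptyenv())

small_config <- function(seed = 11, ...) {
  sim_config(n_genes = 40L, as_events = c(IR = 6L, ES = 3L,
                                          A5SS = 3L, A3SS = 3L),
             n_ntr = 8L, n_uorf = 12L, seed = seed, ...)
}

small_run <- function() {
  if (is.null(.sim_cache$run)) {
    .sim_cache$run <- run_pipeline(small_config())
  }
  .sim_cache$run
}

event_key <- function(d) paste(d$gene_id, d$event_type, d$start, d$end)

# tiny hand-built locus helpers --------------------------------------------

toy_gene <- function(gene_id = "g1", chrom = "chrV", strand = "+",
                     starts = c(0L, 200L, 400L), ends = c(100L, 300L, 500L)) {
  data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
             start = starts, end = ends, stringsAsFactors = FALSE)
}

toy_tx <- function(transcript_id, starts, ends, strand = "+",
                   chrom = "chrV", tissues = NA_character_) {
  data.frame(transcript_id = transcript_id, chrom = chrom, strand = strand,
             start = starts, end = ends, tissues = tissues,
             stringsAsFactors = FALSE)
}

toy_junctions <- function(starts, ends, support, chrom = "chrV",
                          tissues = c("root", "leaf")) {
  jx <- data.frame(chrom = chrom, start = starts, end = ends, strand = ".",
                   stringsAsFactors = FALSE)
  for (i in seq_along(tissues)) {
    jx[[paste0("support_", tissues[[i]])]] <-
      if (is.matrix(support)) support[, i] else support
  }
  jx
}
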