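#!/usr/bin/env Rscript
# Stage 4: splice junctions and alternative splicing. Per-tissue support
# filtering, border-motif census with strand inference, known/novel
# junction classification, typed AS event detection (IR/ES/A5SS/A3SS),
# tissue breadth, and the retained-vs-all intron size contrast.

suppressMessages(library(txomeatlas))

simdir <- "results/simdata"
outdir <- "results/splicing"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

genome <- read_genome(file.path(simdir, "genome.fa"))
gene_models <- read_gene_models(file.path(simdir, "genes.gff3"))
transcripts <- merge_transcripts(
  read_transcripts(file.path(simdir, "transcripts.gtf")))
junctions <- read_junctions(
  file.path(simdir, "junctions.bed"),
  support_path = file.path(simdir, "junctions.bed.support.tsv"))

flt <- filter_junctions(junctions, min_support = 3)
cat("Junctions with support >= 3 in at least one tissue:",
    nrow(flt), "of", nrow(junctions), "\n")

flt <- junction_motif(flt, genome)
cens <- sort(table(flt$motif), decreasing = TRUE)
cat("Border motif census:\n"); print(cens)
cat("GT-AG fraction:",
    summary_ratios(sum(flt$motif == "GT-AG"), nrow(flt))$label, "\n")

flt <- classify_junctions(flt, gene_models)
cat("Known (annotated intron) junctions:", sum(flt$known),
    "; novel:", sum(!flt$known), "\n")

asr <- detect_as_events(flt, transcripts, gene_models)
events <- asr$events
tab <- as_event_table(events, k = 2)
cat("AS events by type (shared = tissue breadth, at least / more than 2):\n")
print(tab, row.names = FALSE)
cat("Genes with multiple AS events:",
    sum(table(events$gene_id) > 1), "\n")
cat("Orphan junctions (no locus):", nrow(asr$orphans), "\n")

bs <- breadth_summary(events$breadth, k = 2)
cat("Events shared by >= 2 tissues:",
    summary_ratios(bs$n_ge_k, bs$n)$label, "\n")

ir <- events[events$event_type == "IR", ]
st <- intron_size_stats(ir, gene_models)
cat(sprintf(
  "Retained introns mean %.0f bp vs all introns %.0f bp (rank-sum p = %.3g)\n",
  st$mean_retained, st$mean_all, st$p_value))

write.table(flt, file.path(outdir, "junctions_classified.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(events, file.path(outdir, "as_events.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(tab, file.path(outdir, "as_event_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(asr$orphans, file.path(outdir, "orphan_junctions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Tables written to", outdir, "\n")
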