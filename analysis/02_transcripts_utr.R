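#!/usr/bin/env Rscript
# Stage 2: annotation improvement. Merge the per-tissue transcripts,
# reconcile them against the CDS-only gene models (complete / partial /
# novel), score novel transcribed regions for coding potential, define
# 5'/3' UTR boundaries from the complete transcripts, scan uORFs, and
# compare UTR lengths across functional categories.

suppressMessages(library(txomeatlas))

simdir <- "results/simdata"
outdir <- "results/annotation"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

genome <- read_genome(file.path(simdir, "genome.fa"))
gene_models <- read_gene_models(file.path(simdir, "genes.gff3"))
transcripts <- read_transcripts(file.path(simdir, "transcripts.gtf"))
categories <- read.table(file.path(simdir, "gene2cat.tsv"), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)

merged <- merge_transcripts(transcripts)
labels <- classify_transcripts(merged, gene_models)
cat("Merged", length(unique(transcripts$transcript_id)),
    "per-tissue transcripts into", nrow(labels), "models\n")
n <- table(labels$label)
for (lbl in names(n)) {
  cat(sprintf("  %-9s %4d  (%s)\n", lbl, n[[lbl]],
              summary_ratios(n[[lbl]], nrow(labels))$label))
}

ntr <- ntr_coding_potential(merged, labels, genome)
cat("NTRs with an ORF > 100 aa:",
    summary_ratios(sum(ntr$coding_flag), nrow(ntr))$label, "\n")

utrs <- annotate_utrs(merged, labels, gene_models)
cat("UTRs defined for", nrow(utrs), "genes; median 5'/3' lengths:",
    median(utrs$utr5_len), "/", median(utrs$utr3_len), "nt\n")

uorfs <- annotate_uorfs(utrs, merged, genome)
cat("Genes with a uORF (10-50 nt) in the 5' UTR:",
    length(unique(uorfs$gene_id)), "\n")

utr5 <- setNames(utrs$utr5_len, utrs$gene_id)
by_cat <- compare_utr_by_category(utr5, categories)
sig <- by_cat[by_cat$direction != "none", ]
cat("Categories with significantly longer/shorter 5' UTRs:",
    nrow(sig), "of", nrow(by_cat), "\n")

write.table(merged, file.path(outdir, "merged_transcripts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(labels, file.path(outdir, "overlap_labels.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ntr, file.path(outdir, "ntr_coding.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(utrs, file.path(outdir, "utrs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(uorfs, file.path(outdir, "uorfs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(by_cat, file.path(outdir, "utr5_by_category.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Tables written to", outdir, "\n")
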