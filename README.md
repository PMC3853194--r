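# txomeatlas

Downstream characterization of a multi-tissue plant transcriptome from
assembler-level inputs. The package is aimed at the analysis layer that
sits *after* read mapping, transcript assembly and expression
quantification: it consumes CDS-only gene models (GFF3), per-tissue
assembled transcripts (GTF), splice junctions with per-tissue read
support (BED + support matrix), per-tissue FPKM tables with 95%
confidence bounds (TSV), and the genome (FASTA), and produces

* **transcript reconciliation** — cuffmerge-style merging of per-tissue
  transcripts, `complete` / `partial` / `novel` overlap labels against
  the gene models, novel transcribed regions (NTRs) and their coding
  potential via a six-frame longest-ORF scan (coding = ORF > 100 aa);
* **UTR and uORF annotation** — 5′/3′ UTR lengths in mature (spliced)
  coordinates from length-complete transcripts vs CDS-only models, and
  upstream ORFs of 10–50 nt inside the 5′ UTR;
* **an expression atlas** — expressed calls (95% CI lower bound of FPKM
  > 0), constitutive and housekeeping sets (FPKM > 50 in every tissue),
  FPKM tiers (≤ 5 < medium ≤ 50 < high), the tissue-specificity index

  τᵢ = Σⱼ (1 − Sᵢⱼ / Sᵢ,max) / (n − 1)

  (0 for uniform expression, 1 for single-tissue expression), and a
  tissue dendrogram (1 − Pearson correlation of log2(FPKM+1) profiles of
  constitutive genes, average linkage);
* **alternative-splicing events** — junction filtering (support ≥ 3 per
  tissue, no pooling), border-motif typing with strand inference
  (GT-AG / GC-AG / AT-AC on either strand), known/novel junction
  classification, and typed events: intron retention (IR), exon
  skipping (ES), alternative 5′ and 3′ splice sites (A5SS/A3SS), each
  with a tissue-detection vector;
* **enrichment statistics** — one-sided Fisher exact test when the 2×2
  table's minimum expected cell is ≤ 5, Pearson chi-square otherwise,
  with Benjamini–Hochberg FDR across categories.

Because genome-scale inputs are bulky, the package ships a
**synthetic-data generator** (`sim_config()`, `simulate_transcriptome()`)
that emits a toy genome with every feature class planted — AS events of
all four types, NTRs, UTR extensions, uORFs, and an expression-class
partition (housekeeping / tissue-specific / graded / silent) — together
with a machine-readable truth table, so every pipeline stage can be
scored for exact recovery.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on the
default synthetic dataset (200 genes, 6 tissues, 100 planted AS events,
50 NTRs, 100 uORF genes):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_transcripts_utr.R
Rscript analysis/03_expression_atlas.R
Rscript analysis/04_splicing.R
Rscript analysis/05_enrichment.R
Rscript analysis/06_report.R
```

Stage 4 prints, for example:

```
Junctions with support >= 3 in at least one tissue: 815 of 898
GT-AG fraction: 100.0% (815/815)
Known (annotated intron) junctions: 755 ; novel: 60
AS events by type (shared = tissue breadth, at least / more than 2):
 as_type events genes shared_ge_k shared_gt_k
      IR     40    40          29          25
    A3SS     20    20          12           9
    A5SS     20    20          12          10
      ES     20    20          13          11
   Total    100   100          66          55
Retained introns mean 117 bp vs all introns 184 bp (rank-sum p = 4.87e-09)
```

All 100 planted events are recovered with their exact coordinates and
tissue vectors (precision = recall = 1 at zero noise); the retained
introns are shorter than introns in general because retention is
planted on each host gene's shortest intron. Stage 3 prints the
expression atlas (here 90.0% (180/200) of genes expressed, 30
housekeeping genes, the tissue dendrogram in newick), and stage 5 the
enrichment table, whose top hit is the category planted to be
over-represented among AS genes.

The same counts can be produced in one call:

```r
library(txomeatlas)
res <- run_pipeline(sim_config(seed = 1))
res$report$as_events$total        # 100
res$report$expression$pct_expressed$label  # "90.0% (180/200)"
```

Every percentage in the report carries its integer numerator and
denominator (`summary_ratios()`), so the printed arithmetic is always
reproducible from the counts.

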