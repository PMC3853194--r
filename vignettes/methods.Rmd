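---
title: "Methods: transcriptome characterization from assembler-level inputs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptome characterization from assembler-level inputs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txomeatlas)
```

## Scope and model

`txomeatlas` characterizes a multi-tissue plant transcriptome starting
from the outputs of a mapping/assembly/quantification stack, not from
reads: gene models annotated as CDS only (no UTR features), per-tissue
assembled transcripts, splice junctions with per-tissue read counts,
and per-tissue FPKM tables with 95% confidence bounds. All
coordinates are 0-based half-open internally; GFF3/GTF are converted
exactly once at the I/O boundary, which keeps the interval arithmetic
free of ±1 bookkeeping.

The workflow has five statistical/algorithmic components, each a small,
explicit contract:

**Transcript reconciliation.** Per-tissue transcripts are merged the
way cuffmerge merges assemblies: multi-exon transcripts with identical
intron chains (same strand) collapse, terminal exons taking the union
of the inputs; overlapping mono-exon transcripts collapse to their
union interval. Merging is idempotent. A merged transcript is
`complete` for a gene when its exons cover every CDS base *and* its
intron chain restricted to the CDS span equals the gene's intron chain;
`partial` when it overlaps exonic sequence on the same strand without
being complete; `novel` when it overlaps no gene model's exons on
either strand. "Complete" is deliberately strict because UTR calling
is only meaningful for transcripts whose structure agrees with the
gene model over the CDS. A transcript overlapping a gene only in the
antisense orientation is a boundary case: it is not independent of the
locus, so it is labeled `partial` with no linked gene rather than
`novel`; a relaxed (antisense-novel) convention would change NTR counts
and is intentionally not the default.

**UTR and uORF annotation.** For a complete transcript, the 5′ UTR is
the mature (spliced) sequence upstream of the CDS start on the coding
strand, the 3′ UTR the mature sequence downstream of the CDS end; by
construction `utr5 + cds + utr3 = mature length`, and the package
asserts this on every call. Transcripts not complete for a gene yield
an explicit undefined result, never a zero. The uORF scan reports
every ATG-initiated ORF ending at its first in-frame stop wholly
inside the 5′ UTR with total length (stop included) between 10 and
50 nt — i.e. effective lengths 12, 15, …, 48, since ORF lengths are
multiples of 3. Overlapping uORFs are all reported; a uORF can never
extend into the CDS because the scanned sequence ends at the CDS
start. The longest-ORF scan used for NTR coding potential examines
all six frames (the strand of a novel region is unknown); amino-acid
length counts codons from the ATG through the last sense codon — the
initiator Met counts, the stop does not — and coding means > 100 aa.

**Expression atlas.** A gene is *expressed* in a tissue when the lower
bound of the 95% CI of its FPKM exceeds zero (a count-driven interval:
a handful of supporting fragments moves the bound off zero);
*constitutive* when expressed everywhere; *housekeeping* when FPKM is
strictly above 50 in every tissue. Tiers cut the FPKM axis at 5 and
50 (low/medium/high); the cuts are closed on the left tier, so 5.0 is
low and 50.0 is medium. Tissue specificity is the Yanai-style index
τ = Σⱼ(1 − Sⱼ/S_max)/(n − 1) with n the number of tissues; replicate
samples of one tissue should be averaged before τ is computed. τ is 0
for uniform rows, 1 for one-hot rows, undefined (an error) for
all-zero rows. The tissue-specific call combines τ ≥ 0.9 — a
conventional default, configurable, since no canonical threshold
exists — with the requirement that the gene be expressed in its
maximal tissue. Tissues are clustered on log2(FPKM + 1) profiles of
constitutive genes (the pseudo-count avoids −∞ at zero), distance
1 − Pearson correlation, average linkage; columns are sorted by tissue
name first so ties resolve deterministically, and a constant column is
an error naming the offending tissue rather than a silent NaN.

**Splice junctions and AS events.** A junction is detected in a tissue
when its read support there is at least 3; there is no pooling across
tissues, so a junction with support 2 in each of two tissues is
dropped. Border motifs are read on the splicing strand: genomic
GT..AG (or GC..AG, AT..AC) implies the plus strand, their reverse
complements (CT..AC etc.) the minus strand; anything else is reported
as observed with unknown strand, and the host gene's strand is used
downstream. A junction exactly equal to an annotated intron is
*known*; known + novel partition the retained set. Event typing is
anchored to annotated introns: a junction whose donor matches intron
*i* and whose acceptor matches intron *i+1* skips the exon between
them (ES); a junction sharing exactly one boundary with an annotated
intron — the other boundary not coinciding with any annotated same-side
boundary of that gene — is an alternative splice site, donor-side
shifts being A5SS and acceptor-side shifts A3SS on the coding strand;
an intron (annotated or junction-defined) wholly contained within a
single exon of a merged transcript at the locus, while its spliced
junction is also detected, is retained (IR) — retention evidence thus
requires both isoforms. ES is checked first and is exclusive, which
prevents an exon-skipping junction from also being typed as an
alternative site; a multi-exon-skipping junction (acceptor two or more
introns downstream) matches no type and remains an unclassified novel
junction. One deliberate consequence of the contract: an
alternative-site variant intron that is itself spanned by a retention
exon is typed both ways (A3SS and IR), since both pieces of evidence
are real. Junctions assignable to no gene or transcript locus are
reported as orphans, never silently dropped. The detector is verified
against a brute-force enumeration of all junction/intron pairs and
junction/exon containments on small random loci.

**Enrichment.** For a category with K members in a background of M
genes and k hits among n study genes, the 2×2 table's minimum expected
cell count N selects the test: N ≤ 5 uses the one-sided Fisher exact
test (hypergeometric upper tail — "enriched" is a one-sided question),
N > 5 the Pearson chi-square with 1 df without continuity correction.
The threshold rule is stated in terms of expected counts because that
is the standard chi-square validity criterion; the chosen N is
reported alongside each result. P-values are adjusted with the
Benjamini–Hochberg step-up across categories. Category structure is
flat (a two-column gene/category map); ontology DAG propagation is out
of scope.

## The synthetic-data generator

The generator exists so that every stage can be scored against a known
truth, at desk scale, without downloads. Its defaults mirror the
study conditions the package emulates: six tissues (callus, root,
stem, leaf, flower, silique), 200 CDS-only gene models of 2–8 exons
(exon lengths 90–300 bp in multiples of 3, introns 60–300 bp, UTR
extensions 60–400 nt), 100 AS events (40 IR, 20 ES, 20 A5SS, 20 A3SS —
IR dominant, as in plants), 50 intergenic NTRs (half carrying a
110–150 aa ORF; low, tissue-restricted expression), 100 uORF genes,
and an expression-class partition of 15% housekeeping, 15%
tissue-specific, 60% graded, 10% silent. A fixed seed gives
byte-identical output files.

Design choices worth knowing:

* The genome is uniform random A/C/G/T with planted signals
  overwritten: GT..AG borders on every annotated intron (CT..AC on the
  minus strand), start/stop codons at the mature CDS ends, donor or
  acceptor dinucleotides at planted alternative sites inside the
  affected intron. Sequence content beyond these motifs is never
  interpreted by the pipeline.
* 5′-UTR regions are scrubbed of chance ATG triplets (strand-aware),
  and planted uORF bodies are built from stop-free, G-free codons, so
  at zero noise the planted uORFs are exactly the set of upstream ORFs
  present — recovery is then precision = recall = 1 by construction,
  and any deviation is a detector bug, not generator noise. Real
  5′ UTRs of course contain incidental uORFs; the recovery tests
  measure the scanner's correctness, not its behaviour on real UTR
  composition (the brute-force equivalence test on random sequence
  covers that).
* Each AS event occupies its own gene: IR events retain the host
  gene's *shortest* intron (the intron-definition view of retention),
  which also gives the retained-vs-all intron size contrast its
  direction; ES picks a random internal exon, requiring a gene with at
  least 3 exons (requesting ES when no such gene remains is a
  generation error); alternative sites are shifted 4–12 bp into the
  intron and receive the boundary motif. Event evidence (junction
  support, and for IR the exon-spanning transcript) is placed in a
  random subset of the tissues where the host gene is expressed, which
  becomes the event's truth tissue vector.
* Expression: housekeeping genes draw FPKM uniformly in (55, 400) per
  tissue; graded genes in (5, 30) per tissue — which bounds their τ at
  5/6, keeping them below the 0.9 tissue-specific threshold, so the
  four classes are exactly separable by the published calling rules;
  tissue-specific genes are one-hot (τ = 1); silent genes have small
  FPKM with ≤ 2 supporting fragments. The CI lower bound is
  `max(0, fpkm·(1 − 1.96/√(c+1)))` with c a simulated fragment count —
  a Poisson-flavoured stand-in chosen because the only property
  consumed downstream is whether the bound clears zero.
* Junction noise (`noise_rate`) does two things: each support cell
  drops below the detection threshold with that probability, and a
  matching fraction of spurious junctions (random intervals inside
  gene spans, borders left as random sequence, hence mostly
  non-canonical) is added. At the default rate of 0 the data are
  clean; at 0.05 planted-event recall stays above 0.9 in the test
  suite.

What the generator does **not** emulate: read-level errors and
coverage, realistic sequence composition, overlapping or nested genes,
paralogy, replicate samples, correlated tissue profiles beyond the
class structure, and incidental uORFs/ORFs in UTRs. Tests passing on
synthetic data therefore demonstrate the correctness of the
contracts — not performance on real assemblies, where assembler
artifacts and ambiguous loci dominate error rates.

## Numerical and reporting conventions

* Percentages in reports are rounded half-up to one decimal and always
  carried with their integer numerator/denominator pair
  (`summary_ratios()`), so every printed ratio can be re-derived.
* Wilcoxon rank-sum comparisons (UTR lengths per category,
  retained-vs-all intron sizes, NTR-vs-gene τ) use `stats::wilcox.test`
  — exact for small tie-free samples, normal approximation with tie
  correction otherwise. Categories with fewer than two observations
  are skipped with a warning.
* Tissue-breadth summaries report both "at least k" and "more than k"
  counts (k = 2 by default) because the phrase "shared by more than
  two tissues" is ambiguous between the two in common usage.
* Problem sizes in the test suite and acceptance script: the shared
  unit-test dataset uses 40 genes with 15 planted events; the
  full-scale recovery check uses the default 200-gene configuration;
  oracle equivalences enumerate all 2×2 tables with background ≤ 25
  and 65 random small loci; null calibration uses 1000 replicates of
  15 random categories over 400 genes. These sizes give exact or
  well-resolved answers for every contract while keeping a complete
  run in the low minutes on one core.

## Known limitations

* IR calling is evidence-based (two isoforms: spanning exon +
  junction), not coverage-based; intronic read depth is out of scope
  because the package consumes junctions and transcripts, not
  alignments.
* No quantitative splicing index (PSI) is computed; events carry
  detection vectors, not usage fractions.
* The known/novel junction split and "complete" labels inherit any
  errors present in the input gene models.
* Enrichment treats categories as flat labels; genes in no category
  simply dilute the background.
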