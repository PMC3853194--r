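# Reconciliation of assembled transcripts against CDS-only gene models:
# cuffmerge-like merging, complete/partial/novel overlap labels, and a
# six-frame longest-ORF scan for coding potential of novel regions.

intron_chain <- function(starts, ends) {
  n <- length(starts)
  if (n < 2L) return(character())
  sprintf("%d-%d", ends[-n], starts[-1])
}

tx_split <- function(transcripts) split(transcripts, transcripts$transcript_id)

#' Merge per-tissue transcript sets
#'
#' Multi-exon transcripts on the same chromosome and strand with
#' identical intron chains collapse to one record whose terminal exons
#' are the union of the inputs' terminal exons; mono-exon transcripts on
#' the same strand overlapping by at least 1 bp collapse to their union
#' interval. `tissues` is the union of the inputs' tissues. Merged
#' records are renamed `TCONS_<n>` in coordinate order; the operation is
#' idempotent.
#'
#' @param transcripts exon-level transcript data.frame
#'   (see [read_transcripts()]); per-tissue records share coordinates but
#'   differ in `transcript_id`/`tissues`.
#' @return merged transcript data.frame in the same format.
#' @export
merge_transcripts <- function(transcripts) {
  if (nrow(transcripts) == 0L) return(transcripts)
  parts <- tx_split(transcripts)
  info <- do.call(rbind, lapply(parts, function(d) {
    d <- d[order(d$start), ]
    data.frame(chrom = d$chrom[[1]], strand = d$strand[[1]],
               n_exons = nrow(d),
               chain = paste(intron_chain(d$start, d$end), collapse = ";"),
               start = min(d$start), end = max(d$end),
               tissues = d$tissues[[1]], stringsAsFactors = FALSE)
  }))
  info$id <- names(parts)

  merged <- list()
  # multi-exon: group by (chrom, strand, intron chain)
  multi <- info[info$n_exons > 1L, ]
  if (nrow(multi) > 0L) {
    key <- paste(multi$chrom, multi$strand, multi$chain)
    for (grp in split(multi, key)) {
      ids <- grp$id
      ex <- parts[[ids[[1]]]][order(parts[[ids[[1]]]]$start), ]
      starts <- ex$start; ends <- ex$end
      starts[[1]] <- min(grp$start)
      ends[[length(ends)]] <- max(grp$end)
      merged[[length(merged) + 1L]] <- list(
        chrom = grp$chrom[[1]], strand = grp$strand[[1]],
        start = starts, end = ends,
        tissues = sort(unique(unlist(strsplit(grp$tissues, ",")))))
    }
  }
  # mono-exon: union of overlapping intervals per chrom/strand
  mono <- info[info$n_exons == 1L, ]
  if (nrow(mono) > 0L) {
    for (grp in split(mono, paste(mono$chrom, mono$strand))) {
      ir <- IRanges::IRanges(grp$start + 1L, grp$end)
      comp <- S4Vectors::subjectHits(
        IRanges::findOverlaps(ir, IRanges::reduce(ir)))
      for (ci in unique(comp)) {
        g <- grp[comp == ci, ]
        merged[[length(merged) + 1L]] <- list(
          chrom = g$chrom[[1]], strand = g$strand[[1]],
          start = min(g$start), end = max(g$end),
          tissues = sort(unique(unlist(strsplit(g$tissues, ",")))))
      }
    }
  }
  ord <- order(vapply(merged, function(m) m$chrom, ""),
               vapply(merged, function(m) min(m$start), 1),
               vapply(merged, function(m) max(m$end), 1),
               vapply(merged, function(m) m$strand, ""))
  merged <- merged[ord]
  out <- do.call(rbind, lapply(seq_along(merged), function(i) {
    m <- merged[[i]]
    data.frame(transcript_id = sprintf("TCONS_%05d", i), chrom = m$chrom,
               strand = m$strand, start = m$start, end = m$end,
               tissues = paste(m$tissues, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Label transcripts against gene models
#'
#' Each transcript gets exactly one label: `complete` when its exons
#' cover every CDS base of some gene and its intron chain restricted to
#' that gene's CDS span equals the gene's intron chain; `partial` when it
#' has any same-strand exonic overlap with a gene but is not complete for
#' any; `novel` when it has no exonic overlap with any gene model on
#' either strand. For non-novel transcripts the linked gene is the one
#' with the most overlapping exonic bases (ties broken by gene id).
#'
#' @param transcripts exon-level transcript data.frame (typically merged).
#' @param gene_models CDS exon data.frame (see [read_gene_models()]).
#' @return data.frame: `transcript_id`, `label`, `gene_id` (NA for
#'   novel), one row per transcript.
#' @export
classify_transcripts <- function(transcripts, gene_models) {
  parts <- tx_split(transcripts)
  gparts <- split(gene_models, gene_models$gene_id)
  tx_gr <- GenomicRanges::GRanges(
    transcripts$chrom,
    IRanges::IRanges(transcripts$start + 1L, transcripts$end),
    strand = "*", transcript_id = transcripts$transcript_id)
  gm_gr <- GenomicRanges::GRanges(
    gene_models$chrom,
    IRanges::IRanges(gene_models$start + 1L, gene_models$end),
    strand = "*", gene_id = gene_models$gene_id)
  hits <- GenomicRanges::findOverlaps(tx_gr, gm_gr, ignore.strand = TRUE)
  ov_w <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(tx_gr)[S4Vectors::queryHits(hits)],
    IRanges::ranges(gm_gr)[S4Vectors::subjectHits(hits)]))
  pair <- data.frame(
    tid = tx_gr$transcript_id[S4Vectors::queryHits(hits)],
    gid = gm_gr$gene_id[S4Vectors::subjectHits(hits)],
    gstrand = gene_models$strand[S4Vectors::subjectHits(hits)],
    w = ov_w, stringsAsFactors = FALSE)

  res <- lapply(names(parts), function(tid) {
    d <- parts[[tid]][order(parts[[tid]]$start), ]
    p <- pair[pair$tid == tid, , drop = FALSE]
    if (nrow(p) == 0L) {
      return(data.frame(transcript_id = tid, label = "novel",
                        gene_id = NA_character_, stringsAsFactors = FALSE))
    }
    p <- p[p$gstrand == d$strand[[1]], , drop = FALSE]
    if (nrow(p) == 0L) {
      # antisense-only overlap: overlapped, hence not novel, but no
      # same-strand gene to be partial/complete for
      return(data.frame(transcript_id = tid, label = "partial",
                        gene_id = NA_character_, stringsAsFactors = FALSE))
    }
    ag <- tapply(p$w, p$gid, sum)
    cand <- names(sort(ag, decreasing = TRUE))
    for (gid in cand) {
      if (is_complete_for(d, gparts[[gid]])) {
        return(data.frame(transcript_id = tid, label = "complete",
                          gene_id = gid, stringsAsFactors = FALSE))
      }
    }
    data.frame(transcript_id = tid, label = "partial", gene_id = cand[[1]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# complete = CDS bases covered + intron chain identical within CDS span
is_complete_for <- function(tx_ex, gene_ex) {
  gene_ex <- gene_ex[order(gene_ex$start), ]
  tx_ir <- IRanges::IRanges(tx_ex$start + 1L, tx_ex$end)
  gm_ir <- IRanges::IRanges(gene_ex$start + 1L, gene_ex$end)
  uncovered <- IRanges::setdiff(gm_ir, tx_ir)
  if (sum(IRanges::width(uncovered)) > 0L) return(FALSE)
  cds_lo <- min(gene_ex$start); cds_hi <- max(gene_ex$end)
  tx_introns <- if (nrow(tx_ex) > 1L) {
    data.frame(start = tx_ex$end[-nrow(tx_ex)], end = tx_ex$start[-1])
  } else data.frame(start = integer(), end = integer())
  inside <- tx_introns[tx_introns$start >= cds_lo & tx_introns$end <= cds_hi,
                       , drop = FALSE]
  gm_introns <- if (nrow(gene_ex) > 1L) {
    data.frame(start = gene_ex$end[-nrow(gene_ex)], end = gene_ex$start[-1])
  } else data.frame(start = integer(), end = integer())
  identical(sprintf("%d-%d", inside$start, inside$end),
            sprintf("%d-%d", gm_introns$start, gm_introns$end))
}

#' Longest open reading frame in a sequence (six frames)
#'
#' Scans all three frames on both strands for ATG..in-frame-stop ORFs
#' lying wholly inside the sequence. The amino-acid length counts codons
#' from the ATG up to but excluding the stop codon. A transcript with a
#' longest ORF over `aa_threshold` amino acids is flagged as coding.
#'
#' @param sequence nucleotide string over ACGTN.
#' @param aa_threshold coding-potential cutoff in amino acids.
#' @return list: `aa` (0 when no ORF), `coding` (logical), `strand`,
#'   `start`, `end` (0-based half-open ORF interval on the input
#'   sequence, including the stop codon; NA when no ORF).
#' @export
find_longest_orf <- function(sequence, aa_threshold = 100L) {
  best <- list(aa = 0L, coding = FALSE, strand = NA_character_,
               start = NA_integer_, end = NA_integer_)
  n <- nchar(sequence)
  if (n < 6L) return(best)
  for (str in c("+", "-")) {
    s <- if (str == "+") sequence else revcomp(sequence)
    chars <- strsplit(toupper(s), "")[[1]]
    for (frame in 0:2) {
      idx <- seq(frame + 1L, n, by = 3L)
      idx <- idx[idx + 2L <= n]
      codons <- paste0(chars[idx], chars[idx + 1L], chars[idx + 2L])
      open_at <- NA_integer_
      for (ci in seq_along(codons)) {
        cd <- codons[[ci]]
        if (is.na(open_at) && cd == "ATG") open_at <- ci
        if (!is.na(open_at) && cd %in% c("TAA", "TAG", "TGA")) {
          aa <- ci - open_at
          if (aa > best$aa) {
            s0 <- idx[[open_at]] - 1L       # 0-based on strand `s`
            e0 <- idx[[ci]] + 2L
            if (str == "-") { tmp <- s0; s0 <- n - e0; e0 <- n - tmp }
            best <- list(aa = aa, coding = aa > aa_threshold, strand = str,
                         start = s0, end = e0)
          }
          open_at <- NA_integer_
        }
      }
    }
  }
  best$coding <- best$aa > aa_threshold
  best
}

#' Mature (spliced) sequence of a transcript
#'
#' Concatenates exon sequences in 5'->3' order on the coding strand.
#'
#' @param tx_exons exon data.frame rows of one transcript.
#' @param genome a [Biostrings::DNAStringSet].
#' @return character scalar.
#' @export
mature_sequence <- function(tx_exons, genome) {
  d <- tx_exons[order(tx_exons$start), ]
  pieces <- vapply(seq_len(nrow(d)), function(i) {
    extract_sequence(genome, d$chrom[[i]], d$start[[i]], d$end[[i]], "+")
  }, "")
  s <- paste(pieces, collapse = "")
  if (d$strand[[1]] == "-") revcomp(s) else s
}

#' Score novel transcripts for coding potential
#'
#' @param transcripts merged transcript data.frame.
#' @param labels output of [classify_transcripts()].
#' @param genome a [Biostrings::DNAStringSet].
#' @param aa_threshold coding cutoff in amino acids.
#' @return data.frame: `transcript_id`, `longest_orf_aa`, `coding_flag`
#'   for transcripts labeled `novel`.
#' @export
ntr_coding_potential <- function(transcripts, labels, genome,
                                 aa_threshold = 100L) {
  novel_ids <- labels$transcript_id[labels$label == "novel"]
  parts <- tx_split(transcripts[transcripts$transcript_id %in% novel_ids, ])
  out <- do.call(rbind, lapply(names(parts), function(tid) {
    orf <- find_longest_orf(mature_sequence(parts[[tid]], genome),
                            aa_threshold)
    data.frame(transcript_id = tid, longest_orf_aa = orf$aa,
               coding_flag = orf$coding, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(),
                      longest_orf_aa = integer(), coding_flag = logical(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
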