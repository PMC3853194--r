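# Splice-junction filtering, motif typing and strand inference,
# known/novel classification, and typed alternative-splicing event
# detection (IR / ES / A5SS / A3SS) with tissue breadth.

annotated_introns <- function(gene_models) {
  parts <- split(gene_models, gene_models$gene_id)
  out <- do.call(rbind, lapply(names(parts), function(gid) {
    ex <- parts[[gid]][order(parts[[gid]]$start), ]
    n <- nrow(ex)
    if (n < 2L) return(NULL)
    data.frame(gene_id = gid, chrom = ex$chrom[[1]], strand = ex$strand[[1]],
               start = ex$end[-n], end = ex$start[-1],
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  }
  out
}

#' Filter junctions by per-tissue read support
#'
#' A junction is detected in a tissue when its support there is at least
#' `min_support`; there is no pooling across tissues. Junctions detected
#' in no tissue are dropped.
#'
#' @param junctions junction data.frame with `support_<tissue>` columns.
#' @param min_support per-tissue read-support threshold (default 3).
#' @return the retained junctions with added logical `det_<tissue>`
#'   columns and a `breadth` column.
#' @export
filter_junctions <- function(junctions, min_support = 3) {
  sup <- junction_support(junctions)
  det <- sup >= min_support
  out <- junctions
  for (t in colnames(det)) out[[paste0("det_", t)]] <- det[, t]
  out$breadth <- rowSums(det)
  out <- out[out$breadth > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

det_matrix <- function(junctions) {
  cols <- grep("^det_", names(junctions), value = TRUE)
  if (length(cols) == 0L) stop("junctions not filtered: no det_ columns")
  m <- as.matrix(junctions[, cols, drop = FALSE])
  colnames(m) <- sub("^det_", "", cols)
  m
}

CANONICAL_MOTIFS <- c("GT-AG", "GC-AG", "AT-AC")

#' Border motif and inferred strand of junctions
#'
#' The motif is the first two plus last two intron bases on the splicing
#' strand. A junction whose genomic borders read as a canonical donor/
#' acceptor pair (GT-AG, GC-AG, AT-AC) is assigned the plus strand; one
#' whose reverse complement does (e.g. genomic CT..AC) is assigned the
#' minus strand. Otherwise the observed genomic dinucleotides are
#' reported as-is with strand ".".
#'
#' @param junctions junction data.frame.
#' @param genome a [Biostrings::DNAStringSet].
#' @return the junctions with `motif` and `inferred_strand` columns.
#' @export
junction_motif <- function(junctions, genome) {
  n <- nrow(junctions)
  motif <- character(n); istr <- character(n)
  for (i in seq_len(n)) {
    if (junctions$end[[i]] - junctions$start[[i]] < 4L) {
      stop("intron shorter than 4 bp at ",
           jx_id(junctions[i, , drop = FALSE]))
    }
    d <- extract_sequence(genome, junctions$chrom[[i]],
                          junctions$start[[i]], junctions$start[[i]] + 2L)
    a <- extract_sequence(genome, junctions$chrom[[i]],
                          junctions$end[[i]] - 2L, junctions$end[[i]])
    fwd <- paste0(d, "-", a)
    rev <- paste0(revcomp(a), "-", revcomp(d))
    if (fwd %in% CANONICAL_MOTIFS) {
      motif[[i]] <- fwd; istr[[i]] <- "+"
    } else if (rev %in% CANONICAL_MOTIFS) {
      motif[[i]] <- rev; istr[[i]] <- "-"
    } else {
      motif[[i]] <- fwd; istr[[i]] <- "."
    }
  }
  junctions$motif <- motif
  junctions$inferred_strand <- istr
  junctions
}

#' Classify junctions as known or novel
#'
#' Known = the intron interval exactly equals an annotated intron of
#' some gene model; everything else is novel. Known + novel partition
#' the retained junctions.
#'
#' @param junctions junction data.frame.
#' @param gene_models CDS exon data.frame.
#' @return the junctions with a logical `known` column.
#' @export
classify_junctions <- function(junctions, gene_models) {
  ai <- annotated_introns(gene_models)
  keys <- sprintf("%s:%d-%d", ai$chrom, ai$start, ai$end)
  junctions$known <- jx_id(junctions) %in% keys
  junctions
}

#' Detect alternative-splicing events
#'
#' Per locus, four event types are called from filtered junctions,
#' merged transcripts and annotated introns:
#' \itemize{
#'   \item ES: a junction whose donor equals the donor of annotated
#'     intron i and whose acceptor equals the acceptor of intron i+1,
#'     skipping the internal exon between them.
#'   \item A5SS / A3SS: a junction sharing exactly one boundary with an
#'     annotated intron, the other boundary not coinciding with any
#'     annotated same-side boundary of the gene; whether the shifted
#'     site is the donor (5') or acceptor (3') follows the coding
#'     strand.
#'   \item IR: an annotated or junction-defined intron wholly contained
#'     within a single exon of a merged transcript at the locus while
#'     the spliced junction itself is also detected (both isoforms
#'     present).
#' }
#' A junction's strand is its motif-inferred strand when available,
#' otherwise the host gene's. Junctions assignable to no gene or
#' transcript locus are reported as orphans, never silently dropped.
#' Tissue detection of an event follows the junction's per-tissue
#' detection (for IR, intersected with the spanning transcript's
#' tissues when known).
#'
#' @param junctions filtered junctions (see [filter_junctions()]).
#' @param transcripts merged transcript data.frame.
#' @param gene_models CDS exon data.frame.
#' @return list: `events` (gene_id, event_type, chrom, strand, start,
#'   end, ref_start, ref_end, tissues, breadth), `orphans` (junction
#'   rows assigned to no locus).
#' @export
detect_as_events <- function(junctions, transcripts, gene_models) {
  det <- det_matrix(junctions)
  tissues <- colnames(det)
  ai <- annotated_introns(gene_models)
  gspan <- span_by(gene_models, "gene_id")
  tx_parts <- if (nrow(transcripts)) tx_split(transcripts) else list()
  tspan <- if (nrow(transcripts)) span_by(transcripts, "transcript_id") else
    data.frame(transcript_id = character(), chrom = character(),
               strand = character(), start = integer(), end = integer())

  jstrand <- if ("inferred_strand" %in% names(junctions)) {
    junctions$inferred_strand
  } else rep(".", nrow(junctions))

  events <- list()
  orphan_idx <- integer()
  emit <- function(gene_id, type, chrom, strand, s, e, rs, re, tis) {
    events[[length(events) + 1L]] <<- data.frame(
      gene_id = gene_id, event_type = type, chrom = chrom, strand = strand,
      start = s, end = e, ref_start = rs, ref_end = re,
      tissues = paste(sort(tis), collapse = ","), breadth = length(tis),
      stringsAsFactors = FALSE)
  }

  for (ji in seq_len(nrow(junctions))) {
    js <- junctions$start[[ji]]; je <- junctions$end[[ji]]
    jc <- junctions$chrom[[ji]]
    hosts <- gspan[gspan$chrom == jc & gspan$start < je & gspan$end > js, ,
                   drop = FALSE]
    if (jstrand[[ji]] != ".") {
      hosts <- hosts[hosts$strand == jstrand[[ji]], , drop = FALSE]
    }
    if (nrow(hosts) == 0L) {
      at_tx <- any(tspan$chrom == jc & tspan$start < je & tspan$end > js)
      if (!at_tx) orphan_idx <- c(orphan_idx, ji)
      next
    }
    jt <- tissues[det[ji, ]]
    for (hi in seq_len(nrow(hosts))) {
      gid <- hosts$gene_id[[hi]]
      strand <- hosts$strand[[hi]]
      a <- ai[ai$gene_id == gid, , drop = FALSE]
      if (nrow(a) == 0L) next
      if (any(a$start == js & a$end == je)) next     # annotated intron
      # exon skipping: donor of intron i, acceptor of intron i+1
      es_i <- which(a$start[-nrow(a)] == js & a$end[-1] == je)
      if (length(es_i)) {
        emit(gid, "ES", jc, strand, a$end[[es_i]], a$start[[es_i + 1L]],
             js, je, jt)
        next
      }
      share_s <- which(a$start == js & a$end != je)
      share_e <- which(a$end == je & a$start != js)
      if (length(share_s) && !je %in% a$end) {
        type <- if (strand == "+") "A3SS" else "A5SS"
        emit(gid, type, jc, strand, js, je,
             a$start[[share_s[[1]]]], a$end[[share_s[[1]]]], jt)
      } else if (length(share_e) && !js %in% a$start) {
        type <- if (strand == "+") "A5SS" else "A3SS"
        emit(gid, type, jc, strand, js, je,
             a$start[[share_e[[1]]]], a$end[[share_e[[1]]]], jt)
      }
    }
  }

  # intron retention: detected intron contained in a transcript exon
  for (ji in seq_len(nrow(junctions))) {
    js <- junctions$start[[ji]]; je <- junctions$end[[ji]]
    jc <- junctions$chrom[[ji]]
    jt <- tissues[det[ji, ]]
    hosts <- gspan[gspan$chrom == jc & gspan$start < je & gspan$end > js, ,
                   drop = FALSE]
    if (jstrand[[ji]] != ".") {
      hosts <- hosts[hosts$strand == jstrand[[ji]], , drop = FALSE]
    }
    for (hi in seq_len(nrow(hosts))) {
      gid <- hosts$gene_id[[hi]]
      strand <- hosts$strand[[hi]]
      span <- gspan[gspan$gene_id == gid, ]
      cand_tx <- tspan[tspan$chrom == jc & tspan$strand == strand &
                         tspan$start < span$end & tspan$end > span$start, ,
                       drop = FALSE]
      ret_tis <- character(); found <- FALSE
      for (tid in cand_tx$transcript_id) {
        ex <- tx_parts[[tid]]
        if (any(ex$start < js & ex$end > je)) {
          found <- TRUE
          tt <- ex$tissues[[1]]
          ret_tis <- union(ret_tis,
                           if (is.na(tt)) jt else
                             intersect(jt, strsplit(tt, ",")[[1]]))
        }
      }
      if (found) {
        emit(gid, "IR", jc, strand, js, je, NA_integer_, NA_integer_,
             ret_tis)
      }
    }
  }

  ev <- if (length(events)) unique(do.call(rbind, events)) else
    data.frame(gene_id = character(), event_type = character(),
               chrom = character(), strand = character(), start = integer(),
               end = integer(), ref_start = integer(), ref_end = integer(),
               tissues = character(), breadth = integer(),
               stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  list(events = ev, orphans = junctions[orphan_idx, , drop = FALSE])
}

#' Tissue breadth summary
#'
#' Breadth = number of tissues in which an item (event or junction) was
#' detected. Because the study's own phrasing of "shared by more than
#' two tissues" is used inconsistently, both the `>= k` and `> k`
#' summaries are reported.
#'
#' @param breadth integer vector of per-item breadths.
#' @param k sharing threshold (default 2).
#' @return list: `n`, `n_ge_k`, `n_gt_k`, `histogram` (named counts by
#'   breadth; sums to `n`).
#' @export
breadth_summary <- function(breadth, k = 2) {
  h <- table(factor(breadth, levels = seq_len(max(breadth, 1))))
  list(n = length(breadth), n_ge_k = sum(breadth >= k),
       n_gt_k = sum(breadth > k), histogram = h)
}

#' Retained-intron versus all-intron size statistics
#'
#' @param ir_events IR rows of the event table (their anchor interval is
#'   the retained intron).
#' @param gene_models CDS exon data.frame (source of all annotated
#'   intron lengths).
#' @return list: `mean_retained`, `mean_all`, `p_value` (two-sided
#'   Wilcoxon rank-sum), `n_retained`, `n_all`.
#' @export
intron_size_stats <- function(ir_events, gene_models) {
  ai <- annotated_introns(gene_models)
  if (nrow(ir_events) == 0L) stop("no retained introns")
  if (nrow(ai) == 0L) stop("no annotated introns")
  retained <- ir_events$end - ir_events$start
  all_len <- ai$end - ai$start
  p <- suppressWarnings(wilcox.test(retained, all_len)$p.value)
  list(mean_retained = mean(retained), mean_all = mean(all_len),
       p_value = p, n_retained = length(retained), n_all = length(all_len))
}
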