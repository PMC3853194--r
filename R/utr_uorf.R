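# UTR boundary definition from length-complete transcripts vs CDS-only
# gene models, upstream-ORF scanning, and UTR-length comparisons across
# flat functional categories.

# mature (spliced) offset of a genomic position within an exon chain,
# counting on the plus strand from the leftmost exon base
mature_offset <- function(starts, ends, gpos) {
  off <- 0L
  for (k in seq_along(starts)) {
    if (gpos >= ends[[k]]) {
      off <- off + (ends[[k]] - starts[[k]])
    } else {
      if (gpos > starts[[k]]) off <- off + (gpos - starts[[k]])
      break
    }
  }
  off
}

#' Define 5'/3' UTR lengths for a complete transcript
#'
#' UTR lengths are measured in mature (spliced) nucleotides: the 5' UTR
#' is everything upstream of the CDS start on the coding strand, the 3'
#' UTR everything downstream of the CDS end. Calls are only defined for
#' transcripts labeled `complete` for the gene; anything else returns an
#' explicit undefined result, never zero.
#'
#' @param tx_exons exon rows of one transcript.
#' @param gene_exons CDS exon rows of the linked gene.
#' @param label the transcript's overlap label for this gene.
#' @return list: `defined` (logical), `utr5_len`, `utr3_len`,
#'   `mature_len`, `cds_len` (NA when undefined).
#' @export
define_utrs <- function(tx_exons, gene_exons, label = "complete") {
  if (!identical(label, "complete")) {
    return(list(defined = FALSE, utr5_len = NA_integer_,
                utr3_len = NA_integer_, mature_len = NA_integer_,
                cds_len = NA_integer_))
  }
  d <- tx_exons[order(tx_exons$start), ]
  g <- gene_exons[order(gene_exons$start), ]
  strand <- d$strand[[1]]
  mature_len <- sum(d$end - d$start)
  cds_len <- sum(g$end - g$start)
  cds_lo <- min(g$start); cds_hi <- max(g$end)
  up <- mature_offset(d$start, d$end, cds_lo)         # left of CDS, mature nt
  down <- mature_len - mature_offset(d$start, d$end, cds_hi)
  utr5 <- if (strand == "-") down else up
  utr3 <- if (strand == "-") up else down
  list(defined = TRUE, utr5_len = as.integer(utr5),
       utr3_len = as.integer(utr3), mature_len = as.integer(mature_len),
       cds_len = as.integer(cds_len))
}

#' UTR annotation for all complete transcripts
#'
#' @param transcripts merged transcript data.frame.
#' @param labels output of [classify_transcripts()].
#' @param gene_models CDS exon data.frame.
#' @return data.frame: `gene_id`, `transcript_id`, `utr5_len`,
#'   `utr3_len`, `mature_len`, `cds_len`; one row per complete
#'   transcript. The conservation invariant
#'   `utr5 + cds + utr3 == mature length` holds on every row.
#' @export
annotate_utrs <- function(transcripts, labels, gene_models) {
  comp <- labels[labels$label == "complete", , drop = FALSE]
  parts <- tx_split(transcripts)
  gparts <- split(gene_models, gene_models$gene_id)
  out <- do.call(rbind, lapply(seq_len(nrow(comp)), function(i) {
    tid <- comp$transcript_id[[i]]; gid <- comp$gene_id[[i]]
    u <- define_utrs(parts[[tid]], gparts[[gid]], "complete")
    stopifnot(u$utr5_len + u$cds_len + u$utr3_len == u$mature_len)
    data.frame(gene_id = gid, transcript_id = tid,
               utr5_len = u$utr5_len, utr3_len = u$utr3_len,
               mature_len = u$mature_len, cds_len = u$cds_len,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), transcript_id = character(),
                      utr5_len = integer(), utr3_len = integer(),
                      mature_len = integer(), cds_len = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Scan a 5'-UTR sequence for upstream ORFs
#'
#' Reports every ATG-initiated ORF terminated by an in-frame stop wholly
#' inside the UTR whose length (stop codon included) lies within
#' `len_range` nucleotides; overlapping uORFs are all reported. Because
#' the input ends at the CDS start, a reported uORF can never overlap
#' the main CDS.
#'
#' @param utr5_seq mature 5'-UTR sequence on the coding strand.
#' @param len_range allowed ORF length window in nt, stop included
#'   (default 10-50, i.e. effective lengths 12, 15, ..., 48).
#' @return data.frame: `offset` (0-based nt from the 5' transcript end),
#'   `length_nt`.
#' @export
scan_uorfs <- function(utr5_seq, len_range = c(10L, 50L)) {
  chars <- strsplit(toupper(utr5_seq), "")[[1]]
  n <- length(chars)
  hits <- list()
  if (n >= 6L) {
    starts <- which(chars == "A")
    starts <- starts[starts + 2L <= n]
    starts <- starts[chars[starts + 1L] == "T" & chars[starts + 2L] == "G"]
    for (s in starts) {
      p <- s + 3L
      while (p + 2L <= n) {
        cd <- paste0(chars[p], chars[p + 1L], chars[p + 2L])
        if (cd %in% c("TAA", "TAG", "TGA")) {
          len <- p + 3L - s
          if (len >= len_range[[1]] && len <= len_range[[2]]) {
            hits[[length(hits) + 1L]] <-
              data.frame(offset = s - 1L, length_nt = len)
          }
          break
        }
        p <- p + 3L
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(offset = integer(), length_nt = integer())
  rownames(out) <- NULL
  out
}

#' uORF annotation for all UTR-called genes
#'
#' @param utrs output of [annotate_utrs()].
#' @param transcripts merged transcript data.frame.
#' @param genome a [Biostrings::DNAStringSet].
#' @return data.frame: `gene_id`, `transcript_id`, `offset`,
#'   `length_nt`; one row per uORF.
#' @export
annotate_uorfs <- function(utrs, transcripts, genome) {
  parts <- tx_split(transcripts)
  out <- do.call(rbind, lapply(seq_len(nrow(utrs)), function(i) {
    r <- utrs[i, ]
    if (r$utr5_len < 6L) return(NULL)
    seq5 <- substr(mature_sequence(parts[[r$transcript_id]], genome),
                   1L, r$utr5_len)
    u <- scan_uorfs(seq5)
    if (nrow(u) == 0L) return(NULL)
    data.frame(gene_id = r$gene_id, transcript_id = r$transcript_id, u,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), transcript_id = character(),
                      offset = integer(), length_nt = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Compare UTR lengths per category against the full set
#'
#' Two-sided Wilcoxon rank-sum test of each category's UTR lengths
#' against all UTR lengths; categories are flagged `longer` or `shorter`
#' at p < `alpha` by the sign of the median difference. Categories with
#' fewer than 2 observations are skipped with a warning.
#'
#' @param lengths named numeric vector of UTR lengths (names = gene ids).
#' @param category_map data.frame with columns `gene_id`, `category`.
#' @param alpha significance level for the direction flag.
#' @return data.frame: `category`, `n`, `median`, `median_all`,
#'   `direction` (`longer`/`shorter`/`none`), `p_value`.
#' @export
compare_utr_by_category <- function(lengths, category_map, alpha = 0.05) {
  med_all <- stats::median(lengths)
  out <- list()
  for (cat in sort(unique(category_map$category))) {
    gids <- category_map$gene_id[category_map$category == cat]
    x <- lengths[names(lengths) %in% gids]
    if (length(x) < 2L) {
      warning("category ", cat, " has fewer than 2 observations; skipped")
      next
    }
    p <- suppressWarnings(wilcox.test(x, lengths)$p.value)
    dir <- if (p < alpha) {
      if (stats::median(x) > med_all) "longer" else "shorter"
    } else "none"
    out[[length(out) + 1L]] <- data.frame(
      category = cat, n = length(x), median = stats::median(x),
      median_all = med_all, direction = dir, p_value = p,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(category = character(), n = integer(), median = numeric(),
               median_all = numeric(), direction = character(),
               p_value = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
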