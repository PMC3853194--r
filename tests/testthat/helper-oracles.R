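# Independent brute-force oracles. These re-derive expected results by
# naive enumeration and share no code with the implementation paths they
# check.

# every ORF substring: starts ATG, ends at its first in-frame stop, both
# codons inside the sequence; returns 0-based offset and nt length
oracle_orfs <- function(s) {
  chars <- strsplit(toupper(s), "")[[1]]
  n <- length(chars)
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (i in seq_len(max(n - 5L, 0L))) {
    if (paste(chars[i:(i + 2L)], collapse = "") != "ATG") next
    p <- i + 3L
    while (p + 2L <= n) {
      cd <- paste(chars[p:(p + 2L)], collapse = "")
      if (cd %in% stops) {
        out[[length(out) + 1L]] <-
          data.frame(offset = i - 1L, length_nt = p + 3L - i)
        break
      }
      p <- p + 3L
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(offset = integer(), length_nt = integer())
}

# longest ORF over both strands by enumeration; aa excludes the stop
oracle_longest_orf_aa <- function(s) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  lens <- c(oracle_orfs(s)$length_nt, oracle_orfs(rc)$length_nt)
  if (length(lens) == 0L) return(0L)
  max(lens) / 3L - 1L
}

# one-sided (over-representation) Fisher p by hypergeometric enumeration
oracle_fisher_p <- function(k, n, K, M) {
  xs <- k:min(n, K)
  sum(choose(K, xs) * choose(M - K, n - xs)) / choose(M, n)
}

# Benjamini-Hochberg step-up by the textbook formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# AS events by exhaustive enumeration over (junction, intron) pairs and
# (junction, transcript exon) containments; junctions must already carry
# det_ columns (i.e. be filtered)
oracle_as_events <- function(junctions, transcripts, gene_models) {
  out <- list()
  add <- function(gid, type, s, e) {
    out[[length(out) + 1L]] <<- data.frame(
      gene_id = gid, event_type = type, start = s, end = e,
      stringsAsFactors = FALSE)
  }
  for (gid in unique(gene_models$gene_id)) {
    ex <- gene_models[gene_models$gene_id == gid, ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) < 2L) next
    gchrom <- ex$chrom[[1]]; gstrand <- ex$strand[[1]]
    glo <- min(ex$start); ghi <- max(ex$end)
    is_ <- ex$end[-nrow(ex)]; ie_ <- ex$start[-1]
    ni <- length(is_)
    for (ji in seq_len(nrow(junctions))) {
      j <- junctions[ji, ]
      if (j$chrom != gchrom || j$end <= glo || j$start >= ghi) next
      annotated <- any(is_ == j$start & ie_ == j$end)
      if (!annotated) {
        es_hit <- FALSE
        if (ni >= 2L) {
          for (i in seq_len(ni - 1L)) {
            if (j$start == is_[[i]] && j$end == ie_[[i + 1L]]) {
              add(gid, "ES", ie_[[i]], is_[[i + 1L]])
              es_hit <- TRUE
            }
          }
        }
        if (!es_hit) {
          if (any(is_ == j$start) && !any(ie_ == j$end)) {
            add(gid, if (gstrand == "+") "A3SS" else "A5SS", j$start, j$end)
          } else if (any(ie_ == j$end) && !any(is_ == j$start)) {
            add(gid, if (gstrand == "+") "A5SS" else "A3SS", j$start, j$end)
          }
        }
      }
      # retention: any same-strand transcript exon strictly spanning it
      spanned <- FALSE
      for (tid in unique(transcripts$transcript_id)) {
        tx <- transcripts[transcripts$transcript_id == tid, ]
        if (tx$chrom[[1]] != gchrom || tx$strand[[1]] != gstrand) next
        if (max(tx$end) <= glo || min(tx$start) >= ghi) next
        for (r in seq_len(nrow(tx))) {
          if (tx$start[[r]] < j$start && tx$end[[r]] > j$end) spanned <- TRUE
        }
      }
      if (spanned) add(gid, "IR", j$start, j$end)
    }
  }
  res <- if (length(out)) unique(do.call(rbind, out)) else
    data.frame(gene_id = character(), event_type = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  res[order(res$gene_id, res$event_type, res$start), , drop = FALSE]
}

as_key_sorted <- function(d) {
  sort(paste(d$gene_id, d$event_type, d$start, d$end))
}

# random toy locus with <= 6 junctions for detector/oracle equivalence
random_locus <- function(seed) {
  set.seed(seed)
  n_ex <- sample(3:5, 1)
  ex_len <- sample(20:40, n_ex, replace = TRUE)
  in_len <- sample(12:30, n_ex - 1, replace = TRUE)
  starts <- integer(n_ex); ends <- integer(n_ex)
  p <- 50L
  for (k in seq_len(n_ex)) {
    starts[[k]] <- p; ends[[k]] <- p + ex_len[[k]]
    p <- ends[[k]] + if (k < n_ex) in_len[[k]] else 0L
  }
  strand <- sample(c("+", "-"), 1)
  gm <- toy_gene("gX", strand = strand, starts = starts, ends = ends)
  is_ <- ends[-n_ex]; ie_ <- starts[-1]
  cand <- list()
  for (i in seq_along(is_)) {
    cand[[length(cand) + 1L]] <- c(is_[[i]], ie_[[i]])              # annotated
    cand[[length(cand) + 1L]] <- c(is_[[i]], ie_[[i]] - sample(3:8, 1))
    cand[[length(cand) + 1L]] <- c(is_[[i]] + sample(3:8, 1), ie_[[i]])
    if (i < length(is_)) cand[[length(cand) + 1L]] <- c(is_[[i]], ie_[[i + 1L]])
  }
  cand[[length(cand) + 1L]] <- c(starts[[1]] - 40L, starts[[1]] - 10L) # orphanish
  pick <- sample(seq_along(cand), min(6L, sample(2:6, 1)))
  jx <- do.call(rbind, lapply(cand[pick], function(se) {
    data.frame(chrom = "chrV", start = se[[1]], end = se[[2]], strand = ".",
               support_root = sample(3:9, 1), support_leaf = sample(0:9, 1),
               stringsAsFactors = FALSE)
  }))
  jx <- jx[jx$end - jx$start >= 4, , drop = FALSE]
  # transcripts: the reference chain plus sometimes a retention isoform
  txs <- toy_tx("t.ref", starts, ends, strand = strand)
  if (runif(1) < 0.7) {
    k <- sample(seq_len(n_ex - 1L), 1)
    rs <- starts[-(k + 1L)]; re <- ends[-k]
    txs <- rbind(txs, toy_tx("t.ret", rs, re, strand = strand))
  }
  list(gene = gm, junctions = jx, transcripts = txs)
}
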