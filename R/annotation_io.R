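# I/O layer. Internal convention everywhere: 0-based half-open intervals
# (BED-like). GFF3/GTF are 1-based inclusive on disk and are converted
# exactly once, here.

#' Read a genome FASTA
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet] named by sequence.
#' @export
read_genome <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write a genome FASTA
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Reverse complement of a nucleotide string
#' @param x character scalar over ACGTN.
#' @return character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract a genomic subsequence
#'
#' Returns the sequence of a 0-based half-open interval; on the minus
#' strand the reverse complement is returned.
#'
#' @param genome a [Biostrings::DNAStringSet] named by chromosome.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"`, `"-"` or `"."` (treated as `"+"`).
#' @return character scalar.
#' @export
extract_sequence <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) {
    stop("unknown chromosome '", chrom, "'")
  }
  len <- length(genome[[chrom]])
  if (start < 0 || end > len || start >= end) {
    stop("interval [", start, ",", end, ") out of bounds on ", chrom,
         " (length ", len, ")")
  }
  s <- as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
  if (identical(strand, "-")) revcomp(s) else s
}

# -- validation helper for tab-delimited annotation files ---------------------

validate_tabular <- function(path, min_fields, one_based) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  for (i in idx) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < min_fields) {
      stop(path, " line ", i, ": expected >= ", min_fields,
           " tab-separated fields, found ", length(f))
    }
    st <- suppressWarnings(as.numeric(f[[4 - 2 * !one_based]])) # col 4/2
    en <- suppressWarnings(as.numeric(f[[5 - 2 * !one_based]])) # col 5/3
    if (is.na(st) || is.na(en)) {
      stop(path, " line ", i, ": non-numeric coordinates")
    }
    bad <- if (one_based) en < st else en <= st
    if (bad) {
      stop(path, " line ", i, ": end (", en, ") < start (", st, ")")
    }
    if (one_based && !f[[7]] %in% c("+", "-", ".")) {
      stop(path, " line ", i, ": unknown strand '", f[[7]], "'")
    }
  }
  invisible(length(idx))
}

# -- gene models --------------------------------------------------------------

#' Read CDS-only gene models from GFF3
#'
#' Keeps `CDS` features and groups them into gene models by their `Parent`
#' attribute. File coordinates (1-based inclusive) become 0-based
#' half-open.
#'
#' @param path a GFF3 file.
#' @return a data.frame with one row per CDS exon: `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, sorted by position within gene.
#' @export
read_gene_models <- function(path) {
  validate_tabular(path, 9L, one_based = TRUE)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L) stop("no CDS features in ", path)
  if (any(S4Vectors::elementNROWS(gr$Parent) != 1L)) {
    stop("CDS feature without a single Parent in ", path)
  }
  parent <- as.character(unlist(gr$Parent))
  df <- data.frame(
    gene_id = parent,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$gene_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write gene models to GFF3 (CDS features only)
#'
#' @param gene_models data.frame as returned by [read_gene_models()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(gene_models, path) {
  gm <- gene_models[order(gene_models$gene_id, gene_models$start), ,
                    drop = FALSE]
  span <- span_by(gm, "gene_id")
  gene_gr <- GenomicRanges::GRanges(
    span$chrom,
    IRanges::IRanges(span$start + 1L, span$end),
    strand = span$strand,
    type = "gene", ID = span$gene_id
  )
  phase <- unlist(lapply(split(gm, gm$gene_id), function(d) {
    len <- d$end - d$start
    if (d$strand[[1]] == "-") len <- rev(len)
    ph <- (3L - cumsum(c(0L, len[-length(len)])) %% 3L) %% 3L
    if (d$strand[[1]] == "-") rev(ph) else ph
  }), use.names = FALSE)
  cds_gr <- GenomicRanges::GRanges(
    gm$chrom,
    IRanges::IRanges(gm$start + 1L, gm$end),
    strand = gm$strand,
    phase = phase,
    type = "CDS",
    ID = sprintf("%s.cds%d", gm$gene_id,
                 stats::ave(seq_len(nrow(gm)), gm$gene_id, FUN = seq_along)),
    Parent = gm$gene_id
  )
  gr <- c(gene_gr, cds_gr)
  gr <- gr[order(GenomicRanges::start(gr), match(gr$type, c("gene", "CDS")))]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# span (min start, max end) per group; assumes single chrom/strand per group
span_by <- function(df, key) {
  sp <- do.call(rbind, lapply(split(df, df[[key]]), function(d) {
    data.frame(chrom = d$chrom[[1]], strand = d$strand[[1]],
               start = min(d$start), end = max(d$end),
               stringsAsFactors = FALSE)
  }))
  sp[[key]] <- rownames(sp)
  rownames(sp) <- NULL
  sp[, c(key, "chrom", "strand", "start", "end")]
}

# -- transcripts --------------------------------------------------------------

#' Read assembled transcripts from GTF
#'
#' Keeps `exon` features grouped by `transcript_id`. An optional `tissues`
#' attribute (comma-separated) records the tissues in which the transcript
#' was assembled.
#'
#' @param path a GTF file.
#' @return data.frame with one row per exon: `transcript_id`, `chrom`,
#'   `strand`, `start`, `end`, `tissues`.
#' @export
read_transcripts <- function(path) {
  validate_tabular(path, 9L, one_based = TRUE)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  tiss <- if ("tissues" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$tissues)
  } else {
    rep(NA_character_, length(gr))
  }
  df <- data.frame(
    transcript_id = as.character(gr$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    tissues = tiss,
    stringsAsFactors = FALSE
  )
  df <- df[order(df$transcript_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write transcripts to GTF
#'
#' @param transcripts data.frame as returned by [read_transcripts()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(transcripts, path) {
  tx <- transcripts[order(transcripts$transcript_id, transcripts$start), ,
                    drop = FALSE]
  gr <- GenomicRanges::GRanges(
    tx$chrom,
    IRanges::IRanges(tx$start + 1L, tx$end),
    strand = tx$strand,
    type = "exon",
    source = "txomeatlas",
    gene_id = tx$transcript_id,
    transcript_id = tx$transcript_id
  )
  if (!all(is.na(tx$tissues))) gr$tissues <- tx$tissues
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

# -- splice junctions ---------------------------------------------------------

jx_id <- function(jx) sprintf("%s:%d-%d", jx$chrom, jx$start, jx$end)

#' Tissue names carried by a junction table
#' @param junctions junction data.frame.
#' @return character vector of tissue names.
#' @export
junction_tissues <- function(junctions) {
  sub("^support_", "", grep("^support_", names(junctions), value = TRUE))
}

#' Per-tissue support counts as a matrix
#' @param junctions junction data.frame.
#' @return numeric matrix, junctions x tissues.
#' @export
junction_support <- function(junctions) {
  cols <- grep("^support_", names(junctions), value = TRUE)
  m <- as.matrix(junctions[, cols, drop = FALSE])
  colnames(m) <- sub("^support_", "", cols)
  rownames(m) <- jx_id(junctions)
  m
}

#' Read splice junctions (BED6 intron-interval or BED12 dialect)
#'
#' The dialect is auto-detected from the column count: 6 columns are read
#' as intron intervals directly; 12 columns are read as BED12 where the
#' two blocks are the flanking exon anchors and the intron is the gap
#' between them (records with a block count other than 2 are rejected with
#' a warning). Per-tissue support is attached from a sidecar TSV (columns:
#' `junction`, then one column per tissue) or, failing that, from the BED
#' score column under the supplied `tissue` name. Duplicate junction
#' records are aggregated by summing support per tissue.
#'
#' @param path BED file.
#' @param support_path optional sidecar support-matrix TSV.
#' @param tissue tissue name for the score column when no sidecar is given.
#' @return data.frame: `chrom`, `start`, `end`, `strand`, plus
#'   `support_<tissue>` columns.
#' @export
read_junctions <- function(path, support_path = NULL, tissue = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|track|$)", lines)]
  if (length(lines) == 0L) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol1 <- length(fields[[1]])
  if (!ncol1 %in% c(6L, 12L)) {
    stop("ambiguous junction file: ", ncol1,
         " columns (expected 6 or 12): ", path)
  }
  if (any(lengths(fields) != ncol1)) {
    stop("ragged junction file: ", path)
  }
  m <- do.call(rbind, fields)
  chrom <- m[, 1]
  st <- as.integer(m[, 2])
  en <- as.integer(m[, 3])
  score <- suppressWarnings(as.numeric(m[, 5]))
  strand <- m[, 6]
  if (ncol1 == 12L) {
    nblock <- as.integer(m[, 10])
    ok <- nblock == 2L
    if (any(!ok)) {
      warning(sum(!ok), " BED12 record(s) without exactly 2 blocks rejected")
    }
    sizes <- strsplit(m[, 11], ",", fixed = TRUE)
    starts <- strsplit(m[, 12], ",", fixed = TRUE)
    istart <- st + vapply(sizes, function(x) as.integer(x[[1]]), 1L)
    iend <- st + vapply(starts, function(x) as.integer(x[[2]]), 1L)
    chrom <- chrom[ok]; istart <- istart[ok]; iend <- iend[ok]
    score <- score[ok]; strand <- strand[ok]
    st <- istart; en <- iend
  }
  jx <- data.frame(chrom = chrom, start = st, end = en, strand = strand,
                   stringsAsFactors = FALSE)
  if (any(jx$end - jx$start < 4L)) {
    stop("junction with intron shorter than 4 bp in ", path)
  }
  if (!is.null(support_path)) {
    sup <- read.table(support_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE)
    tiss <- setdiff(names(sup), "junction")
    idx <- match(jx_id(jx), sup$junction)
    if (anyNA(idx)) stop("junction missing from support matrix: ",
                         jx_id(jx)[which(is.na(idx))[1]])
    for (t in tiss) jx[[paste0("support_", t)]] <- sup[[t]][idx]
  } else {
    tname <- if (is.null(tissue)) "total" else tissue
    jx[[paste0("support_", tname)]] <- ifelse(is.na(score), 0, score)
  }
  aggregate_junctions(jx)
}

# sum support of duplicate (chrom,start,end) records; keep first strand
aggregate_junctions <- function(jx) {
  key <- jx_id(jx)
  if (!anyDuplicated(key)) {
    rownames(jx) <- NULL
    return(jx[order(jx$chrom, jx$start, jx$end), , drop = FALSE])
  }
  cols <- grep("^support_", names(jx), value = TRUE)
  first <- jx[!duplicated(key), , drop = FALSE]
  fkey <- jx_id(first)
  for (cl in cols) {
    first[[cl]] <- as.numeric(tapply(jx[[cl]], key, sum)[fkey])
  }
  first <- first[order(first$chrom, first$start, first$end), , drop = FALSE]
  rownames(first) <- NULL
  first
}

#' Write junctions as BED6 plus a per-tissue support sidecar TSV
#'
#' @param junctions junction data.frame with `support_<tissue>` columns.
#' @param path BED output path.
#' @param support_path sidecar TSV path (default: `path` + ".support.tsv").
#' @return `path`, invisibly.
#' @export
write_junctions <- function(junctions, path,
                            support_path = paste0(path, ".support.tsv")) {
  jx <- junctions[order(junctions$chrom, junctions$start, junctions$end), ,
                  drop = FALSE]
  sup <- junction_support(jx)
  bed <- data.frame(jx$chrom, jx$start, jx$end, jx_id(jx),
                    as.integer(rowSums(sup)), jx$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  supdf <- data.frame(junction = jx_id(jx), sup, check.names = FALSE,
                      stringsAsFactors = FALSE)
  write.table(supdf, support_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# -- expression tables --------------------------------------------------------

#' Read a per-tissue expression table
#'
#' Long-format TSV with columns `gene_id`, `tissue`, `fpkm`, `ci_lo`,
#' `ci_hi` (FPKM point estimate and 95% confidence bounds). Missing values
#' are an error: expression calls never impute.
#'
#' @param path TSV path.
#' @return data.frame in the same long format.
#' @export
read_expression <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("gene_id", "tissue", "fpkm", "ci_lo", "ci_hi")
  if (!all(need %in% names(df))) {
    stop("expression table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyNA(df[need])) stop("missing values in expression table ", path)
  if (any(df$ci_lo > df$fpkm + 1e-9) || any(df$fpkm > df$ci_hi + 1e-9)) {
    stop("expression table violates ci_lo <= fpkm <= ci_hi: ", path)
  }
  df
}

#' Write a per-tissue expression table
#' @param expr long-format expression data.frame.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' FPKM values as a gene x tissue matrix
#' @param expr long-format expression data.frame.
#' @param value which column to spread (`"fpkm"`, `"ci_lo"` or `"ci_hi"`).
#' @return numeric matrix with genes as rows, tissues as columns (sorted).
#' @export
fpkm_matrix <- function(expr, value = "fpkm") {
  genes <- sort(unique(expr$gene_id))
  tissues <- sort(unique(expr$tissue))
  m <- matrix(NA_real_, length(genes), length(tissues),
              dimnames = list(genes, tissues))
  m[cbind(match(expr$gene_id, genes), match(expr$tissue, tissues))] <-
    expr[[value]]
  if (anyNA(m)) stop("expression table is not a complete gene x tissue grid")
  m
}
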