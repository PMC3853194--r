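# Synthetic transcriptome generator. Emits a toy genome, CDS-only gene
# models, per-tissue assembled transcripts, splice junctions with
# per-tissue read support, an FPKM table with 95% CI bounds, and a truth
# table recording every planted feature, so that each pipeline stage can
# be scored for exact recovery.

#' Simulation configuration
#'
#' Defaults describe the study conditions the package emulates: six
#' tissues (callus/root/stem/leaf/flower/silique), CDS-only gene models,
#' four planted alternative-splicing event types, novel transcribed
#' regions in intergenic space, and expression profiles spanning
#' housekeeping, graded, single-tissue-specific and silent genes.
#'
#' @param n_genes number of gene models.
#' @param tissues tissue names (length >= 2).
#' @param exons_per_gene integer range (min, max) of CDS exons per gene.
#' @param intron_length bp range for annotated introns (min >= 4 so the
#'   border dinucleotides fit).
#' @param cds_exon_length bp range for CDS exons (multiples of 3 drawn).
#' @param utr5_length,utr3_length bp ranges for planted UTR extensions.
#' @param as_events named integer vector of planted event counts, names
#'   in `IR`, `ES`, `A5SS`, `A3SS`.
#' @param n_ntr number of planted novel transcribed regions.
#' @param n_uorf number of genes given one planted upstream ORF.
#' @param class_props named proportions for expression classes
#'   `housekeeping`, `tissue_specific`, `graded`, `silent` (sum to 1).
#' @param noise_rate junction noise rate: fraction of spurious junctions
#'   added and per-cell probability that a planted support count drops
#'   below the detection threshold.
#' @param seed RNG seed; identical config (including seed) gives
#'   byte-identical outputs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 200L,
                       tissues = c("callus", "root", "stem", "leaf",
                                   "flower", "silique"),
                       exons_per_gene = c(2L, 8L),
                       intron_length = c(60L, 300L),
                       cds_exon_length = c(90L, 300L),
                       utr5_length = c(60L, 400L),
                       utr3_length = c(60L, 400L),
                       as_events = c(IR = 40L, ES = 20L,
                                     A5SS = 20L, A3SS = 20L),
                       n_ntr = 50L,
                       n_uorf = 100L,
                       class_props = c(housekeeping = 0.15,
                                       tissue_specific = 0.15,
                                       graded = 0.60, silent = 0.10),
                       noise_rate = 0,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), tissues = as.character(tissues),
              exons_per_gene = as.integer(exons_per_gene),
              intron_length = as.integer(intron_length),
              cds_exon_length = as.integer(cds_exon_length),
              utr5_length = as.integer(utr5_length),
              utr3_length = as.integer(utr3_length),
              as_events = as_events, n_ntr = as.integer(n_ntr),
              n_uorf = as.integer(n_uorf), class_props = class_props,
              noise_rate = noise_rate, seed = as.integer(seed))
  if (cfg$n_genes < 1L) stop("n_genes must be positive")
  if (length(cfg$tissues) < 2L) {
    stop("at least 2 tissues required (tau is undefined otherwise)")
  }
  if (cfg$intron_length[[1]] < 4L) {
    stop("intron range shorter than 4 bp cannot hold border dinucleotides")
  }
  if (any(cfg$as_events < 0L) || cfg$n_ntr < 0L || cfg$n_uorf < 0L) {
    stop("feature counts must be non-negative")
  }
  if (!all(names(cfg$as_events) %in% c("IR", "ES", "A5SS", "A3SS"))) {
    stop("as_events names must be IR, ES, A5SS, A3SS")
  }
  if (abs(sum(cfg$class_props) - 1) > 1e-8) {
    stop("class_props must sum to 1")
  }
  if (cfg$noise_rate < 0 || cfg$noise_rate > 1) stop("noise_rate in [0,1]")
  class(cfg) <- "sim_config"
  cfg
}

#' Read a simulation configuration from YAML
#' @param path YAML file whose keys are `sim_config()` arguments.
#' @return a `sim_config` list.
#' @export
read_sim_config <- function(path) {
  args <- yaml::read_yaml(path)
  if (!is.null(args$as_events)) args$as_events <- unlist(args$as_events)
  if (!is.null(args$class_props)) args$class_props <- unlist(args$class_props)
  do.call(sim_config, args)
}

rand_dna <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

# remove every occurrence of `pat` (character triple) in seq_vec[lo:hi]
# (1-based, inclusive) by flipping its middle base to `repl`, except
# occurrences starting at positions listed in `keep`.
scrub_triplet <- function(seq_vec, lo, hi, pat, repl, keep = integer()) {
  if (hi - lo < 2L) return(seq_vec)
  i <- lo
  while (i <= hi - 2L) {
    if (seq_vec[i] == pat[1] && seq_vec[i + 1L] == pat[2] &&
        seq_vec[i + 2L] == pat[3] && !(i %in% keep)) {
      seq_vec[i + 1L] <- repl
    }
    i <- i + 1L
  }
  seq_vec
}

write_codons <- function(seq_vec, at, text) {
  chars <- strsplit(text, "")[[1]]
  seq_vec[seq(at, length.out = length(chars))] <- chars
  seq_vec
}

#' Generate a toy genome and CDS-only gene models
#'
#' Gene models carry no UTR features (CDS-only annotation); introns are
#' written with canonical GT..AG borders (CT..AC genomically on the minus
#' strand); start and stop codons are written into the sequence; 5'-UTR
#' regions are kept free of spurious ATG triplets so that planted uORFs
#' are the only upstream ORFs. Intergenic slots are reserved for novel
#' transcribed regions.
#'
#' @param config a [sim_config()].
#' @return a `sim_annotation` list: `genome` (DNAStringSet),
#'   `gene_models` (CDS exon data.frame), `meta` (per-gene layout),
#'   `ntr_slots`, and the `config`.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  exr <- config$exons_per_gene
  ir <- config$intron_length
  cer <- config$cds_exon_length
  chrom <- "chr1"

  # layout: shuffle genes and NTR slots along one chromosome
  items <- c(rep("gene", ng), rep("ntr", config$n_ntr))
  items <- sample(items)
  cursor <- 200L
  meta <- vector("list", ng)
  slots <- vector("list", config$n_ntr)
  exon_rows <- vector("list", ng)
  gi <- 0L; si <- 0L
  exon_len_choices <- seq(cer[[1]] - cer[[1]] %% 3L, cer[[2]], by = 3L)
  for (it in items) {
    cursor <- cursor + sample(300:800, 1L)
    if (it == "ntr") {
      si <- si + 1L
      len <- sample(700:1000, 1L)
      slots[[si]] <- data.frame(chrom = chrom, start = cursor,
                                end = cursor + len, stringsAsFactors = FALSE)
      cursor <- cursor + len
      next
    }
    gi <- gi + 1L
    gid <- sprintf("gene%04d", gi)
    strand <- sample(c("+", "-"), 1L)
    n_ex <- sample(exr[[1]]:exr[[2]], 1L)
    ex_len <- sample(exon_len_choices, n_ex, replace = TRUE)
    in_len <- if (n_ex > 1L) sample(ir[[1]]:ir[[2]], n_ex - 1L,
                                    replace = TRUE) else integer()
    utr5 <- sample(config$utr5_length[[1]]:config$utr5_length[[2]], 1L)
    utr3 <- sample(config$utr3_length[[1]]:config$utr3_length[[2]], 1L)
    left_pad <- if (strand == "+") utr5 else utr3
    right_pad <- if (strand == "+") utr3 else utr5
    tx_start <- cursor
    es <- integer(n_ex); ee <- integer(n_ex)
    p <- tx_start + left_pad
    for (k in seq_len(n_ex)) {
      es[[k]] <- p; ee[[k]] <- p + ex_len[[k]]
      p <- ee[[k]] + if (k < n_ex) in_len[[k]] else 0L
    }
    tx_end <- ee[[n_ex]] + right_pad
    cursor <- tx_end
    meta[[gi]] <- data.frame(
      gene_id = gid, chrom = chrom, strand = strand,
      tx_start = tx_start, tx_end = tx_end,
      cds_start = es[[1]], cds_end = ee[[n_ex]],
      n_exons = n_ex, utr5_len = utr5, utr3_len = utr3,
      stringsAsFactors = FALSE
    )
    exon_rows[[gi]] <- data.frame(
      gene_id = gid, chrom = chrom, strand = strand,
      start = es, end = ee, stringsAsFactors = FALSE
    )
  }
  meta <- do.call(rbind, meta)
  gene_models <- do.call(rbind, exon_rows)
  ntr_slots <- if (config$n_ntr > 0L) do.call(rbind, slots) else
    data.frame(chrom = character(), start = integer(), end = integer())

  glen <- cursor + 300L
  seq_vec <- rand_dna(glen)

  # overwrite planted signals (0-based coords -> 1-based vector index)
  for (g in seq_len(ng)) {
    m <- meta[g, ]
    ex <- gene_models[gene_models$gene_id == m$gene_id, ]
    n_ex <- nrow(ex)
    # splice motifs on annotated introns
    if (n_ex > 1L) {
      for (k in seq_len(n_ex - 1L)) {
        is0 <- ex$end[[k]]; ie0 <- ex$start[[k + 1L]]
        if (m$strand == "+") {
          seq_vec <- write_codons(seq_vec, is0 + 1L, "GT")
          seq_vec <- write_codons(seq_vec, ie0 - 1L, "AG")
        } else {
          seq_vec <- write_codons(seq_vec, is0 + 1L, "CT")
          seq_vec <- write_codons(seq_vec, ie0 - 1L, "AC")
        }
      }
    }
    # start/stop codons at the mature CDS ends
    if (m$strand == "+") {
      seq_vec <- write_codons(seq_vec, m$cds_start + 1L, "ATG")
      seq_vec <- write_codons(seq_vec, m$cds_end - 2L, "TAA")
      seq_vec <- scrub_triplet(seq_vec, m$tx_start + 1L, m$cds_start,
                               c("A", "T", "G"), "C")
    } else {
      seq_vec <- write_codons(seq_vec, m$cds_end - 2L, "CAT")
      seq_vec <- write_codons(seq_vec, m$cds_start + 1L, "TTA")
      seq_vec <- scrub_triplet(seq_vec, m$cds_end + 1L, m$tx_end,
                               c("C", "A", "T"), "G")
    }
  }

  genome <- Biostrings::DNAStringSet(
    stats::setNames(paste(seq_vec, collapse = ""), chrom))
  structure(list(genome = genome, gene_models = gene_models, meta = meta,
                 ntr_slots = ntr_slots, config = config),
            class = "sim_annotation")
}

sample_subset <- function(x, k) {
  if (length(x) == 1L) x else sample(x, k)
}

#' Plant transcripts, junctions, uORFs, NTRs and AS events
#'
#' Assigns every gene an expression class, plants the requested
#' alternative-splicing events (with the junction/transcript evidence the
#' detector requires), places novel transcribed regions in reserved
#' intergenic slots, writes uORFs into 5'-UTR sequence, and assigns flat
#' functional categories (one of which is enriched among AS genes). The
#' genome returned carries the planted sequence edits.
#'
#' @param annotation result of [generate_annotation()].
#' @param config the same [sim_config()].
#' @return list: `genome`, `transcripts` (per-tissue exon data.frame),
#'   `junctions` (with `support_<tissue>` columns), `categories`
#'   (gene_id/category), and `truth` (the truth table).
#' @export
plant_features <- function(annotation, config) {
  stopifnot(inherits(annotation, "sim_annotation"))
  set.seed(config$seed + 1L)
  meta <- annotation$meta
  gm <- annotation$gene_models
  tissues <- config$tissues
  nt <- length(tissues)
  seq_vec <- strsplit(as.character(annotation$genome[[1]]), "")[[1]]
  chrom <- names(annotation$genome)[[1]]

  # -- expression classes (exact partition of the gene set) -------------------
  ng <- config$n_genes
  counts <- floor(config$class_props * ng)
  rem <- ng - sum(counts)
  if (rem > 0L) counts[order(config$class_props * ng - counts,
                             decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(config$class_props * ng - counts,
                   decreasing = TRUE)[seq_len(rem)]] + 1L
  classes <- sample(rep(names(counts), counts))
  class_df <- data.frame(gene_id = meta$gene_id, class = classes,
                         tissue = NA_character_, stringsAsFactors = FALSE)
  is_ts <- class_df$class == "tissue_specific"
  class_df$tissue[is_ts] <- sample(tissues, sum(is_ts), replace = TRUE)
  expressed_in <- function(gid) {
    cl <- class_df[class_df$gene_id == gid, ]
    switch(cl$class,
           housekeeping = tissues, graded = tissues,
           tissue_specific = cl$tissue, silent = character())
  }

  # -- AS event genes ---------------------------------------------------------
  nonsilent <- meta$gene_id[classes != "silent"]
  pool <- nonsilent
  pick_gene <- function(type) {
    need_ex <- if (type == "ES") 3L else 2L
    ok <- pool[meta$n_exons[match(pool, meta$gene_id)] >= need_ex]
    if (length(ok) == 0L) {
      stop("cannot plant ", type, " event: no eligible gene with ",
           if (type == "ES") "an internal exon" else "an intron",
           " remains")
    }
    g <- sample_subset(ok, 1L)
    pool <<- setdiff(pool, g)
    g
  }
  ev <- list()
  jx_extra <- list()
  tx_extra <- list()
  req <- config$as_events
  for (type in names(req)) {
    for (r in seq_len(req[[type]])) {
      gid <- pick_gene(type)
      m <- meta[meta$gene_id == gid, ]
      ex <- gm[gm$gene_id == gid, ]
      n_ex <- nrow(ex)
      introns <- data.frame(start = ex$end[-n_ex], end = ex$start[-1])
      expr_t <- expressed_in(gid)
      tset <- sample_subset(expr_t, sample(seq_along(expr_t), 1L))
      if (type == "IR") {
        # retain the shortest intron: an exon-spanning transcript plus the
        # spliced junction (both isoforms present)
        k <- which.min(introns$end - introns$start)
        es <- ex$start; ee <- ex$end
        res <- es[-(k + 1L)]; ree <- ee[-k]
        # UTR-style terminal extensions so the transcript looks assembled
        res[[1]] <- m$tx_start; ree[[length(ree)]] <- m$tx_end
        tx_extra[[length(tx_extra) + 1L]] <- data.frame(
          base_id = paste0(gid, ".ir"), chrom = chrom, strand = m$strand,
          start = res, end = ree,
          tissues = paste(tset, collapse = ","), stringsAsFactors = FALSE)
        ev[[length(ev) + 1L]] <- data.frame(
          gene_id = gid, event_type = "IR", chrom = chrom,
          strand = m$strand, start = introns$start[[k]],
          end = introns$end[[k]], ref_start = NA_integer_,
          ref_end = NA_integer_, tissues = paste(sort(tset), collapse = ","),
          stringsAsFactors = FALSE)
      } else if (type == "ES") {
        i <- sample_subset(2:(n_ex - 1L), 1L)
        js <- introns$start[[i - 1L]]; je <- introns$end[[i]]
        jx_extra[[length(jx_extra) + 1L]] <-
          list(start = js, end = je, tissues = tset)
        ev[[length(ev) + 1L]] <- data.frame(
          gene_id = gid, event_type = "ES", chrom = chrom,
          strand = m$strand, start = ex$start[[i]], end = ex$end[[i]],
          ref_start = js, ref_end = je,
          tissues = paste(sort(tset), collapse = ","), stringsAsFactors = FALSE)
      } else {
        k <- sample_subset(seq_len(n_ex - 1L), 1L)
        a <- introns[k, ]
        delta <- sample(4:12, 1L)
        # donor = 5' splice site on the coding strand; the alternative site
        # lies inside the annotated intron and receives the boundary motif
        shift_start <- (type == "A5SS") == (m$strand == "+")
        if (shift_start) {
          js <- a$start + delta; je <- a$end
          motif <- if (m$strand == "+") "GT" else "CT"
          seq_vec <- write_codons(seq_vec, js + 1L, motif)
        } else {
          js <- a$start; je <- a$end - delta
          motif <- if (m$strand == "+") "AG" else "AC"
          seq_vec <- write_codons(seq_vec, je - 1L, motif)
        }
        jx_extra[[length(jx_extra) + 1L]] <-
          list(start = js, end = je, tissues = tset)
        ev[[length(ev) + 1L]] <- data.frame(
          gene_id = gid, event_type = type, chrom = chrom,
          strand = m$strand, start = js, end = je,
          ref_start = a$start, ref_end = a$end,
          tissues = paste(sort(tset), collapse = ","), stringsAsFactors = FALSE)
      }
    }
  }
  as_truth <- if (length(ev)) do.call(rbind, ev) else
    data.frame(gene_id = character(), event_type = character(),
               chrom = character(), strand = character(), start = integer(),
               end = integer(), ref_start = integer(), ref_end = integer(),
               tissues = character(), stringsAsFactors = FALSE)

  # -- uORFs ------------------------------------------------------------------
  body_codons <- c("CCT", "CTC", "TCC", "CCA", "CAC")
  u_ok <- nonsilent[meta$utr5_len[match(nonsilent, meta$gene_id)] >= 70L]
  if (config$n_uorf > length(u_ok)) {
    stop("not enough genes with long 5' UTRs to plant ", config$n_uorf,
         " uORFs")
  }
  u_genes <- if (config$n_uorf > 0L) sample(u_ok, config$n_uorf) else
    character()
  uorf_rows <- vector("list", length(u_genes))
  for (i in seq_along(u_genes)) {
    gid <- u_genes[[i]]
    m <- meta[meta$gene_id == gid, ]
    L <- sample(seq(12L, 48L, 3L), 1L)
    o <- sample(0:(m$utr5_len - L), 1L)
    body <- paste(sample(body_codons, L / 3L - 2L, replace = TRUE),
                  collapse = "")
    orf <- paste0("ATG", body, "TAA")
    if (m$strand == "+") {
      gpos <- m$tx_start + o                 # 0-based genomic start
      seq_vec <- write_codons(seq_vec, gpos + 1L, orf)
      seq_vec <- scrub_triplet(seq_vec, m$tx_start + 1L, m$cds_start,
                               c("A", "T", "G"), "C", keep = gpos + 1L)
    } else {
      gpos <- m$tx_end - o - L
      seq_vec <- write_codons(seq_vec, gpos + 1L, revcomp(orf))
      keep_at <- m$tx_end - o - 3L + 1L      # genomic "CAT" of the mature ATG
      seq_vec <- scrub_triplet(seq_vec, m$cds_end + 1L, m$tx_end,
                               c("C", "A", "T"), "G", keep = keep_at)
    }
    uorf_rows[[i]] <- data.frame(gene_id = gid, offset = o, length_nt = L,
                                 stringsAsFactors = FALSE)
  }
  uorf_truth <- if (length(uorf_rows)) do.call(rbind, uorf_rows) else
    data.frame(gene_id = character(), offset = integer(),
               length_nt = integer(), stringsAsFactors = FALSE)

  # -- NTRs in reserved intergenic slots --------------------------------------
  ntr_rows <- vector("list", config$n_ntr)
  for (i in seq_len(config$n_ntr)) {
    slot <- annotation$ntr_slots[i, ]
    len <- (slot$end - slot$start) - 200L
    s0 <- slot$start + 100L
    strand <- sample(c("+", "-"), 1L)
    orf_aa <- NA_integer_
    if (i %% 2L == 1L) {  # half the NTRs carry a long ORF (coding)
      k <- sample(110:150, 1L)
      sense <- setdiff(names(Biostrings::GENETIC_CODE)[
        Biostrings::GENETIC_CODE != "*"], character())
      orf <- paste0("ATG", paste(sample(sense, k - 1L, replace = TRUE),
                                 collapse = ""), "TAA")
      off <- sample(0:(len - nchar(orf)), 1L)
      text <- if (strand == "+") orf else revcomp(orf)
      seq_vec <- write_codons(seq_vec, s0 + off + 1L, text)
      orf_aa <- k
    }
    n_tis <- sample(1:2, 1L, prob = c(0.7, 0.3))
    tset <- sample_subset(tissues, n_tis)
    ntr_rows[[i]] <- data.frame(
      ntr_id = sprintf("NTR%04d", i), chrom = slot$chrom, start = s0,
      end = s0 + len, strand = strand, orf_aa = orf_aa,
      tissues = paste(sort(tset), collapse = ","), stringsAsFactors = FALSE)
  }
  ntr_truth <- if (config$n_ntr > 0L) do.call(rbind, ntr_rows) else
    data.frame(ntr_id = character(), chrom = character(), start = integer(),
               end = integer(), strand = character(), orf_aa = integer(),
               tissues = character(), stringsAsFactors = FALSE)

  # -- transcripts (per-tissue records, as an assembler would emit) -----------
  tx_models <- list()
  for (g in seq_len(ng)) {
    gid <- meta$gene_id[[g]]
    expr_t <- expressed_in(gid)
    if (length(expr_t) == 0L) next   # silent genes assemble no transcript
    m <- meta[g, ]
    ex <- gm[gm$gene_id == gid, ]
    es <- ex$start; ee <- ex$end
    es[[1]] <- m$tx_start; ee[[length(ee)]] <- m$tx_end
    tx_models[[length(tx_models) + 1L]] <- data.frame(
      base_id = paste0(gid, ".t1"), chrom = chrom, strand = m$strand,
      start = es, end = ee, tissues = paste(expr_t, collapse = ","),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(ntr_truth))) {
    n <- ntr_truth[i, ]
    tx_models[[length(tx_models) + 1L]] <- data.frame(
      base_id = n$ntr_id, chrom = n$chrom, strand = n$strand,
      start = n$start, end = n$end, tissues = n$tissues,
      stringsAsFactors = FALSE)
  }
  tx_models <- c(tx_models, tx_extra)
  tx_rows <- lapply(tx_models, function(t) {
    do.call(rbind, lapply(strsplit(t$tissues[[1]], ",")[[1]], function(ti) {
      data.frame(transcript_id = paste0(t$base_id[[1]], "@", ti),
                 chrom = t$chrom, strand = t$strand, start = t$start,
                 end = t$end, tissues = ti, stringsAsFactors = FALSE)
    }))
  })
  transcripts <- do.call(rbind, tx_rows)
  transcripts <- transcripts[order(transcripts$transcript_id,
                                   transcripts$start), ]
  rownames(transcripts) <- NULL

  # -- junctions --------------------------------------------------------------
  sup0 <- function() stats::setNames(rep(0, nt), tissues)
  jrows <- list()
  for (g in seq_len(ng)) {
    gid <- meta$gene_id[[g]]
    ex <- gm[gm$gene_id == gid, ]
    if (nrow(ex) < 2L) next
    expr_t <- expressed_in(gid)
    for (k in seq_len(nrow(ex) - 1L)) {
      s <- sup0()
      if (length(expr_t)) {
        s[expr_t] <- 3L + rpois(length(expr_t), 12)
      } else {
        s[] <- sample(0:2, nt, replace = TRUE)  # silent: below threshold
      }
      jrows[[length(jrows) + 1L]] <-
        c(list(chrom = chrom, start = ex$end[[k]], end = ex$start[[k + 1L]],
               strand = "."), as.list(s))
    }
  }
  for (j in jx_extra) {
    s <- sup0()
    s[j$tissues] <- 3L + rpois(length(j$tissues), 12)
    jrows[[length(jrows) + 1L]] <-
      c(list(chrom = chrom, start = j$start, end = j$end, strand = "."),
        as.list(s))
  }
  junctions <- do.call(rbind, lapply(jrows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  names(junctions) <- c("chrom", "start", "end", "strand",
                        paste0("support_", tissues))
  junctions <- aggregate_junctions(junctions)

  # -- junction noise ---------------------------------------------------------
  if (config$noise_rate > 0) {
    sup_cols <- paste0("support_", tissues)
    # per-cell dropout below the detection threshold
    m <- as.matrix(junctions[, sup_cols])
    drop <- matrix(runif(length(m)) < config$noise_rate, nrow(m))
    m[drop & m > 0] <- sample(0:2, sum(drop & m > 0), replace = TRUE)
    junctions[, sup_cols] <- m
    # spurious junctions at random positions inside gene spans
    n_sp <- ceiling(config$noise_rate * nrow(junctions))
    glen <- length(seq_vec)
    sp <- lapply(seq_len(n_sp), function(i) {
      g <- sample(ng, 1L)
      mrow <- meta[g, ]
      len <- sample(config$intron_length[[1]]:config$intron_length[[2]], 1L)
      lo <- mrow$tx_start
      hi <- max(lo + 1L, mrow$tx_end - len)
      st <- sample(lo:hi, 1L)
      s <- sup0()
      s[sample(tissues, sample(1:2, 1L))] <- 3L + rpois(1L, 5)
      c(list(chrom = chrom, start = st, end = min(st + len, glen - 4L),
             strand = "."), as.list(s))
    })
    sp <- do.call(rbind, lapply(sp, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    names(sp) <- names(junctions)
    junctions <- aggregate_junctions(rbind(junctions, sp))
  }

  # -- flat functional categories (one planted AS-enriched) -------------------
  cats <- sprintf("CAT%02d", 1:12)
  as_genes <- unique(as_truth$gene_id)
  cat_rows <- lapply(meta$gene_id, function(gid) {
    p1 <- if (gid %in% as_genes) 0.6 else 0.08
    assigned <- character()
    if (runif(1) < p1) assigned <- cats[[1]]
    assigned <- unique(c(assigned,
                         sample(cats[-1], sample(1:2, 1L))))
    data.frame(gene_id = gid, category = assigned, stringsAsFactors = FALSE)
  })
  categories <- do.call(rbind, cat_rows)

  utr_truth <- meta[meta$gene_id %in% nonsilent,
                    c("gene_id", "utr5_len", "utr3_len")]
  rownames(utr_truth) <- NULL

  genome <- Biostrings::DNAStringSet(
    stats::setNames(paste(seq_vec, collapse = ""), chrom))
  truth <- list(
    ntr = ntr_truth,
    as_events = as_truth,
    utr = utr_truth,
    uorfs = uorf_truth,
    expression_class = class_df,
    enriched_category = cats[[1]],
    tissues = tissues
  )
  list(genome = genome, transcripts = transcripts, junctions = junctions,
       categories = categories, truth = truth)
}

#' Simulate the per-tissue expression table
#'
#' Housekeeping genes draw FPKM > 50 in every tissue; tissue-specific
#' genes are nonzero in exactly one tissue; graded genes are moderately
#' and variably expressed in all tissues; silent genes have a 95% CI
#' lower bound of 0 everywhere. The lower bound is
#' `max(0, fpkm * (1 - 1.96 / sqrt(c + 1)))` with `c` a simulated
#' fragment count, so "expressed" (lower bound > 0) tracks the fragment
#' count the way a count-driven interval would.
#'
#' @param annotation result of [generate_annotation()].
#' @param truth truth table from [plant_features()].
#' @param config the same [sim_config()].
#' @return long-format expression data.frame (`gene_id`, `tissue`,
#'   `fpkm`, `ci_lo`, `ci_hi`) covering gene models and NTR transcripts.
#' @export
simulate_expression <- function(annotation, truth, config) {
  set.seed(config$seed + 2L)
  tissues <- config$tissues
  if (length(tissues) < 2L) stop("n_tissues < 2: tau undefined downstream")
  rows <- list()
  ci <- function(fpkm, cnt) {
    h <- 1.96 / sqrt(cnt + 1)
    c(lo = max(0, fpkm * (1 - h)), hi = fpkm * (1 + h))
  }
  emit <- function(id, tissue, fpkm, cnt) {
    b <- ci(fpkm, cnt)
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = id, tissue = tissue, fpkm = round(fpkm, 3),
      ci_lo = round(b[["lo"]], 3), ci_hi = round(b[["hi"]], 3),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(truth$expression_class))) {
    cl <- truth$expression_class[i, ]
    for (t in tissues) {
      if (cl$class == "housekeeping") {
        emit(cl$gene_id, t, runif(1, 55, 400), 50L + rpois(1L, 100))
      } else if (cl$class == "graded") {
        emit(cl$gene_id, t, runif(1, 5, 30), 20L + rpois(1L, 30))
      } else if (cl$class == "tissue_specific") {
        if (t == cl$tissue) {
          emit(cl$gene_id, t, runif(1, 10, 200), 20L + rpois(1L, 50))
        } else {
          emit(cl$gene_id, t, 0, 0L)
        }
      } else {
        emit(cl$gene_id, t, runif(1, 0, 0.4), sample(0:2, 1L))
      }
    }
  }
  for (i in seq_len(nrow(truth$ntr))) {
    n <- truth$ntr[i, ]
    in_t <- strsplit(n$tissues, ",")[[1]]
    for (t in tissues) {
      if (t %in% in_t) {
        emit(n$ntr_id, t, runif(1, 0.5, 5), 10L + rpois(1L, 10))
      } else {
        emit(n$ntr_id, t, 0, 0L)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a full synthetic dataset on disk
#'
#' Runs [generate_annotation()], [plant_features()] and
#' [simulate_expression()] and writes: `genome.fa`, `genes.gff3`,
#' `transcripts.gtf`, `junctions.bed` (+ `.support.tsv`),
#' `expression.tsv`, `gene2cat.tsv` and `truth.json`.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the in-memory objects and file paths.
#' @export
simulate_transcriptome <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ann <- generate_annotation(config)
  pf <- plant_features(ann, config)
  expr <- simulate_expression(ann, pf$truth, config)
  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    gene_models = file.path(outdir, "genes.gff3"),
    transcripts = file.path(outdir, "transcripts.gtf"),
    junctions = file.path(outdir, "junctions.bed"),
    expression = file.path(outdir, "expression.tsv"),
    categories = file.path(outdir, "gene2cat.tsv"),
    truth = file.path(outdir, "truth.json")
  )
  write_genome(pf$genome, paths$genome)
  write_gene_models(ann$gene_models, paths$gene_models)
  write_transcripts(pf$transcripts, paths$transcripts)
  write_junctions(pf$junctions, paths$junctions)
  write_expression(expr, paths$expression)
  write.table(pf$categories, paths$categories, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(pf$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(list(annotation = ann, genome = pf$genome,
                 transcripts = pf$transcripts, junctions = pf$junctions,
                 categories = pf$categories, expression = expr,
                 truth = pf$truth, paths = paths))
}

#' Read a truth table written by [simulate_transcriptome()]
#' @param path truth.json path.
#' @return the truth list with data.frame components.
#' @export
read_truth <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
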