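# End-to-end orchestration and the study-style summary report: every
# derived percentage is recorded together with its integer
# numerator/denominator pair so the report arithmetic is reproducible.

#' Format a ratio the way the study prints one
#'
#' The percentage is rounded half-up to one decimal; the integer pair is
#' echoed so the number can be re-derived.
#'
#' @param numerator,denominator non-negative integers; a zero
#'   denominator is an error.
#' @return list: `numerator`, `denominator`, `percent`, `label` (e.g.
#'   `"29.4% (7668/26063)"`).
#' @export
summary_ratios <- function(numerator, denominator) {
  if (denominator == 0) stop("zero denominator")
  pct <- floor(numerator / denominator * 1000 + 0.5) / 10
  list(numerator = numerator, denominator = denominator, percent = pct,
       label = sprintf("%.1f%% (%d/%d)", pct, numerator, denominator))
}

#' Run the full characterization pipeline
#'
#' Either simulates a dataset from `config` or loads the files named in
#' `inputs` (a list with `genome`, `gene_models`, `transcripts`,
#' `junctions`, `junction_support`, `expression`, and optionally
#' `categories`), then runs every stage in dependency order: transcript
#' merging, overlap labeling, NTR coding potential, UTR and uORF
#' annotation, expression atlas, junction filtering/motifs/known-novel
#' classification, AS event detection, and AS-gene category enrichment.
#'
#' @param config a [sim_config()] (ignored when `inputs` is given).
#' @param inputs optional named list of input file paths.
#' @param outdir optional directory for stage TSVs and the JSON report.
#' @param min_support per-tissue junction support threshold.
#' @param breadth_k tissue-sharing threshold for breadth summaries.
#' @return an `atlas_report` list with all stage tables (`tables`) and
#'   the summary counts (`report`).
#' @export
run_pipeline <- function(config = sim_config(), inputs = NULL,
                         outdir = NULL, min_support = 3, breadth_k = 2) {
  if (is.null(inputs)) {
    sim <- simulate_transcriptome_memory(config)
    genome <- sim$genome; gene_models <- sim$gene_models
    transcripts <- sim$transcripts; junctions <- sim$junctions
    expr <- sim$expression; categories <- sim$categories
    truth <- sim$truth
  } else {
    need <- c("genome", "gene_models", "transcripts", "junctions",
              "expression")
    miss <- setdiff(need, names(inputs))
    if (length(miss)) {
      stop("missing inputs: ", paste(miss, collapse = ", "))
    }
    for (f in unlist(inputs)) {
      if (!file.exists(f)) stop("input file not found: ", f)
    }
    genome <- read_genome(inputs$genome)
    gene_models <- read_gene_models(inputs$gene_models)
    transcripts <- read_transcripts(inputs$transcripts)
    junctions <- read_junctions(inputs$junctions,
                                support_path = inputs$junction_support)
    expr <- read_expression(inputs$expression)
    categories <- if (!is.null(inputs$categories)) {
      read.table(inputs$categories, header = TRUE, sep = "\t",
                 stringsAsFactors = FALSE)
    } else NULL
    truth <- NULL
  }

  merged <- merge_transcripts(transcripts)
  labels <- classify_transcripts(merged, gene_models)
  ntr <- ntr_coding_potential(merged, labels, genome)
  utrs <- annotate_utrs(merged, labels, gene_models)
  uorfs <- annotate_uorfs(utrs, merged, genome)

  gene_ids <- unique(gene_models$gene_id)
  expr_genes <- expr[expr$gene_id %in% gene_ids, , drop = FALSE]
  expressed <- call_expressed(expr_genes)
  taus <- tau_table(expr_genes)
  hk <- find_housekeeping(expr_genes)
  ts <- find_tissue_specific(expr_genes)
  const_ids <- expressed$gene_id[expressed$constitutive]
  dendro <- if (length(const_ids) >= 2L &&
                length(unique(expr_genes$tissue)) >= 3L) {
    cluster_tissues(expr_genes, const_ids)$newick
  } else NA_character_

  if (nrow(junctions) > 0L) {
    filtered <- filter_junctions(junctions, min_support)
    filtered <- junction_motif(filtered, genome)
    filtered <- classify_junctions(filtered, gene_models)
    asr <- detect_as_events(filtered, merged, gene_models)
  } else {
    filtered <- junctions
    asr <- list(events = data.frame(gene_id = character(),
                                    event_type = character(),
                                    chrom = character(),
                                    strand = character(),
                                    start = integer(), end = integer(),
                                    ref_start = integer(),
                                    ref_end = integer(),
                                    tissues = character(),
                                    breadth = integer(),
                                    stringsAsFactors = FALSE),
                orphans = junctions)
  }
  events <- asr$events

  enr <- if (!is.null(categories) && nrow(events) > 0L) {
    enrich_categories(unique(events$gene_id), gene_ids, categories)
  } else NULL

  # -- summary counts ---------------------------------------------------------
  types <- c("IR", "A3SS", "A5SS", "ES")
  per_type <- lapply(types, function(ty) {
    e <- events[events$event_type == ty, , drop = FALSE]
    list(events = nrow(e), genes = length(unique(e$gene_id)),
         shared_ge_k = sum(e$breadth >= breadth_k),
         shared_gt_k = sum(e$breadth > breadth_k))
  })
  names(per_type) <- types
  total_events <- sum(vapply(per_type, function(x) x$events, 1))
  as_genes <- unique(events$gene_id)
  multi_as <- if (length(as_genes)) sum(table(events$gene_id) > 1) else 0L

  n_expressed <- sum(expressed$expressed_any)
  excount <- table(gene_models$gene_id)
  intron_genes <- names(excount)[excount >= 2]
  expressed_intron_genes <- intersect(
    expressed$gene_id[expressed$expressed_any], intron_genes)

  report <- list(
    transcripts = list(
      merged = nrow(unique(merged["transcript_id"])),
      complete = sum(labels$label == "complete"),
      partial = sum(labels$label == "partial"),
      novel = sum(labels$label == "novel"),
      novel_coding = sum(ntr$coding_flag),
      pct_novel_coding = if (nrow(ntr)) {
        summary_ratios(sum(ntr$coding_flag), nrow(ntr))
      } else NULL
    ),
    utr = list(
      genes_with_utr5 = sum(utrs$utr5_len > 0),
      genes_with_utr3 = sum(utrs$utr3_len > 0),
      median_utr5 = if (nrow(utrs)) stats::median(utrs$utr5_len) else NA,
      median_utr3 = if (nrow(utrs)) stats::median(utrs$utr3_len) else NA,
      genes_with_uorf = length(unique(uorfs$gene_id))
    ),
    expression = list(
      annotated_genes = length(gene_ids),
      expressed = n_expressed,
      pct_expressed = summary_ratios(n_expressed, length(gene_ids)),
      constitutive = length(const_ids),
      housekeeping = length(hk),
      tissue_specific = nrow(ts),
      dendrogram = dendro
    ),
    junctions = list(
      retained = nrow(filtered),
      known = sum(filtered$known %in% TRUE),
      novel = sum(filtered$known %in% FALSE),
      pct_gtag = if (nrow(filtered)) {
        summary_ratios(sum(filtered$motif == "GT-AG"), nrow(filtered))
      } else NULL,
      orphans = nrow(asr$orphans)
    ),
    as_events = list(
      per_type = per_type,
      total = total_events,
      genes = length(as_genes),
      genes_multiple = multi_as,
      pct_as_of_intron_genes = if (length(expressed_intron_genes)) {
        summary_ratios(length(intersect(as_genes, expressed_intron_genes)),
                       length(expressed_intron_genes))
      } else NULL
    )
  )

  tables <- list(merged = merged, labels = labels, ntr = ntr, utrs = utrs,
                 uorfs = uorfs, expressed = expressed, tau = taus,
                 housekeeping = hk, tissue_specific = ts,
                 junctions = filtered, events = events,
                 orphans = asr$orphans, enrichment = enr)
  out <- structure(list(report = report, tables = tables, truth = truth),
                   class = "atlas_report")
  if (!is.null(outdir)) write_report(out, outdir)
  out
}

# in-memory variant of simulate_transcriptome (no files)
simulate_transcriptome_memory <- function(config) {
  ann <- generate_annotation(config)
  pf <- plant_features(ann, config)
  expr <- simulate_expression(ann, pf$truth, config)
  list(genome = pf$genome, gene_models = ann$gene_models,
       transcripts = pf$transcripts, junctions = pf$junctions,
       categories = pf$categories, expression = expr, truth = pf$truth)
}

#' Write the stage tables and JSON report of a pipeline run
#' @param x an `atlas_report`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(x, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tb <- x$tables
  for (nm in c("merged", "labels", "ntr", "utrs", "uorfs", "expressed",
               "tau", "tissue_specific", "junctions", "events",
               "orphans", "enrichment")) {
    if (!is.null(tb[[nm]]) && is.data.frame(tb[[nm]])) {
      write.table(tb[[nm]], file.path(outdir, paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  writeLines(tb$housekeeping, file.path(outdir, "housekeeping.txt"))
  jsonlite::write_json(x$report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(outdir)
}

#' Table-style AS event summary
#'
#' One row per event type plus a total row: event count, genes with the
#' event, and events shared by at least / more than `k` tissues. The
#' per-type counts sum to the totals row by construction.
#'
#' @param events event table from [detect_as_events()].
#' @param k tissue-sharing threshold.
#' @return data.frame.
#' @export
as_event_table <- function(events, k = 2) {
  types <- c("IR", "A3SS", "A5SS", "ES")
  rows <- lapply(types, function(ty) {
    e <- events[events$event_type == ty, , drop = FALSE]
    data.frame(as_type = ty, events = nrow(e),
               genes = length(unique(e$gene_id)),
               shared_ge_k = sum(e$breadth >= k),
               shared_gt_k = sum(e$breadth > k), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rbind(tab, data.frame(as_type = "Total", events = sum(tab$events),
                        genes = length(unique(events$gene_id)),
                        shared_ge_k = sum(tab$shared_ge_k),
                        shared_gt_k = sum(tab$shared_gt_k),
                        stringsAsFactors = FALSE))
}
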