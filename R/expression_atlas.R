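# Expression atlas statistics: expressed/constitutive calls from the 95%
# CI lower bound, FPKM tiers, the tau tissue-specificity index,
# housekeeping and tissue-specific gene sets, and tissue clustering.

#' Expressed and constitutive calls
#'
#' A gene is expressed in a tissue when the lower boundary of the 95%
#' confidence interval of its FPKM is greater than zero (zero itself is
#' not expressed); it is constitutive when expressed in every tissue.
#'
#' @param expr long-format expression data.frame.
#' @return data.frame: `gene_id`, one logical `expressed_<tissue>` column
#'   per tissue, `n_expressed`, `expressed_any`, `constitutive`.
#' @export
call_expressed <- function(expr) {
  lo <- fpkm_matrix(expr, "ci_lo")
  flags <- lo > 0
  out <- data.frame(gene_id = rownames(flags), flags > 0,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[-1] <- paste0("expressed_", colnames(flags))
  out$n_expressed <- rowSums(flags)
  out$expressed_any <- out$n_expressed > 0
  out$constitutive <- out$n_expressed == ncol(flags)
  rownames(out) <- NULL
  out
}

#' Expression tier of an FPKM value
#'
#' `low` for FPKM <= 5, `medium` for 5 < FPKM <= 50, `high` for
#' FPKM > 50; the tiers partition the non-negative axis.
#'
#' @param fpkm numeric vector, non-negative.
#' @return character vector of tiers.
#' @export
classify_tier <- function(fpkm) {
  if (any(fpkm < 0)) stop("negative FPKM")
  ifelse(fpkm > 50, "high", ifelse(fpkm > 5, "medium", "low"))
}

#' Tissue-specificity index tau
#'
#' For a gene with FPKM `S_j` across `n` tissues,
#' `tau = sum_j (1 - S_j / S_max) / (n - 1)`: 0 for uniformly expressed
#' (housekeeping-like) genes, 1 for single-tissue expression.
#'
#' @param fpkm non-negative numeric vector of length >= 2 with a
#'   positive maximum; an all-zero vector is an error.
#' @return list: `tau`, `argmax_tissue` (name or index of the maximal
#'   tissue).
#' @export
compute_tau <- function(fpkm) {
  n <- length(fpkm)
  if (n < 2L) stop("tau needs at least 2 tissues")
  if (any(is.na(fpkm)) || any(fpkm < 0)) stop("FPKM must be non-negative")
  mx <- max(fpkm)
  if (mx <= 0) stop("tau undefined for an all-zero expression row")
  tau <- sum(1 - fpkm / mx) / (n - 1)
  am <- which.max(fpkm)
  list(tau = tau,
       argmax_tissue = if (!is.null(names(fpkm))) names(fpkm)[[am]] else am)
}

#' Tau for every gene in an expression table
#'
#' @param expr long-format expression data.frame.
#' @return data.frame: `gene_id`, `tau`, `argmax_tissue`; genes with
#'   all-zero rows are returned with `tau = NA` rather than dropped.
#' @export
tau_table <- function(expr) {
  m <- fpkm_matrix(expr, "fpkm")
  out <- do.call(rbind, lapply(rownames(m), function(g) {
    v <- m[g, ]
    if (max(v) <= 0) {
      return(data.frame(gene_id = g, tau = NA_real_,
                        argmax_tissue = NA_character_,
                        stringsAsFactors = FALSE))
    }
    t <- compute_tau(v)
    data.frame(gene_id = g, tau = t$tau, argmax_tissue = t$argmax_tissue,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Housekeeping gene set
#'
#' Genes whose FPKM is strictly greater than `threshold` in every tissue
#' (highly and stably expressed).
#'
#' @param expr long-format expression data.frame.
#' @param threshold FPKM cutoff (default 50).
#' @return character vector of gene ids.
#' @export
find_housekeeping <- function(expr, threshold = 50) {
  m <- fpkm_matrix(expr, "fpkm")
  if (nrow(m) == 0L) return(character())
  rownames(m)[apply(m > threshold, 1L, all)]
}

#' Tissue-specific gene assignments
#'
#' Genes with `tau >= tau_threshold` that are expressed (CI lower bound
#' > 0) in their maximal tissue are assigned to that tissue.
#'
#' @param expr long-format expression data.frame.
#' @param tau_threshold tau cutoff (default 0.9).
#' @return data.frame: `gene_id`, `tissue`, `tau`.
#' @export
find_tissue_specific <- function(expr, tau_threshold = 0.9) {
  tt <- tau_table(expr)
  lo <- fpkm_matrix(expr, "ci_lo")
  keep <- !is.na(tt$tau) & tt$tau >= tau_threshold
  tt <- tt[keep, , drop = FALSE]
  expressed_there <- lo[cbind(tt$gene_id, tt$argmax_tissue)] > 0
  out <- data.frame(gene_id = tt$gene_id[expressed_there],
                    tissue = tt$argmax_tissue[expressed_there],
                    tau = tt$tau[expressed_there], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# 1 - Pearson correlation between tissue columns of log2(FPKM + 1)
expr_dist <- function(logm) {
  cc <- apply(logm, 2L, function(x) stats::sd(x))
  if (any(cc == 0)) {
    stop("constant expression column for tissue '",
         colnames(logm)[which(cc == 0)[1]], "': correlation undefined")
  }
  as.dist(1 - cor(logm))
}

#' Cluster tissues on constitutively expressed genes
#'
#' Columns are log2(FPKM + 1) profiles of constitutive genes; distance is
#' 1 - Pearson correlation between tissues; linkage is average. Tissues
#' are ordered by name before clustering so tie-breaks are deterministic.
#'
#' @param expr long-format expression data.frame.
#' @param constitutive optional character vector of constitutive gene
#'   ids; computed with [call_expressed()] when missing.
#' @return list: `hclust` (the tree), `newick` (newick string).
#' @export
cluster_tissues <- function(expr, constitutive = NULL) {
  if (is.null(constitutive)) {
    ce <- call_expressed(expr)
    constitutive <- ce$gene_id[ce$constitutive]
  }
  m <- fpkm_matrix(expr, "fpkm")
  if (ncol(m) < 3L) stop("tissue clustering needs at least 3 tissues")
  if (length(constitutive) < 2L) {
    stop("tissue clustering needs at least 2 constitutive genes")
  }
  m <- m[constitutive, sort(colnames(m)), drop = FALSE]
  logm <- log2(m + 1)
  hc <- hclust(expr_dist(logm), method = "average")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, newick = ape::write.tree(phy))
}
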