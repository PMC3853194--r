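# Category over-representation testing with the small-count rule (exact
# test when the 2x2 table has a small expected cell, Pearson chi-square
# otherwise) and Benjamini-Hochberg FDR control.

#' Over-representation test for one category
#'
#' Tests whether a category with `K` members in a background of `M`
#' genes is over-represented among `n` study genes of which `k` hit the
#' category. The minimum expected cell count `N` of the 2x2 table picks
#' the test: `N <= 5` uses the one-sided Fisher exact test
#' (hypergeometric upper tail); `N > 5` uses the Pearson chi-square test
#' with 1 df (no continuity correction).
#'
#' @param k study genes in the category.
#' @param n study size.
#' @param K category size in the background.
#' @param M background size.
#' @return list: `p_value`, `test_used` (`fisher`/`chisq`),
#'   `min_expected`.
#' @export
enrichment_test <- function(k, n, K, M) {
  if (k < 0 || n < 0 || K < 0 || M < 1 || k > n || k > K || n > M ||
      K > M || (n - k) > (M - K)) {
    stop("inconsistent counts: k=", k, " n=", n, " K=", K, " M=", M)
  }
  tab <- matrix(c(k, n - k, K - k, M - n - K + k), nrow = 2)
  expected <- outer(rowSums(tab), colSums(tab)) / M
  N <- min(expected)
  if (N <= 5) {
    p <- phyper(k - 1, K, M - K, n, lower.tail = FALSE)
    list(p_value = p, test_used = "fisher", min_expected = N)
  } else {
    p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    list(p_value = p, test_used = "chisq", min_expected = N)
  }
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment `q_(i) = min_(j >= i) p_(j) * m / j`, mapped
#' back to the input order; `q >= p` elementwise.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Category enrichment table for a study gene set
#'
#' @param study character vector of study gene ids.
#' @param background character vector of background gene ids (superset
#'   of `study`).
#' @param category_map data.frame with columns `gene_id`, `category`.
#' @return data.frame sorted by q-value: `category`, `k`, `n`, `K`, `M`,
#'   `p_value`, `q_value`, `test_used`, `min_expected`.
#' @export
enrich_categories <- function(study, background, category_map) {
  study <- unique(study); background <- unique(background)
  if (!all(study %in% background)) {
    stop("study genes missing from background")
  }
  cm <- category_map[category_map$gene_id %in% background, , drop = FALSE]
  M <- length(background)
  n <- length(study)
  out <- do.call(rbind, lapply(sort(unique(cm$category)), function(cat) {
    members <- unique(cm$gene_id[cm$category == cat])
    K <- length(members)
    k <- sum(study %in% members)
    r <- enrichment_test(k, n, K, M)
    data.frame(category = cat, k = k, n = n, K = K, M = M,
               p_value = r$p_value, test_used = r$test_used,
               min_expected = r$min_expected, stringsAsFactors = FALSE)
  }))
  out$q_value <- bh_adjust(out$p_value)
  out <- out[order(out$q_value, out$p_value, out$category), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("category", "k", "n", "K", "M", "p_value", "q_value",
          "test_used", "min_expected")]
}
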