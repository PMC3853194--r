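# Expressed calls, tiers, tau, housekeeping/tissue-specific sets,
# tissue clustering.

mk_expr <- function(m, lo = NULL) {
  if (is.null(lo)) lo <- m * 0.5
  do.call(rbind, lapply(rownames(m), function(g) {
    do.call(rbind, lapply(colnames(m), function(t) {
      data.frame(gene_id = g, tissue = t, fpkm = m[g, t],
                 ci_lo = lo[g, t], ci_hi = m[g, t] * 1.5,
                 stringsAsFactors = FALSE)
    }))
  }))
}

test_that("expressed means CI lower bound strictly above zero", {
  m <- matrix(c(2, 0.3, 7, 8), 2, 2,
              dimnames = list(c("g1", "g2"), c("root", "leaf")))
  lo <- matrix(c(0.4, 0, 2, 3), 2, 2, dimnames = dimnames(m))
  ce <- call_expressed(mk_expr(m, lo))
  expect_true(ce$expressed_root[ce$gene_id == "g1"])
  expect_false(ce$expressed_root[ce$gene_id == "g2"]) # zero is not > 0
  expect_true(ce$constitutive[ce$gene_id == "g1"])
  expect_false(ce$constitutive[ce$gene_id == "g2"])
})

test_that("expression tiers partition the axis at 5 and 50", {
  expect_equal(classify_tier(c(0, 5, 5.01, 50, 50.01, 300)),
               c("low", "low", "medium", "medium", "high", "high"))
  expect_error(classify_tier(-1), "negative")
  # exactly one tier per value
  set.seed(1)
  v <- runif(1000, 0, 100)
  expect_true(all(classify_tier(v) %in% c("low", "medium", "high")))
})

test_that("tau identities: uniform 0, one-hot 1, hand case 0.9", {
  expect_equal(compute_tau(c(5, 5, 5, 5, 5, 5))$tau, 0)
  expect_equal(compute_tau(c(0, 0, 0, 0, 0, 9))$tau, 1)
  expect_equal(compute_tau(c(10, 5, 0, 0, 0, 0))$tau, 0.9)
  expect_error(compute_tau(c(0, 0, 0)), "all-zero")
  expect_error(compute_tau(5), "2 tissues")
})

test_that("tau stays in [0,1] on random non-negative vectors", {
  set.seed(2024)
  taus <- vapply(1:10000, function(i) {
    v <- runif(sample(2:8, 1), 0, 100)
    v[sample(length(v), sample(0:(length(v) - 1), 1))] <- 0
    if (max(v) <= 0) v[1] <- 1
    compute_tau(v)$tau
  }, 1)
  expect_true(all(taus >= 0 & taus <= 1))
})

test_that("adding expression in a second tissue strictly lowers tau", {
  v <- c(50, 0, 0, 0, 0, 0)
  tau0 <- compute_tau(v)$tau
  for (x in c(1, 10, 25, 50)) {
    v2 <- v; v2[[2]] <- x
    expect_lt(compute_tau(v2)$tau, tau0)
    tau0 <- compute_tau(v2)$tau
  }
})

test_that("housekeeping requires FPKM strictly above 50 everywhere", {
  m <- matrix(c(51, 60, 70, 80, 90, 55,
                51, 60, 70, 80, 90, 50), 2, 6, byrow = TRUE,
              dimnames = list(c("in", "out"), paste0("t", 1:6)))
  hk <- find_housekeeping(mk_expr(m))
  expect_equal(hk, "in")
  empty <- mk_expr(m)[0, ]
  expect_length(find_housekeeping(empty), 0) # empty table, empty set
})

test_that("tissue-specific assignment needs high tau and expression there", {
  m <- matrix(0, 3, 6, dimnames = list(c("one", "uni", "dead"),
                                       paste0("t", 1:6)))
  m["one", "t3"] <- 80
  m["uni", ] <- 20
  m["dead", "t5"] <- 4
  lo <- m * 0.5
  lo["dead", ] <- 0  # not expressed anywhere
  ts <- find_tissue_specific(mk_expr(m, lo))
  expect_equal(ts$gene_id, "one")
  expect_equal(ts$tissue, "t3")
  # threshold 1.0 keeps only strictly one-hot genes
  m2 <- rbind(m[c("one", "uni"), ], near = c(79, 1, 0, 0, 0, 0))
  ts2 <- find_tissue_specific(mk_expr(m2, m2 * 0.5), tau_threshold = 1)
  expect_equal(ts2$gene_id, "one")
})

test_that("tissue distance is 1 - Pearson correlation", {
  logm <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4),
                c = c(4, 3, 2, 1), d = c(1, 3, 2, 5))
  d <- as.matrix(txomeatlas:::expr_dist(logm))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 2)  # perfectly anti-correlated
  logm_bad <- cbind(logm, e = c(2, 2, 2, 2))
  expect_error(txomeatlas:::expr_dist(logm_bad), "e")
})

test_that("planted block structure is recovered in the dendrogram", {
  set.seed(8)
  base <- runif(40, 2, 8)
  m <- cbind(A = base * 2, B = base * 2 + rnorm(40, 0, 0.05),
             C = pmax(base + rnorm(40, 0, 2), 0.2),
             D = rev(base) * 2, E = rev(base) * 2 + rnorm(40, 0, 0.05),
             F = pmax(rev(base) + rnorm(40, 0, 2), 0.2))
  rownames(m) <- sprintf("g%02d", 1:40)
  expr <- mk_expr(m)
  cl <- cluster_tissues(expr, constitutive = rownames(m))
  tree <- ape::read.tree(text = cl$newick)
  expect_equal(sort(ape::extract.clade(
    tree, ape::getMRCA(tree, c("A", "B")))$tip.label), c("A", "B"))
  expect_equal(sort(ape::extract.clade(
    tree, ape::getMRCA(tree, c("D", "E")))$tip.label), c("D", "E"))
})

test_that("expression classes are recovered exactly at zero noise", {
  run <- small_run()
  cls <- run$truth$expression_class
  tb <- run$tables
  ok <- vapply(seq_len(nrow(cls)), function(i) {
    g <- cls$gene_id[[i]]
    e <- tb$expressed[tb$expressed$gene_id == g, ]
    switch(cls$class[[i]],
      housekeeping = g %in% tb$housekeeping &&
        !(g %in% tb$tissue_specific$gene_id),
      tissue_specific = g %in% tb$tissue_specific$gene_id &&
        tb$tissue_specific$tissue[tb$tissue_specific$gene_id == g] ==
          cls$tissue[[i]],
      graded = e$constitutive && !(g %in% tb$housekeeping) &&
        !(g %in% tb$tissue_specific$gene_id),
      silent = !e$expressed_any)
  }, TRUE)
  expect_equal(mean(ok), 1)
})
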