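make_groups <- function(n_genes, n1, n2, shift = 0, sd = 1, seed = 1) {
  set.seed(seed)
  mk <- function(n, mu) {
    m <- matrix(rnorm(n_genes * n, mean = mu, sd = sd), nrow = n_genes,
                dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                sprintf("s%03d", seq_len(n))))
    expression_dataset(m, is_tf = rep(FALSE, n_genes),
                       condition = rep("x", n))
  }
  list(disease = mk(n1, shift), control = mk(n2, 0))
}

test_that("null data give centred logfc and uniform p-values", {
  gr <- make_groups(5000, 20, 20, shift = 0, seed = 2)
  de <- differential_expression(gr$disease, gr$control, moderation = "none")
  expect_lt(abs(mean(de$logfc)), 0.02)
  ks <- suppressWarnings(stats::ks.test(de$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(de$p_adj >= de$p))
})

test_that("swapping the groups negates logfc and t but preserves p", {
  gr <- make_groups(200, 8, 12, shift = 0.5, seed = 3)
  de_ab <- differential_expression(gr$disease, gr$control)
  de_ba <- differential_expression(gr$control, gr$disease)
  expect_equal(de_ab$logfc, -de_ba$logfc)
  expect_equal(de_ab$t_stat, -de_ba$t_stat)
  expect_equal(de_ab$p, de_ba$p)
})

test_that("the unmoderated t equals the classical pooled formula", {
  set.seed(4)
  for (i in 1:10) {
    n1 <- sample(3:8, 1)
    n2 <- sample(3:8, 1)
    x <- matrix(rnorm(5 * n1), 5, dimnames = list(paste0("g", 1:5), NULL))
    y <- matrix(rnorm(5 * n2), 5, dimnames = list(paste0("g", 1:5), NULL))
    colnames(x) <- paste0("a", 1:n1)
    colnames(y) <- paste0("b", 1:n2)
    dx <- expression_dataset(x, rep(FALSE, 5), rep("d", n1))
    dy <- expression_dataset(y, rep(FALSE, 5), rep("c", n2))
    de <- differential_expression(dx, dy, moderation = "none")
    for (g in 1:5) {
      tt <- stats::t.test(x[g, ], y[g, ], var.equal = TRUE)
      expect_equal(de$t_stat[g], unname(tt$statistic), tolerance = 1e-10)
      expect_equal(de$p[g], tt$p.value, tolerance = 1e-10)
    }
  }
})

test_that("the moderated t tracks limma's empirical-Bayes statistics", {
  gr <- make_groups(400, 6, 6, shift = 0, seed = 5)
  # plant heterogeneous variances so there is something to shrink
  set.seed(6)
  scale <- sqrt(rchisq(400, 4) / 4)
  vals_d <- gr$disease$values * scale
  vals_c <- gr$control$values * scale
  dx <- expression_dataset(vals_d, rep(FALSE, 400), rep("d", 6))
  dy <- expression_dataset(vals_c, rep(FALSE, 400), rep("c", 6))
  de <- differential_expression(dx, dy, moderation = "empirical_bayes")

  design <- cbind(1, rep(c(1, 0), each = 6))
  fit <- limma::eBayes(limma::lmFit(cbind(vals_d, vals_c), design))
  expect_gt(cor(de$t_stat, fit$t[, 2]), 0.999)
  expect_equal(attr(de, "d0"), fit$df.prior, tolerance = 0.2)
  expect_equal(attr(de, "s0_sq"), fit$s2.prior, tolerance = 0.05)
})

test_that("critical genes are ranked by decreasing logfc with the tie rules", {
  classes <- data.frame(node = c("gA", "gB", "gC", "gD", "gE"),
                        type1 = c("critical", "ordinary", "critical",
                                  "redundant", "critical"),
                        type2 = c("ordinary", "critical", "ordinary",
                                  "ordinary", "ordinary"),
                        stringsAsFactors = FALSE)
  de <- data.frame(gene_id = c("gA", "gB", "gC", "gD", "gE"),
                   logfc = c(2.0, -1.5, 0.3, 5.0, 1.0),
                   t_stat = 0, p = c(0.001, 0.002, 0.003, 0.001, 0.10),
                   p_adj = c(0.01, 0.02, 0.03, 0.01, 0.20),
                   stringsAsFactors = FALSE)
  rk <- rank_critical_genes(classes, de, order = "signed")
  # gD is not critical under either scheme: excluded entirely
  expect_false("gD" %in% rk$gene_id)
  expect_equal(rk$rank[match(c("gA", "gB", "gC"), rk$gene_id)], c(1L, 3L, 2L))
  # non-significant critical gene present but unranked
  expect_true(is.na(rk$rank[rk$gene_id == "gE"]))

  rk_abs <- rank_critical_genes(classes, de, order = "absolute")
  expect_equal(rk_abs$rank[match(c("gA", "gB", "gC"), rk_abs$gene_id)],
               c(1L, 2L, 3L))

  # deterministic under input row permutation
  rk2 <- rank_critical_genes(classes[c(3, 1, 5, 2, 4), ], de[5:1, ])
  expect_equal(rk2, rk)
})

test_that("hypergeometric overlap enrichment matches direct evaluation", {
  universe <- paste0("u", 1:10)
  hits <- universe[1:5]
  reference <- universe[c(1:4)]
  out <- overlap_enrichment(hits, reference, universe)
  expect_equal(out$overlap, 4L)
  expect_equal(out$p, choose(4, 4) * choose(6, 1) / choose(10, 5),
               tolerance = 1e-12)

  expect_equal(overlap_enrichment(universe, universe, universe)$p, 1)
  expect_equal(overlap_enrichment(character(), universe, universe)$p, 1)
  expect_error(overlap_enrichment("a", "a", character()), "empty universe")
  expect_error(overlap_enrichment("zzz", universe[1], universe), "subset")
})
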