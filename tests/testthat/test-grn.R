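test_that("pearson_test matches the textbook formula and its edge cases", {
  x <- c(1, 2, 3, 5, 8)
  out <- pearson_test(x, 2 * x + 1)
  expect_equal(out$r, 1)
  expect_equal(out$p, 0)

  # hand-computed oracle from the raw sums
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 3, 3)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r_hand <- sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt((4 - 2) / (1 - r_hand^2))
  p_hand <- 2 * stats::pt(-abs(t_hand), 4 - 2)
  out <- pearson_test(x, y)
  expect_equal(out$r, r_hand, tolerance = 1e-12)
  expect_equal(out$p, p_hand, tolerance = 1e-12)

  expect_error(pearson_test(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_test(1:2, 1:2), "at least 3")
})

test_that("bh_adjust follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  p <- c(0.001, 0.9, 0.04, 0.3)
  out <- bh_adjust(p)
  expect_true(all(out >= p) && all(out <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

# a tiny hand-built scenario: TF A drives mRNA B; mRNA M tracks TF T;
# genes U and V are significantly correlated but their direction is not
# in the PPI.
make_orientation_fixture <- function() {
  set.seed(3)
  n <- 30
  a <- rnorm(n)
  t_ <- rnorm(n)
  u <- rnorm(n)
  vals <- rbind(A = a, B = 0.95 * a + rnorm(n, sd = 0.2),
                T = t_, M = 0.95 * t_ + rnorm(n, sd = 0.2),
                U = u, V = 0.95 * u + rnorm(n, sd = 0.2))
  colnames(vals) <- paste0("s", seq_len(n))
  ds <- expression_dataset(vals,
                           is_tf = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
                           condition = rep("disease", n))
  ppi <- interaction_set(data.frame(
    from = c("A", "M", "V"), to = c("B", "T", "B"),
    stringsAsFactors = FALSE))
  list(ds = ds, ppi = ppi)
}

test_that("build_network applies significance, orientation and PPI rules", {
  fx <- make_orientation_fixture()
  rn <- build_network(fx$ds, fx$ppi, alpha = 0.05)
  # TF -> mRNA, correlated, in PPI: kept
  expect_true(has_edge(rn$interactions, "A", "B"))
  # mRNA -> TF direction is blocked even though M ~ T is significant
  expect_false(has_edge(rn$interactions, "M", "T"))
  # U ~ V significant but the PPI lacks U->V / V->U: absent entirely
  expect_false(any(c("U", "V") %in% rn$interactions$nodes))
  # output edges are always a subset of the PPI
  expect_true(all(has_edge(fx$ppi, rn$interactions$edges$from,
                           rn$interactions$edges$to)))
  # only the expression/PPI gene intersection is analysed: U has no PPI
  # link, leaving 5 testable genes
  expect_equal(rn$summary$n_tests, choose(5, 2))
  # provenance carries the correlation statistics
  expect_true(all(c("r", "p", "p_adj") %in% names(rn$provenance)))
  expect_true(all(rn$provenance$p_adj >= rn$provenance$p))
})

test_that("both test universes agree on which PPI edges survive", {
  fx <- make_orientation_fixture()
  rn_all <- build_network(fx$ds, fx$ppi, universe = "all_pairs")
  rn_ppi <- build_network(fx$ds, fx$ppi, universe = "ppi_pairs")
  expect_equal(rn_ppi$summary$n_tests, 3L)
  # with only 3 vs 15 tests the BH family differs, but this strong-signal
  # fixture passes in both
  expect_equal(rn_all$interactions$edges, rn_ppi$interactions$edges)
})

test_that("raising alpha never removes edges and sample order is irrelevant", {
  sim <- simulate_regulatory_system(seed = 8, n_tf = 10, n_mrna = 40,
                                    n_samples_per_condition = 30)
  ds <- filter_samples(sim$dataset, "disease")
  ppi <- sim$truth$decoy_ppi
  rn1 <- build_network(ds, ppi, alpha = 0.01)
  rn2 <- build_network(ds, ppi, alpha = 0.10)
  expect_true(all(edge_set <- has_edge(rn2$interactions,
                                       rn1$interactions$edges$from,
                                       rn1$interactions$edges$to)))
  perm <- sample(ncol(ds$values))
  ds_perm <- expression_dataset(ds$values[, perm],
                                is_tf = ds$genes$is_tf,
                                condition = ds$samples$condition[perm],
                                ds$samples$gestational_age_weeks[perm])
  rn_perm <- build_network(ds_perm, ppi, alpha = 0.01)
  expect_equal(rn_perm$interactions$edges, rn1$interactions$edges)
})

test_that("constant genes are excluded rather than failing the build", {
  fx <- make_orientation_fixture()
  vals <- rbind(fx$ds$values, K = rep(1, ncol(fx$ds$values)))
  ds <- expression_dataset(vals, is_tf = c(fx$ds$genes$is_tf, FALSE),
                           condition = fx$ds$samples$condition)
  ppi <- interaction_set(rbind(fx$ppi$edges,
                               data.frame(from = "A", to = "K")))
  expect_message(rn <- build_network(ds, ppi), "constant")
  expect_equal(rn$summary$n_constant_dropped, 1L)
  expect_false("K" %in% rn$interactions$nodes)
})
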