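#' Pearson correlation test for one gene pair
#'
#' Sample Pearson coefficient with the classical two-sided t test:
#' t = r * sqrt((n - 2) / (1 - r^2)) against Student's t with n - 2
#' degrees of freedom; a perfectly linear pair yields p = 0.
#'
#' @param x,y numeric vectors of equal length n >= 3, neither constant
#' @return list with elements `r` and `p`
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment: sort ascending, scale p(i) by m/i, enforce
#' monotonicity from the largest rank down, cap at 1; returned in input
#' order (delegates to [stats::p.adjust()] after validating the inputs).
#'
#' @param p_values numeric vector of p-values in \[0, 1\]
#' @return adjusted p-values, same order and length
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Build a condition-specific directed regulatory network
#'
#' Three-stage construction: (1) Pearson-test every unordered gene pair in
#' the chosen universe on the dataset's samples; (2) Benjamini-Hochberg
#' adjust across exactly the family of tests performed and keep pairs with
#' adjusted p < `alpha`; (3) orient each retained pair by the regulatory
#' assumption — a TF may regulate TFs and mRNAs, an mRNA may regulate only
#' mRNAs — and keep a directed edge only if that exact direction is present
#' in the prior directed PPI network. Only genes present in both the
#' expression catalog and the PPI node set are analysed; constant-expression
#' genes are excluded with a logged count.
#'
#' @param ds an [expression_dataset()] (samples of one condition)
#' @param ppi an [interaction_set()]: the prior directed PPI network
#' @param alpha adjusted-p threshold (strict `<`), default 0.05
#' @param universe `"all_pairs"` (test every gene pair, the default) or
#'   `"ppi_pairs"` (test only pairs connected in the PPI, a fast mode);
#'   the BH family is the set of tests performed and its size is recorded.
#' @return an object of class `regulatory_network`: list with
#'   `interactions` (an `interaction_set`), `node_roles` (data.frame
#'   `gene_id`, `is_tf`), `provenance` (per-edge `from`, `to`, `r`, `p`,
#'   `p_adj`) and `summary` (test-family size, edge-type counts, fraction
#'   of candidate PPI edges retained, dropped-gene counts).
#' @export
build_network <- function(ds, ppi, alpha = 0.05,
                          universe = c("all_pairs", "ppi_pairs")) {
  universe <- match.arg(universe)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  genes <- intersect(ds$genes$gene_id, ppi$nodes)
  if (length(genes) == 0L)
    stop("no genes shared between the expression catalog and the PPI")
  vals <- ds$values[genes, , drop = FALSE]
  ns <- ncol(vals)
  if (ns < 3L) stop("need at least 3 samples to test correlations")
  sds <- apply(vals, 1L, stats::sd)
  n_constant <- sum(sds == 0)
  if (n_constant > 0L) {
    message("build_network: excluded ", n_constant,
            " constant-expression gene(s)")
    genes <- genes[sds > 0]
    vals <- vals[genes, , drop = FALSE]
  }
  ng <- length(genes)
  if (ng < 2L) stop("fewer than 2 testable genes")
  is_tf <- stats::setNames(ds$genes$is_tf[match(genes, ds$genes$gene_id)],
                           genes)

  # candidate unordered pairs
  if (universe == "all_pairs") {
    cm <- stats::cor(t(vals))
    ut <- upper.tri(cm)
    idx <- which(ut, arr.ind = TRUE)
    ia <- idx[, 1L]
    ib <- idx[, 2L]
    r <- cm[ut]
  } else {
    ed <- ppi$edges[ppi$edges$from %in% genes & ppi$edges$to %in% genes, ]
    a <- pmin(match(ed$from, genes), match(ed$to, genes))
    b <- pmax(match(ed$from, genes), match(ed$to, genes))
    keep <- !duplicated(cbind(a, b))
    ia <- a[keep]
    ib <- b[keep]
    if (length(ia) == 0L) stop("no PPI-connected gene pairs to test")
    xs <- vals[ia, , drop = FALSE]
    ys <- vals[ib, , drop = FALSE]
    xs <- xs - rowMeans(xs)
    ys <- ys - rowMeans(ys)
    r <- rowSums(xs * ys) / sqrt(rowSums(xs^2) * rowSums(ys^2))
  }
  df <- ns - 2L
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[abs(r) >= 1] <- 0
  p_adj <- bh_adjust(p)

  sig <- which(p_adj < alpha)
  cand <- data.frame(a = genes[ia[sig]], b = genes[ib[sig]],
                     r = r[sig], p = p[sig], p_adj = p_adj[sig],
                     stringsAsFactors = FALSE)
  # orientation: TF source -> any target; mRNA source -> mRNA target only;
  # then keep a direction only if it is an edge of the prior PPI.
  dir1 <- cand[(is_tf[cand$a] | !is_tf[cand$b]) &
                 has_edge(ppi, cand$a, cand$b), , drop = FALSE]
  dir2 <- cand[(is_tf[cand$b] | !is_tf[cand$a]) &
                 has_edge(ppi, cand$b, cand$a), , drop = FALSE]
  prov <- rbind(
    data.frame(from = dir1$a, to = dir1$b, r = dir1$r, p = dir1$p,
               p_adj = dir1$p_adj, stringsAsFactors = FALSE),
    data.frame(from = dir2$b, to = dir2$a, r = dir2$r, p = dir2$p,
               p_adj = dir2$p_adj, stringsAsFactors = FALSE))
  prov <- prov[order(prov$from, prov$to), , drop = FALSE]
  rownames(prov) <- NULL
  net <- interaction_set(prov[, c("from", "to")])

  src_tf <- is_tf[prov$from]
  tgt_tf <- is_tf[prov$to]
  ppi_candidate <- sum(ppi$edges$from %in% genes & ppi$edges$to %in% genes)
  structure(list(
    interactions = net,
    node_roles = data.frame(gene_id = genes, is_tf = unname(is_tf),
                            stringsAsFactors = FALSE),
    provenance = prov,
    summary = list(
      n_genes = ng,
      n_tests = length(p),
      universe = universe,
      alpha = alpha,
      n_significant_pairs = length(sig),
      n_edges = nrow(prov),
      n_tf_tf = sum(src_tf & tgt_tf),
      n_tf_mrna = sum(src_tf & !tgt_tf),
      n_mrna_mrna = sum(!src_tf & !tgt_tf),
      n_ppi_candidate_edges = ppi_candidate,
      frac_ppi_retained = if (ppi_candidate > 0)
        nrow(prov) / ppi_candidate else NA_real_,
      n_constant_dropped = n_constant
    )
  ), class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  s <- x$summary
  cat("regulatory_network:", length(x$interactions$nodes), "nodes,",
      s$n_edges, "edges (TF-TF", s$n_tf_tf, ", TF-mRNA", s$n_tf_mrna,
      ", mRNA-mRNA", s$n_mrna_mrna, ")\n")
  cat("tests:", s$n_tests, "(", s$universe, "), significant pairs:",
      s$n_significant_pairs, ", PPI retention:",
      sprintf("%.1f%%", 100 * s$frac_ppi_retained), "\n")
  invisible(x)
}
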