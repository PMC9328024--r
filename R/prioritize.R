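#' Differential expression between disease and control datasets
#'
#' Per-gene two-sample comparison on the log2 scale. The log fold change is
#' the disease-group mean minus the control-group mean. The default test is
#' the classical pooled-variance t with n1 + n2 - 2 degrees of freedom;
#' `moderation = "empirical_bayes"` shrinks each gene's pooled variance
#' toward a common prior, s2_tilde = (d0 * s0^2 + d * s^2) / (d0 + d),
#' with the prior (d0, s0^2) fitted by moment-matching the distribution of
#' log sample variances across genes (digamma/trigamma inversion) and the
#' t degrees of freedom inflated by d0 — a moderated-t in the microarray
#' tradition, not a bit-exact clone of any particular implementation.
#' P-values are Benjamini-Hochberg adjusted across all genes.
#'
#' @param ds_disease,ds_control [expression_dataset()]s sharing one gene
#'   catalog, each with at least 2 samples
#' @param moderation `"empirical_bayes"` (default) or `"none"`
#' @return data.frame with columns `gene_id`, `logfc`, `t_stat`, `p`,
#'   `p_adj`; attributes `d0` and `s0_sq` when moderated.
#' @export
differential_expression <- function(ds_disease, ds_control,
                                    moderation = c("empirical_bayes",
                                                   "none")) {
  moderation <- match.arg(moderation)
  if (!identical(ds_disease$genes$gene_id, ds_control$genes$gene_id))
    stop("disease and control datasets must share the same gene catalog")
  x <- ds_disease$values
  y <- ds_control$values
  n1 <- ncol(x)
  n2 <- ncol(y)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 samples per group")
  m1 <- rowMeans(x)
  m2 <- rowMeans(y)
  logfc <- m1 - m2
  v1 <- rowSums((x - m1)^2) / (n1 - 1L)
  v2 <- rowSums((y - m2)^2) / (n2 - 1L)
  d <- n1 + n2 - 2L
  s2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / d
  scale2 <- 1 / n1 + 1 / n2

  d0 <- Inf
  s0_sq <- NA_real_
  if (moderation == "empirical_bayes") {
    pos <- s2 > 0
    if (sum(pos) >= 2L) {
      e <- log(s2[pos])
      excess <- stats::var(e) - trigamma(d / 2)
      d0 <- if (excess > 0) 2 * trigamma_inverse(excess) else Inf
      s0_sq <- if (is.finite(d0))
        exp(mean(e) - digamma(d / 2) + log(d / 2) +
              digamma(d0 / 2) - log(d0 / 2))
      else exp(mean(e) - digamma(d / 2) + log(d / 2))
      s2 <- if (is.finite(d0)) (d0 * s0_sq + d * s2) / (d0 + d)
      else rep(s0_sq, length(s2))
    }
    df_t <- d + d0
  } else {
    df_t <- d
  }

  zero_var <- s2 <= 0
  if (any(zero_var))
    warning(sum(zero_var), " gene(s) with zero variance in both groups; ",
            "p set to 1")
  tstat <- ifelse(zero_var, 0, logfc / sqrt(s2 * scale2))
  p <- if (is.finite(df_t)) 2 * stats::pt(-abs(tstat), df_t)
  else 2 * stats::pnorm(-abs(tstat))
  p[zero_var] <- 1
  out <- data.frame(gene_id = ds_disease$genes$gene_id,
                    logfc = unname(logfc), t_stat = unname(tstat),
                    p = unname(p), p_adj = bh_adjust(unname(p)),
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

# Newton inversion of the trigamma function (y = trigamma(x), y > 0);
# monotone decreasing, standard iteration on 1/trigamma.
trigamma_inverse <- function(y) {
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

#' Rank critical genes by log fold change
#'
#' Genes classified critical under either scheme (type-1 or type-2) are
#' joined with the differential-expression table; those significant at
#' `alpha` are ranked by decreasing signed log fold change (default) or by
#' decreasing absolute log fold change, ties broken by gene id.
#' Non-significant critical genes remain in the table with rank `NA`.
#'
#' @param classes per-node classification from [classify_nodes()]
#' @param de differential-expression table from
#'   [differential_expression()]
#' @param order `"signed"` (default) or `"absolute"`
#' @param alpha significance threshold on the (adjusted) p-value,
#'   inclusive (`<=`), default 0.05
#' @param use_adjusted compare `alpha` against the BH-adjusted p (default)
#'   or the raw p
#' @return data.frame with columns `gene_id`, `type1`, `type2`, `logfc`,
#'   `p`, `p_adj`, `rank` (1-based; `NA` when unranked), ranked rows
#'   first.
#' @export
rank_critical_genes <- function(classes, de, order = c("signed", "absolute"),
                                alpha = 0.05, use_adjusted = TRUE) {
  order <- match.arg(order)
  crit <- classes[classes$type1 == "critical" |
                    classes$type2 == "critical", , drop = FALSE]
  tab <- merge(crit[, c("node", "type1", "type2")], de,
               by.x = "node", by.y = "gene_id")
  if (nrow(tab) == 0L)
    return(data.frame(gene_id = character(), type1 = character(),
                      type2 = character(), logfc = numeric(), p = numeric(),
                      p_adj = numeric(), rank = integer(),
                      stringsAsFactors = FALSE))
  names(tab)[1L] <- "gene_id"
  pcol <- if (use_adjusted) tab$p_adj else tab$p
  sig <- pcol <= alpha
  key <- if (order == "signed") tab$logfc else abs(tab$logfc)
  tab$rank <- NA_integer_
  if (any(sig)) {
    ord <- order(-key[sig], tab$gene_id[sig])
    tab$rank[which(sig)[ord]] <- seq_len(sum(sig))
  }
  tab <- tab[order(is.na(tab$rank), tab$rank, tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab[, c("gene_id", "type1", "type2", "logfc", "p", "p_adj", "rank")]
}

#' Hypergeometric overlap enrichment
#'
#' Upper-tail hypergeometric probability of observing at least the realised
#' overlap between a hit set and a reference set drawn from a common
#' universe — the usual test for whether a predicted gene list is enriched
#' for genes in a curated database.
#'
#' @param hits,reference,universe character vectors of gene ids;
#'   `hits` and `reference` must be subsets of `universe`
#' @return list with `overlap` (integer) and `p` (upper-tail p-value)
#' @export
overlap_enrichment <- function(hits, reference, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  hits <- unique(hits)
  reference <- unique(reference)
  if (!all(hits %in% universe)) stop("hits must be a subset of universe")
  if (!all(reference %in% universe))
    stop("reference must be a subset of universe")
  k <- length(intersect(hits, reference))
  p <- stats::phyper(k - 1, length(reference),
                     length(universe) - length(reference),
                     length(hits), lower.tail = FALSE)
  list(overlap = k, p = p)
}
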