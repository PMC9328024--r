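#' Mean in/out-degree per classification category
#'
#' Summarises, for each classification scheme (type-1 and type-2) and each
#' category (critical / ordinary / redundant), the mean in- and out-degree
#' of its nodes. Empty categories are reported with mean 0 and a flag.
#'
#' @param net an [interaction_set()]
#' @param classes per-node table from [classify_nodes()]
#' @return data.frame with columns `scheme`, `category`, `n_nodes`,
#'   `mean_in_degree`, `mean_out_degree`, `empty`
#' @export
degree_summary <- function(net, classes) {
  cats <- c("critical", "ordinary", "redundant")
  rows <- lapply(c("type1", "type2"), function(scheme) {
    do.call(rbind, lapply(cats, function(cat) {
      sel <- classes[[scheme]] == cat
      data.frame(scheme = scheme, category = cat, n_nodes = sum(sel),
                 mean_in_degree = if (any(sel))
                   mean(classes$in_degree[sel]) else 0,
                 mean_out_degree = if (any(sel))
                   mean(classes$out_degree[sel]) else 0,
                 empty = !any(sel), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kleinberg hub scores
#'
#' HITS hub centrality: the principal eigenvector of A A^T (A the 0/1
#' adjacency matrix), computed by deterministic power iteration from a
#' uniform start to an infinity-norm tolerance of 1e-10, then normalised
#' so the maximum score is 1. The fixed starting vector makes the result
#' bit-reproducible; scores below 1e-10 are zapped to exact zero.
#'
#' @param net an [interaction_set()]
#' @return named numeric vector of hub scores in \[0, 1\], one per node
#' @export
hub_scores <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  if (n_edges(net) == 0L) {
    warning("empty network: all hub scores 0")
    return(stats::setNames(rep(0, n), nodes))
  }
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  A[cbind(net$edges$from, net$edges$to)] <- 1
  h <- rep(1 / n, n)
  for (it in 1:10000) {
    h_new <- as.numeric(A %*% (crossprod(A, h)))
    nrm <- max(h_new)
    if (nrm == 0) { h <- h_new; break }
    h_new <- h_new / nrm
    if (max(abs(h_new - h)) < 1e-10) { h <- h_new; break }
    h <- h_new
  }
  h[h < 1e-10] <- 0
  stats::setNames(h, nodes)
}

#' Betweenness centrality
#'
#' Directed, unweighted shortest-path betweenness, unnormalised raw path
#' counts (only the induced ranking is used downstream).
#'
#' @param net an [interaction_set()]
#' @return named numeric vector of betweenness scores, one per node
#' @export
betweenness_scores <- function(net) {
  if (length(net$nodes) == 0L) return(stats::setNames(numeric(), character()))
  g <- as_igraph(net)
  b <- igraph::betweenness(g, directed = TRUE, normalized = FALSE)
  b[net$nodes]
}

#' Rank genes by a centrality score
#'
#' Retains genes with strictly positive scores and ranks them by
#' decreasing score, ties broken by gene id — the deterministic "method
#' ranking" used when comparing gene lists across methods.
#'
#' @param scores named numeric vector (e.g. from [hub_scores()] or
#'   [betweenness_scores()])
#' @return data.frame with columns `gene_id`, `score`, `rank`
#' @export
rank_by_score <- function(scores) {
  keep <- which(scores > 0)
  ord <- keep[order(-scores[keep], names(scores)[keep])]
  data.frame(gene_id = names(scores)[ord], score = unname(scores[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

# draw n values from the discrete power law with exponent alpha and lower
# cutoff xmin (continuous-approximation inversion, standard practice for
# bootstrap resampling).
rpldis <- function(n, alpha, xmin) {
  u <- stats::runif(n)
  floor((xmin - 0.5) * (1 - u)^(-1 / (alpha - 1)) + 0.5)
}

#' Discrete power-law fit with bootstrap goodness of fit
#'
#' Fits Pr(k) ~ k^(-lambda) to the positive degrees by discrete maximum
#' likelihood, choosing the lower cutoff `xmin` to minimise the
#' Kolmogorov-Smirnov distance between the empirical tail and the fitted
#' model (the plfit estimator, via [igraph::fit_power_law()]). The
#' goodness-of-fit p-value is the semiparametric bootstrap of Clauset et
#' al.: each replicate resamples the body (below `xmin`) empirically and
#' the tail from the fitted power law, refits from scratch, and the
#' p-value is the fraction of replicates whose KS distance is at least the
#' observed one. The degree sequence is called scale-free when the
#' p-value exceeds 0.1.
#'
#' @param degrees non-negative integer degree vector (zeros are ignored
#'   for fitting); fewer than 50 positive degrees triggers a warning
#' @param n_bootstrap bootstrap replicates (default 200)
#' @param seed RNG seed for the bootstrap
#' @return object of class `power_law_fit`: list with `lambda`, `xmin`,
#'   `ks_stat`, `gof_p`, `scale_free`, `n_tail`, `n`
#' @export
fit_power_law <- function(degrees, n_bootstrap = 200L, seed = 1L) {
  if (length(degrees) == 0L || all(degrees == 0))
    stop("degree vector is empty or all zero")
  if (any(degrees < 0)) stop("degrees must be non-negative")
  x <- as.integer(degrees[degrees > 0])
  if (length(x) < 50L)
    warning("fewer than 50 positive degrees: power-law fit is unreliable")
  if (length(unique(x)) < 2L) {
    warning("degenerate (constant) degree sequence: no tail to fit")
    return(structure(list(lambda = NA_real_, xmin = NA_real_,
                          ks_stat = NA_real_, gof_p = NA_real_,
                          scale_free = FALSE, n_tail = length(x),
                          n = length(x)), class = "power_law_fit"))
  }
  fit <- igraph::fit_power_law(x, implementation = "plfit")
  lambda <- fit$alpha
  xmin <- fit$xmin
  ks_obs <- fit$KS.stat

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- length(x)
  body <- x[x < xmin]
  p_tail <- 1 - length(body) / n
  ks_boot <- vapply(seq_len(n_bootstrap), function(b) {
    from_tail <- stats::runif(n) < p_tail
    xb <- integer(n)
    nt <- sum(from_tail)
    if (nt > 0L) xb[from_tail] <- rpldis(nt, lambda, xmin)
    if (nt < n) xb[!from_tail] <- sample(body, n - nt, replace = TRUE)
    if (length(unique(xb)) < 2L) return(0)
    igraph::fit_power_law(xb, implementation = "plfit")$KS.stat
  }, numeric(1))
  gof_p <- mean(ks_boot >= ks_obs)
  structure(list(lambda = lambda, xmin = xmin, ks_stat = ks_obs,
                 gof_p = gof_p, scale_free = (gof_p > 0.1 && lambda > 1),
                 n_tail = sum(x >= xmin), n = n),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "power_law_fit: lambda = %.3f, xmin = %s, KS = %.4f, GoF p = %.3f (%s)\n",
    x$lambda, format(x$xmin), x$ks_stat, x$gof_p,
    if (isTRUE(x$scale_free)) "scale-free" else "not scale-free"))
  invisible(x)
}

#' Scale-free assessment of a directed network
#'
#' Fits the in-degree and out-degree distributions to separate power laws
#' and calls the network scale-free only when both pass the bootstrap
#' goodness-of-fit rule (p > 0.1).
#'
#' @param net an [interaction_set()]
#' @param n_bootstrap,seed passed to [fit_power_law()]
#' @return list with `in_fit`, `out_fit` (each a `power_law_fit`) and
#'   `scale_free`
#' @export
assess_scale_free <- function(net, n_bootstrap = 200L, seed = 1L) {
  degenerate_fit <- function() structure(
    list(lambda = NA_real_, xmin = NA_real_, ks_stat = NA_real_,
         gof_p = NA_real_, scale_free = FALSE, n_tail = 0L, n = 0L),
    class = "power_law_fit")
  safe_fit <- function(deg, seed) {
    if (length(deg) == 0L || all(deg == 0)) {
      warning("no positive degrees: power-law fit skipped")
      return(degenerate_fit())
    }
    fit_power_law(deg, n_bootstrap, seed)
  }
  g <- as_igraph(net)
  in_fit <- safe_fit(igraph::degree(g, mode = "in"), seed)
  out_fit <- safe_fit(igraph::degree(g, mode = "out"), seed + 1L)
  list(in_fit = in_fit, out_fit = out_fit,
       scale_free = isTRUE(in_fit$scale_free) && isTRUE(out_fit$scale_free))
}
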