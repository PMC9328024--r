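# Independent oracles and random-graph helpers used across the suite.

# Erdos-Renyi style random digraph (no self-loops) with edge prob p.
random_digraph <- function(n, p) {
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- stats::runif(nrow(pairs)) < p
  interaction_set(data.frame(from = as.character(pairs$from[keep]),
                             to = as.character(pairs$to[keep]),
                             stringsAsFactors = FALSE),
                  nodes = as.character(seq_len(n)))
}

# maximum matching size of the bipartite split graph, via igraph
# (independent of the package's Kuhn implementation).
oracle_matching_size <- function(net) {
  n <- length(net$nodes)
  if (n == 0L) return(0L)
  types <- c(rep(FALSE, n), rep(TRUE, n))
  from <- match(net$edges$from, net$nodes)
  to <- match(net$edges$to, net$nodes) + n
  g <- igraph::make_empty_graph(2L * n, directed = FALSE)
  igraph::V(g)$type <- types
  if (length(from) > 0L)
    g <- igraph::add_edges(g, rbind(from, to))
  igraph::max_bipartite_match(g)$matching_size
}

oracle_mdns <- function(net) {
  n <- length(net$nodes)
  if (n == 0L) return(0L)
  max(n - oracle_matching_size(net), 1L)
}

delete_node <- function(net, v) {
  ed <- net$edges[net$edges$from != v & net$edges$to != v, , drop = FALSE]
  interaction_set(ed, nodes = setdiff(net$nodes, v))
}

# brute-force betweenness: count, over all ordered node pairs (s, t),
# the fraction of shortest s-t paths passing through each interior node.
naive_betweenness <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  bc <- stats::setNames(rep(0, n), nodes)
  adj <- split(net$edges$to, factor(net$edges$from, levels = nodes))
  all_paths <- function(s, t) {
    found <- list()
    best <- Inf
    walk <- function(path) {
      v <- path[length(path)]
      if (length(path) - 1L > best) return()
      if (v == t) {
        if (length(path) - 1L < best) {
          best <<- length(path) - 1L
          found <<- list(path)
        } else found[[length(found) + 1L]] <<- path
        return()
      }
      for (w in adj[[v]]) if (!w %in% path) walk(c(path, w))
    }
    walk(s)
    found
  }
  for (s in nodes) for (t in nodes) {
    if (s == t) next
    paths <- all_paths(s, t)
    if (length(paths) == 0L) next
    for (p in paths) {
      interior <- p[-c(1L, length(p))]
      bc[interior] <- bc[interior] + 1 / length(paths)
    }
  }
  bc
}

# hub scores by direct eigen-decomposition of A %*% t(A)
naive_hub <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  A[cbind(net$edges$from, net$edges$to)] <- 1
  ev <- eigen(A %*% t(A), symmetric = TRUE)
  h <- abs(ev$vectors[, 1L])
  if (max(h) > 0) h <- h / max(h)
  stats::setNames(h, nodes)
}

# nodes reachable from a seed set along directed edges
reachable_from <- function(net, seeds) {
  seen <- unique(seeds)
  frontier <- seen
  while (length(frontier) > 0L) {
    nxt <- unique(net$edges$to[net$edges$from %in% frontier])
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  seen
}

# exact discrete power-law sampler (truncated zeta inversion), independent
# of the package's bootstrap resampler
rpldis_test <- function(n, alpha, xmin, kmax = 1e6L) {
  k <- seq.int(xmin, kmax)
  p <- k^(-alpha)
  sample(k, n, replace = TRUE, prob = p / sum(p))
}

# tiny expression fixture: 3 genes x 4 samples written to tempfiles
write_mini_dataset <- function(dir = tempfile("mini")) {
  dir.create(dir)
  writeLines(c("gene_id\ts1\ts2\ts3\ts4",
               "G1\t1.0\t2.0\t3.0\t4.0",
               "G2\t2.0\t4.0\t6.0\t8.0",
               "G3\t5.0\t5.5\t4.5\t5.0"),
             file.path(dir, "expr.tsv"))
  writeLines(c("sample_id\tcondition\tgestational_age_weeks",
               "s1\tdisease\t32", "s2\tdisease\t38",
               "s3\tcontrol\t36", "s4\tcontrol\t40"),
             file.path(dir, "meta.tsv"))
  writeLines("G1", file.path(dir, "tf.txt"))
  dir
}
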