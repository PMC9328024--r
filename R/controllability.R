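# Structural controllability of a directed network via maximum matching on
# the bipartite split graph: each node u is split into an out-copy u+ (left
# side) and an in-copy u- (right side); every directed edge u -> v becomes a
# bipartite edge u+ -- v-. A matching of this graph is a set of directed
# edges no two of which share a start node or an end node. Nodes whose
# in-copy is unmatched in a maximum matching must receive an external input
# (driver nodes); the minimum number of driver nodes (|MDNS|) is
# N - |maximum matching|, clamped below at 1 for a non-empty network because
# at least one input is always needed.

# internal representation: nodes sorted; adj[[u]] = sorted integer targets
# (right copies reachable from left copy u); radj[[v]] = sorted sources.
split_graph <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  from <- match(net$edges$from, nodes)
  to <- match(net$edges$to, nodes)
  adj <- rep(list(integer()), n)
  radj <- rep(list(integer()), n)
  if (length(from) > 0L) {
    sp <- split(to, factor(from, levels = seq_len(n)))
    adj <- lapply(sp, function(v) sort(unique(v)))
    sp <- split(from, factor(to, levels = seq_len(n)))
    radj <- lapply(sp, function(v) sort(unique(v)))
  }
  list(nodes = nodes, n = n, adj = adj, radj = radj)
}

# one augmenting-path search from free left vertex u (Kuhn's algorithm).
# match_right[v] = left vertex matched to right copy v, 0 if free.
# alive_right[v] = FALSE marks deleted in-copies. Environment-based so the
# recursion mutates a single matching state.
try_augment <- function(u, st) {
  for (v in st$adj[[u]]) {
    if (!st$alive_right[v] || st$visited[v]) next
    st$visited[v] <- TRUE
    if (st$match_right[v] == 0L || try_augment(st$match_right[v], st)) {
      st$match_right[v] <- u
      st$match_left[u] <- v
      return(TRUE)
    }
  }
  FALSE
}

new_match_state <- function(sg, alive_left = NULL, alive_right = NULL) {
  st <- new.env(parent = emptyenv())
  st$adj <- sg$adj
  st$n <- sg$n
  st$match_left <- integer(sg$n)
  st$match_right <- integer(sg$n)
  st$alive_left <- if (is.null(alive_left)) rep(TRUE, sg$n) else alive_left
  st$alive_right <- if (is.null(alive_right)) rep(TRUE, sg$n) else alive_right
  st
}

run_kuhn <- function(st) {
  for (u in seq_len(st$n)) {
    if (!st$alive_left[u] || st$match_left[u] != 0L) next
    st$visited <- rep(FALSE, st$n)
    try_augment(u, st)
  }
  st
}

mdns_from <- function(n_alive, matching_size) {
  if (n_alive == 0L) return(0L)
  max(n_alive - matching_size, 1L)
}

#' Maximum matching and driver nodes of a directed network
#'
#' Computes a canonical maximum matching of the bipartite split graph
#' (left vertices processed in sorted node order, neighbours in sorted
#' order, so the matching is reproducible), the matched/unmatched node
#' sets, the driver set (nodes whose in-copy is unmatched) and the size of
#' the minimum driver node set. The matching itself can differ between
#' equally large matchings; the driver-set *size* is matching-invariant.
#'
#' @param net an [interaction_set()] (no self-loops)
#' @return an object of class `driver_analysis`: list with `matching`
#'   (data.frame `from`, `to` of matched links), `matched_nodes`,
#'   `drivers` (character vectors), `mdns_size` (integer) and
#'   `matching_size`.
#' @export
maximum_matching <- function(net) {
  sg <- split_graph(net)
  st <- run_kuhn(new_match_state(sg))
  matched_right <- which(st$match_right != 0L)
  matching <- data.frame(from = sg$nodes[st$match_right[matched_right]],
                         to = sg$nodes[matched_right],
                         stringsAsFactors = FALSE)
  matching <- matching[order(matching$from, matching$to), , drop = FALSE]
  rownames(matching) <- NULL
  drivers <- sg$nodes[st$match_right == 0L]
  structure(list(
    matching = matching,
    matched_nodes = sg$nodes[matched_right],
    drivers = drivers,
    matching_size = length(matched_right),
    mdns_size = mdns_from(sg$n, length(matched_right))
  ), class = "driver_analysis")
}

#' @export
print.driver_analysis <- function(x, ...) {
  cat("driver_analysis: matching size", x$matching_size,
      "| drivers:", length(x$drivers),
      "| |MDNS| =", x$mdns_size, "\n")
  invisible(x)
}

#' Enumerate all minimum driver node sets (brute force)
#'
#' Enumerates every maximum matching of the bipartite split graph and
#' collects the distinct unmatched-node (driver) sets. Exponential in the
#' worst case; intended as the exhaustive oracle for the scalable
#' classifiers on small networks.
#'
#' @param net an [interaction_set()]
#' @param max_nodes refuse networks larger than this (default 15)
#' @return a list of character vectors (each a distinct driver set,
#'   sorted); the list itself sorted lexicographically.
#' @export
enumerate_driver_sets <- function(net, max_nodes = 15L) {
  sg <- split_graph(net)
  if (sg$n > max_nodes)
    stop("network has ", sg$n, " nodes (> ", max_nodes,
         "); use classify_type1() for large networks")
  m <- maximum_matching(net)$matching_size
  results <- new.env(parent = emptyenv())
  used_left <- rep(FALSE, sg$n)
  match_of_right <- integer(sg$n)
  recurse <- function(i, matched) {
    # prune: even matching every remaining right copy cannot reach m
    if (matched + (sg$n - i + 1L) < m) return(invisible())
    if (i > sg$n) {
      if (matched == m) {
        key <- paste0("k", paste(which(match_of_right == 0L),
                                 collapse = ","))
        results[[key]] <- sg$nodes[match_of_right == 0L]
      }
      return(invisible())
    }
    recurse(i + 1L, matched)  # leave in-copy i unmatched
    for (u in sg$radj[[i]]) {
      if (used_left[u]) next
      used_left[u] <<- TRUE
      match_of_right[i] <<- u
      recurse(i + 1L, matched + 1L)
      used_left[u] <<- FALSE
      match_of_right[i] <<- 0L
    }
  }
  recurse(1L, 0L)
  sets <- unname(as.list(results))
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, paste, "", collapse = ","))]
}

# max matching size with one in-copy removed, warm-started from a full
# canonical matching: if v- was matched to u+, free the pair and try one
# augmenting search from u+ avoiding v-.
matching_size_without_right <- function(sg, st_full, v) {
  u <- st_full$match_right[v]
  if (u == 0L) return(sum(st_full$match_right != 0L))
  st <- new_match_state(sg)
  st$match_left <- st_full$match_left
  st$match_right <- st_full$match_right
  st$alive_right[v] <- FALSE
  st$match_left[u] <- 0L
  st$match_right[v] <- 0L
  st$visited <- rep(FALSE, sg$n)
  m <- sum(st$match_right != 0L)
  if (try_augment(u, st)) m + 1L else m
}

#' Type-1 node classification (membership across minimum driver sets)
#'
#' A node is *critical* if it is a driver in every minimum driver node
#' set, *ordinary* if in at least one but not all, and *redundant* if in
#' none. Implemented without enumeration: a node is critical iff its
#' in-degree is zero (it can never be matched, hence is always a driver;
#' conversely any node with an incoming edge is matched in some maximum
#' matching by an exchange argument); a node is redundant iff deleting its
#' in-copy lowers the maximum matching size (its in-copy is covered by
#' every maximum matching); otherwise ordinary.
#'
#' @param net an [interaction_set()]
#' @return character vector (levels `critical`, `ordinary`, `redundant`)
#'   named by node
#' @export
classify_type1 <- function(net) {
  sg <- split_graph(net)
  st <- run_kuhn(new_match_state(sg))
  m <- sum(st$match_right != 0L)
  in_deg <- lengths(sg$radj)
  out <- character(sg$n)
  for (v in seq_len(sg$n)) {
    if (in_deg[v] == 0L) {
      out[v] <- "critical"
    } else if (matching_size_without_right(sg, st, v) == m - 1L) {
      out[v] <- "redundant"   # in-copy covered by every maximum matching
    } else {
      out[v] <- "ordinary"    # avoidable, but coverable (in-degree > 0)
    }
  }
  stats::setNames(out, sg$nodes)
}

# max matching of the graph with node v (both copies) deleted, warm-started
# from the canonical full matching.
matching_size_without_node <- function(sg, st_full, v) {
  st <- new_match_state(sg)
  st$match_left <- st_full$match_left
  st$match_right <- st_full$match_right
  st$alive_left[v] <- FALSE
  st$alive_right[v] <- FALSE
  if (st$match_left[v] != 0L) {
    st$match_right[st$match_left[v]] <- 0L
    st$match_left[v] <- 0L
  }
  if (st$match_right[v] != 0L) {
    st$match_left[st$match_right[v]] <- 0L
    st$match_right[v] <- 0L
  }
  for (u in seq_len(sg$n)) {
    if (!st$alive_left[u] || st$match_left[u] != 0L) next
    st$visited <- rep(FALSE, sg$n)
    try_augment(u, st)
  }
  sum(st$match_right != 0L)
}

#' Type-2 node classification (effect of node deletion on |MDNS|)
#'
#' For each node v, delete v and all incident edges, recompute the minimum
#' driver node set size, and categorise by the sign of
#' delta = |MDNS|(G - v) - |MDNS|(G): +1 critical (the network becomes
#' harder to control without v), -1 redundant, 0 ordinary. Deleting one
#' node always changes |MDNS| by at most one in either direction.
#'
#' @param net an [interaction_set()]
#' @return data.frame with columns `node`, `type2`, `delta_mdns`,
#'   `mdns_without`
#' @export
classify_type2 <- function(net) {
  sg <- split_graph(net)
  st <- run_kuhn(new_match_state(sg))
  m <- sum(st$match_right != 0L)
  mdns <- mdns_from(sg$n, m)
  delta <- integer(sg$n)
  mdns_without <- integer(sg$n)
  for (v in seq_len(sg$n)) {
    mv <- matching_size_without_node(sg, st, v)
    mdns_without[v] <- mdns_from(sg$n - 1L, mv)
    delta[v] <- mdns_without[v] - mdns
  }
  type2 <- ifelse(delta > 0L, "critical",
                  ifelse(delta < 0L, "redundant", "ordinary"))
  data.frame(node = sg$nodes, type2 = type2, delta_mdns = delta,
             mdns_without = mdns_without, stringsAsFactors = FALSE)
}

#' Full per-node controllability classification
#'
#' Convenience wrapper combining degrees, canonical-matching driver flags,
#' and both classification schemes.
#'
#' @param net an [interaction_set()]
#' @return data.frame with columns `node`, `in_degree`, `out_degree`,
#'   `degree`, `is_driver` (in the canonical maximum matching), `type1`,
#'   `type2`, `delta_mdns`; attribute `mdns_size`.
#' @export
classify_nodes <- function(net) {
  sg <- split_graph(net)
  da <- maximum_matching(net)
  t1 <- classify_type1(net)
  t2 <- classify_type2(net)
  out <- data.frame(node = sg$nodes,
                    in_degree = lengths(sg$radj),
                    out_degree = lengths(sg$adj),
                    degree = lengths(sg$radj) + lengths(sg$adj),
                    is_driver = sg$nodes %in% da$drivers,
                    type1 = unname(t1[sg$nodes]),
                    type2 = t2$type2[match(sg$nodes, t2$node)],
                    delta_mdns = t2$delta_mdns[match(sg$nodes, t2$node)],
                    stringsAsFactors = FALSE)
  attr(out, "mdns_size") <- da$mdns_size
  out
}

#' Kalman rank oracle for a candidate driver set
#'
#' Draws random nonzero weights (uniform on \[0.5, 1.5\], seeded) for the
#' adjacency matrix A (entry (i, j) nonzero for edge j -> i) and for the
#' diagonal input matrix B restricted to the driver rows, builds the
#' controllability matrix C = (B, AB, A^2 B, ..., A^(N-1) B) and tests
#' whether rank(C) = N in any of `trials` draws. Structural
#' controllability holds for almost every weight draw, so a handful of
#' trials suffices; this is a numerical oracle for small networks only.
#'
#' @param net an [interaction_set()] with at most `max_nodes` nodes
#' @param driver_subset character vector of driver node ids
#' @param trials number of random weight draws (default 5)
#' @param seed RNG seed for the weight draws
#' @param max_nodes hard size cap (default 12)
#' @return `TRUE` if full rank was achieved in any trial
#' @export
kalman_rank_check <- function(net, driver_subset, trials = 5L, seed = 1L,
                              max_nodes = 12L) {
  n <- length(net$nodes)
  if (n > max_nodes)
    stop("Kalman oracle limited to ", max_nodes, " nodes (got ", n, ")")
  if (n == 0L) return(TRUE)
  driver_subset <- as.character(driver_subset)
  if (!all(driver_subset %in% net$nodes))
    stop("driver_subset contains unknown node(s)")
  m <- length(driver_subset)
  if (m == 0L) return(FALSE)
  from <- match(net$edges$from, net$nodes)
  to <- match(net$edges$to, net$nodes)
  rows <- match(driver_subset, net$nodes)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (trial in seq_len(trials)) {
    A <- matrix(0, n, n)
    if (length(from) > 0L)
      A[cbind(to, from)] <- stats::runif(length(from), 0.5, 1.5)
    B <- matrix(0, n, m)
    B[cbind(rows, seq_len(m))] <- stats::runif(m, 0.5, 1.5)
    C <- matrix(0, n, n * m)
    blk <- B
    for (k in seq_len(n)) {
      C[, ((k - 1L) * m + 1L):(k * m)] <- blk
      if (k < n) blk <- A %*% blk
    }
    if (qr(C)$rank == n) return(TRUE)
  }
  FALSE
}
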