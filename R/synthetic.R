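#' Simulate a regulatory system with a known ground truth
#'
#' Generates everything the pipeline consumes, with the statistical
#' structure the method assumes: a gene catalog of TFs and mRNAs; a
#' planted acyclic condition-specific regulatory network obeying the
#' orientation rules (TF may regulate anything, mRNA only mRNAs); a decoy
#' directed PPI that contains every planted edge plus random decoy edges
#' absent from the condition; and two-condition expression data in which
#' each target gene is a linear function of its planted regulators plus
#' Gaussian noise, with condition-specific mean shifts on a set of
#' differentially expressed genes.
#'
#' The planted network is modular: genes are partitioned into regulatory
#' modules of about `module_size` genes each, and planted edges connect
#' only genes within a module. This mirrors the sparse, locally organised
#' structure of real regulatory programs and keeps genes in different
#' modules statistically independent. Each root gene is drawn i.i.d.
#' standard normal per sample; each target is `regulator_weight` times the
#' mean of its regulators plus `N(0, noise_sd^2)`, evaluated in
#' topological order; a per-gene baseline (uniform on 6-10 log2 units, the
#' microarray intensity range) is added; disease samples get `de_shift`
#' added on the planted DE genes.
#'
#' @param seed RNG seed; the whole object is reproducible from it
#' @param n_tf,n_mrna catalog sizes (defaults 50 TFs, 300 mRNAs)
#' @param n_samples_per_condition samples per condition (default 60)
#' @param module_size approximate genes per regulatory module (default 8)
#' @param planted_parents mean number of planted regulators per non-root
#'   gene (default 1.2, capped at `max_parents`)
#' @param max_parents cap on regulators per gene (default 2)
#' @param edge_density decoy PPI edges as a multiple of planted edges
#'   (default 2)
#' @param regulator_weight linear effect of the mean regulator signal on a
#'   target (default 0.9)
#' @param noise_sd residual standard deviation per target (default 0.3)
#' @param n_de number of differentially expressed genes (default 50)
#' @param de_shift log2 mean shift applied to DE genes in the disease
#'   condition (default 1.0)
#' @param conditions labels for the two conditions
#'   (default `c("disease", "control")`)
#' @return list with `truth` (list: `catalog`, `true_network`,
#'   `decoy_ppi`, `de_genes` data.frame) and `dataset`
#'   (an [expression_dataset()] holding both conditions)
#' @export
simulate_regulatory_system <- function(seed = 1L, n_tf = 50L, n_mrna = 300L,
                                       n_samples_per_condition = 60L,
                                       module_size = 8L,
                                       planted_parents = 1.2,
                                       max_parents = 2L,
                                       edge_density = 2,
                                       regulator_weight = 0.9,
                                       noise_sd = 0.3,
                                       n_de = 50L, de_shift = 1.0,
                                       conditions = c("disease", "control")) {
  stopifnot(n_tf > 0L, n_mrna > 0L, n_samples_per_condition > 1L,
            regulator_weight > 0, noise_sd > 0, length(conditions) == 2L,
            conditions[1L] != conditions[2L])
  set.seed(seed)
  genes <- c(sprintf("TF%03d", seq_len(n_tf)),
             sprintf("M%04d", seq_len(n_mrna)))
  ng <- length(genes)
  is_tf <- c(rep(TRUE, n_tf), rep(FALSE, n_mrna))

  # planted modular DAG in the order TFs then mRNAs; parents of a TF must
  # be TFs (no mRNA -> TF edge), parents of an mRNA may be any earlier
  # gene of the same module; modules are mutually unconnected, so genes
  # in different modules are independent by construction.
  n_modules <- max(1L, round(ng / module_size))
  module <- sort(rep_len(seq_len(n_modules), ng))
  # interleave TFs across modules: assign module labels to a random
  # permutation within the TF block and the mRNA block separately
  module <- c(sample(module[seq_len(n_tf)]),
              sample(module[n_tf + seq_len(n_mrna)]))
  parents <- vector("list", ng)
  for (i in seq_len(ng)[-1L]) {
    eligible <- seq_len(if (is_tf[i]) min(i - 1L, n_tf) else i - 1L)
    eligible <- eligible[module[eligible] == module[i]]
    k <- min(stats::rpois(1L, planted_parents), max_parents,
             length(eligible))
    if (k > 0L)
      parents[[i]] <- sort(eligible[sample.int(length(eligible), k)])
  }
  true_edges <- do.call(rbind, lapply(seq_len(ng), function(i) {
    if (length(parents[[i]]) == 0L) return(NULL)
    data.frame(from = genes[parents[[i]]], to = genes[i],
               stringsAsFactors = FALSE)
  }))
  true_network <- interaction_set(true_edges)

  # decoy PPI: true edges plus random ordered decoy pairs not planted
  n_true <- n_edges(true_network)
  n_decoy <- round(edge_density * n_true)
  decoys <- data.frame(from = character(), to = character(),
                       stringsAsFactors = FALSE)
  if (n_decoy > 0L) {
    seen <- edge_keys(true_network$edges)
    out <- vector("list", n_decoy)
    got <- 0L
    while (got < n_decoy) {
      a <- sample.int(ng, 1L)
      b <- sample.int(ng, 1L)
      if (a == b) next
      key <- paste(genes[a], genes[b], sep = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      got <- got + 1L
      out[[got]] <- c(genes[a], genes[b])
    }
    m <- do.call(rbind, out)
    decoys <- data.frame(from = m[, 1], to = m[, 2],
                         stringsAsFactors = FALSE)
  }
  decoy_ppi <- interaction_set(rbind(true_network$edges, decoys))

  de_idx <- sort(sample.int(ng, min(n_de, ng)))
  de_genes <- data.frame(gene_id = genes[de_idx], shift = de_shift,
                         stringsAsFactors = FALSE)

  n_total <- 2L * n_samples_per_condition
  vals <- matrix(0, nrow = ng, ncol = n_total)
  for (i in seq_len(ng)) {
    if (length(parents[[i]]) == 0L) {
      vals[i, ] <- stats::rnorm(n_total)
    } else {
      sig <- colMeans(vals[parents[[i]], , drop = FALSE])
      vals[i, ] <- regulator_weight * sig +
        stats::rnorm(n_total, sd = noise_sd)
    }
  }
  baseline <- stats::runif(ng, 6, 10)
  vals <- vals + baseline
  condition <- rep(conditions, each = n_samples_per_condition)
  vals[de_idx, condition == conditions[1L]] <-
    vals[de_idx, condition == conditions[1L]] + de_shift
  rownames(vals) <- genes
  colnames(vals) <- sprintf("S%03d", seq_len(n_total))
  ga <- round(stats::runif(n_total, 28, 41), 1)

  dataset <- expression_dataset(vals, is_tf = is_tf, condition = condition,
                                gestational_age_weeks = ga)
  list(truth = list(catalog = data.frame(gene_id = genes, is_tf = is_tf,
                                         stringsAsFactors = FALSE),
                    true_network = true_network,
                    decoy_ppi = decoy_ppi,
                    de_genes = de_genes),
       dataset = dataset)
}

#' Write simulated inputs to a directory
#'
#' Materialises a simulation as the four pipeline input files plus a
#' ground-truth JSON (`expr.tsv`, `meta.tsv`, `tf_list.txt`, `ppi.tsv`,
#' `truth.json`).
#'
#' @param sim output of [simulate_regulatory_system()]
#' @param dir output directory (created if needed)
#' @return invisibly, `dir`
#' @export
write_synthetic_inputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(sim$dataset,
                   file.path(dir, "expr.tsv"),
                   file.path(dir, "meta.tsv"),
                   file.path(dir, "tf_list.txt"))
  write_interactions(sim$truth$decoy_ppi, file.path(dir, "ppi.tsv"))
  truth <- list(
    true_edges = sim$truth$true_network$edges,
    de_genes = sim$truth$de_genes
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns")
  invisible(dir)
}

#' Built-in toy networks
#'
#' Small hand-built directed networks used throughout the documentation
#' and tests: the worked 4-node example for the type-1 scheme (edges
#' 1->3, 3->2, 3->4: two minimum driver sets \{1,2\} and \{1,4\}; node 1
#' critical, 2 and 4 ordinary, 3 redundant), the worked 4-node example
#' for the type-2 scheme (edges 1->3, 2->3, 3->4: baseline |MDNS| = 2;
#' deleting node 3 raises it to 3, deleting 1 or 2 lowers it to 1,
#' deleting 4 leaves it at 2), and chain / star / 2-cycle
#' micro-fixtures.
#'
#' @return named list of [interaction_set()]s: `type1_example`,
#'   `type2_example`, `chain`, `star`, `two_cycle`
#' @export
toy_networks <- function() {
  list(
    type1_example = interaction_set(data.frame(
      from = c("1", "3", "3"), to = c("3", "2", "4"),
      stringsAsFactors = FALSE)),
    type2_example = interaction_set(data.frame(
      from = c("1", "2", "3"), to = c("3", "3", "4"),
      stringsAsFactors = FALSE)),
    chain = interaction_set(data.frame(
      from = c("1", "2"), to = c("2", "3"), stringsAsFactors = FALSE)),
    star = interaction_set(data.frame(
      from = c("c", "c"), to = c("a", "b"), stringsAsFactors = FALSE)),
    two_cycle = interaction_set(data.frame(
      from = c("1", "2"), to = c("2", "1"), stringsAsFactors = FALSE))
  )
}
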