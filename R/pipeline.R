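#' Pipeline run configuration
#'
#' Collects the input paths, condition labels, thresholds and seeds for an
#' end-to-end run. Serialises to/from YAML; the configuration actually
#' used is echoed into the output directory.
#'
#' @param expr,meta,tf_list,ppi paths to the four inputs (see
#'   [read_expression()] and [read_interactions()])
#' @param condition,control condition labels for the disease and control
#'   groups (must differ)
#' @param ga_min_weeks,ga_max_weeks,require_ga gestational-age filter for
#'   the disease group (see [filter_samples()]); the 34-week cutoff splits
#'   early- from late-onset disease
#' @param control_ga_min_weeks optional lower gestational-age bound for
#'   controls (term controls only, e.g. 34)
#' @param alpha_correlation,alpha_de significance thresholds in (0, 1)
#' @param universe correlation-test universe, `"all_pairs"` or
#'   `"ppi_pairs"`
#' @param order ranking order, `"signed"` or `"absolute"`
#' @param moderation DE moderation, `"empirical_bayes"` or `"none"`
#' @param log2_transform apply `log2(x + 1)` on loading
#' @param n_bootstrap bootstrap replicates for the power-law fits
#' @param seed seed for all randomised routines
#' @param out_dir output directory
#' @return an object of class `run_config` (a named list)
#' @export
run_config <- function(expr, meta, tf_list, ppi,
                       condition = "disease", control = "control",
                       ga_min_weeks = NULL, ga_max_weeks = NULL,
                       require_ga = FALSE, control_ga_min_weeks = NULL,
                       alpha_correlation = 0.05, alpha_de = 0.05,
                       universe = "all_pairs", order = "signed",
                       moderation = "empirical_bayes",
                       log2_transform = FALSE,
                       n_bootstrap = 200L, seed = 1L, out_dir = "ctrlgrn_out") {
  cfg <- list(expr = expr, meta = meta, tf_list = tf_list, ppi = ppi,
              condition = condition, control = control,
              ga_min_weeks = ga_min_weeks, ga_max_weeks = ga_max_weeks,
              require_ga = isTRUE(require_ga),
              control_ga_min_weeks = control_ga_min_weeks,
              alpha_correlation = alpha_correlation, alpha_de = alpha_de,
              universe = universe, order = order, moderation = moderation,
              log2_transform = isTRUE(log2_transform),
              n_bootstrap = as.integer(n_bootstrap), seed = as.integer(seed),
              out_dir = out_dir)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  if (identical(cfg$condition, cfg$control))
    stop("disease and control condition labels must differ")
  for (th in c("alpha_correlation", "alpha_de"))
    if (!(cfg[[th]] > 0 && cfg[[th]] < 1))
      stop(th, " must lie in (0, 1)")
  if (!cfg$universe %in% c("all_pairs", "ppi_pairs"))
    stop("universe must be 'all_pairs' or 'ppi_pairs'")
  if (!cfg$order %in% c("signed", "absolute"))
    stop("order must be 'signed' or 'absolute'")
  if (!cfg$moderation %in% c("empirical_bayes", "none"))
    stop("moderation must be 'empirical_bayes' or 'none'")
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#' @param path YAML file
#' @return a `run_config`
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' @rdname read_config
#' @param cfg a `run_config`
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}

fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.6g", x))

write_tsv_out <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes the four stages end to end — network construction,
#' controllability classification, differential-expression ranking and the
#' comparator network metrics — and writes `network.tsv`, `classes.tsv`,
#' `ranked.tsv`, `metrics.tsv`, `summary.json`, `config.yaml` and
#' `run.log` to the configured output directory. All floating-point output
#' is formatted to fixed precision, so identical inputs and seeds give
#' byte-identical outputs.
#'
#' @param cfg a [run_config()]
#' @return invisibly, a list with the in-memory results (`network`,
#'   `classes`, `de`, `ranked`, `metrics`, `summary`)
#' @export
run_pipeline <- function(cfg) {
  validate_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  t0 <- Sys.time()
  stage <- function(name, expr) {
    st <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
    log_lines <<- c(log_lines,
                    sprintf("stage %-14s %8.2fs", name,
                            as.numeric(Sys.time() - st, units = "secs")))
    res
  }

  ds <- stage("load", read_expression(cfg$expr, cfg$meta, cfg$tf_list,
                                      log2_transform = cfg$log2_transform))
  ppi <- stage("load-ppi", read_interactions(cfg$ppi))
  ds_disease <- stage("filter-disease",
                      filter_samples(ds, cfg$condition,
                                     ga_min_weeks = cfg$ga_min_weeks,
                                     ga_max_weeks = cfg$ga_max_weeks,
                                     require_ga = cfg$require_ga))
  ds_control <- stage("filter-control",
                      filter_samples(ds, cfg$control,
                                     ga_min_weeks = cfg$control_ga_min_weeks))

  rn <- stage("build-network",
              build_network(ds_disease, ppi, alpha = cfg$alpha_correlation,
                            universe = cfg$universe))
  net <- rn$interactions
  classes <- stage("control", classify_nodes(net))
  de <- stage("de", differential_expression(ds_disease, ds_control,
                                            moderation = cfg$moderation))
  ranked <- stage("rank", rank_critical_genes(classes, de,
                                              order = cfg$order,
                                              alpha = cfg$alpha_de))
  hub <- stage("hub", hub_scores(net))
  bc <- stage("betweenness", betweenness_scores(net))
  sf <- stage("powerlaw", assess_scale_free(net,
                                            n_bootstrap = cfg$n_bootstrap,
                                            seed = cfg$seed))
  metrics <- data.frame(gene_id = net$nodes,
                        hub_score = unname(hub[net$nodes]),
                        bc_score = unname(bc[net$nodes]),
                        stringsAsFactors = FALSE)
  metrics <- merge(metrics,
                   classes[, c("node", "in_degree", "out_degree", "degree")],
                   by.x = "gene_id", by.y = "node")
  metrics <- metrics[order(metrics$gene_id), , drop = FALSE]

  cat_pct <- function(col) {
    tab <- table(factor(col, levels = c("critical", "ordinary",
                                        "redundant")))
    as.list(round(100 * tab / max(sum(tab), 1L), 2))
  }
  summary <- list(
    n_nodes = length(net$nodes),
    n_edges = n_edges(net),
    network = rn$summary,
    mdns_size = attr(classes, "mdns_size"),
    n_drivers = sum(classes$is_driver),
    type1_pct = cat_pct(classes$type1),
    type2_pct = cat_pct(classes$type2),
    n_critical_genes = nrow(ranked),
    n_ranked_genes = sum(!is.na(ranked$rank)),
    scale_free = list(in_degree = sf$in_fit$scale_free,
                      out_degree = sf$out_fit$scale_free,
                      network = sf$scale_free,
                      lambda_in = round(sf$in_fit$lambda, 4),
                      lambda_out = round(sf$out_fit$lambda, 4),
                      gof_p_in = sf$in_fit$gof_p,
                      gof_p_out = sf$out_fit$gof_p),
    seed = cfg$seed
  )

  write_tsv_out(rn$provenance, file.path(cfg$out_dir, "network.tsv"))
  write_tsv_out(classes, file.path(cfg$out_dir, "classes.tsv"))
  write_tsv_out(ranked, file.path(cfg$out_dir, "ranked.tsv"))
  write_tsv_out(metrics, file.path(cfg$out_dir, "metrics.tsv"))
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_config(cfg, file.path(cfg$out_dir, "config.yaml"))
  log_lines <- c(log_lines, sprintf("total %21.2fs",
                                    as.numeric(Sys.time() - t0,
                                               units = "secs")))
  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))

  invisible(list(network = rn, classes = classes, de = de, ranked = ranked,
                 metrics = metrics, summary = summary))
}
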