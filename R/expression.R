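#' Expression dataset with gene catalog and sample metadata
#'
#' Container for a genes x samples matrix of log2-scale expression values,
#' a gene catalog flagging transcription-factor (TF) genes, and per-sample
#' metadata (condition label, optional gestational age in weeks). Genes not
#' in the TF list are treated as (non-TF) mRNAs, so the TF and mRNA subsets
#' partition the catalog.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids); no missing values.
#' @param is_tf logical vector (named by gene or in row order) flagging
#'   TF genes.
#' @param condition character vector of per-sample condition labels.
#' @param gestational_age_weeks optional numeric vector of per-sample
#'   gestational ages (weeks); `NA` = unknown.
#'
#' @return an object of class `expression_dataset` with elements `values`,
#'   `genes` (data.frame: `gene_id`, `is_tf`) and `samples` (data.frame:
#'   `sample_id`, `condition`, `gestational_age_weeks`).
#' @export
expression_dataset <- function(values, is_tf, condition,
                               gestational_age_weeks = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene rownames and sample colnames")
  gene_id <- rownames(values)
  if (anyDuplicated(gene_id))
    stop("duplicate gene id(s): ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id(s): ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (any(!nzchar(gene_id))) stop("empty gene id")
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (!is.null(names(is_tf))) is_tf <- is_tf[gene_id]
  is_tf <- as.logical(is_tf)
  if (length(is_tf) != nrow(values) || anyNA(is_tf))
    stop("is_tf must give one TRUE/FALSE per gene")
  if (length(condition) != ncol(values))
    stop("condition must give one label per sample")
  if (is.null(gestational_age_weeks))
    gestational_age_weeks <- rep(NA_real_, ncol(values))
  if (length(gestational_age_weeks) != ncol(values))
    stop("gestational_age_weeks must give one value per sample")
  if (any(gestational_age_weeks < 0, na.rm = TRUE))
    stop("gestational ages must be non-negative")
  structure(list(
    values = values,
    genes = data.frame(gene_id = gene_id, is_tf = is_tf,
                       stringsAsFactors = FALSE),
    samples = data.frame(sample_id = colnames(values),
                         condition = as.character(condition),
                         gestational_age_weeks =
                           as.numeric(gestational_age_weeks),
                         stringsAsFactors = FALSE)
  ), class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", nrow(x$values), "genes (",
      sum(x$genes$is_tf), "TFs ) x", ncol(x$values), "samples\n")
  cat("conditions:", paste(sprintf("%s=%d", names(table(x$samples$condition)),
                                   table(x$samples$condition)),
                           collapse = ", "), "\n")
  invisible(x)
}

read_tsv_table <- function(path, ...) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Read an expression dataset from TSV files
#'
#' @param path expression TSV: header row of sample ids, first column gene
#'   ids, tab-separated, `#` comments ignored.
#' @param metadata_path sample metadata TSV with columns `sample_id`,
#'   `condition` and optionally `gestational_age_weeks`.
#' @param tf_list_path plain-text transcription-factor list, one gene
#'   symbol per line; genes absent from it are mRNAs.
#' @param log2_transform if `TRUE`, apply `log2(x + 1)` to the matrix
#'   (for raw-intensity inputs); by default values are assumed to be on
#'   the log2 scale already.
#' @return an [expression_dataset()]
#' @details Samples present in the expression matrix but missing from the
#'   metadata are a hard error naming the offender; metadata rows for
#'   unknown samples are ignored with a warning. Gene rows containing
#'   missing values are dropped with a message reporting the count.
#' @export
read_expression <- function(path, metadata_path, tf_list_path,
                            log2_transform = FALSE) {
  tab <- read_tsv_table(path)
  if (ncol(tab) < 2L) stop("expression table needs gene ids plus >=1 sample")
  gene_id <- as.character(tab[[1L]])
  if (anyDuplicated(gene_id))
    stop("duplicate gene id(s) in ", path, ": ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- gene_id
  incomplete <- !stats::complete.cases(values)
  if (any(incomplete)) {
    message("read_expression: dropped ", sum(incomplete),
            " gene row(s) with missing values")
    values <- values[!incomplete, , drop = FALSE]
  }
  if (log2_transform) values <- log2(values + 1)

  meta <- read_tsv_table(metadata_path)
  if (!all(c("sample_id", "condition") %in% names(meta)))
    stop("metadata must have columns sample_id and condition")
  meta$sample_id <- as.character(meta$sample_id)
  missing_meta <- setdiff(colnames(values), meta$sample_id)
  if (length(missing_meta) > 0L)
    stop("sample(s) without metadata: ", paste(missing_meta, collapse = ", "))
  unknown <- setdiff(meta$sample_id, colnames(values))
  if (length(unknown) > 0L)
    warning("metadata for unknown sample(s) ignored: ",
            paste(unknown, collapse = ", "))
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  ga <- if ("gestational_age_weeks" %in% names(meta))
    suppressWarnings(as.numeric(meta$gestational_age_weeks)) else NULL

  tfs <- readLines(tf_list_path)
  tfs <- trimws(tfs)
  tfs <- tfs[nzchar(tfs) & !startsWith(tfs, "#")]
  expression_dataset(values, is_tf = rownames(values) %in% tfs,
                     condition = meta$condition,
                     gestational_age_weeks = ga)
}

#' Write an expression dataset to TSV files
#'
#' Inverse of [read_expression()]; numeric values are written with full
#' precision (`%.10g`) so a write/read cycle is lossless at TSV precision.
#'
#' @param ds an `expression_dataset`
#' @param path,metadata_path,tf_list_path output files (see
#'   [read_expression()] for their formats)
#' @return invisibly, `path`
#' @export
write_expression <- function(ds, path, metadata_path, tf_list_path) {
  tab <- data.frame(gene_id = rownames(ds$values),
                    apply(ds$values, 2, function(x) sprintf("%.10g", x)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(tab) <- c("gene_id", colnames(ds$values))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$samples, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(ds$genes$gene_id[ds$genes$is_tf], tf_list_path)
  invisible(path)
}

#' Subset samples by condition and gestational-age window
#'
#' Selects the samples of one condition, optionally restricted to a
#' gestational-age window (weeks). This is how early-/late-onset disease
#' subsets are expressed: e.g. `ga_max_weeks = 34` (exclusive upper bound
#' via `ga_min_weeks` on the complementary subset) splits at the
#' 34-week cutoff.
#'
#' @param ds an `expression_dataset`
#' @param condition the condition label to keep
#' @param ga_min_weeks,ga_max_weeks optional inclusive lower / exclusive
#'   upper gestational-age bounds; samples with unknown age fail any bound.
#' @param require_ga if `TRUE`, samples with unknown gestational age are
#'   dropped even when no bound is given.
#' @return a new `expression_dataset` (the input is never modified)
#' @export
filter_samples <- function(ds, condition, ga_min_weeks = NULL,
                           ga_max_weeks = NULL, require_ga = FALSE) {
  if (!condition %in% ds$samples$condition)
    stop("no samples with condition '", condition, "'")
  keep <- ds$samples$condition == condition
  ga <- ds$samples$gestational_age_weeks
  if (require_ga || !is.null(ga_min_weeks) || !is.null(ga_max_weeks))
    keep <- keep & !is.na(ga)
  if (!is.null(ga_min_weeks)) keep <- keep & !is.na(ga) & ga >= ga_min_weeks
  if (!is.null(ga_max_weeks)) keep <- keep & !is.na(ga) & ga < ga_max_weeks
  if (!any(keep))
    stop("sample filter left no samples (condition '", condition, "')")
  expression_dataset(ds$values[, keep, drop = FALSE],
                     is_tf = ds$genes$is_tf,
                     condition = ds$samples$condition[keep],
                     gestational_age_weeks = ga[keep])
}
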