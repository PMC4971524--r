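#' Median-of-ratios scaling factors
#'
#' The "scaling factor" normalisation for RNA-seq counts: the reference for
#' each gene is its geometric mean across samples (genes with any zero count
#' are excluded from the reference), each sample's factor is the median over
#' genes of count/reference, and the factors are rescaled to geometric mean 1
#' for identifiability. Normalised expression is count / factor.
#'
#' @param x a [count_matrix].
#' @return named numeric vector of per-sample factors (geometric mean 1).
#' @export
compute_scaling_factors <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  cnt <- x$counts
  usable <- rowSums(cnt == 0) == 0L
  if (!any(usable))
    stop_cdc(paste("no gene has nonzero counts in every sample;",
                   "relax the expression filter or supply more data"))
  ref <- exp(rowMeans(log(cnt[usable, , drop = FALSE])))
  fac <- apply(cnt[usable, , drop = FALSE] / ref, 2, stats::median)
  fac <- fac / exp(mean(log(fac)))
  stats::setNames(fac, x$sample_ids)
}

#' Expression filter: keep genes reaching 1 count per million
#'
#' A gene is retained iff its CPM (count * 1e6 / library size) reaches
#' `threshold` in at least one sample — i.e. a gene is excluded only when it
#' stays below the threshold in every sample. Gene order is preserved and
#' library sizes are carried over unchanged (the CPM denominator remains the
#' total mapped reads of the unfiltered library).
#'
#' @param x a [count_matrix].
#' @param threshold CPM threshold (default 1).
#' @return filtered [count_matrix].
#' @export
filter_low_expression <- function(x, threshold = 1) {
  stopifnot(inherits(x, "count_matrix"))
  cpm <- sweep(x$counts, 2, x$library_sizes, "/") * 1e6
  keep <- rowSums(cpm >= threshold) > 0L
  count_matrix(x$counts[keep, , drop = FALSE],
               gene_ids = x$gene_ids[keep], sample_ids = x$sample_ids,
               library_sizes = x$library_sizes)
}

#' Log-scale normalised expression matrix
#'
#' value = log2(count / factor + pseudocount). The factors and pseudocount
#' are recorded on the result so downstream stages (clustering, PCA,
#' correlation mapping) are reproducible from the object alone.
#'
#' @param x a [count_matrix].
#' @param factors per-sample scaling factors, e.g. from
#'   [compute_scaling_factors()]; defaults to computing them.
#' @param pseudocount positive offset added before the log (default 1).
#' @return list of class `normalized_matrix` with elements `values`
#'   (genes x samples, log2 scale), `gene_ids`, `sample_ids`,
#'   `scaling_factors`, `pseudocount`, `log_transformed = TRUE`.
#' @export
log_normalize <- function(x, factors = compute_scaling_factors(x),
                          pseudocount = 1) {
  stopifnot(inherits(x, "count_matrix"))
  if (pseudocount <= 0) stop_cdc("pseudocount must be positive")
  if (length(factors) != length(x$sample_ids) || any(factors <= 0))
    stop_cdc("need one positive scaling factor per sample")
  vals <- log2(sweep(x$counts, 2, factors, "/") + pseudocount)
  structure(list(values = vals, gene_ids = x$gene_ids,
                 sample_ids = x$sample_ids,
                 scaling_factors = stats::setNames(factors, x$sample_ids),
                 pseudocount = pseudocount, log_transformed = TRUE),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d samples (log2, pseudocount %g)\n",
              nrow(x$values), ncol(x$values), x$pseudocount))
  invisible(x)
}

#' Select the most variable genes
#'
#' Top `k` genes by across-sample variance of the (log) expression values;
#' ties are broken by gene-id lexicographic order so the selection is
#' deterministic.
#'
#' @param x a `normalized_matrix`.
#' @param k number of genes to keep (`1 <= k <= n_genes`).
#' @return character vector of `k` gene ids, in decreasing-variance order.
#' @export
select_top_variable_genes <- function(x, k = 2000) {
  stopifnot(inherits(x, "normalized_matrix"))
  if (k <= 0) stop_cdc("k must be positive")
  if (k > nrow(x$values)) stop_cdc("k exceeds the number of genes")
  v <- apply(x$values, 1, stats::var)
  ord <- order(-v, x$gene_ids, method = "radix")
  x$gene_ids[ord[seq_len(k)]]
}

#' Write a normalised matrix as TSV with a YAML provenance sidecar
#'
#' @param x a `normalized_matrix`.
#' @param path TSV output path; the sidecar is written at `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_normalized_matrix <- function(x, path) {
  tab <- data.frame(gene_id = x$gene_ids, x$values,
                    check.names = FALSE, row.names = NULL)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(scaling_factors = as.list(x$scaling_factors),
                        pseudocount = x$pseudocount,
                        log_transformed = x$log_transformed),
                   paste0(path, ".yaml"))
  invisible(path)
}
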