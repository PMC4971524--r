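#' Gene-by-sample count matrix
#'
#' Container for raw RNA-seq gene counts: an integer matrix with unique gene
#' and sample identifiers plus per-sample library sizes. Library sizes default
#' to column sums of the (unfiltered) matrix, matching the counts-per-million
#' convention of "per million total mapped reads"; they are carried along
#' explicitly so that filtering a matrix does not change the CPM denominator.
#'
#' @param counts integer matrix, genes in rows, samples in columns. Dimnames
#'   are used as gene/sample ids when `gene_ids`/`sample_ids` are absent.
#' @param gene_ids,sample_ids character vectors of unique identifiers.
#' @param library_sizes positive per-sample totals; defaults to column sums.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `gene_ids`, `sample_ids`, `library_sizes`.
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         sample_ids = colnames(counts),
                         library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop_cdc("gene and sample identifiers are required")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(counts) != length(gene_ids) || ncol(counts) != length(sample_ids))
    stop_cdc("count matrix dimensions (%d x %d) do not match id lengths (%d, %d)",
             nrow(counts), ncol(counts), length(gene_ids), length(sample_ids))
  if (anyDuplicated(gene_ids))
    stop_cdc("duplicated gene id(s): %s",
             paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop_cdc("duplicated sample id(s): %s",
             paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (any(is.na(counts)) || any(counts < 0))
    stop_cdc("counts must be non-negative and complete")
  if (any(counts != round(counts)))
    stop_cdc("counts must be integers")
  storage.mode(counts) <- "double"  # keeps totals > .Machine$integer.max safe
  dimnames(counts) <- list(gene_ids, sample_ids)
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  library_sizes <- as.numeric(library_sizes)
  if (length(library_sizes) != ncol(counts) || any(library_sizes <= 0))
    stop_cdc("library_sizes must be positive, one per sample")
  names(library_sizes) <- sample_ids
  structure(list(counts = counts, gene_ids = gene_ids,
                 sample_ids = sample_ids, library_sizes = library_sizes),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              length(x$gene_ids), length(x$sample_ids)))
  cat(sprintf("library sizes: %s .. %s\n",
              format(min(x$library_sizes), big.mark = ","),
              format(max(x$library_sizes), big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix from TSV or MatrixMarket
#'
#' TSV layout: first column gene id, header row of sample ids. MatrixMarket
#' (`format = "mtx"`) expects sidecar files `<path>.genes` and `<path>.samples`
#' holding one id per line; implicit zeros are restored on densification.
#'
#' @param path file path.
#' @param format `"tsv"` or `"mtx"`.
#' @param library_sizes optional per-sample totals (defaults to column sums).
#' @return A [count_matrix].
#' @export
read_count_matrix <- function(path, format = c("tsv", "mtx"),
                              library_sizes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_cdc("file not found: %s", path)
  if (format == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character")
    if (ncol(tab) < 2L) stop_cdc("count TSV needs a gene column plus samples")
    gene_ids <- tab[[1L]]
    num <- suppressWarnings(
      vapply(tab[-1L], as.numeric, numeric(nrow(tab))))
    num <- matrix(num, nrow = nrow(tab),
                  dimnames = list(gene_ids, colnames(tab)[-1L]))
    if (any(is.na(num)))
      stop_cdc("non-numeric count entries in %s", path)
    mat <- num
  } else {
    m <- Matrix::readMM(path)
    genes_f <- paste0(path, ".genes")
    samples_f <- paste0(path, ".samples")
    if (!file.exists(genes_f) || !file.exists(samples_f))
      stop_cdc("missing MTX index sidecars %s / %s", genes_f, samples_f)
    gene_ids <- readLines(genes_f)
    sample_ids <- readLines(samples_f)
    mat <- as.matrix(m)
    dimnames(mat) <- list(gene_ids, sample_ids)
  }
  count_matrix(mat, library_sizes = library_sizes)
}

#' Write a count matrix as TSV or MatrixMarket
#'
#' @param x a [count_matrix].
#' @param path output path; for `"mtx"` the `.genes`/`.samples` sidecars are
#'   written next to it.
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "count_matrix"))
  if (format == "tsv") {
    tab <- data.frame(gene_id = x$gene_ids, x$counts,
                      check.names = FALSE, row.names = NULL)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), path)
    writeLines(x$gene_ids, paste0(path, ".genes"))
    writeLines(x$sample_ids, paste0(path, ".samples"))
  }
  invisible(path)
}

#' Sample annotation table
#'
#' Validates a sample-to-tissue-type assignment against the controlled
#' vocabulary used throughout the workflow.
#'
#' @param sample_id unique sample identifiers.
#' @param tissue_type per-sample label from [tissue_vocabulary()] (CDC,
#'   UTUC, NORMAL_KIDNEY, KIRC, KIRP, KICH, XP11RCC, BLADDER).
#' @param cohort optional free-text cohort label (defaults to tissue type).
#' @return data.frame with columns sample_id, tissue_type, cohort.
#' @export
sample_annotation <- function(sample_id, tissue_type, cohort = tissue_type) {
  sample_id <- as.character(sample_id)
  tissue_type <- as.character(tissue_type)
  if (anyDuplicated(sample_id))
    stop_cdc("duplicated sample_id in annotation")
  bad <- setdiff(unique(tissue_type), tissue_vocabulary())
  if (length(bad))
    stop_cdc("unknown tissue type(s): %s", paste(bad, collapse = ", "))
  if (length(tissue_type) != length(sample_id))
    stop_cdc("tissue_type must align with sample_id")
  data.frame(sample_id = sample_id, tissue_type = tissue_type,
             cohort = as.character(cohort), stringsAsFactors = FALSE)
}

#' Controlled vocabulary of tissue types
#' @return character vector of admissible tissue-type labels.
#' @export
tissue_vocabulary <- function() {
  c("CDC", "UTUC", "NORMAL_KIDNEY", "KIRC", "KIRP", "KICH",
    "XP11RCC", "BLADDER")
}
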