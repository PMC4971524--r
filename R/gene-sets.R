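#' Read a gene-set collection from a GMT file
#'
#' GMT is the tab-separated format used by MSigDB-style collections: one set
#' per line as `name<TAB>description<TAB>member1<TAB>member2...`. Blank lines
#' are skipped. Members duplicated within a set are deduplicated with a
#' warning, the common convention for GMT consumers.
#'
#' @param path GMT file.
#' @return A named list of class `gene_set_collection`; each element is a
#'   list with `description` and `genes`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop_cdc("file not found: %s", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop_cdc("GMT line %d ('%s') has no members", line_no[i], parts[1L])
    genes <- parts[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop_cdc("GMT line %d ('%s') has no members", line_no[i], parts[1L])
    if (anyDuplicated(genes)) {
      warn_cdc("gene set '%s': duplicated members deduplicated", parts[1L])
      genes <- unique(genes)
    }
    sets[[i]] <- list(description = parts[2L], genes = genes)
    nms[i] <- parts[1L]
  }
  names(sets) <- nms
  if (anyDuplicated(nms)) stop_cdc("duplicated set names in %s", path)
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param sets a `gene_set_collection` (or plain named list of character
#'   vectors, in which case descriptions default to `"na"`).
#' @param path output GMT file.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (is.character(s)) s <- list(description = "na", genes = s)
    paste(c(names(sets)[i], s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x, function(s) length(s$genes), integer(1))
  cat(sprintf("gene_set_collection: %d sets (sizes %d..%d)\n",
              length(x), min(sizes), max(sizes)))
  invisible(x)
}
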