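#' Hierarchical clustering of samples with Pearson distance and Ward linkage
#'
#' Samples are compared by d(i, j) = 1 - r(i, j), the Pearson correlation
#' distance over the supplied genes, and agglomerated with Ward's
#' minimum-variance rule via the Lance-Williams update applied to these
#' distances as given (the classical "ward" update on a non-Euclidean
#' distance — a methodological quirk of this workflow that is kept, not
#' corrected to a Euclidean embedding). With this update the merge heights
#' are provably monotone non-decreasing.
#'
#' @param x a `normalized_matrix`, or a plain genes x samples matrix.
#' @param genes optional gene ids to cluster on (e.g. from
#'   [select_top_variable_genes()]); default all genes.
#' @return object of class `c("pearson_ward", "hclust")`; usable with
#'   [cut_tree()], `stats::cutree`, `plot` etc.
#' @export
pearson_ward_cluster <- function(x, genes = NULL) {
  vals <- if (inherits(x, "normalized_matrix")) x$values else as.matrix(x)
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(vals))
    if (length(miss)) stop_cdc("unknown gene id(s): %s", miss[1])
    vals <- vals[genes, , drop = FALSE]
  }
  if (ncol(vals) < 2L) stop_cdc("need at least two samples")
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0))
    stop_cdc("constant expression profile for sample '%s'",
             colnames(vals)[which(sds == 0)[1]])
  d <- stats::as.dist(1 - stats::cor(vals))
  hc <- stats::hclust(d, method = "ward.D")
  class(hc) <- c("pearson_ward", "hclust")
  hc
}

#' Cut a dendrogram into k flat clusters
#'
#' Wraps `stats::cutree` with stable label numbering: clusters are numbered
#' by the position of their first leaf in the dendrogram's leaf order, so
#' cluster 1 always contains the leftmost leaf.
#'
#' @param dend an `hclust`-like tree (e.g. from [pearson_ward_cluster()]).
#' @param k number of clusters, `1 <= k <= n`.
#' @return named integer vector of cluster labels per sample.
#' @export
cut_tree <- function(dend, k) {
  n <- length(dend$labels)
  if (k < 1 || k > n) stop_cdc("k must lie in [1, %d]", n)
  cl <- stats::cutree(dend, k = k)
  first <- cl[dend$order]
  relabel <- stats::setNames(seq_along(unique(first)), unique(first))
  out <- as.integer(relabel[as.character(cl)])
  stats::setNames(out, names(cl))
}

#' Concordance between a clustering and reference labels
#'
#' Adjusted Rand index under the permutation model (chance-corrected pair
#' agreement) plus per-cluster purity (largest reference-label fraction).
#'
#' @param labels cluster assignment per sample.
#' @param reference reference partition (e.g. tissue types), same samples.
#' @return list with `ari`, `purity` (named per cluster), and the
#'   contingency `table`.
#' @export
cluster_concordance <- function(labels, reference) {
  if (length(labels) != length(reference))
    stop_cdc("partitions must cover the same samples")
  tab <- table(labels, reference)
  n <- sum(tab)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  maxidx <- (sum_a + sum_b) / 2
  ari <- if (maxidx == expected) 1 else (sum_ij - expected) / (maxidx - expected)
  purity <- apply(tab, 1, function(r) max(r) / sum(r))
  list(ari = ari, purity = purity, table = tab)
}

#' Principal component analysis of expression profiles
#'
#' Gene-centred SVD: each gene's mean across samples is removed, samples are
#' projected on the right singular vectors. Explained-variance fractions are
#' the squared singular values over their total. Sign convention: within
#' each component the largest-magnitude gene loading is positive.
#'
#' @param x a `normalized_matrix` or genes x samples matrix.
#' @param n_components number of components to return
#'   (`1 <= n_components <= min(genes, samples)`).
#' @return list with `scores` (samples x components), `loadings`
#'   (genes x components), `explained_variance` (fractions).
#' @export
run_pca <- function(x, n_components = 2) {
  vals <- if (inherits(x, "normalized_matrix")) x$values else as.matrix(x)
  if (n_components < 1) stop_cdc("n_components must be >= 1")
  if (n_components > min(dim(vals)))
    stop_cdc("n_components exceeds min(genes, samples)")
  centered <- vals - rowMeans(vals)
  sv <- svd(t(centered))  # samples x genes
  keep <- seq_len(n_components)
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], n_components)
  loadings <- sv$v[, keep, drop = FALSE]
  for (j in keep) {
    flip <- sign(loadings[which.max(abs(loadings[, j])), j])
    if (flip < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(colnames(vals), paste0("PC", keep))
  dimnames(loadings) <- list(rownames(vals), paste0("PC", keep))
  list(scores = scores, loadings = loadings,
       explained_variance = sv$d^2 / sum(sv$d^2))
}

#' Export a dendrogram as Newick and as a merge table
#'
#' @param dend an `hclust`-like tree.
#' @param newick_path optional path for the Newick rendering (heights as
#'   branch lengths, via `ape`).
#' @param merges_path optional path for a TSV of the merge history
#'   (`node_a`, `node_b`, `height`, `size`; negative entries are leaves).
#' @return list with the `newick` string and the merge data.frame.
#' @export
export_dendrogram <- function(dend, newick_path = NULL, merges_path = NULL) {
  phy <- ape::as.phylo(stats::as.hclust(dend))
  newick <- ape::write.tree(phy)
  sizes <- integer(nrow(dend$merge))
  for (i in seq_len(nrow(dend$merge))) {
    m <- dend$merge[i, ]
    sizes[i] <- sum(ifelse(m < 0, 1L, sizes[pmax(m, 1L)]))
  }
  merges <- data.frame(node_a = dend$merge[, 1], node_b = dend$merge[, 2],
                       height = dend$height, size = sizes)
  if (!is.null(newick_path)) writeLines(newick, newick_path)
  if (!is.null(merges_path))
    utils::write.table(merges, merges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(newick = newick, merges = merges)
}
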