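#' Hypergeometric over-representation analysis
#'
#' For each gene set, membership is first intersected with the universe;
#' the upper-tail hypergeometric probability of drawing at least the
#' observed overlap when sampling `|query|` genes from the universe is the
#' enrichment p-value. Benjamini-Hochberg adjustment is applied across the
#' tested sets. Sets disjoint from the universe are excluded with a warning;
#' the query must be a subset of the universe.
#'
#' @param query character vector of genes of interest (e.g. an up-regulated
#'   list).
#' @param universe character vector of all tested genes.
#' @param sets a `gene_set_collection` (or named list of character vectors).
#' @param min_size,max_size set-size bounds after universe intersection
#'   (defaults 5 and 500).
#' @return data.frame: `set`, `overlap`, `set_size`, `universe_size`,
#'   `query_size`, `p_value`, `q_value`, ordered by p.
#' @export
hypergeom_enrich <- function(query, universe, sets,
                             min_size = 5, max_size = 500) {
  query <- unique(query)
  universe <- unique(universe)
  if (!length(query) || !length(universe))
    stop_cdc("query and universe must be non-empty")
  if (length(setdiff(query, universe)))
    stop_cdc("query contains genes outside the universe")
  members <- lapply(sets, function(s) if (is.list(s)) s$genes else s)
  members <- lapply(members, intersect, universe)
  sizes <- lengths(members)
  empty <- sizes == 0L
  if (any(empty)) {
    warn_cdc("%d set(s) disjoint from the universe excluded", sum(empty))
  }
  keep <- !empty & sizes >= min_size & sizes <= max_size
  members <- members[keep]
  if (!length(members))
    return(data.frame(set = character(), overlap = integer(),
                      set_size = integer(), universe_size = integer(),
                      query_size = integer(), p_value = numeric(),
                      q_value = numeric()))
  N <- length(universe)
  n <- length(query)
  res <- do.call(rbind, lapply(names(members), function(nm) {
    K <- length(members[[nm]])
    k <- length(intersect(members[[nm]], query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, universe_size = N,
               query_size = n, p_value = p, stringsAsFactors = FALSE)
  }))
  res$q_value <- adjust_bh(res$p_value)
  res[order(res$p_value), ]
}

## weighted running-sum enrichment score over a ranked list.
## hit_idx: positions of set members in the ranking; scores aligned with the
## ranking (used only through |score|^weight at the hit positions).
running_sum_es <- function(n, hit_idx, hit_weights) {
  steps <- rep(-1 / (n - length(hit_idx)), n)
  steps[hit_idx] <- hit_weights / sum(hit_weights)
  cum <- cumsum(steps)
  i <- which.max(abs(cum))
  list(es = cum[i], position = i, running = cum)
}

#' Preranked gene-set enrichment (weighted running sum)
#'
#' Walks the ranking from top to bottom accumulating |score|^weight
#' (normalised to sum 1 over the set) at set members and -1/(N - Nh) at
#' non-members; the enrichment score ES is the extremum of the running sum.
#' The null is by gene-label permutation: set membership is reassigned to
#' random positions, holding the ranking fixed. NES is ES divided by the
#' mean |null ES| of the same sign, and the nominal p is the empirical
#' two-sided tail `(1 + #{|ES_null| >= |ES|}) / (n_permutations + 1)`. The
#' leading edge is the set members at or before (after, for negative ES)
#' the extremum. Deterministic under `seed`.
#'
#' @param scores named numeric vector: ranking metric per gene (e.g. the
#'   Wald statistic); names must be unique. Genes are ranked by decreasing
#'   score.
#' @param set character vector of member genes; the part present in the
#'   ranking must be non-empty and a proper subset of it.
#' @param weight exponent on |score| (0 = classic Kolmogorov-Smirnov-like,
#'   1 = weighted; default 1).
#' @param n_permutations permutations for the null (default 1000).
#' @param seed integer RNG seed.
#' @return list of class `gsea_result`: `set_size` (members in ranking),
#'   `es`, `nes`, `p_value`, `q_value` (equal to `p_value` for a single
#'   set; see [gsea_collection()]), `leading_edge`, `n_permutations`.
#' @export
gsea_preranked <- function(scores, set, weight = 1, n_permutations = 1000,
                           seed = 1L) {
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop_cdc("scores must be uniquely named by gene")
  ord <- order(scores, decreasing = TRUE)
  ranked <- names(scores)[ord]
  s <- abs(scores[ord])^weight
  n <- length(ranked)
  in_set <- ranked %in% set
  nh <- sum(in_set)
  if (nh == 0L) stop_cdc("set has no genes in the ranking")
  if (nh == n) stop_cdc("set covers the whole ranking; misses undefined")
  hit_idx <- which(in_set)
  obs <- running_sum_es(n, hit_idx, s[hit_idx])
  null_es <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      idx <- sort(sample.int(n, nh))
      running_sum_es(n, idx, s[idx])$es
    }, numeric(1))
  })
  same_sign <- null_es[sign(null_es) == sign(obs$es)]
  nes <- if (length(same_sign)) obs$es / mean(abs(same_sign)) else NA_real_
  p <- (1 + sum(abs(null_es) >= abs(obs$es))) / (n_permutations + 1)
  leading <- if (obs$es >= 0) {
    ranked[hit_idx[hit_idx <= obs$position]]
  } else {
    ranked[hit_idx[hit_idx >= obs$position]]
  }
  structure(list(set_size = nh, es = obs$es, nes = nes, p_value = p,
                 q_value = p, leading_edge = leading,
                 n_permutations = n_permutations),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("GSEA: ES %.3f (NES %.3f), p = %.4g, %d members, leading edge %d\n",
              x$es, x$nes, x$p_value, x$set_size, length(x$leading_edge)))
  invisible(x)
}

#' Preranked GSEA over a collection, with FDR across sets
#'
#' Runs [gsea_preranked()] for every set in the collection (after filtering
#' by in-ranking size) and applies Benjamini-Hochberg adjustment across the
#' sets' nominal p-values.
#'
#' @param scores named ranking metric (see [gsea_preranked()]).
#' @param sets a `gene_set_collection` or named list of character vectors.
#' @param weight,n_permutations,seed passed through.
#' @param min_size,max_size bounds on in-ranking set size (defaults 5, 500).
#' @return data.frame: `set`, `set_size`, `es`, `nes`, `p_value`, `q_value`.
#' @export
gsea_collection <- function(scores, sets, weight = 1, n_permutations = 1000,
                            seed = 1L, min_size = 5, max_size = 500) {
  members <- lapply(sets, function(s) if (is.list(s)) s$genes else s)
  ssize <- vapply(members, function(g) sum(names(scores) %in% g), integer(1))
  keep <- ssize >= min_size & ssize <= max_size
  members <- members[keep]
  res <- do.call(rbind, lapply(seq_along(members), function(i) {
    r <- gsea_preranked(scores, members[[i]], weight = weight,
                        n_permutations = n_permutations,
                        seed = derive_seed(seed, names(members)[i]))
    data.frame(set = names(members)[i], set_size = r$set_size, es = r$es,
               nes = r$nes, p_value = r$p_value, stringsAsFactors = FALSE)
  }))
  if (is.null(res)) stop_cdc("no set passed the size filter")
  res$q_value <- adjust_bh(res$p_value)
  res[order(res$p_value), ]
}
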