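# Independent brute-force oracles used to validate the package's
# implementations. Deliberately naive; kept free of any package internals.

# Benjamini-Hochberg step-up from the definition.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q_sorted <- sapply(seq_len(m), function(j) min(1, min(m * ps[j:m] / (j:m))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# O(n^3) re-scan Ward agglomeration with the Lance-Williams update applied
# to the supplied distances; ties broken by the smallest (i, j) index pair.
# Returns merge heights and the leaf sets merged at every step.
ward_oracle <- function(d) {
  D <- as.matrix(d)
  n <- nrow(D)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(n - 1)
  merged_sets <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA)
    best_d <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        i <- active[ii]; j <- active[jj]
        if (D[i, j] < best_d - 1e-12) {
          best_d <- D[i, j]; best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- best_d
    new_members <- sort(c(members[[i]], members[[j]]))
    merged_sets[[step]] <- new_members
    for (k in active) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <-
        ((sizes[i] + sizes[k]) * D[i, k] + (sizes[j] + sizes[k]) * D[j, k] -
           sizes[k] * D[i, j]) / (sizes[i] + sizes[j] + sizes[k])
    }
    members[[i]] <- new_members
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  list(heights = heights, merged_sets = merged_sets)
}

# leaf sets merged at each step of an hclust tree
hclust_merge_sets <- function(hc) {
  n <- length(hc$labels %||% seq_len(nrow(hc$merge) + 1))
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    grab <- function(x) if (x < 0) -x else sets[[x]]
    sets[[i]] <- sort(c(grab(hc$merge[i, 1]), grab(hc$merge[i, 2])))
  }
  sets
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force weighted running-sum enrichment score
es_oracle <- function(scores, set, weight) {
  ord <- order(scores, decreasing = TRUE)
  genes <- names(scores)[ord]
  s <- abs(scores[ord])^weight
  hits <- genes %in% set
  nr <- sum(s[hits])
  run <- 0
  best <- 0
  for (i in seq_along(genes)) {
    run <- run + if (hits[i]) s[i] / nr else -1 / (length(genes) - sum(hits))
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# exact Mann-Whitney two-sided p by enumeration of all group assignments,
# mirroring the doubled-tail convention of the exact test
mann_whitney_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">"))
  combos <- utils::combn(n, na)
  us <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  u_obs <- u_of(a, b)
  mu <- na * length(b) / 2
  p <- if (u_obs > mu) 2 * mean(us >= u_obs) else 2 * mean(us <= u_obs)
  list(u = u_obs, p = min(1, p))
}

# upper-tail hypergeometric probability by explicit combinatorial counting
hyper_tail_oracle <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# adjusted Rand index from the contingency-table closed form
ari_oracle <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  exp_ <- sa * sb / choose(n, 2)
  max_ <- (sa + sb) / 2
  if (max_ == exp_) return(1)
  (sij - exp_) / (max_ - exp_)
}

# small planted three-tissue simulation used by clustering tests
plant_three_tissues <- function(seed, n_genes = 1000) {
  spec <- list(
    lfc_entry(1:100, c("UTUC", "CDC"), 3),
    lfc_entry(1:100, c("UTUC", "NORMAL_KIDNEY"), 3),
    lfc_entry(101:200, c("UTUC", "CDC"), -3),
    lfc_entry(101:200, c("UTUC", "NORMAL_KIDNEY"), -3),
    lfc_entry(201:260, c("CDC", "NORMAL_KIDNEY"), 2),
    lfc_entry(261:320, c("CDC", "NORMAL_KIDNEY"), -2))
  simulate_counts(simulation_config(
    n_genes = n_genes,
    group_sizes = c(CDC = 11, UTUC = 9, NORMAL_KIDNEY = 3),
    dispersion = 0.05, lfc_spec = spec, seed = seed))
}
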