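random_profiles <- function(n_samples, n_genes = 20) {
  m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  m
}

test_that("identical samples merge first at height zero", {
  m <- random_profiles(4)
  m[, 2] <- m[, 1]
  hc <- pearson_ward_cluster(m)
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  expect_setequal(abs(hc$merge[1, ]), c(1, 2))
})

test_that("constant profiles are rejected by name", {
  m <- random_profiles(3)
  m[, 2] <- 5
  expect_error(pearson_ward_cluster(m), "s2")
})

test_that("merge sequence matches a naive re-scan agglomeration oracle", {
  set.seed(42)
  for (i in 1:50) {
    m <- random_profiles(8)
    d <- as.dist(1 - cor(m))
    hc <- pearson_ward_cluster(m)
    oracle <- ward_oracle(d)
    expect_equal(hc$height, oracle$heights, tolerance = 1e-9)
    expect_equal(hclust_merge_sets(hc), oracle$merged_sets)
    # heights monotone non-decreasing for the Ward update
    expect_true(all(diff(hc$height) >= -1e-12))
  }
})

test_that("clustering is invariant to gene and sample permutations", {
  set.seed(5)
  m <- random_profiles(7, 30)
  hc <- pearson_ward_cluster(m)
  gp <- sample(nrow(m))
  hc_g <- pearson_ward_cluster(m[gp, ])
  expect_equal(hc$height, hc_g$height, tolerance = 1e-12)
  sp <- sample(ncol(m))
  hc_s <- pearson_ward_cluster(m[, sp])
  expect_equal(sort(hc$height), sort(hc_s$height), tolerance = 1e-12)
  k3_a <- cut_tree(hc, 3)
  k3_b <- cut_tree(hc_s, 3)[names(k3_a)]
  expect_equal(cluster_concordance(k3_a, k3_b)$ari, 1)
})

test_that("tree cuts behave at the extremes and on a toy topology", {
  m <- random_profiles(5)
  hc <- pearson_ward_cluster(m)
  expect_equal(length(unique(cut_tree(hc, 5))), 5)
  expect_equal(length(unique(cut_tree(hc, 1))), 1)
  expect_error(cut_tree(hc, 0), "k must")
  expect_error(cut_tree(hc, 6), "k must")

  # two tight pairs: k = 2 recovers {a,b}, {c,d}
  base <- rnorm(20)
  m2 <- cbind(a = base + rnorm(20, 0, 0.01), b = base + rnorm(20, 0, 0.01),
              c = -base + rnorm(20, 0, 0.01), d = -base + rnorm(20, 0, 0.01))
  cl <- cut_tree(pearson_ward_cluster(m2), 2)
  expect_equal(cl[["a"]], cl[["b"]])
  expect_equal(cl[["c"]], cl[["d"]])
  expect_false(cl[["a"]] == cl[["c"]])
  # first-leaf-order numbering: cluster 1 contains the leftmost leaf
  expect_equal(unname(cl[pearson_ward_cluster(m2)$order[1]]), 1L)
})

test_that("concordance matches the closed-form adjusted Rand index", {
  expect_equal(cluster_concordance(c(1, 1, 2, 2), c("x", "x", "y", "y"))$ari, 1)
  expect_equal(cluster_concordance(rep(1, 6), rep(1:3, each = 2))$ari, 0)
  # hand-worked 6-sample contingency table: ARI = 8/33
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 2, 3, 3)
  expect_equal(cluster_concordance(a, b)$ari, 8 / 33, tolerance = 1e-12)
  set.seed(9)
  for (i in 1:25) {
    x <- sample(1:3, 12, replace = TRUE)
    y <- sample(1:4, 12, replace = TRUE)
    expect_equal(cluster_concordance(x, y)$ari, ari_oracle(x, y),
                 tolerance = 1e-12)
  }
  pur <- cluster_concordance(c(1, 1, 2), c("u", "v", "v"))$purity
  expect_equal(unname(pur), c(0.5, 1))
})

test_that("concordance agrees with an established ARI implementation", {
  skip_if_not_installed("mclust")
  set.seed(11)
  for (i in 1:10) {
    x <- sample(1:4, 20, replace = TRUE)
    y <- sample(1:3, 20, replace = TRUE)
    expect_equal(cluster_concordance(x, y)$ari,
                 mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
  }
})

test_that("PCA is a gene-centred SVD with the stated conventions", {
  # exact line: one component carries all variance
  t_line <- seq(-2, 2, length.out = 6)
  m <- outer(rnorm(10), t_line)
  rownames(m) <- paste0("g", 1:10); colnames(m) <- paste0("s", 1:6)
  p <- run_pca(m, 2)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-10)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  # sign convention: largest-magnitude loading positive
  expect_gt(p$loadings[which.max(abs(p$loadings[, 1])), 1], 0)

  set.seed(3)
  m2 <- random_profiles(5, 12)
  full <- run_pca(m2, 5)
  recon <- full$scores %*% t(full$loadings)
  centered <- t(m2 - rowMeans(m2))
  expect_equal(recon, centered, tolerance = 1e-8, ignore_attr = TRUE)
  expect_lte(sum(full$explained_variance), 1 + 1e-12)
  expect_error(run_pca(m2, 0), "n_components")
  expect_error(run_pca(m2, 9), "exceeds")
})

test_that("dendrograms export as Newick and a merge table", {
  m <- random_profiles(5)
  hc <- pearson_ward_cluster(m)
  nwk <- withr::local_tempfile(fileext = ".nwk")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  out <- export_dendrogram(hc, nwk, tsv)
  tr <- ape::read.tree(nwk)
  expect_setequal(tr$tip.label, colnames(m))
  merges <- read.delim(tsv)
  expect_equal(nrow(merges), 4)
  expect_equal(merges$size[4], 5)
})
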