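test_that("count simulation is deterministic under a fixed seed", {
  cfg <- simulation_config(n_genes = 50, group_sizes = c(A = 4, B = 4),
                           seed = 9)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_counts(simulation_config(n_genes = 50,
                                          group_sizes = c(A = 4, B = 4),
                                          seed = 10))
  expect_false(identical(s1$counts$counts, s3$counts$counts))
})

test_that("dispersion zero gives Poisson-like variance (var/mean near 1)", {
  cfg <- simulation_config(n_genes = 1, group_sizes = c(A = 10000),
                           baseline_mean = 100, baseline_log_sd = 0,
                           dispersion = 0,
                           library_size_range = c(1e6, 1e6), seed = 4)
  y <- simulate_counts(cfg)$counts$counts[1, ]
  ratio <- var(y) / mean(y)
  # 3 standard errors of the dispersion index at n = 10000
  expect_lt(abs(ratio - 1), 3 * sqrt(2 / (length(y) - 1)))
})

test_that("simulated moments match the NB law Var = mu + alpha mu^2", {
  cfg <- simulation_config(n_genes = 1, group_sizes = c(A = 10000),
                           baseline_mean = 100, baseline_log_sd = 0,
                           dispersion = 0.1,
                           library_size_range = c(1e6, 1e6), seed = 5)
  y <- simulate_counts(cfg)$counts$counts[1, ]
  expect_lt(abs(mean(y) - 100), 3 * sqrt(1100 / 10000))
  expect_lt(abs(var(y) / 1100 - 1), 0.10)
})

test_that("a planted log2 fold change of 2 yields a mean ratio near 4", {
  cfg <- simulation_config(n_genes = 5, group_sizes = c(A = 50, B = 50),
                           baseline_mean = 200, baseline_log_sd = 0,
                           dispersion = 0.05,
                           lfc_spec = list(lfc_entry(1L, c("A", "B"), 2)),
                           library_size_range = c(1e6, 1e6), seed = 11)
  sim <- simulate_counts(cfg)
  g <- sim$counts$counts[1, ]
  grp <- sim$annotations$tissue_type
  ratio <- mean(g[grp == "A"]) / mean(g[grp == "B"])
  expect_lt(abs(ratio - 4), 0.6)
  expect_equal(sim$truth$true_log2fc[sim$truth$gene_id == "GENE00001"], 2)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simulation_config(n_genes = 0), class = "cdcseq_invalid_config")
  expect_error(simulation_config(group_sizes = integer()),
               class = "cdcseq_invalid_config")
  expect_error(simulation_config(dispersion = -1),
               class = "cdcseq_invalid_config")
  expect_error(simulation_config(library_size_range = c(10, 5)),
               class = "cdcseq_invalid_config")
  expect_error(
    atlas_simulation_config(n_genes = 100, signature_size = 50),
    class = "cdcseq_invalid_config")
  expect_error(atlas_simulation_config(tumor_origin_segment = "nope"),
               class = "cdcseq_invalid_config")
})

test_that("atlas replicates are identical at zero noise and differ by species case", {
  cfg <- atlas_simulation_config(n_genes = 500, signature_size = 20,
                                 noise_sd = 0, replicates_per_segment = 2,
                                 seed = 2)
  res <- simulate_atlas_and_tumors(cfg)
  h <- res$atlases$human
  j <- which(h$segments == "DCT")
  expect_equal(h$profiles[, j[1]], h$profiles[, j[2]],
               ignore_attr = TRUE)
  expect_identical(h$segments, res$atlases$mouse$segments)
  expect_identical(toupper(rownames(res$atlases$mouse$profiles)),
                   rownames(h$profiles))
  expect_false(identical(rownames(res$atlases$mouse$profiles),
                         rownames(h$profiles)))
})

test_that("strong signatures propagate to the downstream origin call", {
  cfg <- atlas_simulation_config(tumor_origin_segment = "DCT",
                                 signature_effect = 4, noise_sd = 0.25,
                                 seed = 13)
  res <- simulate_atlas_and_tumors(cfg)
  asg <- map_cell_of_origin(res$tumors, res$atlases$human,
                            cohort_labels = res$tumor_cohorts)$assignment
  expect_equal(asg$segment[asg$group == "CDC"], "DCT")
})

test_that("TIL simulation respects clipping, determinism and the null shift", {
  r1 <- simulate_til(5, 5, shift = 30, seed = 3)
  r2 <- simulate_til(5, 5, shift = 30, seed = 3)
  expect_identical(r1, r2)
  expect_true(all(r1$til_percent >= 0 & r1$til_percent <= 100))
  expect_setequal(unique(r1$marker), c("CD3", "CD8"))
  expect_error(simulate_til(-1, 5), class = "cdcseq_invalid_config")
  # with no shift, large-sample group medians nearly coincide
  r0 <- simulate_til(300, 300, shift = 0, seed = 8)
  cd3 <- r0[r0$marker == "CD3", ]
  gap <- abs(median(cd3$til_percent[cd3$metastatic]) -
               median(cd3$til_percent[!cd3$metastatic]))
  expect_lt(gap, 5)
})
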