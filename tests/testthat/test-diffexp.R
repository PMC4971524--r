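test_that("moment dispersion estimates hit their closed form", {
  # within-group variance equal to the mean sits on the Poisson boundary
  y <- matrix(rep(c(9, 10, 11), 2), 1)  # mean 10, var 1 < mean
  expect_equal(unname(estimate_dispersion(y, rep("A", 6))), 0)

  # one group with mean 10, variance 30: alpha = (30 - 10) / 100
  g <- c(10 + sqrt(30) * scale(c(-1, 0, 1)))  # mean 10, var 30
  expect_equal(unname(estimate_dispersion(matrix(g, 1), rep("A", 3))),
               (var(g) - mean(g)) / mean(g)^2, tolerance = 1e-12)
  expect_equal(unname(estimate_dispersion(matrix(g, 1), rep("A", 3))),
               0.2, tolerance = 1e-6)
})

test_that("moment dispersion recovers a known alpha on NB draws", {
  cfg <- simulation_config(n_genes = 200, group_sizes = c(A = 100, B = 100),
                           baseline_mean = 100, baseline_log_sd = 0,
                           dispersion = 0.1,
                           library_size_range = c(1e6, 1e6), seed = 21)
  sim <- simulate_counts(cfg)
  a <- estimate_dispersion(sim$counts, sim$annotations$tissue_type)
  expect_lt(abs(mean(a) - 0.1) / 0.1, 0.2)
})

test_that("at alpha 0 the Wald machinery matches Poisson closed forms", {
  fit <- fit_nb_wald(c(10, 10, 20, 20), c("A", "A", "B", "B"))
  t <- fit$tests
  expect_equal(abs(t$log_estimate), log(2), tolerance = 1e-6)
  expect_equal(t$se, sqrt(1 / 40 + 1 / 20), tolerance = 1e-6)
  expect_equal(abs(t$wald_stat), log(2) / sqrt(1 / 40 + 1 / 20),
               tolerance = 1e-6)
  # closed-form Poisson MLE: coefficients are log group means
  expect_equal(unname(fit$coefficients), log(c(10, 20)), tolerance = 1e-8)

  sym <- fit_nb_wald(c(5, 7, 5, 7), c("A", "A", "B", "B"))
  expect_equal(sym$tests$log_estimate, 0, tolerance = 1e-10)
  expect_equal(sym$tests$p_value, 1, tolerance = 1e-8)
})

test_that("degenerate and unconverged fits are flagged, not tested", {
  fit <- fit_nb_wald(c(0, 0, 0, 0), c("A", "A", "B", "B"))
  expect_true(fit$degenerate)
  expect_true(is.na(fit$tests$p_value))
  expect_error(fit_nb_wald(1:4, rep("A", 4)), "two groups")
})

test_that("BH adjustment equals the brute-force step-up on random vectors", {
  expect_equal(adjust_bh(0.05), 0.05)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(77)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(adjust_bh(p), bh_stepup_oracle(p), tolerance = 1e-12)
  }
  # NA propagation with m = number tested
  p <- c(0.01, NA, 0.03)
  q <- adjust_bh(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_stepup_oracle(p[c(1, 3)]))
  # q >= p and monotone in p-rank
  p <- runif(50)
  q <- adjust_bh(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("DE classification applies inclusive FC and strict FDR boundaries", {
  res <- data.frame(signed_fc = c(2.5, 1.5, -2.0, 3, 2),
                    q_value = c(0.01, 0.001, 0.049, NA, 0.05))
  out <- classify_de(res)
  expect_identical(out$call, c("up", "ns", "down", "ns", "ns"))
  expect_error(classify_de(res, fc_cut = 0.5), "fc_cut")
  # monotone: lowering q or raising |fc| never flips a call to ns
  base <- classify_de(data.frame(signed_fc = 2, q_value = 0.04))$call
  expect_identical(classify_de(data.frame(signed_fc = 3,
                                          q_value = 0.01))$call, base)
})

test_that("pairwise DE recovers planted truth and is orientation-antisymmetric", {
  spec <- list(lfc_entry(1:20, c("A", "B"), 2),
               lfc_entry(21:40, c("A", "B"), -2))
  cfg <- simulation_config(n_genes = 300, group_sizes = c(A = 10, B = 10),
                           dispersion = 0.05, lfc_spec = spec, seed = 31)
  sim <- simulate_counts(cfg)
  de_ab <- run_pairwise_de(sim$counts, sim$annotations,
                           contrasts = list(c("A", "B")))
  de_ba <- run_pairwise_de(sim$counts, sim$annotations,
                           contrasts = list(c("B", "A")))
  expect_equal(de_ab$log2fc, -de_ba$log2fc, tolerance = 1e-8)
  expect_equal(de_ab$p_value, de_ba$p_value, tolerance = 1e-10)

  planted <- sim$truth$gene_id[abs(sim$truth$true_log2fc) >= 2]
  called <- de_ab$gene_id[de_ab$call != "ns"]
  expect_gte(mean(planted %in% called), 0.9)
  up <- de_ab$gene_id[de_ab$call == "up"]
  expect_true(all(up %in% sim$truth$gene_id[sim$truth$true_log2fc > 0]))

  expect_error(run_pairwise_de(sim$counts, sim$annotations,
                               contrasts = list(c("A", "C"))), "C")
})
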