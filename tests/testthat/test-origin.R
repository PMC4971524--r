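test_that("centroid centring follows the stated arithmetic", {
  m <- matrix(c(2, 4, 6, 5), 1, 4,
              dimnames = list("g1", c("a1", "b1", "c1", "x1")))
  centred <- center_tumor_profiles(m, c("A", "B", "C", "X"),
                                   centroid_cohorts = c("A", "B", "C"))
  # centroid = mean(2, 4, 6) = 4; sample value 5 -> 1; X is centred too
  expect_equal(unname(centred[1, ]), c(-2, 0, 2, 1))

  # single cohort covering everything reduces to gene-mean centring
  m2 <- matrix(rnorm(20), 4, 5)
  centred2 <- center_tumor_profiles(m2, rep("ALL", 5))
  expect_equal(centred2, m2 - rowMeans(m2), ignore_attr = TRUE)
  # idempotence: the centred data's centroid is zero
  expect_equal(center_tumor_profiles(centred2, rep("ALL", 5)), centred2,
               ignore_attr = TRUE)
  expect_error(center_tumor_profiles(m2, rep("A", 5), "B"), "no samples")
})

test_that("atlas centring subtracts per-gene medians per species", {
  prof <- matrix(c(1, 2, 9), 1, 3,
                 dimnames = list("G1", paste0("p", 1:3)))
  atlas <- atlas_profile_set("human", prof, c("DCT", "CCD", "Glom"))
  centred <- center_atlas_profiles(atlas)
  expect_equal(unname(centred$profiles[1, ]), c(-1, 0, 7))

  const <- atlas_profile_set("human", matrix(3, 1, 3,
                                             dimnames = list("G1",
                                                             paste0("p", 1:3))),
                             c("DCT", "CCD", "Glom"))
  expect_equal(unname(center_atlas_profiles(const)$profiles[1, ]), c(0, 0, 0))

  # species sets are centred independently
  res <- simulate_atlas_and_tumors(
    atlas_simulation_config(n_genes = 400, signature_size = 10, seed = 6))
  ch <- center_atlas_profiles(res$atlases$human)
  cm <- center_atlas_profiles(res$atlases$mouse)
  expect_false(isTRUE(all.equal(unname(ch$profiles), unname(cm$profiles))))
})

test_that("gene matching is case-insensitive with deterministic order", {
  shared <- match_genes(c("GATA3", "TP63"), c("Gata3", "Krt7"),
                        min_shared = 1)
  expect_identical(shared$tumor_id, "GATA3")
  expect_identical(shared$atlas_id, "Gata3")
  expect_error(match_genes(c("A", "B"), c("C", "D"), min_shared = 1),
               "shared")
  expect_warning(
    collided <- match_genes(c("DUP", "dup", "KEEP"), c("Dup", "Keep"),
                            min_shared = 1),
    "collision")
  expect_identical(collided$tumor_id, "KEEP")

  res <- simulate_atlas_and_tumors(
    atlas_simulation_config(n_genes = 300, signature_size = 10, seed = 8))
  sh <- match_genes(rownames(res$tumors), rownames(res$atlases$mouse$profiles))
  expect_equal(nrow(sh), 300)
  expect_identical(sh$tumor_id, rownames(res$tumors))
})

test_that("inter-profile correlations behave as Pearson r", {
  atlas <- atlas_profile_set(
    "human", matrix(c(2, 4, 6, 1, 0, 1), 3, 2,
                    dimnames = list(c("G1", "G2", "G3"), c("p1", "p2"))),
    c("DCT", "CCD"))
  tumors <- matrix(c(1, 2, 3), 3, 1,
                   dimnames = list(c("G1", "G2", "G3"), "t1"))
  shared <- match_genes(rownames(tumors), rownames(atlas$profiles),
                        min_shared = 1)
  map <- interprofile_correlation(tumors, atlas, shared)
  expect_equal(map$r["p1", "t1"], 1, tolerance = 1e-12)
  expect_equal(map$r["p2", "t1"], 0, tolerance = 1e-12)
  expect_equal(map$n_shared_genes, 3)

  neg <- interprofile_correlation(-tumors, atlas, shared)
  expect_equal(neg$r["p1", "t1"], -1, tolerance = 1e-12)

  # Pearson invariance under positive affine rescaling of a tumor profile
  resc <- interprofile_correlation(tumors * 3.7 + 2, atlas, shared)
  expect_equal(resc$r, map$r, tolerance = 1e-12)
})

test_that("origin assignment recovers planted segments and flags null input", {
  res <- simulate_atlas_and_tumors(
    atlas_simulation_config(tumor_origin_segment = "Glom",
                            signature_effect = 2, noise_sd = 0.5, seed = 14))
  asg <- map_cell_of_origin(res$tumors, res$atlases$human,
                            cohort_labels = res$tumor_cohorts)$assignment
  expect_equal(asg$segment[asg$group == "CDC"], "Glom")
  # reference cohorts are recovered as their own seeding segments
  expect_equal(asg$segment[asg$group == "KIRC"], "PT1")

  # pure-noise tumors: no segment wins by more than the margin
  set.seed(2)
  noise <- matrix(rnorm(2000 * 6, 5, 1), 2000, 6,
                  dimnames = list(rownames(res$atlases$human$profiles),
                                  paste0("n", 1:6)))
  shared <- match_genes(rownames(noise),
                        rownames(res$atlases$human$profiles))
  map <- interprofile_correlation(
    center_tumor_profiles(noise, rep("N", 6)),
    center_atlas_profiles(res$atlases$human), shared)
  null_asg <- assign_origin(map, rep("N", 6))
  expect_false(null_asg$confident)
  expect_gt(length(strsplit(null_asg$candidates, ",")[[1]]), 1)
})

test_that("human and mouse atlases give the same origin call", {
  res <- simulate_atlas_and_tumors(
    atlas_simulation_config(tumor_origin_segment = "OMCD", seed = 15))
  h <- map_cell_of_origin(res$tumors, res$atlases$human,
                          cohort_labels = res$tumor_cohorts)$assignment
  m <- map_cell_of_origin(res$tumors, res$atlases$mouse,
                          cohort_labels = res$tumor_cohorts)$assignment
  expect_equal(h$segment[h$group == "CDC"], m$segment[m$group == "CDC"])
  expect_equal(h$segment[h$group == "CDC"], "OMCD")
})
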