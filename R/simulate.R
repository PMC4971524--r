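#' Configuration for the negative-binomial count simulator
#'
#' The simulator emulates the statistical structure the downstream analysis
#' assumes: per-gene counts drawn from a negative binomial with
#' Var = mu + alpha * mu^2, group-specific log2 fold changes, and per-sample
#' sequencing depths applied as multiplicative offsets. The default group
#' sizes are the study's: 11 CDC, 9 muscle-invasive UTUC and 3 normal kidney
#' libraries.
#'
#' @param n_genes number of genes (> 0).
#' @param group_sizes named integer vector of samples per tissue group.
#' @param baseline_mean expected baseline count per gene before depth scaling.
#' @param baseline_log_sd natural-log SD of per-gene baseline means around
#'   `baseline_mean` (mean-preserving lognormal); 0 gives every gene the same
#'   baseline.
#' @param dispersion NB dispersion alpha (>= 0); 0 is the Poisson limit.
#' @param lfc_spec list of [lfc_entry()] objects planting true fold changes.
#' @param library_size_range integer pair; depths drawn uniformly in this
#'   range and applied as offsets relative to their mean.
#' @param seed integer RNG seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000,
                              group_sizes = c(CDC = 11, UTUC = 9,
                                              NORMAL_KIDNEY = 3),
                              baseline_mean = 100,
                              baseline_log_sd = 1,
                              dispersion = 0.05,
                              lfc_spec = list(),
                              library_size_range = c(5e5, 2e6),
                              seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
    stop_cdc("n_genes must be a positive integer",
             class = "cdcseq_invalid_config")
  if (length(group_sizes) == 0L || is.null(names(group_sizes)) ||
      any(!nzchar(names(group_sizes))))
    stop_cdc("group_sizes must be a non-empty named vector",
             class = "cdcseq_invalid_config")
  if (any(group_sizes < 1))
    stop_cdc("every group needs at least one sample",
             class = "cdcseq_invalid_config")
  assert_scalar_number(baseline_mean, "baseline_mean", lower = 1e-12)
  assert_scalar_number(baseline_log_sd, "baseline_log_sd", lower = 0)
  assert_scalar_number(dispersion, "dispersion", lower = 0)
  if (length(library_size_range) != 2L ||
      library_size_range[1] > library_size_range[2] ||
      any(library_size_range <= 0))
    stop_cdc("library_size_range must be an increasing positive pair",
             class = "cdcseq_invalid_config")
  if (!is.list(lfc_spec) ||
      !all(vapply(lfc_spec, inherits, logical(1), "lfc_entry")))
    stop_cdc("lfc_spec must be a list of lfc_entry objects",
             class = "cdcseq_invalid_config")
  structure(list(n_genes = as.integer(n_genes), group_sizes = group_sizes,
                 baseline_mean = baseline_mean,
                 baseline_log_sd = baseline_log_sd,
                 dispersion = dispersion, lfc_spec = lfc_spec,
                 library_size_range = library_size_range,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Plant a log2 fold change for a subset of genes in one contrast
#'
#' The first group of `contrast` is shifted by `lfc` (log2) relative to the
#' second for the listed genes; entries for the same gene/group accumulate.
#'
#' @param genes integer gene indices (1-based).
#' @param contrast character pair `c(A, B)`: A is elevated relative to B.
#' @param lfc log2 fold change.
#' @return list of class `lfc_entry`.
#' @export
lfc_entry <- function(genes, contrast, lfc) {
  if (length(contrast) != 2L || contrast[1] == contrast[2])
    stop_cdc("contrast must name two distinct groups",
             class = "cdcseq_invalid_config")
  structure(list(genes = as.integer(genes),
                 contrast = as.character(contrast), lfc = lfc),
            class = "lfc_entry")
}

## per-(gene, group) log2 effect matrix implied by the lfc entries
lfc_effect_matrix <- function(config) {
  groups <- names(config$group_sizes)
  eff <- matrix(0, config$n_genes, length(groups),
                dimnames = list(NULL, groups))
  for (e in config$lfc_spec) {
    miss <- setdiff(e$contrast, groups)
    if (length(miss))
      stop_cdc("lfc_spec references unknown group(s): %s",
               paste(miss, collapse = ", "),
               class = "cdcseq_invalid_config")
    if (any(e$genes < 1 | e$genes > config$n_genes))
      stop_cdc("lfc_spec gene index out of range",
               class = "cdcseq_invalid_config")
    eff[e$genes, e$contrast[1]] <- eff[e$genes, e$contrast[1]] + e$lfc
  }
  eff
}

#' Simulate a count matrix with known differential-expression truth
#'
#' Counts for gene g in sample j of group k are drawn from
#' NB(mu = b_g * 2^effect(g, k) * d_j, Var = mu + alpha * mu^2) where b_g is
#' the per-gene baseline, effect() the planted log2 fold structure, and d_j
#' the sample's depth factor (drawn library size divided by the mean drawn
#' library size). At alpha = 0 the Poisson limit is used. Identical
#' configurations (including seed) give byte-identical output.
#'
#' @param config a [simulation_config()].
#' @return list with `counts` (a [count_matrix]), `annotations`
#'   (sample annotation data.frame), `truth` (per gene and group pair, the
#'   true log2 fold change), and the `config`.
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop_cdc("config must come from simulation_config()",
             class = "cdcseq_invalid_config")
  eff <- lfc_effect_matrix(config)
  groups <- names(config$group_sizes)
  group_of <- rep(groups, times = config$group_sizes)
  n_samp <- length(group_of)
  sample_ids <- paste0(group_of, "_",
                       unlist(lapply(config$group_sizes, seq_len)))
  gene_ids <- sprintf("GENE%05d", seq_len(config$n_genes))

  sim <- with_seed(config$seed, {
    b <- config$baseline_mean *
      exp(stats::rnorm(config$n_genes, 0, config$baseline_log_sd) -
            config$baseline_log_sd^2 / 2)
    lib <- round(stats::runif(n_samp, config$library_size_range[1],
                              config$library_size_range[2]))
    depth <- lib / mean(lib)
    mu <- outer(b, depth) * 2^(eff[, group_of, drop = FALSE])
    cnt <- if (config$dispersion == 0) {
      matrix(stats::rpois(length(mu), mu), nrow = config$n_genes)
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu,
                            size = 1 / config$dispersion),
             nrow = config$n_genes)
    }
    list(counts = cnt)
  })
  dimnames(sim$counts) <- list(gene_ids, sample_ids)

  truth <- if (length(groups) >= 2L) {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    do.call(rbind, lapply(pairs, function(p) {
      data.frame(gene_id = gene_ids,
                 contrast = paste(p[1], p[2], sep = "_vs_"),
                 true_log2fc = eff[, p[1]] - eff[, p[2]],
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(gene_id = character(), contrast = character(),
               true_log2fc = numeric(), stringsAsFactors = FALSE)
  }
  ann <- if (all(group_of %in% tissue_vocabulary())) {
    sample_annotation(sample_ids, group_of, cohort = group_of)
  } else {
    data.frame(sample_id = sample_ids, tissue_type = group_of,
               cohort = group_of, stringsAsFactors = FALSE)
  }
  list(counts = count_matrix(sim$counts),
       annotations = ann,
       truth = truth,
       config = config)
}

#' Configuration for the nephron-atlas and tumor-profile simulator
#'
#' Emulates a microdissected nephron expression atlas over eight anatomical
#' segments (glomerulus; two proximal-tubule portions; medullary and cortical
#' thick ascending limb; distal convoluted tubule; cortical and outer
#' medullary collecting duct), with segment-specific signature genes, plus
#' tumor profiles seeded from one segment's signature. Two species tags are
#' emitted by default; the mouse set carries title-case gene symbols
#' ("Gata3") versus the human upper-case ("GATA3") so that cross-species
#' symbol matching is exercised.
#'
#' @param n_genes total genes in the atlas.
#' @param segment_labels eight distinct segment labels.
#' @param signature_size signature genes per segment
#'   (`8 * signature_size <= n_genes`).
#' @param signature_effect log-scale elevation of a segment's signature genes.
#' @param replicates_per_segment atlas replicates per segment.
#' @param species_tags e.g. `c("human", "mouse")`.
#' @param tumor_origin_segment segment whose signature seeds the cohort of
#'   interest (labelled `CDC`).
#' @param n_tumors number of tumor profiles in the cohort of interest.
#' @param reference_cohorts named character vector mapping each reference
#'   cohort to its origin segment. The default mirrors the comparator renal
#'   cohorts: clear-cell and papillary RCC seeded from the two proximal
#'   tubule portions and chromophobe RCC from the distal nephron.
#' @param n_per_reference profiles per reference cohort.
#' @param noise_sd SD of the additive log-scale noise.
#' @param seed integer RNG seed.
#' @return list of class `atlas_simulation_config`.
#' @export
atlas_simulation_config <- function(n_genes = 2000,
                                    segment_labels = c("Glom", "PT1", "PT2",
                                                       "mTAL", "cTAL", "DCT",
                                                       "CCD", "OMCD"),
                                    signature_size = 50,
                                    signature_effect = 2,
                                    replicates_per_segment = 3,
                                    species_tags = c("human", "mouse"),
                                    tumor_origin_segment = "DCT",
                                    n_tumors = 10,
                                    reference_cohorts = c(KIRC = "PT1",
                                                          KIRP = "PT2",
                                                          KICH = "cTAL"),
                                    n_per_reference = 5,
                                    noise_sd = 0.5,
                                    seed = 1L) {
  if (anyDuplicated(segment_labels) || length(segment_labels) != 8L)
    stop_cdc("segment_labels must be 8 distinct labels",
             class = "cdcseq_invalid_config")
  if (!tumor_origin_segment %in% segment_labels)
    stop_cdc("tumor_origin_segment '%s' is not an atlas segment",
             tumor_origin_segment, class = "cdcseq_invalid_config")
  if (signature_size * 8 > n_genes)
    stop_cdc("8 x signature_size (%d) exceeds n_genes (%d)",
             signature_size * 8, n_genes, class = "cdcseq_invalid_config")
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(signature_effect, "signature_effect")
  if (replicates_per_segment < 1 || n_tumors < 1)
    stop_cdc("replicates_per_segment and n_tumors must be >= 1",
             class = "cdcseq_invalid_config")
  if (length(reference_cohorts)) {
    if (is.null(names(reference_cohorts)) ||
        !all(reference_cohorts %in% segment_labels))
      stop_cdc("reference_cohorts must be named and map to atlas segments",
               class = "cdcseq_invalid_config")
  }
  structure(list(n_genes = as.integer(n_genes),
                 segment_labels = segment_labels,
                 signature_size = as.integer(signature_size),
                 signature_effect = signature_effect,
                 replicates_per_segment = as.integer(replicates_per_segment),
                 species_tags = species_tags,
                 tumor_origin_segment = tumor_origin_segment,
                 n_tumors = as.integer(n_tumors),
                 reference_cohorts = reference_cohorts,
                 n_per_reference = as.integer(n_per_reference),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "atlas_simulation_config")
}

#' Atlas profile set container
#'
#' @param species species tag.
#' @param profiles genes x profiles matrix (log scale), rownames = gene ids.
#' @param segments segment label per profile column.
#' @return list of class `atlas_profile_set`.
#' @export
atlas_profile_set <- function(species, profiles, segments) {
  if (ncol(profiles) != length(segments))
    stop_cdc("one segment label per profile column is required")
  if (anyDuplicated(rownames(profiles)))
    stop_cdc("atlas gene ids must be unique")
  structure(list(species = species, profiles = profiles,
                 segments = as.character(segments)),
            class = "atlas_profile_set")
}

#' @export
print.atlas_profile_set <- function(x, ...) {
  cat(sprintf("atlas_profile_set (%s): %d genes x %d profiles over %d segments\n",
              x$species, nrow(x$profiles), ncol(x$profiles),
              length(unique(x$segments))))
  invisible(x)
}

## title-case a gene symbol ("GENE00001" -> "Gene00001"), mouse convention
mouse_case <- function(ids) {
  paste0(substr(ids, 1, 1), tolower(substring(ids, 2)))
}

#' Simulate a nephron atlas and tumors seeded from one segment
#'
#' Shared per-gene baseline log expression; each segment's replicates elevate
#' that segment's signature genes by `signature_effect` plus N(0, noise_sd)
#' noise; tumor profiles are built on the `tumor_origin_segment` signature.
#' All species share the planted structure; only the gene-symbol case differs
#' (mouse title-case), so matching them back is a genuine exercise.
#'
#' Besides the cohort of interest (labelled `CDC`, seeded from
#' `tumor_origin_segment`), reference tumor cohorts are generated from the
#' segments of `reference_cohorts`, so that the centroid-centred mapping has
#' comparator cohorts to centre on — the design the correlation mapping
#' assumes.
#'
#' @param config an [atlas_simulation_config()].
#' @return list with `atlases` (one [atlas_profile_set] per species tag),
#'   `tumors` (genes x tumor-samples log-expression matrix, human-style ids,
#'   cohort of interest plus reference cohorts), `tumor_cohorts` (cohort
#'   label per tumor column), `signatures` (named list of signature gene ids
#'   per segment), `origin_segment` (the planted truth for the `CDC`
#'   cohort), and the `config`.
#' @export
simulate_atlas_and_tumors <- function(config) {
  if (!inherits(config, "atlas_simulation_config"))
    stop_cdc("config must come from atlas_simulation_config()",
             class = "cdcseq_invalid_config")
  gene_ids <- sprintf("NPH%05d", seq_len(config$n_genes))
  segs <- config$segment_labels
  sig_idx <- split(seq_len(config$signature_size * 8),
                   rep(segs, each = config$signature_size))
  sig_idx <- sig_idx[segs]  # split() sorts; restore atlas order

  out <- with_seed(config$seed, {
    base <- stats::rnorm(config$n_genes, mean = 5, sd = 1)
    make_profiles <- function(n_cols, seg_of_col) {
      m <- matrix(base, config$n_genes, n_cols)
      for (j in seq_len(n_cols)) {
        m[sig_idx[[seg_of_col[j]]], j] <-
          m[sig_idx[[seg_of_col[j]]], j] + config$signature_effect
      }
      m + matrix(stats::rnorm(length(m), 0, config$noise_sd),
                 nrow = config$n_genes)
    }
    seg_of_col <- rep(segs, each = config$replicates_per_segment)
    atlases <- lapply(config$species_tags, function(sp) {
      make_profiles(length(seg_of_col), seg_of_col)
    })
    cohorts <- c(rep("CDC", config$n_tumors),
                 rep(names(config$reference_cohorts),
                     each = config$n_per_reference))
    seg_of_tumor <- c(rep(config$tumor_origin_segment, config$n_tumors),
                      rep(unname(config$reference_cohorts),
                          each = config$n_per_reference))
    tumors <- make_profiles(length(seg_of_tumor), seg_of_tumor)
    list(atlases = atlases, tumors = tumors, seg_of_col = seg_of_col,
         cohorts = cohorts)
  })

  atlases <- stats::setNames(vector("list", length(config$species_tags)),
                             config$species_tags)
  for (i in seq_along(config$species_tags)) {
    sp <- config$species_tags[i]
    ids <- if (grepl("mouse", sp, ignore.case = TRUE))
      mouse_case(gene_ids) else gene_ids
    m <- out$atlases[[i]]
    dimnames(m) <- list(ids, paste0(sp, "_", out$seg_of_col, "_",
                                    seq_along(out$seg_of_col)))
    atlases[[sp]] <- atlas_profile_set(sp, m, out$seg_of_col)
  }
  tumors <- out$tumors
  dimnames(tumors) <- list(gene_ids,
                           paste0(out$cohorts, "_", seq_along(out$cohorts)))
  list(atlases = atlases, tumors = tumors, tumor_cohorts = out$cohorts,
       signatures = lapply(sig_idx, function(i) gene_ids[i]),
       origin_segment = config$tumor_origin_segment,
       config = config)
}

#' Simulate tumor-infiltrating-lymphocyte percentage records
#'
#' Emulates per-case CD3/CD8 TIL percentages scored on tissue microarrays:
#' each case contributes one record per marker, drawn from a normal location
#' model and clipped to [0, 100]. Metastatic cases are shifted upward by
#' `shift` percentage points for both markers. Marker baselines (CD3 about
#' 20%, CD8 about 10%) mirror the magnitudes reported for this tumor type.
#'
#' @param n_met,n_nonmet numbers of metastatic / non-metastatic cases (>= 0).
#' @param shift location shift (percentage points) added to metastatic cases.
#' @param seed integer RNG seed.
#' @param marker_means named baseline means per marker.
#' @param sd within-group SD (percentage points).
#' @return data.frame with `case_id`, `marker`, `til_percent`, `metastatic`.
#' @export
simulate_til <- function(n_met, n_nonmet, shift = 15, seed = 1L,
                         marker_means = c(CD3 = 20, CD8 = 10), sd = 10) {
  if (n_met < 0 || n_nonmet < 0)
    stop_cdc("case counts must be non-negative",
             class = "cdcseq_invalid_config")
  n <- n_met + n_nonmet
  metastatic <- rep(c(TRUE, FALSE), c(n_met, n_nonmet))
  case_id <- sprintf("CASE%03d", seq_len(n))
  recs <- with_seed(seed, {
    do.call(rbind, lapply(names(marker_means), function(mk) {
      mu <- marker_means[[mk]] + ifelse(metastatic, shift, 0)
      val <- pmin(100, pmax(0, stats::rnorm(n, mu, sd)))
      data.frame(case_id = case_id, marker = mk, til_percent = val,
                 metastatic = metastatic, stringsAsFactors = FALSE)
    }))
  })
  rownames(recs) <- NULL
  recs
}

#' Write simulated TIL records / truth tables as plain text
#'
#' @param x data.frame.
#' @param path output path.
#' @param sep field separator (`","` for the TIL CSV, `"\t"` for truth TSV).
#' @return `path`, invisibly.
#' @export
write_records <- function(x, path, sep = ",") {
  utils::write.table(x, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulation configuration as YAML
#' @param config a `simulation_config` or `atlas_simulation_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config_yaml <- function(config, path) {
  plain <- lapply(unclass(config), function(f) {
    if (is.list(f)) lapply(f, unclass) else f
  })
  yaml::write_yaml(plain, path)
  invisible(path)
}
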