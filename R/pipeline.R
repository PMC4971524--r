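#' Build a pipeline configuration
#'
#' Assembles, validates and defaults every stage parameter of the end-to-end
#' workflow. All randomness in a run is derived deterministically from the
#' single `seed`, so a rerun with an identical configuration reproduces
#' every output bit for bit.
#'
#' @param outdir output directory (created if needed).
#' @param seed master integer seed for the run.
#' @param sim a [simulation_config()] for the count simulator.
#' @param atlas an [atlas_simulation_config()] for the atlas simulator.
#' @param til list: `n_met`, `n_nonmet`, `shift` for [simulate_til()].
#' @param de list: `fc_cut`, `fdr_cut`, `cpm_threshold`, optional
#'   `contrasts` (list of label pairs).
#' @param cluster list: `top_k` (most-variable genes), `cut_k` (flat cut).
#' @param origin list: `min_shared`, `margin`.
#' @param enrich list: `weight`, `n_permutations`, optional `gmt` path
#'   (when absent, gene sets are planted from the simulation truth).
#' @param counts,annotations optional paths to a count TSV and annotation
#'   CSV to analyse instead of simulating.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("cdcseq_run_"), seed = 1L,
                            sim = NULL, atlas = NULL,
                            til = list(n_met = 6, n_nonmet = 6, shift = 15),
                            de = list(fc_cut = 2, fdr_cut = 0.05,
                                      cpm_threshold = 1),
                            cluster = list(top_k = 500, cut_k = 3),
                            origin = list(min_shared = 100, margin = 0.05),
                            enrich = list(weight = 1, n_permutations = 200),
                            counts = NULL, annotations = NULL) {
  if (is.null(sim))
    sim <- simulation_config(seed = derive_seed(seed, "simulate"))
  if (is.null(atlas))
    atlas <- atlas_simulation_config(seed = derive_seed(seed, "atlas"))
  structure(list(outdir = outdir, seed = as.integer(seed), sim = sim,
                 atlas = atlas, til = til, de = de, cluster = cluster,
                 origin = origin, enrich = enrich, counts = counts,
                 annotations = annotations),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar stage parameters are read from the YAML mapping; `sim` and
#' `atlas` blocks are passed to their config constructors.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("outdir", "seed", "til", "de", "cluster", "origin", "enrich",
               "counts", "annotations"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$sim)) {
    y$sim$group_sizes <- unlist(y$sim$group_sizes)
    args$sim <- do.call(simulation_config, y$sim)
  }
  if (!is.null(y$atlas)) args$atlas <- do.call(atlas_simulation_config, y$atlas)
  do.call(pipeline_config, args)
}

## one provenance record, written next to the stage outputs
write_provenance <- function(outdir, stage, params, inputs, outputs, seed) {
  rec <- list(stage = stage, seed = seed, params = params,
              inputs = inputs, outputs = outputs,
              package = "cdcseq",
              version = as.character(utils::packageVersion("cdcseq")))
  path <- file.path(outdir, paste0("provenance_", stage, ".json"))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  rec
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order. `de`, `cluster` and
#' `enrich` consume the count stage (`simulate`, or supplied count/annotation
#' files); `origin` consumes the atlas stage of `simulate`; `til` and
#' `clinical` are self-contained. Each stage writes its outputs plus a JSON
#' provenance record (parameters, seed, inputs, outputs, package version)
#' under `config$outdir`, and errors name the stage whose dependency is
#' missing.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @param stages subset of
#'   `c("simulate", "de", "cluster", "origin", "enrich", "til", "clinical")`.
#' @return list of class `pipeline_report`: one record per executed stage
#'   (with stage outputs attached), plus `outdir` and `seed`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "de", "cluster", "origin",
                                    "enrich", "til", "clinical")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  known <- c("simulate", "de", "cluster", "origin", "enrich", "til",
             "clinical")
  bad <- setdiff(stages, known)
  if (length(bad)) stop_cdc("unknown stage(s): %s", paste(bad, collapse = ", "))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list()
  state <- new.env(parent = emptyenv())

  need_counts <- function(stage) {
    if (!is.null(state$sim)) return(invisible())
    if (!is.null(config$counts)) {
      if (!file.exists(config$counts))
        stop_cdc("stage '%s': count file %s not found", stage, config$counts)
      cm <- read_count_matrix(config$counts)
      ann <- utils::read.csv(config$annotations, stringsAsFactors = FALSE)
      state$sim <- list(counts = cm, annotations = ann, truth = NULL)
      return(invisible())
    }
    stop_cdc("stage '%s' needs the 'simulate' stage or supplied counts",
             stage)
  }

  if ("simulate" %in% stages) {
    simres <- simulate_counts(config$sim)
    atlasres <- simulate_atlas_and_tumors(config$atlas)
    state$sim <- simres
    state$atlas <- atlasres
    counts_path <- file.path(config$outdir, "counts.tsv")
    write_count_matrix(simres$counts, counts_path)
    truth_path <- file.path(config$outdir, "truth.tsv")
    write_records(simres$truth, truth_path, sep = "\t")
    ann_path <- file.path(config$outdir, "annotations.csv")
    write_records(simres$annotations, ann_path)
    report$simulate <- write_provenance(
      config$outdir, "simulate",
      params = list(n_genes = config$sim$n_genes,
                    group_sizes = as.list(config$sim$group_sizes),
                    dispersion = config$sim$dispersion,
                    atlas_segments = config$atlas$segment_labels,
                    origin = config$atlas$tumor_origin_segment),
      inputs = list(), outputs = list(counts_path, truth_path, ann_path),
      seed = config$seed)
    report$simulate$result <- simres["truth"]
  }

  if ("de" %in% stages) {
    need_counts("de")
    de <- run_pairwise_de(state$sim$counts, state$sim$annotations,
                          contrasts = config$de$contrasts,
                          fc_cut = config$de$fc_cut,
                          fdr_cut = config$de$fdr_cut,
                          cpm_threshold = config$de$cpm_threshold)
    state$de <- de
    de_path <- file.path(config$outdir, "de_table.tsv")
    write_de_table(de, de_path)
    report$de <- write_provenance(
      config$outdir, "de", params = config$de,
      inputs = list(file.path(config$outdir, "counts.tsv")),
      outputs = list(de_path), seed = config$seed)
    report$de$result <- list(n_up = sum(de$call == "up"),
                             n_down = sum(de$call == "down"))
  }

  if ("cluster" %in% stages) {
    need_counts("cluster")
    filtered <- filter_low_expression(state$sim$counts,
                                      config$de$cpm_threshold %||% 1)
    norm <- log_normalize(filtered)
    k <- min(config$cluster$top_k, length(norm$gene_ids))
    genes <- select_top_variable_genes(norm, k)
    dend <- pearson_ward_cluster(norm, genes)
    labels <- cut_tree(dend, config$cluster$cut_k)
    conc <- cluster_concordance(
      labels, state$sim$annotations$tissue_type[
        match(names(labels), state$sim$annotations$sample_id)])
    pca <- run_pca(list_values <- structure(
      list(values = norm$values[genes, , drop = FALSE],
           gene_ids = genes, sample_ids = norm$sample_ids),
      class = "normalized_matrix"),
      n_components = min(3, ncol(norm$values)))
    newick_path <- file.path(config$outdir, "dendrogram.nwk")
    merge_path <- file.path(config$outdir, "dendrogram_merges.tsv")
    export_dendrogram(dend, newick_path, merge_path)
    labels_path <- file.path(config$outdir, "cluster_labels.tsv")
    write_records(data.frame(sample_id = names(labels), cluster = labels),
                  labels_path, sep = "\t")
    state$cluster <- list(dendrogram = dend, labels = labels,
                          concordance = conc, pca = pca)
    report$cluster <- write_provenance(
      config$outdir, "cluster", params = config$cluster,
      inputs = list(file.path(config$outdir, "counts.tsv")),
      outputs = list(newick_path, merge_path, labels_path),
      seed = config$seed)
    report$cluster$result <- list(ari = conc$ari,
                                  explained = pca$explained_variance[1])
  }

  if ("origin" %in% stages) {
    if (is.null(state$atlas))
      stop_cdc("stage 'origin' needs the 'simulate' stage (atlas missing)")
    atlasres <- state$atlas
    res <- map_cell_of_origin(atlasres$tumors,
                              atlasres$atlases[[1]],
                              cohort_labels = atlasres$tumor_cohorts,
                              min_shared = config$origin$min_shared,
                              margin = config$origin$margin)
    map_path <- file.path(config$outdir, "correlation_map.tsv")
    rep_path <- file.path(config$outdir, "origin_assignment.json")
    write_origin_outputs(res$map, res$assignment, map_path, rep_path)
    state$origin <- res
    report$origin <- write_provenance(
      config$outdir, "origin", params = config$origin,
      inputs = list(), outputs = list(map_path, rep_path),
      seed = config$seed)
    cdc_row <- match("CDC", res$assignment$group)
    if (is.na(cdc_row)) cdc_row <- 1L
    report$origin$result <- list(assigned = res$assignment$segment[cdc_row],
                                 truth = atlasres$origin_segment)
  }

  if ("enrich" %in% stages) {
    if (is.null(state$de))
      stop_cdc("stage 'enrich' needs the 'de' stage (DE table missing)")
    de <- state$de
    ctr <- unique(de$contrast)[1]
    sub <- de[de$contrast == ctr & !is.na(de$wald_stat), ]
    scores <- stats::setNames(sub$wald_stat, sub$gene_id)
    sets <- if (!is.null(config$enrich$gmt)) {
      read_gene_sets(config$enrich$gmt)
    } else {
      ## planted sets from the simulation truth: genes with true effect in
      ## this contrast, plus a random decoy set
      tr <- state$sim$truth
      if (is.null(tr)) stop_cdc("stage 'enrich' needs gene sets or truth")
      up <- tr$gene_id[tr$contrast == ctr & tr$true_log2fc > 0]
      dn <- tr$gene_id[tr$contrast == ctr & tr$true_log2fc < 0]
      decoy <- with_seed(derive_seed(config$seed, "enrich"),
                         sample(names(scores), min(50, length(scores))))
      Filter(function(s) length(s) >= 2,
             list(planted_up = up, planted_down = dn, decoy = decoy))
    }
    gsea <- gsea_collection(scores, sets, weight = config$enrich$weight,
                            n_permutations = config$enrich$n_permutations,
                            seed = derive_seed(config$seed, "perm"),
                            min_size = 2)
    query <- de$gene_id[de$contrast == ctr & de$call == "up"]
    over <- if (length(query)) {
      hypergeom_enrich(query, sub$gene_id, sets, min_size = 2)
    } else NULL
    gsea_path <- file.path(config$outdir, "gsea.tsv")
    write_records(gsea, gsea_path, sep = "\t")
    outs <- list(gsea_path)
    if (!is.null(over)) {
      over_path <- file.path(config$outdir, "overrepresentation.tsv")
      write_records(over, over_path, sep = "\t")
      outs <- c(outs, over_path)
    }
    state$enrich <- list(gsea = gsea, overrepresentation = over)
    report$enrich <- write_provenance(
      config$outdir, "enrich",
      params = config$enrich[setdiff(names(config$enrich), "gmt")],
      inputs = list(file.path(config$outdir, "de_table.tsv")),
      outputs = outs, seed = config$seed)
    report$enrich$result <- list(top_set = gsea$set[1])
  }

  if ("til" %in% stages) {
    rec <- simulate_til(config$til$n_met, config$til$n_nonmet,
                        shift = config$til$shift,
                        seed = derive_seed(config$seed, "til"))
    summ <- summarize_til(rec)
    cmp <- compare_til_groups(rec)
    til_path <- file.path(config$outdir, "til_records.csv")
    write_records(rec, til_path)
    summ_path <- file.path(config$outdir, "til_summary.tsv")
    write_records(summ, summ_path, sep = "\t")
    state$til <- list(records = rec, summary = summ, tests = cmp)
    report$til <- write_provenance(
      config$outdir, "til", params = config$til, inputs = list(),
      outputs = list(til_path, summ_path), seed = config$seed)
    report$til$result <- list(tests = cmp)
  }

  if ("clinical" %in% stages) {
    tab <- load_clinical_fixture()
    summ <- summarize_clinical(tab)
    sum_path <- file.path(config$outdir, "clinical_summary.json")
    jsonlite::write_json(summ[c("n_cases", "median_age", "min_age",
                                "max_age", "n_rnaseq", "n_ihc",
                                "metastatic_fraction")],
                         sum_path, auto_unbox = TRUE, digits = NA)
    state$clinical <- summ
    report$clinical <- write_provenance(
      config$outdir, "clinical", params = list(), inputs = list(),
      outputs = list(sum_path), seed = config$seed)
    report$clinical$result <- list(n_cases = summ$n_cases,
                                   median_age = summ$median_age)
  }

  structure(list(stages = report, outdir = config$outdir,
                 seed = config$seed),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline run (seed %d) -> %s\n", x$seed, x$outdir))
  for (nm in names(x$stages)) cat(" -", nm, "\n")
  invisible(x)
}
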