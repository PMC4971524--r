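#' Centre tumor profiles on the mean centroid of designated cohorts
#'
#' For every gene, the centroid is the mean over the designated cohorts of
#' that cohort's mean expression; the centroid is subtracted from every
#' sample, including samples of cohorts outside the centroid list. Centring
#' the combined tumor set on the centroid of the reference cohorts (rather
#' than the grand mean) stops the cohort of interest from dragging the
#' reference point toward itself.
#'
#' @param mat genes x samples (log-scale) expression matrix.
#' @param cohort_labels cohort label per sample (column).
#' @param centroid_cohorts cohorts defining the centroid; each must have at
#'   least one sample.
#' @return centred matrix, same shape.
#' @export
center_tumor_profiles <- function(mat, cohort_labels,
                                  centroid_cohorts = unique(cohort_labels)) {
  mat <- as.matrix(mat)
  if (length(cohort_labels) != ncol(mat))
    stop_cdc("one cohort label per sample is required")
  if (!length(centroid_cohorts)) stop_cdc("centroid_cohorts must be non-empty")
  means <- vapply(centroid_cohorts, function(ch) {
    j <- which(cohort_labels == ch)
    if (!length(j)) stop_cdc("centroid cohort '%s' has no samples", ch)
    rowMeans(mat[, j, drop = FALSE])
  }, numeric(nrow(mat)))
  centroid <- rowMeans(matrix(means, nrow = nrow(mat)))
  mat - centroid
}

#' Centre atlas profiles on the per-gene median
#'
#' Each species' atlas is centred independently: for every gene, the median
#' across that species' profiles is subtracted.
#'
#' @param atlas an [atlas_profile_set].
#' @return centred [atlas_profile_set].
#' @export
center_atlas_profiles <- function(atlas) {
  stopifnot(inherits(atlas, "atlas_profile_set"))
  if (ncol(atlas$profiles) < 2L) stop_cdc("need at least two atlas profiles")
  med <- apply(atlas$profiles, 1, stats::median)
  atlas$profiles <- atlas$profiles - med
  atlas
}

#' Case-insensitive gene-symbol intersection
#'
#' Matches tumor gene symbols against atlas symbols ignoring case, so human
#' upper-case symbols ("GATA3") meet their mouse title-case counterparts
#' ("Gata3"). Symbols that collide after case-folding (one-to-many matches
#' on either side) are dropped with a warning. Output order follows the
#' tumor matrix.
#'
#' @param tumor_ids,atlas_ids character vectors of gene symbols.
#' @param min_shared minimum acceptable intersection size (default 100).
#' @return data.frame with `tumor_id` and `atlas_id` of the shared genes.
#' @export
match_genes <- function(tumor_ids, atlas_ids, min_shared = 100) {
  t_key <- toupper(tumor_ids)
  a_key <- toupper(atlas_ids)
  t_dup <- unique(t_key[duplicated(t_key)])
  a_dup <- unique(a_key[duplicated(a_key)])
  drop <- union(t_dup, a_dup)
  if (length(drop))
    warn_cdc("%d case-folded symbol collision(s) dropped from matching",
             length(drop))
  shared <- setdiff(intersect(t_key, a_key), drop)
  keep <- t_key %in% shared
  out <- data.frame(tumor_id = tumor_ids[keep],
                    atlas_id = atlas_ids[match(t_key[keep], a_key)],
                    stringsAsFactors = FALSE)
  if (nrow(out) < min_shared)
    stop_cdc("only %d shared gene(s) after matching (minimum %d)",
             nrow(out), min_shared)
  out
}

#' Inter-profile Pearson correlation map
#'
#' Pearson correlation between every (atlas profile, tumor sample) pair over
#' the shared genes, both inputs already centred. Missing values are
#' excluded pairwise; a zero-variance profile over the shared genes yields a
#' missing value with a warning.
#'
#' @param tumors centred genes x samples tumor matrix.
#' @param atlas centred [atlas_profile_set].
#' @param shared data.frame from [match_genes()] (`tumor_id`, `atlas_id`).
#' @return list of class `correlation_map`: `r` (atlas profiles x tumor
#'   samples), `segments` (per atlas profile), `n_shared_genes`.
#' @export
interprofile_correlation <- function(tumors, atlas, shared) {
  tm <- as.matrix(tumors)[shared$tumor_id, , drop = FALSE]
  am <- atlas$profiles[shared$atlas_id, , drop = FALSE]
  suppressWarnings(r <- stats::cor(am, tm, use = "pairwise.complete.obs"))
  if (any(is.na(r)))
    warn_cdc("zero-variance profile(s) over shared genes: correlations set missing")
  structure(list(r = r, segments = atlas$segments,
                 species = atlas$species, n_shared_genes = nrow(shared)),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("correlation_map (%s): %d atlas profiles x %d tumors over %d shared genes\n",
              x$species, nrow(x$r), ncol(x$r), x$n_shared_genes))
  invisible(x)
}

#' Assign a nephron segment of origin per tumor group
#'
#' For each tumor group, the correlations are averaged over the group's
#' samples and each segment's atlas profiles; the assigned origin is the
#' segment with the highest mean correlation. When the top two segments are
#' closer than `margin`, the call is flagged low-confidence and all tied
#' segments (within the margin) are reported.
#'
#' @param map a `correlation_map`.
#' @param tumor_groups group label per tumor sample (default: one group).
#' @param margin confidence margin on the mean-correlation gap (default 0.05).
#' @return data.frame of class `origin_assignment`: per group, `segment`,
#'   `mean_r`, `runner_up`, `gap`, `confident`, `candidates`; the full
#'   group x segment mean-correlation matrix is attached as attribute
#'   `"profile"`.
#' @export
assign_origin <- function(map, tumor_groups = rep("tumor", ncol(map$r)),
                          margin = 0.05) {
  stopifnot(inherits(map, "correlation_map"))
  if (length(tumor_groups) != ncol(map$r))
    stop_cdc("one group label per tumor sample is required")
  segs <- unique(map$segments)
  groups <- unique(tumor_groups)
  prof <- matrix(NA_real_, length(groups), length(segs),
                 dimnames = list(groups, segs))
  for (g in groups) {
    jc <- tumor_groups == g
    for (s in segs) {
      jr <- map$segments == s
      prof[g, s] <- mean(map$r[jr, jc], na.rm = TRUE)
    }
  }
  out <- do.call(rbind, lapply(groups, function(g) {
    ord <- order(prof[g, ], decreasing = TRUE)
    gap <- prof[g, ord[1]] - prof[g, ord[2]]
    cand <- segs[prof[g, ] > prof[g, ord[1]] - margin]
    data.frame(group = g, segment = segs[ord[1]],
               mean_r = prof[g, ord[1]], runner_up = segs[ord[2]],
               gap = gap, confident = gap >= margin,
               candidates = paste(cand, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  attr(out, "profile") <- prof
  class(out) <- c("origin_assignment", "data.frame")
  out
}

#' Map tumors onto nephron segments end to end
#'
#' Convenience wrapper: centre tumors on the designated cohort centroid,
#' centre the atlas on per-gene medians, match symbols case-insensitively,
#' correlate, and assign origins per tumor group.
#'
#' @param tumors genes x samples log-expression matrix (uncentred).
#' @param atlas an [atlas_profile_set] (uncentred).
#' @param cohort_labels cohort label per tumor sample.
#' @param centroid_cohorts cohorts defining the centring centroid. Default:
#'   every cohort except `CDC` (the comparator cohorts), so the cohort of
#'   interest does not pull the reference point toward itself; when no other
#'   cohort exists, all cohorts are used (plain gene-mean centring).
#' @param min_shared minimum shared genes (default 100).
#' @param margin assignment confidence margin.
#' @return list with `map` (the `correlation_map`) and `assignment`.
#' @export
map_cell_of_origin <- function(tumors, atlas, cohort_labels = NULL,
                               centroid_cohorts = NULL, min_shared = 100,
                               margin = 0.05) {
  tumors <- as.matrix(tumors)
  if (is.null(cohort_labels)) cohort_labels <- rep("tumor", ncol(tumors))
  if (is.null(centroid_cohorts)) {
    centroid_cohorts <- setdiff(unique(cohort_labels), "CDC")
    if (!length(centroid_cohorts)) centroid_cohorts <- unique(cohort_labels)
  }
  centred_t <- center_tumor_profiles(tumors, cohort_labels, centroid_cohorts)
  centred_a <- center_atlas_profiles(atlas)
  shared <- match_genes(rownames(tumors), rownames(atlas$profiles),
                        min_shared = min_shared)
  map <- interprofile_correlation(centred_t, centred_a, shared)
  list(map = map,
       assignment = assign_origin(map, cohort_labels, margin = margin))
}

#' Write a correlation map and assignment report
#'
#' @param map a `correlation_map`.
#' @param assignment an `origin_assignment`.
#' @param matrix_path TSV path for the correlation matrix.
#' @param report_path JSON path for the assignment report.
#' @return invisibly, the paths written.
#' @export
write_origin_outputs <- function(map, assignment, matrix_path, report_path) {
  tab <- data.frame(profile = rownames(map$r), segment = map$segments,
                    map$r, check.names = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(n_shared_genes = map$n_shared_genes, species = map$species,
         assignments = assignment[, setdiff(names(assignment), "profile")]),
    report_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(matrix_path, report_path))
}
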