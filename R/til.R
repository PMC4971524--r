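#' Summarise TIL percentages by marker and metastatic status
#'
#' Medians and ranges of tumor-infiltrating-lymphocyte percentages per
#' marker, overall and stratified by metastatic status.
#'
#' @param records data.frame with `marker`, `til_percent`, `metastatic`
#'   (e.g. from [simulate_til()] or [read_til_records()]).
#' @return data.frame: `marker`, `group` (overall / metastatic /
#'   non_metastatic), `n`, `median`, `min`, `max`.
#' @export
summarize_til <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    stop_cdc("no TIL records to summarise")
  if (any(records$til_percent < 0 | records$til_percent > 100))
    stop_cdc("TIL percentages must lie in [0, 100]")
  one <- function(v, marker, group) {
    data.frame(marker = marker, group = group, n = length(v),
               median = stats::median(v), min = min(v), max = max(v),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(unique(records$marker), function(mk) {
    r <- records[records$marker == mk, ]
    rbind(one(r$til_percent, mk, "overall"),
          if (any(r$metastatic))
            one(r$til_percent[r$metastatic], mk, "metastatic"),
          if (any(!r$metastatic))
            one(r$til_percent[!r$metastatic], mk, "non_metastatic"))
  }))
  rownames(out) <- NULL
  out
}

#' Rank-based two-group comparison (Mann-Whitney U)
#'
#' The two-group location comparison used for TIL percentages: Mann-Whitney
#' U with a two-sided p-value, computed exactly by enumeration of rank
#' assignments when the combined sample size is at most 12 and there are no
#' ties, and by the normal approximation with tie correction otherwise.
#'
#' @param a,b numeric vectors, both non-empty.
#' @return list with `u` (U statistic for `a`), `p_value`, and `method`
#'   (`"exact"` or `"normal_approx"`).
#' @export
compare_groups <- function(a, b) {
  if (!length(a) || !length(b)) stop_cdc("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b)) <= 12 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = !exact))
  list(u = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal_approx")
}

#' Compare metastatic vs non-metastatic TIL percentages per marker
#'
#' @param records TIL records (see [summarize_til()]).
#' @return data.frame: `marker`, `n_metastatic`, `n_non_metastatic`,
#'   `u`, `p_value`, `method`.
#' @export
compare_til_groups <- function(records) {
  out <- do.call(rbind, lapply(unique(records$marker), function(mk) {
    r <- records[records$marker == mk, ]
    met <- r$til_percent[r$metastatic]
    non <- r$til_percent[!r$metastatic]
    if (!length(met) || !length(non))
      stop_cdc("marker %s lacks one of the groups", mk)
    cmp <- compare_groups(met, non)
    data.frame(marker = mk, n_metastatic = length(met),
               n_non_metastatic = length(non), u = cmp$u,
               p_value = cmp$p_value, method = cmp$method,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read TIL records from CSV
#'
#' Expected columns: `case_id`, `marker`, `til_percent`, `metastatic`.
#'
#' @param path CSV path.
#' @return validated data.frame of records.
#' @export
read_til_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "marker", "til_percent", "metastatic")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    stop_cdc("TIL table missing column(s): %s", paste(miss, collapse = ", "))
  rec$metastatic <- as.logical(rec$metastatic)
  if (any(rec$til_percent < 0 | rec$til_percent > 100))
    stop_cdc("TIL percentages must lie in [0, 100]")
  rec
}
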