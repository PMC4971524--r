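#' Load the packaged 17-case CDC clinical table
#'
#' Returns the clinicopathological records of the 17 collecting duct carcinoma
#' cases the workflow was designed around, transcribed verbatim from the
#' published cohort table (including its capitalisation quirks in the pTNM
#' strings). Metastatic status at diagnosis is derived from the "M1" suffix of
#' the pTNM string, the only place the table encodes it.
#'
#' @return data.frame of class `clinical_table` with one row per case:
#'   `case_id`, `age`, `sex`, `surgery`, `tumor_size_cm`, `ptnm`,
#'   `ajcc_stage`, `metastatic_at_diagnosis`, `metastatic_sites`, `status`,
#'   `rnaseq_available`, `ihc_available`.
#' @export
load_clinical_fixture <- function() {
  path <- system.file("extdata", "cdc_clinical_cases.csv", package = "cdcseq",
                      mustWork = TRUE)
  read_clinical_table(path)
}

#' Read a clinical table from CSV
#'
#' @param path CSV with the columns of the packaged fixture.
#' @return data.frame of class `clinical_table`; see [load_clinical_fixture()].
#' @export
read_clinical_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "age", "sex", "surgery", "tumor_size_cm", "ptnm",
            "ajcc_stage", "metastatic_sites", "status", "rnaseq", "ihc")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop_cdc("clinical table missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(raw$case_id)) stop_cdc("duplicated case_id")
  if (any(raw$age < 0 | raw$age > 120)) stop_cdc("ages must lie in [0, 120]")
  if (!all(raw$ajcc_stage %in% 2:4))
    stop_cdc("AJCC stage must be 2, 3 or 4")
  if (!all(raw$sex %in% c("M", "F"))) stop_cdc("sex must be M or F")
  out <- data.frame(
    case_id = raw$case_id,
    age = as.numeric(raw$age),
    sex = raw$sex,
    surgery = raw$surgery,
    tumor_size_cm = as.numeric(raw$tumor_size_cm),
    ptnm = raw$ptnm,
    ajcc_stage = as.integer(raw$ajcc_stage),
    metastatic_at_diagnosis = grepl("M1$", raw$ptnm, ignore.case = TRUE),
    metastatic_sites = raw$metastatic_sites,
    status = raw$status,
    rnaseq_available = raw$rnaseq == "Yes",
    ihc_available = raw$ihc == "Yes",
    stringsAsFactors = FALSE
  )
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' Summarise a clinical table
#'
#' Cohort-level descriptives: median/min/max age (median as the middle order
#' statistic, mean of the two middle values for even n), sex counts, AJCC
#' stage distribution, metastatic fraction, and counts of cases with RNA-seq
#' and immunohistochemistry material.
#'
#' @param table a `clinical_table`.
#' @return list of class `clinical_summary`.
#' @export
summarize_clinical <- function(table) {
  if (!inherits(table, "clinical_table")) stop_cdc("need a clinical_table")
  if (nrow(table) == 0L) stop_cdc("clinical table is empty")
  stages <- table(factor(table$ajcc_stage, levels = 2:4))
  out <- list(
    n_cases = nrow(table),
    median_age = stats::median(table$age),
    min_age = min(table$age),
    max_age = max(table$age),
    sex_counts = c(M = sum(table$sex == "M"), F = sum(table$sex == "F")),
    stage_counts = stats::setNames(as.integer(stages), names(stages)),
    n_metastatic = sum(table$metastatic_at_diagnosis),
    metastatic_fraction = mean(table$metastatic_at_diagnosis),
    n_rnaseq = sum(table$rnaseq_available),
    n_ihc = sum(table$ihc_available)
  )
  class(out) <- "clinical_summary"
  out
}

#' @export
print.clinical_summary <- function(x, ...) {
  cat(sprintf("%d cases; median age %g (range %g-%g); M/F %d/%d\n",
              x$n_cases, x$median_age, x$min_age, x$max_age,
              x$sex_counts[["M"]], x$sex_counts[["F"]]))
  cat(sprintf("AJCC stages 2/3/4: %s; metastatic at diagnosis: %d (%.1f%%)\n",
              paste(x$stage_counts, collapse = "/"), x$n_metastatic,
              100 * x$metastatic_fraction))
  cat(sprintf("RNA-seq available: %d; IHC available: %d\n",
              x$n_rnaseq, x$n_ihc))
  invisible(x)
}
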