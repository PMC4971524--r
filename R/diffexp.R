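#' Method-of-moments dispersion estimate per gene
#'
#' For each gene, within every tissue group the sample mean m and variance s2
#' of the normalised counts give a moment estimate (s2 - m) / m^2 of the
#' negative-binomial dispersion alpha (Var = mu + alpha * mu^2). Group
#' estimates are pooled by their degrees of freedom (n_g - 1) and truncated
#' at zero; a gene at or below the Poisson boundary (s2 <= m) gets alpha = 0.
#' No shrinkage is applied, so the estimator is directly checkable against
#' its closed form.
#'
#' @param x a [count_matrix] or plain count matrix (genes x samples).
#' @param groups group label per sample.
#' @param factors optional per-sample scaling factors used to normalise
#'   counts before the moments are taken (default: all 1).
#' @return named numeric vector, one dispersion per gene.
#' @export
estimate_dispersion <- function(x, groups, factors = NULL) {
  cnt <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  if (ncol(cnt) < 2L) stop_cdc("need at least two samples")
  if (length(groups) != ncol(cnt))
    stop_cdc("one group label per sample is required")
  if (is.null(factors)) factors <- rep(1, ncol(cnt))
  y <- sweep(cnt, 2, factors, "/")
  num <- rep(0, nrow(cnt))
  den <- rep(0, nrow(cnt))
  for (g in unique(groups)) {
    j <- which(groups == g)
    if (length(j) < 2L) next
    m <- rowMeans(y[, j, drop = FALSE])
    s2 <- apply(y[, j, drop = FALSE], 1, stats::var)
    ok <- m > 0
    w <- length(j) - 1
    num[ok] <- num[ok] + w * (s2[ok] - m[ok]) / m[ok]^2
    den[ok] <- den[ok] + w
  }
  alpha <- ifelse(den > 0, pmax(0, num / den), 0)
  stats::setNames(alpha, rownames(cnt))
}

## one Fisher-scoring NB GLM fit, log link, cell-means design over groups.
## y: counts for one gene; offsets: log depth factors; alpha: dispersion.
nb_irls <- function(y, groups, offsets, alpha, max_iter = 50, tol = 1e-10) {
  glev <- unique(groups)
  X <- stats::model.matrix(~ 0 + factor(groups, levels = glev))
  colnames(X) <- glev
  p <- ncol(X)
  if (all(y == 0))
    return(list(coefficients = stats::setNames(rep(NA_real_, p), glev),
                standard_errors = stats::setNames(rep(NA_real_, p), glev),
                converged = FALSE, iterations = 0L, degenerate = TRUE))
  ## init from group means on the offset-adjusted scale
  adj <- y / exp(offsets)
  beta <- vapply(glev, function(g) log(mean(adj[groups == g]) + 1e-8),
                 numeric(1))
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    eta <- drop(X %*% beta) + offsets
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offsets) + (y - mu) / mu
    xtwx <- crossprod(X, X * w)
    beta_new <- tryCatch(drop(solve(xtwx, crossprod(X, w * z))),
                         error = function(e) rep(NA_real_, p))
    if (anyNA(beta_new) || any(!is.finite(beta_new))) break
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  se <- rep(NA_real_, p)
  if (converged) {
    eta <- drop(X %*% beta) + offsets
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    cov <- tryCatch(solve(crossprod(X, X * w)), error = function(e) NULL)
    if (is.null(cov)) converged <- FALSE else se <- sqrt(diag(cov))
  }
  list(coefficients = stats::setNames(beta, glev),
       standard_errors = stats::setNames(se, glev),
       converged = converged, iterations = it, degenerate = FALSE)
}

#' Fit a negative-binomial GLM to one gene and test group contrasts
#'
#' Maximises the NB log likelihood (log link, fixed dispersion, per-sample
#' log-scale offsets) by iteratively reweighted least squares over a
#' cell-means design on the tissue groups. For each requested pair of groups
#' the Wald statistic is the natural-log contrast estimate divided by its
#' standard error from the observed Fisher information, with a two-sided p
#' from the standard normal. Genes with all-zero counts are flagged
#' degenerate and not tested; non-convergence flags the fit and sets p to
#' missing.
#'
#' @param gene_counts integer counts for one gene (one per sample).
#' @param groups group label per sample (>= 2 groups).
#' @param offsets log-scale offsets, typically `log(scaling_factors)`.
#' @param dispersion NB dispersion alpha (0 gives the Poisson model).
#' @param contrasts list of group-label pairs; default all pairs in
#'   first-appearance order.
#' @return list of class `nb_fit`: `coefficients` and `standard_errors`
#'   (natural-log scale, one per group), `dispersion`, `converged`,
#'   `iterations`, and `tests` (data.frame with `contrast`, `log_estimate`,
#'   `se`, `log2fc`, `wald_stat`, `p_value`).
#' @export
fit_nb_wald <- function(gene_counts, groups, offsets = rep(0, length(groups)),
                        dispersion = 0, contrasts = NULL) {
  groups <- as.character(groups)
  if (length(unique(groups)) < 2L) stop_cdc("need at least two groups")
  if (length(gene_counts) != length(groups) ||
      length(offsets) != length(groups))
    stop_cdc("counts, groups and offsets must align")
  if (dispersion < 0) stop_cdc("dispersion must be non-negative")
  if (is.null(contrasts))
    contrasts <- utils::combn(unique(groups), 2, simplify = FALSE)
  fit <- nb_irls(gene_counts, groups, offsets, dispersion)
  tests <- do.call(rbind, lapply(contrasts, function(p) {
    a <- p[1]; b <- p[2]
    if (!all(c(a, b) %in% groups))
      stop_cdc("contrast group '%s' not present in design",
               setdiff(c(a, b), groups)[1])
    if (fit$converged && !fit$degenerate &&
        all(is.finite(fit$standard_errors[c(a, b)]))) {
      est <- fit$coefficients[[a]] - fit$coefficients[[b]]
      se <- sqrt(fit$standard_errors[[a]]^2 + fit$standard_errors[[b]]^2)
      z <- est / se
      pval <- 2 * stats::pnorm(-abs(z))
    } else {
      est <- se <- z <- pval <- NA_real_
    }
    data.frame(contrast = paste(a, b, sep = "_vs_"),
               log_estimate = est, se = se, log2fc = est / log(2),
               wald_stat = z, p_value = pval, stringsAsFactors = FALSE)
  }))
  structure(list(coefficients = fit$coefficients,
                 standard_errors = fit$standard_errors,
                 dispersion = dispersion, converged = fit$converged,
                 degenerate = fit$degenerate, iterations = fit$iterations,
                 tests = tests),
            class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf("nb_fit (alpha = %g, %s after %d iterations)\n", x$dispersion,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' q_i = min over j >= i of (m * p_(j) / j), capped at 1 and mapped back to
#' the input order, with m the number of non-missing p-values; missing
#' p-values propagate as missing.
#'
#' @param p numeric p-values in [0, 1]; `NA` allowed.
#' @return numeric q-values, same length and order.
#' @export
adjust_bh <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop_cdc("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Classify genes as up, down or not significant
#'
#' A gene is `up` iff signed fold change >= `fc_cut` and q < `fdr_cut`,
#' `down` iff signed fold change <= -`fc_cut` and q < `fdr_cut`, else `ns`.
#' The fold-change boundary is inclusive and the FDR boundary strict,
#' matching the ">= 2 / <= -2 and FDR < 0.05" convention. Genes with missing
#' q (unconverged fits) are `ns`.
#'
#' @param results data.frame with columns `signed_fc` and `q_value`.
#' @param fc_cut linear fold-change threshold (>= 1).
#' @param fdr_cut FDR threshold.
#' @return `results` with a `call` column (`up`/`down`/`ns`).
#' @export
classify_de <- function(results, fc_cut = 2, fdr_cut = 0.05) {
  if (fc_cut < 1) stop_cdc("fc_cut must be >= 1")
  call <- rep("ns", nrow(results))
  sig <- !is.na(results$q_value) & results$q_value < fdr_cut
  call[sig & results$signed_fc >= fc_cut] <- "up"
  call[sig & results$signed_fc <= -fc_cut] <- "down"
  results$call <- call
  results
}

## signed linear fold change: +2^lfc for lfc >= 0, -2^(-lfc) otherwise
signed_fold_change <- function(log2fc) {
  ifelse(log2fc >= 0, 2^log2fc, -(2^(-log2fc)))
}

#' Pairwise differential expression over a count matrix
#'
#' Orchestrates the whole per-gene pipeline: CPM expression filter,
#' median-of-ratios scaling factors, method-of-moments dispersion, NB GLM
#' fits with Wald contrasts, Benjamini-Hochberg adjustment within each
#' contrast across all tested genes, and up/down/ns classification.
#'
#' @param x a [count_matrix].
#' @param annotations data.frame with `sample_id` and a grouping column
#'   (`tissue_type` by default) covering every sample of `x`.
#' @param contrasts list of group-label pairs to test; default all pairs.
#' @param group_col name of the grouping column in `annotations`.
#' @param fc_cut,fdr_cut classification thresholds (see [classify_de()]).
#' @param cpm_threshold expression-filter threshold.
#' @return data.frame of class `de_table`: `gene_id`, `contrast`, `log2fc`,
#'   `signed_fc`, `wald_stat`, `p_value`, `q_value`, `call`, `converged`.
#' @export
run_pairwise_de <- function(x, annotations, contrasts = NULL,
                            group_col = "tissue_type",
                            fc_cut = 2, fdr_cut = 0.05, cpm_threshold = 1) {
  stopifnot(inherits(x, "count_matrix"))
  idx <- match(x$sample_ids, annotations$sample_id)
  if (anyNA(idx)) stop_cdc("annotations do not cover every sample")
  groups <- as.character(annotations[[group_col]][idx])
  if (is.null(contrasts))
    contrasts <- utils::combn(unique(groups), 2, simplify = FALSE)
  for (p in contrasts) {
    miss <- setdiff(p, groups)
    if (length(miss))
      stop_cdc("contrast label '%s' absent from annotations", miss[1])
  }
  filtered <- filter_low_expression(x, threshold = cpm_threshold)
  factors <- compute_scaling_factors(filtered)
  offsets <- log(factors)
  alpha <- estimate_dispersion(filtered, groups, factors)
  fits <- lapply(seq_along(filtered$gene_ids), function(i) {
    fit_nb_wald(filtered$counts[i, ], groups, offsets, alpha[[i]], contrasts)
  })
  res <- do.call(rbind, lapply(seq_along(fits), function(i) {
    t <- fits[[i]]$tests
    t$gene_id <- filtered$gene_ids[i]
    t$converged <- fits[[i]]$converged
    t
  }))
  res$signed_fc <- signed_fold_change(res$log2fc)
  res$q_value <- NA_real_
  for (ctr in unique(res$contrast)) {
    j <- res$contrast == ctr
    res$q_value[j] <- adjust_bh(res$p_value[j])
  }
  res <- classify_de(res, fc_cut = fc_cut, fdr_cut = fdr_cut)
  res <- res[, c("gene_id", "contrast", "log2fc", "signed_fc", "wald_stat",
                 "p_value", "q_value", "call", "converged")]
  class(res) <- c("de_table", "data.frame")
  res
}

#' Write a differential-expression table as TSV
#' @param x a `de_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
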