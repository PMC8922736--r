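#' Wilcoxon rank-sum differential-expression pipeline
#'
#' The recommended non-parametric pipeline for large-sample two-condition
#' designs: low-expression filtering, TMM scaling factors, CPM, per-gene
#' two-sided Wilcoxon rank-sum test on the CPM values of the two groups, and
#' Benjamini-Hochberg correction. The per-gene statistic is the rank sum of
#' the level-2 group; log2 fold changes are level 2 versus level 1.
#'
#' @param m count matrix.
#' @param labels two-level named factor over `m`'s samples.
#' @param fdr_threshold FDR threshold recorded with the result (used by
#'   [write_de_result()]'s `discovered` column); discovery sets at any
#'   threshold come from [discoveries()].
#' @param exact_limit passed to [wilcoxon_p()].
#' @param use_effective use TMM-effective (default) or raw library sizes for
#'   the CPM fed to the test.
#' @return data.frame with one row per gene of `m`: `gene_id`, `statistic`,
#'   `log2fc`, `p_value`, `q_value`; filtered genes carry `NA` p and q.
#'   Attributes: `method_name`, `fdr_threshold`, `kept_gene_ids`, `levels`.
#' @export
run_wilcoxon_pipeline <- function(m, labels, fdr_threshold = 0.05,
                                  exact_limit = 25L, use_effective = TRUE) {
  stopifnot(fdr_threshold > 0, fdr_threshold < 1)
  fd <- filter_low_expression(m, labels)
  kept <- fd$kept_gene_ids
  res <- data.frame(gene_id = rownames(m), statistic = NA_real_,
                    log2fc = NA_real_, p_value = NA_real_, q_value = NA_real_,
                    stringsAsFactors = FALSE)
  lab <- labels[colnames(m)]
  if (length(kept)) {
    mk <- m[kept, , drop = FALSE]
    norm <- tmm_factors(mk)
    cp <- cpm(mk, norm, use_effective = use_effective)
    idx2 <- lab == levels(lab)[2L]
    tests <- apply(cp, 1L, function(v) {
      wt <- wilcoxon_p(v[idx2], v[!idx2], exact_limit = exact_limit)
      c(wt$p_value, wt$statistic)
    })
    ki <- match(kept, res$gene_id)
    res$p_value[ki] <- tests[1L, ]
    res$statistic[ki] <- tests[2L, ]
    res$log2fc[ki] <- log2_fold_change(cp, lab)
    res$q_value <- benjamini_hochberg(res$p_value)
  }
  structure(res, method_name = "wilcoxon", fdr_threshold = fdr_threshold,
            kept_gene_ids = kept, levels = levels(lab))
}

#' Negative-binomial Wald differential-expression pipeline
#'
#' A deliberately simple parametric comparator sharing the Wilcoxon pipeline's
#' filtering and TMM normalization: per kept gene, group-specific NB means with
#' log effective-library-size offsets and a profiled gene-wise dispersion, a
#' Wald test of equal means, and Benjamini-Hochberg correction. It performs no
#' dispersion shrinkage and no outlier handling, so it exhibits the
#' anti-conservative behavior of parametric DE tests when counts violate the
#' NB model; it is not a replica of any published tool.
#'
#' @inheritParams run_wilcoxon_pipeline
#' @return data.frame as in [run_wilcoxon_pipeline()] with `statistic` the
#'   Wald z; attribute `nb_fit` carries the per-gene fit table.
#' @export
nb_wald_pipeline <- function(m, labels, fdr_threshold = 0.05) {
  stopifnot(fdr_threshold > 0, fdr_threshold < 1)
  fd <- filter_low_expression(m, labels)
  kept <- fd$kept_gene_ids
  res <- data.frame(gene_id = rownames(m), statistic = NA_real_,
                    log2fc = NA_real_, p_value = NA_real_, q_value = NA_real_,
                    stringsAsFactors = FALSE)
  lab <- labels[colnames(m)]
  fit <- NULL
  if (length(kept)) {
    mk <- m[kept, , drop = FALSE]
    norm <- tmm_factors(mk)
    fit <- nb_wald_fit(mk, norm$effective_library_sizes, lab)
    ki <- match(kept, res$gene_id)
    res$p_value[ki] <- fit$p_value
    res$statistic[ki] <- fit$z
    res$log2fc[ki] <- fit$log_ratio / log(2)
    res$q_value <- benjamini_hochberg(res$p_value)
  }
  structure(res, method_name = "nbwald", fdr_threshold = fdr_threshold,
            kept_gene_ids = kept, levels = levels(lab), nb_fit = fit)
}

#' Load an externally produced per-gene p-value table as a DE result
#'
#' Adapter so results computed by other tools can enter the evaluation stages.
#' q-values are recomputed with [benjamini_hochberg()].
#'
#' @param path TSV with columns `gene_id`, `p_value` and optionally `log2fc`
#'   and `statistic`.
#' @param method_name name recorded on the result.
#' @return DE result data.frame as in [run_wilcoxon_pipeline()].
#' @export
load_external_result <- function(path, method_name = "external") {
  df <- read_tsv_meta(path)
  if (!all(c("gene_id", "p_value") %in% colnames(df))) {
    stop("external result needs columns 'gene_id' and 'p_value': ", path)
  }
  res <- data.frame(gene_id = as.character(df$gene_id),
                    statistic = if ("statistic" %in% colnames(df)) as.numeric(df$statistic) else NA_real_,
                    log2fc = if ("log2fc" %in% colnames(df)) as.numeric(df$log2fc) else NA_real_,
                    p_value = as.numeric(df$p_value),
                    stringsAsFactors = FALSE)
  res$q_value <- benjamini_hochberg(res$p_value)
  structure(res, method_name = method_name,
            kept_gene_ids = res$gene_id[!is.na(res$p_value)])
}

#' Write a DE result table
#'
#' @param result DE result data.frame.
#' @param path output TSV.
#' @param threshold optional FDR threshold adding a `discovered` column
#'   (strict `q < threshold`).
#' @param meta extra metadata lines.
#' @return `path`, invisibly.
#' @export
write_de_result <- function(result, path, threshold = attr(result, "fdr_threshold"),
                            meta = list()) {
  df <- result[, c("gene_id", "statistic", "log2fc", "p_value", "q_value")]
  meta <- c(list(method = attr(result, "method_name") %||% "unknown"), meta)
  if (!is.null(threshold)) {
    df$discovered <- !is.na(df$q_value) & df$q_value < threshold
    meta$fdr_threshold <- threshold
  }
  write_tsv_meta(df, path, meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
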