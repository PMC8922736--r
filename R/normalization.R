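#' Filter genes with very low counts
#'
#' A gene is kept iff (a) its CPM computed on raw library sizes reaches the
#' data-driven threshold `T = 10 / (median raw library size / 1e6)` in at least
#' `k` samples, where `k` is the size of the smaller condition group, and
#' (b) its total count across all samples is at least `min_total_count`.
#' This reproduces the behavior of the usual expression filter used ahead of
#' TMM normalization while being fully specified here.
#'
#' @param m count matrix.
#' @param labels two-level named factor aligned to `m`'s samples.
#' @param min_total_count minimum total count across all samples (default 15).
#' @return list with `kept_gene_ids` and `params`
#'   (`cpm_threshold`, `min_samples`, `min_total_count`).
#' @export
filter_low_expression <- function(m, labels, min_total_count = 15L) {
  validate_labels(labels)
  lab <- labels[colnames(m)]
  if (anyNA(names(lab))) stop("labels do not cover all samples of m")
  lib <- colSums(m)
  if (any(lib <= 0)) {
    stop("degenerate sample with zero library size: ",
         colnames(m)[which(lib <= 0)[1L]])
  }
  cpm_threshold <- 10 / (stats::median(lib) / 1e6)
  k <- min(table(lab))
  raw_cpm <- sweep(m, 2L, lib, "/") * 1e6
  keep <- rowSums(raw_cpm >= cpm_threshold) >= k & rowSums(m) >= min_total_count
  list(kept_gene_ids = rownames(m)[keep],
       params = list(cpm_threshold = cpm_threshold,
                     min_samples = as.integer(k),
                     min_total_count = as.integer(min_total_count)))
}

# 75th-percentile count/library-size ratio used to pick the TMM reference
.tmm_q75 <- function(m, lib) {
  vapply(seq_len(ncol(m)),
         function(j) stats::quantile(m[, j] / lib[j], 0.75, names = FALSE),
         0)
}

#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Between-sample scaling factors from weighted, doubly trimmed gene-wise
#' log-ratios against a reference sample. The reference is the sample whose
#' 75th-percentile count/library-size ratio is closest to the mean of that
#' quantity (ties broken by lowest column index). For each other sample j,
#' over genes with positive counts in both j and the reference r:
#' `M_g = log2((y_gj/N_j)/(y_gr/N_r))`, `A_g = 0.5*log2((y_gj/N_j)*(y_gr/N_r))`,
#' precision weight `w_g = 1 / ((N_j-y_gj)/(N_j*y_gj) + (N_r-y_gr)/(N_r*y_gr))`.
#' Genes outside the central `1 - trim_m` mass of M or the central `1 - trim_a`
#' mass of A (equal-tail trimming by rank, lower ranks kept on boundary ties)
#' are discarded, and `factor_j = 2^(sum(w*M)/sum(w))`. Factors are finally
#' rescaled to geometric mean 1.
#'
#' @param m count matrix with at least two samples, all library sizes positive.
#' @param trim_m fraction of the M distribution trimmed in total (default 0.30,
#'   i.e. 15% per tail).
#' @param trim_a fraction of the A distribution trimmed in total (default 0.05).
#' @return list with `library_sizes`, `scaling_factors` (geometric mean 1) and
#'   `effective_library_sizes` (= library_sizes * scaling_factors), each named
#'   by sample.
#' @export
tmm_factors <- function(m, trim_m = 0.30, trim_a = 0.05) {
  validate_count_matrix(m)
  if (ncol(m) < 2L) stop("TMM needs at least 2 samples")
  lib <- colSums(m)
  if (any(lib <= 0)) stop("sample with zero library size: ",
                          colnames(m)[which(lib <= 0)[1L]])
  q75 <- .tmm_q75(m, lib)
  r <- which.min(abs(q75 - mean(q75)))[1L]
  f <- rep(1, ncol(m))
  for (j in seq_len(ncol(m))) {
    if (j == r) next
    f[j] <- .tmm_pair_factor(m[, j], m[, r], lib[j], lib[r], trim_m, trim_a,
                             sample_id = colnames(m)[j])
  }
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(m)
  list(library_sizes = lib,
       scaling_factors = f,
       effective_library_sizes = lib * f)
}

.tmm_pair_factor <- function(yj, yr, Nj, Nr, trim_m, trim_a, sample_id = "?") {
  pos <- yj > 0 & yr > 0
  yj <- yj[pos]; yr <- yr[pos]
  M <- log2((yj / Nj) / (yr / Nr))
  A <- 0.5 * log2((yj / Nj) * (yr / Nr))
  w <- 1 / ((Nj - yj) / (Nj * yj) + (Nr - yr) / (Nr * yr))
  ok <- is.finite(M) & is.finite(A) & is.finite(w)
  M <- M[ok]; A <- A[ok]; w <- w[ok]
  n <- length(M)
  keep_central <- function(x, trim) {
    k <- floor(n * trim / 2)
    rk <- rank(x, ties.method = "first")
    rk > k & rk <= n - k
  }
  keep <- keep_central(M, trim_m) & keep_central(A, trim_a)
  if (sum(keep) < 10L) {
    warning("fewer than 10 genes survive TMM trimming for sample ", sample_id,
            "; factor set to 1")
    return(1)
  }
  2 ^ (sum(w[keep] * M[keep]) / sum(w[keep]))
}

#' Counts per million
#'
#' @param m count matrix.
#' @param norm normalization result from [tmm_factors()]; its effective library
#'   sizes are used. Pass `use_effective = FALSE` to scale by raw library sizes.
#' @param use_effective logical; divide by TMM-effective (default) or raw
#'   library sizes.
#' @return real-valued matrix, same dimnames as `m`:
#'   `count / library size * 1e6`.
#' @export
cpm <- function(m, norm = tmm_factors(m), use_effective = TRUE) {
  sizes <- if (use_effective) norm$effective_library_sizes else norm$library_sizes
  if (!identical(names(sizes), colnames(m))) {
    sizes <- sizes[colnames(m)]
    if (anyNA(sizes)) stop("normalization result does not cover all samples of m")
  }
  sweep(m, 2L, sizes, "/") * 1e6
}

#' Per-gene log2 fold change of mean CPM (level 2 vs level 1)
#'
#' @param cpm_matrix real-valued CPM matrix.
#' @param labels two-level named factor over the matrix's samples.
#' @param pseudocount positive stabilizer added to both group means (default 1).
#' @return named numeric vector,
#'   `log2((mean2 + pseudocount) / (mean1 + pseudocount))` per gene.
#' @export
log2_fold_change <- function(cpm_matrix, labels, pseudocount = 1.0) {
  stopifnot(pseudocount > 0)
  validate_labels(labels)
  lab <- labels[colnames(cpm_matrix)]
  m1 <- rowMeans(cpm_matrix[, lab == levels(lab)[1L], drop = FALSE])
  m2 <- rowMeans(cpm_matrix[, lab == levels(lab)[2L], drop = FALSE])
  log2((m2 + pseudocount) / (m1 + pseudocount))
}
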