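#' False discovery proportion
#'
#' Proportion of false positives among the discoveries; 0 when the discovery
#' set is empty (convention).
#'
#' @param disc character vector of discovered gene ids.
#' @param truth character vector of true DEG ids.
#' @return numeric in `[0, 1]`.
#' @export
fdp <- function(disc, truth) {
  if (length(disc) == 0L) return(0)
  length(setdiff(disc, truth)) / length(disc)
}

#' Empirical power
#'
#' Proportion of true DEGs identified as DEGs.
#'
#' @inheritParams fdp
#' @return numeric in `[0, 1]`.
#' @export
empirical_power <- function(disc, truth) {
  if (length(truth) == 0L) stop("empirical power is undefined for an empty truth set")
  length(intersect(disc, truth)) / length(truth)
}

#' Evaluate DE methods across replicates and FDR thresholds
#'
#' For every (method, threshold) pair computes the per-replicate FDP and
#' empirical power of the discovery set, then the across-replicate means: the
#' mean FDP estimates the actual FDR at that claimed (nominal) level, and the
#' mean empirical power estimates the power.
#'
#' @param results_by_method named list; each element a list of per-replicate
#'   DE result data.frames.
#' @param truths list of per-replicate true-DEG id vectors (same length as
#'   each method's replicate list).
#' @param thresholds nominal BH FDR thresholds. The default grid is
#'   `c(1e-5, 1e-4, 1e-3, 0.01, 0.05)` (0.001% to 5%).
#' @return list of class `"evaluation_summary"`: `summary` data.frame with
#'   columns method, claimed_fdr, actual_fdr, power, R; `fdp` and `power`
#'   per-replicate matrices (rows = replicates) per method/threshold, stored
#'   as named lists of matrices.
#' @export
evaluate_methods <- function(results_by_method, truths,
                             thresholds = c(1e-5, 1e-4, 1e-3, 0.01, 0.05)) {
  stopifnot(length(results_by_method) >= 1L, !is.null(names(results_by_method)))
  R <- length(truths)
  rows <- list()
  fdp_store <- list()
  pow_store <- list()
  for (meth in names(results_by_method)) {
    reps <- results_by_method[[meth]]
    if (length(reps) != R) {
      stop("method '", meth, "' has ", length(reps),
           " replicates but ", R, " truth sets were supplied")
    }
    fmat <- matrix(NA_real_, R, length(thresholds),
                   dimnames = list(NULL, format(thresholds)))
    pmat <- fmat
    for (r in seq_len(R)) {
      for (t in seq_along(thresholds)) {
        disc <- discoveries(reps[[r]], thresholds[t])
        fmat[r, t] <- fdp(disc, truths[[r]])
        pmat[r, t] <- empirical_power(disc, truths[[r]])
      }
    }
    fdp_store[[meth]] <- fmat
    pow_store[[meth]] <- pmat
    rows[[meth]] <- data.frame(method = meth, claimed_fdr = thresholds,
                               actual_fdr = colMeans(fmat),
                               power = colMeans(pmat), R = R,
                               row.names = NULL)
  }
  structure(list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 fdp = fdp_store, power = pow_store),
            class = "evaluation_summary")
}

#' Power at matched actual FDR
#'
#' Power comparisons across methods are only meaningful at equal actual FDR,
#' not at equal nominal threshold. Per method the (actual FDR, power) pairs of
#' the threshold sweep are made non-decreasing in actual FDR by their isotonic
#' upper envelope (cumulative maximum after sorting by actual FDR) and then
#' linearly interpolated at the query FDRs; queries outside the observed range
#' yield `NA`.
#'
#' @param summary `"evaluation_summary"` object spanning at least two
#'   thresholds.
#' @param query_fdrs actual-FDR values at which to read off power.
#' @return data.frame with columns method, actual_fdr, power.
#' @export
power_at_actual_fdr <- function(summary, query_fdrs) {
  stopifnot(inherits(summary, "evaluation_summary"))
  df <- summary$summary
  out <- lapply(split(df, df$method), function(d) {
    if (nrow(d) < 2L) stop("need at least two thresholds per method")
    o <- order(d$actual_fdr, d$power)
    x <- d$actual_fdr[o]
    y <- cummax(d$power[o]) # isotonic upper envelope
    keep <- !duplicated(x, fromLast = TRUE) # one point per x: the hull value
    p <- if (sum(keep) >= 2L) {
      stats::approx(x[keep], y[keep], xout = query_fdrs, rule = 1)$y
    } else {
      ifelse(query_fdrs == x[keep], y[keep], NA_real_)
    }
    data.frame(method = d$method[1L], actual_fdr = query_fdrs, power = p)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Summarize discoveries across permutation-null datasets
#'
#' @param original DE result on the unpermuted data.
#' @param permuted list of DE results on label-permuted datasets (common gene
#'   universe with `original`).
#' @param threshold FDR threshold defining a discovery.
#' @return list of class `"permutation_summary"`: `original_count`,
#'   `original_discoveries`, `perm_counts` (length B), `gene_freq` (named,
#'   fraction of permutations in which each gene was identified),
#'   `exceed_fraction` (fraction of permutations yielding more discoveries
#'   than the original data), `B`, `threshold`.
#' @export
permutation_summary <- function(original, permuted, threshold) {
  if (length(permuted) == 0L) stop("no permuted results supplied")
  orig_disc <- discoveries(original, threshold)
  genes <- original$gene_id
  freq <- structure(numeric(length(genes)), names = genes)
  counts <- integer(length(permuted))
  for (b in seq_along(permuted)) {
    d <- discoveries(permuted[[b]], threshold)
    counts[b] <- length(d)
    freq[d] <- freq[d] + 1
  }
  freq <- freq / length(permuted)
  structure(list(original_count = length(orig_disc),
                 original_discoveries = orig_disc,
                 perm_counts = counts,
                 gene_freq = freq,
                 exceed_fraction = mean(counts > length(orig_disc)),
                 B = length(permuted),
                 threshold = threshold),
            class = "permutation_summary")
}

#' Genes recurrently identified across permutations, and their overlap with
#' the original discoveries
#'
#' @param ps `"permutation_summary"` object.
#' @param min_pct minimum identification percentage (e.g. 50 for ">= 50% of
#'   permutations").
#' @return list with `gene_ids`, `n`, `overlap_with_original` and
#'   `overlap_fraction` (share of original discoveries that are recurrent).
#' @export
recurrent_genes <- function(ps, min_pct) {
  ids <- names(ps$gene_freq)[ps$gene_freq >= min_pct / 100]
  ov <- intersect(ids, ps$original_discoveries)
  list(gene_ids = ids, n = length(ids),
       overlap_with_original = ov,
       overlap_fraction = if (ps$original_count > 0)
         length(ov) / ps$original_count else NA_real_)
}

#' Permutation-identification frequency ordered by original fold change
#'
#' Restricted to the original discovery set: genes sorted by absolute log2
#' fold change in the original data (descending, ties by gene id), paired with
#' the fraction of permutations in which each was identified. No smoothing is
#' applied.
#'
#' @param ps `"permutation_summary"` object.
#' @param log2fc named per-gene log2 fold changes from the original analysis.
#' @return data.frame with columns rank, gene_id, abs_log2fc, frequency.
#' @export
foldchange_frequency_profile <- function(ps, log2fc) {
  ids <- ps$original_discoveries
  if (length(ids) == 0L) {
    return(data.frame(rank = integer(0), gene_id = character(0),
                      abs_log2fc = numeric(0), frequency = numeric(0)))
  }
  afc <- abs(log2fc[ids])
  o <- order(-afc, ids)
  data.frame(rank = seq_along(ids), gene_id = ids[o], abs_log2fc = afc[o],
             frequency = unname(ps$gene_freq[ids[o]]), row.names = NULL)
}
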