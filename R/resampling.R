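#' Generate permuted condition-label vectors
#'
#' Produces `B` independent uniform permutations of the label vector while the
#' sample order of the count matrix stays untouched; every gene detected on a
#' permuted dataset is a false positive by construction. Each permutation's
#' seed derives deterministically from `(seed, index)`.
#'
#' @param labels two-level named factor.
#' @param B number of permutations.
#' @param seed integer seed.
#' @return list with `base_labels`, `B`, `seed` and `permuted_labels`, a list
#'   of `B` named factors (same names/order as `labels`, values permuted).
#' @export
permute_labels <- function(labels, B, seed) {
  validate_labels(labels)
  stopifnot(B >= 1)
  perms <- lapply(seq_len(B), function(b) {
    with_seed(derive_seed(seed, 1L, b), {
      f <- sample(as.character(labels))
      condition_labels(names(labels), f, levels = levels(labels))
    })
  })
  list(base_labels = labels, B = as.integer(B), seed = as.integer(seed),
       permuted_labels = perms)
}

#' Define true DEGs as the cross-method intersection at a strict threshold
#'
#' On real data without ground truth, genes called by every supplied method at
#' a very small FDR threshold serve as the true-DEG set for semi-synthetic
#' benchmark construction.
#'
#' @param results list of at least two DE result data.frames over a common
#'   gene universe.
#' @param strict_threshold FDR threshold (default 1e-6, i.e. 0.0001%).
#' @return list with `true_deg_ids` and `provenance = "method-intersection"`.
#' @export
define_true_degs <- function(results, strict_threshold = 1e-6) {
  if (length(results) < 2L) {
    stop("true-DEG definition requires at least two methods' results")
  }
  universes <- lapply(results, `[[`, "gene_id")
  common <- Reduce(intersect, universes)
  if (length(common) == 0L) stop("results have disjoint gene universes")
  sets <- lapply(results, discoveries, threshold = strict_threshold)
  list(true_deg_ids = Reduce(intersect, sets),
       provenance = "method-intersection")
}

#' Build one semi-synthetic dataset with known true DEGs
#'
#' `k = round(select_fraction * |truth|)` true DEGs are sampled uniformly
#' without replacement and keep their observed counts in both conditions; for
#' every other gene the pooled row `(X_i, Y_i)` is uniformly permuted and split
#' back by original column positions, making it exchangeable across conditions
#' (a true negative). Per-gene permutation seeds derive from `(seed, gene
#' index)` so the result is independent of traversal order.
#'
#' @param X,Y count matrices for the two conditions (same genes, same order).
#' @param truth list from [define_true_degs()] or a character vector of true
#'   DEG ids.
#' @param select_fraction fraction of true DEGs preserved (default 0.5).
#' @param seed integer seed.
#' @param replicate_index index recorded on the dataset.
#' @return list of class `"semi_synthetic"` with `X`, `Y`,
#'   `selected_true_degs`, `replicate_index`, `seed`.
#' @export
make_semisynthetic <- function(X, Y, truth, select_fraction = 0.5, seed,
                               replicate_index = 1L) {
  if (is.list(truth)) truth <- truth$true_deg_ids
  stopifnot(identical(rownames(X), rownames(Y)),
            select_fraction > 0, select_fraction <= 1)
  if (!all(truth %in% rownames(X))) {
    stop("truth contains ids absent from the matrices")
  }
  if (length(truth) == 0L) stop("empty truth set with select_fraction > 0")
  k <- round(select_fraction * length(truth))
  selected <- with_seed(derive_seed(seed, 2L, 0L),
                        sample(truth, size = k, replace = FALSE))
  n1 <- ncol(X)
  Xp <- X; Yp <- Y
  to_permute <- setdiff(rownames(X), selected)
  idx <- match(to_permute, rownames(X))
  for (i in idx) {
    pooled <- c(X[i, ], Y[i, ])
    perm <- with_seed(derive_seed(seed, 3L, i), sample(pooled))
    Xp[i, ] <- perm[seq_len(n1)]
    Yp[i, ] <- perm[-seq_len(n1)]
  }
  structure(list(X = Xp, Y = Yp, selected_true_degs = sort(selected),
                 replicate_index = as.integer(replicate_index),
                 seed = as.integer(seed)),
            class = "semi_synthetic")
}

#' Down-sample a semi-synthetic dataset to n columns per condition
#'
#' @param ds `"semi_synthetic"` object.
#' @param n per-condition sample size, `2 <= n <= min(ncol(X), ncol(Y))`.
#' @param seed integer seed.
#' @return `"semi_synthetic"` object with `n` columns per condition; the truth
#'   set is unchanged.
#' @export
downsample <- function(ds, n, seed) {
  stopifnot(inherits(ds, "semi_synthetic"))
  if (n < 2 || n > min(ncol(ds$X), ncol(ds$Y))) {
    stop("n must lie in [2, ", min(ncol(ds$X), ncol(ds$Y)), "]")
  }
  cx <- with_seed(derive_seed(seed, 4L, 1L), sort(sample(ncol(ds$X), n)))
  cy <- with_seed(derive_seed(seed, 4L, 2L), sort(sample(ncol(ds$Y), n)))
  structure(list(X = ds$X[, cx, drop = FALSE], Y = ds$Y[, cy, drop = FALSE],
                 selected_true_degs = ds$selected_true_degs,
                 replicate_index = ds$replicate_index,
                 seed = as.integer(seed)),
            class = "semi_synthetic")
}

#' Generate independent semi-synthetic replicates
#'
#' @inheritParams make_semisynthetic
#' @param R number of replicates (default 50).
#' @return list of `R` `"semi_synthetic"` objects with `replicate_index`
#'   1..R and per-replicate derived seeds.
#' @export
generate_replicates <- function(X, Y, truth, R = 50L, select_fraction = 0.5,
                                seed = 1L) {
  lapply(seq_len(R), function(r) {
    make_semisynthetic(X, Y, truth, select_fraction = select_fraction,
                       seed = derive_seed(seed, 5L, r), replicate_index = r)
  })
}

#' Reassemble a semi-synthetic dataset into one matrix plus labels
#'
#' @param ds `"semi_synthetic"` object.
#' @param level_names names for the two condition levels.
#' @return list with `counts` (X columns then Y columns) and `labels`.
#' @export
semisynthetic_to_dataset <- function(ds, level_names = c("cond1", "cond2")) {
  counts <- cbind(ds$X, ds$Y)
  labels <- condition_labels(colnames(counts),
                             rep(level_names, c(ncol(ds$X), ncol(ds$Y))),
                             levels = level_names)
  list(counts = counts, labels = labels)
}
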