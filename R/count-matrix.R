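#' Construct a validated gene-by-sample count matrix
#'
#' The package represents a count matrix as a plain numeric matrix with unique
#' rownames (gene ids) and colnames (sample ids), all entries non-negative
#' integers. Normalized, real-valued matrices (CPM) are a distinct downstream
#' product and are never re-ingested as counts.
#'
#' @param counts numeric matrix, genes in rows, samples in columns.
#' @param gene_ids,sample_ids optional identifier vectors; defaults to the
#'   dimnames of `counts`.
#' @return the validated count matrix (numeric matrix with dimnames).
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("count_matrix: gene and sample identifiers are required")
  }
  rownames(counts) <- as.character(gene_ids)
  colnames(counts) <- as.character(sample_ids)
  validate_count_matrix(counts)
  counts
}

#' Validate count-matrix invariants
#'
#' Checks unique gene/sample identifiers and non-negative integer entries.
#'
#' @param m matrix to check.
#' @return `m`, invisibly; stops with an informative error otherwise.
#' @export
validate_count_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("counts must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("counts must carry gene ids (rownames) and sample ids (colnames)")
  }
  if (anyDuplicated(rownames(m))) {
    dup <- rownames(m)[duplicated(rownames(m))][1L]
    stop("duplicate gene id: ", dup)
  }
  if (anyDuplicated(colnames(m))) {
    dup <- colnames(m)[duplicated(colnames(m))][1L]
    stop("duplicate sample id: ", dup)
  }
  if (anyNA(m)) stop("counts contain missing values")
  bad <- which(m < 0 | m != round(m))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(m))
    stop(sprintf("counts must be non-negative integers; offending entry gene '%s', sample '%s' (value %s)",
                 rownames(m)[i[1L]], colnames(m)[i[2L]], format(m[bad[1L]])))
  }
  invisible(m)
}

#' Construct two-condition sample labels
#'
#' @param sample_ids character vector of sample identifiers.
#' @param labels vector of condition labels, same length; must take exactly two
#'   distinct values, each on at least two samples.
#' @param levels optional explicit level order; defaults to lexicographic. Fold
#'   changes downstream are reported as level 2 versus level 1.
#' @return a named factor (names = sample ids) with two levels.
#' @export
condition_labels <- function(sample_ids, labels, levels = NULL) {
  sample_ids <- as.character(sample_ids)
  labels <- as.character(labels)
  if (length(sample_ids) != length(labels)) {
    stop("sample_ids and labels must have equal length")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  }
  lv <- if (is.null(levels)) sort(unique(labels)) else as.character(levels)
  f <- factor(labels, levels = lv)
  names(f) <- sample_ids
  validate_labels(f)
  f
}

#' @rdname condition_labels
#' @param labels_factor named factor to validate.
#' @export
validate_labels <- function(labels_factor) {
  if (!is.factor(labels_factor) || is.null(names(labels_factor))) {
    stop("labels must be a named factor")
  }
  if (anyNA(labels_factor)) stop("labels contain values outside the declared levels")
  if (nlevels(labels_factor) != 2L) {
    stop("more than two conditions" , if (nlevels(labels_factor) < 2L) " required: exactly two distinct levels" else "")
  }
  tab <- table(labels_factor)
  if (any(tab < 2L)) {
    stop("condition '", names(tab)[tab < 2L][1L], "' has fewer than 2 samples")
  }
  invisible(labels_factor)
}

#' Split a count matrix into its two condition sub-matrices
#'
#' Columns are aligned to the labels by sample identifier, not position, so a
#' reordered label table yields the same split. Within each condition the
#' original column order of `m` is preserved.
#'
#' @param m count matrix (see [count_matrix()]).
#' @param labels two-level named factor (see [condition_labels()]).
#' @return list with `X` (first level), `Y` (second level) and `levels`.
#' @export
split_by_condition <- function(m, labels) {
  validate_labels(labels)
  unmatched <- union(setdiff(colnames(m), names(labels)),
                     setdiff(names(labels), colnames(m)))
  if (length(unmatched)) {
    stop("sample ids do not match between counts and labels: ",
         paste(unmatched, collapse = ", "))
  }
  lab <- labels[colnames(m)] # align by id, keep m's column order
  list(X = m[, names(lab)[lab == levels(lab)[1L]], drop = FALSE],
       Y = m[, names(lab)[lab == levels(lab)[2L]], drop = FALSE],
       levels = levels(lab))
}
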