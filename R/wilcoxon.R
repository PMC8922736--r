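#' Two-sided Wilcoxon rank-sum (Mann-Whitney) p-value
#'
#' Exact enumeration of the null rank-sum distribution (via the Mann-Whitney U
#' distribution) when both group sizes are at most `exact_limit` and the pooled
#' values are tie-free; otherwise a normal approximation with tie-corrected
#' variance `n1*n2/12 * ((N+1) - sum(t^3 - t)/(N*(N-1)))` and continuity
#' correction 1/2. The two-sided p-value doubles the smaller tail, capped at 1.
#' The test is invariant to strictly monotone transformations of the pooled
#' values and symmetric in its arguments.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param exact_limit use the exact null distribution when both sizes are at
#'   most this and no ties are present (default 25).
#' @return list with `p_value`, `statistic` (rank sum of `x` within the pooled
#'   sample), `u` (Mann-Whitney U of `x`) and `exact` (logical).
#' @export
wilcoxon_p <- function(x, y, exact_limit = 25L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) stop("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("missing values in input")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  rk <- rank(pooled)
  W <- sum(rk[seq_len(n1)]) # rank sum of x
  U <- W - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && n1 <= exact_limit && n2 <= exact_limit) {
    lower <- stats::pwilcox(U, n1, n2)
    upper <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    p <- min(1, 2 * min(lower, upper))
    return(list(p_value = p, statistic = W, u = U, exact = TRUE))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(pooled)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sigma2 <= 0) { # all pooled values identical
    return(list(p_value = 1, statistic = W, u = U, exact = FALSE))
  }
  s <- sqrt(sigma2)
  lower <- stats::pnorm((U + 0.5 - mu) / s)
  upper <- stats::pnorm((U - 0.5 - mu) / s, lower.tail = FALSE)
  p <- min(1, 2 * min(lower, upper))
  list(p_value = p, statistic = W, u = U, exact = FALSE)
}

#' Benjamini-Hochberg q-values with missing values preserved
#'
#' Applies the BH step-up transform over the non-missing p-values only (so `m`
#' in `q_(i) = min_{j>=i} m*p_(j)/j` is the number of tested genes), restores
#' the original order, and leaves missing entries missing.
#'
#' @param pvalues numeric vector in `[0, 1]`, `NA` allowed.
#' @return numeric vector of q-values, same length and order, `NA` where the
#'   input was `NA`.
#' @export
benjamini_hochberg <- function(pvalues) {
  p <- as.numeric(pvalues)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  names(q) <- names(pvalues)
  q
}

#' Discovery set at an FDR threshold
#'
#' Strict inequality (`q < threshold`), matching the "FDR < t" convention.
#'
#' @param result a DE result data frame (see [run_wilcoxon_pipeline()]).
#' @param threshold FDR threshold in (0, 1].
#' @return character vector of discovered gene ids.
#' @export
discoveries <- function(result, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  q <- result$q_value
  result$gene_id[!is.na(q) & q < threshold]
}
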