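#' Negative-binomial goodness-of-fit poorness for one gene in one condition
#'
#' Chi-square goodness-of-fit of the NB law with fixed size `1/dispersion`
#' against a gene's normalized counts: values are rounded to integers and
#' tabulated over cells `0..max(value)` plus one open tail cell with expected
#' mass `1 - CDF(max)`; the NB mean is set to the sample mean (the fixed-size
#' maximum-likelihood estimate). Adjacent cells are pooled left to right until
#' each pooled cell reaches an expected count of `min_expected` (a trailing
#' remainder is merged into the last cell), which keeps the chi-square
#' reference distribution honest when the count range is wide and most raw
#' cells are nearly empty. Pearson `X^2` over the pooled cells is referred to
#' a chi-square with `df = cells - 2`. Poorness of fit is `-log10(p)`: larger
#' means a worse fit.
#'
#' @param counts non-negative normalized counts for one gene in one condition
#'   (at least 8 observations for a non-degenerate test).
#' @param dispersion NB dispersion `phi > 0` (variance `mu + phi*mu^2`).
#' @param min_expected minimum expected count per pooled cell (default 1).
#' @return list with `mean`, `dispersion`, `p_value`, `poorness`, `df`,
#'   `statistic`, `degenerate`. Degenerate inputs (too few observations, all
#'   values identical, or no degrees of freedom) carry `NA` p and poorness.
#' @export
nb_gof_poorness <- function(counts, dispersion, min_expected = 1) {
  stopifnot(dispersion > 0, all(counts >= 0))
  v <- round(as.numeric(counts))
  degen <- list(mean = mean(v), dispersion = dispersion, p_value = NA_real_,
                poorness = NA_real_, df = NA_integer_, statistic = NA_real_,
                degenerate = TRUE)
  if (length(v) < 8L || length(unique(v)) < 2L) return(degen)
  mu <- mean(v)
  size <- 1 / dispersion
  cells <- 0:max(v)
  obs <- tabulate(v + 1L, nbins = length(cells))
  dens <- stats::dnbinom(cells, size = size, mu = mu)
  tail_mass <- stats::pnbinom(max(v), size = size, mu = mu, lower.tail = FALSE)
  expd <- length(v) * c(dens, tail_mass)
  obs <- c(obs, 0L) # open tail cell: nothing observed beyond the maximum

  # pool adjacent cells until each reaches min_expected
  grp <- integer(length(expd))
  g <- 1L; acc <- 0
  for (i in seq_along(expd)) {
    grp[i] <- g
    acc <- acc + expd[i]
    if (acc >= min_expected) { g <- g + 1L; acc <- 0 }
  }
  if (acc > 0 && g > 1L) grp[grp == g] <- g - 1L # merge remainder leftwards
  po <- as.numeric(tapply(obs, grp, sum))
  pe <- as.numeric(tapply(expd, grp, sum))
  pos <- pe > 0
  df <- sum(pos) - 2L
  if (df <= 0L) return(degen)
  x2 <- sum((po[pos] - pe[pos])^2 / pe[pos])
  p <- stats::pchisq(x2, df = df, lower.tail = FALSE)
  list(mean = mu, dispersion = dispersion, p_value = p,
       poorness = -log10(p), df = df, statistic = x2, degenerate = FALSE)
}

#' Goodness-of-fit poorness table for a whole count matrix
#'
#' Applies [nb_gof_poorness()] per gene and condition on size-factor
#' normalized counts (counts divided by effective library size over its mean),
#' using supplied per-gene dispersions (e.g. those profiled by
#' [nb_wald_fit()]) so externally estimated dispersions can be audited.
#'
#' @param m count matrix.
#' @param labels two-level named factor.
#' @param dispersions named per-gene dispersion vector; genes without a finite
#'   dispersion are skipped.
#' @param norm normalization result from [tmm_factors()]; defaults to TMM on
#'   `m`.
#' @return data.frame: gene_id, condition, mean, dispersion, p_value,
#'   poorness, degenerate.
#' @export
nb_gof_table <- function(m, labels, dispersions, norm = tmm_factors(m)) {
  validate_labels(labels)
  lab <- labels[colnames(m)]
  eff <- norm$effective_library_sizes[colnames(m)]
  sf <- eff / mean(eff)
  normed <- sweep(m, 2L, sf, "/")
  genes <- intersect(rownames(m), names(dispersions)[is.finite(dispersions) & dispersions > 0])
  out <- vector("list", 2L * length(genes))
  k <- 0L
  for (g in genes) {
    for (lv in levels(lab)) {
      r <- nb_gof_poorness(normed[g, lab == lv], dispersions[[g]])
      k <- k + 1L
      out[[k]] <- data.frame(gene_id = g, condition = lv, mean = r$mean,
                             dispersion = r$dispersion, p_value = r$p_value,
                             poorness = r$poorness, degenerate = r$degenerate,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Aggregate a goodness-of-fit table per gene by worst (maximum) poorness
#'
#' @param gof_table output of [nb_gof_table()].
#' @return named numeric vector of per-gene poorness (NA if all conditions
#'   degenerate).
#' @export
gof_poorness_by_gene <- function(gof_table) {
  sp <- split(gof_table$poorness, gof_table$gene_id)
  vapply(sp, function(x) {
    x <- x[!is.na(x)]
    if (length(x)) max(x) else NA_real_
  }, 0)
}

#' Compare two groups of poorness values with the Wilcoxon rank-sum test
#'
#' @param a,b numeric poorness vectors; missing values are dropped.
#' @return two-sided p-value.
#' @export
compare_poorness_groups <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("a group is empty after dropping missing values")
  wilcoxon_p(a, b)$p_value
}
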