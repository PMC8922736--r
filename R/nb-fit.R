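# Vectorized two-group negative-binomial fits with gene-wise dispersion.
#
# Model per gene g, sample j:  y_gj ~ NB(mean = s_j * q_{g,c(j)}, var = mu + phi_g mu^2)
# with s_j a fixed per-sample offset (effective library size). The gene-wise
# dispersion phi_g is profiled: for a candidate phi the two group log-means are
# fit by Fisher scoring (the log-likelihood is concave in log q), and phi is
# maximized over a log-spaced grid refined by golden-section search.

.nb_fit_logmean <- function(Y, s, phi, t0 = NULL, iters = 8L) {
  # per-gene MLE of t = log q for fixed per-gene phi; all genes at once
  if (is.null(t0)) t0 <- log((rowSums(Y) + 0.5) / sum(s))
  t <- t0
  for (it in seq_len(iters)) {
    mu <- exp(t) %o% s
    denom <- 1 + phi * mu
    score <- rowSums((Y - mu) / denom)
    info <- rowSums(mu / denom) # expected information in t
    t <- t + score / pmax(info, 1e-10)
    t <- pmin(t, 50) # guard against divergence on pathological rows
  }
  t
}

.nb_loglik <- function(Y, s, phi, t) {
  mu <- exp(t) %o% s
  size <- 1 / pmax(phi, 1e-8)
  rowSums(stats::dnbinom(Y, size = size, mu = mu, log = TRUE))
}

.nb_profile <- function(Y1, Y2, s1, s2, phi, t1, t2) {
  t1 <- .nb_fit_logmean(Y1, s1, phi, t0 = t1, iters = 5L)
  t2 <- .nb_fit_logmean(Y2, s2, phi, t0 = t2, iters = 5L)
  list(ll = .nb_loglik(Y1, s1, phi, t1) + .nb_loglik(Y2, s2, phi, t2),
       t1 = t1, t2 = t2)
}

#' Two-group negative-binomial Wald fit for every gene
#'
#' Gene-wise profile-likelihood dispersion (log-spaced grid refined by
#' golden-section search), group-specific means with log library-size offsets,
#' and a Wald statistic for the log mean ratio from the observed information at
#' the optimum. Deliberately simple: no dispersion shrinkage, no outlier
#' refitting — it exists to exhibit the parametric failure mode under model
#' violations, and is not a replica of any published DE tool.
#'
#' @param counts genes x samples count matrix (kept genes only).
#' @param offsets positive per-sample effective library sizes, aligned to
#'   columns.
#' @param labels two-level named factor over the samples.
#' @param phi_grid dispersion grid for the profile search.
#' @param golden_iters golden-section refinement iterations on log10(phi).
#' @return data.frame per gene: `log_ratio` (log mean ratio level2 vs level1),
#'   `se`, `z`, `p_value`, `phi`, `converged`.
#' @export
nb_wald_fit <- function(counts, offsets, labels,
                        phi_grid = 10 ^ seq(-4, 1, length.out = 13),
                        golden_iters = 12L) {
  validate_labels(labels)
  lab <- labels[colnames(counts)]
  i1 <- which(lab == levels(lab)[1L]); i2 <- which(lab == levels(lab)[2L])
  Y1 <- counts[, i1, drop = FALSE]; Y2 <- counts[, i2, drop = FALSE]
  s1 <- offsets[i1]; s2 <- offsets[i2]
  G <- nrow(counts)
  ok <- rowSums(Y1) > 0 & rowSums(Y2) > 0
  out <- data.frame(log_ratio = rep(NA_real_, G), se = NA_real_, z = NA_real_,
                    p_value = NA_real_, phi = NA_real_, converged = ok,
                    row.names = rownames(counts))
  if (!any(ok)) return(out)
  Y1 <- Y1[ok, , drop = FALSE]; Y2 <- Y2[ok, , drop = FALSE]
  g <- nrow(Y1)

  # profile log-likelihood over the phi grid
  ll_grid <- matrix(-Inf, g, length(phi_grid))
  t1 <- t2 <- NULL
  t1_best <- t2_best <- matrix(0, g, length(phi_grid))
  for (k in seq_along(phi_grid)) {
    pr <- .nb_profile(Y1, Y2, s1, s2, rep(phi_grid[k], g), t1, t2)
    ll_grid[, k] <- pr$ll
    t1 <- pr$t1; t2 <- pr$t2
    t1_best[, k] <- t1; t2_best[, k] <- t2
  }
  best <- max.col(ll_grid, ties.method = "first")
  lo <- log10(phi_grid[pmax(best - 1L, 1L)])
  hi <- log10(phi_grid[pmin(best + 1L, length(phi_grid))])
  t1 <- t1_best[cbind(seq_len(g), best)]
  t2 <- t2_best[cbind(seq_len(g), best)]

  # golden-section refinement, one personal bracket per gene
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- .nb_profile(Y1, Y2, s1, s2, 10 ^ x1, t1, t2)
  f2 <- .nb_profile(Y1, Y2, s1, s2, 10 ^ x2, t1, t2)
  for (it in seq_len(golden_iters)) {
    take1 <- f1$ll >= f2$ll # maximum lies in [lo, x2]
    hi <- ifelse(take1, x2, hi)
    lo <- ifelse(take1, lo, x1)
    x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
    t1 <- ifelse(take1, f1$t1, f2$t1)
    t2 <- ifelse(take1, f1$t2, f2$t2)
    f1 <- .nb_profile(Y1, Y2, s1, s2, 10 ^ x1, t1, t2)
    f2 <- .nb_profile(Y1, Y2, s1, s2, 10 ^ x2, t1, t2)
  }
  phi <- 10 ^ ((lo + hi) / 2)
  fin <- .nb_profile(Y1, Y2, s1, s2, phi, t1, t2)
  t1 <- .nb_fit_logmean(Y1, s1, phi, t0 = fin$t1, iters = 8L)
  t2 <- .nb_fit_logmean(Y2, s2, phi, t0 = fin$t2, iters = 8L)

  obs_info <- function(Y, s, t) {
    mu <- exp(t) %o% s
    rowSums(mu * (1 + phi * Y) / (1 + phi * mu) ^ 2)
  }
  I1 <- obs_info(Y1, s1, t1); I2 <- obs_info(Y2, s2, t2)
  se <- sqrt(1 / pmax(I1, 1e-12) + 1 / pmax(I2, 1e-12))
  beta <- t2 - t1
  z <- beta / se
  out$log_ratio[ok] <- beta
  out$se[ok] <- se
  out$z[ok] <- z
  out$p_value[ok] <- 2 * stats::pnorm(-abs(z))
  out$phi[ok] <- phi
  bad <- ok
  bad[ok] <- !is.finite(z)
  out$p_value[bad] <- NA_real_
  out$converged[bad] <- FALSE
  if (any(bad)) {
    warning("NB-Wald fit did not converge for ",
            paste(utils::head(rownames(counts)[bad], 5L), collapse = ", "),
            if (sum(bad) > 5L) " ..." else "")
  }
  out
}
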