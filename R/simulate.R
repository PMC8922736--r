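#' Configuration for the two-condition negative-binomial count simulator
#'
#' The simulator emulates the statistical structure the benchmark assumes in
#' bulk two-condition RNA-seq: gene-wise NB counts (variance `mu + phi*mu^2`),
#' log-normal baseline means and dispersions, per-sample library-size
#' variation, a configurable proportion of true DEGs with random-sign
#' log2 fold changes, and sporadic multiplicative outlier entries that violate
#' the NB model.
#'
#' Defaults: baseline means log-normal(meanlog 3, sdlog 1.5); dispersions
#' log-normal(meanlog -1.5, sdlog 0.8); per-sample depth factors
#' log-normal(sdlog 0.3) normalized to mean 1 and scaled so the median library
#' size is near 5e6 reads; DEG log2 fold-change magnitudes Uniform(0.5, 3)
#' with random sign; outlier entries multiplied by log-uniform [5, 50]
#' magnitudes.
#'
#' @param G number of genes.
#' @param n1,n2 per-condition sample sizes.
#' @param pi proportion of true DEGs in `[0, 1]`.
#' @param epsilon per-entry outlier probability.
#' @param seed integer seed (mandatory).
#' @param lfc_min,lfc_max log2 fold-change magnitude range for DEGs.
#' @param mean_meanlog,mean_sdlog log-normal parameters of baseline means.
#' @param disp_meanlog,disp_sdlog log-normal parameters of dispersions.
#' @param libsize_sdlog log-sd of per-sample depth factors.
#' @param depth target median library size in reads.
#' @param outlier_min,outlier_max multiplicative outlier magnitude range
#'   (log-uniform).
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(G = 5000L, n1 = 100L, n2 = 100L, pi = 0.05,
                       epsilon = 0, seed,
                       lfc_min = 0.5, lfc_max = 3,
                       mean_meanlog = 3, mean_sdlog = 1.5,
                       disp_meanlog = -1.5, disp_sdlog = 0.8,
                       libsize_sdlog = 0.3, depth = 5e6,
                       outlier_min = 5, outlier_max = 50) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(G >= 1, n1 >= 2, n2 >= 2, pi >= 0, pi <= 1,
            epsilon >= 0, epsilon < 1, lfc_min > 0, lfc_max >= lfc_min,
            mean_sdlog > 0, disp_sdlog > 0, libsize_sdlog >= 0, depth > 0,
            outlier_min > 1, outlier_max >= outlier_min)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a two-condition NB count dataset with known truth
#'
#' Counts are drawn as
#' `y_gj ~ NB(mean = s_j * mu_g * f_g^[j in condition 2], var = mu + phi_g*mu^2)`
#' with `f_g = 2^lfc_g` for the `round(pi*G)` truth genes and 1 otherwise.
#' Each entry is then independently replaced, with probability `epsilon`, by
#' `round(count * m)` with `m` drawn log-uniformly from the outlier magnitude
#' range, and flagged in the outlier mask. Fully reproducible from the seed.
#'
#' @param config `"sim_config"` object.
#' @return list of class `"simulated_dataset"`: `counts` (count matrix),
#'   `labels` (two-level factor, levels `cond1`/`cond2`), `truth` (list with
#'   `true_deg_ids`, `provenance = "simulator"`), `log2fc` (named truth-gene
#'   effects), `outlier_mask` (logical matrix), `mu`, `phi`, `lib_factor`,
#'   `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  G <- as.integer(cf$G); n <- as.integer(cf$n1 + cf$n2)
  gene_ids <- sprintf("g%0*d", nchar(G), seq_len(G))
  sample_ids <- sprintf("s%0*d", nchar(n), seq_len(n))
  labels <- condition_labels(sample_ids,
                             rep(c("cond1", "cond2"), c(cf$n1, cf$n2)),
                             levels = c("cond1", "cond2"))
  with_seed(derive_seed(cf$seed, 10L), {
    mu <- stats::rlnorm(G, cf$mean_meanlog, cf$mean_sdlog)
    phi <- stats::rlnorm(G, cf$disp_meanlog, cf$disp_sdlog)
    l <- stats::rlnorm(n, 0, cf$libsize_sdlog)
    l <- l / mean(l)
    n_deg <- round(cf$pi * G)
    truth_ids <- if (n_deg > 0) sort(sample(gene_ids, n_deg)) else character(0)
    lfc <- if (n_deg > 0) {
      stats::runif(n_deg, cf$lfc_min, cf$lfc_max) *
        sample(c(-1, 1), n_deg, replace = TRUE)
    } else numeric(0)
    names(lfc) <- truth_ids

    # scale depth factors so the median library size lands near cf$depth
    s <- l * cf$depth / sum(mu)
    f <- rep(1, G); names(f) <- gene_ids
    f[truth_ids] <- 2 ^ lfc
    is2 <- labels == "cond2"
    mean_mat <- mu %o% s # G x n baseline
    mean_mat[, is2] <- mean_mat[, is2] * f
    counts <- matrix(stats::rnbinom(G * n, size = 1 / phi, mu = mean_mat),
                     G, n)
    mask <- matrix(stats::runif(G * n) < cf$epsilon, G, n)
    if (any(mask)) {
      mult <- exp(stats::runif(sum(mask), log(cf$outlier_min),
                               log(cf$outlier_max)))
      counts[mask] <- round(counts[mask] * mult)
    }
    dimnames(counts) <- list(gene_ids, sample_ids)
    dimnames(mask) <- dimnames(counts)
    structure(list(counts = count_matrix(counts),
                   labels = labels,
                   truth = list(true_deg_ids = truth_ids,
                                provenance = "simulator"),
                   log2fc = lfc,
                   outlier_mask = mask,
                   mu = structure(mu, names = gene_ids),
                   phi = structure(phi, names = gene_ids),
                   lib_factor = structure(s, names = sample_ids),
                   config = cf),
              class = "simulated_dataset")
  })
}

#' Simulate a null dataset (no true DEGs)
#'
#' Convenience wrapper forcing `pi = 0`; useful for negative-control
#' experiments where every discovery is a false positive.
#'
#' @param config `"sim_config"` object; its `pi` is overridden to 0.
#' @return `"simulated_dataset"` with an empty truth set.
#' @export
simulate_null_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config$pi <- 0
  simulate_dataset(config)
}
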