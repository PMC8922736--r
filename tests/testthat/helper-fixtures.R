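# Shared fixtures and independent oracles. Oracles are deliberately naive
# (full enumeration, step-by-step arithmetic) and never call the code paths
# they check.

toy_counts <- function() {
  m <- matrix(c(10, 12, 11, 13, 9,
                100, 110, 95, 105, 102,
                0, 0, 0, 0, 0,
                50, 5, 55, 6, 52,
                7, 70, 8, 72, 6,
                30, 31, 29, 33, 28), nrow = 6, byrow = TRUE)
  dimnames(m) <- list(paste0("g", 1:6), paste0("s", 1:5))
  m
}

toy_labels <- function() {
  condition_labels(paste0("s", 1:5), c("A", "A", "B", "A", "B"))
}

random_counts <- function(G, n, max_count = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rpois(G * n, lambda = runif(G, 1, max_count)), G, n)
  dimnames(m) <- list(paste0("g", seq_len(G)), paste0("s", seq_len(n)))
  m
}

# Full-enumeration oracle for the two-sided rank-sum p-value: every C(N, n1)
# assignment of pooled ranks to group 1 is equally likely under the null.
enum_wilcox_p <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  pooled <- c(x, y)
  w_obs <- sum(rank(pooled)[seq_len(n1)])
  splits <- utils::combn(N, n1)
  rk <- rank(pooled)
  w_all <- apply(splits, 2L, function(idx) sum(rk[idx]))
  lower <- mean(w_all <= w_obs)
  upper <- mean(w_all >= w_obs)
  min(1, 2 * min(lower, upper))
}

# Step-up rejection oracle: reject the k smallest p-values where
# k = max{i : p_(i) <= i * t / m}.
bh_reject_oracle <- function(p, t) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * t / m)
  if (!length(ok)) return(integer(0))
  sort(o[seq_len(max(ok))])
}

# Minimal DE-result table for evaluation-layer tests.
fake_result <- function(gene_ids, q) {
  data.frame(gene_id = gene_ids, statistic = NA_real_, log2fc = NA_real_,
             p_value = q, q_value = q, stringsAsFactors = FALSE)
}

small_sim <- function(seed, G = 300L, n1 = 20L, n2 = 20L, pi = 0, epsilon = 0,
                      ...) {
  simulate_dataset(sim_config(G = G, n1 = n1, n2 = n2, pi = pi,
                              epsilon = epsilon, seed = seed, ...))
}
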