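test_that("exact rank-sum p equals full enumeration for all group sizes <= 6", {
  set.seed(407)
  cases <- 0L
  for (n1 in 2:6) for (n2 in 2:6) {
    for (rep in 1:4) {
      x <- rnorm(n1); y <- rnorm(n2) # continuous, tie-free a.s.
      wt <- wilcoxon_p(x, y)
      expect_true(wt$exact)
      expect_equal(wt$p_value, enum_wilcox_p(x, y))
      cases <- cases + 1L
    }
  }
  expect_gte(cases, 100L)
})

test_that("rank-sum p has the documented closed-form and invariance properties", {
  expect_equal(wilcoxon_p(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1) # 2/20
  expect_equal(wilcoxon_p(c(5, 1, 9), c(9, 5, 1))$p_value, 1)   # identical multisets
  set.seed(408)
  x <- rnorm(12); y <- rnorm(9, 1)
  expect_equal(wilcoxon_p(x, y)$p_value, wilcoxon_p(y, x)$p_value)
  expect_equal(wilcoxon_p(x, y)$p_value, wilcoxon_p(exp(x), exp(y))$p_value)
  xl <- rnorm(40); yl <- rnorm(35)
  expect_equal(wilcoxon_p(xl, yl)$p_value, wilcoxon_p(exp(xl), exp(yl))$p_value)
  expect_error(wilcoxon_p(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum p agrees with the standard routine in both modes", {
  set.seed(409)
  for (i in 1:25) {
    x <- rnorm(sample(2:20, 1)); y <- rnorm(sample(2:20, 1))
    expect_equal(wilcoxon_p(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value)
  }
  for (i in 1:25) { # ties force the corrected normal approximation
    x <- sample(1:12, sample(26:50, 1), replace = TRUE)
    y <- sample(1:12, sample(26:50, 1), replace = TRUE)
    expect_equal(wilcoxon_p(x, y)$p_value,
                 wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  }
})

test_that("BH q-values match the hand example and preserve missingness", {
  expect_equal(benjamini_hochberg(c(0.002, 0.01, 0.03, 0.04)),
               c(0.008, 0.02, 0.04, 0.04))
  expect_equal(benjamini_hochberg(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(benjamini_hochberg(0.037), 0.037)
  q <- benjamini_hochberg(c(0.01, NA, 0.5, NA))
  expect_true(all(is.na(q[c(2, 4)])))
  # m counts only non-missing values: with one NA, m = 2
  expect_equal(q[1], min(1, 2 * 0.01 / 1))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH q-values reproduce the step-up rejection rule", {
  set.seed(410)
  for (i in 1:200) {
    m <- sample(5:80, 1)
    p <- runif(m) ^ sample(1:3, 1) # varying signal density
    q <- benjamini_hochberg(p)
    t <- runif(1, 0.01, 0.3)
    if (any(abs(q - t) < 1e-12)) next
    expect_identical(which(q < t), bh_reject_oracle(p, t))
  }
})

test_that("discoveries use strict inequality and tolerate empty results", {
  res <- fake_result(c("a", "b", "c"), c(0.04, 0.05, 0.9))
  expect_identical(discoveries(res, 0.05), "a")
  expect_identical(discoveries(res, 1), c("a", "b", "c"))
  empty <- fake_result(c("a", "b"), c(NA_real_, NA_real_))
  expect_identical(discoveries(empty, 0.05), character(0))
  # lowering a p-value never removes a discovery
  set.seed(411)
  p <- runif(40)
  res1 <- fake_result(paste0("g", 1:40), benjamini_hochberg(p))
  p2 <- p; p2[7] <- p2[7] / 10
  res2 <- fake_result(paste0("g", 1:40), benjamini_hochberg(p2))
  expect_true(all(discoveries(res1, 0.2) %in% discoveries(res2, 0.2)))
})

test_that("the Wilcoxon pipeline carries the exact-test p-value floor at n = 7", {
  ds <- small_sim(21, G = 200, n1 = 7, n2 = 7, pi = 0.04,
                  lfc_min = 4, lfc_max = 6)
  res <- run_wilcoxon_pipeline(ds$counts, ds$labels)
  p <- res$p_value[!is.na(res$p_value)]
  floor_p <- 2 / choose(14, 7)
  expect_gte(min(p), floor_p - 1e-15)
  expect_true(any(abs(p - floor_p) < 1e-12)) # separated truth genes sit at the floor
})

test_that("a fully filtered dataset yields an all-missing result", {
  m <- matrix(1L, 5, 4, dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  m[1, 1] <- 2L # non-degenerate library sizes
  lab <- condition_labels(colnames(m), c("A", "A", "B", "B"))
  res <- run_wilcoxon_pipeline(m, lab)
  expect_true(all(is.na(res$p_value)))
  expect_identical(discoveries(res, 0.05), character(0))
})

test_that("NB-Wald p-values are near-uniform on clean null data", {
  ds <- small_sim(31, G = 2000, n1 = 50, n2 = 50)
  res <- nb_wald_pipeline(ds$counts, ds$labels)
  p <- res$p_value[!is.na(res$p_value)]
  expect_gt(length(p), 1900)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("NB-Wald log2fc is zero for equal group multisets at equal library sizes", {
  v <- c(12, 40, 7, 90, 23)
  m <- cbind(s1 = v, s2 = rev(v), s3 = v, s4 = rev(v))
  m <- rbind(m, matrix(50L, 30, 4)) # stabilize library sizes / filtering
  rownames(m) <- paste0("g", seq_len(nrow(m)))
  lab <- condition_labels(colnames(m), c("A", "A", "B", "B"))
  off <- structure(rep(1, 4), names = colnames(m))
  fit <- nb_wald_fit(m, off, lab)
  expect_equal(fit["g1", "log_ratio"], 0, tolerance = 1e-6)
})

test_that("in the Poisson limit the Wald p matches a likelihood-ratio oracle", {
  set.seed(11)
  G <- 20L; nsamp <- 50L
  Y <- matrix(rpois(G * 2 * nsamp, 50), nrow = G)
  lab <- condition_labels(paste0("s", 1:(2 * nsamp)), rep(c("a", "b"), each = nsamp))
  dimnames(Y) <- list(paste0("g", 1:G), names(lab))
  off <- structure(rep(1, 2 * nsamp), names = names(lab))
  fit <- nb_wald_fit(Y, off, lab, phi_grid = 1e-8, golden_iters = 0L)
  lr_p <- vapply(seq_len(G), function(g) {
    y1 <- Y[g, 1:nsamp]; y2 <- Y[g, nsamp + 1:nsamp]
    ll <- function(m, y) sum(dpois(y, m, log = TRUE))
    lr <- 2 * (ll(mean(y1), y1) + ll(mean(y2), y2) - ll(mean(c(y1, y2)), c(y1, y2)))
    pchisq(lr, 1, lower.tail = FALSE)
  }, 0)
  expect_lt(max(abs(fit$p_value - lr_p) / lr_p), 0.10)
})

test_that("NB-Wald over-discovers relative to Wilcoxon on contaminated null data", {
  n_w <- n_nb <- integer(6)
  for (s in 1:6) {
    ds <- small_sim(400 + s, G = 400, n1 = 25, n2 = 25, epsilon = 0.05)
    n_w[s] <- length(discoveries(run_wilcoxon_pipeline(ds$counts, ds$labels), 0.05))
    n_nb[s] <- length(discoveries(nb_wald_pipeline(ds$counts, ds$labels), 0.05))
  }
  expect_gt(median(n_nb), median(n_w))
})

test_that("external result tables round-trip with identical discoveries", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tp_value\tlog2fc",
               "g1\t0.001\t2.5", "g2\t0.6\t-0.1", "g3\t0.04\t1.0"), path)
  res <- load_external_result(path)
  expect_equal(res$q_value, benjamini_hochberg(c(0.001, 0.6, 0.04)))
  expect_identical(attr(res, "method_name"), "external")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tq_value", "g1\t0.01"), bad)
  expect_error(load_external_result(bad), "p_value")

  ds <- small_sim(51, G = 80, n1 = 10, n2 = 10, pi = 0.2)
  orig <- run_wilcoxon_pipeline(ds$counts, ds$labels)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_de_result(orig, out)
  back <- load_external_result(out)
  for (t in c(0.01, 0.05, 0.2, 0.8)) {
    expect_setequal(discoveries(back, t), discoveries(orig, t))
  }
})
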