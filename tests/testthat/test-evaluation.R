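test_that("FDP and empirical power follow their definitions and conventions", {
  disc <- paste0("g", 1:4); truth <- c("g1", "g2")
  expect_equal(fdp(disc, truth), 0.5)
  expect_equal(fdp(c("g1", "g2"), truth), 0)
  expect_equal(fdp(character(0), truth), 0) # empty discovery convention
  expect_equal(empirical_power(disc, truth), 1)
  expect_equal(empirical_power(character(0), truth), 0)
  expect_equal(empirical_power(c("x", "y"), truth), 0)
  expect_error(empirical_power(disc, character(0)), "empty truth")
})

test_that("evaluate_methods averages per-replicate FDP and power exactly", {
  r1 <- fake_result(paste0("g", 1:6), c(0.001, 0.002, 0.003, 0.004, 0.9, 0.9))
  r2 <- fake_result(paste0("g", 1:6), c(0.001, 0.002, 0.9, 0.9, 0.9, 0.9))
  truths <- list(c("g1", "g2"), c("g1", "g2"))
  ev <- evaluate_methods(list(m1 = list(r1, r2)), truths, thresholds = c(0.05))
  # replicate FDPs: 4 discoveries/2 false -> 0.5; 2 discoveries/0 false -> 0
  expect_equal(ev$fdp$m1[, 1], c(0.5, 0))
  expect_equal(ev$summary$actual_fdr, mean(c(0.5, 0)))
  expect_equal(ev$power$m1[, 1], c(1, 1))
  expect_equal(ev$summary$power, 1)
  expect_identical(ev$summary$R, 2L)

  # single replicate composition of the two operations
  ev1 <- evaluate_methods(list(m1 = list(r1)), truths[1], thresholds = c(0.05))
  expect_equal(ev1$summary$actual_fdr, 0.5)
  expect_equal(ev1$summary$power, 1)

  expect_error(evaluate_methods(list(m1 = list(r1)), truths), "2 truth sets")
})

test_that("discovery counts are non-decreasing along an ascending threshold grid", {
  set.seed(415)
  res <- fake_result(paste0("g", 1:50), benjamini_hochberg(runif(50) ^ 2))
  thresholds <- c(0.001, 0.01, 0.05, 0.2)
  n_disc <- vapply(thresholds, function(t) length(discoveries(res, t)), 0L)
  expect_true(all(diff(n_disc) >= 0))
})

test_that("power at matched actual FDR interpolates on the isotonic hull", {
  mk <- function(method, fdr, pow) {
    structure(list(summary = data.frame(method = method, claimed_fdr = NA,
                                        actual_fdr = fdr, power = pow, R = 1)),
              class = "evaluation_summary")
  }
  ev <- mk("a", c(0.01, 0.05), c(0.2, 0.6))
  out <- power_at_actual_fdr(ev, 0.03)
  expect_equal(out$power, 0.4) # hand linear interpolation
  expect_true(is.na(power_at_actual_fdr(ev, 0.005)$power))
  expect_true(is.na(power_at_actual_fdr(ev, 0.9)$power))

  # two methods with identical curves interpolate identically
  ev2 <- structure(list(summary = rbind(mk("a", c(0.01, 0.05), c(0.2, 0.6))$summary,
                                        mk("b", c(0.01, 0.05), c(0.2, 0.6))$summary)),
                   class = "evaluation_summary")
  out2 <- power_at_actual_fdr(ev2, c(0.02, 0.04))
  expect_equal(out2$power[out2$method == "a"], out2$power[out2$method == "b"])

  # a power dip is lifted onto the upper envelope before interpolation
  ev3 <- mk("a", c(0.01, 0.03, 0.05), c(0.5, 0.3, 0.6))
  expect_equal(power_at_actual_fdr(ev3, 0.03)$power, 0.5)
})

test_that("permutation summaries count discoveries and exceedances correctly", {
  genes <- paste0("g", 1:10)
  orig <- fake_result(genes, c(rep(0.001, 4), rep(0.9, 6)))       # 4 discoveries
  qs <- list(rep(0.9, 10),
             c(rep(0.001, 5), rep(0.9, 5)),
             c(rep(0.9, 5), rep(0.001, 5)),
             c(rep(0.001, 9), 0.9))
  perm <- lapply(qs, function(q) fake_result(genes, q))
  ps <- permutation_summary(orig, perm, threshold = 0.05)
  expect_identical(ps$perm_counts, c(0L, 5L, 5L, 9L))
  expect_equal(ps$exceed_fraction, 0.75)
  expect_equal(unname(ps$gene_freq["g1"]), 0.5)
  expect_equal(unname(ps$gene_freq["g10"]), 0.25) # discovered in one of four

  rec <- recurrent_genes(ps, 50)
  expect_setequal(rec$gene_ids, paste0("g", 1:9))
  expect_setequal(rec$overlap_with_original, paste0("g", 1:4))
  expect_equal(rec$overlap_fraction, 1)

  none <- permutation_summary(orig, perm[c(1, 1)], threshold = 0.05)
  expect_true(all(none$gene_freq == 0))
  expect_equal(none$exceed_fraction, 0)
})

test_that("permutation bookkeeping matches brute-force enumeration on a 5-sample toy", {
  set.seed(416)
  m <- random_counts(30, 5, max_count = 300)
  lab <- toy_labels()
  all_assign <- utils::combn(5, 2) # positions of the B level
  perms <- lapply(seq_len(ncol(all_assign)), function(k) {
    l <- rep("A", 5); l[all_assign[, k]] <- "B"
    condition_labels(colnames(m), l)
  })
  results <- lapply(perms, function(pl) run_wilcoxon_pipeline(m, pl))
  orig <- run_wilcoxon_pipeline(m, lab)
  ps <- permutation_summary(orig, results, threshold = 0.5)

  # oracle: recount everything directly from the q-value tables
  disc_sets <- lapply(results, function(r) r$gene_id[!is.na(r$q_value) & r$q_value < 0.5])
  expect_identical(ps$perm_counts, lengths(disc_sets))
  for (g in rownames(m)) {
    expect_equal(unname(ps$gene_freq[g]),
                 mean(vapply(disc_sets, function(d) g %in% d, TRUE)))
  }
  n_orig <- sum(!is.na(orig$q_value) & orig$q_value < 0.5)
  expect_equal(ps$exceed_fraction, mean(lengths(disc_sets) > n_orig))
})

test_that("fold-change frequency profiles order original DEGs by effect size", {
  genes <- c("up", "dn", "null")
  orig <- fake_result(genes, c(0.001, 0.001, 0.9))
  perm <- list(fake_result(genes, c(0.001, 0.9, 0.9)),
               fake_result(genes, c(0.001, 0.001, 0.9)))
  ps <- permutation_summary(orig, perm, 0.05)
  fc <- c(up = 0.5, dn = -2.0, null = 0)
  prof <- foldchange_frequency_profile(ps, fc)
  expect_identical(prof$gene_id, c("dn", "up")) # |fc| descending
  expect_identical(prof$rank, 1:2)
  expect_equal(prof$frequency, c(0.5, 1))

  empty <- permutation_summary(fake_result(genes, rep(0.9, 3)), perm, 0.05)
  expect_identical(nrow(foldchange_frequency_profile(empty, fc)), 0L)
})

test_that("the NB goodness-of-fit diagnostic is calibrated under the true law", {
  set.seed(417)
  po <- replicate(50, nb_gof_poorness(rnbinom(500, size = 1 / 0.22, mu = 60), 0.22)$poorness)
  expect_gte(median(po), 0.15)
  expect_lte(median(po), 0.55)
})

test_that("gross outliers inflate poorness of fit", {
  set.seed(418)
  v <- rnbinom(100, size = 1 / 0.22, mu = 60)
  v[1] <- round(50 * mean(v)) # one entry at 50x the mean
  expect_gt(nb_gof_poorness(v, 0.22)$poorness, 2)

  v2 <- rnbinom(500, size = 1 / 0.22, mu = 60)
  idx <- 1:25 # 5% of entries contaminated at 20x
  v2[idx] <- round(v2[idx] * 20)
  expect_gt(nb_gof_poorness(v2, 0.22)$poorness, 2)
})

test_that("degenerate goodness-of-fit inputs are flagged, not tested", {
  expect_true(nb_gof_poorness(rep(7, 50), 0.2)$degenerate)
  expect_true(is.na(nb_gof_poorness(rep(7, 50), 0.2)$poorness))
  expect_true(nb_gof_poorness(c(1, 2, 3), 0.2)$degenerate) # < 8 observations
})

test_that("poorness group comparison is a symmetric rank-sum test", {
  a <- c(0.1, 0.5, 0.3, 0.8, 0.2, 0.9, 0.4, 0.25)
  expect_equal(compare_poorness_groups(a, a), 1)
  set.seed(419)
  b <- runif(50); worse <- b + 10
  expect_lt(compare_poorness_groups(worse, b), 0.01)
  expect_equal(compare_poorness_groups(worse, b), compare_poorness_groups(b, worse))
  expect_error(compare_poorness_groups(NA_real_, b), "empty")
})

test_that("gof tables aggregate per gene by worst condition", {
  df <- data.frame(gene_id = c("a", "a", "b", "b"),
                   condition = c("c1", "c2", "c1", "c2"),
                   poorness = c(0.2, 1.5, NA, NA))
  agg <- gof_poorness_by_gene(df)
  expect_equal(unname(agg["a"]), 1.5)
  expect_true(is.na(agg["b"]))
})
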