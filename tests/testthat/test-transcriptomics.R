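# Quantile normalization, log2 centering, probe collapsing, ordinary and
# random-variance t-tests, KS gene-set enrichment.

test_that("quantile normalization equalizes column distributions", {
  m <- toy_matrix(cbind(c(1, 2, 3), c(4, 5, 6)), kind = "expression_intensity")
  qn <- quantile_normalize(m)
  expect_equal(unname(unclass(qn)[, 1]), c(2.5, 3.5, 4.5), tolerance = 1e-12)
  expect_equal(unname(unclass(qn)[, 2]), c(2.5, 3.5, 4.5), tolerance = 1e-12)

  # identical columns are a fixed point
  same <- toy_matrix(cbind(c(3, 1, 2), c(3, 1, 2)), kind = "expression_intensity")
  expect_equal(unclass(quantile_normalize(same)), unclass(same), tolerance = 1e-12)

  # all column quantiles equal, and idempotent, on random input
  set.seed(SUITE_SEED)
  r <- random_feature_matrix(50, 6, "expression_intensity")
  q1 <- quantile_normalize(r)
  sorted <- apply(unclass(q1), 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
  expect_equal(unclass(quantile_normalize(q1)), unclass(q1), tolerance = 1e-12)
})

test_that("log2 centering zeroes every gene's mean", {
  m <- toy_matrix(rbind(c(2, 8), c(4, 4)), c("g1", "g2"),
                  kind = "expression_intensity")
  lc <- log2_center(m)
  expect_equal(unname(unclass(lc)["g1", ]), c(-1, 1), tolerance = 1e-12)
  expect_equal(unname(unclass(lc)["g2", ]), c(0, 0), tolerance = 1e-12)
  set.seed(SUITE_SEED)
  r <- toy_matrix(matrix(exp(rnorm(60)), 10, 6), kind = "expression_intensity")
  expect_lt(max(abs(rowMeans(unclass(log2_center(r))))), 1e-12)
  bad <- toy_matrix(rbind(c(1, -2)), "g1", kind = "expression_log2")
  expect_error(log2_center(bad), "g1")
})

test_that("probes collapse to the max-mean probe per gene", {
  m <- toy_matrix(rbind(c(1, 1), c(10, 10), c(5, 7)),
                  c("p1", "p2", "p3"), kind = "expression_intensity")
  map <- c(p1 = "GENEA", p2 = "GENEA", p3 = "GENEB")
  g <- collapse_probes(m, map)
  expect_identical(rownames(g), c("GENEA", "GENEB"))
  expect_equal(unname(unclass(g)["GENEA", ]), c(10, 10))
  expect_error(collapse_probes(m, map[1:2]), "p3")
})

test_that("the moderated t reduces to the ordinary t as the prior vanishes", {
  # with a = 0 the shrunk variance is the pooled variance and df are n - 2;
  # verify the formula path directly against the ordinary statistics
  set.seed(SUITE_SEED + 1L)
  x <- matrix(rnorm(200 * 10), 200, 10,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:10)))
  sh <- toy_sheet(5L)
  colnames(x) <- sh$sample_id
  fm <- feature_matrix(x, "expression_log2")
  ord <- differential_expression(fm, sh, method = "ordinary")
  a_seq <- c(1, 0.1, 0.001, 1e-6)
  b <- 1
  d <- 8
  s2 <- apply(x, 1, function(r) {
    (4 * var(r[sh$condition == "S"]) + 4 * var(r[sh$condition == "P"])) / d
  })
  delta <- rowMeans(x[, sh$condition == "S"]) - rowMeans(x[, sh$condition == "P"])
  dev <- vapply(a_seq, function(a) {
    s2t <- (d * s2 + 2 * a * b) / (d + 2 * a)
    max(abs(delta / sqrt(s2t * (2 / 5)) - ord$t_stat))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[length(dev)], 1e-5)

  # the package's moderated statistics are consistent with its fitted prior
  rv <- differential_expression(fm, sh, method = "random_variance")
  a <- attr(rv, "prior_a"); bb <- attr(rv, "prior_b")
  s2t <- (d * s2 + 2 * a * bb) / (d + 2 * a)
  expect_equal(rv$t_stat, unname(delta / sqrt(s2t * (2 / 5))), tolerance = 1e-10)
  expect_equal(unique(rv$df), d + 2 * a, tolerance = 1e-12)
})

test_that("the variance-prior ML fit recovers the scaled-F model", {
  # simulate gene variances from the inverse-gamma prior model and compare
  # the fitted hyperparameters against limma's moment/ML machinery
  set.seed(SUITE_SEED + 2L)
  d <- 8; d0 <- 6; s02 <- 0.8
  s2 <- s02 * rf(4000, d, d0)
  fit <- stemomics:::fit_variance_prior(s2, d)
  lf <- limma::fitFDist(s2, df1 = d)
  expect_equal(fit$d0, lf$df2, tolerance = 0.15)
  expect_equal(fit$s02, lf$scale, tolerance = 0.1)
  expect_equal(fit$d0, d0, tolerance = 0.25)
  expect_equal(fit$s02, s02, tolerance = 0.1)
})

test_that("differential expression p-values are uniform under the null", {
  # aggregate over five independent null panels: a single KS draw at one
  # seed has a 1% false-alarm rate by construction, so require the KS
  # p-values to show no systematic depression instead
  ksp <- sapply(1:5, function(s) {
    truth <- synthetic_truth(metab_fold_changes = c(NAAD = 1),
                             module_genes = character(0), module_strength = 0,
                             seed = SUITE_SEED + 300L + s, n_per_group = 3L)
    tx <- simulate_transcriptome(truth, n_genes = 2000L)
    vapply(c("ordinary", "random_variance"), function(meth) {
      de <- differential_expression(tx$matrix, tx$sheet, method = meth)
      ks.test(de$p_value, "punif")$p.value
    }, numeric(1))
  })
  expect_gt(median(ksp["ordinary", ]), 0.05)
  expect_gt(median(ksp["random_variance", ]), 0.05)
  expect_true(all(ksp > 1e-4))

  # invariant to sample order
  truth <- synthetic_truth(metab_fold_changes = c(NAAD = 1), module_genes = character(0),
                           module_strength = 0, seed = SUITE_SEED + 3L, n_per_group = 3L)
  tx <- simulate_transcriptome(truth, n_genes = 500L)
  perm <- sample(ncol(tx$matrix))
  de1 <- differential_expression(tx$matrix, tx$sheet)
  de2 <- differential_expression(
    feature_matrix(unclass(tx$matrix)[, perm], "expression_log2"), tx$sheet)
  expect_equal(de1$t_stat, de2$t_stat, tolerance = 1e-12)
})

test_that("planted differentially expressed genes are recovered by FDR selection", {
  de_truth <- stats::setNames(rep(3, 20), paste0("GENE", sprintf("%04d", 1:20)))
  truth <- synthetic_truth(module_genes = character(0), module_strength = 0,
                           de_genes = de_truth, seed = SUITE_SEED + 4L,
                           n_per_group = 5L)
  tx <- simulate_transcriptome(truth, n_genes = 1000L)
  de <- differential_expression(tx$matrix, tx$sheet, method = "random_variance")
  q <- p.adjust(de$p_value, "BH")
  called <- de$gene[q < 0.05]
  tp <- sum(called %in% names(de_truth))
  expect_gte(tp, 18L)                     # nearly all planted genes found
  expect_lte(sum(!called %in% names(de_truth)), 0.2 * length(called))  # FDR respected
})

test_that("KS enrichment matches exhaustive running-sum enumeration", {
  stats_vec <- stats::setNames(seq(10, 1), paste0("g", 1:10))
  set3 <- gene_set("TOP3", "", c("g1", "g2", "g3"))
  res <- enrichment_ks(stats_vec, list(set3), n_perm = 200, seed = 1, min_size = 3)
  hit <- names(sort(stats_vec, decreasing = TRUE)) %in% set3$members
  expect_equal(res$ES, brute_force_ks(hit), tolerance = 1e-15)
  # a set that is exactly the top k reaches the maximal possible ES
  expect_equal(res$ES, 1, tolerance = 1e-15)
  expect_identical(res$direction, "up_in_S")

  # ES sign flips when the ranking is negated
  bottom <- gene_set("BOT3", "", c("g8", "g9", "g10"))
  res_b <- enrichment_ks(stats_vec, list(bottom), n_perm = 200, seed = 1, min_size = 3)
  res_neg <- enrichment_ks(-stats_vec, list(bottom), n_perm = 200, seed = 1, min_size = 3)
  expect_equal(res_neg$ES, -res_b$ES, tolerance = 1e-15)

  # random-set enumeration oracle over every 3-subset of 10 genes
  set.seed(SUITE_SEED)
  for (rep in 1:10) {
    members <- sample(names(stats_vec), 3)
    r <- enrichment_ks(stats_vec, list(gene_set("S", "", members)),
                       n_perm = 50, seed = 1, min_size = 3)
    expect_equal(r$ES, brute_force_ks(names(sort(stats_vec, TRUE)) %in% members),
                 tolerance = 1e-15)
  }

  # sets below the overlap floor are skipped
  tiny <- gene_set("TINY", "", c("g1", "nope"))
  expect_identical(nrow(enrichment_ks(stats_vec, list(tiny), n_perm = 50, seed = 1)), 0L)
})

test_that("enrichment p-values are calibrated for random sets", {
  set.seed(SUITE_SEED + 5L)
  stats_vec <- stats::setNames(rnorm(200), paste0("g", 1:200))
  sets <- lapply(1:60, function(i)
    gene_set(paste0("R", i), "", sample(names(stats_vec), 15)))
  res <- enrichment_ks(stats_vec, sets, n_perm = 200, seed = 2)
  rate <- mean(res$nominal_p <= 0.05)
  expect_lt(abs(rate - 0.05), 0.08)   # binomial slack at 60 sets
  expect_true(all(res$nominal_p >= 1 / 201))
})
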