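# NIPALS PLS-DA, scaling, Q2 cross-validation, VIP, Hotelling ellipse,
# permutation validation.

test_that("autoscaling centers, scales, warns on constants and inverts", {
  X <- cbind(a = c(1, 2, 3), b = c(10, 20, 60), const = c(5, 5, 5))
  expect_warning(sc <- autoscale(X), "const")
  expect_equal(unname(colMeans(sc$X)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(sc$X, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(sc$X[, "a"]), c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(unscale(sc$X, sc), X[, c("a", "b")], tolerance = 1e-12)

  # already-standardized input is a fixed point
  Z <- scale(matrix(rnorm(20), 5, 4))
  attr(Z, "scaled:center") <- attr(Z, "scaled:scale") <- NULL
  colnames(Z) <- paste0("f", 1:4)
  expect_equal(autoscale(Z)$X, Z, tolerance = 1e-12)
})

test_that("fitted models satisfy the PLS-DA invariants", {
  set.seed(SUITE_SEED)
  for (rep in 1:5) {
    X <- matrix(rnorm(12 * 8), 12, 8, dimnames = list(NULL, paste0("f", 1:8)))
    y <- rep(c("P", "S"), each = 6)
    m <- fit_plsda(X, y, ncomp = 3)
    # unit-norm weights
    expect_equal(unname(sqrt(colSums(m$W^2))), rep(1, 3), tolerance = 1e-10)
    # mutually orthogonal scores
    g <- crossprod(m$T)
    expect_lt(max(abs(g[upper.tri(g)])), 1e-8 * max(diag(g)))
    # variance fractions in [0, 1]
    expect_true(m$R2X >= 0 && m$R2X <= 1 + 1e-12)
    expect_true(m$R2Y >= 0 && m$R2Y <= 1 + 1e-12)
    # VIP normalization identity: sum of squares equals feature count
    expect_equal(sum(m$vip^2), ncol(X), tolerance = 1e-8)
    # R2X and R2Y are non-decreasing in the number of components
    m1 <- fit_plsda(X, y, ncomp = 1)
    expect_lte(m1$R2X, m$R2X + 1e-12)
    expect_lte(m1$R2Y, m$R2Y + 1e-12)
    # refit is bit-identical
    expect_identical(fit_plsda(X, y, ncomp = 3)$T, m$T)
  }
})

test_that("NIPALS matches the eigendecomposition PLS oracle", {
  set.seed(SUITE_SEED + 1L)
  for (rep in 1:10) {
    X <- matrix(rnorm(10 * 6), 10, 6, dimnames = list(NULL, paste0("f", 1:6)))
    y <- rep(c("P", "S"), each = 5)
    m <- fit_plsda(X, y, ncomp = 2, scale = FALSE)
    Xs <- X  # scale = FALSE: used as given, y centered internally
    orc <- eigen_pls_oracle(Xs, as.numeric(y == "S"), 2)
    for (a in 1:2) {
      sgn <- sign(sum(orc$W[, a] * m$W[, a]))
      expect_equal(unname(m$W[, a]), sgn * orc$W[, a], tolerance = 1e-6)
      expect_equal(unname(m$T[, a]), sgn * drop(orc$T[, a]), tolerance = 1e-6)
      expect_equal(unname(m$P[, a]), sgn * drop(orc$P[, a]), tolerance = 1e-6)
    }
  }
})

test_that("a perfectly predictive feature drives R2Y and Q2 toward 1", {
  # degenerate case: the class dummy duplicated as the only feature content
  y <- rep(c("P", "S"), each = 6)
  dup <- cbind(f1 = as.numeric(y == "S"), f2 = as.numeric(y == "S"))
  m <- suppressWarnings(fit_plsda(dup, y, ncomp = 1))
  expect_equal(m$R2Y, 1, tolerance = 1e-10)

  # strong single feature among unit-scale noise still cross-validates high
  set.seed(SUITE_SEED + 2L)
  n <- 20
  y2 <- rep(c("P", "S"), each = n / 2)
  X <- cbind(sig = as.numeric(y2 == "S") + rnorm(n, 0, 0.01),
             matrix(rnorm(n * 5), n, 5))
  colnames(X) <- c("sig", paste0("noise", 1:5))
  expect_gt(cross_validate_q2(X, y2, ncomp = 2, folds = 7, seed = 1), 0.85)
  expect_error(fit_plsda(X, rep("P", n)), "class")
})

test_that("Q2 behaves under the null and leave-one-out equals k-fold at k = n", {
  set.seed(SUITE_SEED + 3L)
  n <- 40
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- rep(c("P", "S"), each = n / 2)
  q2_null <- mean(vapply(1:10, function(s)
    cross_validate_q2(X, y, ncomp = 2, folds = 5, seed = s), numeric(1)))
  expect_lt(q2_null, 0)

  # with folds = n the split is LOO regardless of the fold assignment seed
  small_X <- X[1:12, ]; small_y <- y[c(1:6, 21:26)]
  q_a <- cross_validate_q2(small_X, small_y, ncomp = 2, folds = 12, seed = 1)
  q_b <- cross_validate_q2(small_X, small_y, ncomp = 2, folds = 12, seed = 99)
  expect_equal(q_a, q_b, tolerance = 1e-12)
})

test_that("VIP scores are symmetric under equal weights and rank planted signals", {
  # single component, equal |weights|: all VIP exactly 1
  y <- rep(c("P", "S"), each = 4)
  base <- as.numeric(y == "S")
  X <- cbind(f1 = base, f2 = base, f3 = -base, f4 = base) +
    matrix(0, 8, 4)
  m <- fit_plsda(X, y, ncomp = 1, scale = FALSE)
  expect_equal(unname(m$vip), rep(1, 4), tolerance = 1e-10)

  # planted discriminating metabolites occupy the top VIP ranks
  truth <- synthetic_truth(seed = SUITE_SEED + 4L, n_per_group = 5L)
  mb <- simulate_metabolome(truth)
  norm <- normalize_to_protein(mb$matrix, mb$sheet)
  mod <- fit_plsda(t(unclass(norm)), mb$sheet$condition, ncomp = 2)
  top <- names(sort(mod$vip, decreasing = TRUE))[1:4]
  expect_setequal(top, c("NAAD", "ADP", "glutamate", "proline"))
  st <- compare_groups(norm, mb$sheet)
  sel <- select_discriminant(mod, st)
  expect_true(all(c("NAAD", "ADP") %in% sel$feature))
  expect_true(all(sel$vip > 1 & sel$p_value < 0.05))
})

test_that("Hotelling ellipse scales with the scores and covers ~95%", {
  set.seed(SUITE_SEED + 5L)
  t1 <- rnorm(50); t2 <- rnorm(50, sd = 2)
  e <- hotelling_ellipse(t1, t2)
  e2 <- hotelling_ellipse(2 * t1, 2 * t2)
  expect_equal(e2$semi_axis_1, 2 * e$semi_axis_1, tolerance = 1e-12)
  expect_equal(e2$semi_axis_2, 2 * e$semi_axis_2, tolerance = 1e-12)
  # alpha -> 1 degenerates toward a point
  tiny <- hotelling_ellipse(t1, t2, alpha = 0.9999)
  expect_lt(tiny$semi_axis_1, 0.05 * e$semi_axis_1)
  expect_error(hotelling_ellipse(t1[1:2], t2[1:2]), ">= 3")

  # coverage of the 95% region over bivariate normal score draws
  inside <- vapply(1:200, function(s) {
    set.seed(SUITE_SEED + s)
    a <- rnorm(200); b <- rnorm(200, sd = 3)
    el <- hotelling_ellipse(a, b)
    mean((((a - mean(a)) / el$semi_axis_1)^2 +
            ((b - mean(b)) / el$semi_axis_2)^2) <= 1)
  }, numeric(1))
  expect_lt(abs(mean(inside) - 0.95), 0.02)
})

test_that("permutation validation reports the +1/+1 empirical p", {
  set.seed(SUITE_SEED + 6L)
  n <- 20
  y <- rep(c("P", "S"), each = n / 2)
  X <- cbind(matrix(rnorm(n * 3), n, 3) + as.numeric(y == "S") * 3,
             matrix(rnorm(n * 7), n, 7))
  colnames(X) <- paste0("f", 1:10)
  pr <- permutation_validate(X, y, ncomp = 2, n_perm = 25, seed = 3)
  expect_equal(pr$empirical_p_Q2,
               (1 + sum(pr$permuted_Q2 >= pr$observed_Q2)) /
                 (length(pr$permuted_Q2) + 1), tolerance = 1e-15)
  expect_gte(pr$empirical_p_Q2, 1 / (pr$n_perm + 1))
  expect_error(permutation_validate(X, y, n_perm = 5), "n_perm")

  # separable data at n_perm = 100: observed beats every permutation
  pr100 <- permutation_validate(X, y, ncomp = 2, n_perm = 100, seed = 4)
  expect_equal(pr100$empirical_p_Q2, 1 / 101, tolerance = 1e-15)
  expect_gt(pr100$observed_R2Y, max(pr100$permuted_R2Y))
})
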