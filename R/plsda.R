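# Two-class PLS-DA by NIPALS with the full chemometric validation surface:
# unit-variance scaling, R2X/R2Y, cross-validated Q2, VIP scores, Hotelling's
# T2 ellipse for the score plot, and repeated permutation validation.

#' Mean-center and scale a sample x feature matrix to unit variance
#'
#' Per-feature autoscaling (the chemometric convention before PLS-DA): each
#' column gets mean 0 and SD 1. Constant features cannot be scaled and are
#' excluded with a warning.
#'
#' @param X numeric matrix, samples in rows, features in columns.
#' @return list: `X` (scaled matrix), `center`, `scale` (named per-feature),
#'   `excluded` (constant features).
#' @export
autoscale <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sd_ <- apply(X, 2L, stats::sd)
  drop <- sd_ == 0 | is.na(sd_)
  if (any(drop)) {
    warnf("excluding constant feature(s): %s", paste(colnames(X)[drop], collapse = ", "))
  }
  keep <- !drop
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2L, mu[keep], `-`), 2L, sd_[keep], `/`)
  list(X = Xs, center = mu[keep], scale = sd_[keep], excluded = colnames(X)[drop])
}

#' Invert [autoscale()]
#' @param Xs scaled matrix.
#' @param scaling the list returned by [autoscale()].
#' @return the original-scale matrix (excluded features are not restored).
#' @export
unscale <- function(Xs, scaling) {
  sweep(sweep(Xs, 2L, scaling$scale, `*`), 2L, scaling$center, `+`)
}

encode_class <- function(y) {
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) != 2L) stopf("PLS-DA here is two-class; got %d class(es)", length(lev))
  list(y01 = as.numeric(y == lev[2L]), levels = lev)
}

# One NIPALS PLS component for a single centered response: with univariate y
# the weight vector has the closed form w = X'y / ||X'y|| and the NIPALS
# iteration converges at once. Sign convention: first nonzero weight positive.
nipals_component <- function(X, y) {
  w <- drop(crossprod(X, y))
  nw <- sqrt(sum(w^2))
  if (nw < .Machine$double.eps) stopf("degenerate component: X'y is zero")
  w <- w / nw
  nz <- which(abs(w) > 1e-12)[1L]
  if (length(nz) && w[nz] < 0) w <- -w
  t_ <- drop(X %*% w)
  tt <- sum(t_^2)
  p_ <- drop(crossprod(X, t_)) / tt
  q_ <- sum(y * t_) / tt
  list(w = w, t = t_, p = p_, q = q_, tt = tt)
}

#' Fit a two-class PLS-DA model by NIPALS
#'
#' The class vector is coded as a single 0/1 dummy (second level in sort order
#' = 1, i.e. S for P/S labels) and centered; X is autoscaled unless
#' `scale = FALSE` (in which case it is used as given, assumed pre-scaled).
#' Components are extracted by NIPALS with sequential deflation of X and y.
#' R2X and R2Y are cumulative explained fractions of the scaled X and centered
#' y sums of squares. A requested `ncomp` beyond the effective rank is
#' truncated with a warning.
#'
#' @param X samples x features numeric matrix.
#' @param y two-class vector (factor or character), length `nrow(X)`.
#' @param ncomp number of components, default 2.
#' @param scale autoscale X internally (default TRUE).
#' @return an object of class `plsda_model`: weights `W`, loadings `P`,
#'   scores `T`, y-loadings `q`, `R2X`, `R2Y` (cumulative), per-component
#'   `ssy` (y-variance explained), `scaling`, `class_encoding`, `vip`.
#' @export
fit_plsda <- function(X, y, ncomp = 2L, scale = TRUE) {
  X <- as.matrix(X)
  enc <- encode_class(y)
  if (min(table(enc$y01)) < 2L) stopf("each class needs >= 2 samples")
  if (scale) {
    sc <- autoscale(X)
    Xs <- sc$X
  } else {
    sc <- list(center = rep(0, ncol(X)), scale = rep(1, ncol(X)), excluded = character())
    Xs <- X
  }
  y0 <- enc$y01 - mean(enc$y01)
  ssx_tot <- sum(Xs^2)
  ssy_tot <- sum(y0^2)
  max_rank <- qr(Xs)$rank
  if (ncomp > max_rank) {
    warnf("ncomp %d exceeds rank %d; truncated", ncomp, max_rank)
    ncomp <- max_rank
  }
  p <- ncol(Xs); n <- nrow(Xs)
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  qv <- ssx_a <- ssy_a <- numeric(ncomp)
  Xd <- Xs; yd <- y0
  for (a in seq_len(ncomp)) {
    cmp <- nipals_component(Xd, yd)
    W[, a] <- cmp$w; P[, a] <- cmp$p; Tm[, a] <- cmp$t; qv[a] <- cmp$q
    ssx_a[a] <- cmp$tt * sum(cmp$p^2)
    ssy_a[a] <- cmp$tt * cmp$q^2
    Xd <- Xd - tcrossprod(cmp$t, cmp$p)
    yd <- yd - cmp$t * cmp$q
  }
  dimnames(W) <- dimnames(P) <- list(colnames(Xs), paste0("comp", seq_len(ncomp)))
  dimnames(Tm) <- list(rownames(X), paste0("comp", seq_len(ncomp)))
  model <- structure(list(ncomp = ncomp, W = W, P = P, T = Tm, q = qv,
                          ssx_per_comp = ssx_a, ssy_per_comp = ssy_a,
                          R2X = sum(ssx_a) / ssx_tot, R2Y = sum(ssy_a) / ssy_tot,
                          scaling = sc, class_encoding = enc,
                          y_mean = mean(enc$y01)),
                     class = "plsda_model")
  model$vip <- vip_scores(model)
  model
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("plsda_model: %d component(s), %d features; R2X = %.3f, R2Y = %.3f\n",
              x$ncomp, nrow(x$W), x$R2X, x$R2Y))
  invisible(x)
}

# Regression coefficients on the scaled X scale: B = W (P'W)^-1 q.
plsda_coef <- function(model) {
  A <- model$ncomp
  PW <- crossprod(model$P, model$W)
  drop(model$W %*% solve(PW, model$q[seq_len(A)]))
}

#' Predict class scores for new samples
#' @param object a `plsda_model`.
#' @param newdata samples x features matrix on the original scale.
#' @param ... unused.
#' @return list: `y_hat` (continuous class score in [0,1]-ish), `class`
#'   (label at the 0.5 threshold), `scores` (projected T).
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)[, names(object$scaling$center), drop = FALSE]
  Xs <- sweep(sweep(newdata, 2L, object$scaling$center, `-`),
              2L, object$scaling$scale, `/`)
  B <- plsda_coef(object)
  y_hat <- drop(Xs %*% B) + object$y_mean
  # project scores with deflation-consistent weights W* = W (P'W)^-1
  Wstar <- object$W %*% solve(crossprod(object$P, object$W))
  lev <- object$class_encoding$levels
  list(y_hat = y_hat,
       class = ifelse(y_hat >= 0.5, lev[2L], lev[1L]),
       scores = Xs %*% Wstar)
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt( p * sum_a SSY_a w_ja^2 / sum_a SSY_a )` with unit-norm
#' weight vectors and SSY_a the y-variance explained by component a. The mean
#' square VIP is 1 by construction (`sum_j VIP_j^2 = p`).
#'
#' @param model a fitted `plsda_model`.
#' @return named numeric vector of VIP scores (>= 0).
#' @export
vip_scores <- function(model) {
  if (!inherits(model, "plsda_model")) stopf("vip_scores needs a fitted plsda_model")
  p <- nrow(model$W)
  ssy <- model$ssy_per_comp
  w2 <- model$W^2   # columns already unit norm
  vip <- sqrt(p * drop(w2 %*% ssy) / sum(ssy))
  names(vip) <- rownames(model$W)
  vip
}

#' Select discriminant features by VIP and univariate p-value
#'
#' The chemometric selection rule: keep features with VIP > `vip_cut`
#' (default 1) whose univariate two-sample p-value is below `p_cut`
#' (default 0.05).
#'
#' @param model fitted `plsda_model`.
#' @param stats data.frame from [compare_groups()] (needs `metabolite`,
#'   `p_value`).
#' @param vip_cut,p_cut selection thresholds.
#' @return data.frame of selected features with vip and p_value, VIP-sorted.
#' @export
select_discriminant <- function(model, stats, vip_cut = 1, p_cut = 0.05) {
  vip <- model$vip
  p <- stats$p_value[match(names(vip), stats$metabolite)]
  keep <- !is.na(p) & vip > vip_cut & p < p_cut
  out <- data.frame(feature = names(vip)[keep], vip = vip[keep],
                    p_value = p[keep], stringsAsFactors = FALSE)
  out[order(-out$vip), , drop = FALSE]
}

stratified_folds <- function(y01, k) {
  n <- length(y01)
  fold <- integer(n)
  start <- 0L
  # classes fill folds in one continuing round-robin so fold sizes stay
  # balanced overall; k = n therefore yields singleton folds (leave-one-out)
  for (cls in unique(y01)) {
    idx <- sample(which(y01 == cls))
    fold[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
    start <- start + length(idx)
  }
  fold
}

#' Cross-validated Q2 for a PLS-DA model
#'
#' `Q2 = 1 - PRESS / TSS` with PRESS accumulated over held-out samples of a
#' stratified k-fold split; scaling and the model are re-estimated inside
#' every training fold (no leakage). TSS is the total sum of squares of the
#' centered class dummy. `folds = n` gives leave-one-out.
#'
#' @param X samples x features matrix.
#' @param y two-class vector.
#' @param ncomp number of components.
#' @param folds number of folds (default 7, the chemometric convention).
#' @param seed optional seed for the fold assignment (fold membership is the
#'   only randomness).
#' @return Q2 (scalar; can be negative for uninformative models).
#' @export
cross_validate_q2 <- function(X, y, ncomp = 2L, folds = 7L, seed = NULL) {
  X <- as.matrix(X)
  enc <- encode_class(y)
  n <- nrow(X)
  folds <- min(folds, n)
  if (folds < 2L) stopf("folds must be >= 2")
  assign_folds <- function() stratified_folds(enc$y01, folds)
  fold <- if (is.null(seed)) assign_folds() else with_seed(seed, assign_folds())
  # every training split must keep both classes; with stratification this
  # holds whenever each class has >= 2 members
  press <- 0
  for (f in seq_len(folds)) {
    test <- fold == f
    if (!any(test)) next
    if (length(unique(enc$y01[!test])) < 2L) stopf("fold %d lost a class in training", f)
    fit <- suppressWarnings(fit_plsda(X[!test, , drop = FALSE], y[!test], ncomp = ncomp))
    pr <- predict(fit, X[test, , drop = FALSE])
    # map held-out labels onto the training fold's encoding
    y_test <- as.numeric(as.character(y[test]) == fit$class_encoding$levels[2L])
    press <- press + sum((y_test - pr$y_hat)^2)
  }
  tss <- sum((enc$y01 - mean(enc$y01))^2)
  1 - press / tss
}

#' Permutation validation of a PLS-DA model
#'
#' Repeats the full fit + cross-validation under uniformly random label
#' permutations and reports the null distributions of R2Y and Q2 together
#' with the empirical p-value for the observed Q2,
#' `p = (1 + #\{Q2_perm >= Q2_obs\}) / (n_perm + 1)` (never exactly zero).
#' Rounds where the fit fails are recorded and excluded.
#'
#' @param X samples x features matrix.
#' @param y two-class vector.
#' @param ncomp components.
#' @param n_perm number of permutation rounds, default 100.
#' @param seed RNG seed for permutations and fold draws.
#' @param folds CV folds for Q2.
#' @return list of class `permutation_record`: `n_perm`, `permuted_R2Y`,
#'   `permuted_Q2`, `observed_R2Y`, `observed_Q2`, `empirical_p_Q2`,
#'   `failed_rounds`.
#' @export
permutation_validate <- function(X, y, ncomp = 2L, n_perm = 100L, seed = 1L,
                                 folds = 7L) {
  if (n_perm < 20L) stopf("n_perm must be >= 20")
  X <- as.matrix(X)
  obs_fit <- suppressWarnings(fit_plsda(X, y, ncomp = ncomp))
  obs_q2 <- cross_validate_q2(X, y, ncomp = ncomp, folds = folds,
                              seed = sub_seed(seed, 0L))
  res <- with_seed(seed, {
    r2y <- q2 <- rep(NA_real_, n_perm)
    failed <- 0L
    for (b in seq_len(n_perm)) {
      yp <- sample(y)
      ok <- tryCatch({
        fitp <- suppressWarnings(fit_plsda(X, yp, ncomp = ncomp))
        r2y[b] <- fitp$R2Y
        q2[b] <- cross_validate_q2(X, yp, ncomp = ncomp, folds = folds,
                                   seed = sub_seed(seed, b))
        TRUE
      }, error = function(e) FALSE)
      if (!ok) failed <- failed + 1L
    }
    list(r2y = r2y, q2 = q2, failed = failed)
  })
  keep <- !is.na(res$q2)
  n_eff <- sum(keep)
  p_emp <- (1 + sum(res$q2[keep] >= obs_q2)) / (n_eff + 1)
  structure(list(n_perm = n_perm, permuted_R2Y = res$r2y[keep],
                 permuted_Q2 = res$q2[keep], observed_R2Y = obs_fit$R2Y,
                 observed_Q2 = obs_q2, empirical_p_Q2 = p_emp,
                 failed_rounds = res$failed),
            class = "permutation_record")
}

#' Hotelling's T2 confidence ellipse for a 2-component score plot
#'
#' The axis-aligned (1 - alpha) region in score space:
#' `semi_axis_a = sd(t_a) * sqrt(2 (n - 1) / (n - 2) * F_{2, n-2}(1 - alpha))`.
#'
#' @param t1,t2 score vectors of the two components.
#' @param alpha significance level, default 0.05 (a 95\% ellipse).
#' @return list: `semi_axis_1`, `semi_axis_2`, `angle` (radians; 0 —
#'   axis-aligned), `n`.
#' @export
hotelling_ellipse <- function(t1, t2, alpha = 0.05) {
  n <- length(t1)
  if (n != length(t2)) stopf("score vectors differ in length")
  if (n < 3L) stopf("Hotelling ellipse needs >= 3 samples")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  crit <- sqrt(2 * (n - 1) / (n - 2) * stats::qf(1 - alpha, 2, n - 2))
  list(semi_axis_1 = stats::sd(t1) * crit,
       semi_axis_2 = stats::sd(t2) * crit,
       angle = 0, n = n)
}
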