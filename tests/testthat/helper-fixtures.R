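# Shared fixtures and independent oracles used across the suite.

SUITE_SEED <- 20250926L

# small labelled matrix builders ------------------------------------------

toy_matrix <- function(values, features = NULL, samples = NULL,
                       kind = "metabolite_conc") {
  m <- as.matrix(values)
  rownames(m) <- features %||% paste0("F", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("smp", seq_len(ncol(m)))
  feature_matrix(m, kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_sheet <- function(n_per_group = 3L, protein = 1) {
  n <- 2L * n_per_group
  sample_sheet(paste0("smp", seq_len(n)),
               rep(c("P", "S"), each = n_per_group),
               "plus", protein)
}

random_feature_matrix <- function(nf, ns, kind = "expression_log2") {
  toy_matrix(matrix(rnorm(nf * ns), nf, ns), kind = kind)
}

# independent oracles ------------------------------------------------------

# Eigendecomposition-based PLS for a univariate response: per component the
# weight is the leading eigenvector of X' y y' X, then standard deflation.
# Shares no code with the NIPALS path.
eigen_pls_oracle <- function(X, y01, ncomp) {
  y0 <- y01 - mean(y01)
  Xd <- X
  W <- P <- matrix(0, ncol(X), ncomp)
  Tm <- matrix(0, nrow(X), ncomp)
  q <- numeric(ncomp)
  yd <- y0
  for (a in seq_len(ncomp)) {
    M <- crossprod(Xd, yd) %*% crossprod(yd, Xd)
    w <- eigen(M, symmetric = TRUE)$vectors[, 1L]
    nz <- which(abs(w) > 1e-12)[1L]
    if (w[nz] < 0) w <- -w
    t_ <- Xd %*% w
    tt <- sum(t_^2)
    p_ <- crossprod(Xd, t_) / tt
    q[a] <- sum(yd * t_) / tt
    W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_
    Xd <- Xd - t_ %*% t(p_)
    yd <- yd - drop(t_) * q[a]
  }
  list(W = W, P = P, T = Tm, q = q)
}

# Literal pair-enumeration reference for differential edge selection.
brute_force_selection <- function(r_P, r_S, tau) {
  g <- rownames(r_S)
  out <- character()
  for (i in seq_along(g)) for (j in seq_along(g)) {
    if (i >= j) next
    rs <- r_S[i, j]; rp <- r_P[i, j]
    if (!is.na(rs) && !is.na(rp) && rs > 0 && (rs - rp) > tau) {
      pair <- sort(c(g[i], g[j]))
      out <- c(out, paste(pair[1L], pair[2L], sep = "\r"))
    }
  }
  sort(out)
}

selected_keys <- function(sel) {
  if (!nrow(sel)) return(character())
  sort(paste(sel[, 1L], sel[, 2L], sep = "\r"))
}

# Naive agglomerative average-linkage trace over columns of a profile matrix
# with distance 1 - Pearson r; returns merge heights in order.
naive_average_linkage <- function(profiles) {
  d <- 1 - cor(profiles)
  diag(d) <- NA
  n <- ncol(profiles)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  dist_cc <- function(c1, c2) mean(d[c1, c2]) # average linkage on original dissimilarities
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- dist_cc(clusters[[i]], clusters[[j]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters <- c(clusters[-best], list(merged))
  }
  heights
}

# Exhaustive running-sum KS enrichment for a hit indicator vector.
brute_force_ks <- function(hit) {
  n <- length(hit); nh <- sum(hit)
  rs <- 0; best <- 0
  for (i in seq_len(n)) {
    rs <- rs + if (hit[i]) 1 / nh else -1 / (n - nh)
    if (abs(rs) > abs(best)) best <- rs
  }
  best
}
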