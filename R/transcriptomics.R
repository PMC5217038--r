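# Expression preprocessing and per-gene statistics: quantile normalization,
# log2 centering, ordinary and random-variance (moderated) t-tests, and
# classic Kolmogorov-Smirnov gene-set enrichment with a permutation null.

#' Quantile-normalize an expression matrix
#'
#' Forces every sample column to share one reference distribution — the
#' row-wise mean of the sorted columns; ties share the mean of their would-be
#' values. Idempotent, and a fixed point for identical columns.
#'
#' @param X [feature_matrix()] (genes x samples), >= 2 samples.
#' @return quantile-normalized [feature_matrix()], same kind.
#' @export
quantile_normalize <- function(X) {
  x <- unclass(X)
  if (ncol(x) < 2L) stopf("quantile normalization needs >= 2 samples")
  if (any(colSums(!is.na(x)) == 0L)) stopf("all-missing sample column")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  feature_matrix(out, fm_kind(X))
}

#' Log2-transform and gene-center an expression matrix
#'
#' `log2(x)` followed by subtracting each gene's mean, so every row has mean
#' zero — the representation used for clustering and heat maps.
#'
#' @param X [feature_matrix()] with strictly positive values.
#' @return centered log2 [feature_matrix()] (kind `expression_log2`).
#' @export
log2_center <- function(X) {
  x <- unclass(X)
  bad <- which(x <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("non-positive value at feature '%s', sample '%s'",
          rownames(x)[bad[1L, 1L]], colnames(x)[bad[1L, 2L]])
  }
  lx <- log2(x)
  out <- lx - rowMeans(lx)
  feature_matrix(out, "expression_log2")
}

#' Collapse probes to genes by maximum mean intensity
#'
#' Keeps, for each gene, the probe with the largest mean intensity across
#' samples (a common convention when the platform's collapsing rule is not
#' specified).
#'
#' @param X probe-level [feature_matrix()].
#' @param probe_to_gene named character vector mapping probe id -> gene id.
#' @return gene-level [feature_matrix()].
#' @export
collapse_probes <- function(X, probe_to_gene) {
  x <- unclass(X)
  genes <- probe_to_gene[rownames(x)]
  if (anyNA(genes)) stopf("probe(s) without a gene mapping: %s",
                          paste(rownames(x)[is.na(genes)], collapse = ", "))
  means <- rowMeans(x, na.rm = TRUE)
  keep <- unlist(lapply(split(seq_len(nrow(x)), genes), function(ix) ix[which.max(means[ix])]))
  out <- x[keep, , drop = FALSE]
  rownames(out) <- names(keep)
  log_msg("info", "collapsed %d probes to %d genes (max mean intensity)",
          nrow(x), nrow(out))
  feature_matrix(out[order(rownames(out)), , drop = FALSE], fm_kind(X))
}

# ML fit of the scaled-F marginal of per-gene sample variances under an
# inverse-gamma prior on sigma^2 (equivalently 1/sigma^2 ~ Gamma(a, rate b)):
# s^2 ~ b/a' ... parameterized as s^2 ~ s0^2 * F(d, d0) with d0 = 2a, s0^2 = b.
fit_variance_prior <- function(s2, df) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 10L) stopf("too few positive variances to fit the prior")
  negll <- function(par) {
    d0 <- exp(par[1L]); s02 <- exp(par[2L])
    -sum(stats::df(s2 / s02, df, d0, log = TRUE) - log(s02))
  }
  init <- c(log(4), log(stats::median(s2)))
  opt <- stats::optim(init, negll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (opt$convergence != 0L) stopf("variance prior fit did not converge")
  list(a = exp(opt$par[1L]) / 2, b = exp(opt$par[2L]),
       d0 = exp(opt$par[1L]), s02 = exp(opt$par[2L]))
}

#' Per-gene differential expression between conditions S and P
#'
#' `method = "ordinary"` is the pooled-variance Student t per gene.
#' `method = "random_variance"` shrinks each gene's pooled variance toward an
#' inverse-gamma prior fitted across genes by maximum likelihood:
#' `s~^2 = ((n - 2) s^2 + 2 a b) / ((n - 2) + 2 a)` on `n - 2 + 2a` degrees of
#' freedom — borrowing strength across the array where per-gene replication
#' is small. If the prior fit fails the ordinary test is used with a warning.
#'
#' @param X expression [feature_matrix()] (log2 scale recommended).
#' @param sheet [sample_sheet()].
#' @param method `"random_variance"` (default) or `"ordinary"`.
#' @return data.frame: gene, log2_fc (S - P mean difference), t_stat, df,
#'   p_value, method; plus attributes `prior_a`, `prior_b` for the
#'   random-variance fit.
#' @export
differential_expression <- function(X, sheet, method = c("random_variance", "ordinary")) {
  method <- match.arg(method)
  cond <- group_index(X, sheet)
  x <- unclass(X)
  a_idx <- cond == "S"; b_idx <- cond == "P"
  n1 <- sum(a_idx); n2 <- sum(b_idx)
  m1 <- rowMeans(x[, a_idx, drop = FALSE]); m2 <- rowMeans(x[, b_idx, drop = FALSE])
  v1 <- apply(x[, a_idx, drop = FALSE], 1L, stats::var)
  v2 <- apply(x[, b_idx, drop = FALSE], 1L, stats::var)
  d <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
  inv_n <- 1 / n1 + 1 / n2
  prior <- NULL
  if (method == "random_variance") {
    prior <- tryCatch(fit_variance_prior(s2, d), error = function(e) {
      warnf("variance prior fit failed (%s); falling back to ordinary t", conditionMessage(e))
      NULL
    })
  }
  if (!is.null(prior)) {
    s2_t <- (d * s2 + 2 * prior$a * prior$b) / (d + 2 * prior$a)
    df_t <- d + 2 * prior$a
    used <- "random_variance"
  } else {
    s2_t <- s2
    df_t <- d
    used <- "ordinary"
  }
  tstat <- (m1 - m2) / sqrt(s2_t * inv_n)
  p <- 2 * stats::pt(-abs(tstat), df_t)
  out <- data.frame(gene = rownames(x), log2_fc = m1 - m2, t_stat = tstat,
                    df = df_t, p_value = p, method = used,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(prior)) {
    attr(out, "prior_a") <- prior$a
    attr(out, "prior_b") <- prior$b
  }
  out
}

# Classic (unweighted) KS running-sum enrichment score for one set of hit
# positions within a ranked list of length n: hits step +1/Nh, misses step
# -1/(N - Nh); ES is the extreme deviation (signed), so |ES| <= 1.
ks_running_score <- function(hit, n) {
  nh <- sum(hit)
  step <- ifelse(hit, 1 / nh, -1 / (n - nh))
  rs <- cumsum(step)
  i <- which.max(abs(rs))
  rs[i]
}

#' Kolmogorov-Smirnov gene-set enrichment
#'
#' Genes are ranked by a per-gene statistic (descending: up in S first). For
#' each set the classic unweighted KS running sum gives an enrichment score in
#' [-1, 1]; the nominal p-value comes from random membership (gene-set)
#' permutations of the same size, with the +1/+1 estimator so p is never
#' zero. Sets overlapping the ranking by fewer than `min_size` genes are
#' skipped with a log message. Benjamini-Hochberg q-values across sets are
#' included.
#'
#' @param ranked_stats named numeric vector of per-gene statistics (e.g.
#'   signed t from [differential_expression()]); need not be pre-sorted.
#' @param sets list of [gene_set()] objects.
#' @param n_perm membership permutations per set, default 1000.
#' @param seed RNG seed.
#' @param min_size minimum overlap with the ranking, default 5.
#' @return data.frame: set, size, ES, direction (`up_in_S`/`down_in_S`),
#'   nominal_p, q_value.
#' @export
enrichment_ks <- function(ranked_stats, sets, n_perm = 1000L, seed = 1L,
                          min_size = 5L) {
  ord <- order(ranked_stats, decreasing = TRUE)
  ranking <- names(ranked_stats)[ord]
  n <- length(ranking)
  rows <- list()
  with_seed(seed, {
    for (s in sets) {
      members <- intersect(s$members, ranking)
      if (length(members) < min_size) {
        log_msg("info", "skipping set '%s': overlap %d < %d", s$name,
                length(members), min_size)
        next
      }
      hit <- ranking %in% members
      es <- ks_running_score(hit, n)
      nh <- sum(hit)
      perm_es <- vapply(seq_len(n_perm), function(b) {
        ph <- logical(n)
        ph[sample.int(n, nh)] <- TRUE
        ks_running_score(ph, n)
      }, numeric(1L))
      p <- (1 + sum(abs(perm_es) >= abs(es))) / (n_perm + 1)
      rows[[length(rows) + 1L]] <- data.frame(
        set = s$name, size = nh, ES = es,
        direction = if (es >= 0) "up_in_S" else "down_in_S",
        nominal_p = p, stringsAsFactors = FALSE)
    }
  })
  if (!length(rows)) {
    return(data.frame(set = character(), size = integer(), ES = numeric(),
                      direction = character(), nominal_p = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$nominal_p, "BH")
  out
}
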