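# Gene-metabolite correlation integration: per-condition Pearson matrices,
# hierarchical clustering of genes into k sub-clusters, display capping, and
# per-cluster differential-association summaries.

#' Gene-metabolite Pearson correlation matrix for one condition
#'
#' Pairs the metabolite and expression layers sample-by-sample within one
#' condition (and glucose arm) and computes `r[m, g]`, the Pearson correlation
#' of metabolite m with gene g across the paired samples. Zero-variance
#' features give missing entries, logged.
#'
#' @param expr expression [feature_matrix()].
#' @param metab normalized metabolite [feature_matrix()].
#' @param expr_sheet,metab_sheet the layers' [sample_sheet()]s.
#' @param condition `"P"` or `"S"`.
#' @param genes [gene_set()] or character vector (default: all genes).
#' @param metabolites character vector (default: all metabolites).
#' @param glucose glucose arm to pair within, default `"plus"`.
#' @return metabolites x genes correlation matrix.
#' @export
gene_metabolite_correlations <- function(expr, metab, expr_sheet, metab_sheet,
                                         condition, genes = NULL,
                                         metabolites = NULL, glucose = "plus") {
  gids <- if (is.null(genes)) rownames(expr) else
    if (inherits(genes, "gene_set")) genes$members else as.character(genes)
  gids <- intersect(gids, rownames(expr))
  mids <- if (is.null(metabolites)) rownames(metab) else
    intersect(as.character(metabolites), rownames(metab))
  if (!length(gids) || !length(mids)) stopf("no genes or metabolites to correlate")
  pr <- pair_layers(metab_sheet, expr_sheet, condition, glucose)
  em <- t(unclass(expr)[gids, expr_sheet$sample_id[pr$expr_idx], drop = FALSE])
  mm <- t(unclass(metab)[mids, metab_sheet$sample_id[pr$metab_idx], drop = FALSE])
  r <- suppressWarnings(stats::cor(mm, em))
  if (anyNA(r)) log_msg("info", "zero-variance features give %d missing correlations", sum(is.na(r)))
  r
}

#' Hierarchically cluster genes by their correlation profiles
#'
#' Agglomerative (average linkage) clustering of the gene columns of a
#' metabolite x gene correlation matrix. The distance between two genes is
#' `1 - r` where r is the Pearson correlation of their metabolite-correlation
#' profiles, so sign-discordant genes separate. The tree is cut into exactly
#' `k` clusters; ids are contiguous 1..k in order of first appearance.
#'
#' @param r_matrix metabolites x genes correlation matrix (columns clustered).
#' @param k number of sub-clusters, default 10.
#' @return list: `clusters` (named integer vector gene -> 1..k), `hclust`
#'   (the dendrogram), `k`.
#' @export
cluster_genes <- function(r_matrix, k = 10L) {
  ng <- ncol(r_matrix)
  if (k > ng) stopf("k = %d exceeds the %d genes", k, ng)
  if (any(colSums(!is.na(r_matrix)) == 0L)) stopf("all-missing gene column(s)")
  d <- profile_distance(r_matrix)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  raw <- stats::cutree(hc, k = k)
  # relabel contiguously in order of first appearance over input gene order
  ids <- match(raw, unique(raw))
  names(ids) <- colnames(r_matrix)
  list(clusters = ids, hclust = hc, k = k)
}

# 1 - Pearson correlation between gene columns' profiles.
profile_distance <- function(r_matrix) {
  pc <- suppressWarnings(stats::cor(r_matrix, use = "pairwise.complete.obs"))
  d <- 1 - pc
  diag(d) <- 0
  d
}

#' Cap a correlation matrix for display export
#'
#' Clips values into `[-c, +c]` (default 0.7), the saturation range used when
#' rendering correlation heat maps. Display-only: all statistics in this
#' package use uncapped values. Idempotent.
#'
#' @param r_matrix correlation matrix.
#' @param cap positive cap, default 0.7.
#' @return the clipped matrix.
#' @export
cap_matrix <- function(r_matrix, cap = 0.7) {
  if (cap <= 0) stopf("cap must be > 0")
  pmin(pmax(r_matrix, -cap), cap)
}

#' Per-cluster differential gene-metabolite association summary
#'
#' For every cluster x metabolite cell: the mean correlation in P, in S, and
#' the difference `delta = mean_r_S - mean_r_P`. Clusters whose mean
#' association with a metabolite flips sign between conditions (both means
#' beyond `flip_min` in absolute value, opposite signs) are flagged.
#'
#' @param r_P,r_S matched metabolites x genes correlation matrices.
#' @param clusters named integer vector from [cluster_genes()].
#' @param flip_min minimum |mean r| on both sides to call a sign flip,
#'   default 0.2.
#' @return data.frame with k x n_metabolites rows: cluster, metabolite,
#'   mean_r_P, mean_r_S, delta, sign_flip.
#' @export
differential_association_report <- function(r_P, r_S, clusters, flip_min = 0.2) {
  stopifnot(identical(dim(r_P), dim(r_S)))
  k <- max(clusters)
  rows <- list()
  for (cl in seq_len(k)) {
    g <- names(clusters)[clusters == cl]
    for (m in rownames(r_S)) {
      mp <- mean(r_P[m, g], na.rm = TRUE)
      ms <- mean(r_S[m, g], na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, metabolite = m, mean_r_P = mp, mean_r_S = ms,
        delta = ms - mp,
        sign_flip = is.finite(mp) && is.finite(ms) &&
          abs(mp) >= flip_min && abs(ms) >= flip_min && sign(mp) != sign(ms),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the full gene-metabolite correlation cluster map
#'
#' Computes per-condition correlation matrices, clusters genes on their
#' concatenated P and S profiles (so condition-discordant genes separate),
#' and returns capped display matrices alongside the uncapped originals and
#' the per-cluster differential report.
#'
#' @param expr,metab,expr_sheet,metab_sheet as in
#'   [gene_metabolite_correlations()].
#' @param genes,metabolites feature selections.
#' @param k sub-clusters, default 10.
#' @param cap display cap, default 0.7.
#' @param glucose glucose arm, default `"plus"`.
#' @return object of class `correlation_cluster_map`: `r_P`, `r_S`,
#'   `capped_P`, `capped_S`, `clusters`, `k`, `cap`, `report`.
#' @export
build_cluster_map <- function(expr, metab, expr_sheet, metab_sheet,
                              genes = NULL, metabolites = NULL, k = 10L,
                              cap = 0.7, glucose = "plus") {
  r_P <- gene_metabolite_correlations(expr, metab, expr_sheet, metab_sheet,
                                      "P", genes, metabolites, glucose)
  r_S <- gene_metabolite_correlations(expr, metab, expr_sheet, metab_sheet,
                                      "S", genes, metabolites, glucose)
  cl <- cluster_genes(rbind(r_P, r_S), k = k)
  structure(list(r_P = r_P, r_S = r_S,
                 capped_P = cap_matrix(r_P, cap), capped_S = cap_matrix(r_S, cap),
                 clusters = cl$clusters, hclust = cl$hclust, k = k, cap = cap,
                 report = differential_association_report(r_P, r_S, cl$clusters)),
            class = "correlation_cluster_map")
}

#' @export
print.correlation_cluster_map <- function(x, ...) {
  cat(sprintf("correlation_cluster_map: %d metabolites x %d genes, %d clusters, cap %.2f; %d sign-flip cells\n",
              nrow(x$r_S), ncol(x$r_S), x$k, x$cap, sum(x$report$sign_flip)))
  invisible(x)
}
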