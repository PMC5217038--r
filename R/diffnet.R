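# Differential co-expression network over a pathway gene set: per-condition
# Pearson correlation matrices, positive-edge filter, edge-difference
# selection at threshold tau, and hub ranking by degree.

#' Per-condition pairwise Pearson correlations for a gene set
#'
#' Restricts the expression matrix to the given condition's samples and the
#' gene set's members, and returns the pairwise Pearson correlation matrix.
#' Members absent from the matrix are dropped with a log message;
#' zero-variance genes get missing (`NA`) correlations, never edges.
#'
#' @param X expression [feature_matrix()].
#' @param sheet [sample_sheet()].
#' @param genes a [gene_set()] or character vector of gene ids.
#' @param condition `"P"` or `"S"`.
#' @param glucose optional glucose arm filter (`"plus"`/`"minus"`); default
#'   uses all samples of the condition.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
condition_correlations <- function(X, sheet, genes, condition, glucose = NULL) {
  ids <- if (inherits(genes, "gene_set")) genes$members else as.character(genes)
  x <- unclass(X)
  missing_g <- setdiff(ids, rownames(x))
  if (length(missing_g)) {
    log_msg("info", "gene(s) absent from matrix dropped: %s", paste(missing_g, collapse = ", "))
  }
  ids <- intersect(ids, rownames(x))
  if (length(ids) < 2L) stopf("need >= 2 gene-set members present in the matrix")
  idx <- match(colnames(x), sheet$sample_id)
  sel <- sheet$condition[idx] == condition
  if (!is.null(glucose)) sel <- sel & sheet$glucose[idx] == glucose
  if (sum(sel, na.rm = TRUE) < 3L) stopf("condition %s has fewer than 3 samples", condition)
  if (sum(sel, na.rm = TRUE) < 8L) {
    warnf("condition %s has only %d samples; correlations will be very noisy",
          condition, sum(sel, na.rm = TRUE))
  }
  sub <- t(x[ids, which(sel), drop = FALSE])
  sds <- apply(sub, 2L, stats::sd)
  r <- suppressWarnings(stats::cor(sub))
  zero_var <- sds == 0 | is.na(sds)
  if (any(zero_var)) {
    log_msg("info", "zero-variance gene(s) get missing correlations: %s",
            paste(ids[zero_var], collapse = ", "))
    r[zero_var, ] <- NA_real_
    r[, zero_var] <- NA_real_
  }
  diag(r) <- 1
  r
}

pairs_from_matrix <- function(r, predicate) {
  g <- rownames(r)
  ut <- which(upper.tri(r) & predicate(r), arr.ind = TRUE)
  if (!nrow(ut)) return(matrix(character(), 0L, 2L, dimnames = list(NULL, c("gene_a", "gene_b"))))
  a <- g[ut[, 1L]]; b <- g[ut[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  m <- cbind(gene_a = a, gene_b = b)
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

#' Positive-correlation edge filter
#'
#' Retains gene pairs with strictly positive correlation (`r > 0`); missing
#' correlations never form edges. Negative correlations are removed, matching
#' the convention that a co-expression edge requires positive association.
#'
#' @param r_matrix symmetric correlation matrix.
#' @return two-column character matrix of unordered pairs (gene_a < gene_b).
#' @export
positive_filter <- function(r_matrix) {
  pairs_from_matrix(r_matrix, function(r) !is.na(r) & r > 0)
}

#' Select differential co-expression edges
#'
#' Default direction `S_gain`: pairs with `r_S > 0` (the edge must exist in
#' the gained network after the positive filter) and `r_S - r_P > tau` —
#' gene pairs strongly co-expressed in the stem-like cells but not in the
#' parental cells. `P_gain` is the mirror image; `both` is the union.
#' Strict inequality; missing correlations never select.
#'
#' @param r_P,r_S per-condition correlation matrices on identical gene order.
#' @param tau difference threshold in (0, 2), default 0.6.
#' @param direction `"S_gain"` (default), `"P_gain"`, or `"both"`.
#' @return two-column character matrix of selected unordered pairs.
#' @export
select_differential_edges <- function(r_P, r_S, tau = 0.6,
                                      direction = c("S_gain", "P_gain", "both")) {
  direction <- match.arg(direction)
  if (!identical(dim(r_P), dim(r_S)) || !identical(rownames(r_P), rownames(r_S))) {
    stopf("correlation matrices must share dimensions and gene order")
  }
  if (tau <= 0 || tau >= 2) stopf("tau must be in (0, 2)")
  s_gain <- function(rp, rs) !is.na(rs) & !is.na(rp) & rs > 0 & (rs - rp) > tau
  sel <- switch(direction,
    S_gain = pairs_from_matrix(r_S, function(...) s_gain(r_P, r_S)),
    P_gain = pairs_from_matrix(r_P, function(...) s_gain(r_S, r_P)),
    both = {
      a <- pairs_from_matrix(r_S, function(...) s_gain(r_P, r_S))
      b <- pairs_from_matrix(r_P, function(...) s_gain(r_S, r_P))
      m <- unique(rbind(a, b))
      m[order(m[, 1L], m[, 2L]), , drop = FALSE]
    })
  sel
}

#' Build a differential co-expression network
#'
#' Runs [condition_correlations()] for both conditions,
#' [positive_filter()] on each, and [select_differential_edges()], returning
#' the full `diff_network` record with per-gene degree over selected edges.
#'
#' @param X expression [feature_matrix()].
#' @param sheet [sample_sheet()].
#' @param genes [gene_set()] or character vector.
#' @param tau difference threshold, default 0.6.
#' @param direction see [select_differential_edges()].
#' @param glucose optional glucose arm filter.
#' @return object of class `diff_network`: `genes`, `r_P`, `r_S`, `edges_P`,
#'   `edges_S`, `selected`, `tau`, `direction`, `degree`.
#' @export
build_diff_network <- function(X, sheet, genes, tau = 0.6,
                               direction = "S_gain", glucose = NULL) {
  r_P <- condition_correlations(X, sheet, genes, "P", glucose)
  r_S <- condition_correlations(X, sheet, genes, "S", glucose)
  selected <- select_differential_edges(r_P, r_S, tau, direction)
  deg <- stats::setNames(integer(nrow(r_S)), rownames(r_S))
  if (nrow(selected)) {
    tab <- table(c(selected[, 1L], selected[, 2L]))
    deg[names(tab)] <- as.integer(tab)
  }
  structure(list(genes = rownames(r_S), r_P = r_P, r_S = r_S,
                 edges_P = positive_filter(r_P), edges_S = positive_filter(r_S),
                 selected = selected, tau = tau, direction = direction,
                 degree = deg),
            class = "diff_network")
}

#' @export
print.diff_network <- function(x, ...) {
  cat(sprintf("diff_network: %d genes; %d/%d positive edges (P/S); %d selected at tau = %g (%s)\n",
              length(x$genes), nrow(x$edges_P), nrow(x$edges_S),
              nrow(x$selected), x$tau, x$direction))
  invisible(x)
}

#' Rank genes by degree in the selected differential edge set
#'
#' Hub ranking: genes sorted by decreasing degree over selected edges, ties
#' broken lexicographically. Zero-degree genes are omitted.
#'
#' @param net a `diff_network`.
#' @param top_k how many genes to return; default all with degree > 0.
#' @return data.frame: gene, degree (sorted).
#' @export
hub_ranking <- function(net, top_k = Inf) {
  deg <- net$degree[net$degree > 0L]
  if (!length(deg)) return(data.frame(gene = character(), degree = integer(),
                                      stringsAsFactors = FALSE))
  ord <- order(-deg, names(deg))
  out <- data.frame(gene = names(deg)[ord], degree = as.integer(deg[ord]),
                    stringsAsFactors = FALSE)
  utils::head(out, top_k)
}
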