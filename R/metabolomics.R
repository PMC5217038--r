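# Targeted metabolite statistics: protein normalization, group comparison
# (Student/Welch t), derived ratios (NAAD+/NAADP+), and Z-score profiling.

#' Normalize metabolite concentrations to per-sample protein mass
#'
#' Divides each sample's column by its protein mass (mg), yielding
#' concentrations in pmol per 1e6 cells per mg protein. Linear: scaling one
#' sample's protein by c scales its column by 1/c.
#'
#' @param raw raw [feature_matrix()] (kind `metabolite_conc`).
#' @param sheet [sample_sheet()] with `protein_mg` for every sample of `raw`.
#' @return normalized [feature_matrix()], same kind.
#' @export
normalize_to_protein <- function(raw, sheet) {
  idx <- match(colnames(raw), sheet$sample_id)
  if (anyNA(idx)) {
    stopf("no protein mass for sample(s): %s",
          paste(colnames(raw)[is.na(idx)], collapse = ", "))
  }
  out <- sweep(unclass(raw), 2L, sheet$protein_mg[idx], `/`)
  feature_matrix(out, fm_kind(raw))
}

group_index <- function(x, sheet, min_n = 2L) {
  idx <- match(colnames(x), sheet$sample_id)
  if (anyNA(idx)) stopf("sample(s) missing from sheet: %s",
                        paste(colnames(x)[is.na(idx)], collapse = ", "))
  cond <- sheet$condition[idx]
  for (g in c("P", "S")) {
    if (sum(cond == g) < min_n) stopf("group %s has fewer than %d samples", g, min_n)
  }
  cond
}

significance_tier <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("p<0.001", "p<0.01", "p<0.05", "ns"), right = FALSE)
}

# Closed-form two-sample t (both flavours); returns t, df, p. Zero variance in
# both groups with equal means yields p = 1 by convention.
two_sample_t <- function(a, b, test = c("student", "welch")) {
  test <- match.arg(test)
  n1 <- length(a); n2 <- length(b)
  m1 <- mean(a); m2 <- mean(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  if (v1 == 0 && v2 == 0) {
    if (m1 == m2) return(list(t = 0, df = n1 + n2 - 2, p = 1, degenerate = TRUE))
    return(list(t = sign(m1 - m2) * Inf, df = n1 + n2 - 2, p = 0, degenerate = TRUE))
  }
  if (test == "student") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

#' Per-metabolite group comparison (S vs P)
#'
#' Two-sided two-sample t-tests per metabolite with fold change
#' `mean_S / mean_P` and the usual significance tiers (0.05 / 0.01 / 0.001).
#' Student's equal-variance t is the default; Welch available. Optionally the
#' test is run on log-transformed values (fold change still reported on the
#' concentration scale). Raw p-values are reported; Benjamini-Hochberg
#' q-values are added when `adjust = TRUE`.
#'
#' @param norm normalized [feature_matrix()].
#' @param sheet [sample_sheet()].
#' @param test `"student"` (default) or `"welch"`.
#' @param log_transform test on `log(x)` instead of x; default FALSE.
#' @param adjust add BH-adjusted q-values; default FALSE.
#' @return data.frame: metabolite, mean_P, mean_S, fold_change, t_stat, df,
#'   p_value, significance_tier (and q_value when `adjust`).
#' @export
compare_groups <- function(norm, sheet, test = c("student", "welch"),
                           log_transform = FALSE, adjust = FALSE) {
  test <- match.arg(test)
  cond <- group_index(norm, sheet)
  x <- unclass(norm)
  if (log_transform) {
    if (any(x <= 0, na.rm = TRUE)) stopf("log transform requires positive values")
    xt <- log(x)
  } else xt <- x
  res <- lapply(rownames(x), function(m) {
    a <- xt[m, cond == "S"]; b <- xt[m, cond == "P"]
    tt <- two_sample_t(a[!is.na(a)], b[!is.na(b)], test)
    if (tt$degenerate) log_msg("info", "metabolite %s has zero variance in both groups", m)
    data.frame(metabolite = m,
               mean_P = mean(x[m, cond == "P"], na.rm = TRUE),
               mean_S = mean(x[m, cond == "S"], na.rm = TRUE),
               fold_change = mean(x[m, cond == "S"], na.rm = TRUE) /
                 mean(x[m, cond == "P"], na.rm = TRUE),
               t_stat = tt$t, df = tt$df, p_value = tt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significance_tier <- as.character(significance_tier(out$p_value))
  if (adjust) out$q_value <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}

#' Per-sample ratio of two metabolites
#'
#' Elementwise ratio (e.g. NAAD+ / NAADP+) returned as a 1-row feature matrix
#' so it can be fed straight back into [compare_groups()].
#'
#' @param norm normalized [feature_matrix()].
#' @param numerator,denominator metabolite ids present in `norm`.
#' @return a 1 x n_samples [feature_matrix()] named
#'   `"<numerator>/<denominator>"`.
#' @export
metabolite_ratio <- function(norm, numerator, denominator) {
  for (id in c(numerator, denominator)) {
    if (!id %in% rownames(norm)) stopf("metabolite '%s' not in matrix", id)
  }
  den <- unclass(norm)[denominator, ]
  zero <- names(den)[!is.na(den) & den == 0]
  if (length(zero)) stopf("denominator %s is zero in sample(s): %s",
                          denominator, paste(zero, collapse = ", "))
  r <- unclass(norm)[numerator, ] / den
  m <- matrix(r, nrow = 1L, dimnames = list(paste(numerator, denominator, sep = "/"),
                                            colnames(norm)))
  feature_matrix(m, fm_kind(norm))
}

#' Z-score profile against a reference group
#'
#' Standardizes every sample's metabolite value against the reference group's
#' mean and (n-1 denominator) SD: `z = (x - mean_ref) / sd_ref`. By
#' construction the reference group's own z-scores have mean 0 and SD 1 per
#' metabolite. Metabolites with zero reference SD are excluded with a log
#' message. The default reference is the parental group, so positive z in S
#' reads as relative elevation in the stem-like cells.
#'
#' @param norm normalized [feature_matrix()].
#' @param sheet [sample_sheet()].
#' @param reference `"P"` (default) or `"S"`.
#' @return list: `z` (metabolite x sample matrix), `reference_group`,
#'   `excluded` (zero-SD metabolites).
#' @export
zscore_profile <- function(norm, sheet, reference = c("P", "S")) {
  reference <- match.arg(reference)
  cond <- group_index(norm, sheet)
  x <- unclass(norm)
  ref <- x[, cond == reference, drop = FALSE]
  mu <- rowMeans(ref)
  sd_ <- apply(ref, 1L, stats::sd)
  drop <- sd_ == 0 | is.na(sd_)
  if (any(drop)) {
    log_msg("info", "excluding zero-reference-SD metabolite(s): %s",
            paste(rownames(x)[drop], collapse = ", "))
  }
  z <- (x[!drop, , drop = FALSE] - mu[!drop]) / sd_[!drop]
  list(z = z, reference_group = reference, excluded = rownames(x)[drop])
}
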