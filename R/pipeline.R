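# End-to-end orchestration: synthetic data -> metabolomics -> PLS-DA ->
# transcriptomics -> differential network -> integration, with one master
# seed and a JSON-serializable run report.

#' Default pipeline configuration
#'
#' All stage parameters with their defaults; override any subset via the
#' `config` argument of [run_pipeline()]. Unknown keys are rejected before
#' any stage runs.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 17L,
    n_per_group = 5L,
    cv = 0.1,
    n_metabolites = 38L,
    n_genes = 194L,
    noise_sd = 1,
    module_strength = 0.85,
    module_size = 10L,
    naad_fold = 2.0,
    ncomp = 2L,
    folds = 7L,
    n_perm = 100L,
    tau = 0.6,
    direction = "S_gain",
    k_clusters = 10L,
    cap = 0.7,
    vip_cut = 1,
    p_cut = 0.05,
    test = "student",
    zscore_ref = "P",
    de_method = "random_variance"
  )
}

merge_config <- function(config) {
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  base[names(config)] <- config
  base
}

#' Run the integrated metabolome-transcriptome pipeline on synthetic data
#'
#' Simulates a paired dataset with planted structure (a fold-elevated NAAD+
#' panel and an S-only co-expression module), then runs every analysis stage:
#' protein normalization, group t-tests and the NAAD+/NAADP+ ratio, Z-score
#' profiling, PLS-DA with VIP selection, permutation validation and the
#' Hotelling ellipse, differential expression, the differential Wnt-like
#' co-expression network with hub ranking (scored against the planted
#' module), and gene-metabolite correlation clustering. Identical config +
#' seed gives an identical report.
#'
#' @param config named list overriding [default_config()] entries.
#' @param out_dir optional directory; when given, stage tables, the network
#'   and the JSON report are written there.
#' @return a `pipeline_report` list of per-stage summary results.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- merge_config(config)
  stage <- function(name, expr) {
    log_msg("info", "stage %s", name)
    tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  ds <- stage("simulate", {
    truth <- synthetic_truth(
      metab_fold_changes = c(NAAD = cfg$naad_fold, ADP = 1.5,
                             glutamate = 0.7, proline = 0.7),
      module_genes = paste0("WNTG", sprintf("%03d", seq_len(cfg$module_size))),
      module_strength = cfg$module_strength,
      seed = cfg$seed, n_per_group = cfg$n_per_group)
    simulate_dataset(truth, cv = cfg$cv, n_metabolites = cfg$n_metabolites,
                     n_genes = cfg$n_genes, noise_sd = cfg$noise_sd)
  })

  metab <- stage("metabolomics", {
    norm <- normalize_to_protein(ds$metab, ds$metab_sheet)
    stats_tab <- compare_groups(norm, ds$metab_sheet, test = cfg$test)
    ratio <- metabolite_ratio(norm, "NAAD", "NAADP")
    ratio_stats <- compare_groups(ratio, ds$metab_sheet, test = cfg$test)
    zs <- zscore_profile(norm, ds$metab_sheet, reference = cfg$zscore_ref)
    list(norm = norm, stats = stats_tab, ratio_stats = ratio_stats, zscore = zs)
  })

  pls <- stage("plsda", {
    X <- t(unclass(metab$norm))
    y <- ds$metab_sheet$condition
    model <- fit_plsda(X, y, ncomp = cfg$ncomp)
    q2 <- cross_validate_q2(X, y, ncomp = cfg$ncomp, folds = cfg$folds,
                            seed = sub_seed(cfg$seed, 11L))
    perm <- permutation_validate(X, y, ncomp = cfg$ncomp, n_perm = cfg$n_perm,
                                 seed = sub_seed(cfg$seed, 12L), folds = cfg$folds)
    ell <- hotelling_ellipse(model$T[, 1L], model$T[, 2L])
    sel <- select_discriminant(model, metab$stats, cfg$vip_cut, cfg$p_cut)
    list(model = model, Q2 = q2, permutation = perm, ellipse = ell, selected = sel)
  })

  de <- stage("transcriptomics", {
    differential_expression(ds$expr, ds$expr_sheet, method = cfg$de_method)
  })

  net <- stage("diffnet", {
    wnt <- gene_set("WNT_MODULE_PANEL", "synthetic Wnt-like panel", rownames(ds$expr))
    build_diff_network(ds$expr, ds$expr_sheet, wnt, tau = cfg$tau,
                       direction = cfg$direction)
  })
  net_score <- score_network(net, ds$truth)

  integ <- stage("integration", {
    build_cluster_map(ds$expr, metab$norm, ds$expr_sheet, ds$metab_sheet,
                      metabolites = TARGETED_METABOLITES[seq_len(min(10L, nrow(metab$norm)))],
                      k = cfg$k_clusters, cap = cfg$cap)
  })

  naad <- metab$stats[metab$stats$metabolite == "NAAD", ]
  report <- list(
    config = cfg,
    metabolomics = list(
      naad_fold_change = naad$fold_change,
      naad_p_value = naad$p_value,
      naad_tier = naad$significance_tier,
      ratio_fold_change = metab$ratio_stats$fold_change,
      ratio_p_value = metab$ratio_stats$p_value,
      n_significant = sum(metab$stats$p_value < 0.05)),
    plsda = list(R2X = pls$model$R2X, R2Y = pls$model$R2Y, Q2 = pls$Q2,
                 permutation_p = pls$permutation$empirical_p_Q2,
                 n_selected = nrow(pls$selected),
                 selected = pls$selected$feature),
    transcriptomics = list(n_de_p05 = sum(de$p_value < 0.05),
                           prior_a = attr(de, "prior_a")),
    diffnet = list(n_selected_edges = nrow(net$selected),
                   precision = net_score$precision, recall = net_score$recall,
                   top_hub = if (nrow(hub_ranking(net, 1L))) hub_ranking(net, 1L)$gene else NA_character_,
                   top_hub_degree = if (nrow(hub_ranking(net, 1L))) hub_ranking(net, 1L)$degree else 0L),
    integration = list(k = integ$k, n_sign_flips = sum(integ$report$sign_flip),
                       max_abs_delta = max(abs(integ$report$delta), na.rm = TRUE))
  )
  class(report) <- "pipeline_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_matrix(metab$norm, file.path(out_dir, "metabolites_normalized.tsv"))
    utils::write.table(metab$stats, file.path(out_dir, "metabolite_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(de, file.path(out_dir, "differential_expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_network(net, file.path(out_dir, "diffnet_edges.tsv"), "tsv_edgelist")
    write_network(net, file.path(out_dir, "diffnet.graphml"), "graphml")
    utils::write.table(integ$report, file.path(out_dir, "integration_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' Score a differential network against planted module pairs
#'
#' Precision and recall of the selected edge set relative to all unordered
#' pairs of the planted module genes.
#'
#' @param net a `diff_network`.
#' @param truth a [synthetic_truth()].
#' @return list: precision, recall, n_true_pairs, n_selected.
#' @export
score_network <- function(net, truth) {
  mod <- sort(intersect(truth$module_genes, net$genes))
  true_pairs <- if (length(mod) >= 2L) {
    cmb <- utils::combn(mod, 2L)
    paste(cmb[1L, ], cmb[2L, ], sep = "\r")
  } else character()
  sel <- if (nrow(net$selected)) paste(net$selected[, 1L], net$selected[, 2L], sep = "\r") else character()
  tp <- length(intersect(sel, true_pairs))
  list(precision = if (length(sel)) tp / length(sel) else NA_real_,
       recall = if (length(true_pairs)) tp / length(true_pairs) else NA_real_,
       n_true_pairs = length(true_pairs), n_selected = length(sel))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("stemomics pipeline report\n")
  cat(sprintf("  NAAD+ fold change (S/P): %.3f (p = %.2e, %s)\n",
              x$metabolomics$naad_fold_change, x$metabolomics$naad_p_value,
              x$metabolomics$naad_tier))
  cat(sprintf("  NAAD+/NAADP+ ratio fold: %.3f (p = %.2e)\n",
              x$metabolomics$ratio_fold_change, x$metabolomics$ratio_p_value))
  cat(sprintf("  PLS-DA: R2X = %.3f, R2Y = %.3f, Q2 = %.3f; permutation p = %.4f\n",
              x$plsda$R2X, x$plsda$R2Y, x$plsda$Q2, x$plsda$permutation_p))
  cat(sprintf("  VIP>1 & p<0.05 metabolites: %d (%s)\n", x$plsda$n_selected,
              paste(utils::head(x$plsda$selected, 5L), collapse = ", ")))
  cat(sprintf("  diffnet: %d selected edges; precision %.2f, recall %.2f; top hub %s (deg %d)\n",
              x$diffnet$n_selected_edges, x$diffnet$precision, x$diffnet$recall,
              x$diffnet$top_hub, x$diffnet$top_hub_degree))
  cat(sprintf("  integration: k = %d clusters, %d sign-flip cells\n",
              x$integration$k, x$integration$n_sign_flips))
  invisible(x)
}
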