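# Synthetic paired metabolome/transcriptome generator with planted effects.
# The generator writes down its ground truth (fold changes, module membership,
# module strength) so downstream estimators can be scored against it.

# Canonical targeted panel: the NAD(H) biosynthesis / salvage intermediates
# quantified by targeted LC-MS/MS, NAAD+ first.
TARGETED_METABOLITES <- c("NAAD", "NAADP", "NAD", "NADH", "NADP", "NADPH",
                          "Nam", "NMN", "NA_acid", "NaMN")

# 28-metabolite NMR panel typical of aqueous cell extracts.
NMR_METABOLITES <- c(
  "ADP", "AMP", "ATP", "acetate", "alanine", "aspartate", "choline",
  "creatine", "formate", "fumarate", "glucose", "glutamate", "glutamine",
  "glutathione", "glycine", "sn-GPC", "isoleucine", "lactate", "leucine",
  "myo-inositol", "niacinamide", "O-PC", "phenylalanine", "proline",
  "succinate", "taurine", "tyrosine", "valine")

#' Ground truth for a synthetic multi-omics dataset
#'
#' Holds everything the generator plants: multiplicative metabolite fold
#' changes (stem-like S over parental P), the gene module co-expressed only in
#' condition S with pairwise correlation `module_strength`, additive log2
#' differential-expression effects, sample size per group and the master seed.
#'
#' Defaults encode the study conditions this package emulates: a ~2-fold
#' NAAD+ elevation in S with smaller shifts in ADP (up) and glutamate/proline
#' (down), and a 10-gene module at pairwise correlation 0.85 present only in S.
#'
#' @param metab_fold_changes named numeric vector of S/P fold changes (> 0);
#'   metabolites not named default to fold 1.
#' @param module_genes character vector of genes co-expressed only in S.
#' @param module_strength planted pairwise Pearson correlation rho in [0, 1].
#' @param de_genes named numeric vector of additive log2 effects in S.
#' @param seed master seed (integer); per-block sub-seeds are derived from it.
#' @param n_per_group samples per condition x glucose group (>= 3).
#' @return a list with class `synthetic_truth`.
#' @export
synthetic_truth <- function(metab_fold_changes = c(NAAD = 2.0, ADP = 1.5,
                                                   glutamate = 0.7, proline = 0.7),
                            module_genes = paste0("WNTG", sprintf("%03d", 1:10)),
                            module_strength = 0.85,
                            de_genes = c(NAAD = 0)[0],
                            seed = 17L,
                            n_per_group = 5L) {
  if (any(metab_fold_changes <= 0)) stopf("metabolite fold changes must be > 0")
  if (module_strength < 0 || module_strength > 1) stopf("module_strength must be in [0, 1]")
  if (n_per_group < 3L) stopf("n_per_group must be >= 3 (group statistics undefined below that)")
  structure(list(metab_fold_changes = metab_fold_changes,
                 module_genes = as.character(module_genes),
                 module_strength = as.numeric(module_strength),
                 de_genes = de_genes,
                 seed = as.integer(seed),
                 n_per_group = as.integer(n_per_group)),
            class = "synthetic_truth")
}

#' Serialize / restore ground truth as JSON
#' @param truth a [synthetic_truth()].
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  # named vectors serialize as JSON objects so names survive the round trip
  x$metab_fold_changes <- as.list(x$metab_fold_changes)
  x$de_genes <- as.list(x$de_genes)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  synthetic_truth(metab_fold_changes = unlist(x$metab_fold_changes),
                  module_genes = x$module_genes,
                  module_strength = x$module_strength,
                  de_genes = if (length(x$de_genes)) unlist(x$de_genes) else c(a = 0)[0],
                  seed = x$seed, n_per_group = x$n_per_group)
}

default_metabolite_panel <- function(n_metabolites) {
  panel <- c(TARGETED_METABOLITES, NMR_METABOLITES)
  if (n_metabolites <= length(panel)) return(panel[seq_len(n_metabolites)])
  c(panel, paste0("M", sprintf("%03d", seq_len(n_metabolites - length(panel)))))
}

make_sheet <- function(prefix, n_per_group, glucose_levels, seed) {
  grid <- expand.grid(condition = c("P", "S"), glucose = glucose_levels,
                      rep = seq_len(n_per_group), stringsAsFactors = FALSE)
  grid <- grid[order(grid$condition, grid$glucose, grid$rep), ]
  ids <- sprintf("%s_%s_%s_%02d", prefix, grid$condition,
                 ifelse(grid$glucose == "plus", "G1", "G0"), grid$rep)
  protein <- with_seed(seed, stats::runif(nrow(grid), 0.8, 1.2))
  sample_sheet(ids, grid$condition, grid$glucose, protein)
}

#' Simulate a targeted/NMR metabolite concentration table
#'
#' Concentrations are log-normal around a per-metabolite baseline: for group g
#' the log concentration is `log(baseline) + [g = S] * log(fold) + eps` with
#' `eps ~ Normal(0, log(1 + cv)^2)`, so planted effects are multiplicative and
#' values stay positive. Per-sample protein mass is a Uniform(0.8, 1.2)
#' nuisance; the returned matrix holds raw (pre-normalization) values,
#' `raw = concentration * protein_mg`, so that [normalize_to_protein()]
#' recovers the simulated concentrations exactly.
#'
#' @param truth a [synthetic_truth()].
#' @param cv within-group coefficient of variation (> 0), default 0.1.
#' @param n_metabolites panel size, default 38 (10 targeted + 28 NMR).
#' @param glucose_levels glucose arms to simulate; default `"plus"` only,
#'   matching a targeted panel measured in complete medium.
#' @return list with `matrix` (raw [feature_matrix()], kind
#'   `metabolite_conc`), `sheet` (the [sample_sheet()]), and `concentrations`
#'   (the pre-protein-jitter normalized values, for testing).
#' @export
simulate_metabolome <- function(truth, cv = 0.1, n_metabolites = 38L,
                                glucose_levels = "plus") {
  if (cv <= 0) stopf("cv must be > 0")
  mets <- default_metabolite_panel(n_metabolites)
  unknown <- setdiff(names(truth$metab_fold_changes), mets)
  folds <- rep(1, n_metabolites)
  names(folds) <- mets
  known <- intersect(names(truth$metab_fold_changes), mets)
  folds[known] <- truth$metab_fold_changes[known]
  if (length(unknown)) log_msg("warn", "fold changes for metabolites not in panel ignored: %s",
                               paste(unknown, collapse = ", "))
  sheet <- make_sheet("MB", truth$n_per_group, glucose_levels, sub_seed(truth$seed, 1L))
  n <- nrow(sheet)
  sdlog <- log(1 + cv)
  sim <- with_seed(sub_seed(truth$seed, 2L), {
    baseline <- exp(stats::runif(n_metabolites, log(5), log(500)))
    eps <- matrix(stats::rnorm(n_metabolites * n, 0, sdlog), n_metabolites, n)
    list(baseline = baseline, eps = eps)
  })
  is_s <- as.numeric(sheet$condition == "S")
  logc <- log(sim$baseline) + log(folds) %o% is_s + sim$eps
  conc <- exp(logc)
  dimnames(conc) <- list(mets, sheet$sample_id)
  raw <- sweep(conc, 2L, sheet$protein_mg, `*`)
  list(matrix = feature_matrix(raw, "metabolite_conc"),
       sheet = sheet,
       concentrations = feature_matrix(conc, "metabolite_conc"))
}

#' Simulate an expression matrix with a condition-specific co-expression module
#'
#' Genes are on a log2-like scale with Gaussian noise of SD `noise_sd`. In
#' condition S each module gene i is `sqrt(rho) * f + sqrt(1 - rho) * eps_i`
#' (times `noise_sd`, plus the gene's baseline) with one shared latent factor
#' f per sample, so the expected within-module pairwise Pearson correlation is
#' exactly rho. In condition P all genes are independent. Genes named in
#' `truth$de_genes` additionally shift their S mean by the planted log2
#' effect.
#'
#' @param truth a [synthetic_truth()]; `module_genes` must lie inside the
#'   simulated gene universe.
#' @param n_genes gene universe size, default 194.
#' @param noise_sd per-gene Gaussian noise SD on the log2 scale, default 1.
#' @param glucose_levels glucose arms; default both (`plus` then `minus`).
#' @param n_per_group samples per condition x glucose cell; defaults to
#'   `truth$n_per_group`.
#' @return list with `matrix` (kind `expression_log2`) and `sheet`.
#' @export
simulate_transcriptome <- function(truth, n_genes = 194L, noise_sd = 1,
                                   glucose_levels = c("plus", "minus"),
                                   n_per_group = truth$n_per_group) {
  rho <- truth$module_strength
  genes <- union(truth$module_genes, paste0("GENE", sprintf("%04d", seq_len(n_genes))))
  genes <- genes[seq_len(max(n_genes, length(truth$module_genes)))]
  if (!all(truth$module_genes %in% genes)) stopf("module_genes must fit inside the gene universe")
  sheet <- make_sheet("TX", n_per_group, glucose_levels, sub_seed(truth$seed, 3L))
  n <- nrow(sheet)
  p <- length(genes)
  sim <- with_seed(sub_seed(truth$seed, 4L), {
    baseline <- stats::runif(p, 6, 12)
    eps <- matrix(stats::rnorm(p * n), p, n)
    f <- stats::rnorm(n)
    list(baseline = baseline, eps = eps, f = f)
  })
  noise <- sim$eps
  in_mod <- genes %in% truth$module_genes
  s_cols <- sheet$condition == "S"
  if (any(in_mod) && any(s_cols)) {
    noise[in_mod, s_cols] <- sqrt(rho) * matrix(sim$f[s_cols], sum(in_mod),
                                                sum(s_cols), byrow = TRUE) +
      sqrt(1 - rho) * sim$eps[in_mod, s_cols]
  }
  x <- sim$baseline + noise_sd * noise
  de <- intersect(names(truth$de_genes), genes)
  if (length(de) && any(s_cols)) {
    x[match(de, genes), s_cols] <- x[match(de, genes), s_cols] + truth$de_genes[de]
  }
  dimnames(x) <- list(genes, sheet$sample_id)
  list(matrix = feature_matrix(x, "expression_log2"), sheet = sheet)
}

#' Simulate a full paired multi-omics dataset
#'
#' Composes [simulate_metabolome()] and [simulate_transcriptome()] under one
#' master seed (deterministic sub-seeds per block). The two layers carry their
#' own sample sheets; integration-stage pairing uses matched replicate
#' structure via [pair_layers()].
#'
#' @param truth a [synthetic_truth()].
#' @param cv metabolite coefficient of variation.
#' @param n_metabolites metabolite panel size.
#' @param n_genes gene universe size.
#' @param noise_sd expression noise SD.
#' @param glucose_levels glucose arms for the transcriptome.
#' @return list with class `omics_dataset`: `metab` (raw), `metab_conc`,
#'   `metab_sheet`, `expr`, `expr_sheet`, `truth`.
#' @export
simulate_dataset <- function(truth = synthetic_truth(), cv = 0.1,
                             n_metabolites = 38L, n_genes = 194L,
                             noise_sd = 1, glucose_levels = c("plus", "minus")) {
  mb <- simulate_metabolome(truth, cv = cv, n_metabolites = n_metabolites)
  tx <- simulate_transcriptome(truth, n_genes = n_genes, noise_sd = noise_sd,
                               glucose_levels = glucose_levels)
  structure(list(metab = mb$matrix, metab_conc = mb$concentrations,
                 metab_sheet = mb$sheet, expr = tx$matrix,
                 expr_sheet = tx$sheet, truth = truth),
            class = "omics_dataset")
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf("omics_dataset: %d metabolites x %d samples; %d genes x %d samples (seed %d)\n",
              nrow(x$metab), ncol(x$metab), nrow(x$expr), ncol(x$expr), x$truth$seed))
  invisible(x)
}

#' Read a simulation configuration from YAML
#'
#' Recognized keys: `seed`, `n_per_group`, `cv`, `n_metabolites`, `n_genes`,
#' `noise_sd`, `module_strength`, `module_genes`, `metab_fold_changes`
#' (mapping), `de_genes` (mapping). Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return a named list of arguments.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("seed", "n_per_group", "cv", "n_metabolites", "n_genes",
               "noise_sd", "module_strength", "module_genes",
               "metab_fold_changes", "de_genes")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg
}

#' Build a dataset from a configuration list
#' @param cfg list as returned by [read_sim_config()].
#' @return an `omics_dataset`.
#' @export
dataset_from_config <- function(cfg) {
  truth_args <- cfg[intersect(names(cfg), c("metab_fold_changes", "module_genes",
                                            "module_strength", "de_genes",
                                            "seed", "n_per_group"))]
  if (!is.null(truth_args$metab_fold_changes)) {
    truth_args$metab_fold_changes <- unlist(truth_args$metab_fold_changes)
  }
  if (!is.null(truth_args$de_genes)) truth_args$de_genes <- unlist(truth_args$de_genes)
  truth <- do.call(synthetic_truth, truth_args)
  sim_args <- cfg[intersect(names(cfg), c("cv", "n_metabolites", "n_genes", "noise_sd"))]
  do.call(simulate_dataset, c(list(truth = truth), sim_args))
}

#' Pair metabolome and transcriptome samples for integration
#'
#' Both layers are simulated (or measured) on the same biological replicates;
#' pairing matches samples within each condition x glucose group by replicate
#' order. Returns index vectors into each layer's sheet for the paired
#' samples of one condition.
#'
#' @param metab_sheet,expr_sheet the two layers' [sample_sheet()]s.
#' @param condition `"P"` or `"S"`.
#' @param glucose glucose arm to pair within, default `"plus"`.
#' @return list with integer vectors `metab_idx` and `expr_idx` (equal length).
#' @export
pair_layers <- function(metab_sheet, expr_sheet, condition, glucose = "plus") {
  mi <- which(metab_sheet$condition == condition & metab_sheet$glucose == glucose)
  ei <- which(expr_sheet$condition == condition & expr_sheet$glucose == glucose)
  k <- min(length(mi), length(ei))
  if (k < 3L) stopf("fewer than 3 paired samples for condition %s", condition)
  list(metab_idx = mi[seq_len(k)], expr_idx = ei[seq_len(k)])
}
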