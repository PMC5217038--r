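# Tabular and graph I/O: feature matrices, sample sheets, GMT gene sets,
# network exports. These define the on-disk contracts all stages consume.

FEATURE_KINDS <- c("metabolite_conc", "expression_intensity", "expression_log2")

#' Construct a validated feature matrix
#'
#' A feature matrix is a plain numeric matrix (features in rows, samples in
#' columns) carrying a `kind` attribute that records what the values are:
#' metabolite concentrations (pmol per 1e6 cells), raw expression intensities,
#' or log2 expression. Concentrations must be non-negative; missing values are
#' explicit `NA`s, never silent zeros.
#'
#' @param values numeric matrix with rownames (feature ids) and colnames
#'   (sample ids).
#' @param kind one of `"metabolite_conc"`, `"expression_intensity"`,
#'   `"expression_log2"`.
#' @return the matrix with class `feature_matrix` and a `kind` attribute.
#' @export
feature_matrix <- function(values, kind) {
  kind <- match.arg(kind, FEATURE_KINDS)
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("feature matrix values must be a numeric matrix")
  }
  if (nrow(values) == 0L || ncol(values) == 0L) stopf("feature matrix is empty")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("feature matrix needs feature ids (rownames) and sample ids (colnames)")
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) stopf("duplicate feature id(s): %s", paste(unique(dup), collapse = ", "))
  if (kind == "metabolite_conc" && any(values < 0, na.rm = TRUE)) {
    stopf("metabolite concentrations must be >= 0")
  }
  structure(values, kind = kind, class = c("feature_matrix", class(values)))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix [%s]: %d features x %d samples\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  invisible(x)
}

fm_kind <- function(x) attr(x, "kind") %||% "expression_intensity"

`%||%` <- function(a, b) if (is.null(a)) b else a

delim_for <- function(path, delimiter = NULL) {
  if (!is.null(delimiter)) return(delimiter)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a feature matrix from delimited text
#'
#' First column is the feature id, header row holds sample ids. Delimiter is
#' auto-detected from the extension (`.csv` comma, otherwise tab) unless
#' overridden. Row and column order are preserved as on disk. Missing values
#' are the token `NA`.
#'
#' @param path file path.
#' @param kind value semantics; see [feature_matrix()].
#' @param delimiter optional explicit field delimiter.
#' @return a [feature_matrix()].
#' @export
read_matrix <- function(path, kind, delimiter = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  sep <- delim_for(path, delimiter)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          na.strings = "NA", comment.char = "")
  if (nrow(df) == 0L || ncol(df) < 2L) stopf("empty matrix in %s", path)
  ids <- trimws(as.character(df[[1L]]))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stopf("duplicate feature id(s) in %s: %s", path, paste(dup, collapse = ", "))
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        stopf("non-numeric cell at row %d (feature '%s'), column '%s' in %s",
              bad[1L], ids[bad[1L]], colnames(vals)[j], path)
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  feature_matrix(m, kind)
}

#' Write a feature matrix as delimited text
#'
#' Inverse of [read_matrix()]; the pair is a lossless round trip (values to
#' full double precision, ids exact). Missing values are written as `NA`.
#'
#' @param x a [feature_matrix()] or numeric matrix with dimnames.
#' @param path output path; delimiter auto-detected from extension.
#' @param delimiter optional explicit delimiter.
#' @export
write_matrix <- function(x, path, delimiter = NULL) {
  sep <- delim_for(path, delimiter)
  df <- data.frame(feature_id = rownames(x), as.data.frame(unclass(x), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Construct a validated sample sheet
#'
#' One row per sample: condition `P` (parental) or `S` (stem-like), glucose
#' `plus`/`minus`, and the per-sample total protein mass (mg) used for
#' metabolite normalization. `group_key` is the derived `condition:glucose`
#' label.
#'
#' @param sample_id character vector of unique sample ids.
#' @param condition factor/character, levels `P` and `S`.
#' @param glucose factor/character, levels `plus` and `minus`.
#' @param protein_mg positive protein mass per sample (mg).
#' @return a `data.frame` with class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, condition, glucose = "plus", protein_mg = 1) {
  sample_id <- trimws(as.character(sample_id))
  n <- length(sample_id)
  if (anyDuplicated(sample_id)) stopf("duplicate sample ids in sample sheet")
  condition <- as.character(condition)
  glucose <- rep_len(as.character(glucose), n)
  protein_mg <- rep_len(as.numeric(protein_mg), n)
  if (!all(condition %in% c("P", "S"))) stopf("condition must be 'P' or 'S'")
  if (!all(glucose %in% c("plus", "minus"))) stopf("glucose must be 'plus' or 'minus'")
  if (any(!is.finite(protein_mg)) || any(protein_mg <= 0)) {
    bad <- sample_id[!is.finite(protein_mg) | protein_mg <= 0][1L]
    stopf("protein_mg must be a positive number (sample '%s')", bad)
  }
  out <- data.frame(sample_id = sample_id, condition = condition, glucose = glucose,
                    protein_mg = protein_mg,
                    group_key = paste(condition, glucose, sep = ":"),
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_sheet", "data.frame")
  out
}

#' Read a sample sheet from delimited text
#' @param path file path with columns sample_id, condition, glucose, protein_mg.
#' @param delimiter optional explicit delimiter.
#' @return a [sample_sheet()].
#' @export
read_sample_sheet <- function(path, delimiter = NULL) {
  sep <- delim_for(path, delimiter)
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "glucose", "protein_mg")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("sample sheet %s missing column(s): %s", path, paste(miss, collapse = ", "))
  sample_sheet(df$sample_id, df$condition, df$glucose, df$protein_mg)
}

#' Write a sample sheet
#' @param sheet a [sample_sheet()].
#' @param path output path.
#' @param delimiter optional explicit delimiter.
#' @export
write_sample_sheet <- function(sheet, path, delimiter = NULL) {
  sep <- delim_for(path, delimiter)
  utils::write.table(sheet[, c("sample_id", "condition", "glucose", "protein_mg")],
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT dialect: `name <tab> description <tab> member ids...`, one set
#' per non-empty line. Member ids are whitespace-trimmed and matched
#' case-sensitively throughout the package. Member order is preserved.
#'
#' @param path GMT file path.
#' @return a list of gene sets, each `list(name, description, members)`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) stopf("GMT line %d has fewer than 3 fields", i)
    members <- trimws(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stopf("GMT line %d ('%s') has an empty member list", i, fields[1L])
    if (anyDuplicated(members)) {
      stopf("GMT line %d ('%s') has duplicate members", i, fields[1L])
    }
    out[[length(out) + 1L]] <- gene_set(fields[1L], fields[2L], members)
  }
  out
}

#' Construct a gene set
#' @param name set name.
#' @param description free-text description.
#' @param members non-empty character vector of unique gene ids.
#' @export
gene_set <- function(name, description = "", members) {
  members <- trimws(as.character(members))
  if (!length(members)) stopf("gene set '%s' has no members", name)
  if (anyDuplicated(members)) stopf("gene set '%s' has duplicate members", name)
  structure(list(name = as.character(name), description = as.character(description),
                 members = members),
            class = "gene_set")
}

#' Write gene sets in GMT format
#' @param sets list of [gene_set()] objects.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$members), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Export a differential co-expression network
#'
#' `tsv_edgelist` writes one row per gene pair that survives the positive
#' filter in either condition, with columns `gene_a`, `gene_b`, `r_P`, `r_S`,
#' `delta` (`r_S - r_P`) and `selected` (passed the differential threshold),
#' in deterministic lexicographic pair order. `graphml` writes the same pairs
#' and attributes as an igraph GraphML document.
#'
#' @param net a `diff_network` from [build_diff_network()].
#' @param path output path.
#' @param format `"tsv_edgelist"` or `"graphml"`.
#' @export
write_network <- function(net, path, format = c("tsv_edgelist", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "diff_network"))
  df <- network_edge_table(net)
  if (format == "tsv_edgelist") {
    utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  } else {
    g <- igraph::make_empty_graph(directed = FALSE) +
      igraph::vertices(net$genes)
    if (nrow(df)) {
      g <- igraph::add_edges(g, rbind(df$gene_a, df$gene_b))
      igraph::E(g)$r_P <- df$r_P
      igraph::E(g)$r_S <- df$r_S
      igraph::E(g)$delta <- df$delta
      igraph::E(g)$selected <- df$selected
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a TSV edge list written by [write_network()]
#' @param path edge-list path.
#' @return data.frame with gene_a, gene_b, r_P, r_S, delta, selected.
#' @export
read_network_edges <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(df)) df$selected <- as.logical(df$selected)
  df
}

# Deterministic edge table: all pairs positive in either condition, sorted
# lexicographically; pair order inside a row is gene_a < gene_b.
network_edge_table <- function(net) {
  pairs <- rbind(net$edges_P, net$edges_S)
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      r_P = numeric(), r_S = numeric(), delta = numeric(),
                      selected = logical(), stringsAsFactors = FALSE))
  }
  key <- unique(paste(pairs[, 1L], pairs[, 2L], sep = "\r"))
  parts <- strsplit(key, "\r", fixed = TRUE)
  a <- vapply(parts, `[[`, character(1L), 1L)
  b <- vapply(parts, `[[`, character(1L), 2L)
  ord <- order(a, b)
  a <- a[ord]; b <- b[ord]
  rp <- net$r_P[cbind(a, b)]
  rs <- net$r_S[cbind(a, b)]
  sel_key <- if (nrow(net$selected)) paste(net$selected[, 1L], net$selected[, 2L], sep = "\r") else character()
  data.frame(gene_a = a, gene_b = b, r_P = rp, r_S = rs, delta = rs - rp,
             selected = paste(a, b, sep = "\r") %in% sel_key,
             stringsAsFactors = FALSE)
}
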