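## iocore: data model, readers/writers, configuration.
##
## ExpressionMatrix is a plain numeric matrix (genes x samples, log-scale
## intensities) validated by as_expression_matrix(); ClinicalTable is a
## data.frame with typed columns validated by as_clinical_table(). Both carry
## no extra class — downstream code only relies on the validated contract —
## which keeps them directly usable with base matrix/data.frame tooling.

#' Validate a genes-by-samples expression matrix
#'
#' Checks the expression-matrix contract: a numeric matrix with unique,
#' non-empty gene rownames and sample colnames, all values finite, and at
#' least 2 genes and 2 samples. Values are assumed to be on a log scale and
#' already normalized; no normalization is performed here. If more than 1% of
#' values exceed 30 a warning suggests the data may still be on a linear scale.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene ids) and colnames (sample ids).
#' @return The validated matrix, invisibly unchanged.
#' @export
as_expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression matrix must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicated gene ids: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicated sample ids: ", paste(dup_s, collapse = ", "))
  if (nrow(values) < 2 || ncol(values) < 2)
    stop("expression matrix needs at least 2 genes and 2 samples")
  if (!all(is.finite(values)))
    stop("expression matrix contains non-finite values; impute or drop before use")
  if (mean(values > 30) > 0.01)
    warning(">1% of expression values exceed 30; data may be linear-scale, not log-scale",
            call. = FALSE)
  invisible(values)
}

#' Read an expression matrix from delimited text
#'
#' Expects a header row and an identifier first column (GCT-like layout
#' without the GCT header). Tab is the canonical delimiter; comma is accepted
#' by sniffing the header line. No normalization is applied.
#'
#' @param path file path.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`;
#'   output is always genes x samples.
#' @param impute_missing if `TRUE`, missing cells are filled with the
#'   per-gene median; the default rejects files with missing values.
#' @return numeric matrix, genes x samples.
#' @export
read_expression <- function(path, orientation = c("genes_in_rows", "samples_in_rows"),
                            impute_missing = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  ids <- as.character(df[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated identifiers in ", path, ": ", paste(dup, collapse = ", "))
  body <- df[-1L]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & col != "" & is.na(num))
      if (length(bad))
        stop(sprintf("non-numeric cell at row %d, column '%s' in %s",
                     bad[1L], names(body)[j], path))
      body[[j]] <- num
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (orientation == "samples_in_rows") m <- t(m)
  if (anyNA(m)) {
    if (!impute_missing)
      stop("missing expression values in ", path,
           "; set impute_missing = TRUE for per-gene median imputation")
    for (i in which(rowSums(is.na(m)) > 0L))
      m[i, is.na(m[i, ])] <- stats::median(m[i, ], na.rm = TRUE)
    clear_log("iocore", "imputed missing expression cells with per-gene medians")
  }
  as_expression_matrix(m)
  m
}

#' Write an expression matrix to TSV
#'
#' Tab-delimited UTF-8, gene id first column, values at 6 significant digits.
#'
#' @param expr genes x samples numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  as_expression_matrix(expr)
  df <- data.frame(gene_id = rownames(expr),
                   signif(expr, 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("\t", header) && grepl(",", header)) "," else "\t"
}

clin_known_cols <- c("sample_id", "grade", "stage", "size", "time", "event",
                     "tumor_id", "group_label")

#' Validate a clinical annotation table
#'
#' Enforces the clinical-table contract: unique `sample_id`; `time` >= 0;
#' `event` in \{0, 1\}; `grade` in \{1, 2, 3, 4\} when present. Absent
#' optional fields stay `NA` (never coerced to zero). Unknown columns are
#' preserved untouched.
#'
#' @param df data.frame with at least a `sample_id` column.
#' @return The validated data.frame with typed known columns.
#' @export
as_clinical_table <- function(df) {
  if (!is.data.frame(df) || !"sample_id" %in% names(df))
    stop("clinical table must be a data.frame with a sample_id column")
  df$sample_id <- as.character(df$sample_id)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) stop("duplicated sample ids: ", paste(dup, collapse = ", "))
  for (col in c("grade", "stage", "size", "time", "event"))
    if (col %in% names(df)) {
      v <- suppressWarnings(as.numeric(as.character(df[[col]])))
      bad <- !is.na(df[[col]]) & df[[col]] != "" & is.na(v)
      if (any(bad))
        stop(sprintf("non-numeric %s for sample %s", col, df$sample_id[which(bad)[1L]]))
      df[[col]] <- v
    }
  if (!is.null(df$time) && any(df$time < 0, na.rm = TRUE))
    stop("negative follow-up time for sample(s): ",
         paste(df$sample_id[which(df$time < 0)], collapse = ", "))
  if (!is.null(df$event) && !all(df$event %in% c(0, 1) | is.na(df$event)))
    stop("event must be 0 (censored) or 1 (cancer-specific death)")
  if (!is.null(df$grade) && !all(df$grade %in% 1:4 | is.na(df$grade)))
    stop("grade must be an ordinal in 1..4 when present")
  for (col in c("tumor_id", "group_label"))
    if (col %in% names(df)) {
      df[[col]] <- as.character(df[[col]])
      df[[col]][df[[col]] == ""] <- NA_character_
    }
  df
}

#' Read a clinical annotation table from delimited text
#'
#' Recognized columns: `sample_id`, `grade`, `stage`, `size` (cm), `time`
#' (months), `event` (1 = cancer-specific death), `tumor_id`, `group_label`.
#' Extra columns pass through as opaque annotations. Blank cells become `NA`.
#'
#' @param path file path (TSV canonical; comma sniffed).
#' @return validated clinical data.frame.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", na.strings = c("NA", ""))
  as_clinical_table(df)
}

#' Write a clinical table to TSV
#' @param clin clinical data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clin, path) {
  clin <- as_clinical_table(clin)
  num <- vapply(clin, is.numeric, logical(1))
  clin[num] <- lapply(clin[num], signif, digits = 6)
  utils::write.table(clin, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Restrict expression and clinical data to shared samples
#'
#' Both outputs carry exactly the intersection of sample ids, in the
#' expression matrix's sample order; counts dropped from each side are logged.
#' Idempotent.
#'
#' @param expr genes x samples matrix.
#' @param clin clinical data.frame.
#' @return list with elements `expr` and `clin`.
#' @export
align_samples <- function(expr, clin) {
  clin <- as_clinical_table(clin)
  common <- intersect(colnames(expr), clin$sample_id)
  if (!length(common))
    stop("no samples shared between expression matrix and clinical table")
  keep <- colnames(expr)[colnames(expr) %in% common]
  clear_log("iocore", sprintf("align: kept %d samples (dropped %d expression-only, %d clinical-only)",
                              length(keep), ncol(expr) - length(keep),
                              nrow(clin) - length(keep)))
  list(expr = expr[, keep, drop = FALSE],
       clin = clin[match(keep, clin$sample_id), , drop = FALSE])
}

#' Scoring configuration
#'
#' Bundles every tunable of the scoring core. Defaults encode the published
#' procedure where it is stated (filter: log expression > 8 in at least 10%
#' of samples; median reference centroids) and documented conventions where
#' it is not (bootstrap draw count and subset fraction are unanchored;
#' distance is 1 - Pearson correlation so that high scores mean
#' grade-4-like).
#'
#' @param gene_filter_threshold log-expression cutoff for the gene filter.
#' @param gene_filter_fraction minimum fraction of samples above the cutoff.
#' @param subset_fraction fraction of the filtered gene set drawn per
#'   bootstrap subset (0 < f <= 1).
#' @param n_boot number of bootstrap gene subsets m.
#' @param correlation_method `"pearson"` or `"spearman"`.
#' @param distance_kind `"one_minus_corr"` (d = 1 - r; default) or
#'   `"raw_corr"` (d = r, the literal reading).
#' @param centroid_statistic `"median"` or `"mean"` reference centroid.
#' @param epsilon positive floor applied to distances before the ratio.
#' @param seed integer master seed; per-sample seeds are derived from it.
#' @return list of class `clear_config`.
#' @export
clear_config <- function(gene_filter_threshold = 8,
                         gene_filter_fraction = 0.10,
                         subset_fraction = 0.5,
                         n_boot = 100,
                         correlation_method = c("pearson", "spearman"),
                         distance_kind = c("one_minus_corr", "raw_corr"),
                         centroid_statistic = c("median", "mean"),
                         epsilon = 1e-8,
                         seed = 1L) {
  cfg <- list(gene_filter_threshold = gene_filter_threshold,
              gene_filter_fraction = gene_filter_fraction,
              subset_fraction = subset_fraction,
              n_boot = as.integer(n_boot),
              correlation_method = match.arg(correlation_method),
              distance_kind = match.arg(distance_kind),
              centroid_statistic = match.arg(centroid_statistic),
              epsilon = epsilon,
              seed = as.integer(seed))
  if (!(cfg$subset_fraction > 0 && cfg$subset_fraction <= 1))
    stop("subset_fraction must satisfy 0 < f <= 1")
  if (cfg$n_boot < 1L) stop("n_boot must be >= 1")
  if (!(cfg$epsilon > 0)) stop("epsilon must be > 0")
  if (!(cfg$gene_filter_fraction > 0 && cfg$gene_filter_fraction <= 1))
    stop("gene_filter_fraction must satisfy 0 < f <= 1")
  class(cfg) <- "clear_config"
  cfg
}

#' Read a flat TOML-style key = value configuration file
#'
#' Lines of the form `key = value`; `#` comments and blank lines ignored;
#' string values may be quoted. Keys must name [clear_config()] fields.
#'
#' @param path file path.
#' @param base config the file overrides (default [clear_config()] defaults).
#' @return `clear_config` list.
#' @export
read_config <- function(path, base = clear_config()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vals <- as.list(base)
  class(vals) <- NULL
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stop("malformed config line: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- gsub('^"|"$', "", val)
    if (!key %in% names(vals)) stop("unknown config key: ", key)
    vals[[key]] <- if (is.numeric(vals[[key]])) as.numeric(val) else val
  }
  do.call(clear_config, vals)
}
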