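#' Expression matrix container
#'
#' A genes-by-samples numeric matrix carrying a declared measurement scale.
#' `scale = "rsem"` holds non-negative RSEM estimated abundances, `"tpm"`
#' holds transcripts-per-million (every column sums to 1e6), `"log2"` holds
#' log2-transformed values and `"zscore"` holds per-gene cohort z-scores
#' (the cBioPortal export dialect).
#'
#' @param values Numeric matrix, genes in rows (rownames are gene symbols),
#'   samples in columns (colnames are sample identifiers).
#' @param scale One of `"rsem"`, `"tpm"`, `"log2"`, `"zscore"`.
#' @return An `expr_matrix` object.
#' @export
expr_matrix <- function(values, scale = c("rsem", "tpm", "log2", "zscore")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    abort("Expression matrix is empty.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("Expression matrix needs gene symbols as rownames and sample ids as colnames.")
  }
  if (anyDuplicated(colnames(values))) {
    abort("Sample ids must be unique.")
  }
  if (anyDuplicated(rownames(values))) {
    abort("Gene symbols must be unique; collapse duplicates first (see `read_expression_matrix()`).")
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "Non-finite value at gene '%s', sample '%s'.",
      rownames(values)[bad[1L]], colnames(values)[bad[2L]]
    ))
  }
  if (scale %in% c("rsem", "tpm") && any(values < 0)) {
    abort(sprintf("Scale '%s' requires non-negative values.", scale))
  }
  if (scale == "tpm") {
    cs <- colSums(values)
    if (any(abs(cs - 1e6) > 1e-6 * 1e6)) {
      abort("TPM columns must each sum to 1e6 (relative tolerance 1e-6).")
    }
  }
  structure(values, scale = scale, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d genes x %d samples, scale = %s\n",
    nrow(x), ncol(x), attr(x, "scale")
  ))
  invisible(x)
}

#' @rdname expr_matrix
#' @param x An `expr_matrix`.
#' @export
expr_scale <- function(x) attr(x, "scale")

#' Read a tab-delimited gene-by-sample expression table
#'
#' Parses the cBioPortal `data_mrna` dialect: first column `Hugo_Symbol`
#' (or any symbol column), an optional `Entrez_Gene_Id` column that is
#' ignored, and one column per sample. Duplicate gene symbols are collapsed
#' by keeping the row with maximal variance across samples; the dropped
#' rows are recorded in the collapse report (see [collapse_report()]).
#'
#' @param path Path to the tab-delimited file.
#' @param scale Declared scale of the values (see [expr_matrix()]).
#' @return An `expr_matrix`; the collapse report is attached as an
#'   attribute and retrievable with [collapse_report()].
#' @export
read_expression_matrix <- function(path, scale = c("rsem", "tpm", "log2", "zscore")) {
  scale <- match.arg(scale)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    abort(sprintf("'%s' does not contain an expression matrix.", path))
  }
  df <- df[, !(names(df) %in% "Entrez_Gene_Id"), drop = FALSE]
  genes <- df[[1L]]
  value_cols <- names(df)[-1L]
  mat <- matrix(NA_real_, nrow = nrow(df), ncol = length(value_cols),
                dimnames = list(NULL, value_cols))
  for (j in seq_along(value_cols)) {
    raw <- df[[value_cols[j]]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw) | is.na(raw))
    if (length(bad)) {
      abort(sprintf(
        "Non-numeric cell at gene '%s', sample column '%s' (value '%s').",
        genes[bad[1L]], value_cols[j], as.character(raw[bad[1L]])
      ))
    }
    mat[, j] <- num
  }
  rownames(mat) <- genes
  collapsed <- collapse_duplicate_genes(mat)
  out <- expr_matrix(collapsed$values, scale = scale)
  attr(out, "collapse_report") <- collapsed$report
  out
}

# Keep, for each duplicated symbol, the row with maximal variance across
# samples (ties broken by first occurrence); report what was dropped.
collapse_duplicate_genes <- function(mat) {
  genes <- rownames(mat)
  dup_symbols <- unique(genes[duplicated(genes)])
  if (length(dup_symbols) == 0L) {
    return(list(
      values = mat,
      report = tibble(gene = character(), n_rows = integer(), kept_row = integer())
    ))
  }
  keep <- rep(TRUE, nrow(mat))
  report <- vector("list", length(dup_symbols))
  for (i in seq_along(dup_symbols)) {
    g <- dup_symbols[i]
    rows <- which(genes == g)
    vars <- apply(mat[rows, , drop = FALSE], 1L, var)
    kept <- rows[which.max(vars)]
    keep[setdiff(rows, kept)] <- FALSE
    report[[i]] <- tibble(gene = g, n_rows = length(rows), kept_row = kept)
  }
  list(values = mat[keep, , drop = FALSE], report = bind_rows(report))
}

#' @rdname read_expression_matrix
#' @param x An `expr_matrix` returned by [read_expression_matrix()].
#' @export
collapse_report <- function(x) {
  attr(x, "collapse_report") %||%
    tibble(gene = character(), n_rows = integer(), kept_row = integer())
}

#' Write an expression matrix as tab-delimited text
#'
#' Inverse of [read_expression_matrix()]: full `%.17g` precision so a
#' write/read round trip reproduces values bit-identically.
#'
#' @param x An `expr_matrix`.
#' @param path Output path.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(Hugo_Symbol = rownames(x),
                   format(unclass(x), digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  colnames(df) <- c("Hugo_Symbol", colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Broad-dialect GMT: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Symbols are deduplicated
#' within each set.
#'
#' @param path Path to the `.gmt` file.
#' @return A named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort(sprintf("GMT file '%s' is empty.", path))
  }
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      abort(sprintf("GMT line %d has %d field(s); need name, description and >=1 gene.",
                    i, length(fields)))
    }
    nm[i] <- fields[1L]
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      abort(sprintf("GMT line %d ('%s') lists no genes.", i, nm[i]))
    }
    sets[[i]] <- genes
  }
  setNames(sets, nm)
}

#' Write a gene-set collection as GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(
    names(sets),
    function(nm) paste(c(nm, nm, sets[[nm]]), collapse = "\t"),
    character(1)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Canonical immune cell-type names
#'
#' Mapping from CIBERSORT-style column headers to the canonical names used
#' throughout the package, shipped as data under `inst/extdata/`.
#'
#' @return A tibble with columns `raw` and `canonical`.
#' @export
cell_type_canonical_map <- function() {
  path <- system.file("extdata", "cell_type_canonical.tsv", package = "immunophen")
  readr::read_tsv(path, col_types = "cc", progress = FALSE)
}

#' Read a per-sample immune-cell fraction table
#'
#' Tab-delimited, first column the sample id, remaining columns the 22
#' CIBERSORT cell-type relative fractions. Column names are canonicalized
#' via [cell_type_canonical_map()]; fractions must lie in `[0, 1]` and each
#' row must sum to 1 within tolerance `1e-3`.
#'
#' @param path Path to the table.
#' @param check_row_sums Validate rows sum to 1 (relative-fraction mode).
#' @return A tibble with `sample_id` and one canonical column per cell type.
#' @export
read_immune_fractions <- function(path, check_row_sums = TRUE) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  names(df)[1L] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  map <- cell_type_canonical_map()
  idx <- match(names(df), map$raw)
  names(df)[!is.na(idx)] <- map$canonical[idx[!is.na(idx)]]
  frac <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(frac)) abort("Fraction columns must be numeric.")
  if (any(frac < -1e-9 | frac > 1 + 1e-9, na.rm = TRUE)) {
    abort("Immune-cell fractions must lie in [0, 1].")
  }
  if (check_row_sums) {
    rs <- rowSums(frac)
    if (any(abs(rs - 1) > 1e-3)) {
      abort("Each sample's cell-type fractions must sum to 1 (tolerance 1e-3).")
    }
  }
  if (!"T_cells_CD8" %in% names(df)) {
    abort("No CD8 T-cell column found (expected canonical name 'T_cells_CD8').")
  }
  as_tibble(df)
}

#' Read a per-sample clinical table
#'
#' Tab-delimited with header. Receptor statuses are normalized to the
#' closed set `negative`/`positive`/`unknown`; blank or unrecognized
#' entries become `"unknown"` rather than `NA` so they survive into the
#' contingency tables that list them explicitly.
#'
#' @param path Path to the table.
#' @return A tibble keyed by `sample_id`.
#' @export
read_clinical <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  names(df)[1L] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  for (col in intersect(c("er_status", "pgr_status", "her2_status"), names(df))) {
    df[[col]] <- normalize_status(df[[col]])
  }
  time_cols <- grep("_months$", names(df), value = TRUE)
  for (col in time_cols) {
    if (any(df[[col]] < 0, na.rm = TRUE)) {
      abort(sprintf("Negative follow-up time in column '%s'.", col))
    }
  }
  event_cols <- grep("_event$", names(df), value = TRUE)
  for (col in event_cols) {
    if (!all(df[[col]] %in% c(0, 1, NA))) {
      abort(sprintf("Event flags in '%s' must be 0/1.", col))
    }
  }
  as_tibble(df)
}

normalize_status <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("negative", "neg", "-", "0")] <- "negative"
  out[x %in% c("positive", "pos", "+", "1")] <- "positive"
  out
}

#' Read a per-sample numeric feature table
#'
#' Tab-delimited with header; first column the sample id, remaining columns
#' numeric features (TMB, mutation rates, neoantigen counts, checkpoint
#' gene expression...). Missing values stay `NA`; they are never dropped
#' at parse time.
#'
#' @param path Path to the table.
#' @return A tibble keyed by `sample_id`.
#' @export
read_sample_features <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  names(df)[1L] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  num <- df[, -1L, drop = FALSE]
  if (!all(vapply(num, is.numeric, logical(1)))) {
    abort("All feature columns must be numeric.")
  }
  as_tibble(df)
}

#' Align cohort tables on their common samples
#'
#' Restricts the expression matrix and any per-sample tables to the
#' intersection of their sample ids and puts every table in the same
#' sample order. The number of samples dropped from each source is
#' recorded in the `drop_log` attribute.
#'
#' @param expr An `expr_matrix`.
#' @param fractions,clinical,features Optional per-sample tibbles keyed by
#'   `sample_id`.
#' @return A list of class `cohort` with elements `expr`, `fractions`,
#'   `clinical`, `features`, `sample_ids`, and attribute `drop_log`.
#' @export
align_cohort <- function(expr, fractions = NULL, clinical = NULL, features = NULL) {
  ids <- colnames(expr)
  tables <- list(fractions = fractions, clinical = clinical, features = features)
  for (tab in tables) {
    if (!is.null(tab)) ids <- intersect(ids, tab$sample_id)
  }
  if (length(ids) == 0L) {
    abort("No samples shared by all supplied tables.")
  }
  drop_log <- c(expr = ncol(expr) - length(ids))
  out <- list(expr = expr[, ids, drop = FALSE], sample_ids = ids)
  class(out$expr) <- class(expr)
  attr(out$expr, "scale") <- expr_scale(expr)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    if (is.null(tab)) {
      out[[nm]] <- NULL
      next
    }
    drop_log[nm] <- nrow(tab) - length(ids)
    out[[nm]] <- tab[match(ids, tab$sample_id), , drop = FALSE]
  }
  structure(out, drop_log = drop_log, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d samples; tables: %s\n",
              length(x$sample_ids),
              paste(setdiff(names(x), "sample_ids"), collapse = ", ")))
  invisible(x)
}
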