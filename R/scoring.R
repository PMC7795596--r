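#' Convert RSEM estimated abundances to TPM
#'
#' Each sample's abundances are renormalized to proportions and multiplied
#' by 1e6, so every column of the result sums to 1e6. The conversion is
#' therefore invariant to any positive per-sample rescaling of the input;
#' columns that already sum to 1 pass through unchanged up to the factor
#' of 1e6.
#'
#' @param expr An `expr_matrix` with scale `"rsem"`.
#' @return An `expr_matrix` with scale `"tpm"`.
#' @export
rsem_to_tpm <- function(expr) {
  if (expr_scale(expr) != "rsem") {
    abort("`rsem_to_tpm()` expects an expression matrix on the 'rsem' scale.")
  }
  cs <- colSums(expr)
  if (any(cs <= 0)) {
    abort(sprintf("Sample '%s' has all-zero expression; cannot normalize to TPM.",
                  colnames(expr)[which(cs <= 0)[1L]]))
  }
  vals <- sweep(unclass(expr), 2L, cs, "/") * 1e6
  expr_matrix(vals, scale = "tpm")
}

#' Immune cytolytic activity (CYT) score
#'
#' CYT is the per-sample geometric mean of GZMA and PRF1 expression in
#' TPM. A small pseudocount (default 0.01 TPM) is added to both genes
#' before the geometric mean so samples with a zero count remain defined;
#' the mean is computed in log space for numerical safety.
#'
#' @param expr An `expr_matrix` with scale `"tpm"` containing GZMA and
#'   PRF1 rows.
#' @param pseudocount Non-negative TPM offset added to both genes.
#' @param genes Length-2 character vector of the effector genes.
#' @return A tibble with columns `sample_id` and `cyt`; the pseudocount
#'   and source scale are attached as attributes.
#' @export
cyt_score <- function(expr, pseudocount = 0.01, genes = c("GZMA", "PRF1")) {
  if (expr_scale(expr) != "tpm") {
    abort("`cyt_score()` expects TPM expression; see `rsem_to_tpm()` or `rank_based_cyt()`.")
  }
  if (pseudocount < 0) abort("`pseudocount` must be >= 0.")
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) {
    abort(sprintf("Gene row(s) missing from the expression matrix: %s.",
                  paste(missing, collapse = ", ")))
  }
  lg <- log(unclass(expr)[genes, , drop = FALSE] + pseudocount)
  cyt <- exp(colMeans(lg))
  out <- tibble(sample_id = colnames(expr), cyt = unname(cyt))
  attr(out, "pseudocount") <- pseudocount
  attr(out, "source_scale") <- "tpm"
  out
}

#' Rank-based CYT surrogate for non-TPM cohorts
#'
#' The geometric mean is undefined for microarray z-scores, which take
#' negative values. For cohorts distributed only on a log or z-score
#' scale, this surrogate scores each sample by the mean of the two
#' effector genes' within-cohort fractional ranks (mid-ranks for ties),
#' giving values in (0, 1]. The score is invariant to any strictly
#' increasing per-gene transform, so it depends only on each gene's
#' within-cohort ordering.
#'
#' @param expr An `expr_matrix` with scale `"zscore"` or `"log2"`.
#' @inheritParams cyt_score
#' @return A tibble with columns `sample_id` and `cyt` in (0, 1].
#' @export
rank_based_cyt <- function(expr, genes = c("GZMA", "PRF1")) {
  if (!expr_scale(expr) %in% c("zscore", "log2")) {
    abort("`rank_based_cyt()` expects a 'zscore' or 'log2' expression matrix.")
  }
  if (ncol(expr) < 2L) abort("Rank-based CYT needs at least 2 samples.")
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) {
    abort(sprintf("Gene row(s) missing from the expression matrix: %s.",
                  paste(missing, collapse = ", ")))
  }
  n <- ncol(expr)
  fr <- vapply(genes, function(g) rank(unclass(expr)[g, ]) / n, numeric(n))
  out <- tibble(sample_id = colnames(expr), cyt = unname(rowMeans(fr)))
  attr(out, "source_scale") <- "rank_based"
  out
}

#' Score a cohort's CYT on whichever scale it is distributed
#'
#' Dispatches on the expression scale: RSEM is converted to TPM and the
#' geometric-mean CYT computed; TPM is scored directly; log2 and z-score
#' cohorts use the rank-based surrogate.
#'
#' @inheritParams cyt_score
#' @return A tibble with `sample_id` and `cyt`.
#' @export
score_cyt_auto <- function(expr, pseudocount = 0.01, genes = c("GZMA", "PRF1")) {
  switch(expr_scale(expr),
    rsem = cyt_score(rsem_to_tpm(expr), pseudocount = pseudocount, genes = genes),
    tpm = cyt_score(expr, pseudocount = pseudocount, genes = genes),
    rank_based_cyt(expr, genes = genes)
  )
}
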