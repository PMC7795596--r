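#' Two-group differential expression
#'
#' Per-gene log2 fold change (mean difference on a log-like scale) and
#' Welch's t statistic with its two-sided p-value, for one pairwise
#' phenotype comparison. TPM/RSEM input is moved to `log2(x + 1)` first;
#' z-score and log2 input is used as is. BH-adjusted p-values are
#' computed across all genes tested. Genes with zero variance in both
#' groups have no defined t statistic: they are flagged (`flagged =
#' TRUE`) and excluded from downstream ranking; when their group means
#' are also equal the p-value is 1 by convention.
#'
#' @param expr An `expr_matrix`.
#' @param labels Phenotype label per sample (character or factor, aligned
#'   with `colnames(expr)`), or a `phenotype_assignment` whose
#'   `sample_id`s match.
#' @param pair Length-2 character vector `c(groupA, groupB)`; fold
#'   changes are A minus B.
#' @return A `dge_result` tibble: `gene`, `log2_fc`, `t_score`,
#'   `p_value`, `adj_p`, `flagged`.
#' @export
differential_expression <- function(expr, labels, pair) {
  if (inherits(labels, "phenotype_assignment") ||
      (is.data.frame(labels) && all(c("sample_id", "label") %in% names(labels)))) {
    labels <- as.character(labels$label)[match(colnames(expr), labels$sample_id)]
  }
  labels <- as.character(labels)
  if (length(labels) != ncol(expr)) {
    abort("`labels` must align with the expression matrix samples.")
  }
  if (length(pair) != 2L || anyNA(match(pair, labels))) {
    abort("`pair` must name two groups present in `labels`.")
  }
  vals <- unclass(expr)
  if (expr_scale(expr) %in% c("tpm", "rsem")) vals <- log2(vals + 1)
  a <- vals[, labels == pair[1L], drop = FALSE]
  b <- vals[, labels == pair[2L], drop = FALSE]
  n1 <- ncol(a)
  n2 <- ncol(b)
  if (n1 < 3L || n2 < 3L) abort("Each group needs at least 3 samples.")
  m1 <- rowMeans(a)
  m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  fc <- m1 - m2
  t_score <- fc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t_score), df)
  degenerate <- se2 == 0
  t_score[degenerate] <- NA_real_
  p[degenerate] <- ifelse(fc[degenerate] == 0, 1, NA_real_)
  out <- tibble(
    gene = rownames(expr),
    log2_fc = unname(fc),
    t_score = unname(t_score),
    p_value = unname(p),
    flagged = unname(degenerate)
  )
  out$adj_p <- bh_adjust(out$p_value)
  out <- out[, c("gene", "log2_fc", "t_score", "p_value", "adj_p", "flagged")]
  attr(out, "pair") <- pair
  attr(out, "test") <- "welch"
  class(out) <- c("dge_result", class(out))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (a thin wrapper over
#' [stats::p.adjust()] that preserves `NA`s).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, each `>=` its input.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Volcano categorization
#'
#' Classifies each gene as `up` (log2FC > log2(fc_threshold) and
#' p < p_threshold), `down` (log2FC < -log2(fc_threshold) and
#' p < p_threshold), else `ns`. Raw p-values are used by default;
#' `use_adjusted` switches to the BH column.
#'
#' @param results A `dge_result` tibble.
#' @param fc_threshold Fold-change threshold on the natural scale
#'   (default 1.5, i.e. |log2FC| > log2(1.5)).
#' @param p_threshold Significance threshold (default 0.05).
#' @param use_adjusted Classify on `adj_p` instead of `p_value`.
#' @return The input with a `volcano_class` factor column added.
#' @export
volcano_classify <- function(results, fc_threshold = 1.5, p_threshold = 0.05,
                             use_adjusted = FALSE) {
  stopifnot(fc_threshold > 1, p_threshold > 0)
  p <- if (use_adjusted) results$adj_p else results$p_value
  lfc <- log2(fc_threshold)
  cls <- ifelse(is.na(p), "ns",
         ifelse(results$log2_fc > lfc & p < p_threshold, "up",
         ifelse(results$log2_fc < -lfc & p < p_threshold, "down", "ns")))
  results$volcano_class <- factor(cls, levels = c("up", "down", "ns"))
  results
}

#' Rank genes for pre-ranked GSEA
#'
#' Orders genes by t-score, descending; flagged (degenerate-variance)
#' genes are excluded; ties are broken alphabetically by symbol and
#' recorded in the `ties` attribute.
#'
#' @param results A `dge_result` tibble.
#' @return A `ranked_list` tibble with columns `gene` and `score`.
#' @export
rank_genes <- function(results) {
  keep <- results[!results$flagged & !is.na(results$t_score), , drop = FALSE]
  if (nrow(keep) == 0L) abort("No rankable genes (all flagged).")
  ord <- order(-keep$t_score, keep$gene)
  out <- tibble(gene = keep$gene[ord], score = keep$t_score[ord])
  tied <- unique(out$score[duplicated(out$score)])
  attr(out, "ties") <- out$gene[out$score %in% tied]
  class(out) <- c("ranked_list", class(out))
  out
}

#' Write a .rnk file (gene TAB score)
#'
#' @param ranked A `ranked_list` tibble.
#' @param path Output path.
#' @export
write_rnk <- function(ranked, path) {
  utils::write.table(ranked[, c("gene", "score")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a .rnk file
#'
#' @param path Path to a two-column gene/score file.
#' @return A `ranked_list` tibble sorted by score, descending.
#' @export
read_rnk <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("gene", "score"),
                          stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene)) abort("Duplicate genes in .rnk file.")
  ord <- order(-df$score, df$gene)
  out <- tibble(gene = df$gene[ord], score = df$score[ord])
  class(out) <- c("ranked_list", class(out))
  out
}
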