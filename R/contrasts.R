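#' Two-sided Mann-Whitney U test
#'
#' Wraps the rank-sum machinery in [stats::wilcox.test()]: the exact null
#' distribution is enumerated when `n1 * n2 <= 400` and the data are
#' tie-free; otherwise the tie-corrected normal approximation (with
#' continuity correction) is used. The reported statistic is U for the
#' first group, so `U1 + U2 = n1 * n2`.
#'
#' @param x,y Numeric vectors for the two groups; `NA`s are dropped.
#' @param exact Force the exact (`TRUE`) or normal-approximation
#'   (`FALSE`) path; `NULL` (default) picks automatically. The exact
#'   path requires tie-free data.
#' @return A list with `statistic` (U for `x`), `p_value`, `n1`, `n2`,
#'   and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0L || n2 == 0L) abort("Both groups must be non-empty.")
  ties <- anyDuplicated(c(x, y)) > 0L
  if (is.null(exact)) exact <- !ties && n1 * n2 <= 400
  if (exact && ties) abort("Exact Mann-Whitney p requires tie-free data.")
  u <- sum(rank(c(x, y))[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (u == n1 * n2 / 2 && identical(sort(x), sort(y)) && n1 == n2) {
    # identical multisets: the two-sided p is 1 by symmetry
    return(list(statistic = u, p_value = 1, n1 = n1, n2 = n2,
                method = if (exact) "exact" else "normal"))
  }
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact, correct = TRUE)
  )
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # degenerate tie structure: no evidence either way
  list(statistic = u, p_value = min(p, 1), n1 = n1, n2 = n2,
       method = if (exact) "exact" else "normal")
}

#' Significance star annotation
#'
#' Maps p-values to the conventional star labels with strict thresholds:
#' `****` for p < 1e-4, `***` for p < 1e-3, `**` for p < 0.01, `*` for
#' p < 0.05, `NS` otherwise. Boundary values (e.g. p = 0.05) are not
#' starred.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of annotations.
#' @export
star_annotation <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- rep("NS", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 1e-3] <- "***"
  out[p < 1e-4] <- "****"
  out[is.na(p)] <- NA_character_
  out
}

#' Spearman rank correlation
#'
#' Mid-rank Pearson correlation on ranks, over pairwise-complete
#' observations. A constant vector has no rank ordering, so the
#' correlation is undefined and returned as `NA` with a warning.
#'
#' @param x,y Numeric vectors of equal length, n >= 3 after removing
#'   incomplete pairs.
#' @return Spearman's rho in `[-1, 1]`, or `NA` if undefined.
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) abort("Spearman correlation needs at least 3 complete pairs.")
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    warn("Constant vector: Spearman correlation undefined.")
    return(NA_real_)
  }
  unname(cor(x, y, method = "spearman"))
}

#' Chi-square / Fisher contingency test
#'
#' Pearson chi-square by default; Fisher's exact test when the table is
#' 2x2 and any expected cell count falls below 5. Rows or columns named
#' `"unknown"`/`"Unknown"` are excluded first when `exclude_unknown` is
#' set, matching how clinical tables list an Unknown stratum that the
#' test itself ignores.
#'
#' @param tab Integer matrix (or table) of non-negative counts.
#' @param exclude_unknown Drop dimnames matching "unknown" before testing.
#' @return A list with `statistic` (chi-square; `NA` for Fisher),
#'   `p_value`, `method`, and the tested table.
#' @export
contingency_test <- function(tab, exclude_unknown = TRUE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("Contingency table must hold non-negative integer counts.")
  }
  if (exclude_unknown) {
    if (!is.null(rownames(tab))) {
      tab <- tab[!tolower(rownames(tab)) %in% "unknown", , drop = FALSE]
    }
    if (!is.null(colnames(tab))) {
      tab <- tab[, !tolower(colnames(tab)) %in% "unknown", drop = FALSE]
    }
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    abort("Need at least a 2x2 table after exclusions.")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("Degenerate table: a row or column margin is zero.")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use_fisher <- any(expected < 5) && all(dim(tab) == 2L)
  if (use_fisher) {
    ft <- fisher.test(tab)
    list(statistic = NA_real_, p_value = ft$p.value, method = "fisher",
         table = tab)
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(statistic = unname(ct$statistic), p_value = ct$p.value,
         method = "chisq", table = tab)
  }
}

#' Phenotype-wise contrast panel
#'
#' Runs a two-sided Mann-Whitney test for every numeric feature and every
#' pairwise combination of phenotype labels (HTI-CTI, HTI-NI, CTI-NI),
#' annotating each p-value with significance stars. Per-panel results are
#' reported without multiplicity correction, mirroring how per-feature
#' star panels are conventionally displayed; set `adjust = "BH"` to add a
#' Benjamini-Hochberg column.
#'
#' @param features A data frame keyed by `sample_id` whose remaining
#'   numeric columns are the features (an immune-fraction table or a
#'   sample-feature table).
#' @param assignment A `phenotype_assignment` (or a data frame with
#'   `sample_id` and `label`).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A tibble with one row per (feature, pair): `feature`,
#'   `group1`, `group2`, `statistic`, `p_value`, `n1`, `n2`, `method`,
#'   `annotation` (and `adj_p` if requested). Features skipped for lack
#'   of data are recorded in the `skip_log` attribute.
#' @export
contrast_panel <- function(features, assignment, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  features <- as_tibble(features)
  lab <- tibble(sample_id = assignment$sample_id,
                label = as.character(assignment$label))
  joined <- dplyr::inner_join(features, lab, by = "sample_id")
  if (length(unique(joined$label)) < 2L) {
    abort("Need at least 2 non-empty phenotype groups.")
  }
  feat_cols <- setdiff(names(features), "sample_id")
  feat_cols <- feat_cols[vapply(features[feat_cols], is.numeric, logical(1))]
  pairs <- utils::combn(PHENOTYPE_LEVELS[PHENOTYPE_LEVELS %in% joined$label], 2L,
                        simplify = FALSE)
  rows <- list()
  skip_log <- character()
  for (f in feat_cols) {
    for (pr in pairs) {
      v1 <- joined[[f]][joined$label == pr[1L]]
      v2 <- joined[[f]][joined$label == pr[2L]]
      v1 <- v1[!is.na(v1)]
      v2 <- v2[!is.na(v2)]
      if (length(v1) == 0L || length(v2) == 0L) {
        skip_log <- c(skip_log, sprintf("%s [%s vs %s]: empty group", f, pr[1L], pr[2L]))
        next
      }
      mw <- mann_whitney(v1, v2)
      rows[[length(rows) + 1L]] <- tibble(
        feature = f, group1 = pr[1L], group2 = pr[2L],
        statistic = mw$statistic, p_value = mw$p_value,
        n1 = mw$n1, n2 = mw$n2, method = mw$method
      )
    }
  }
  if (length(rows) == 0L) {
    out <- tibble(feature = character(), group1 = character(),
                  group2 = character(), statistic = numeric(),
                  p_value = numeric(), n1 = integer(), n2 = integer(),
                  method = character())
  } else {
    out <- bind_rows(rows)
  }
  out$annotation <- star_annotation(out$p_value)
  if (adjust == "BH") out$adj_p <- p.adjust(out$p_value, method = "BH")
  attr(out, "skip_log") <- skip_log
  class(out) <- c("contrast_panel", class(out))
  out
}

#' @rdname contrast_panel
#' @param x A `contrast_panel`.
#' @export
skip_log <- function(x) attr(x, "skip_log") %||% character()
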