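#' Weighted running-sum enrichment score
#'
#' The classic pre-ranked GSEA statistic: walking down the ranked list,
#' the running sum increases by `|score|^weight_exponent` (normalized by
#' the set's total weight) at each set member ("hit") and decreases by
#' `1 / (N - Nh)` at each non-member. The enrichment score is the signed
#' maximum deviation of this walk from zero, and the leading edge is the
#' set members appearing up to (positive ES) or after (negative ES) the
#' extremum.
#'
#' @param ranked A `ranked_list` tibble (`gene`, `score`, scores
#'   non-increasing) as produced by [rank_genes()] or [read_rnk()].
#' @param gene_set Character vector of gene symbols.
#' @param weight_exponent Exponent on |score| for hit increments;
#'   0 gives the unweighted Kolmogorov-Smirnov walk, 1 (default) the
#'   standard weighted statistic.
#' @return A list with `es`, `running_sum` (length N), `leading_edge`,
#'   `n_hits`, and `hit_index`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  check_ranked(ranked)
  hits <- ranked$gene %in% gene_set
  n <- nrow(ranked)
  nh <- sum(hits)
  if (nh == 0L) abort("Gene set has no members in the ranked list.")
  if (nh == n) abort("Gene set covers the whole ranked list.")
  w <- abs(ranked$score)^weight_exponent
  w[!hits] <- 0
  walk <- es_walk(w, hits, n - nh)
  running <- walk$running
  es <- walk$es
  i_max <- which.max(running)
  i_min <- which.min(running)
  hit_index <- which(hits)
  leading_edge <- if (es >= 0) {
    ranked$gene[hit_index[hit_index <= i_max]]
  } else {
    ranked$gene[hit_index[hit_index >= i_min]]
  }
  list(es = es, running_sum = running, leading_edge = leading_edge,
       n_hits = nh, hit_index = hit_index)
}

check_ranked <- function(ranked) {
  if (!all(c("gene", "score") %in% names(ranked))) {
    abort("A ranked list needs `gene` and `score` columns.")
  }
  if (anyDuplicated(ranked$gene)) abort("Ranked list has duplicate genes.")
  if (is.unsorted(rev(ranked$score))) abort("Ranked list scores must be non-increasing.")
  invisible(TRUE)
}

# Full running-sum walk shared by the observed statistic and the
# permutation null, so ties at the extremum break identically everywhere.
es_walk <- function(w, hits, n_miss) {
  total <- sum(w[hits])
  if (total == 0) {
    w[hits] <- 1
    total <- sum(hits)
  }
  step <- w / total
  step[!hits] <- -1 / n_miss
  running <- cumsum(step)
  hi <- max(running)
  lo <- min(running)
  # exact ties between the positive and negative extremum are possible
  # (both can be rational in the miss counts); they resolve positive
  list(es = if (hi >= -lo - 1e-12) hi else lo, running = running)
}

#' Permutation null for a gene-set size
#'
#' Draws `n_perm` uniformly random same-size gene sets from the ranked
#' list and returns their enrichment scores. Reproducible under a fixed
#' seed; genes outside a drawn set never influence its ES.
#'
#' @inheritParams enrichment_score
#' @param set_size Size of the random sets.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the draw.
#' @return Numeric vector of `n_perm` null enrichment scores.
#' @export
permutation_null <- function(ranked, set_size, n_perm = 1000, seed = 1,
                             weight_exponent = 1) {
  check_ranked(ranked)
  n <- nrow(ranked)
  if (set_size >= n) abort("`set_size` must be smaller than the ranked list.")
  if (set_size < 1L) abort("`set_size` must be at least 1.")
  if (n_perm < 100) abort("`n_perm` must be at least 100.")
  w_all <- abs(ranked$score)^weight_exponent
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  hits <- logical(n)
  vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, set_size)
    hits[] <- FALSE
    hits[idx] <- TRUE
    w <- w_all
    w[!hits] <- 0
    es_walk(w, hits, n - set_size)$es
  }, numeric(1))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Normalize enrichment scores and attach permutation FDR q-values
#'
#' For each set, NES = ES divided by the mean |null ES| of the same sign,
#' and the nominal p is the same-sign tail fraction of the null. The FDR
#' q follows the standard sign-stratified construction: all null ES are
#' normalized by their set's same-sign null mean, pooled, and for each
#' observed NES the ratio of null to observed tail fractions on that side
#' is taken, clipped to `[0, 1]`, and made monotone in |NES|.
#'
#' @param observed A tibble with columns `set` and `es`.
#' @param nulls A list (one element per row of `observed`) of null ES
#'   vectors from [permutation_null()].
#' @return `observed` with `nes`, `p_nominal`, `fdr_q` and `flagged`
#'   columns added.
#' @export
normalize_and_fdr <- function(observed, nulls) {
  stopifnot(nrow(observed) == length(nulls))
  n_sets <- nrow(observed)
  nes <- numeric(n_sets)
  p_nom <- numeric(n_sets)
  flagged <- logical(n_sets)
  null_nes_all <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    es <- observed$es[i]
    null <- nulls[[i]]
    pos_mean <- mean(null[null > 0])
    neg_mean <- mean(abs(null[null < 0]))
    null_nes <- ifelse(null > 0,
                       null / pos_mean,
                       ifelse(null < 0, null / neg_mean, 0))
    null_nes_all[[i]] <- null_nes[is.finite(null_nes)]
    if (es == 0) {
      nes[i] <- 0
      p_nom[i] <- 1
      next
    }
    same <- if (es > 0) null[null > 0] else null[null < 0]
    if (length(same) == 0L) {
      nes[i] <- sign(es) * abs(es) / mean(abs(null))
      p_nom[i] <- 1 / (length(null) + 1)
      flagged[i] <- TRUE
      next
    }
    denom <- mean(abs(same))
    nes[i] <- es / denom
    p_nom[i] <- if (es > 0) mean(same >= es) else mean(same <= es)
    p_nom[i] <- max(p_nom[i], 1 / (length(null) + 1))
  }
  pooled_null <- unlist(null_nes_all)
  fdr_q <- fdr_from_nes(nes, pooled_null)
  observed$nes <- nes
  observed$p_nominal <- p_nom
  observed$fdr_q <- fdr_q
  observed$flagged <- flagged
  observed
}

# Sign-stratified GSEA FDR: tail fraction of pooled null NES over tail
# fraction of observed NES, per side, clipped and monotone in |NES|.
fdr_from_nes <- function(nes, pooled_null) {
  q <- rep(NA_real_, length(nes))
  null_pos <- pooled_null[pooled_null >= 0]
  null_neg <- pooled_null[pooled_null <= 0]
  obs_pos <- nes[nes >= 0]
  obs_neg <- nes[nes <= 0]
  for (i in seq_along(nes)) {
    v <- nes[i]
    if (v >= 0) {
      null_frac <- if (length(null_pos)) mean(null_pos >= v) else 0
      obs_frac <- mean(obs_pos >= v)
    } else {
      null_frac <- if (length(null_neg)) mean(null_neg <= v) else 0
      obs_frac <- mean(obs_neg <= v)
    }
    q[i] <- min(1, max(0, null_frac / obs_frac))
  }
  # monotone enforcement: a more extreme |NES| never has a larger q
  for (sgn in c(1, -1)) {
    idx <- which(if (sgn > 0) nes >= 0 else nes < 0)
    if (length(idx) < 2L) next
    ord <- idx[order(-abs(nes[idx]))]
    q[ord] <- rev(cummin(rev(q[ord])))  # suffix minima: non-decreasing in rank
  }
  q
}

#' Pre-ranked GSEA over a gene-set collection
#'
#' Runs the weighted running-sum statistic for every set, builds a
#' size-matched gene-set permutation null (sizes are pooled so sets of
#' equal effective size share one null), and reports NES, nominal p and
#' FDR q per set. Genes in a set but absent from the ranked list are
#' dropped per set, with counts in the `n_dropped` column; sets with no
#' overlap are skipped and listed in the `skip_log` attribute.
#'
#' @inheritParams enrichment_score
#' @param gene_sets Named list of character vectors (see [read_gmt()]).
#' @param n_perm Permutations per set size (default 1000).
#' @param seed Integer seed; fixed seed gives bit-identical results.
#' @return A `gsea_result` tibble: `set`, `size`, `n_dropped`, `es`,
#'   `nes`, `p_nominal`, `fdr_q`, `flagged`, `leading_edge`
#'   (semicolon-joined).
#' @export
gsea_preranked <- function(ranked, gene_sets, n_perm = 1000, seed = 1,
                           weight_exponent = 1) {
  check_ranked(ranked)
  skip <- character()
  rows <- list()
  nulls <- list()
  null_cache <- list()
  for (nm in names(gene_sets)) {
    genes <- unique(gene_sets[[nm]])
    present <- intersect(genes, ranked$gene)
    if (length(present) == 0L || length(present) >= nrow(ranked)) {
      skip <- c(skip, nm)
      next
    }
    es_res <- enrichment_score(ranked, present, weight_exponent)
    key <- as.character(length(present))
    if (is.null(null_cache[[key]])) {
      # per-size seed offset keeps sizes independent but reproducible
      null_cache[[key]] <- permutation_null(
        ranked, length(present), n_perm = n_perm,
        seed = seed + length(present), weight_exponent = weight_exponent
      )
    }
    rows[[length(rows) + 1L]] <- tibble(
      set = nm, size = length(present),
      n_dropped = length(genes) - length(present),
      es = es_res$es,
      leading_edge = paste(es_res$leading_edge, collapse = ";")
    )
    nulls[[length(nulls) + 1L]] <- null_cache[[key]]
  }
  if (length(rows) == 0L) abort("No gene set overlaps the ranked list.")
  observed <- bind_rows(rows)
  out <- normalize_and_fdr(observed[, c("set", "size", "n_dropped", "es")], nulls)
  out$leading_edge <- observed$leading_edge
  attr(out, "skip_log") <- skip
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("gsea_result", class(out))
  out
}

#' Filter GSEA results to significant sets
#'
#' Retains sets with |NES| above the threshold and FDR q below the
#' threshold (defaults |NES| > 1.7 and q < 0.01).
#'
#' @param results A `gsea_result` tibble.
#' @param nes_threshold Minimum |NES| (strict).
#' @param q_threshold Maximum FDR q (strict).
#' @return The filtered tibble.
#' @export
significant_sets <- function(results, nes_threshold = 1.7, q_threshold = 0.01) {
  results[abs(results$nes) > nes_threshold & results$fdr_q < q_threshold, ,
          drop = FALSE]
}
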