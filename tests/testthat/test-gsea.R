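ranked_list <- function(scores, genes = sprintf("g%03d", seq_along(scores))) {
  ord <- order(-scores, genes)
  structure(tibble::tibble(gene = genes[ord], score = scores[ord]),
            class = c("ranked_list", class(tibble::tibble())))
}

test_that("the unweighted walk on a top-k set matches direct enumeration", {
  rk <- ranked_list(rep(1, 10))
  set <- rk$gene[1:3]
  res <- enrichment_score(rk, set, weight_exponent = 0)
  # after the third straight hit the walk sits at 3/3 with no misses taken
  expect_equal(res$es, 1)
  expect_equal(res$es, oracle_es(rk$score, rk$gene %in% set, 0))
  expect_identical(res$leading_edge, set)
  # balanced walk: the running sum returns to zero at the end
  expect_equal(res$running_sum[10], 0)
})

test_that("bottom sets with negative scores get negative ES", {
  rk <- ranked_list(c(5, 4, 3, 1, 0.5, -0.5, -1, -3, -4, -5))
  res <- enrichment_score(rk, rk$gene[8:10])
  expect_lt(res$es, 0)
  expect_identical(res$leading_edge, rk$gene[8:10])
})

test_that("ES matches the brute-force oracle on random instances and stays in [-1, 1]", {
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(10:50, 1)
    scores <- sort(rnorm(n), decreasing = TRUE)
    rk <- ranked_list(scores)
    k <- sample(2:(n - 2), 1)
    set <- sample(rk$gene, k)
    p <- sample(c(0, 1), 1)
    es <- enrichment_score(rk, set, p)$es
    expect_equal(es, oracle_es(rk$score, rk$gene %in% set, p))
    expect_gte(es, -1)
    expect_lte(es, 1)
  }
})

test_that("reversing the ranking and negating scores negates ES", {
  set.seed(77)
  for (rep in 1:20) {
    scores <- sort(rnorm(20), decreasing = TRUE)
    rk <- ranked_list(scores)
    set <- sample(rk$gene, 5)
    fwd <- enrichment_score(rk, set)$es
    rev_rk <- structure(
      tibble::tibble(gene = rev(rk$gene), score = rev(-rk$score)),
      class = class(rk)
    )
    bwd <- enrichment_score(rev_rk, set)$es
    expect_equal(fwd, -bwd, tolerance = 1e-12)
  }
})

test_that("genes outside the set never influence ES", {
  set.seed(13)
  scores <- sort(rnorm(30), decreasing = TRUE)
  rk <- ranked_list(scores)
  set <- rk$gene[c(2, 9, 17)]
  base <- enrichment_score(rk, set)$es
  renamed <- rk
  outside <- !(renamed$gene %in% set)
  renamed$gene[outside] <- paste0("zz_", renamed$gene[outside])
  expect_equal(enrichment_score(renamed, set)$es, base)
})

test_that("the permutation null is reproducible, centered, and guarded", {
  rk <- ranked_list(sort(rnorm(100), decreasing = TRUE))
  a <- permutation_null(rk, set_size = 10, n_perm = 300, seed = 5)
  b <- permutation_null(rk, set_size = 10, n_perm = 300, seed = 5)
  expect_identical(a, b)
  big <- permutation_null(rk, set_size = 10, n_perm = 2000, seed = 6)
  expect_lt(abs(mean(big)), 0.1)  # symmetric score list: null ES near zero
  expect_error(permutation_null(rk, 200, 100, 1), "smaller")
  expect_error(permutation_null(rk, 10, 0, 1), "at least 100")
})

test_that("permutation-null draws agree with the oracle walk", {
  set.seed(55)
  rk <- ranked_list(sort(rnorm(60), decreasing = TRUE))
  for (rep in 1:25) {
    set <- sample(rk$gene, sample(3:20, 1))
    expect_equal(permutation_null(rk, length(set), 100, seed = rep)[1],
                 {
                   set.seed(rep)
                   idx <- sample.int(60, length(set))
                   oracle_es(rk$score, seq_len(60) %in% idx, 1)
                 })
  }
})

test_that("NES, nominal p and FDR q behave under planted and null signal", {
  set.seed(19)
  n <- 500
  scores <- sort(rnorm(n, sd = 2), decreasing = TRUE)
  rk <- ranked_list(scores)
  top_decile <- rk$gene[1:50]
  sets <- c(list(PLANTED = top_decile),
            random_gene_sets(rk$gene, 30, 50, seed = 2))
  res <- gsea_preranked(rk, sets, n_perm = 1000, seed = 3)
  planted <- res[res$set == "PLANTED", ]
  expect_gt(planted$nes, 1.7)
  expect_lt(planted$fdr_q, 0.01)
  expect_identical(sign(res$nes), sign(res$es))
  expect_true(all(res$p_nominal >= 0 & res$p_nominal <= 1))
  expect_true(all(res$fdr_q >= 0 & res$fdr_q <= 1))
})

test_that("fixed seeds give bit-identical GSEA results", {
  set.seed(23)
  rk <- ranked_list(sort(rnorm(300), decreasing = TRUE))
  sets <- random_gene_sets(rk$gene, 5, 25, seed = 9)
  r1 <- gsea_preranked(rk, sets, n_perm = 200, seed = 4)
  r2 <- gsea_preranked(rk, sets, n_perm = 200, seed = 4)
  expect_identical(r1$nes, r2$nes)
  expect_identical(r1$fdr_q, r2$fdr_q)
})

test_that("ES agrees with an established implementation on shared fixtures", {
  skip_if_not_installed("fgsea")
  set.seed(71)
  scores <- sort(rnorm(80, sd = 1.5), decreasing = TRUE)
  rk <- ranked_list(scores)
  stats_vec <- setNames(rk$score, rk$gene)
  for (rep in 1:10) {
    set <- sample(rk$gene, sample(5:15, 1))
    ours <- enrichment_score(rk, set)$es
    theirs <- fgsea::calcGseaStat(stats_vec, selectedStats = which(rk$gene %in% set),
                                  gseaParam = 1)
    expect_equal(ours, theirs, tolerance = 1e-9)
  }
})

test_that("the significance filter keeps only |NES| > 1.7 with q < 0.01", {
  res <- tibble::tibble(
    set = c("keep", "weak_nes", "weak_q"),
    size = 50, n_dropped = 0,
    es = c(0.8, 0.5, -0.7),
    nes = c(2.54, 1.6, -2.0),
    p_nominal = c(1e-4, 1e-3, 0.01),
    fdr_q = c(1e-5, 0.001, 0.02),
    flagged = FALSE
  )
  kept <- significant_sets(res)
  expect_identical(kept$set, "keep")
})

test_that("sets with no overlap are skipped and absent genes are counted", {
  rk <- ranked_list(sort(rnorm(50), decreasing = TRUE))
  sets <- list(
    GOOD = c(rk$gene[1:5], "NOT_A_GENE_1", "NOT_A_GENE_2"),
    MISSING = c("NOPE_1", "NOPE_2")
  )
  res <- gsea_preranked(rk, sets, n_perm = 100, seed = 1)
  expect_identical(res$set, "GOOD")
  expect_identical(res$n_dropped, 2L)
  expect_identical(attr(res, "skip_log"), "MISSING")
})
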