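#' Simulation configuration for a synthetic breast-cancer cohort
#'
#' Bundles every knob of the generator with defaults emulating a
#' TCGA-like cohort: three latent phenotypes in proportions 0.40 (HTI) /
#' 0.46 (CTI) / 0.14 (NI), zero-inflated CD8 fractions, lognormal
#' effector-gene (GZMA/PRF1) expression ordered HTI > CTI >= NI and
#' coupled to CD8 through a latent immune axis so that the CD8-CYT
#' Spearman correlation is about 0.5, planted gene-set enrichments
#' (an interferon-response-like set up in HTI; estrogen-response-like
#' sets up in CTI and NI), and phenotype-dependent exponential survival
#' hazards (ratio 0.5 for HTI vs NI) under an independent uniform
#' censoring horizon.
#'
#' @param n_samples Cohort size.
#' @param phenotype_proportions Named 3-vector over HTI/CTI/NI, summing
#'   to 1.
#' @param cd8_zero_mass Base zero-inflation probability for the CD8
#'   fraction; scaled per phenotype by `cd8_zero_scale`.
#' @param cd8_zero_scale Per-phenotype multipliers on `cd8_zero_mass`
#'   (zero-inflation is rarer in the infiltrated phenotypes).
#' @param cd8_beta_params Per-phenotype `c(shape1, shape2)` of the
#'   non-zero CD8 Beta component.
#' @param cyt_lognormal_params Per-phenotype `c(meanlog2, sdlog2)` of
#'   GZMA/PRF1 TPM; means must be ordered HTI > CTI >= NI.
#' @param latent_r Correlation of CD8 and of the effector genes with the
#'   shared latent immune axis.
#' @param n_genes Number of background genes (excluding GZMA/PRF1).
#' @param planted_sets Named list; each element has `phenotypes` (labels
#'   in which the set is up-regulated), `log2_effect` and `size`.
#' @param noise_sd_log2 SD of per-gene log2 expression noise.
#' @param hazard_rates Named per-phenotype exponential hazards, per month.
#' @param censoring_horizon_months Upper end of the uniform censoring
#'   horizon.
#' @param feature_shift_log2 Log2 shift of TMB/neoantigen/checkpoint
#'   features in HTI.
#' @param seed Integer seed; recorded in every simulated table.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    n_samples = 1075,
    phenotype_proportions = c(HTI = 0.40, CTI = 0.46, NI = 0.14),
    cd8_zero_mass = 0.15,
    cd8_zero_scale = c(HTI = 0.25, CTI = 0.5, NI = 3),
    cd8_beta_params = list(HTI = c(4, 12), CTI = c(3, 14), NI = c(1.3, 20)),
    cyt_lognormal_params = list(HTI = c(6, 1), CTI = c(3.5, 1), NI = c(3, 1)),
    latent_r = 0.55,
    n_genes = 2000,
    planted_sets = list(
      IFN_RESPONSE_LIKE = list(phenotypes = "HTI", log2_effect = 1, size = 50),
      ESTROGEN_RESPONSE_EARLY_LIKE = list(phenotypes = c("CTI", "NI"),
                                          log2_effect = 1, size = 50),
      ESTROGEN_RESPONSE_LATE_LIKE = list(phenotypes = c("CTI", "NI"),
                                         log2_effect = 1, size = 50)
    ),
    noise_sd_log2 = 1,
    hazard_rates = c(HTI = 0.004, CTI = 0.006, NI = 0.008),
    censoring_horizon_months = 240,
    feature_shift_log2 = 1,
    seed = 1) {
  cfg <- list(
    n_samples = n_samples,
    phenotype_proportions = phenotype_proportions,
    cd8_zero_mass = cd8_zero_mass,
    cd8_zero_scale = cd8_zero_scale,
    cd8_beta_params = cd8_beta_params,
    cyt_lognormal_params = cyt_lognormal_params,
    latent_r = latent_r,
    n_genes = n_genes,
    planted_sets = planted_sets,
    noise_sd_log2 = noise_sd_log2,
    hazard_rates = hazard_rates,
    censoring_horizon_months = censoring_horizon_months,
    feature_shift_log2 = feature_shift_log2,
    seed = seed
  )
  if (abs(sum(phenotype_proportions) - 1) > 1e-9) {
    abort("`phenotype_proportions` must sum to 1.")
  }
  if (cd8_zero_mass < 0 || cd8_zero_mass >= 1) {
    abort("`cd8_zero_mass` must lie in [0, 1).")
  }
  if (any(hazard_rates < 0) || noise_sd_log2 < 0) {
    abort("Rates and noise SDs must be non-negative.")
  }
  mus <- vapply(cyt_lognormal_params, `[`, numeric(1), 1L)
  if (!(mus[["HTI"]] > mus[["CTI"]] && mus[["CTI"]] >= mus[["NI"]])) {
    abort("Effector-gene means must be ordered HTI > CTI >= NI.")
  }
  total_planted <- sum(vapply(planted_sets, function(s) s$size, numeric(1)))
  if (total_planted > n_genes) {
    abort("Planted sets exceed `n_genes`.")
  }
  structure(cfg, class = "simulation_config")
}

#' Generate a synthetic cohort
#'
#' Draws a cohort under a [simulation_config()]: per-sample phenotype
#' labels, a shared standard-normal latent immune axis coupling the CD8
#' fraction and the effector genes, a zero-inflated Beta CD8 fraction
#' with the remaining composition spread over the other 21 cell types by
#' a Dirichlet draw, lognormal TPM expression with planted gene-set
#' shifts, exponential survival with uniform censoring, and
#' immunogenomic features with an HTI shift. Fixed seed gives a
#' bit-identical cohort.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_cohort` list with elements `expr` (TPM
#'   `expr_matrix`), `fractions`, `clinical`, `features`, `true_labels`,
#'   `gene_sets` (the planted sets), and `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  n <- config$n_samples
  ids <- sprintf("S%05d", seq_len(n))
  labels <- sample(PHENOTYPE_LEVELS, n, replace = TRUE,
                   prob = config$phenotype_proportions[PHENOTYPE_LEVELS])

  # shared latent immune axis
  z <- rnorm(n)
  r <- config$latent_r
  mix <- function(eps) r * z + sqrt(1 - r^2) * eps

  # CD8 fraction: zero-inflated Beta via Gaussian copula on the latent axis
  a <- vapply(config$cd8_beta_params, `[`, numeric(1), 1L)[labels]
  b <- vapply(config$cd8_beta_params, `[`, numeric(1), 2L)[labels]
  cd8 <- qbeta(pnorm(mix(rnorm(n))), a, b)
  p_zero <- pmin(config$cd8_zero_mass * config$cd8_zero_scale[labels], 0.9)
  cd8[runif(n) < p_zero] <- 0

  # effector genes (lognormal TPM, label-dependent means, latent-coupled)
  mu <- vapply(config$cyt_lognormal_params, `[`, numeric(1), 1L)
  sd_ <- vapply(config$cyt_lognormal_params, `[`, numeric(1), 2L)
  gzma <- 2^(mu[labels] + sd_[labels] * mix(rnorm(n)))
  prf1 <- 2^(mu[labels] + sd_[labels] * mix(rnorm(n)))

  # background + planted genes on the log2 scale
  ng <- config$n_genes
  gene_ids <- sprintf("GENE%05d", seq_len(ng))
  baseline <- runif(ng, min = 2, max = 9)
  log2_expr <- matrix(rnorm(ng * n, mean = 0, sd = config$noise_sd_log2),
                      nrow = ng) + baseline
  gene_sets <- list()
  next_gene <- 1L
  for (nm in names(config$planted_sets)) {
    ps <- config$planted_sets[[nm]]
    members <- gene_ids[next_gene:(next_gene + ps$size - 1L)]
    next_gene <- next_gene + ps$size
    in_target <- labels %in% ps$phenotypes
    log2_expr[gene_ids %in% members, in_target] <-
      log2_expr[gene_ids %in% members, in_target] + ps$log2_effect
    gene_sets[[nm]] <- members
  }
  vals <- rbind(2^log2_expr, GZMA = gzma, PRF1 = prf1)
  rownames(vals) <- c(gene_ids, "GZMA", "PRF1")
  colnames(vals) <- ids
  vals <- sweep(vals, 2L, colSums(vals), "/") * 1e6  # TPM renormalization
  expr <- expr_matrix(vals, scale = "tpm")

  # immune-cell composition: CD8 plus a Dirichlet split of the remainder
  other_types <- setdiff(cell_type_canonical_map()$canonical, "T_cells_CD8")
  other_types <- unique(other_types)
  alpha <- matrix(1, nrow = n, ncol = length(other_types),
                  dimnames = list(NULL, other_types))
  # mild phenotype structure: suppressive M2 low / effector M1 high in HTI
  alpha[, "Macrophages_M2"] <- c(HTI = 0.5, CTI = 1, NI = 2)[labels]
  alpha[, "Macrophages_M1"] <- c(HTI = 2, CTI = 1, NI = 0.5)[labels]
  alpha[, "NK_cells_activated"] <- c(HTI = 1.5, CTI = 1, NI = 0.7)[labels]
  gam <- matrix(stats::rgamma(n * length(other_types), shape = alpha),
                nrow = n, dimnames = dimnames(alpha))
  rest <- gam / rowSums(gam) * (1 - cd8)
  fractions <- as_tibble(cbind(
    tibble(sample_id = ids, T_cells_CD8 = cd8),
    as.data.frame(rest)
  ))

  # clinical covariates with phenotype-linked receptor status
  p_er_neg <- c(HTI = 0.30, CTI = 0.14, NI = 0.26)[labels]
  p_pgr_neg <- c(HTI = 0.37, CTI = 0.27, NI = 0.32)[labels]
  er <- ifelse(runif(n) < p_er_neg, "negative", "positive")
  pgr <- ifelse(runif(n) < p_pgr_neg, "negative", "positive")
  her2 <- ifelse(runif(n) < 0.17, "positive", "negative")
  unknown_mask <- runif(n) < 0.03
  her2[unknown_mask] <- "unknown"
  grade <- sample(c("1/2", "3"), n, replace = TRUE,
                  prob = c(0.5, 0.5))
  stage <- sample(c("I/II", "III/IV", "unknown"), n, replace = TRUE,
                  prob = c(0.72, 0.25, 0.03))
  histology <- sample(c("ductal", "lobular", "other"), n, replace = TRUE,
                      prob = c(0.72, 0.18, 0.10))
  sim_endpoint <- function() {
    t_event <- rexp(n, rate = config$hazard_rates[labels])
    t_cens <- runif(n, 0, config$censoring_horizon_months)
    tibble(time = pmin(t_event, t_cens), event = as.integer(t_event <= t_cens))
  }
  os <- sim_endpoint()
  pfs <- sim_endpoint()
  bcss <- sim_endpoint()
  rfs <- sim_endpoint()
  recurrence <- ifelse(rfs$event == 1L,
                       ifelse(runif(n) < 0.7, "distant", "local"),
                       "none")
  clinical <- tibble(
    sample_id = ids,
    age_years = round(pmax(25, rnorm(n, 58, 12))),
    er_status = er, pgr_status = pgr, her2_status = her2,
    grade = grade, stage = stage, histology = histology,
    os_months = os$time, os_event = os$event,
    pfs_months = pfs$time, pfs_event = pfs$event,
    bcss_months = bcss$time, bcss_event = bcss$event,
    rfs_months = rfs$time, rfs_event = rfs$event,
    recurrence_type = recurrence
  )

  # immunogenomic features, shifted up in HTI
  shift <- ifelse(labels == "HTI", config$feature_shift_log2, 0)
  tmb <- 2^(rnorm(n, mean = 1 + shift, sd = 0.8))
  features <- tibble(
    sample_id = ids,
    tmb = tmb,
    nonsilent_mutation_rate = tmb * 2^rnorm(n, 0, 0.2),
    silent_mutation_rate = tmb * 0.4 * 2^rnorm(n, 0, 0.2),
    snv_neoantigens = stats::rpois(n, lambda = 20 * 2^shift),
    indel_neoantigens = stats::rpois(n, lambda = 3),
    HLA_A = 2^(rnorm(n, 9 + shift, 0.7)),
    PD1 = 2^(rnorm(n, 3 + shift, 0.7)),
    PDL1 = 2^(rnorm(n, 4 + shift, 0.7)),
    PDL2 = 2^(rnorm(n, 4 + shift, 0.7)),
    IDO1 = 2^(rnorm(n, 5 + shift, 0.7))
  )

  structure(
    list(
      expr = expr,
      fractions = fractions,
      clinical = clinical,
      features = features,
      true_labels = tibble(sample_id = ids,
                           label = factor(labels, levels = PHENOTYPE_LEVELS)),
      gene_sets = gene_sets,
      config = config
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d samples, %d genes, seed = %d\n",
              nrow(x$true_labels), nrow(x$expr), x$config$seed))
  print(table(x$true_labels$label))
  invisible(x)
}

#' Null cohort with all phenotype effects removed
#'
#' Same generative machinery as [simulate_cohort()] but with every
#' label effect zeroed: one shared effector-gene distribution, one CD8
#' distribution, no planted expression shifts, equal hazards, identical
#' feature and receptor distributions. Labels are still drawn, so the
#' cohort calibrates type-I error of every downstream test.
#'
#' @inheritParams simulate_cohort
#' @return A `synthetic_cohort`.
#' @export
null_cohort <- function(config = simulation_config()) {
  cfg <- config
  mid_beta <- config$cd8_beta_params$CTI
  mid_cyt <- config$cyt_lognormal_params$CTI
  cfg$cd8_beta_params <- list(HTI = mid_beta, CTI = mid_beta, NI = mid_beta)
  # keep the required mean ordering with a negligible epsilon; effects are
  # orders of magnitude below any noise scale in use
  eps <- 1e-9
  cfg$cyt_lognormal_params <- list(
    HTI = c(mid_cyt[1] + 2 * eps, mid_cyt[2]),
    CTI = c(mid_cyt[1] + eps, mid_cyt[2]),
    NI = c(mid_cyt[1], mid_cyt[2])
  )
  cfg$cd8_zero_scale <- c(HTI = 1, CTI = 1, NI = 1)
  cfg$planted_sets <- lapply(config$planted_sets, function(s) {
    s$log2_effect <- 0
    s
  })
  mid_h <- unname(config$hazard_rates["CTI"])
  cfg$hazard_rates <- c(HTI = mid_h, CTI = mid_h, NI = mid_h)
  cfg$feature_shift_log2 <- 0
  out <- simulate_cohort(cfg)
  out$config <- cfg
  out
}

#' Random gene sets drawn from a gene universe
#'
#' Utility for building background collections for enrichment analysis.
#'
#' @param genes Character vector (the universe).
#' @param n_sets Number of sets.
#' @param size Genes per set.
#' @param seed Integer seed.
#' @return A named list of character vectors.
#' @export
random_gene_sets <- function(genes, n_sets, size, seed = 1) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(i) sample(genes, size))
  setNames(sets, sprintf("RANDOM_SET_%03d", seq_len(n_sets)))
}

#' Tiny deterministic worked cohort
#'
#' A 12-sample, 30-gene cohort built from fixed arithmetic (no RNG) whose
#' CYT scores, phenotype labels, rank-sum statistics and enrichment
#' scores can all be checked by hand. GZMA/PRF1 values are perfect
#' products so the pseudocount-free CYT scores are the integers
#' 600, 500, 400, 120, 110, 100, 90, 80, 70, 60, 50, 40; with
#' `cd8_top_fraction = 0.5` and `cyt_top_fraction = 0.25` the cohort
#' partitions into 3 HTI, 4 CTI and 5 NI. A 5-gene planted set
#' (`PLANT01`-`PLANT05`) is strongly up in the HTI samples.
#'
#' @return A list with `expr` (TPM `expr_matrix`), `scores` (tibble
#'   `sample_id`, `cd8`, `cyt_expected`), `expected_labels`, and
#'   `planted_set`.
#' @export
worked_fixture <- function() {
  ids <- sprintf("s%02d", 1:12)
  gzma <- c(400, 250, 160, 90, 110, 50, 81, 64, 49, 36, 25, 16)
  prf1 <- c(900, 1000, 1000, 160, 110, 200, 100, 100, 100, 100, 100, 100)
  cyt <- sqrt(gzma * prf1)  # 600 500 400 120 110 100 90 80 70 60 50 40
  cd8 <- c(0.30, 0.28, 0.05, 0.26, 0.24, 0.22, 0.20, 0.10, 0.08, 0.06, 0.04, 0.02)
  planted <- sprintf("PLANT%02d", 1:5)
  hti <- c(TRUE, TRUE, TRUE, rep(FALSE, 9))
  plant_vals <- t(vapply(1:5, function(k) {
    ifelse(hti, 1000 + 10 * k, 10 + k) + 0.25 * (1:12)  # jitter keeps variances nonzero
  }, numeric(12)))
  rownames(plant_vals) <- planted
  filler <- t(vapply(1:22, function(g) {
    ((g * 7 + (1:12) * 13) %% 50) + 1
  }, numeric(12)))
  rownames(filler) <- sprintf("G%02d", 1:22)
  partial <- rbind(GZMA = gzma, PRF1 = prf1, plant_vals, filler)
  fill <- 1e6 - colSums(partial)
  stopifnot(all(fill > 0))
  vals <- rbind(partial, FILL = fill)
  colnames(vals) <- ids
  list(
    expr = expr_matrix(vals, scale = "tpm"),
    scores = tibble(sample_id = ids, cd8 = cd8, cyt_expected = cyt),
    expected_labels = factor(
      c("HTI", "HTI", "HTI", "CTI", "CTI", "CTI", "CTI",
        "NI", "NI", "NI", "NI", "NI"),
      levels = PHENOTYPE_LEVELS
    ),
    planted_set = planted
  )
}
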