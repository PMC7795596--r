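#' Write a synthetic cohort to disk in the standard table dialects
#'
#' Writes the five cohort tables as the tab-delimited formats the readers
#' consume (expression in the `Hugo_Symbol` dialect, fractions, clinical
#' and feature tables keyed by sample id), the planted gene sets as GMT,
#' and a JSON manifest carrying the generator configuration, seed, and a
#' checksum per file.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    expression = file.path(dir, "expression_tpm.tsv"),
    fractions = file.path(dir, "immune_fractions.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    features = file.path(dir, "sample_features.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    true_labels = file.path(dir, "true_labels.tsv")
  )
  write_expression_matrix(cohort$expr, paths[["expression"]])
  for (nm in c("fractions", "clinical", "features", "true_labels")) {
    utils::write.table(cohort[[nm]], paths[[nm]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_gmt(cohort$gene_sets, paths[["gene_sets"]])
  manifest <- list(
    seed = cohort$config$seed,
    config = unclass(cohort$config),
    checksums = as.list(vapply(paths, function(p) digest::digest(file = p),
                               character(1)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# tab-delimited writer with a provenance/units comment header
write_stage_table <- function(df, path, comments) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_pipeline_config <- function(config) {
  req <- c("inputs", "output_dir")
  missing <- setdiff(req, names(config))
  if (length(missing)) {
    abort(sprintf("Pipeline config lacks field(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  inp <- config$inputs
  if (is.null(inp$expression) || is.null(inp$scale)) {
    abort("Config must name an expression file and its scale.")
  }
  for (f in intersect(c("expression", "fractions", "clinical", "features",
                        "gene_sets"), names(inp))) {
    if (!file.exists(inp[[f]])) {
      abort(sprintf("Input file for '%s' not found: %s", f, inp[[f]]))
    }
  }
  for (f in c("cd8_top_fraction", "cyt_top_fraction")) {
    v <- config[[f]]
    if (!is.null(v) && (v <= 0 || v >= 1)) {
      abort(sprintf("`%s` must lie in (0, 1).", f))
    }
  }
  if (!is.null(config$gsea) && is.null(config$gsea$seed)) {
    abort("A seed is mandatory when the GSEA stage is enabled.")
  }
  invisible(config)
}

#' Run the immunofunctional phenotyping pipeline end-to-end
#'
#' Orchestrates every stage from a single structured configuration:
#' cohort reading and alignment, CYT scoring, cutoff calibration and
#' phenotype assignment, the contrast panel over immune fractions and
#' sample features, pairwise differential expression with `.rnk` export,
#' pre-ranked GSEA, and the phenotype survival panel. Every output
#' carries the configuration hash and seed; rerunning with an identical
#' config reproduces the stochastic stages bit-identically. A failure in
#' any stage aborts with the stage name after writing a partial-output
#' manifest.
#'
#' @param config A named list, or the path of a YAML file, with fields
#'   `inputs` (paths `expression`, `fractions`, `clinical`, `features`,
#'   `gene_sets`, plus `scale`), `pseudocount`, `cd8_top_fraction`,
#'   `cyt_top_fraction`, `dge_pairs` (list of 2-vectors), `gsea`
#'   (`n_perm`, `seed`, `nes_threshold`, `q_threshold`), `survival`
#'   (`endpoints`, `strata`), and `output_dir`.
#' @return The output directory, invisibly; a `run_manifest.json` in it
#'   lists every artifact.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  validate_pipeline_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config_hash <- digest::digest(config)
  seed <- config$gsea$seed %||% NA_integer_
  stamp <- sprintf("immunophen run; config sha1 %s; seed %s", config_hash,
                   as.character(seed))
  outputs <- character()
  finish_manifest <- function(status, failed_stage = NULL) {
    manifest <- list(
      status = status, failed_stage = failed_stage,
      config_hash = config_hash, config = config, outputs = outputs
    )
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      finish_manifest("failed", name)
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  inp <- config$inputs
  cohort <- stage("read_inputs", function() {
    expr <- read_expression_matrix(inp$expression, scale = inp$scale)
    fractions <- if (!is.null(inp$fractions)) read_immune_fractions(inp$fractions)
    clinical <- if (!is.null(inp$clinical)) read_clinical(inp$clinical)
    features <- if (!is.null(inp$features)) read_sample_features(inp$features)
    align_cohort(expr, fractions, clinical, features)
  })
  gene_sets <- if (!is.null(inp$gene_sets)) {
    stage("read_gene_sets", function() read_gmt(inp$gene_sets))
  }

  cyt <- stage("cyt_scoring", function() {
    score_cyt_auto(cohort$expr, pseudocount = config$pseudocount %||% 0.01)
  })
  p <- file.path(out_dir, "cyt_scores.tsv")
  write_stage_table(cyt, p, c(stamp, "cyt: geometric-mean GZMA/PRF1 (TPM) or rank surrogate"))
  outputs <- c(outputs, p)

  assignment <- stage("phenotyping", function() {
    dat <- tibble(sample_id = cohort$sample_ids,
                  cd8 = cohort$fractions$T_cells_CD8,
                  cyt = cyt$cyt)
    calibrate_and_classify(dat,
                           cd8_top_fraction = config$cd8_top_fraction %||% 0.85,
                           cyt_top_fraction = config$cyt_top_fraction %||% 0.40)
  })
  p <- file.path(out_dir, "phenotype_assignment.tsv")
  write_stage_table(as_tibble(assignment), p,
                    c(stamp, "label: HTI/CTI/NI; cd8: fraction; cyt: score"))
  outputs <- c(outputs, p)
  th <- assignment_thresholds(assignment)
  p <- file.path(out_dir, "phenotype_cutoffs.json")
  jsonlite::write_json(
    list(config_hash = config_hash,
         cd8_cutoff = th$cd8_cutoff, cyt_cutoff = th$cyt_cutoff,
         cd8_top_fraction = th$cd8_top_fraction,
         cyt_top_fraction = th$cyt_top_fraction,
         realized_fractions = as.list(realized_fractions(assignment)),
         group_counts = as.list(group_counts(assignment))),
    p, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  outputs <- c(outputs, p)

  contrasts <- stage("contrast_panel", function() {
    panels <- list()
    if (!is.null(cohort$fractions)) {
      panels$fractions <- contrast_panel(cohort$fractions, assignment)
    }
    if (!is.null(cohort$features)) {
      panels$features <- contrast_panel(cohort$features, assignment)
    }
    bind_rows(panels, .id = "source")
  })
  p <- file.path(out_dir, "contrast_panel.tsv")
  write_stage_table(contrasts, p,
                    c(stamp, "two-sided Mann-Whitney per feature and phenotype pair"))
  outputs <- c(outputs, p)

  dge_pairs <- config$dge_pairs %||% list(c("HTI", "NI"), c("HTI", "CTI"), c("CTI", "NI"))
  for (pair in dge_pairs) {
    pair <- as.character(pair)
    tag <- paste(pair, collapse = "_vs_")
    dge <- stage(paste0("dge_", tag), function() {
      res <- differential_expression(cohort$expr, assignment, pair)
      volcano_classify(res,
                       fc_threshold = config$fc_threshold %||% 1.5,
                       p_threshold = config$p_threshold %||% 0.05)
    })
    p <- file.path(out_dir, sprintf("dge_%s.tsv", tag))
    write_stage_table(dge, p, c(stamp, sprintf(
      "Welch t per gene, log2 scale, %s minus %s", pair[1], pair[2])))
    outputs <- c(outputs, p)
    ranked <- rank_genes(dge)
    p <- file.path(out_dir, sprintf("ranked_%s.rnk", tag))
    write_rnk(ranked, p)
    outputs <- c(outputs, p)
    if (!is.null(gene_sets)) {
      gs <- stage(paste0("gsea_", tag), function() {
        gsea_preranked(ranked, gene_sets,
                       n_perm = config$gsea$n_perm %||% 1000,
                       seed = config$gsea$seed)
      })
      p <- file.path(out_dir, sprintf("gsea_%s.tsv", tag))
      write_stage_table(gs, p, c(stamp, sprintf(
        "pre-ranked GSEA on t-score ranking, %d gene-set permutations",
        config$gsea$n_perm %||% 1000)))
      outputs <- c(outputs, p)
    }
  }

  if (!is.null(cohort$clinical)) {
    surv <- stage("survival_panel", function() {
      survival_panel(cohort$clinical, assignment,
                     endpoints = config$survival$endpoints %||% "os",
                     strata = config$survival$strata %||% "subtype")
    })
    p <- file.path(out_dir, "survival_panel.tsv")
    write_stage_table(surv[, setdiff(names(surv), "curves")], p,
                      c(stamp, "log-rank across phenotypes per endpoint and stratum"))
    outputs <- c(outputs, p)
  }

  finish_manifest("complete")
  outputs <- c(outputs, file.path(out_dir, "run_manifest.json"))
  invisible(out_dir)
}
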