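#' Percentile cutoff retaining the top fraction of a cohort
#'
#' Returns the linear-interpolation empirical quantile at probability
#' `1 - top_fraction`. Downstream classification uses a strict `>`, so on
#' tie-free data the fraction of samples above the cutoff equals
#' `top_fraction` to within `1/n`, while point masses at the cutoff (for
#' example zero-inflated CD8 fractions) fall below it and shrink the
#' realized fraction — the behavior that yields realized fractions such as
#' 83.8% under a requested 85%.
#'
#' @param values Numeric vector (the calibrating cohort).
#' @param top_fraction Fraction of the cohort to retain above the cutoff,
#'   in (0, 1).
#' @return The cutoff value.
#' @export
percentile_cutoff <- function(values, top_fraction) {
  if (length(values) < 2L) abort("Need at least 2 values to calibrate a cutoff.")
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction >= 1) {
    abort("`top_fraction` must lie strictly between 0 and 1.")
  }
  if (anyNA(values) || !all(is.finite(values))) {
    abort("Cutoff calibration requires finite, non-missing values.")
  }
  if (diff(range(values)) == 0) {
    warn("All values are identical; no sample will exceed the cutoff.")
  }
  unname(quantile(values, probs = 1 - top_fraction, type = 7))
}

#' Phenotype thresholds
#'
#' Bundles the requested top fractions with the calibrated cutoff values.
#'
#' @param cd8_cutoff,cyt_cutoff Calibrated cutoff values.
#' @param cd8_top_fraction,cyt_top_fraction The requested top fractions.
#' @return A `phenotype_thresholds` list.
#' @export
phenotype_thresholds <- function(cd8_cutoff, cyt_cutoff,
                                 cd8_top_fraction = NA_real_,
                                 cyt_top_fraction = NA_real_) {
  stopifnot(is.finite(cd8_cutoff), is.finite(cyt_cutoff))
  structure(
    list(cd8_cutoff = cd8_cutoff, cyt_cutoff = cyt_cutoff,
         cd8_top_fraction = cd8_top_fraction, cyt_top_fraction = cyt_top_fraction),
    class = "phenotype_thresholds"
  )
}

#' @export
print.phenotype_thresholds <- function(x, ...) {
  cat(sprintf("<phenotype_thresholds> CD8 > %.4g (top %.0f%%), CYT > %.4g (top %.0f%%)\n",
              x$cd8_cutoff, 100 * x$cd8_top_fraction,
              x$cyt_cutoff, 100 * x$cyt_top_fraction))
  invisible(x)
}

#' Assign immunofunctional phenotypes from CD8 fraction and CYT
#'
#' Implements the three-class definition: a sample with CYT above the CYT
#' cutoff is hot T-cell infiltrated (`HTI`) regardless of its CD8 level;
#' otherwise a sample with CD8 fraction above the CD8 cutoff is cold
#' T-cell infiltrated (`CTI`); everything else is non-inflamed (`NI`).
#' The three labels are exhaustive and mutually exclusive.
#'
#' @param data A data frame with columns `sample_id`, `cd8` and `cyt`.
#' @param thresholds A [phenotype_thresholds()] object.
#' @return A `phenotype_assignment`: the input tibble plus a `label`
#'   factor column, with thresholds and group counts attached.
#' @export
classify_samples <- function(data, thresholds) {
  stopifnot(inherits(thresholds, "phenotype_thresholds"))
  data <- as_tibble(data)
  req <- c("sample_id", "cd8", "cyt")
  if (!all(req %in% names(data))) {
    abort("`data` must have columns sample_id, cd8 and cyt.")
  }
  if (anyNA(data$cd8) || anyNA(data$cyt)) {
    abort("cd8 and cyt must be complete for classification.")
  }
  label <- ifelse(data$cyt > thresholds$cyt_cutoff, "HTI",
           ifelse(data$cd8 > thresholds$cd8_cutoff, "CTI", "NI"))
  out <- mutate(data, label = factor(label, levels = PHENOTYPE_LEVELS))
  counts <- table(out$label)
  structure(out,
            thresholds = thresholds,
            group_counts = setNames(as.integer(counts), names(counts)),
            realized_fractions = c(
              cd8 = mean(data$cd8 > thresholds$cd8_cutoff),
              cyt = mean(data$cyt > thresholds$cyt_cutoff)
            ),
            class = c("phenotype_assignment", class(out)))
}

#' Calibrate cutoffs on a cohort and classify it
#'
#' Computes the CD8 and CYT percentile cutoffs on the supplied cohort
#' (cutoffs are always calibrated per cohort, never transferred) and
#' assigns phenotypes. The realized top fractions — the strictly-above
#' counts divided by n — are attached for audit; on tie-free data they
#' match the requested fractions to within `1/n`, and point masses at or
#' below the cutoff pull them lower.
#'
#' @inheritParams classify_samples
#' @param cd8_top_fraction Fraction of the cohort called CD8-high
#'   (default 0.85).
#' @param cyt_top_fraction Fraction called CYT-high (cohort-specific; 0.40
#'   for a TCGA-like RNA-seq cohort, 0.08 for a METABRIC-like microarray
#'   cohort).
#' @return A `phenotype_assignment` (see [classify_samples()]).
#' @export
calibrate_and_classify <- function(data, cd8_top_fraction = 0.85,
                                   cyt_top_fraction = 0.40) {
  data <- as_tibble(data)
  thresholds <- phenotype_thresholds(
    cd8_cutoff = percentile_cutoff(data$cd8, cd8_top_fraction),
    cyt_cutoff = percentile_cutoff(data$cyt, cyt_top_fraction),
    cd8_top_fraction = cd8_top_fraction,
    cyt_top_fraction = cyt_top_fraction
  )
  classify_samples(data, thresholds)
}

#' @export
print.phenotype_assignment <- function(x, ...) {
  counts <- attr(x, "group_counts")
  rf <- attr(x, "realized_fractions")
  cat(sprintf("<phenotype_assignment> n = %d: %s\n", nrow(x),
              paste(sprintf("%s %d", names(counts), counts), collapse = ", ")))
  cat(sprintf("  realized top fractions: CD8 %.1f%%, CYT %.1f%%\n",
              100 * rf[["cd8"]], 100 * rf[["cyt"]]))
  NextMethod()
}

#' @rdname classify_samples
#' @param x A `phenotype_assignment`.
#' @export
assignment_thresholds <- function(x) attr(x, "thresholds")

#' @rdname classify_samples
#' @export
realized_fractions <- function(x) attr(x, "realized_fractions")

#' @rdname classify_samples
#' @export
group_counts <- function(x) attr(x, "group_counts")
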