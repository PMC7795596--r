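#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a phenotype assignment
#'
#' @param x A `phenotype_assignment`.
#' @param ... Unused.
#' @return A plain tibble: `sample_id`, `cd8`, `cyt`, `label`.
#' @exportS3Method generics::tidy
tidy.phenotype_assignment <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' One-row summary of a phenotype assignment
#'
#' @param x A `phenotype_assignment`.
#' @param ... Unused.
#' @return A one-row tibble with n, group counts, the calibrated
#'   cutoffs, and the realized top fractions.
#' @exportS3Method generics::glance
glance.phenotype_assignment <- function(x, ...) {
  th <- assignment_thresholds(x)
  counts <- group_counts(x)
  rf <- realized_fractions(x)
  tibble(
    n = nrow(x),
    n_hti = counts[["HTI"]], n_cti = counts[["CTI"]], n_ni = counts[["NI"]],
    cd8_cutoff = th$cd8_cutoff, cyt_cutoff = th$cyt_cutoff,
    cd8_top_fraction = th$cd8_top_fraction,
    cyt_top_fraction = th$cyt_top_fraction,
    realized_cd8_fraction = rf[["cd8"]],
    realized_cyt_fraction = rf[["cyt"]]
  )
}

#' Tidy a Kaplan-Meier curve
#'
#' @param x A `km_curve`.
#' @param ... Unused.
#' @return The per-step tibble.
#' @exportS3Method generics::tidy
tidy.km_curve <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' One-row summary of a Kaplan-Meier curve
#'
#' @param x A `km_curve`.
#' @param ... Unused.
#' @return A one-row tibble: records, events, and median survival time
#'   (`NA` when the curve never crosses 0.5).
#' @exportS3Method generics::glance
glance.km_curve <- function(x, ...) {
  crossing <- which(x$surv <= 0.5)
  tibble(
    n = x$n_risk[1L] %||% 0L,
    n_events = sum(x$n_event),
    median_survival = if (length(crossing)) x$time[min(crossing)] else NA_real_
  )
}

#' Tidy a survival panel
#'
#' @param x A `survival_panel`.
#' @param ... Unused.
#' @return The panel without the list-column of curves.
#' @exportS3Method generics::tidy
tidy.survival_panel <- function(x, ...) {
  out <- as_tibble(x)[, setdiff(names(x), "curves")]
  class(out) <- class(tibble())
  out
}
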