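#' @importFrom ggplot2 ggplot aes geom_point geom_step geom_col geom_hline
#'   geom_vline labs scale_color_manual autoplot
NULL

phenotype_palette <- c(HTI = "#D55E00", CTI = "#0072B2", NI = "#999999")

#' Plot a phenotype assignment as a CD8-CYT scatter
#'
#' CD8 fraction against CYT (log10), colored by phenotype, with the two
#' calibrated cutoffs drawn as dashed lines.
#'
#' @param object A `phenotype_assignment`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.phenotype_assignment <- function(object, ...) {
  th <- assignment_thresholds(object)
  ggplot(as_tibble(object), aes(x = .data$cd8, y = .data$cyt,
                                color = .data$label)) +
    geom_point(alpha = 0.6, size = 1) +
    geom_vline(xintercept = th$cd8_cutoff, linetype = "dashed") +
    geom_hline(yintercept = th$cyt_cutoff, linetype = "dashed") +
    scale_color_manual(values = phenotype_palette) +
    ggplot2::scale_y_log10() +
    labs(x = "CD8+ T-cell fraction", y = "CYT score",
         color = "Phenotype")
}

#' Volcano plot of a differential-expression result
#'
#' log2 fold change against -log10 p, colored by volcano class
#' (up / down / ns); threshold lines at the fold-change and p cutoffs.
#'
#' @param results A `dge_result` (run through [volcano_classify()]; it is
#'   applied with defaults otherwise).
#' @param fc_threshold,p_threshold Thresholds for the guide lines.
#' @return A ggplot.
#' @export
plot_volcano <- function(results, fc_threshold = 1.5, p_threshold = 0.05) {
  if (!"volcano_class" %in% names(results)) {
    results <- volcano_classify(results, fc_threshold, p_threshold)
  }
  ggplot(results, aes(x = .data$log2_fc, y = -log10(.data$p_value),
                      color = .data$volcano_class)) +
    geom_point(alpha = 0.5, size = 0.8) +
    geom_vline(xintercept = c(-1, 1) * log2(fc_threshold), linetype = "dashed") +
    geom_hline(yintercept = -log10(p_threshold), linetype = "dashed") +
    scale_color_manual(values = c(up = "#CC3311", down = "#117733", ns = "grey40")) +
    labs(x = "log2 fold change", y = "-log10 p", color = NULL)
}

#' NES bar chart of a GSEA result
#'
#' One bar per gene set, length NES, shaded by -log10 FDR q.
#'
#' @param object A `gsea_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.gsea_result <- function(object, ...) {
  df <- as_tibble(object)
  df$set <- stats::reorder(df$set, df$nes)
  ggplot(df, aes(x = .data$nes, y = .data$set,
                 fill = -log10(pmax(.data$fdr_q, 1e-4)))) +
    geom_col() +
    ggplot2::scale_fill_gradient(low = "#FDD9B5", high = "#D55E00") +
    labs(x = "Normalized enrichment score", y = NULL,
         fill = "-log10 FDR q")
}

#' Kaplan-Meier step plot
#'
#' @param object A `km_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.km_curve <- function(object, ...) {
  df <- bind_rows(tibble(time = 0, surv = 1), as_tibble(object)[, c("time", "surv")])
  ggplot(df, aes(x = .data$time, y = .data$surv)) +
    geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    labs(x = "Months", y = "Survival probability")
}

#' Kaplan-Meier curves for one survival-panel cell
#'
#' @param panel A `survival_panel`.
#' @param endpoint,stratum Which cell of the panel to draw.
#' @return A ggplot with one step per phenotype.
#' @export
plot_km <- function(panel, endpoint, stratum = "whole") {
  row <- panel[panel$endpoint == endpoint & panel$stratum == stratum, ]
  if (nrow(row) == 0L) abort("No such endpoint/stratum in the panel.")
  curves <- row$curves[[1L]]
  df <- bind_rows(lapply(names(curves), function(g) {
    bind_rows(tibble(time = 0, surv = 1),
              as_tibble(curves[[g]])[, c("time", "surv")]) |>
      mutate(group = g)
  }))
  ggplot(df, aes(x = .data$time, y = .data$surv, color = .data$group)) +
    geom_step() +
    scale_color_manual(values = phenotype_palette) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    labs(x = "Months", y = "Survival probability", color = "Phenotype",
         subtitle = sprintf("%s / %s: log-rank p = %.3g",
                            endpoint, stratum, row$p_value))
}
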