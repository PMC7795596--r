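#' Extract survival records for one endpoint
#'
#' Pulls `(time, event)` for a named endpoint out of a clinical tibble
#' whose survival columns follow the `<endpoint>_months` /
#' `<endpoint>_event` convention (endpoints: `os`, `pfs`, `bcss`,
#' `rfs`). For the recurrence-specific endpoints `rfs_distant` and
#' `rfs_local`, the RFS columns are used and events of the other
#' recurrence type are censored at their event time.
#'
#' @param clinical A clinical tibble (see [read_clinical()]).
#' @param endpoint One of `"os"`, `"pfs"`, `"bcss"`, `"rfs"`,
#'   `"rfs_distant"`, `"rfs_local"`.
#' @return A tibble `sample_id`, `time_months`, `event` with incomplete
#'   records dropped.
#' @export
survival_records <- function(clinical,
                             endpoint = c("os", "pfs", "bcss", "rfs",
                                          "rfs_distant", "rfs_local")) {
  endpoint <- match.arg(endpoint)
  base <- if (endpoint %in% c("rfs_distant", "rfs_local")) "rfs" else endpoint
  tcol <- paste0(base, "_months")
  ecol <- paste0(base, "_event")
  if (!all(c(tcol, ecol) %in% names(clinical))) {
    abort(sprintf("Clinical table lacks columns '%s'/'%s'.", tcol, ecol))
  }
  out <- tibble(
    sample_id = clinical$sample_id,
    time_months = clinical[[tcol]],
    event = as.integer(clinical[[ecol]])
  )
  if (endpoint %in% c("rfs_distant", "rfs_local")) {
    if (!"recurrence_type" %in% names(clinical)) {
      abort("Recurrence-specific endpoints need a 'recurrence_type' column.")
    }
    want <- sub("rfs_", "", endpoint)
    other <- out$event == 1L & clinical$recurrence_type != want
    out$event[other] <- 0L
  }
  out <- out[!is.na(out$time_months) & !is.na(out$event), , drop = FALSE]
  if (any(out$time_months < 0)) abort("Negative survival time.")
  out
}

#' Kaplan-Meier product-limit curve
#'
#' Product-limit estimate for one group of records, via
#' [survival::survfit()]. Censored records reduce the risk set without a
#' step; at tied event/censor times censoring is handled after events
#' (the standard convention). Greenwood standard errors are included.
#'
#' @param records A tibble with `time_months` and `event` (1 = event,
#'   0 = censored).
#' @return A `km_curve` tibble: `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`, `std_err` (Greenwood, on the survival scale).
#' @export
kaplan_meier <- function(records) {
  if (nrow(records) == 0L) abort("Need at least one record.")
  if (any(records$time_months < 0)) abort("Negative survival time.")
  fit <- survival::survfit(
    survival::Surv(time_months, event) ~ 1,
    data = records, conf.type = "none"
  )
  out <- tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    surv = fit$surv,
    std_err = fit$std.err * fit$surv  # survfit reports se of log S
  )
  class(out) <- c("km_curve", class(out))
  out
}

#' Survival probability at a time point
#'
#' Step-function evaluation of a [kaplan_meier()] curve.
#'
#' @param curve A `km_curve`.
#' @param time Time point(s).
#' @return Estimated S(t).
#' @export
km_surv_at <- function(curve, time) {
  vapply(time, function(t) {
    idx <- which(curve$time <= t)
    if (length(idx) == 0L) 1 else curve$surv[max(idx)]
  }, numeric(1))
}

#' k-group log-rank test
#'
#' Observed-minus-expected log-rank statistic with hypergeometric
#' variance at each distinct event time, via [survival::survdiff()];
#' supports any k >= 2 (the three immunofunctional phenotypes in
#' particular).
#'
#' @param records A tibble with `time_months`, `event` and `group`.
#' @return A list with `statistic` (chi-square), `df` (k - 1), and
#'   `p_value`.
#' @export
logrank_test <- function(records) {
  groups <- unique(records$group)
  if (length(groups) < 2L) abort("Log-rank test needs at least 2 groups.")
  if (any(table(records$group) == 0L)) abort("Empty group.")
  sd <- survival::survdiff(
    survival::Surv(time_months, event) ~ group, data = records
  )
  df <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p_value = unname(1 - pchisq(sd$chisq, df)))
}

#' Receptor-defined subtype strata
#'
#' Maps ER/PgR/HER2 statuses to the exclusive subtypes: `HER2+` whenever
#' HER2 is positive (taking precedence over hormone-receptor status),
#' `HR+HER2-` when ER and/or PgR is positive with HER2 negative, `TN`
#' when all three are negative, else `unknown`.
#'
#' @param clinical A tibble with `er_status`, `pgr_status`,
#'   `her2_status` in `negative`/`positive`/`unknown`.
#' @return Character vector of subtype labels.
#' @export
subtype_strata <- function(clinical) {
  er <- clinical$er_status
  pgr <- clinical$pgr_status
  her2 <- clinical$her2_status
  out <- rep("unknown", nrow(clinical))
  out[her2 == "positive"] <- "HER2+"
  out[her2 == "negative" & (er == "positive" | pgr == "positive")] <- "HR+HER2-"
  out[her2 == "negative" & er == "negative" & pgr == "negative"] <- "TN"
  out
}

#' Phenotype survival panel across endpoints and subtype strata
#'
#' For each requested endpoint and each stratum (the whole cohort plus
#' each receptor subtype), runs the 3-group log-rank test across
#' phenotypes and fits per-phenotype KM curves. Strata in which fewer
#' than two phenotypes are represented are skipped and logged.
#'
#' @param clinical A clinical tibble (with receptor statuses and
#'   survival columns).
#' @param assignment A `phenotype_assignment` (or data frame with
#'   `sample_id`, `label`).
#' @param endpoints Character vector of endpoints (see
#'   [survival_records()]).
#' @param strata `"subtype"` to stratify on [subtype_strata()] plus the
#'   whole cohort, or `"whole"` for the whole cohort only.
#' @return A `survival_panel` tibble with one row per
#'   (endpoint, stratum): `endpoint`, `stratum`, `n`, `n_events`,
#'   `statistic`, `df`, `p_value`, and a list-column `curves` of named
#'   per-phenotype `km_curve` tibbles. Skipped strata are in the
#'   `skip_log` attribute.
#' @export
survival_panel <- function(clinical, assignment, endpoints = "os",
                           strata = c("subtype", "whole")) {
  strata <- match.arg(strata)
  lab <- tibble(sample_id = assignment$sample_id,
                label = as.character(assignment$label))
  clin <- dplyr::inner_join(clinical, lab, by = "sample_id")
  strat <- list(whole = rep(TRUE, nrow(clin)))
  if (strata == "subtype") {
    st <- subtype_strata(clin)
    for (s in c("HR+HER2-", "HER2+", "TN")) strat[[s]] <- st == s
  }
  rows <- list()
  skip <- character()
  for (ep in endpoints) {
    rec_all <- survival_records(clin, ep)
    rec_all <- left_join(rec_all, lab, by = "sample_id")
    for (s in names(strat)) {
      ids <- clin$sample_id[strat[[s]]]
      rec <- rec_all[rec_all$sample_id %in% ids, , drop = FALSE]
      rec$group <- rec$label
      present <- unique(rec$group)
      if (length(present) < 2L) {
        skip <- c(skip, sprintf("%s/%s: fewer than 2 phenotype groups", ep, s))
        next
      }
      lr <- logrank_test(rec)
      curves <- lapply(split(rec, rec$group), kaplan_meier)
      rows[[length(rows) + 1L]] <- tibble(
        endpoint = ep, stratum = s, n = nrow(rec),
        n_events = sum(rec$event),
        statistic = lr$statistic, df = lr$df, p_value = lr$p_value,
        curves = list(curves)
      )
    }
  }
  out <- bind_rows(rows)
  attr(out, "skip_log") <- skip
  class(out) <- c("survival_panel", class(out))
  out
}
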