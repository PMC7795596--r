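rec <- function(time, event) tibble::tibble(time_months = time, event = event)

test_that("the product-limit estimate matches hand computation", {
  km <- kaplan_meier(rec(c(1, 2, 3, 4), c(1, 1, 1, 1)))
  expect_equal(km_surv_at(km, 2), 0.5)
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))

  censored <- kaplan_meier(rec(c(5, 8, 11), c(0, 0, 0)))
  expect_true(all(censored$surv == 1))

  # events at 1 and 2 with a censor at 1.5: risk set at t=2 is a single
  # subject, so the curve drops to zero
  mixed <- kaplan_meier(rec(c(1, 1.5, 2), c(1, 0, 1)))
  expect_equal(km_surv_at(mixed, 2), 0)
  expect_equal(km_surv_at(mixed, 1), 2 / 3)

  expect_error(kaplan_meier(rec(-1, 1)), "Negative")
  expect_error(kaplan_meier(rec(numeric(0), integer(0))), "at least one")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(2)
  for (rep in 1:10) {
    times <- sort(rexp(25, 0.05))
    km <- kaplan_meier(rec(times, rep(1, 25)))
    at <- runif(5, 0, max(times))
    expect_equal(km_surv_at(km, at), vapply(at, function(t) mean(times > t), 1))
    expect_equal(km$surv, vapply(km$time, oracle_km, 1,
                                 time = times, event = rep(1, 25)))
  }
})

test_that("Greenwood errors and KM steps match hand oracles under censoring", {
  set.seed(14)
  times <- round(rexp(20, 0.1), 2)
  events <- rbinom(20, 1, 0.6)
  km <- kaplan_meier(rec(times, events))
  expect_equal(km$surv[km$n_event > 0],
               vapply(km$time[km$n_event > 0], oracle_km, 1,
                      time = times, event = events))
  expect_true(all(diff(km$surv) <= 1e-12))
})

test_that("the log-rank test matches the hypergeometric tabulation oracle", {
  d <- tibble::tibble(time_months = c(1, 2, 3, 4, 5, 6),
                      event = rep(1L, 6),
                      group = rep(c("A", "B"), each = 3))
  ours <- logrank_test(d)
  oracle <- oracle_logrank(d$time_months, d$event, d$group)
  expect_equal(ours$statistic, oracle$statistic, tolerance = 1e-9)
  expect_equal(ours$p_value, oracle$p_value, tolerance = 1e-9)
  expect_identical(ours$df, 1L)

  set.seed(6)
  for (k in 2:3) {
    for (rep in 1:8) {
      dd <- random_records(n = sample(10:20, 1), k_groups = k, seed = rep * 10 + k)
      if (length(unique(dd$group)) < k || sum(dd$event) == 0) next
      ours <- logrank_test(dd)
      oracle <- oracle_logrank(dd$time_months, dd$event, dd$group)
      expect_equal(ours$statistic, oracle$statistic, tolerance = 1e-6)
    }
  }
})

test_that("identical groups give a null log-rank and duplicate groups change nothing", {
  base <- tibble::tibble(time_months = c(1, 3, 5, 7, 9),
                         event = c(1L, 1L, 0L, 1L, 0L))
  two <- dplyr::bind_rows(
    dplyr::mutate(base, group = "A"),
    dplyr::mutate(base, group = "B")
  )
  res <- logrank_test(two)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  set.seed(9)
  d2 <- random_records(30, 2, seed = 44)
  p2 <- logrank_test(d2)$p_value
  # a third group cloned from group A carries no extra information
  d3 <- dplyr::bind_rows(d2, dplyr::mutate(d2[d2$group == "A", ], group = "C"))
  p3 <- logrank_test(d3)$p_value
  d2b <- dplyr::bind_rows(d2, dplyr::mutate(d2[d2$group == "A", ], group = "A"))
  expect_equal(logrank_test(d3)$df, 2L)
  # permuting rows leaves everything unchanged
  shuffled <- d2[sample(nrow(d2)), ]
  expect_equal(logrank_test(shuffled)$statistic, logrank_test(d2)$statistic)
  expect_error(logrank_test(dplyr::mutate(d2, group = "A")), "2 groups")
})

test_that("receptor subtypes map with HER2 precedence", {
  clin <- tibble::tibble(
    er_status = c("positive", "negative", "positive", "negative", "unknown"),
    pgr_status = c("negative", "negative", "positive", "negative", "unknown"),
    her2_status = c("negative", "negative", "positive", "positive", "unknown")
  )
  expect_identical(subtype_strata(clin),
                   c("HR+HER2-", "TN", "HER2+", "HER2+", "unknown"))
})

test_that("survival records handle endpoints and recurrence-type censoring", {
  clin <- tibble::tibble(
    sample_id = paste0("s", 1:4),
    os_months = c(10, 20, NA, 40), os_event = c(1, 0, 1, 1),
    rfs_months = c(5, 15, 25, 35), rfs_event = c(1L, 1L, 0L, 1L),
    recurrence_type = c("distant", "local", "none", "distant")
  )
  os <- survival_records(clin, "os")
  expect_identical(nrow(os), 3L)  # incomplete record dropped
  dist <- survival_records(clin, "rfs_distant")
  expect_identical(dist$event, c(1L, 0L, 0L, 1L))  # local event censored
  loc <- survival_records(clin, "rfs_local")
  expect_identical(loc$event, c(0L, 1L, 0L, 0L))
  expect_error(survival_records(clin, "bcss"), "lacks columns")
})

test_that("a hazard-ratio-0.5 phenotype effect is detected and single-group strata are skipped", {
  set.seed(20)
  n <- 300
  labels <- rep(c("HTI", "NI", "CTI"), each = n)
  haz <- c(HTI = 0.004, CTI = 0.006, NI = 0.008)[labels]
  t_event <- rexp(3 * n, haz)
  t_cens <- runif(3 * n, 0, 240)
  clin <- tibble::tibble(
    sample_id = sprintf("s%04d", seq_along(labels)),
    er_status = "positive", pgr_status = "positive",
    her2_status = ifelse(seq_along(labels) <= 30, "positive", "negative"),
    os_months = pmin(t_event, t_cens),
    os_event = as.integer(t_event <= t_cens)
  )
  assignment <- tibble::tibble(sample_id = clin$sample_id,
                               label = factor(labels, c("HTI", "CTI", "NI")))
  panel <- survival_panel(clin, assignment, endpoints = "os")
  whole <- panel[panel$stratum == "whole", ]
  expect_lt(whole$p_value, 0.01)
  # the first 30 samples (all HER2+) are HTI only: that stratum is skipped
  expect_false("HER2+" %in% panel$stratum)
  expect_match(attr(panel, "skip_log"), "HER2", all = FALSE)
  # TN never occurs here
  expect_true(all(panel$stratum %in% c("whole", "HR+HER2-")))
})
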