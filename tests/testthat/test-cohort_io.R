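write_expr_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("a well-formed expression file round-trips with its dimensions", {
  path <- write_expr_fixture(c(
    "Hugo_Symbol\tsampleA\tsampleB",
    "GZMA\t1.5\t2.5",
    "PRF1\t3\t4",
    "TP53\t5\t6"
  ))
  x <- read_expression_matrix(path, scale = "rsem")
  expect_identical(dim(x), c(3L, 2L))
  expect_identical(rownames(x), c("GZMA", "PRF1", "TP53"))
  expect_equal(unclass(x)["PRF1", "sampleB"], 4)
  expect_identical(expr_scale(x), "rsem")
  expect_identical(nrow(collapse_report(x)), 0L)
})

test_that("an Entrez id column is ignored in the cBioPortal dialect", {
  path <- write_expr_fixture(c(
    "Hugo_Symbol\tEntrez_Gene_Id\ts1\ts2",
    "GZMA\t3001\t1\t2"
  ))
  x <- read_expression_matrix(path, scale = "rsem")
  expect_identical(colnames(x), c("s1", "s2"))
})

test_that("duplicate gene symbols collapse to the max-variance row and are reported", {
  path <- write_expr_fixture(c(
    "Hugo_Symbol\ts1\ts2\ts3",
    "DUP\t1\t1\t1",
    "DUP\t0\t10\t20",
    "OTHER\t2\t2\t2"
  ))
  x <- read_expression_matrix(path, scale = "rsem")
  expect_identical(nrow(x), 2L)
  # the high-variance duplicate is the survivor
  expect_equal(unclass(x)["DUP", ], c(s1 = 0, s2 = 10, s3 = 20))
  rep <- collapse_report(x)
  expect_identical(rep$gene, "DUP")
  expect_identical(rep$n_rows, 2L)
})

test_that("a non-numeric cell is rejected with its location", {
  path <- write_expr_fixture(c(
    "Hugo_Symbol\ts1\ts2",
    "GZMA\t1\t2",
    "PRF1\tNA\t4"
  ))
  expect_error(read_expression_matrix(path, scale = "tpm"),
               regexp = "PRF1.*s1")
  expect_error(read_expression_matrix(write_expr_fixture("Hugo_Symbol\ts1")),
               regexp = "does not contain")
})

test_that("write then read reproduces values bit-identically", {
  set.seed(42)
  vals <- matrix(rexp(30) * 1000, nrow = 6,
                 dimnames = list(paste0("G", 1:6), paste0("s", 1:5)))
  x <- expr_matrix(vals, scale = "rsem")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(x, path)
  y <- read_expression_matrix(path, scale = "rsem")
  expect_identical(unclass(y)[, ], unclass(x)[, ])
})

test_that("the TPM invariant is enforced at construction", {
  good <- matrix(c(2e5, 8e5, 5e5, 5e5), nrow = 2,
                 dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_s3_class(expr_matrix(good, "tpm"), "expr_matrix")
  bad <- good * 1.01
  expect_error(expr_matrix(bad, "tpm"), "sum to 1e6")
  expect_error(expr_matrix(-good, "rsem"), "non-negative")
})

test_that("GMT parsing dedupes within sets and validates lines", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c(
    "SET_A\tdesc\tG1\tG2\tG3",
    "SET_B\tdesc\tG1\tG4\tG5\tG6\tG7",
    "SET_C\tdesc\tG1\tG1\tG2"
  ), path)
  gs <- read_gmt(path)
  expect_named(gs, c("SET_A", "SET_B", "SET_C"))
  expect_length(gs$SET_A, 3L)
  expect_length(gs$SET_B, 5L)
  expect_length(gs$SET_C, 2L)  # duplicate symbol counted once

  writeLines(c("SET_A\tdesc\tG1", "BROKEN\tonly-two-fields"), path)
  expect_error(read_gmt(path), "line 2")
  writeLines(character(), path)
  expect_error(read_gmt(path), "empty")
})

test_that("GMT round-trips through write_gmt", {
  sets <- list(ONE = c("A", "B"), TWO = c("C", "D", "E"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_identical(read_gmt(path), sets)
})

make_expr <- function(ids) {
  vals <- matrix(seq_len(2 * length(ids)), nrow = 2,
                 dimnames = list(c("G1", "G2"), ids))
  expr_matrix(vals, "rsem")
}

test_that("align_cohort intersects, reorders, logs drops, and is idempotent", {
  expr <- make_expr(paste0("s", 1:5))
  clin <- tibble::tibble(sample_id = c("s3", "s1", "s2"), age_years = c(50, 60, 70))
  co <- align_cohort(expr, clinical = clin)
  expect_identical(co$sample_ids, c("s1", "s2", "s3"))
  expect_identical(co$clinical$sample_id, co$sample_ids)
  expect_identical(attr(co, "drop_log"), c(expr = 2L, clinical = 0L))

  co2 <- align_cohort(co$expr, clinical = co$clinical)
  expect_identical(co2$sample_ids, co$sample_ids)
  expect_identical(attr(co2, "drop_log"), c(expr = 0L, clinical = 0L))

  expect_error(
    align_cohort(make_expr(c("a", "b")),
                 clinical = tibble::tibble(sample_id = c("x", "y"))),
    "No samples shared"
  )
})

test_that("immune fraction tables are canonicalized and validated", {
  path <- withr::local_tempfile(fileext = ".tsv")
  types <- cell_type_canonical_map()
  raw <- unique(types$canonical)
  n_types <- length(raw)
  set.seed(1)
  frac <- t(vapply(1:3, function(i) {
    v <- rexp(n_types)
    v / sum(v)
  }, numeric(n_types)))
  df <- data.frame(sample = paste0("s", 1:3), frac)
  colnames(df) <- c("sample", raw)
  colnames(df)[colnames(df) == "T_cells_CD8"] <- "T cells CD8"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_immune_fractions(path)
  expect_true("T_cells_CD8" %in% names(tab))
  expect_identical(nrow(tab), 3L)

  df2 <- df
  df2[[2]] <- df2[[2]] + 0.5  # breaks the composition constraint
  utils::write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_immune_fractions(path), "sum to 1")
})

test_that("clinical parsing closes the status enums and keeps unknowns explicit", {
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(sample_id = c("s1", "s2", "s3"),
               er_status = c("Positive", "neg", ""),
               pgr_status = c("+", "-", "Positive"),
               her2_status = c("junk", "negative", "positive"),
               os_months = c(10, 20, 30), os_event = c(1, 0, 1)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  clin <- read_clinical(path)
  expect_identical(clin$er_status, c("positive", "negative", "unknown"))
  expect_identical(clin$her2_status, c("unknown", "negative", "positive"))
})
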