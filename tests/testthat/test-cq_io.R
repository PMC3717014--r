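make_long_file <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

study_long_df <- function() {
  grid <- expand.grid(sample = sprintf("s%02d", 1:21),
                      gene = paste0("G", 1:7),
                      replicate = 1:3, stringsAsFactors = FALSE)
  grid$cq <- 20 + (seq_len(nrow(grid)) %% 17) / 10
  grid$condition <- rep(c("naive", "d2", "d4", "d7", "d10", "d14", "d21"),
                        each = 3)[match(grid$sample, sprintf("s%02d", 1:21))]
  grid
}

test_that("long and wide inputs parse to the same validated table", {
  df <- study_long_df()
  tab_long <- read_cq_table(make_long_file(df))
  expect_s3_class(tab_long, "cq_table")
  expect_equal(nrow(tab_long), 7 * 21 * 3)

  wide <- reshape(df, idvar = c("sample", "replicate", "condition"),
                  timevar = "gene", direction = "wide")
  names(wide) <- sub("^cq\\.", "", names(wide))
  wpath <- tempfile(fileext = ".csv")
  write.csv(wide, wpath, row.names = FALSE, quote = FALSE)
  tab_wide <- read_cq_table(wpath)

  key <- function(t) {
    d <- as.data.frame(t)
    d <- d[order(d$sample, d$gene, d$replicate), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(key(tab_wide), key(tab_long))
})

test_that("validation rejects duplicates, bad cq values, missing columns", {
  df <- data.frame(sample = "s1", gene = "GAPDH", replicate = c(1, 1),
                   cq = c(20, 21))
  expect_error(cq_table(df), "s1, GAPDH, 1")
  expect_error(cq_table(data.frame(sample = "s1", gene = "g", cq = -2)),
               "finite and > 0")
  expect_error(cq_table(data.frame(sample = "s1", cq = 20)),
               "mandatory column")
  p <- make_long_file(data.frame(sample = "s1", gene = "g", replicate = 1,
                                 cq = "oops", condition = "naive"))
  expect_error(read_cq_table(p), "non-numeric cq.*1")
})

test_that("a written table reads back field-by-field identical", {
  tab <- cq_table(study_long_df())
  p <- tempfile(fileext = ".csv")
  write_cq_table(tab, p)
  back <- read_cq_table(p)
  expect_equal(as.data.frame(back), as.data.frame(tab),
               ignore_attr = TRUE)
})

test_that("qc removes high-Cq wells and spread outliers, and logs them", {
  tab <- cq_table(data.frame(
    sample = rep(c("s1", "s2"), each = 3),
    gene = "Actb", replicate = rep(1:3, 2),
    cq = c(20.1, 20.2, 20.15,   # tight triplicate: untouched
           20.1, 20.2, 22.0)))  # one outlier
  res <- qc_filter(tab)
  expect_equal(nrow(res$table), 5)
  expect_equal(nrow(res$log), 1)
  expect_equal(res$log$cq, 22.0)
  expect_match(res$log$reason, "outlier")
  kept <- as.data.frame(res$table)
  expect_setequal(kept$cq[kept$sample == "s2"], c(20.1, 20.2))
})

test_that("qc errors when the Cq gate empties a group", {
  tab <- cq_table(data.frame(sample = "s1", gene = "g", replicate = 1,
                             cq = 31))
  expect_error(qc_filter(tab, max_cq = 30), "s1 / g")
})

test_that("qc is idempotent and never adds measurements", {
  set.seed(11)
  for (i in 1:20) {
    df <- data.frame(sample = rep(sprintf("s%d", 1:4), each = 6),
                     gene = rep(rep(c("a", "b"), each = 3), 4),
                     replicate = rep(1:3, 8),
                     cq = runif(24, 18, 29) + rbinom(24, 1, 0.2) * 2)
    tab <- cq_table(df)
    r1 <- qc_filter(tab)
    expect_lte(nrow(r1$table), nrow(tab))
    r2 <- qc_filter(r1$table)
    expect_equal(as.data.frame(r2$table), as.data.frame(r1$table),
                 ignore_attr = TRUE)
    expect_equal(nrow(r2$log), 0)
  }
})

test_that("efficiency files are normalized to fractions with range checks", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("gene,efficiency", "GAPDH,89", "18S,78"), p)
  eff <- read_efficiencies(p, scale = "percent")
  expect_equal(eff$efficiency[eff$gene == "GAPDH"], 0.89)
  expect_equal(read_efficiencies(p)$efficiency[2], 0.78)  # auto detects %

  writeLines(c("gene,efficiency", "A,0.78"), p)
  expect_equal(read_efficiencies(p, scale = "fraction")$efficiency, 0.78)
  writeLines(c("gene,efficiency", "X,-0.1"), p)
  expect_error(read_efficiencies(p), "range")
  expect_error(efficiency_table("g", 1.2), "range")
})
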