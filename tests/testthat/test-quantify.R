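test_that("relative quantities follow (1+E)^(anchor - Cq) with replicate means", {
  # two samples of one gene, perfect doubling: 2-cycle gap = 4-fold
  tab <- cq_table(data.frame(sample = c("s1", "s2"), gene = "g",
                             replicate = 1, cq = c(20, 22)))
  rq <- relative_quantities(tab, efficiency_table("g", 1.0))
  expect_equal(rq["g", "s1"], 1)
  expect_equal(rq["g", "s2"], 0.25)

  # GAPDH-like efficiency 0.89, anchor 18, well at 20
  tab <- cq_table(data.frame(sample = c("s1", "s2"), gene = "GAPDH",
                             replicate = 1, cq = c(18, 20)))
  rq <- relative_quantities(tab, efficiency_table("GAPDH", 0.89))
  expect_equal(rq["GAPDH", "s2"], 1.89^-2, tolerance = 1e-12)

  # replicates are averaged on the RQ scale, not the Cq scale
  tab <- cq_table(data.frame(
    sample = c("s1", "s2", "s2"), gene = "g", replicate = c(1, 1, 2),
    cq = c(20, 22, 20 - log2(0.35))))  # rep RQs 0.25 and 0.35
  rq <- relative_quantities(tab, efficiency_table("g", 1.0))
  expect_equal(rq["g", "s2"], 0.30, tolerance = 1e-12)
})

test_that("shifting all of a gene's Cq values leaves its RQs unchanged", {
  set.seed(3)
  df <- data.frame(sample = rep(sprintf("s%d", 1:5), each = 2),
                   gene = rep(c("a", "b"), 5), replicate = 1,
                   cq = runif(10, 18, 24))
  eff <- efficiency_table(c("a", "b"), c(0.8, 0.95))
  rq1 <- relative_quantities(cq_table(df), eff)
  df2 <- df
  df2$cq[df2$gene == "a"] <- df2$cq[df2$gene == "a"] + 1.7
  rq2 <- relative_quantities(cq_table(df2), eff)
  expect_equal(unclass(rq2), unclass(rq1), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("each gene's maximum RQ sits at the minimum-Cq sample", {
  set.seed(4)
  for (i in 1:10) {
    df <- data.frame(sample = rep(sprintf("s%d", 1:6), each = 3),
                     gene = rep(c("a", "b", "c"), 6), replicate = 1,
                     cq = runif(18, 15, 28))
    rq <- relative_quantities(cq_table(df),
                              efficiency_table(c("a", "b", "c"),
                                               c(0.7, 0.85, 1.0)))
    expect_true(all(rq > 0))
    for (g in rownames(rq)) {
      sub <- df[df$gene == g, ]
      expect_equal(names(which.max(rq[g, ])),
                   sub$sample[which.min(sub$cq)])
      expect_equal(max(rq[g, ]), 1)  # single replicate: min well = min mean
    }
  }
})

test_that("missing efficiencies and incomplete samples are handled", {
  df <- data.frame(sample = c("s1", "s1", "s2"),
                   gene = c("a", "b", "a"), replicate = 1,
                   cq = c(20, 21, 22))
  tab <- cq_table(df)
  eff <- efficiency_table(c("a", "b"), c(1, 1))
  expect_error(relative_quantities(tab, efficiency_table("a", 1)), "b")
  expect_warning(rq <- relative_quantities(tab, eff), "s2")
  expect_equal(colnames(rq), "s1")
  expect_error(relative_quantities(tab, eff, on_incomplete = "error"), "s2")
})

test_that("dilution-series fits invert the slope into an efficiency", {
  # closed-form checks on noiseless series
  s <- dilution_series("g", c(1, 10, 100, 1000),
                       20 + 3.3219 * (0:3))
  fit <- estimate_efficiency(s)
  expect_equal(fit$efficiency, 1.0, tolerance = 1e-3)
  expect_equal(fit$slope, -3.3219, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  s <- dilution_series("g", c(1, 10, 100, 1000), 20 + 3.9 * (0:3))
  expect_equal(estimate_efficiency(s)$efficiency, 10^(1 / 3.9) - 1,
               tolerance = 1e-9)
  expect_equal(10^(1 / 3.9) - 1, 0.805, tolerance = 5e-4)

  expect_error(dilution_series("g", c(1, 10), c(20, 23)), ">= 3 distinct")
  # flat/reversed series: Cq must increase with dilution
  s <- dilution_series("g", c(1, 10, 100), c(20, 19, 18))
  expect_error(estimate_efficiency(s), "slope")
})
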