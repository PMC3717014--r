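test_that("pairwise variations on the micro fixture match hand derivation", {
  rq <- micro_rq()
  V <- pairwise_variation_matrix(rq)
  expect_equal(V["A", "B"], 0)
  # log2 ratios A/C over samples: (0, -2); sample SD = sqrt(2)
  expect_equal(V["A", "C"], sqrt(2), tolerance = 1e-12)
  expect_equal(V, t(V))
  expect_equal(diag(V), c(A = 0, B = 0, C = 0))

  m <- m_values(rq)
  expect_equal(m, c(A = sqrt(2) / 2, B = sqrt(2) / 2, C = sqrt(2)),
               tolerance = 1e-12)
})

test_that("M-values match a brute-force double loop on random matrices", {
  set.seed(21)
  for (i in 1:25) {
    rq <- rand_rq(sample(3:8, 1), sample(4:12, 1))
    expect_equal(m_values(rq), oracle_m(rq), tolerance = 1e-12)
    expect_equal(pairwise_variation_matrix(rq), oracle_pv_matrix(rq),
                 tolerance = 1e-12)
  }
})

test_that("degenerate panels give zero M", {
  rq <- matrix(rep(c(1, 3, 0.5, 2), each = 4), 4, 4,
               dimnames = list(letters[1:4], NULL), byrow = FALSE)
  # identical columns up to per-gene level: all ratios constant
  rq2 <- rbind(a = c(1, 2, 4), b = c(3, 6, 12), c = c(0.5, 1, 2))
  expect_equal(unname(m_values(rq2)), c(0, 0, 0), tolerance = 1e-7)
})

test_that("M is invariant to per-sample and per-gene scaling; CV only per-gene", {
  set.seed(22)
  for (i in 1:10) {
    rq <- rand_rq(5, 8)
    cs <- 2^runif(8, -2, 2)   # per-sample factors
    dg <- 2^runif(5, -2, 2)   # per-gene factors
    scaled_s <- sweep(rq, 2, cs, `*`)
    scaled_g <- sweep(rq, 1, dg, `*`)
    expect_equal(m_values(scaled_s), m_values(rq), tolerance = 1e-9)
    expect_equal(m_values(scaled_g), m_values(rq), tolerance = 1e-9)
    expect_equal(cv_values(scaled_g), cv_values(rq), tolerance = 1e-9)
    # CV must move under per-sample scaling (content shifts)
    expect_gt(max(abs(cv_values(scaled_s) - cv_values(rq))), 1e-4)
  }
})

test_that("CV is sd/mean of the relative quantities", {
  rq <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5))
  cv <- cv_values(rq)
  expect_equal(cv[["g1"]], 0.5)           # sd 1, mean 2
  expect_equal(cv[["g2"]], 0)
  expect_equal(cv_values(rq * 7), cv)     # common scaling cancels
  expect_equal(cv, oracle_cv(rq))
})

test_that("classification applies both gates with strict cut-offs", {
  pol <- cutoff_policy("heterogeneous")
  expect_equal(pol$m_cutoff, 1.0)
  expect_equal(pol$cv_cutoff, 0.50)
  expect_equal(cutoff_policy("homogeneous")$cv_cutoff, 0.25)

  m <- c(g18S = 0.8, gOK = 0.52, gEdge = 1.0)
  cv <- c(g18S = 0.61, gOK = 0.30, gEdge = 0.2)
  rep <- classify_stability(m, cv, pol)
  # acceptable M but CV failure: not validated (the 18S pattern)
  r1 <- rep[rep$gene == "g18S", ]
  expect_true(r1$passes_m); expect_false(r1$passes_cv)
  expect_false(r1$validated)
  expect_true(rep$validated[rep$gene == "gOK"])
  # boundary: M exactly at the cut-off fails (strict inequality)
  expect_false(rep$passes_m[rep$gene == "gEdge"])
})

test_that("input validation rejects degenerate matrices", {
  expect_error(pairwise_variation_matrix(rbind(a = 1, b = 2)),
               "2 samples")
  expect_error(m_values(matrix(1:4, 1, 4)), "2 genes")
  expect_error(pairwise_variation_matrix(rbind(a = c(1, -1), b = c(1, 1))),
               "> 0")
  expect_error(cv_values(matrix(2, 3, 1)), "2 samples")
})
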