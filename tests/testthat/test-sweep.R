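test_that("complete-case filtering matches a brute-force scan", {
  P <- matrix(runif(15), 5, 3)
  P[2, 3] <- NA
  expect_identical(nrow(suppressMessages(drop_incomplete(P))), 4L)
  # no missing values: identity
  P2 <- matrix(runif(12), 4, 3)
  expect_equal(unname(drop_incomplete(P2)[, ]), unname(P2[, ]))
  # random 10% missingness against a direct scan
  set.seed(91)
  P3 <- matrix(runif(3000), 1000, 3)
  P3[sample(length(P3), 300)] <- NA
  kept <- suppressMessages(drop_incomplete(P3))
  expect_identical(nrow(kept), sum(apply(P3, 1, function(r) !anyNA(r))))
  expect_error(drop_incomplete(matrix(NA_real_, 2, 3)), "no complete rows")
})

test_that("binarization thresholds inclusively and monotonically", {
  expect_identical(as.integer(binarize_pvalues(matrix(c(0.04, 0.05, 0.6), 1),
                                               t = 0.05)),
                   c(1L, 1L, 0L))
  set.seed(92)
  P <- matrix(runif(600), 200, 3)
  n05 <- sum(binarize_pvalues(P, 0.05))
  n10 <- sum(binarize_pvalues(P, 0.10))
  expect_gte(n10, n05)
  # a threshold of almost 1 calls everything significant
  expect_true(all(binarize_pvalues(P, 1 - 1e-12) == 1L))
  expect_error(binarize_pvalues(matrix(c(0.1, NA, 0.2), 1), 0.05), "missing")
})

test_that("the default threshold grid has the canonical cutoffs", {
  g <- default_threshold_grid()
  expect_length(g, 18L)
  expect_true(!is.unsorted(g, strictly = TRUE))
  expect_equal(g[c(1, 9, 10, 18)], c(0.01, 0.09, 0.1, 0.9))
})

test_that("a sweep assembles per-threshold fits, FDRs and combined summaries", {
  ps <- sim_pvalues(20000, rho = 0.3, shape = c(0.15, 0.4, 0.7), seed = 93)
  grid <- c(0.02, 0.05, 0.1, 0.3)
  sw <- lc_sweep(ps$P, grid = grid, B = 0, seed = 94)
  expect_s3_class(sw, "lc_sweep")
  expect_identical(nrow(sw), length(grid) * 4L)  # 3 methods + combined
  expect_setequal(unique(sw$method), c(paste0("method", 1:3), "combined"))
  m <- sw[sw$method != "combined", ]
  # estimated sensitivity tracks the closed-form power t^a of the beta
  # alternative and estimated FPR tracks t; asserted over the tight
  # thresholds, where the estimator's own sampling noise is small (at
  # loose cutoffs phi of a near-saturated method is weakly determined)
  shapes <- c(0.15, 0.4, 0.7)
  tight <- grid[grid <= 0.1]
  for (k in 1:3) {
    mk <- m[m$method == paste0("method", k) & m$threshold <= 0.1, ]
    expect_lt(max(abs(mk$tpr - tight^shapes[k])), 0.15)
    expect_lt(max(abs(mk$fpr - tight)), 0.06)
  }
  # raw positive-call counts are non-decreasing in the threshold
  for (k in paste0("method", 1:3))
    expect_true(!is.unsorted(m$n_pos[m$method == k]))
  cb <- sw[sw$method == "combined", ]
  expect_true(all(cb$fdr >= 0 & cb$fdr <= 1))
  expect_true(all(cb$n_sig <= cb$n_pos))
})

test_that("bootstrap whiskers attach to sweep rows when requested", {
  ps <- sim_pvalues(800, rho = 0.3, shape = c(0.1, 0.3, 0.6), seed = 95)
  sw <- lc_sweep(ps$P, grid = c(0.05, 0.2), B = 7, seed = 96, n_starts = 5)
  m <- sw[sw$method != "combined", ]
  expect_true(all(is.finite(m$tpr_se)))
  expect_true(all(m$tpr_se >= 0))
  # rerun reproduces bit-identically
  sw2 <- lc_sweep(ps$P, grid = c(0.05, 0.2), B = 7, seed = 96, n_starts = 5)
  expect_identical(sw$tpr, sw2$tpr)
  expect_identical(sw$tpr_se, sw2$tpr_se)
})

test_that("an all-null p-value matrix is flagged unstable", {
  set.seed(97)
  P <- matrix(runif(30000), 10000, 3)  # no signal at all
  sw <- suppressWarnings(lc_sweep(P, grid = c(0.05, 0.1), B = 0, seed = 98))
  expect_true(any(sw$unstable))
})
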