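test_that("the association score weights positive calls by specificity", {
  sp <- c(0.8, 0.6, 0.6)
  expect_equal(assoc_score(c(1, 0, 0), sp), 0.4)        # 0.8 / 2.0
  expect_equal(assoc_score(c(1, 1, 1), sp), 1)
  expect_equal(assoc_score(c(0, 0, 0), sp), 0)
  # matrix form, bounds, and endpoint characterization
  Y <- all_patterns(3)
  S <- assoc_score(Y, sp)
  expect_true(all(S >= 0 & S <= 1))
  expect_identical(which(S == 0), unname(which(rowSums(Y) == 0)))
  expect_identical(which(S == 1), unname(which(rowSums(Y) == 3)))
  # adding a positive call from a method with positive specificity
  # strictly increases the score
  expect_true(assoc_score(c(1, 1, 0), sp) > assoc_score(c(1, 0, 0), sp))
  expect_error(assoc_score(c(1, 0, 0), c(0, 0, 0)), "undefined")
})

test_that("per-method FDR follows the prevalence-weighted Bayes formula", {
  expect_equal(method_fdr(0.9, 0.1, 0.5), 0.1)  # 0.05 / (0.05 + 0.45)
  expect_equal(method_fdr(0.4, 0.4, 0.25), 0.75)  # uninformative: 1 - rho
  expect_equal(method_fdr(0.8, 0, 0.3), 0)
  expect_error(method_fdr(0, 0, 0.3), "never calls positive")
})

test_that("pair FDR is the posterior probability of no association", {
  # hand evaluation: 0.5*0.2^3 / (0.5*0.2^3 + 0.5*0.8^3) = 0.008/0.520
  expect_equal(pair_fdr(c(1, 1, 1), rho = 0.5, phi = rep(0.8, 3),
                        psi = rep(0.2, 3)),
               0.008 / 0.520, tolerance = 1e-12)
  # all methods uninformative: posterior equals the prior for any pattern
  fdr <- pair_fdr(all_patterns(3), rho = 0.3, phi = c(0.5, 0.2, 0.7),
                  psi = c(0.5, 0.2, 0.7))
  expect_equal(fdr, rep(0.7, 8), tolerance = 1e-12)
  # flipping a call 0 -> 1 strictly lowers the FDR when phi_k > psi_k
  phi <- c(0.8, 0.7, 0.6); psi <- c(0.1, 0.2, 0.3)
  for (k in 1:3) {
    y0 <- c(0, 0, 0); y1 <- y0; y1[k] <- 1
    expect_lt(pair_fdr(y1, 0.3, phi, psi), pair_fdr(y0, 0.3, phi, psi))
  }
})

test_that("pair FDR reduces to the method FDR when other methods carry no information", {
  # methods 2 and 3 uninformative: their factors cancel from the posterior
  phi <- c(0.8, 0.4, 0.6); psi <- c(0.1, 0.4, 0.6)
  expect_equal(pair_fdr(c(1, 0, 1), rho = 0.3, phi = phi, psi = psi),
               method_fdr(0.8, 0.1, 0.3), tolerance = 1e-12)
})

test_that("rank-based inverse-normal weights sum to the discovery count", {
  # single positive pair: the median quantile is zero
  expect_equal(rank_weights(c(0, 0.5))[2], 1)
  # three untied positives: quantiles at 1/6, 3/6, 5/6
  w <- rank_weights(c(0.2, 0.5, 0.9))
  expect_equal(w, qnorm(c(1, 3, 5) / 6) + 1, tolerance = 1e-12)
  expect_equal(sum(w), 3, tolerance = 1e-12)
  # untied positive scores: the raw inverse-normal weights sum to n_pos
  # (clipping negative weights at zero can only raise the sum)
  set.seed(55)
  for (rep in 1:10) {
    S <- c(rep(0, 5), runif(sample(2:40, 1)))
    expect_equal(sum(rank_weights(S, clip = FALSE), na.rm = TRUE),
                 sum(S > 0), tolerance = 1e-9)
    expect_gte(sum(rank_weights(S), na.rm = TRUE), sum(S > 0) - 1e-9)
  }
  expect_error(rank_weights(c(0, 0)), "no positively scored")
})

test_that("the overall FDR is a convex combination of included pair FDRs", {
  # hand-weighted mean for three positives ordered by increasing score
  S <- c(0.2, 0.5, 0.9); fdr <- c(0.2, 0.1, 0.05)
  w <- qnorm(c(1, 3, 5) / 6) + 1
  expect_equal(as.numeric(overall_fdr(S, fdr)),
               sum(w * fdr) / 3, tolerance = 1e-12)
  expect_equal(as.numeric(overall_fdr(S, fdr)), 0.068295,
               tolerance = 1e-4)
  # constants pass through; bounds hold with ties and zeros present
  expect_equal(as.numeric(overall_fdr(c(0, 0.3, 0.7), rep(0.42, 3))), 0.42)
  set.seed(66)
  for (rep in 1:10) {
    S <- sample(c(0, 0.25, 0.5, 1), 30, replace = TRUE)
    fdr <- runif(30)
    o <- as.numeric(overall_fdr(S, fdr))
    expect_gte(o, min(fdr[S > 0]))
    expect_lte(o, max(fdr[S > 0]))
  }
})

test_that("the atlas table combines calls, scores, FDRs and flags", {
  sim <- sim_binary(300, truth_interior$rho, truth_interior$phi,
                    truth_interior$psi, seed = 71)
  fit <- lc_fit(sim$Y, seed = 2)
  atlas <- score_atlas(sim$Y, fit)
  expect_s3_class(atlas, "lc_atlas")
  expect_identical(nrow(atlas), 300L)
  expect_true(all(c("trait", "tissue", "score", "fdr", "significant")
                  %in% colnames(atlas)))
  expect_identical(atlas$significant, atlas$fdr < 0.05)
  expect_true(all(atlas$score[rowSums(sim$Y) == 0] == 0))
  expect_identical(attr(atlas, "n_pos"), sum(atlas$score > 0))
  expect_gte(attr(atlas, "overall_fdr"), 0)
  expect_lte(attr(atlas, "overall_fdr"), 1)
})
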