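test_that("a perfectly separated mixture is recovered at the boundary", {
  Y <- rep_patterns(list(c(1, 1, 1), c(0, 0, 0)), c(500, 500))
  fit <- lc_fit(Y, seed = 1)
  expect_equal(fit$rho, 0.5, tolerance = 0.01)
  expect_true(all(fit$phi > 0.99))
  expect_true(all(fit$psi < 0.01))
  em <- lc_fit(Y, method = "em", seed = 1)
  expect_equal(em$rho, 0.5, tolerance = 0.01)
  expect_true(all(em$phi > 0.99))
  expect_true(all(em$psi < 0.01))
})

test_that("quasi-Newton and EM routes find the same optimum", {
  for (s in 1:5) {
    sim <- sim_binary(2000, truth_interior$rho, truth_interior$phi,
                      truth_interior$psi, seed = 300 + s)
    ml <- lc_fit(sim$Y, seed = s)
    em <- lc_fit(sim$Y, method = "em", seed = s)
    expect_lt(max(abs(coef(ml) - coef(em))), 1e-4)
    expect_lt(abs(ml$loglik - em$loglik) / abs(ml$loglik), 1e-6)
  }
})

test_that("the EM log-likelihood never decreases across iterations", {
  set.seed(404)
  for (rep in 1:5) {
    sim <- sim_binary(500, runif(1, 0.1, 0.9),
                      runif(3, 0.4, 0.95), runif(3, 0.05, 0.6),
                      seed = 400 + rep)
    em <- lc_fit(sim$Y, method = "em", seed = rep)
    expect_true(all(diff(em$trace) > -1e-9))
  }
})

test_that("label switching is resolved to a nonnegative summed Youden index", {
  sw <- lcdiag:::apply_label_convention(0.7, c(0.1, 0.2, 0.1),
                                        c(0.9, 0.8, 0.9))
  expect_true(sw$swapped)
  expect_equal(sw$rho, 0.3)
  expect_equal(sw$phi, c(0.9, 0.8, 0.9))
  expect_equal(sw$psi, c(0.1, 0.2, 0.1))
  # already-conventional estimates are untouched
  id <- lcdiag:::apply_label_convention(0.3, c(0.9, 0.8, 0.9),
                                        c(0.1, 0.2, 0.1))
  expect_false(id$swapped)
  expect_equal(id$phi, c(0.9, 0.8, 0.9))
  # relabelling leaves the likelihood unchanged
  tab <- pattern_table(sim_binary(400, 0.3, truth_interior$phi,
                                  truth_interior$psi, seed = 9)$Y)
  expect_equal(lc_loglik(sw$rho, sw$phi, sw$psi, tab),
               lc_loglik(0.7, c(0.1, 0.2, 0.1), c(0.9, 0.8, 0.9), tab),
               tolerance = 1e-10)
  # a fit always satisfies the convention
  fit <- lc_fit(sim_binary(500, 0.7, c(0.2, 0.3, 0.25),
                           c(0.9, 0.8, 0.85), seed = 10)$Y, seed = 2)
  expect_gte(sum(fit$phi - fit$psi), 0)
  expect_lte(fit$loglik, 0)
})

test_that("identifiability and degeneracy guards fire", {
  expect_error(lc_fit(matrix(rbinom(40, 1, 0.5), 20, 2)), "identifiability")
  expect_warning(
    expect_warning(lc_fit(rep_patterns(list(c(1, 0, 1)), 5), seed = 1),
                   "fewer observations"),
    "one outcome pattern")
  expect_warning(lc_fit(rep_patterns(list(c(1, 0, 1)), 50), seed = 1),
                 "one outcome pattern")
})

test_that("modelling accessors are coherent with the fit", {
  sim <- sim_binary(2000, truth_interior$rho, truth_interior$phi,
                    truth_interior$psi, seed = 77)
  fit <- lc_fit(sim$Y, seed = 3)
  expect_named(coef(fit), c("rho", paste0("phi.method", 1:3),
                            paste0("psi.method", 1:3)))
  expect_equal(as.numeric(logLik(fit)),
               lc_loglik(fit$rho, fit$phi, fit$psi, fit$table))
  expect_equal(sum(fitted(fit)), fit$n, tolerance = 1e-8)
  expect_lt(max(abs(residuals(fit))), 4)  # the model generated the data
  pr <- predict(fit, sim$Y[1:10, ])
  expect_equal(pr$posterior, 1 - pr$fdr)
  expect_true(all(pr$score >= 0 & pr$score <= 1))
  sim2 <- simulate(fit, seed = 5, n = 500)
  expect_identical(dim(sim2$Y), c(500L, 3L))
  expect_output(print(fit), "Prevalence")
  expect_output(print(summary(fit)), "Per-method FDR")
})
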