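# Standard modelling methods for "lcfit" objects.

#' @export
print.lcfit <- function(x, digits = 4, ...) {
  cat("Latent class model for", x$K, "binary testing methods",
      "(no gold standard)\n")
  cat("Fitted by", if (x$method == "ml") "multi-start quasi-Newton ML"
      else "EM", "on", x$n, "hypothesis pairs\n\n")
  cat("Prevalence of true associations: rho =",
      format(x$rho, digits = digits), "\n")
  tab <- cbind(sensitivity = x$phi, specificity = x$specificity,
               fpr = x$psi)
  print(round(tab, digits))
  cat("\nlog-likelihood:", format(x$loglik, digits = 8),
      if (!x$converged) " (optimizer did not report convergence)" else "",
      "\n", sep = "")
  invisible(x)
}

#' @export
coef.lcfit <- function(object, ...) {
  c(rho = object$rho,
    stats::setNames(object$phi, paste0("phi.", names(object$phi))),
    stats::setNames(object$psi, paste0("psi.", names(object$psi))))
}

#' @export
logLik.lcfit <- function(object, ...) {
  structure(object$loglik, df = 2L * object$K + 1L, nobs = object$n,
            class = "logLik")
}

#' Expected pattern counts under a fitted latent class model
#'
#' @param object an [lc_fit()] result.
#' @param ... unused.
#' @return named vector of expected counts for each of the `2^K` patterns.
#' @export
fitted.lcfit <- function(object, ...) {
  object$n * pattern_prob(object$rho, object$phi, object$psi)
}

#' Pearson residuals of the fitted pattern counts
#'
#' Compares the observed count of each joint call pattern with its
#' expectation under the fitted model, standardized by the binomial
#' standard deviation `sqrt(n p (1 - p))`. Large residuals point at
#' patterns the conditional-independence model cannot reproduce, e.g.
#' when two methods are positively dependent within a latent class.
#'
#' @param object an [lc_fit()] result.
#' @param ... unused.
#' @return named vector of Pearson residuals, one per pattern.
#' @export
residuals.lcfit <- function(object, ...) {
  p <- pattern_prob(object$rho, object$phi, object$psi)
  obs <- as.numeric(object$table)
  (obs - object$n * p) / sqrt(object$n * p * (1 - p))
}

#' Posterior association probabilities, scores and FDRs for new calls
#'
#' For each row of a binary outcome matrix, computes the posterior
#' probability of a true association given the joint calls, the
#' specificity-weighted association score, and the per-pair posterior
#' false discovery rate, all at the fitted parameter values.
#'
#' @param object an [lc_fit()] result.
#' @param newdata an `n` by `K` binary outcome matrix; defaults to the
#'   `2^K` distinct patterns.
#' @param ... unused.
#' @return a data frame with columns `pattern`, `posterior`
#'   (`P(A = 1 | calls)`), `score` and `fdr`.
#' @export
predict.lcfit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- all_patterns(object$K)
  if (is.list(newdata) && !is.null(newdata$Y)) newdata <- newdata$Y
  Y <- as_binary_matrix(newdata)
  fdr <- pair_fdr(Y, rho = object$rho, phi = object$phi, psi = object$psi)
  data.frame(pattern = apply(Y, 1L, paste, collapse = ""),
             posterior = 1 - fdr,
             score = assoc_score(Y, specificity = object$specificity),
             fdr = fdr,
             row.names = NULL)
}

#' Simulate binary outcome data from a fitted latent class model
#'
#' @param object an [lc_fit()] result.
#' @param nsim number of datasets to simulate.
#' @param seed integer seed.
#' @param n rows per simulated dataset (defaults to the fitted `n`).
#' @param ... unused.
#' @return a list of [sim_binary()] datasets (a single dataset if
#'   `nsim = 1`).
#' @export
simulate.lcfit <- function(object, nsim = 1, seed = 1L, n = object$n, ...) {
  seeds <- derive_seeds(seed, nsim)
  out <- lapply(seeds, function(s)
    sim_binary(n, rho = object$rho, phi = object$phi, psi = object$psi,
               seed = s))
  if (nsim == 1) out[[1L]] else out
}

#' Summary of a latent class fit, optionally with bootstrap errors
#'
#' @param object an [lc_fit()] result.
#' @param boot optionally an [lc_boot()] result for the same data; its
#'   standard errors are attached to the coefficient table.
#' @param ... unused.
#' @return an object of class `"summary.lcfit"` containing the
#'   coefficient table (estimates, optional SEs), per-method FDR at the
#'   fitted prevalence, and fit metadata.
#' @export
summary.lcfit <- function(object, boot = NULL, ...) {
  est <- coef(object)
  tab <- cbind(estimate = est)
  if (!is.null(boot)) {
    if (!inherits(boot, "lc_boot"))
      stop_validation("boot must be an lc_boot() result")
    tab <- cbind(tab, se = boot$se[names(est)])
  }
  out <- list(coefficients = tab,
              method_fdr = method_fdr(object$phi, object$psi, object$rho),
              loglik = object$loglik, n = object$n, K = object$K,
              method = object$method, converged = object$converged,
              label_swapped = object$label_swapped)
  class(out) <- "summary.lcfit"
  out
}

#' @export
print.summary.lcfit <- function(x, digits = 4, ...) {
  cat("Latent class fit:", x$K, "methods, n =", x$n,
      "| log-likelihood", format(x$loglik, digits = 8), "\n\n")
  print(round(x$coefficients, digits))
  cat("\nPer-method FDR at the estimated prevalence:\n")
  print(round(x$method_fdr, digits))
  invisible(x)
}

#' Plot observed against fitted pattern counts
#'
#' A quick goodness-of-fit display: observed joint-pattern counts against
#' their expectations under the fitted conditional-independence model.
#'
#' @param x an [lc_fit()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.lcfit <- function(x, ...) {
  exp_cnt <- fitted(x)
  obs <- as.numeric(x$table)
  graphics::plot(exp_cnt, obs,
                 xlab = "expected pattern count",
                 ylab = "observed pattern count", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::text(exp_cnt, obs, labels = names(exp_cnt), pos = 3, cex = 0.7)
  invisible(x)
}
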