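# The two-class latent class probability model with conditionally
# independent binary indicators.
#
# Each hypothesis pair has an unobserved association status A in {0, 1}
# with prevalence rho = P(A = 1). Method k calls a pair positive with
# sensitivity phi_k = P(Y_k = 1 | A = 1) and false-positive rate
# psi_k = P(Y_k = 1 | A = 0). Conditionally on A the K calls are
# independent, so the marginal probability of a joint pattern y is
#
#   P(y) = rho * prod_k phi_k^y (1 - phi_k)^(1 - y)
#        + (1 - rho) * prod_k psi_k^y (1 - psi_k)^(1 - y).

# Class-conditional pattern probabilities: P(y | A = 1) and P(y | A = 0)
# for each row of `pat` (a patterns-by-K 0/1 matrix).
class_cond_prob <- function(pat, rate) {
  exp(pat %*% log(clip01(rate)) + (1 - pat) %*% log(clip01(1 - rate)))
}

#' Marginal probability of joint outcome patterns
#'
#' Evaluates the two-class mixture probability of each joint call pattern
#' under conditional independence of the methods given the latent
#' association status.
#'
#' @param rho prevalence of true associations, in `[0, 1]`.
#' @param phi length-`K` vector of sensitivities (true-positive rates).
#' @param psi length-`K` vector of false-positive rates.
#' @param patterns optional 0/1 matrix of patterns to evaluate (one per
#'   row, `K` columns); defaults to all `2^K` patterns in the
#'   [all_patterns()] order, in which case the result sums to 1.
#' @return a numeric vector of probabilities, named by pattern string when
#'   `patterns` has row names.
#' @examples
#' p <- pattern_prob(0.3, phi = c(0.8, 0.7, 0.6), psi = c(0.1, 0.2, 0.3))
#' sum(p)  # 1
#' @export
pattern_prob <- function(rho, phi, psi, patterns = NULL) {
  check_oc(rho, phi, psi)
  K <- length(phi)
  if (is.null(patterns)) patterns <- all_patterns(K)
  if (is.null(dim(patterns))) patterns <- matrix(patterns, nrow = 1L)
  if (ncol(patterns) != K)
    stop_validation("pattern length does not match the number of methods")
  p <- rho * class_cond_prob(patterns, phi) +
    (1 - rho) * class_cond_prob(patterns, psi)
  stats::setNames(as.numeric(p), rownames(patterns))
}

#' Log-likelihood of a pattern table
#'
#' Computes the latent class log-likelihood
#' `sum_y count(y) * log P(y)` from a table of joint pattern counts.
#' Pattern probabilities are clipped to `[1e-10, 1]` before taking logs so
#' degenerate parameter values cannot produce `-Inf`.
#'
#' @inheritParams pattern_prob
#' @param table a [pattern_table()] (or a binary matrix, which is
#'   tabulated first).
#' @return the log-likelihood (a scalar, always `<= 0`).
#' @examples
#' tab <- pattern_table(rbind(c(1, 1, 1), c(0, 0, 0)))
#' lc_loglik(0.5, phi = rep(0.9, 3), psi = rep(0.1, 3), table = tab)
#' @export
lc_loglik <- function(rho, phi, psi, table) {
  table <- pattern_table(table)
  if (attr(table, "K") != length(phi))
    stop_validation("table and parameters disagree on the number of methods")
  p <- pattern_prob(rho, phi, psi)
  sum(as.numeric(table) * log(clip01(p)))
}
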