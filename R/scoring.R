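# Combining the K methods' calls: the specificity-weighted association
# score, per-method and per-pair posterior FDRs, and the rank-weighted
# overall FDR of the combined discoveries.

#' Specificity-weighted association score
#'
#' Sums the estimated specificities of the methods that called a pair
#' positive, normalized by the total specificity of all methods:
#' `S = sum_k Y_k (1 - psi_k) / sum_k (1 - psi_k)`. The score lies in
#' `[0, 1]`; it is 0 exactly when no method calls positive and (for
#' strictly positive specificities) 1 exactly when all do. A positive
#' call from a high-specificity method moves the score more than one
#' from a promiscuous method.
#'
#' @param Y a length-`K` 0/1 pattern or an `n` by `K` binary matrix.
#' @param specificity length-`K` vector of specificities `1 - psi_k`,
#'   with a strictly positive sum.
#' @return a numeric score per row of `Y`.
#' @examples
#' assoc_score(c(1, 0, 0), specificity = c(0.8, 0.6, 0.6))  # 0.4
#' @export
assoc_score <- function(Y, specificity) {
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
  Y <- as_binary_matrix(Y)
  if (length(specificity) != ncol(Y))
    stop_validation("specificity vector does not match the number of methods")
  if (anyNA(specificity) || any(specificity < 0 | specificity > 1))
    stop_validation("specificities must lie in [0, 1]")
  if (sum(specificity) <= 0)
    stop_validation("the association score is undefined when all ",
                    "specificities are zero")
  S <- as.numeric(Y %*% specificity) / sum(specificity)
  # exact endpoints: all-negative rows score 0, all-positive rows score 1
  # (the numerator equals the denominator mathematically; floating-point
  # summation must not leave the score at 1 - 1ulp)
  S[rowSums(Y) == ncol(Y)] <- 1
  pmin(pmax(S, 0), 1)
}

#' Per-method false discovery rate
#'
#' The probability that a positive call from method `k` is a false
#' discovery, `psi_k (1 - rho) / (psi_k (1 - rho) + phi_k rho)`, at the
#' estimated prevalence of true associations.
#'
#' @param phi sensitivity (vectorized over methods).
#' @param psi false-positive rate.
#' @param rho prevalence of true associations.
#' @return FDR per method.
#' @examples
#' method_fdr(phi = 0.9, psi = 0.1, rho = 0.5)  # 0.1
#' @export
method_fdr <- function(phi, psi, rho) {
  check_oc(rho, phi, psi)
  denom <- psi * (1 - rho) + phi * rho
  if (any(denom <= 0))
    stop_validation("method FDR undefined: a method never calls positive")
  psi * (1 - rho) / denom
}

#' Per-pair posterior false discovery rate
#'
#' The posterior probability that a pair is not truly associated given
#' the joint calls of all `K` methods,
#' `P(A = 0 | Y) = (1 - rho) L0 / ((1 - rho) L0 + rho L1)` with
#' `L0 = prod_k psi_k^Y (1 - psi_k)^(1 - Y)` and
#' `L1 = prod_k phi_k^Y (1 - phi_k)^(1 - Y)`. Flipping any call from 0
#' to 1 strictly lowers the FDR whenever that method is informative
#' (`phi_k > psi_k`).
#'
#' @param Y a length-`K` 0/1 pattern or an `n` by `K` binary matrix.
#' @param rho,phi,psi model parameters (see [lc_fit()]); alternatively
#'   pass a fitted model via `fit`.
#' @param fit an [lc_fit()] result supplying `rho`, `phi`, `psi`.
#' @return the posterior FDR per row of `Y`.
#' @examples
#' pair_fdr(c(1, 1, 1), rho = 0.5, phi = rep(0.8, 3), psi = rep(0.2, 3))
#' @export
pair_fdr <- function(Y, rho, phi, psi, fit = NULL) {
  if (!is.null(fit)) { rho <- fit$rho; phi <- fit$phi; psi <- fit$psi }
  check_oc(rho, phi, psi)
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
  Y <- as_binary_matrix(Y)
  if (ncol(Y) != length(phi))
    stop_validation("pattern length does not match the number of methods")
  l1 <- as.numeric(class_cond_prob(Y, phi))
  l0 <- as.numeric(class_cond_prob(Y, psi))
  denom <- (1 - rho) * l0 + rho * l1
  if (any(denom <= 0))
    stop_validation("pair FDR undefined: pattern has probability zero ",
                    "under both latent classes")
  (1 - rho) * l0 / denom
}

#' Rank-based inverse-normal weights for the overall FDR
#'
#' Maps the scores of the positively scored pairs (`S > 0`) to standard
#' normal quantiles of their mid-ranks, shifted by one:
#' `w_i = qnorm((r_i - 0.5) / n_pos) + 1` with average ranks for ties.
#' High-scoring (low-FDR) pairs get weights above 1 and low-scoring ones
#' below 1, so that the weighted overall FDR emphasizes confident
#' discoveries while `sum(w) = n_pos` exactly for untied scores. With
#' many positives the smallest quantile drops below -1; such weights are
#' clipped at zero (by default) so the overall FDR stays a convex
#' combination of the per-pair FDRs.
#'
#' @param S numeric vector of association scores.
#' @param clip if `TRUE` (default), negative weights are set to 0.
#' @return a vector the length of `S`: weights for pairs with `S > 0`,
#'   `NA` elsewhere.
#' @examples
#' rank_weights(c(0, 0.4, 0.7, 1))
#' @export
rank_weights <- function(S, clip = TRUE) {
  if (anyNA(S)) stop_validation("scores contain missing values")
  pos <- S > 0
  n_pos <- sum(pos)
  if (n_pos == 0L)
    stop_validation("no positively scored pairs: weights undefined")
  r <- rank(S[pos], ties.method = "average")
  w <- stats::qnorm((r - 0.5) / n_pos) + 1
  if (clip) w <- pmax(w, 0)
  out <- rep(NA_real_, length(S))
  out[pos] <- w
  out
}

#' Overall FDR of the combined discoveries
#'
#' The rank-weighted average of the per-pair FDRs over pairs with a
#' positive association score: `sum(w_i FDR_i) / sum(w_i)` with weights
#' from [rank_weights()]. The unweighted count of included pairs,
#' `n_pos`, is the number of combined discoveries.
#'
#' @param S association scores (one per pair).
#' @param fdr per-pair FDRs, same length.
#' @param clip passed to [rank_weights()].
#' @return a scalar overall FDR with attribute `n_pos`.
#' @export
overall_fdr <- function(S, fdr, clip = TRUE) {
  if (length(S) != length(fdr))
    stop_validation("scores and FDRs must have the same length")
  w <- rank_weights(S, clip = clip)
  pos <- !is.na(w)
  structure(sum(w[pos] * fdr[pos]) / sum(w[pos]), n_pos = sum(S > 0))
}

#' Combined association atlas for a set of hypothesis pairs
#'
#' Assembles, for every pair, the per-method calls, the
#' specificity-weighted association score, the posterior FDR and a
#' significance flag (`FDR < fdr_cut`), together with the overall FDR of
#' the combined discoveries.
#'
#' @param Y an `n` by `K` binary outcome matrix; row names (or a `pairs`
#'   attribute with `trait`/`tissue` columns, as produced by the table
#'   readers) label the pairs.
#' @param fit an [lc_fit()] result for the same calls.
#' @param fdr_cut significance cutoff for the flag column (default 0.05).
#' @return a data frame of class `"lc_atlas"` with one row per pair:
#'   `trait`, `tissue` (when available), the K call columns, `score`,
#'   `fdr`, `significant`; attributes `overall_fdr` and `n_pos`.
#' @export
score_atlas <- function(Y, fit, fdr_cut = 0.05) {
  if (is.list(Y) && !is.null(Y$Y)) Y <- Y$Y
  pairs <- attr(Y, "pairs")
  Y <- as_binary_matrix(Y)
  if (!inherits(fit, "lcfit")) stop_validation("fit must be an lc_fit() result")
  S <- assoc_score(Y, specificity = fit$specificity)
  fdr <- pair_fdr(Y, fit = fit)
  out <- data.frame(Y, score = S, fdr = fdr,
                    significant = fdr < fdr_cut, row.names = NULL)
  if (!is.null(pairs)) out <- cbind(pairs, out)
  else if (!is.null(rownames(Y))) out <- cbind(pair = rownames(Y), out)
  ofdr <- if (any(S > 0)) overall_fdr(S, fdr) else NA_real_
  structure(out, overall_fdr = as.numeric(ofdr),
            n_pos = sum(S > 0), fdr_cut = fdr_cut,
            class = c("lc_atlas", "data.frame"))
}
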