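# Simulators: binary call matrices with known latent association status,
# repeated estimation studies, and synthetic p-value matrices.

#' Simulate binary calls from the latent class model
#'
#' Draws the latent association status `A_i ~ Bernoulli(rho)` for each of
#' `n` hypothesis pairs and then, conditionally independently across
#' methods, the calls `Y_ik ~ Bernoulli(phi_k)` for associated pairs and
#' `Bernoulli(psi_k)` otherwise. Marginally over `A` this is exactly a
#' multinomial draw of the `2^K` joint patterns with the model's pattern
#' probabilities; sampling `A` first additionally yields ground-truth
#' labels, which the FDR calibration checks need.
#'
#' @param n number of hypothesis pairs.
#' @param rho prevalence of true associations.
#' @param phi length-`K` sensitivities.
#' @param psi length-`K` false-positive rates.
#' @param seed integer seed.
#' @param methods optional method names.
#' @return an object of class `"lc_sim"`: a list with `Y` (the `n` by `K`
#'   0/1 matrix with a `pairs` attribute), `A` (latent labels), `truth`
#'   (list of `rho`, `phi`, `psi`) and `seed`.
#' @examples
#' sim <- sim_binary(1000, rho = 0.3, phi = c(0.35, 0.85, 0.8),
#'                   psi = c(0.15, 0.65, 0.2), seed = 42)
#' colMeans(sim$Y[sim$A == 1, ])  # close to phi
#' @export
sim_binary <- function(n, rho, phi, psi, seed = 1L, methods = NULL) {
  check_oc(rho, phi, psi)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop_validation("n must be a positive integer")
  K <- length(phi)
  if (is.null(methods)) methods <- paste0("method", seq_len(K))
  set.seed(seed)
  A <- stats::rbinom(n, 1L, rho)
  Y <- vapply(seq_len(K), function(k)
    stats::rbinom(n, 1L, ifelse(A == 1L, phi[k], psi[k])), integer(n))
  Y <- matrix(Y, nrow = n, dimnames = list(NULL, methods))
  attr(Y, "pairs") <- sim_pair_labels(n)
  structure(list(Y = Y, A = A,
                 truth = list(rho = rho, phi = phi, psi = psi),
                 seed = as.integer(seed)),
            class = "lc_sim")
}

sim_pair_labels <- function(n) {
  data.frame(trait = sprintf("trait%05d", seq_len(n)),
             tissue = sprintf("tissue%05d", seq_len(n)))
}

#' @export
print.lc_sim <- function(x, ...) {
  cat("Simulated binary calls: n =", nrow(x$Y), "pairs,", ncol(x$Y),
      "methods, true prevalence", x$truth$rho, "\n")
  invisible(x)
}

#' Repeated-simulation study of the estimator
#'
#' Repeats `sim_binary` + `lc_fit` and collects all parameter estimates,
#' to characterize the empirical distribution of the estimator at given
#' truths and sample size (default 100 repeats).
#'
#' @inheritParams sim_binary
#' @param repeats number of independent simulation/estimation rounds.
#' @param n_starts optimization starts per fit (see [lc_fit()]).
#' @return an object of class `"lc_study"`: a list with `estimates`
#'   (`repeats` by `2K+1` matrix, failed fits dropped), `mean` and `sd`
#'   per parameter, `truth`, `n`, `repeats` and the number of `failed`
#'   fits.
#' @examples
#' st <- sim_study(500, rho = 0.3, phi = c(0.8, 0.7, 0.6),
#'                 psi = c(0.1, 0.2, 0.3), repeats = 3, seed = 7)
#' st$mean
#' @export
sim_study <- function(n, rho, phi, psi, repeats = 100L, seed = 1L,
                      n_starts = 20L) {
  check_oc(rho, phi, psi)
  repeats <- as.integer(repeats)
  if (repeats < 1L) stop_validation("repeats must be at least 1")
  seeds <- derive_seeds(seed, repeats)
  rows <- vector("list", repeats)
  failed <- 0L
  for (r in seq_len(repeats)) {
    sim <- sim_binary(n, rho, phi, psi, seed = seeds[r])
    est <- try(suppressWarnings(
      lc_fit(sim$Y, n_starts = n_starts, seed = seeds[r])), silent = TRUE)
    if (inherits(est, "try-error")) { failed <- failed + 1L; next }
    rows[[r]] <- coef(est)
  }
  if (failed > 0L)
    warning(failed, " of ", repeats, " fits failed and were excluded")
  est <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(est)) stop("every simulation fit failed")
  structure(list(estimates = est, mean = colMeans(est),
                 sd = apply(est, 2L, stats::sd),
                 truth = list(rho = rho, phi = phi, psi = psi),
                 n = as.integer(n), repeats = repeats, failed = failed,
                 seed = as.integer(seed)),
            class = "lc_study")
}

#' @export
print.lc_study <- function(x, digits = 4, ...) {
  cat("Simulation study:", nrow(x$estimates), "fits at n =", x$n, "\n\n")
  truth <- c(rho = x$truth$rho,
             stats::setNames(x$truth$phi, paste0("phi.", seq_along(x$truth$phi))),
             stats::setNames(x$truth$psi, paste0("psi.", seq_along(x$truth$psi))))
  print(round(cbind(truth = truth, mean = x$mean, sd = x$sd), digits))
  invisible(x)
}

#' Simulate a multi-method p-value matrix with latent truth
#'
#' Generates `n` hypothesis pairs with latent status
#' `A_i ~ Bernoulli(rho)`; p-values are `Uniform(0, 1)` under the null
#' and `Beta(a_k, 1)` under the alternative, independently across
#' methods given `A_i`. With shape `0 < a_k <= 1` the alternative
#' density piles mass near zero, so thresholding at `t` yields implied
#' sensitivity `t^(a_k)` and false-positive rate exactly `t` — a
#' closed-form ROC to check threshold sweeps against.
#'
#' @param n number of hypothesis pairs.
#' @param rho prevalence of true associations, in `(0, 1)`.
#' @param shape length-`K` vector of beta shapes `a_k` in `(0, 1]`
#'   (smaller = more powerful method).
#' @param seed integer seed.
#' @param methods optional method names.
#' @return a list of class `"lc_psim"` with `P` (the `n` by `K` p-value
#'   matrix, `pairs` attribute attached), `A`, `shape`, `rho`, `seed`.
#' @examples
#' ps <- sim_pvalues(1000, rho = 0.3, shape = c(0.2, 0.5, 1), seed = 3)
#' mean(ps$P[ps$A == 1, 1] <= 0.05)  # about 0.05^0.2
#' @export
sim_pvalues <- function(n, rho, shape, seed = 1L, methods = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop_validation("n must be a positive integer")
  if (length(rho) != 1L || rho <= 0 || rho >= 1)
    stop_validation("rho must lie strictly inside (0, 1)")
  if (anyNA(shape) || any(shape <= 0 | shape > 1))
    stop_validation("beta shapes must lie in (0, 1]")
  K <- length(shape)
  if (is.null(methods)) methods <- paste0("method", seq_len(K))
  set.seed(seed)
  A <- stats::rbinom(n, 1L, rho)
  P <- vapply(seq_len(K), function(k) {
    p <- stats::runif(n)
    alt <- A == 1L
    p[alt] <- stats::rbeta(sum(alt), shape[k], 1)
    p
  }, numeric(n))
  P <- matrix(P, nrow = n, dimnames = list(NULL, methods))
  attr(P, "pairs") <- sim_pair_labels(n)
  structure(list(P = P, A = A, shape = shape, rho = rho,
                 seed = as.integer(seed)),
            class = "lc_psim")
}
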