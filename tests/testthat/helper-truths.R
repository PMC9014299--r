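# Shared generating truths and small utilities for the test suite.

# Interior truths: comfortably identifiable, used for oracle comparisons.
truth_interior <- list(rho = 0.3, phi = c(0.8, 0.7, 0.6),
                       psi = c(0.1, 0.2, 0.3))

# Three methods of unequal quality: sensitivities 0.35/0.85/0.8 and
# specificities 0.85/0.35/0.8 (one specific-but-insensitive method, one
# sensitive-but-unspecific, one good all-round).
truth_study <- list(rho = 0.3, phi = c(0.35, 0.85, 0.8),
                    psi = c(0.15, 0.65, 0.2))

coef_truth <- function(tr, methods = paste0("method", seq_along(tr$phi))) {
  c(rho = tr$rho,
    stats::setNames(tr$phi, paste0("phi.", methods)),
    stats::setNames(tr$psi, paste0("psi.", methods)))
}

# Binary matrix with the given pattern rows repeated.
rep_patterns <- function(patterns, times) {
  do.call(rbind, mapply(function(p, m) {
    matrix(rep(p, m), nrow = m, byrow = TRUE)
  }, patterns, times, SIMPLIFY = FALSE))
}
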