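# Nonparametric bootstrap over hypothesis pairs (rows). Methods
# (columns) are never resampled: the resampling unit is the hypothesis.

#' Bootstrap standard errors for the operating characteristics
#'
#' Resamples the rows of a binary outcome matrix with replacement `B`
#' times, refits the latent class model to each replicate, and reports
#' the standard deviation of every parameter across replicates. Each
#' replicate uses a seed derived deterministically from `seed` and the
#' replicate index, so single replicates are individually reproducible
#' and the result does not depend on evaluation order.
#'
#' @param Y an `n` by `K` binary outcome matrix (or [sim_binary()]
#'   dataset).
#' @param B number of bootstrap replicates (default 99).
#' @param seed integer seed.
#' @param n_starts optimization starts per replicate fit (the moment
#'   start plus random starts; fewer than for the point fit, since each
#'   replicate is a perturbation of data already fitted).
#' @param fit optionally the point [lc_fit()] on `Y`; computed if absent.
#' @return an object of class `"lc_boot"`: a list with `point` (the point
#'   fit), `replicates` (a `B_eff` by `2K+1` matrix of replicate
#'   estimates), `mean` and `se` per parameter, `B` requested and `B_eff`
#'   successful replicates, and `seed`.
#' @examples
#' sim <- sim_binary(500, rho = 0.3, phi = c(0.8, 0.7, 0.6),
#'                   psi = c(0.1, 0.2, 0.3), seed = 1)
#' bt <- lc_boot(sim, B = 19, seed = 1)
#' bt$se
#' @export
lc_boot <- function(Y, B = 99L, seed = 1L, n_starts = 5L, fit = NULL) {
  if (is.list(Y) && !is.null(Y$Y)) Y <- Y$Y
  Y <- as_binary_matrix(Y)
  B <- as.integer(B)
  if (B < 1L) stop_validation("B must be at least 1")
  if (is.null(fit)) fit <- lc_fit(Y, seed = seed)
  n <- nrow(Y)
  seeds <- derive_seeds(seed, B)
  reps <- vector("list", B)
  failed <- 0L
  for (r in seq_len(B)) {
    set.seed(seeds[r])
    idx <- sample.int(n, n, replace = TRUE)
    # the fit seed is shared across replicates so a replicate's estimate
    # depends only on the resampled data, not on its index
    est <- try(suppressWarnings(
      lc_fit(Y[idx, , drop = FALSE], n_starts = n_starts,
             seed = seed)), silent = TRUE)
    if (inherits(est, "try-error")) { failed <- failed + 1L; next }
    reps[[r]] <- coef(est)
  }
  if (failed > 0L)
    warning(failed, " of ", B, " bootstrap replicates failed to fit and ",
            "were excluded")
  reps <- do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
  if (is.null(reps) || nrow(reps) == 0L)
    stop("every bootstrap replicate failed to fit")
  structure(list(point = fit,
                 replicates = reps,
                 mean = colMeans(reps),
                 se = apply(reps, 2L, stats::sd),
                 B = B, B_eff = nrow(reps), seed = as.integer(seed)),
            class = "lc_boot")
}

#' @export
print.lc_boot <- function(x, digits = 4, ...) {
  cat("Bootstrap of the latent class fit:", x$B_eff, "of", x$B,
      "replicates\n\n")
  print(round(cbind(estimate = coef(x$point), boot_mean = x$mean,
                    boot_se = x$se), digits))
  invisible(x)
}
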