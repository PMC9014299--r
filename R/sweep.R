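# Threshold sweeps: binarize p-value matrices at a grid of cutoffs, fit
# the latent class model at each, and assemble ROC-style tables with
# bootstrap whiskers plus FDR-versus-discoveries summaries.

as_pvalue_matrix <- function(P) {
  if (is.list(P) && !is.null(P$P)) {
    pairs <- attr(P$P, "pairs")
    P <- P$P
    attr(P, "pairs") <- pairs
  }
  if (is.data.frame(P)) P <- as.matrix(P)
  if (!is.matrix(P)) stop_validation("p-values must form a matrix")
  if (!is.numeric(P)) stop_validation("p-values must be numeric")
  bad <- !is.na(P) & (P < 0 | P > 1)
  if (any(bad))
    stop_validation("p-values outside [0, 1] at row(s) ",
                    paste(utils::head(which(rowSums(bad) > 0), 5),
                          collapse = ", "))
  if (is.null(colnames(P))) colnames(P) <- paste0("method", seq_len(ncol(P)))
  P
}

#' Drop hypothesis pairs with any missing p-value
#'
#' Complete-case filter: keeps only rows where every method reports a
#' p-value, mirroring the practice of restricting the analysis to pairs
#' assessed by all methods.
#'
#' @param P an `n` by `K` p-value matrix (possibly with `NA`s), or a
#'   [sim_pvalues()] result.
#' @return the filtered matrix, with attribute `n_dropped`.
#' @export
drop_incomplete <- function(P) {
  P <- as_pvalue_matrix(P)
  keep <- stats::complete.cases(P)
  if (!any(keep))
    stop_validation("no complete rows remain after filtering missing p-values")
  dropped <- sum(!keep)
  if (dropped > 0L)
    message("dropped ", dropped, " of ", nrow(P),
            " pairs with missing p-values")
  pairs <- attr(P, "pairs")
  out <- P[keep, , drop = FALSE]
  if (!is.null(pairs)) attr(out, "pairs") <- pairs[keep, , drop = FALSE]
  attr(out, "n_dropped") <- dropped
  out
}

#' Binarize a p-value matrix at a significance threshold
#'
#' Turns p-values into binary calls: `Y_ik = 1` iff `p_ik <= t`
#' (inclusive, so a p-value exactly at the cutoff counts as significant).
#'
#' @param P a complete `n` by `K` p-value matrix (run [drop_incomplete()]
#'   first if it has missing entries).
#' @param t threshold in `(0, 1)`.
#' @return an `n` by `K` integer 0/1 matrix (pair labels carried over).
#' @examples
#' binarize_pvalues(matrix(c(0.04, 0.05, 0.6), 1), t = 0.05)
#' @export
binarize_pvalues <- function(P, t) {
  P <- as_pvalue_matrix(P)
  if (length(t) != 1L || is.na(t) || t <= 0 || t >= 1)
    stop_validation("threshold must lie strictly inside (0, 1)")
  if (anyNA(P))
    stop_validation("p-value matrix has missing entries; ",
                    "apply drop_incomplete() first")
  Y <- matrix(as.integer(P <= t), nrow = nrow(P),
              dimnames = dimnames(P))
  attr(Y, "pairs") <- attr(P, "pairs")
  Y
}

#' The default significance threshold grid
#'
#' Eighteen cutoffs: 0.01 to 0.09 in steps of 0.01, then 0.1 to 0.9 in
#' steps of 0.1, spanning the usable ROC range.
#'
#' @return a strictly increasing numeric vector of length 18.
#' @export
default_threshold_grid <- function() c(1:9 / 100, 1:9 / 10)

#' Threshold sweep: operating characteristics along the ROC curve
#'
#' For each threshold in `grid`, binarizes the p-value matrix, fits the
#' latent class model, optionally bootstraps for standard errors, and
#' evaluates the per-method FDR and the combined score's overall FDR.
#' The result is a long table with one row per (threshold, method) and a
#' `"combined"` row per threshold summarizing the score-based inference.
#'
#' Fits are flagged `unstable` when the estimated prevalence sits at the
#' boundary (below 0.01 or above 0.99), a method makes no positive call,
#' or an estimated sensitivity falls below the corresponding
#' false-positive rate after label resolution.
#'
#' @param P an `n` by `K` p-value matrix (or [sim_pvalues()] result);
#'   rows with missing values are dropped first.
#' @param grid strictly increasing thresholds inside `(0, 1)`; defaults
#'   to [default_threshold_grid()].
#' @param B bootstrap replicates per threshold (default 99; `B = 0`
#'   skips the bootstrap and leaves the SE columns `NA`).
#' @param seed integer seed (per-threshold streams are derived from it).
#' @param n_starts optimization starts for each point fit.
#' @param fdr_cut significance cutoff used for the combined discovery
#'   count column.
#' @return a data frame of class `"lc_sweep"`: columns `threshold`,
#'   `method`, `tpr`, `tpr_se`, `fpr`, `fpr_se`, `rho`, `fdr`, `n_pos`
#'   (positive calls for a method row; `n_pos` of the combined score for
#'   a combined row), `n_sig` (combined rows: pairs with pair FDR below
#'   `fdr_cut`), `unstable`.
#' @export
lc_sweep <- function(P, grid = default_threshold_grid(), B = 99L,
                     seed = 1L, n_starts = 20L, fdr_cut = 0.05) {
  P <- drop_incomplete(P)
  if (length(grid) < 1L || anyNA(grid) || any(grid <= 0 | grid >= 1))
    stop_validation("threshold grid must lie strictly inside (0, 1)")
  if (is.unsorted(grid, strictly = TRUE))
    stop_validation("threshold grid must be strictly increasing")
  K <- ncol(P)
  methods <- colnames(P)
  seeds <- derive_seeds(seed, length(grid))
  rows <- vector("list", length(grid))
  for (j in seq_along(grid)) {
    t <- grid[j]
    Y <- binarize_pvalues(P, t)
    n_calls <- colSums(Y)
    fit <- suppressWarnings(lc_fit(Y, n_starts = n_starts, seed = seeds[j]))
    se <- rep(NA_real_, 2L * K + 1L)
    names(se) <- names(coef(fit))
    if (B > 0L) {
      bt <- suppressWarnings(lc_boot(Y, B = B, seed = seeds[j],
                                     fit = fit))
      se <- bt$se
    }
    unstable <- fit$rho < 0.01 || fit$rho > 0.99 ||
      any(n_calls == 0L) || any(fit$phi < fit$psi)
    mf <- method_fdr(fit$phi, fit$psi, fit$rho)
    S <- assoc_score(Y, specificity = fit$specificity)
    fdr_i <- pair_fdr(Y, fit = fit)
    ofdr <- if (any(S > 0)) as.numeric(overall_fdr(S, fdr_i)) else NA_real_
    rows[[j]] <- rbind(
      data.frame(threshold = t, method = methods,
                 tpr = unname(fit$phi),
                 tpr_se = unname(se[paste0("phi.", methods)]),
                 fpr = unname(fit$psi),
                 fpr_se = unname(se[paste0("psi.", methods)]),
                 rho = fit$rho, fdr = unname(mf), n_pos = unname(n_calls),
                 n_sig = NA_integer_, unstable = unstable),
      data.frame(threshold = t, method = "combined",
                 tpr = NA_real_, tpr_se = NA_real_,
                 fpr = NA_real_, fpr_se = NA_real_,
                 rho = fit$rho, fdr = ofdr, n_pos = sum(S > 0),
                 n_sig = sum(S > 0 & fdr_i < fdr_cut),
                 unstable = unstable))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, seed = as.integer(seed), B = as.integer(B), n = nrow(P),
            fdr_cut = fdr_cut, class = c("lc_sweep", "data.frame"))
}

#' Plot a threshold sweep as ROC points with bootstrap whiskers
#'
#' @param x an [lc_sweep()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.lc_sweep <- function(x, ...) {
  m <- x[x$method != "combined", ]
  methods <- unique(m$method)
  cols <- seq_along(methods)
  graphics::plot(m$fpr, m$tpr, xlim = c(0, 1), ylim = c(0, 1),
                 col = cols[match(m$method, methods)],
                 pch = 16, xlab = "false positive rate",
                 ylab = "true positive rate", ...)
  ok <- !is.na(m$tpr_se)
  if (any(ok)) {
    graphics::arrows(m$fpr[ok], m$tpr[ok] - m$tpr_se[ok],
                     m$fpr[ok], m$tpr[ok] + m$tpr_se[ok],
                     angle = 90, code = 3, length = 0.02,
                     col = cols[match(m$method[ok], methods)])
    graphics::arrows(m$fpr[ok] - m$fpr_se[ok], m$tpr[ok],
                     m$fpr[ok] + m$fpr_se[ok], m$tpr[ok],
                     angle = 90, code = 3, length = 0.02,
                     col = cols[match(m$method[ok], methods)])
  }
  graphics::abline(0, 1, lty = 3)
  graphics::legend("bottomright", legend = methods, col = cols, pch = 16)
  invisible(x)
}
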