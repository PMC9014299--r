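# Tab-separated readers and writers for p-value tables, binary call
# tables, atlases, sweep tables and flat fit summaries.
#
# Two dialects are accepted for p-value tables:
#   wide: trait <TAB> tissue <TAB> <method1> <TAB> <method2> ...
#   long: trait <TAB> tissue <TAB> method <TAB> pvalue
# Missing p-values are empty fields or "NA".

#' Read a p-value table
#'
#' Parses a tab-separated p-value table in wide or long layout into an
#' `n` by `K` matrix with a `pairs` attribute (`trait`, `tissue`).
#' Duplicate (trait, tissue, method) entries and p-values outside
#' `[0, 1]` are errors; missing values are allowed and can be removed
#' with [drop_incomplete()].
#'
#' @param path file path.
#' @param layout `"auto"` (default; a file whose third column is named
#'   `method` is treated as long), `"wide"` or `"long"`.
#' @return a numeric matrix of p-values, methods in columns.
#' @export
read_pvalue_table <- function(path, layout = c("auto", "wide", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop_validation("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          na.strings = c("NA", ""),
                          check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop_validation("p-value table needs at least 3 columns")
  if (layout == "auto")
    layout <- if (tolower(colnames(df)[3L]) == "method" &&
                  ncol(df) == 4L) "long" else "wide"
  if (layout == "long") {
    if (ncol(df) != 4L)
      stop_validation("long layout requires exactly 4 columns: ",
                      "trait, tissue, method, pvalue")
    colnames(df) <- c("trait", "tissue", "method", "pvalue")
    key <- paste(df$trait, df$tissue, df$method, sep = "\r")
    if (anyDuplicated(key))
      stop_validation("duplicate (trait, tissue, method) entries, e.g. row ",
                      which(duplicated(key))[1L])
    df$pvalue <- as.numeric(df$pvalue)
    methods <- unique(df$method)
    pair_key <- paste(df$trait, df$tissue, sep = "\r")
    pairs_u <- !duplicated(pair_key)
    pairs <- data.frame(trait = df$trait[pairs_u],
                        tissue = df$tissue[pairs_u],
                        stringsAsFactors = FALSE)
    P <- matrix(NA_real_, nrow(pairs), length(methods),
                dimnames = list(NULL, methods))
    P[cbind(match(pair_key, pair_key[pairs_u]),
            match(df$method, methods))] <- df$pvalue
  } else {
    pair_key <- paste(df[[1L]], df[[2L]], sep = "\r")
    if (anyDuplicated(pair_key))
      stop_validation("duplicate (trait, tissue) rows, e.g. row ",
                      which(duplicated(pair_key))[1L])
    pairs <- data.frame(trait = as.character(df[[1L]]),
                        tissue = as.character(df[[2L]]),
                        stringsAsFactors = FALSE)
    pv <- df[, -(1:2), drop = FALSE]
    P <- vapply(pv, function(col) as.numeric(col), numeric(nrow(df)))
    P <- matrix(P, nrow = nrow(df), dimnames = list(NULL, colnames(pv)))
  }
  bad <- !is.na(P) & (P < 0 | P > 1)
  if (any(bad))
    stop_validation("p-value outside [0, 1] for pair '",
                    pairs$trait[which(rowSums(bad) > 0)[1L]], "', '",
                    pairs$tissue[which(rowSums(bad) > 0)[1L]], "'")
  attr(P, "pairs") <- pairs
  P
}

#' Write a p-value or binary call table in the wide dialect
#'
#' @param x a matrix with a `pairs` attribute (as made by the readers or
#'   simulators); binary and p-value matrices are both accepted.
#' @param path output file path.
#' @param digits significant digits for numeric entries.
#' @return `path`, invisibly.
#' @export
write_wide_table <- function(x, path, digits = 15) {
  pairs <- attr(x, "pairs")
  if (is.null(pairs))
    pairs <- data.frame(trait = rownames(x) %||% paste0("pair", seq_len(nrow(x))),
                        tissue = "")
  df <- data.frame(pairs,
                   apply(x, 2L, function(col) format(col, digits = digits,
                                                     trim = TRUE)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("trait", "tissue", colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a fit (and optional bootstrap) as flat key/value text
#'
#' One `key<TAB>value` line per quantity, full precision: the estimates,
#' specificities, per-method FDRs, log-likelihood, convergence metadata
#' and (when given) bootstrap standard errors.
#'
#' @param fit an [lc_fit()] result.
#' @param path output file path.
#' @param boot optional [lc_boot()] result.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path, boot = NULL) {
  if (!inherits(fit, "lcfit")) stop_validation("fit must be an lc_fit() result")
  kv <- c(coef(fit),
          stats::setNames(fit$specificity,
                          paste0("specificity.", names(fit$specificity))),
          stats::setNames(method_fdr(fit$phi, fit$psi, fit$rho),
                          paste0("fdr.", names(fit$phi))),
          loglik = fit$loglik, n = fit$n, K = fit$K,
          converged = as.integer(fit$converged),
          label_swapped = as.integer(fit$label_swapped),
          n_starts = fit$n_starts, seed = fit$seed)
  if (!is.null(boot)) {
    kv <- c(kv,
            stats::setNames(boot$se, paste0("se.", names(boot$se))),
            B = boot$B, B_eff = boot$B_eff)
  }
  writeLines(paste(names(kv), format(kv, digits = 17, trim = TRUE),
                   sep = "\t"), path)
  invisible(path)
}

#' Write a combined association atlas as TSV
#'
#' Writes the [score_atlas()] table with six-decimal numeric columns and
#' a sidecar footer file (`<path>.summary`) carrying the overall FDR and
#' the discovery count.
#'
#' @param atlas an [score_atlas()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  df <- as.data.frame(atlas)
  df$score <- fmt6(df$score)
  df$fdr <- fmt6(df$fdr)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(paste0("n_pos\t", attr(atlas, "n_pos")),
               paste0("overall_fdr\t", fmt6(attr(atlas, "overall_fdr"))),
               paste0("fdr_cut\t", attr(atlas, "fdr_cut"))),
             paste0(path, ".summary"))
  invisible(path)
}

#' Write a threshold sweep table as TSV
#'
#' @param sweep an [lc_sweep()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  df <- as.data.frame(sweep)
  for (col in c("tpr", "tpr_se", "fpr", "fpr_se", "rho", "fdr"))
    df[[col]] <- ifelse(is.na(df[[col]]), "NA", fmt6(df[[col]]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
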