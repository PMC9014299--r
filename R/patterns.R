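# Outcome patterns and their counts: the sufficient statistic of the
# latent class likelihood. All estimation works on pattern counts, so one
# likelihood evaluation costs O(2^K) regardless of the number of pairs.

#' Enumerate all K-bit outcome patterns
#'
#' Returns the `2^K` joint call patterns of `K` binary methods in a fixed
#' order: row `j` is the K-bit binary expansion of `j - 1` with method 1 as
#' the most significant bit, so for `K = 3` the rows are
#' `000, 001, 010, ..., 111`.
#'
#' @param K number of methods (positive integer).
#' @return a `2^K` by `K` integer matrix with pattern strings as row names.
#' @examples
#' all_patterns(2)
#' @export
all_patterns <- function(K) {
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop_validation("K must be a positive integer")
  idx <- 0:(2^K - 1)
  pat <- vapply(seq_len(K), function(k) as.integer(idx %/% 2^(K - k) %% 2),
                integer(2^K))
  pat <- matrix(pat, nrow = 2^K, ncol = K)
  rownames(pat) <- apply(pat, 1L, paste, collapse = "")
  pat
}

# Map each row of a 0/1 matrix to its 1-based pattern index.
pattern_index <- function(Y) {
  K <- ncol(Y)
  as.integer(Y %*% 2^((K - 1):0)) + 1L
}

#' Tabulate joint outcome patterns
#'
#' Counts how often each of the `2^K` joint call patterns occurs among the
#' rows of a binary outcome matrix. The resulting table is the sufficient
#' statistic for the latent class likelihood: all fitting functions accept
#' it in place of row-level data.
#'
#' @param Y an `n` by `K` matrix of 0/1 calls (rows = hypothesis pairs,
#'   columns = methods), or an object with an `$Y` component such as the
#'   result of [sim_binary()].
#' @return an object of class `"pattern_table"`: an integer vector of
#'   length `2^K` named by pattern string, with attributes `K`, `n` and
#'   `methods`.
#' @examples
#' Y <- rbind(c(1, 1, 1), c(0, 0, 0), c(1, 1, 1))
#' pattern_table(Y)
#' @export
pattern_table <- function(Y) {
  if (is.list(Y) && !is.null(Y$Y)) Y <- Y$Y
  if (inherits(Y, "pattern_table")) return(Y)
  Y <- as_binary_matrix(Y)
  K <- ncol(Y)
  counts <- tabulate(pattern_index(Y), nbins = 2^K)
  names(counts) <- rownames(all_patterns(K))
  structure(counts, K = K, n = nrow(Y), methods = colnames(Y),
            class = "pattern_table")
}

#' @export
print.pattern_table <- function(x, ...) {
  cat("Joint outcome pattern counts (", attr(x, "K"), " methods, n = ",
      attr(x, "n"), ")\n", sep = "")
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}
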