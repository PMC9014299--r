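# Internal helpers: validation, clipping, seed streams.

# Clip probabilities away from {0, 1} so logs and logits stay finite.
PROB_EPS <- 1e-10

clip01 <- function(x, eps = PROB_EPS) pmin(pmax(x, eps), 1 - eps)

# Validation errors carry their own condition class so the command-line
# driver can map them to a distinct exit code.
stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("lcdiag_validation", "error")))
}

#' Validate a binary outcome matrix
#'
#' Coerces `x` to an integer matrix of 0/1 calls (rows = hypothesis pairs,
#' columns = methods) and checks that no entry is missing or outside
#' \{0, 1\}. Column names are kept (or invented as `method1`, ...).
#'
#' @param x a matrix or data frame of 0/1 calls.
#' @return an integer matrix with dimnames.
#' @keywords internal
as_binary_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop_validation("binary outcomes must be a matrix")
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop_validation("binary outcome matrix must have at least one row and column")
  if (anyNA(x))
    stop_validation("binary outcome matrix contains missing values")
  if (!all(x == 0L | x == 1L))
    stop_validation("binary outcome matrix entries must be 0 or 1")
  storage.mode(x) <- "integer"
  if (is.null(colnames(x))) colnames(x) <- paste0("method", seq_len(ncol(x)))
  x
}

check_oc <- function(rho, phi, psi) {
  if (length(rho) != 1L || is.na(rho) || rho < 0 || rho > 1)
    stop_validation("rho must be a single probability in [0, 1]")
  if (length(phi) != length(psi))
    stop_validation("phi and psi must have the same length")
  if (anyNA(phi) || anyNA(psi) || any(phi < 0 | phi > 1) || any(psi < 0 | psi > 1))
    stop_validation("phi and psi must be probabilities in [0, 1]")
  invisible(TRUE)
}

# Derive independent child seeds from one root seed without disturbing the
# caller's RNG state more than necessary. Kept below .Machine$integer.max.
derive_seeds <- function(seed, m) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, m)
}

fmt6 <- function(x) formatC(x, digits = 6, format = "f")
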