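# Maximum-likelihood estimation of (rho, phi, psi) from joint pattern
# counts, by multi-start quasi-Newton optimization on the logit scale or
# by EM. The two routes are algorithmically independent and are
# cross-checked in the test suite.

# --- parameter packing ------------------------------------------------

pack_logit <- function(rho, phi, psi) stats::qlogis(clip01(c(rho, phi, psi)))

unpack_logit <- function(z, K) {
  p <- stats::plogis(z)
  list(rho = p[1L], phi = p[2:(K + 1)], psi = p[(K + 2):(2 * K + 1)])
}

# Negative log-likelihood and its analytic gradient on the logit scale.
# `pat` is the full 2^K pattern matrix, `cnt` the counts.
neg_loglik_logit <- function(z, pat, cnt, K) {
  th <- unpack_logit(z, K)
  A <- class_cond_prob(pat, th$phi)
  B <- class_cond_prob(pat, th$psi)
  -sum(cnt * log(clip01(th$rho * A + (1 - th$rho) * B)))
}

neg_grad_logit <- function(z, pat, cnt, K) {
  th <- unpack_logit(z, K)
  A <- as.numeric(class_cond_prob(pat, th$phi))
  B <- as.numeric(class_cond_prob(pat, th$psi))
  P <- clip01(th$rho * A + (1 - th$rho) * B)
  w <- cnt / P
  # d/d logit(rho); logistic chain rule gives the rho(1-rho) factor
  g_rho <- sum(w * (A - B)) * th$rho * (1 - th$rho)
  # d/d logit(phi_k) = sum_y w(y) rho A(y) (y_k - phi_k), similarly psi
  g_phi <- th$rho * colSums(w * A * sweep(pat, 2L, th$phi))
  g_psi <- (1 - th$rho) * colSums(w * B * sweep(pat, 2L, th$psi))
  -c(g_rho, g_phi, g_psi)
}

# Moment-flavoured start: prevalence 0.5, sensitivities a little above and
# false-positive rates a little below each method's raw positive rate.
moment_start <- function(table) {
  K <- attr(table, "K")
  pat <- all_patterns(K)
  pos_rate <- as.numeric(crossprod(pat, as.numeric(table))) / attr(table, "n")
  list(rho = 0.5,
       phi = pmin(pos_rate + 0.15, 0.99),
       psi = pmax(pos_rate - 0.15, 0.01))
}

apply_label_convention <- function(rho, phi, psi) {
  # The likelihood is invariant under (rho, phi, psi) -> (1-rho, psi, phi)
  # (relabelling the latent classes). Resolve by requiring the summed
  # Youden index sum_k (phi_k - psi_k) to be nonnegative: the methods are
  # assumed jointly informative rather than anti-informative.
  swapped <- sum(phi - psi) < 0
  if (swapped) {
    tmp <- phi; phi <- psi; psi <- tmp
    rho <- 1 - rho
  }
  list(rho = rho, phi = phi, psi = psi, swapped = swapped)
}

# --- fitting engines --------------------------------------------------

fit_ml_engine <- function(table, n_starts, seed, tol) {
  K <- attr(table, "K")
  pat <- all_patterns(K)
  cnt <- as.numeric(table)
  starts <- list(moment_start(table))
  if (n_starts > 1L) {
    set.seed(seed)
    for (s in seq_len(n_starts - 1L)) {
      starts[[s + 1L]] <- list(rho = stats::runif(1, 0.05, 0.95),
                               phi = stats::runif(K, 0.05, 0.95),
                               psi = stats::runif(K, 0.05, 0.95))
    }
  }
  best <- NULL
  for (st in starts) {
    opt <- try(stats::optim(pack_logit(st$rho, st$phi, st$psi),
                            fn = neg_loglik_logit, gr = neg_grad_logit,
                            pat = pat, cnt = cnt, K = K,
                            method = "BFGS",
                            control = list(maxit = 500L, reltol = tol)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all optimization starts failed")
  # polish once from the winner so the optimum is resolved tightly
  best <- stats::optim(best$par, fn = neg_loglik_logit, gr = neg_grad_logit,
                       pat = pat, cnt = cnt, K = K, method = "BFGS",
                       control = list(maxit = 500L, reltol = tol))
  th <- unpack_logit(best$par, K)
  list(rho = th$rho, phi = th$phi, psi = th$psi,
       loglik = -best$value, converged = best$convergence == 0L)
}

fit_em_engine <- function(table, tol, max_iter, start = NULL) {
  K <- attr(table, "K")
  pat <- all_patterns(K)
  cnt <- as.numeric(table)
  n <- attr(table, "n")
  if (is.null(start)) start <- moment_start(table)
  rho <- start$rho; phi <- start$phi; psi <- start$psi
  ll_old <- -Inf
  converged <- FALSE
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    A <- as.numeric(class_cond_prob(pat, phi))
    B <- as.numeric(class_cond_prob(pat, psi))
    P <- clip01(rho * A + (1 - rho) * B)
    ll <- sum(cnt * log(P))
    trace[it] <- ll
    if (ll - ll_old < tol && it > 1L) { converged <- TRUE; break }
    ll_old <- ll
    gamma <- rho * A / P            # E-step: P(A = 1 | pattern)
    w1 <- cnt * gamma
    w0 <- cnt * (1 - gamma)
    rho <- clip01(sum(w1) / n)      # M-step: weighted positive rates
    phi <- clip01(as.numeric(crossprod(pat, w1)) / sum(w1))
    psi <- clip01(as.numeric(crossprod(pat, w0)) / sum(w0))
  }
  list(rho = rho, phi = phi, psi = psi,
       loglik = lc_loglik(rho, phi, psi, table), converged = converged,
       trace = trace)
}

# --- user-facing fit --------------------------------------------------

#' Fit the latent class model for test operating characteristics
#'
#' Estimates the prevalence of true associations `rho`, the sensitivity
#' `phi_k` and the false-positive rate `psi_k` of each of `K >= 3` binary
#' testing methods applied to the same hypotheses, without a
#' gold-standard reference. Identifiability requires at least three
#' conditionally independent methods, since the joint patterns carry
#' `2^K - 1` degrees of freedom against `2K + 1` free parameters.
#'
#' Two fitting routes are available. `method = "ml"` (default) maximizes
#' the likelihood directly by quasi-Newton (BFGS) iteration on the logit
#' scale, from one moment-based start plus `n_starts - 1` random starts,
#' keeping the best optimum. `method = "em"` runs
#' expectation-maximization from the moment start; its log-likelihood is
#' non-decreasing across iterations. Both routes resolve the latent-class
#' labelling ambiguity by requiring `sum_k (phi_k - psi_k) >= 0`.
#'
#' @param Y an `n` by `K` binary outcome matrix (0/1 calls), a
#'   [pattern_table()], or a simulated dataset from [sim_binary()].
#' @param method `"ml"` for multi-start quasi-Newton maximum likelihood,
#'   `"em"` for expectation-maximization.
#' @param n_starts total number of optimization starts for `"ml"` (the
#'   moment start plus `n_starts - 1` random starts).
#' @param seed integer seed for the random starts.
#' @param tol convergence tolerance: relative function tolerance for
#'   BFGS, absolute log-likelihood gain per iteration for EM.
#' @param max_iter maximum EM iterations.
#' @return an object of class `"lcfit"` with components `rho`, `phi`,
#'   `psi` (the estimates after label resolution), `specificity`
#'   (`1 - psi`), `loglik`, `converged`, `label_swapped`, `method`,
#'   `n_starts`, `seed`, `table` (the pattern table fitted), `n` and `K`.
#' @examples
#' sim <- sim_binary(2000, rho = 0.3, phi = c(0.8, 0.7, 0.6),
#'                   psi = c(0.1, 0.2, 0.3), seed = 1)
#' fit <- lc_fit(sim)
#' coef(fit)
#' @seealso [lc_boot()] for standard errors, [score_atlas()] for combining
#'   the calls into association scores and FDRs.
#' @export
lc_fit <- function(Y, method = c("ml", "em"), n_starts = 20L, seed = 1L,
                   tol = NULL, max_iter = 10000L) {
  method <- match.arg(method)
  table <- pattern_table(Y)
  K <- attr(table, "K")
  n <- attr(table, "n")
  if (K < 3L)
    stop_validation("at least 3 methods are required for identifiability: ",
                    "2^K - 1 >= 2K + 1 fails for K = ", K)
  if (n < 2L * K + 1L)
    warning("fewer observations (", n, ") than free parameters (",
            2L * K + 1L, "); estimates will be unstable")
  if (max(table) == attr(table, "n"))
    warning("all rows share one outcome pattern; estimates lie on the ",
            "parameter boundary")
  if (is.null(tol)) tol <- if (method == "ml") 1e-14 else 1e-10
  eng <- if (method == "ml") {
    fit_ml_engine(table, n_starts = as.integer(n_starts), seed = seed,
                  tol = tol)
  } else {
    fit_em_engine(table, tol = tol, max_iter = as.integer(max_iter))
  }
  lab <- apply_label_convention(eng$rho, eng$phi, eng$psi)
  methods <- attr(table, "methods")
  if (is.null(methods)) methods <- paste0("method", seq_len(K))
  structure(list(rho = lab$rho,
                 phi = stats::setNames(lab$phi, methods),
                 psi = stats::setNames(lab$psi, methods),
                 specificity = stats::setNames(1 - lab$psi, methods),
                 loglik = eng$loglik,
                 converged = eng$converged,
                 label_swapped = lab$swapped,
                 method = method,
                 n_starts = if (method == "ml") as.integer(n_starts) else 1L,
                 trace = eng$trace,
                 seed = as.integer(seed),
                 table = table, n = n, K = K),
            class = "lcfit")
}
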