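#' Factorization parameters
#'
#' Configuration for the sparse nonnegative matrix factorization. The
#' objective minimized is
#' \deqn{\|D - P'S'\|_F^2 + \eta \|P'\|_F^2 + \beta \sum_j \|S'_{\cdot j}\|_1^2}
#' with both factors elementwise nonnegative: an alternating
#' nonnegativity-constrained least-squares scheme in which the L1-squared
#' penalty on each sample's composition column promotes sparse strain usage
#' and the Frobenius penalty on the content factor resolves the scaling
#' indeterminacy of the factorization.
#'
#' @param rank number of strains K (factorization rank).
#' @param sparsity_weight beta, the L1-squared penalty weight on composition
#'   columns. Default 0.01.
#' @param smoothness_weight eta, the Frobenius penalty on the content factor;
#'   a small value suffices to resolve the scaling indeterminacy without
#'   shrinking genuine low-abundance strains. Default 0.01.
#' @param max_iter maximum number of alternating iterations. Default 2000.
#' @param tol relative objective-change convergence tolerance. Default 1e-6.
#' @param n_restarts number of random restarts; the fit with the smallest
#'   objective is kept. Default 3.
#' @param seed integer seed controlling the random initializations.
#' @return a `factorize_params` list.
#' @export
factorize_params <- function(rank,
                             sparsity_weight = 0.01,
                             smoothness_weight = 0.01,
                             max_iter = 2000,
                             tol = 1e-6,
                             n_restarts = 3,
                             seed = 1L) {
  stopifnot(rank >= 1, sparsity_weight >= 0, max_iter >= 1, tol > 0,
            n_restarts >= 1)
  stopifnot(smoothness_weight >= 0)
  structure(list(rank = as.integer(rank),
                 sparsity_weight = sparsity_weight,
                 smoothness_weight = smoothness_weight,
                 max_iter = as.integer(max_iter),
                 tol = tol,
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "factorize_params")
}

#' Sparse NMF of a gene-family abundance matrix
#'
#' Factorizes the preprocessed abundance matrix `D` (N gene families x S
#' samples) into a nonnegative raw gene-content factor `P` (N x K) and a
#' nonnegative raw composition factor `S` (K x S), alternating exact
#' nonnegative least-squares solves for each factor (block principal
#' pivoting on the normal equations). Each block solve is an exact
#' minimizer, so the penalized objective is non-increasing across
#' iterations. Only the content factor is randomly initialized; the first
#' half-step solves the composition factor, which makes the fit equivariant
#' under sample permutations at a fixed seed.
#'
#' @param D a [gene_family_matrix()] (preprocessed: no all-zero rows or
#'   columns).
#' @param params a [factorize_params()].
#' @return list with `P` (N x K), `S` (K x S), `residual` (relative Frobenius
#'   reconstruction error), `objective`, `objective_trace` (per-iteration,
#'   best restart), `converged`, `iterations`, `restart` (index of the best
#'   restart).
#' @export
fit_snmf <- function(D, params) {
  m <- unclass(D)
  N <- nrow(m); S <- ncol(m); K <- params$rank
  if (K > min(N, S)) stop(sprintf("rank %d exceeds min(N, S) = %d", K, min(N, S)))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("D must not contain all-zero rows or columns; run trim_and_filter first")
  }
  eta <- params$smoothness_weight
  beta <- params$sparsity_weight

  best <- NULL
  for (r in seq_len(params$n_restarts)) {
    fit <- withr::with_seed(params$seed + r - 1L,
                            snmf_once(m, K, eta, beta, params$max_iter, params$tol))
    if (is.null(best) || fit$objective < best$objective) {
      best <- fit
      best$restart <- r
    }
  }
  rownames(best$P) <- rownames(m)
  colnames(best$S) <- colnames(m)
  best$residual <- norm(m - best$P %*% best$S, "F") / norm(m, "F")
  if (!best$converged) {
    warning(sprintf("snmf did not reach tol %.1e within %d iterations",
                    params$tol, params$max_iter))
  }
  best
}

snmf_once <- function(m, K, eta, beta, max_iter, tol) {
  N <- nrow(m); S <- ncol(m)
  # scale of initialization: entries of P*S should match the data magnitude
  scale0 <- sqrt(mean(m) / K)
  P <- matrix(runif(N * K, 0, 2 * scale0), N, K)
  Smat <- NULL
  obj <- Inf
  trace <- numeric(0)
  converged <- FALSE
  ones <- matrix(1, K, K)
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    # composition update: rows of the augmented design are [P; sqrt(beta) 1']
    Smat <- nnls_bpp(crossprod(P) + beta * ones, crossprod(P, m))
    # content update (transposed system): design [S'; sqrt(eta) I]
    P <- t(nnls_bpp(tcrossprod(Smat) + eta * diag(K), tcrossprod(Smat, m)))
    R <- m - P %*% Smat
    obj_new <- sum(R^2) + eta * sum(P^2) + beta * sum(colSums(Smat)^2)
    trace <- c(trace, obj_new)
    if (is.finite(obj) && abs(obj - obj_new) <= tol * max(obj, .Machine$double.eps)) {
      obj <- obj_new
      converged <- TRUE
      break
    }
    obj <- obj_new
  }
  list(P = P, S = Smat, objective = obj, objective_trace = trace,
       converged = converged, iterations = it)
}
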