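#' Scale a raw composition factor into relative abundances
#'
#' @param raw K x S nonnegative matrix (strains x samples).
#' @return matrix of the same shape whose columns each sum to 1.
#' @export
scale_composition <- function(raw) {
  raw <- as.matrix(raw)
  if (any(raw < 0)) stop("composition factor must be nonnegative")
  cs <- colSums(raw)
  if (any(cs == 0)) {
    bad <- colnames(raw)[cs == 0] %||% which(cs == 0)
    stop(sprintf("all-zero composition column for sample(s): %s",
                 paste(bad, collapse = ", ")))
  }
  sweep(raw, 2, cs, "/")
}

#' Rank-selection configuration
#'
#' Candidate strain numbers are screened against three plausibility criteria:
#' every strain's mean relative abundance across samples must exceed `tau2`;
#' every strain's called gene-family count must exceed `tau3 * g_min`; and
#' every pair of strains' binary gene-content profiles must be separated by a
#' Jaccard distance above `tau1`. These reject over-split solutions in which
#' a surplus strain is rare, under-sized, or a near-duplicate.
#'
#' @param rank_min,rank_max candidate range for the number of strains.
#'   Defaults 1 and 12.
#' @param tau1 minimum pairwise Jaccard distance between strain profiles.
#'   Default 0.1.
#' @param tau2 minimum mean strain relative abundance. Default 0.1.
#' @param tau3 minimum gene-family count as a fraction of `g_min`. Default 0.5.
#' @param theta_fraction fraction of `p_max` used as the presence threshold.
#'   Default 0.5.
#' @return a `rank_select_config` list.
#' @export
rank_select_config <- function(rank_min = 1, rank_max = 12,
                               tau1 = 0.1, tau2 = 0.1, tau3 = 0.5,
                               theta_fraction = 0.5) {
  stopifnot(rank_min >= 1, rank_max >= rank_min,
            tau1 > 0, tau1 < 1, tau2 > 0, tau2 < 1,
            tau3 > 0, tau3 <= 1,
            theta_fraction > 0, theta_fraction < 1)
  structure(list(rank_min = as.integer(rank_min),
                 rank_max = as.integer(rank_max),
                 tau1 = tau1, tau2 = tau2, tau3 = tau3,
                 theta_fraction = theta_fraction),
            class = "rank_select_config")
}

# factorize at rank K, binarize, re-estimate composition; shared by
# evaluate_rank and the final fit. The raw factors of an NMF are only
# determined up to a benign mixing on the exact-solution manifold, which the
# binarization absorbs for gene content but which biases the raw composition
# factor; refitting the composition by nonnegative least squares against the
# binarized (truly 0/1) content matrix honors the stated model D = P * S and
# removes both the per-strain scale ambiguity and the mixing bias.
fit_at_rank <- function(D, K, params, stats, cfg) {
  params$rank <- as.integer(K)
  fit <- fit_snmf(D, params)
  bin <- apply_binarization(fit$P, stats$g_expected, cfg$theta_fraction)
  comp <- refit_composition(unclass(D), bin$presence, fit$S)
  list(fit = fit, composition = comp, presence = bin$presence,
       confidence = bin$confidence, p_max = bin$p_max, theta = bin$theta)
}

refit_composition <- function(m, presence, raw_S) {
  Sref <- nnls_bpp(crossprod(presence), crossprod(presence, m))
  # a strain with no called families contributes nothing to the refit; fall
  # back to the raw factor for degenerate columns so normalization stays total
  bad <- colSums(Sref) == 0
  if (any(bad)) Sref[, bad] <- raw_S[, bad]
  still <- colSums(Sref) == 0
  if (any(still)) Sref[1, still] <- 1
  dimnames(Sref) <- dimnames(raw_S)
  scale_composition(Sref)
}

apply_binarization <- function(P, expected_count, theta_fraction) {
  K <- ncol(P)
  presence <- matrix(0L, nrow(P), K, dimnames = dimnames(P))
  confidence <- matrix(0, nrow(P), K, dimnames = dimnames(P))
  p_max <- numeric(K); theta <- numeric(K)
  for (j in seq_len(K)) {
    b <- binarize_gene_content(P[, j], expected_count, theta_fraction)
    presence[, j] <- b$presence
    confidence[, j] <- b$confidence
    p_max[j] <- b$p_max
    theta[j] <- b$theta
  }
  list(presence = presence, confidence = confidence, p_max = p_max, theta = theta)
}

#' Evaluate the plausibility criteria at one candidate rank
#'
#' @param D preprocessed [gene_family_matrix()].
#' @param K candidate number of strains.
#' @param params [factorize_params()].
#' @param stats [pangenome_stats()].
#' @param cfg [rank_select_config()].
#' @return a `rank_diagnostics` list recording, for each criterion, the
#'   pass/fail outcome and the offending strain(s) or pair(s).
#' @export
evaluate_rank <- function(D, K, params, stats, cfg = rank_select_config()) {
  f <- fit_at_rank(D, K, params, stats, cfg)
  diagnose_rank(K, f, stats, cfg)
}

diagnose_rank <- function(K, f, stats, cfg) {
  mean_ab <- rowMeans(f$composition)
  fail_ab <- which(!(mean_ab > cfg$tau2))
  gene_counts <- colSums(f$presence)
  fail_size <- which(!(gene_counts > cfg$tau3 * stats$g_min))
  fail_pairs <- list()
  min_jd <- NA_real_
  if (K >= 2) {
    jd <- matrix(NA_real_, K, K)
    for (a in seq_len(K - 1)) for (b in (a + 1):K) {
      # two empty profiles are indistinguishable: distance 0 (fails tau1)
      jd[a, b] <- if (sum(f$presence[, a]) + sum(f$presence[, b]) == 0) 0
                  else jaccard_distance(f$presence[, a], f$presence[, b])
      if (!(jd[a, b] > cfg$tau1)) fail_pairs[[length(fail_pairs) + 1]] <- c(a, b)
    }
    min_jd <- min(jd, na.rm = TRUE)
  }
  structure(list(
    rank = as.integer(K),
    mean_abundance = mean_ab,
    gene_counts = gene_counts,
    min_pairwise_jaccard = min_jd,
    abundance_ok = length(fail_ab) == 0,
    size_ok = length(fail_size) == 0,
    separation_ok = length(fail_pairs) == 0,
    failing_strains_abundance = fail_ab,
    failing_strains_size = fail_size,
    failing_pairs = fail_pairs,
    objective = f$fit$objective,
    residual = f$fit$residual,
    pass = length(fail_ab) == 0 && length(fail_size) == 0 &&
      length(fail_pairs) == 0
  ), class = "rank_diagnostics")
}

#' @export
print.rank_diagnostics <- function(x, ...) {
  cat(sprintf("rank %d: %s (abundance %s, size %s, separation %s)\n",
              x$rank, if (x$pass) "PASS" else "fail",
              x$abundance_ok, x$size_ok, x$separation_ok))
  invisible(x)
}

#' Select the number of strains
#'
#' Evaluates every candidate rank in `[rank_min, min(rank_max, N, S)]` and
#' returns the largest rank at which the fitted solution satisfies all three
#' plausibility criteria (see [rank_select_config()]). Rank 1 is returned
#' when no multi-strain solution passes. The criteria reject over-split
#' solutions, so the selected rank is the largest strain number the data can
#' support without producing a rare, under-sized, or duplicated strain.
#'
#' @inheritParams evaluate_rank
#' @return list with `rank` (selected K) and `diagnostics` (one
#'   `rank_diagnostics` per candidate).
#' @export
select_rank <- function(D, params, stats, cfg = rank_select_config()) {
  kmax <- min(cfg$rank_max, nrow(D), ncol(D))
  kmin <- min(cfg$rank_min, kmax)
  candidates <- seq(kmin, kmax)
  diagnostics <- lapply(candidates, function(K)
    evaluate_rank(D, K, params, stats, cfg))
  names(diagnostics) <- paste0("K", candidates)
  passing <- candidates[vapply(diagnostics, `[[`, logical(1), "pass")]
  rank <- if (length(passing)) max(passing) else 1L
  list(rank = as.integer(rank), diagnostics = diagnostics)
}

#' Decompose a gene-family profile into strain content and composition
#'
#' The main entry point. Decomposes a preprocessed gene-family abundance
#' matrix `D` into a binary gene-content matrix `P` (gene families x strains,
#' with raw weights and per-call confidence scores) and a strain composition
#' matrix `S` (strains x samples, columns summing to 1) by sparse NMF
#' followed by composition scaling and density-based binarization. The
#' number of strains is selected automatically by [select_rank()] unless
#' `rank` is supplied. Strains are ordered by decreasing mean relative
#' abundance (ties by gene-family count, then index).
#'
#' @param D preprocessed [gene_family_matrix()] (see [trim_and_filter()]).
#' @param stats [pangenome_stats()] of the species pangenome.
#' @param params [factorize_params()]; its `rank` field is ignored (set per
#'   candidate). Pass `rank` here to fix the number of strains.
#' @param cfg [rank_select_config()].
#' @param rank optional user-specified number of strains, bypassing
#'   selection.
#' @return an object of class `pandec_fit` with components `presence`,
#'   `raw_weights`, `confidence` (N x K matrices), `composition` (K x S),
#'   `p_max`, `theta` (per strain), `rank`, `rank_diagnostics`, `residual`,
#'   `seed`, `preprocess_log` (NULL unless attached by the caller).
#' @export
pan_decompose <- function(D, stats,
                          params = factorize_params(rank = 1),
                          cfg = rank_select_config(),
                          rank = NULL) {
  if (is.null(rank)) {
    sel <- select_rank(D, params, stats, cfg)
    rank <- sel$rank
    diagnostics <- sel$diagnostics
  } else {
    rank <- as.integer(rank)
    if (rank > min(nrow(D), ncol(D))) {
      stop(sprintf("requested rank %d exceeds min(N, S) = %d",
                   rank, min(nrow(D), ncol(D))))
    }
    diagnostics <- list()
  }
  f <- fit_at_rank(D, rank, params, stats, cfg)

  ord <- order(-rowMeans(f$composition), -colSums(f$presence), seq_len(rank))
  strain_ids <- paste0("strain", seq_len(rank))
  P <- f$fit$P[, ord, drop = FALSE]
  presence <- f$presence[, ord, drop = FALSE]
  confidence <- f$confidence[, ord, drop = FALSE]
  composition <- f$composition[ord, , drop = FALSE]
  colnames(P) <- colnames(presence) <- colnames(confidence) <- strain_ids
  rownames(composition) <- strain_ids

  structure(list(
    presence = presence,
    raw_weights = P,
    confidence = confidence,
    composition = composition,
    p_max = setNames(f$p_max[ord], strain_ids),
    theta = setNames(f$theta[ord], strain_ids),
    rank = as.integer(rank),
    rank_diagnostics = diagnostics,
    residual = f$fit$residual,
    converged = f$fit$converged,
    seed = params$seed,
    preprocess_log = NULL
  ), class = "pandec_fit")
}

#' @export
print.pandec_fit <- function(x, ...) {
  cat(sprintf("pandec_fit: %d strains over %d gene families x %d samples\n",
              x$rank, nrow(x$presence), ncol(x$composition)))
  cat(sprintf("  relative reconstruction error: %.4f\n", x$residual))
  cat("  mean strain relative abundances:",
      paste(sprintf("%.3f", rowMeans(x$composition)), collapse = ", "), "\n")
  cat("  gene families per strain:",
      paste(colSums(x$presence), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a strain decomposition into a long data frame
#'
#' @param x a `pandec_fit`.
#' @param matrix which component to tidy: `"composition"` (strain, sample,
#'   abundance) or `"gene_content"` (family, strain, weight, presence,
#'   confidence).
#' @param ... unused.
#' @return a data frame in long format.
#' @export
tidy.pandec_fit <- function(x, matrix = c("composition", "gene_content"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "composition") {
    df <- expand.grid(strain = rownames(x$composition),
                      sample = colnames(x$composition),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    df$abundance <- as.vector(x$composition)
    df
  } else {
    df <- expand.grid(gene_family = rownames(x$presence),
                      strain = colnames(x$presence),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    df$weight <- as.vector(x$raw_weights)
    df$presence <- as.vector(x$presence)
    df$confidence <- as.vector(x$confidence)
    df
  }
}

#' One-row summary of a strain decomposition
#'
#' @param x a `pandec_fit`.
#' @param ... unused.
#' @return a one-row data frame: rank, residual, convergence, gene-family
#'   count range and mean abundance range over strains.
#' @export
glance.pandec_fit <- function(x, ...) {
  gc <- colSums(x$presence)
  ma <- rowMeans(x$composition)
  data.frame(rank = x$rank,
             residual = x$residual,
             converged = x$converged,
             min_gene_count = min(gc), max_gene_count = max(gc),
             min_mean_abundance = min(ma), max_mean_abundance = max(ma))
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
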