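#' Binarize a strain's raw gene-content weights with confidence scores
#'
#' The raw content weights of a genuine strain are expected to be bimodal:
#' absent families near zero and present families in a tight cluster, because
#' the underlying content profile is binary. A Gaussian kernel density
#' (Silverman bandwidth, 512-point grid from 0 to the column maximum) is
#' fitted to the strictly positive weights and its local maxima enumerated;
#' the selected peak `p_max` is the one whose induced presence threshold
#' `theta = theta_fraction * p_max` calls a number of gene families
#' (`#\{weight >= theta\}`) closest to the expected per-genome gene-family
#' count, ties broken toward the larger peak location. This calibrates the
#' cut against the pangenome: a spurious low-weight mode (leftover numerical
#' noise below the present cluster) would call far more families than a
#' genome holds and is rejected. Weights at or above `theta` are called
#' present. Each call carries a confidence score:
#' \deqn{C = 1 \ \mathrm{if}\ p' \ge \theta; \quad (\theta - p')/\theta \
#' \mathrm{otherwise},}
#' so confidently-present and confidently-absent families both score near 1
#' and families near the threshold score near 0.
#'
#' Degenerate columns (fewer than 10 strictly positive weights, or all
#' positive weights equal) have no usable density structure; the threshold
#' then falls back to `theta_fraction * max(weight)` with a warning.
#'
#' @param weights nonnegative numeric vector of raw content weights for one
#'   strain (length = number of gene families).
#' @param expected_count expected number of gene families per genome
#'   (`g_expected` of the species pangenome).
#' @param theta_fraction fraction of `p_max` at which the density curve is
#'   cut. Default 0.5.
#' @return list with `presence` (0/1 integer vector), `confidence` (in
#'   `[0, 1]`), `p_max`, `theta`.
#' @export
binarize_gene_content <- function(weights, expected_count, theta_fraction = 0.5) {
  stopifnot(expected_count > 0, theta_fraction > 0, theta_fraction < 1)
  if (any(weights < 0)) stop("weights must be nonnegative")
  pos <- weights[weights > 0]
  degenerate <- length(pos) < 10 || diff(range(pos)) == 0
  if (degenerate) {
    if (length(pos) == 0) {
      warning("all-zero weight column: no gene family can be called present")
      p_max <- 0
      theta <- 0
      presence <- integer(length(weights))
      confidence <- rep(1, length(weights))
      return(list(presence = presence, confidence = confidence,
                  p_max = p_max, theta = theta))
    }
    warning("degenerate weight column (no density structure); falling back to theta = ",
            format(theta_fraction), " * max(weight)")
    p_max <- max(pos)
  } else {
    p_max <- density_peak(pos, expected_count, theta_fraction)
  }
  theta <- theta_fraction * p_max
  presence <- as.integer(weights >= theta)
  confidence <- ifelse(weights >= theta, 1, (theta - weights) / theta)
  list(presence = presence, confidence = confidence,
       p_max = p_max, theta = theta)
}

# peak of the KDE whose induced call count #{w >= theta_fraction * peak}
# best matches expected_count
density_peak <- function(pos, expected_count, theta_fraction) {
  d <- stats::density(pos, bw = "nrd0", n = 512, from = 0, to = max(pos))
  y <- d$y; x <- d$x
  n <- length(y)
  is_peak <- c(y[1] > y[2], y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] > y[3:n],
               y[n] > y[n - 1])
  peaks <- x[is_peak]
  if (!length(peaks)) peaks <- x[which.max(y)]
  call_counts <- vapply(peaks, function(p) sum(pos >= theta_fraction * p),
                        numeric(1))
  err <- abs(call_counts - expected_count)
  cand <- peaks[err == min(err)]
  max(cand)  # ties toward the larger peak location
}
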