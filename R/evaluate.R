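#' Jensen-Shannon divergence between strain compositions
#'
#' Both relative-abundance vectors are sorted in decreasing order and the
#' shorter one zero-padded, so that compositions are compared as abundance
#' distributions rather than by strain labels. The divergence uses base-2
#' logarithms, so it is symmetric and lies in `[0, 1]`; 0 is an exact
#' prediction.
#'
#' @param pred,truth nonnegative vectors summing to 1 (within 1e-9).
#' @return the Jensen-Shannon divergence (base 2).
#' @export
jsd <- function(pred, truth) {
  check_composition(pred, "pred")
  check_composition(truth, "truth")
  p <- sort(pred, decreasing = TRUE)
  q <- sort(truth, decreasing = TRUE)
  n <- max(length(p), length(q))
  length(p) <- n; length(q) <- n
  p[is.na(p)] <- 0; q[is.na(q)] <- 0
  js_divergence(p, q)
}

check_composition <- function(v, what) {
  if (any(v < 0)) stop(sprintf("%s has negative entries", what))
  if (abs(sum(v) - 1) > 1e-9) {
    stop(sprintf("%s does not sum to 1 (sum = %.12g)", what, sum(v)))
  }
  invisible(v)
}

#' Raw Jensen-Shannon divergence (base 2, no sorting or padding)
#'
#' @param p,q nonnegative vectors of equal length summing to 1.
#' @return divergence in `[0, 1]`; attains 1 for distributions with disjoint
#'   support, e.g. `(1, 0)` vs `(0, 1)`.
#' @export
js_divergence <- function(p, q) {
  stopifnot(length(p) == length(q))
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  d <- 0.5 * kl(p, m) + 0.5 * kl(q, m)
  min(max(d, 0), 1)  # clamp numerical noise at the interval ends
}

#' Matthews correlation coefficient
#'
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' 1 is an exact prediction, 0 a random one, -1 total disagreement. A zero
#' denominator (a degenerate confusion table) returns 0.
#'
#' @param tp,tn,fp,fn nonnegative confusion counts; alternatively pass a list
#'   with these elements as `tp`.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.list(tp)) {
    c_ <- tp; tp <- c_$tp; tn <- c_$tn; fp <- c_$fp; fn <- c_$fn
  }
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn > 0)
  denom <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

#' Jaccard distance between binary profiles or sets
#'
#' `1 - |A intersect B| / |A union B|` on the sets of present gene families.
#'
#' @param a,b binary vectors of equal length, or vectors of element IDs when
#'   `is_set = TRUE`.
#' @param is_set interpret `a` and `b` as sets of IDs rather than binary
#'   vectors.
#' @return distance in `[0, 1]`.
#' @export
jaccard_distance <- function(a, b, is_set = FALSE) {
  if (is_set) {
    a <- unique(a); b <- unique(b)
    un <- length(union(a, b))
    if (un == 0) stop("both sets are empty")
    return(1 - length(intersect(a, b)) / un)
  }
  stopifnot(length(a) == length(b))
  a <- a > 0; b <- b > 0
  un <- sum(a | b)
  if (un == 0) stop("both profiles are empty")
  1 - sum(a & b) / un
}

#' Annotate predicted strains by nearest reference genome
#'
#' Each predicted strain is annotated with the reference genome minimizing
#' the Jaccard distance between its binary gene-content profile and the
#' genome's gene-family membership. Profiles are aligned on the union of the
#' two family universes, with missing families treated as absent. Exact ties
#' are all reported; the primary annotation is the lexicographically
#' smallest genome ID.
#'
#' @param presence binary gene families x strains matrix with dimnames (e.g.
#'   the `presence` component of a `pandec_fit`).
#' @param stats [pangenome_stats()].
#' @return data frame with columns `strain`, `genome`, `distance`, `ties`
#'   (comma-separated tied genome IDs).
#' @export
annotate_strains <- function(presence, stats) {
  fams <- union(rownames(presence), stats$family_ids)
  P <- matrix(0, length(fams), ncol(presence),
              dimnames = list(fams, colnames(presence)))
  P[rownames(presence), ] <- presence
  M <- matrix(0, length(fams), length(stats$genome_ids),
              dimnames = list(fams, stats$genome_ids))
  M[stats$family_ids, ] <- stats$membership

  res <- lapply(seq_len(ncol(P)), function(j) {
    if (sum(P[, j]) == 0) {
      stop(sprintf("predicted strain '%s' has an empty gene-content profile",
                   colnames(P)[j]))
    }
    d <- vapply(seq_len(ncol(M)), function(g) jaccard_distance(P[, j], M[, g]),
                numeric(1))
    tied <- sort(colnames(M)[d == min(d)])
    data.frame(strain = colnames(P)[j], genome = tied[1], distance = min(d),
               ties = paste(tied, collapse = ","), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Match predicted strains to true strains
#'
#' Minimum-cost bipartite assignment of predicted to true strains on the
#' pairwise Jaccard distance between binary gene-content profiles.
#' Predicted strains left unmatched (when there are more predictions than
#' true strains) are grouped as `"Extras"`. Cost ties are broken toward the
#' lowest predicted-strain index.
#'
#' @param pred_presence,true_presence binary gene families x strains
#'   matrices; family universes are aligned on their union.
#' @return data frame with columns `pred_strain`, `true_strain` (or
#'   `"Extras"`), `distance` (NA for Extras).
#' @export
match_strains <- function(pred_presence, true_presence) {
  fams <- union(rownames(pred_presence), rownames(true_presence))
  align <- function(m) {
    out <- matrix(0, length(fams), ncol(m), dimnames = list(fams, colnames(m)))
    out[rownames(m), ] <- m
    out
  }
  P <- align(pred_presence); Tm <- align(true_presence)
  np <- ncol(P); nt <- ncol(Tm)
  cost <- matrix(0, np, nt)
  for (i in seq_len(np)) for (j in seq_len(nt)) {
    cost[i, j] <- jaccard_distance(P[, i], Tm[, j])
  }
  assign <- min_cost_assignment(cost)
  data.frame(
    pred_strain = colnames(P),
    true_strain = ifelse(is.na(assign), "Extras", colnames(Tm)[assign]),
    distance = ifelse(is.na(assign), NA_real_, cost[cbind(seq_len(np), assign)]),
    stringsAsFactors = FALSE)
}

# min-cost assignment of rows (predicted) to columns (true); returns for each
# row its assigned column or NA. Exhaustive lexicographic search for small
# instances (guaranteeing lowest-index tie-breaks), Hungarian otherwise.
min_cost_assignment <- function(cost) {
  np <- nrow(cost); nt <- ncol(cost)
  n_inject <- prod(seq(nt, by = -1, length.out = min(np, nt)))
  if (is.finite(n_inject) && n_inject <= 2e5) {
    return(assignment_bruteforce(cost))
  }
  assignment_hungarian(cost)
}

assignment_bruteforce <- function(cost) {
  np <- nrow(cost); nt <- ncol(cost)
  best <- NULL; best_cost <- Inf
  # depth-first over rows in index order; the first minimal solution found
  # wins, so cost ties resolve toward matching the lowest predicted index
  rec <- function(i, used, acc, map) {
    if (acc > best_cost + 1e-12) return()
    if (i > np || sum(!used) == 0) {
      if (acc < best_cost - 1e-12) { best_cost <<- acc; best <<- map }
      return()
    }
    for (j in seq_len(nt)) {
      if (!used[j]) {
        used[j] <- TRUE; map[i] <- j
        rec(i + 1, used, acc + cost[i, j], map)
        used[j] <- FALSE; map[i] <- NA
      }
    }
    if (np - i + 1 > sum(!used)) {
      # more rows remain than free columns: this row may go unmatched
      rec(i + 1, used, acc, map)
    }
  }
  rec(1, rep(FALSE, nt), 0, rep(NA_integer_, np))
  best
}

# standard O(n^3) Hungarian with potentials, on a square padded matrix
assignment_hungarian <- function(cost) {
  np <- nrow(cost); nt <- ncol(cost)
  n <- max(np, nt)
  a <- matrix(0, n, n)
  a[seq_len(np), seq_len(nt)] <- cost
  u <- numeric(n + 1); v <- numeric(n + 1); p <- integer(n + 1); way <- integer(n + 1)
  INF <- .Machine$double.xmax / 4
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 0
    minv <- rep(INF, n + 1); used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- a[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) { u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
                           v[j + 1] <- v[j + 1] - delta }
        else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assign <- rep(NA_integer_, np)
  for (j in seq_len(n)) {
    i <- p[j + 1]
    if (i >= 1 && i <= np && j <= nt) assign[i] <- j
  }
  assign
}

#' Gene-content confusion counts for one strain
#'
#' @param pred,truth binary vectors on the same family list.
#' @return list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  pred <- pred > 0; truth <- truth > 0
  list(tp = sum(pred & truth), tn = sum(!pred & !truth),
       fp = sum(pred & !truth), fn = sum(!pred & truth))
}

#' Precision-recall curve from confidence-ranked gene-content calls
#'
#' Gene families are ranked by a signed score: `+confidence` where the
#' binary call is present and `-confidence` where it is absent, so that
#' confidently-present families rank above uncertain ones and
#' confidently-absent families rank last (the confidence score itself is
#' near 1 at both extremes and cannot rank calls on its own). Precision and
#' recall are evaluated at every distinct score threshold and the area is
#' computed by trapezoidal interpolation, anchored at recall 0 with the
#' precision of the most stringent threshold.
#'
#' @param confidence confidence scores in `[0, 1]`.
#' @param presence_calls binary presence calls aligned with `confidence`.
#' @param truth binary ground-truth profile on the same family list.
#' @return an object of class `pr_curve`: list with `thresholds` (descending
#'   distinct signed scores), `precision`, `recall`, `auprc`.
#' @export
pr_auprc <- function(confidence, presence_calls, truth) {
  stopifnot(length(confidence) == length(presence_calls),
            length(confidence) == length(truth))
  truth <- truth > 0
  if (!any(truth)) stop("truth profile is all-zero: recall undefined")
  score <- ifelse(presence_calls > 0, confidence, -confidence)
  thresholds <- sort(unique(score), decreasing = TRUE)
  npos <- sum(truth)
  precision <- recall <- numeric(length(thresholds))
  for (k in seq_along(thresholds)) {
    called <- score >= thresholds[k]
    tp <- sum(called & truth)
    precision[k] <- tp / sum(called)
    recall[k] <- tp / npos
  }
  r <- c(0, recall)
  p <- c(precision[1], precision)
  auprc <- sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
  structure(list(thresholds = thresholds, precision = precision,
                 recall = recall, auprc = min(max(auprc, 0), 1)),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("pr_curve: %d thresholds, AUPRC = %.4f\n",
              length(x$thresholds), x$auprc))
  invisible(x)
}

#' Random gene-content baseline for AUPRC
#'
#' Draws random gene-family profiles by sampling the expected per-genome
#' number of families (`round(g_expected)`) uniformly without replacement
#' from the pangenome as "present" (with confidence 1), and scores each
#' against a truth profile; the mean baseline AUPRC approaches the truth's
#' prevalence for large pangenomes.
#'
#' @param stats [pangenome_stats()].
#' @param truth named binary truth profile over the pangenome families (or a
#'   vector aligned with `stats$family_ids`).
#' @param n_draws number of random profiles. Default 1000.
#' @param seed integer seed.
#' @return numeric vector of `n_draws` baseline AUPRC values.
#' @export
random_profile_baseline <- function(stats, truth, n_draws = 1000, seed = 1L) {
  stopifnot(n_draws >= 1)
  nfam <- length(stats$family_ids)
  k <- round(stats$g_expected)
  if (k > nfam) stop("g_expected exceeds the pangenome size")
  if (!is.null(names(truth))) truth <- truth[stats$family_ids]
  stopifnot(length(truth) == nfam)
  withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_draws), function(i) {
      pres <- integer(nfam)
      pres[sample.int(nfam, k)] <- 1L
      pr_auprc(rep(1, nfam), pres, truth)$auprc
    }, numeric(1))
  })
}

#' Drop trace strains and rescale a composition vector
#'
#' Reporting convention for predicted compositions: strains below
#' `min_abundance` relative abundance are removed and the remainder rescaled
#' to sum to 1.
#'
#' @param v relative-abundance vector.
#' @param min_abundance drop threshold. Default 0.01.
#' @return rescaled vector over the retained strains.
#' @export
filter_composition <- function(v, min_abundance = 0.01) {
  keep <- v >= min_abundance
  if (!any(keep)) stop("no strain at or above the abundance floor")
  v[keep] / sum(v[keep])
}

#' Benchmark a decomposition against simulation ground truth
#'
#' Matches predicted to true strains ([match_strains()]), then computes the
#' standard benchmark report: per-sample Jensen-Shannon divergence between
#' predicted and true compositions (predicted strains below 1% abundance are
#' dropped and the rest rescaled before comparison), and per matched strain
#' the gene-content confusion counts, precision, recall, F1, MCC, and
#' confidence-ranked AUPRC.
#'
#' @param fit a `pandec_fit`.
#' @param truth a `sim_truth` (see [simulate_dataset()]) or a list with
#'   `true_content` (binary families x strains, dimnames) and
#'   `true_composition` (strains x samples).
#' @return list with `matching` (data frame), `per_sample` (data frame:
#'   sample, jsd), `per_strain` (data frame: pred_strain, true_strain, tp,
#'   tn, fp, fn, precision, recall, f1, mcc, auprc).
#' @export
evaluate_decomposition <- function(fit, truth) {
  matching <- match_strains(fit$presence, truth$true_content)

  samples <- intersect(colnames(fit$composition), colnames(truth$true_composition))
  per_sample <- data.frame(sample = samples, jsd = NA_real_)
  for (i in seq_along(samples)) {
    s <- samples[i]
    pred <- filter_composition(fit$composition[, s])
    per_sample$jsd[i] <- jsd(pred, truth$true_composition[, s])
  }

  fams <- union(rownames(fit$presence), rownames(truth$true_content))
  expand <- function(m) {
    out <- matrix(0, length(fams), ncol(m), dimnames = list(fams, colnames(m)))
    out[rownames(m), ] <- m
    out
  }
  P <- expand(fit$presence); Cf <- expand(fit$confidence)
  Tm <- expand(truth$true_content)
  matched <- matching[matching$true_strain != "Extras", , drop = FALSE]
  per_strain <- do.call(rbind, lapply(seq_len(nrow(matched)), function(i) {
    ps <- matched$pred_strain[i]; ts <- matched$true_strain[i]
    cc <- confusion_counts(P[, ps], Tm[, ts])
    pr <- pr_auprc(Cf[, ps], P[, ps], Tm[, ts])
    data.frame(pred_strain = ps, true_strain = ts,
               tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn,
               precision = cc$tp / (cc$tp + cc$fp),
               recall = cc$tp / (cc$tp + cc$fn),
               f1 = 2 * cc$tp / (2 * cc$tp + cc$fp + cc$fn),
               mcc = mcc(cc),
               auprc = pr$auprc,
               stringsAsFactors = FALSE)
  }))
  list(matching = matching, per_sample = per_sample, per_strain = per_strain)
}
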