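#' Preprocessing configuration
#'
#' @param rpkm_cutoff abundances strictly below this RPKM value are trimmed to
#'   zero before decomposition (mapping-noise floor). Default 10.
#' @param sample_min_fraction a sample is kept only if the number of gene
#'   families detected after trimming is at least this fraction of `g_min`.
#'   Default 0.9.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(rpkm_cutoff = 10, sample_min_fraction = 0.9) {
  stopifnot(rpkm_cutoff >= 0,
            sample_min_fraction > 0, sample_min_fraction <= 1)
  structure(list(rpkm_cutoff = rpkm_cutoff,
                 sample_min_fraction = sample_min_fraction),
            class = "preprocess_config")
}

#' RPKM normalization of a raw count matrix
#'
#' Converts raw per-family read counts to reads per kilobase of gene per
#' million mapped reads: `count * 1e9 / (length_bp * library_size)`.
#'
#' @param counts a [gene_family_matrix()] with `units = "counts"`.
#' @param gene_lengths named numeric vector of per-family gene lengths in bp;
#'   names must cover the matrix families.
#' @param library_sizes named numeric vector of per-sample total mapped reads.
#' @return a [gene_family_matrix()] with `units = "rpkm"`.
#' @export
rpkm_normalize <- function(counts, gene_lengths, library_sizes) {
  if (!inherits(counts, "gene_family_matrix") || gfm_units(counts) != "counts") {
    stop("rpkm_normalize expects a gene_family_matrix with units = 'counts'")
  }
  fam <- rownames(counts); smp <- colnames(counts)
  miss_f <- setdiff(fam, names(gene_lengths))
  if (length(miss_f)) stop(sprintf("missing gene length for: %s",
                                   paste(utils::head(miss_f, 5), collapse = ", ")))
  miss_s <- setdiff(smp, names(library_sizes))
  if (length(miss_s)) stop(sprintf("missing library size for: %s",
                                   paste(utils::head(miss_s, 5), collapse = ", ")))
  len <- as.numeric(gene_lengths[fam])
  lib <- as.numeric(library_sizes[smp])
  if (any(len <= 0)) stop("gene lengths must be positive")
  if (any(lib <= 0)) stop("library sizes must be positive")
  vals <- unclass(counts) * 1e9 / outer(len, lib)
  gene_family_matrix(vals, fam, smp, units = "rpkm")
}

#' Trim and filter a gene-family profile before decomposition
#'
#' Applies the standard profile cleanup: (1) entries strictly below
#' `rpkm_cutoff` are trimmed to 0; (2) samples detecting fewer than
#' `sample_min_fraction * g_min` gene families (strictly positive entries
#' after trimming) are dropped; (3) gene families absent in all surviving
#' samples are removed. Thresholds are strict: values exactly at a threshold
#' survive.
#'
#' @param x a [gene_family_matrix()] with `units = "rpkm"`.
#' @param stats [pangenome_stats()] for the same species.
#' @param cfg a [preprocess_config()].
#' @return a list with elements `matrix` (filtered [gene_family_matrix()]) and
#'   `log` (class `preprocess_log`: dropped family/sample records and the
#'   cutoffs used).
#' @export
trim_and_filter <- function(x, stats, cfg = preprocess_config()) {
  if (!inherits(x, "gene_family_matrix")) stop("x must be a gene_family_matrix")
  if (gfm_units(x) != "rpkm") stop("trim_and_filter expects RPKM units; run rpkm_normalize first")
  if (!inherits(stats, "pangenome_stats")) stop("stats must be a pangenome_stats object")
  m <- unclass(x)
  m[m < cfg$rpkm_cutoff] <- 0

  detected <- colSums(m > 0)
  thr <- cfg$sample_min_fraction * stats$g_min
  keep_s <- detected >= thr
  dropped_samples <- data.frame(
    id = colnames(m)[!keep_s],
    detected = unname(detected[!keep_s]),
    threshold = rep(thr, sum(!keep_s)),
    stringsAsFactors = FALSE)
  if (!any(keep_s)) stop("no sample passes coverage filter")
  m <- m[, keep_s, drop = FALSE]

  keep_f <- rowSums(m) > 0
  dropped_families <- rownames(m)[!keep_f]
  if (!any(keep_f)) stop("all gene families removed by trimming")
  m <- m[keep_f, , drop = FALSE]

  log <- structure(list(dropped_families = dropped_families,
                        dropped_samples = dropped_samples,
                        cutoffs = list(rpkm_cutoff = cfg$rpkm_cutoff,
                                       sample_min_fraction = cfg$sample_min_fraction,
                                       g_min = stats$g_min)),
                   class = "preprocess_log")
  list(matrix = gene_family_matrix(m, rownames(m), colnames(m), units = "rpkm"),
       log = log)
}

#' @export
print.preprocess_log <- function(x, ...) {
  cat(sprintf("preprocess_log: %d gene families and %d samples dropped (cutoff %.3g, %.3g x g_min)\n",
              length(x$dropped_families), nrow(x$dropped_samples),
              x$cutoffs$rpkm_cutoff, x$cutoffs$sample_min_fraction))
  invisible(x)
}

preprocess_log_json <- function(log, path) {
  jsonlite::write_json(
    list(dropped_families = log$dropped_families,
         dropped_samples = log$dropped_samples,
         cutoffs = log$cutoffs),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
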