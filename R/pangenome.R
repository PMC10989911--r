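#' Pangenome statistics from a reference gene-content table
#'
#' Derives the per-species pangenome summary used downstream: `g_min`, the
#' minimum number of gene families found in any reference genome (used to
#' filter under-covered samples and to reject under-sized strains during rank
#' selection), and `g_expected`, the mean number of gene families per
#' reference genome (used to calibrate binarization of strain gene-content
#' weights).
#'
#' @param membership binary matrix, gene families x reference genomes, with
#'   dimnames; entries must be 0/1.
#' @return an object of class `pangenome_stats` with elements `family_ids`,
#'   `genome_ids`, `membership`, `g_min`, `g_expected`.
#' @export
pangenome_stats <- function(membership) {
  membership <- as.matrix(membership)
  storage.mode(membership) <- "double"
  if (ncol(membership) < 1) stop("pangenome must contain at least one reference genome")
  if (is.null(rownames(membership)) || is.null(colnames(membership))) {
    stop("membership matrix must carry family and genome IDs as dimnames")
  }
  check_unique_ids(rownames(membership), "family")
  check_unique_ids(colnames(membership), "genome")
  if (anyNA(membership) || !all(membership %in% c(0, 1))) {
    stop("membership entries must all be 0 or 1")
  }
  counts <- colSums(membership)
  structure(
    list(family_ids = rownames(membership),
         genome_ids = colnames(membership),
         membership = membership,
         g_min = as.integer(min(counts)),
         g_expected = mean(counts)),
    class = "pangenome_stats"
  )
}

#' @export
print.pangenome_stats <- function(x, ...) {
  cat(sprintf(
    "pangenome_stats: %d gene families, %d reference genomes (g_min = %d, g_expected = %.1f)\n",
    length(x$family_ids), length(x$genome_ids), x$g_min, x$g_expected))
  invisible(x)
}

#' Read a pangenome membership table
#'
#' TSV/CSV with a header of genome IDs, a leading column of gene-family IDs,
#' and 0/1 entries.
#'
#' @param path file path.
#' @return a [pangenome_stats()] object.
#' @export
read_pangenome <- function(path) {
  tab <- read_labeled_table(path)
  m <- tab$values
  dimnames(m) <- list(tab$row_ids, tab$col_ids)
  pangenome_stats(m)
}
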