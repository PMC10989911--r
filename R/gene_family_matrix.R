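#' Gene-family abundance matrix
#'
#' A validated nonnegative matrix of gene-family abundances with gene families
#' in rows and metagenomic samples in columns, as produced by mapping reads
#' against a species pangenome and summing per-family read counts. Values are
#' either raw counts or RPKM (reads per kilobase of gene per million mapped
#' reads), recorded in the `units` attribute.
#'
#' @param values numeric matrix, gene families x samples, nonnegative.
#' @param family_ids,sample_ids character vectors of unique row/column
#'   identifiers. Default to the dimnames of `values`.
#' @param units `"counts"` or `"rpkm"`.
#'
#' @return an object of class `gene_family_matrix`: a numeric matrix with
#'   dimnames and a `units` attribute.
#' @export
gene_family_matrix <- function(values,
                               family_ids = rownames(values),
                               sample_ids = colnames(values),
                               units = c("rpkm", "counts")) {
  units <- match.arg(units)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(family_ids) || is.null(sample_ids)) {
    stop("family_ids and sample_ids are required (or set dimnames on values)")
  }
  family_ids <- as.character(family_ids)
  sample_ids <- as.character(sample_ids)
  if (length(family_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("label lengths do not match matrix dimensions")
  }
  check_unique_ids(family_ids, "family")
  check_unique_ids(sample_ids, "sample")
  if (anyNA(values)) stop("missing values are not allowed in a gene-family matrix")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at family '%s', sample '%s'",
                 family_ids[bad[1]], sample_ids[bad[2]]))
  }
  dimnames(values) <- list(family_ids, sample_ids)
  structure(values, units = units, class = c("gene_family_matrix", "matrix", "array"))
}

check_unique_ids <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("duplicated %s IDs: %s", what,
                 paste(utils::head(dup, 5), collapse = ", ")))
  }
  invisible(ids)
}

#' @export
print.gene_family_matrix <- function(x, ...) {
  cat(sprintf("gene_family_matrix: %d gene families x %d samples [%s]\n",
              nrow(x), ncol(x), attr(x, "units")))
  invisible(x)
}

gfm_units <- function(x) attr(x, "units") %||% "rpkm"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a gene-family abundance table
#'
#' Reads a delimited table with one header row of sample IDs and a leading
#' column of gene-family IDs. The delimiter is auto-detected between tab and
#' comma from the header line.
#'
#' @param path file path.
#' @param units abundance units of the stored values (`"rpkm"` or `"counts"`).
#' @return a [gene_family_matrix()].
#' @export
read_gene_family_matrix <- function(path, units = c("rpkm", "counts")) {
  units <- match.arg(units)
  tab <- read_labeled_table(path)
  m <- tab$values
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing cell at row '%s', column '%s'",
                 tab$row_ids[bad[1]], tab$col_ids[bad[2]]))
  }
  gene_family_matrix(m, tab$row_ids, tab$col_ids, units = units)
}

#' Write a gene-family matrix (or any labeled matrix) as TSV
#'
#' Output is always tab-delimited, with the row-label header given by
#' `id_column`.
#'
#' @param x matrix with dimnames.
#' @param path output file path.
#' @param id_column header for the leading identifier column.
#' @return `path`, invisibly.
#' @export
write_gene_family_matrix <- function(x, path, id_column = "gene_family") {
  df <- data.frame(rownames(x), as.data.frame(unclass(x)[, , drop = FALSE]),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# shared delimited-table reader: header row of column IDs, leading ID column.
read_labeled_table <- function(path) {
  header <- readLines(path, n = 1L)
  if (!length(header)) stop(sprintf("empty file: %s", path))
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2) stop("table must have an ID column and at least one data column")
  row_ids <- df[[1]]
  vals <- df[, -1, drop = FALSE]
  m <- suppressWarnings(matrix(as.numeric(as.matrix(vals)), nrow = nrow(df)))
  nonnum <- is.na(m)
  if (any(nonnum)) {
    bad <- which(nonnum, arr.ind = TRUE)[1, ]
    stop(sprintf("cannot parse cell '%s' (row '%s', column '%s') as a number (missing or non-numeric)",
                 as.matrix(vals)[bad[1], bad[2]], row_ids[bad[1]],
                 colnames(vals)[bad[2]]))
  }
  list(values = m, row_ids = row_ids, col_ids = colnames(vals))
}
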