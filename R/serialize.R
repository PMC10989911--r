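#' Write a strain decomposition to a directory
#'
#' Writes `P.tsv` (binary presence), `P_weights.tsv` (raw content weights),
#' `confidence.tsv`, `S.tsv` (strain composition), `diagnostics.json`
#' (selected rank, per-candidate-rank criterion outcomes, seed, per-strain
#' thresholds) and, when attached to the fit, `preprocess_log.json`.
#'
#' @param fit a `pandec_fit`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_decomposition <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_family_matrix(fit$presence, file.path(dir, "P.tsv"))
  write_gene_family_matrix(fit$raw_weights, file.path(dir, "P_weights.tsv"))
  write_gene_family_matrix(fit$confidence, file.path(dir, "confidence.tsv"))
  write_gene_family_matrix(fit$composition, file.path(dir, "S.tsv"),
                           id_column = "strain")
  diag <- lapply(fit$rank_diagnostics, function(d) {
    list(rank = d$rank, pass = d$pass,
         abundance_ok = d$abundance_ok, size_ok = d$size_ok,
         separation_ok = d$separation_ok,
         mean_abundance = unname(d$mean_abundance),
         gene_counts = unname(d$gene_counts),
         min_pairwise_jaccard = d$min_pairwise_jaccard,
         residual = d$residual)
  })
  jsonlite::write_json(
    list(selected_rank = fit$rank,
         seed = fit$seed,
         residual = fit$residual,
         converged = fit$converged,
         p_max = as.list(fit$p_max),
         theta = as.list(fit$theta),
         rank_diagnostics = diag),
    file.path(dir, "diagnostics.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(fit$preprocess_log)) {
    preprocess_log_json(fit$preprocess_log, file.path(dir, "preprocess_log.json"))
  }
  invisible(dir)
}

#' Read a strain decomposition written by [write_decomposition()]
#'
#' @param dir directory containing `P.tsv`, `P_weights.tsv`,
#'   `confidence.tsv`, `S.tsv` and `diagnostics.json`.
#' @return a `pandec_fit` (without rank diagnostics detail beyond the JSON
#'   record).
#' @export
read_decomposition <- function(dir) {
  as_mat <- function(f) {
    tab <- read_labeled_table(file.path(dir, f))
    m <- tab$values
    dimnames(m) <- list(tab$row_ids, tab$col_ids)
    m
  }
  P <- as_mat("P.tsv")
  diag <- jsonlite::read_json(file.path(dir, "diagnostics.json"),
                              simplifyVector = TRUE)
  structure(list(
    presence = P,
    raw_weights = as_mat("P_weights.tsv"),
    confidence = as_mat("confidence.tsv"),
    composition = as_mat("S.tsv"),
    p_max = unlist(diag$p_max),
    theta = unlist(diag$theta),
    rank = as.integer(diag$selected_rank),
    rank_diagnostics = diag$rank_diagnostics,
    residual = diag$residual,
    converged = diag$converged,
    seed = diag$seed,
    preprocess_log = NULL
  ), class = "pandec_fit")
}

#' Read simulation ground truth written by [write_simulation()]
#'
#' @param dir directory containing `truth_P.tsv` and `truth_S.tsv`.
#' @return a `sim_truth`-like list usable by [evaluate_decomposition()].
#' @export
read_simulation_truth <- function(dir) {
  as_mat <- function(f) {
    tab <- read_labeled_table(file.path(dir, f))
    m <- tab$values
    dimnames(m) <- list(tab$row_ids, tab$col_ids)
    m
  }
  structure(list(true_content = as_mat("truth_P.tsv"),
                 true_composition = as_mat("truth_S.tsv")),
            class = "sim_truth")
}
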