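#' Run a simulate / decompose / evaluate stage with an artifact manifest
#'
#' Thin programmatic layer behind the command-line interface: binds the
#' simulation, preprocessing, decomposition, and evaluation stages into
#' reproducible runs that log their parameters and write a manifest of every
#' output file with its MD5 checksum.
#'
#' @param config a list describing the run:
#'   \describe{
#'     \item{subcommand}{`"simulate"`, `"decompose"`, or `"evaluate"`.}
#'     \item{out}{output directory (created if absent).}
#'     \item{sim}{(simulate) a [sim_config()] or a list of its arguments.}
#'     \item{matrix, pangenome}{(decompose) paths to the gene-family matrix
#'       TSV and pangenome membership TSV.}
#'     \item{rank}{(decompose) optional fixed number of strains.}
#'     \item{preprocess, factorize, rank_select}{(decompose) optional
#'       [preprocess_config()], [factorize_params()], [rank_select_config()]
#'       or argument lists.}
#'     \item{result, truth}{(evaluate) directories written by
#'       [write_decomposition()] / [write_simulation()].}
#'   }
#' @return invisibly, the manifest data frame (file, md5).
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$subcommand), !is.null(config$out))
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  as_cfg <- function(x, ctor) {
    if (is.null(x)) ctor()
    else if (inherits(x, class(ctor())[1])) x
    else do.call(ctor, x)
  }

  switch(config$subcommand,
    simulate = {
      cfg <- if (inherits(config$sim, "sim_config")) config$sim
             else do.call(sim_config, config$sim %||% list())
      sim <- simulate_dataset(cfg, fixed_design = config$fixed_design)
      write_simulation(sim, out, n_decoys = config$n_decoys %||% 0)
    },
    decompose = {
      stopifnot(file.exists(config$matrix), file.exists(config$pangenome))
      D <- read_gene_family_matrix(config$matrix, units = "rpkm")
      stats <- read_pangenome(config$pangenome)
      pre_cfg <- as_cfg(config$preprocess, preprocess_config)
      pre <- trim_and_filter(D, stats, pre_cfg)
      params <- if (inherits(config$factorize, "factorize_params")) config$factorize
                else do.call(factorize_params,
                             c(list(rank = 1), config$factorize %||% list()))
      cfg <- as_cfg(config$rank_select, rank_select_config)
      fit <- pan_decompose(pre$matrix, stats, params, cfg, rank = config$rank)
      fit$preprocess_log <- pre$log
      write_decomposition(fit, out)
    },
    evaluate = {
      fit <- read_decomposition(config$result)
      truth <- read_simulation_truth(config$truth)
      ev <- evaluate_decomposition(fit, truth)
      jsonlite::write_json(
        list(per_sample = ev$per_sample, per_strain = ev$per_strain,
             matching = ev$matching,
             mean_jsd = mean(ev$per_sample$jsd),
             min_auprc = min(ev$per_strain$auprc)),
        file.path(out, "report.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
      utils::write.table(ev$per_strain, file.path(out, "report_per_strain.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    },
    stop(sprintf("unknown subcommand '%s'", config$subcommand))
  )

  files <- setdiff(list.files(out, full.names = TRUE, recursive = TRUE),
                   file.path(out, "manifest.json"))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
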