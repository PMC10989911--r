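#' Synthetic strain-mixture configuration
#'
#' Defines a matrix-level synthetic benchmark: a synthetic species pangenome
#' with core/accessory structure, strain mixtures drawn from a Dirichlet
#' distribution with a minimum strain frequency acting as one sequencing
#' depth unit, and count noise on the observed abundance matrix. With the
#' default `min_frequency = 0.05`, each sample carries `1/0.05 = 20` depth
#' units in total and a strain at the minimum frequency contributes exactly
#' one unit.
#'
#' @param n_families number of gene families in the pangenome. Default 3000.
#' @param n_strains number of true strains K*. Default 4.
#' @param core_fraction fraction of families present in every strain (core
#'   genome). Default 0.4.
#' @param accessory_presence_prob per-strain presence probability of an
#'   accessory family. Default 0.5.
#' @param min_pairwise_jaccard minimum Jaccard distance required between any
#'   two strain profiles (resampled until satisfied). Default 0.2.
#' @param n_samples number of samples. Default 20.
#' @param dirichlet_alpha symmetric Dirichlet concentration. Default 1.
#' @param min_frequency minimum strain relative abundance; also defines the
#'   depth unit. Default 0.05.
#' @param depth_unit_rpkm expected RPKM contributed by one depth unit (a
#'   strain at `min_frequency`) to each of its gene families. Default 100,
#'   well above the default RPKM trimming cutoff of 10.
#' @param noise_model `"none"`, `"poisson"` (Poisson draws around the
#'   expected abundance), or `"poisson_lognormal"` (per-family multiplicative
#'   lognormal efficiency, then Poisson). Default `"poisson"`.
#' @param overdispersion_sigma lognormal sigma for
#'   `noise_model = "poisson_lognormal"`. Default 0.3.
#' @param background_rate Poisson rate of contaminating counts added to a
#'   random subset of families absent from all strains. Default 0.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_families = 3000,
                       n_strains = 4,
                       core_fraction = 0.4,
                       accessory_presence_prob = 0.5,
                       min_pairwise_jaccard = 0.2,
                       n_samples = 20,
                       dirichlet_alpha = 1,
                       min_frequency = 0.05,
                       depth_unit_rpkm = 100,
                       noise_model = c("poisson", "none", "poisson_lognormal"),
                       overdispersion_sigma = 0.3,
                       background_rate = 0,
                       seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(n_families >= 1, n_strains >= 1,
            core_fraction > 0, core_fraction < 1,
            accessory_presence_prob >= 0, accessory_presence_prob <= 1,
            min_pairwise_jaccard >= 0, min_pairwise_jaccard < 1,
            n_samples >= 1, dirichlet_alpha > 0,
            min_frequency > 0, min_frequency <= 1 / n_strains,
            depth_unit_rpkm > 0, overdispersion_sigma >= 0,
            background_rate >= 0)
  structure(list(n_families = as.integer(n_families),
                 n_strains = as.integer(n_strains),
                 core_fraction = core_fraction,
                 accessory_presence_prob = accessory_presence_prob,
                 min_pairwise_jaccard = min_pairwise_jaccard,
                 n_samples = as.integer(n_samples),
                 dirichlet_alpha = dirichlet_alpha,
                 min_frequency = min_frequency,
                 depth_unit_rpkm = depth_unit_rpkm,
                 noise_model = noise_model,
                 overdispersion_sigma = overdispersion_sigma,
                 background_rate = background_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a synthetic pangenome of strain gene-content profiles
#'
#' The first `floor(core_fraction * n_families)` families are core (present
#' in every strain); each remaining accessory family is present in each
#' strain independently with probability `accessory_presence_prob`. Profiles
#' are resampled (up to 100 attempts) until all pairwise Jaccard distances
#' are at least `min_pairwise_jaccard`.
#'
#' @param cfg a [sim_config()].
#' @return binary matrix, families (`gf...`) x strains (`truth...`).
#' @export
simulate_pangenome <- function(cfg) {
  withr::with_seed(cfg$seed, {
    n_core <- floor(cfg$core_fraction * cfg$n_families)
    n_acc <- cfg$n_families - n_core
    for (attempt in seq_len(100)) {
      P <- rbind(
        matrix(1L, n_core, cfg$n_strains),
        matrix(as.integer(runif(n_acc * cfg$n_strains) <
                            cfg$accessory_presence_prob),
               n_acc, cfg$n_strains))
      ok <- TRUE
      if (cfg$n_strains >= 2) {
        for (a in seq_len(cfg$n_strains - 1)) {
          for (b in (a + 1):cfg$n_strains) {
            if (jaccard_distance(P[, a], P[, b]) < cfg$min_pairwise_jaccard) {
              ok <- FALSE; break
            }
          }
          if (!ok) break
        }
      }
      if (ok) {
        dimnames(P) <- list(paste0("gf", seq_len(cfg$n_families)),
                            paste0("truth", seq_len(cfg$n_strains)))
        return(P)
      }
    }
    stop("could not satisfy min_pairwise_jaccard in 100 attempts; ",
         "lower min_pairwise_jaccard or accessory_presence_prob")
  })
}

#' Simulate strain compositions
#'
#' Columns are drawn from a symmetric Dirichlet(`dirichlet_alpha`) over the
#' strains and rejected until every strain's frequency is at least
#' `min_frequency` (rejection keeps the conditional Dirichlet law, unlike
#' truncation). A fixed-design mode instead emits every distinct permutation
#' of a given abundance vector as one sample, e.g. permuting
#' `(0.05, 0.10, 0.25, 0.60)` over 4 strains yields 24 samples.
#'
#' @param cfg a [sim_config()].
#' @param fixed_design optional abundance vector of length `n_strains`; when
#'   given, all of its distinct permutations become the samples and
#'   `n_samples` is ignored.
#' @return matrix, strains x samples, columns summing to 1 and every entry
#'   at least `min_frequency`.
#' @export
simulate_composition <- function(cfg, fixed_design = NULL) {
  K <- cfg$n_strains
  if (!is.null(fixed_design)) {
    stopifnot(length(fixed_design) == K,
              abs(sum(fixed_design) - 1) < 1e-9)
    perms <- unique(permutations_of(seq_len(K)))
    S <- vapply(perms, function(p) fixed_design[p], numeric(K))
  } else {
    if (cfg$min_frequency * K > 1) stop("min_frequency * n_strains exceeds 1")
    S <- withr::with_seed(cfg$seed + 1L, {
      draw <- function() {
        repeat {
          g <- rgamma(K, shape = cfg$dirichlet_alpha)
          x <- g / sum(g)
          if (min(x) >= cfg$min_frequency) return(x)
        }
      }
      vapply(seq_len(cfg$n_samples), function(i) draw(), numeric(K))
    })
  }
  dimnames(S) <- list(paste0("truth", seq_len(K)),
                      paste0("sample", seq_len(ncol(S))))
  S
}

permutations_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

#' Simulate a synthetic strain-mixture dataset
#'
#' Builds the ground-truth gene-content matrix `P*` ([simulate_pangenome()])
#' and composition matrix `S*` ([simulate_composition()]), forms the expected
#' signal in depth units (a strain at frequency `f` contributes
#' `f / min_frequency` units to each of its families, so each sample totals
#' `1 / min_frequency` units), scales by `depth_unit_rpkm`, and applies the
#' configured count-noise model. With `background_rate > 0`, contaminating
#' `Poisson(background_rate)` counts are added to a random half of the
#' families absent from all strains.
#'
#' @param cfg a [sim_config()].
#' @param fixed_design passed to [simulate_composition()].
#' @return list with `D` (a [gene_family_matrix()], units rpkm) and `truth`
#'   (class `sim_truth`: `true_content`, `true_composition`, `depth_units`
#'   per sample, `config`, `seed`).
#' @export
simulate_dataset <- function(cfg, fixed_design = NULL) {
  P <- simulate_pangenome(cfg)
  S <- simulate_composition(cfg, fixed_design)
  units_per_sample <- 1 / cfg$min_frequency
  M <- P %*% (S / cfg$min_frequency)  # expected depth units per family/sample
  mean_rpkm <- M * cfg$depth_unit_rpkm

  D <- withr::with_seed(cfg$seed + 2L, {
    out <- switch(cfg$noise_model,
      none = mean_rpkm,
      poisson = matrix(rpois(length(mean_rpkm), mean_rpkm),
                       nrow(mean_rpkm), dimnames = dimnames(mean_rpkm)),
      poisson_lognormal = {
        eff <- rlnorm(nrow(mean_rpkm),
                      meanlog = -cfg$overdispersion_sigma^2 / 2,
                      sdlog = cfg$overdispersion_sigma)
        matrix(rpois(length(mean_rpkm), mean_rpkm * eff),
               nrow(mean_rpkm), dimnames = dimnames(mean_rpkm))
      })
    if (cfg$background_rate > 0) {
      empty <- which(rowSums(P) == 0)
      if (length(empty)) {
        hit <- sample(empty, ceiling(length(empty) / 2))
        out[hit, ] <- out[hit, ] +
          matrix(rpois(length(hit) * ncol(out), cfg$background_rate),
                 length(hit))
      }
    }
    out
  })
  dimnames(D) <- dimnames(mean_rpkm)

  truth <- structure(list(true_content = P,
                          true_composition = S,
                          depth_units = rep(units_per_sample, ncol(S)),
                          config = cfg,
                          seed = cfg$seed),
                     class = "sim_truth")
  list(D = gene_family_matrix(D, rownames(D), colnames(D), units = "rpkm"),
       truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d strains, %d gene families, %d samples (%s noise, seed %d)\n",
              ncol(x$true_content), nrow(x$true_content),
              ncol(x$true_composition), x$config$noise_model, x$seed))
  invisible(x)
}

#' Write a simulated dataset to a directory
#'
#' Writes `D.tsv`, `truth_P.tsv`, `truth_S.tsv`, `membership.tsv` (the true
#' strains as synthetic reference genomes, plus optional perturbed decoys)
#' and `sim_config.json`.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if absent).
#' @param n_decoys number of perturbed decoy reference genomes to add to the
#'   membership table. Default 0.
#' @param decoy_flip_prob per-family flip probability used to perturb a true
#'   profile into a decoy. Default 0.05.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, n_decoys = 0, decoy_flip_prob = 0.05) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_family_matrix(sim$D, file.path(dir, "D.tsv"))
  write_gene_family_matrix(sim$truth$true_content, file.path(dir, "truth_P.tsv"))
  write_gene_family_matrix(sim$truth$true_composition,
                           file.path(dir, "truth_S.tsv"), id_column = "strain")
  membership <- sim$truth$true_content
  colnames(membership) <- paste0("genome", seq_len(ncol(membership)))
  if (n_decoys > 0) {
    decoys <- withr::with_seed(sim$truth$seed + 3L, {
      vapply(seq_len(n_decoys), function(i) {
        base <- membership[, 1 + (i - 1) %% ncol(sim$truth$true_content)]
        flip <- runif(length(base)) < decoy_flip_prob
        as.integer(xor(base > 0, flip))
      }, integer(nrow(membership)))
    })
    colnames(decoys) <- paste0("decoy", seq_len(n_decoys))
    membership <- cbind(membership, decoys)
  }
  write_gene_family_matrix(membership, file.path(dir, "membership.tsv"))
  cfg <- sim$truth$config
  jsonlite::write_json(unclass(cfg), file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
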