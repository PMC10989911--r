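test_that("synthetic pangenome has the configured core and separation", {
  cfg <- sim_config(n_families = 1000, n_strains = 4, core_fraction = 0.4,
                    min_pairwise_jaccard = 0.2, seed = 2)
  P <- simulate_pangenome(cfg)
  expect_equal(dim(P), c(1000, 4))
  core <- rowSums(P) == 4
  expect_true(all(core[1:400]))           # exactly the declared core block
  expect_true(all(P %in% c(0L, 1L)))
  for (a in 1:3) for (b in (a + 1):4) {
    expect_gte(jaccard_distance(P[, a], P[, b]), 0.2)
  }
})

test_that("unsatisfiable separation constraints error out with advice", {
  cfg <- sim_config(n_families = 50, n_strains = 3, core_fraction = 0.9,
                    accessory_presence_prob = 1, min_pairwise_jaccard = 0.5,
                    seed = 1)
  expect_error(simulate_pangenome(cfg), "min_pairwise_jaccard")
})

test_that("default mixture design: 20 Dirichlet samples, all strains >= 5%", {
  cfg <- sim_config(seed = 3)
  S <- simulate_composition(cfg)
  expect_equal(ncol(S), 20)
  expect_equal(nrow(S), 4)
  expect_composition_matrix(S)
  expect_true(all(S >= 0.05))
})

test_that("fixed-design mode permutes the abundance vector into 24 samples", {
  cfg <- sim_config(n_strains = 4, seed = 3)
  S <- simulate_composition(cfg, fixed_design = c(0.05, 0.10, 0.25, 0.60))
  expect_equal(ncol(S), 24)
  expect_equal(anyDuplicated(t(S)), 0)
  expect_composition_matrix(S)
  expect_true(all(apply(S, 2, sort) == sort(c(0.05, 0.10, 0.25, 0.60))))
})

test_that("impossible minimum frequency errors", {
  expect_error(sim_config(n_strains = 4, min_frequency = 0.3), "min_frequency")
})

test_that("depth-unit bookkeeping: 5% minimum frequency means 20 units per sample", {
  cfg <- sim_config(n_families = 300, n_strains = 3, n_samples = 6,
                    noise_model = "none", seed = 5)
  sim <- simulate_dataset(cfg)
  expect_equal(sim$truth$depth_units, rep(20, 6))
  # noiseless identity: D / depth_unit_rpkm == P* S* / min_frequency
  M <- sim$truth$true_content %*% sim$truth$true_composition / 0.05
  expect_equal(unclass(sim$D) / cfg$depth_unit_rpkm, M, tolerance = 1e-12,
               ignore_attr = TRUE)
  # families absent from all strains stay all-zero without background
  empty <- rowSums(sim$truth$true_content) == 0
  if (any(empty)) expect_true(all(unclass(sim$D)[empty, ] == 0))
})

test_that("simulation is deterministic in the seed and responsive to it", {
  cfg <- sim_config(n_families = 200, n_strains = 3, n_samples = 5, seed = 9)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(unclass(s1$D), unclass(s2$D))
  expect_identical(s1$truth$true_content, s2$truth$true_content)
  s3 <- simulate_dataset(sim_config(n_families = 200, n_strains = 3,
                                    n_samples = 5, seed = 10))
  expect_false(identical(unclass(s1$D), unclass(s3$D)))
})

test_that("poisson noise is centered on the expected abundance", {
  cfg <- sim_config(n_families = 40, n_strains = 2, n_samples = 2,
                    min_pairwise_jaccard = 0.1, noise_model = "poisson",
                    seed = 4)
  base <- simulate_dataset(sim_config(n_families = 40, n_strains = 2,
                                      n_samples = 2, min_pairwise_jaccard = 0.1,
                                      noise_model = "none", seed = 4))
  mean_rpkm <- unclass(base$D)
  reps <- vapply(1:200, function(i) {
    cfg$seed <- 1000L + i
    # same pangenome/composition per seed pairing is not needed here: draw
    # noise around a fixed mean directly
    matrix(rpois(length(mean_rpkm), mean_rpkm), nrow(mean_rpkm))
  }, matrix(0, nrow(mean_rpkm), ncol(mean_rpkm)))
  avg <- apply(reps, c(1, 2), mean)
  big <- mean_rpkm >= 10
  expect_true(all(abs(avg[big] - mean_rpkm[big]) / mean_rpkm[big] < 0.05))
})

test_that("background contamination hits only strain-absent families", {
  cfg <- sim_config(n_families = 400, n_strains = 3, n_samples = 5,
                    noise_model = "none", background_rate = 30, seed = 6)
  sim <- simulate_dataset(cfg)
  empty <- rowSums(sim$truth$true_content) == 0
  expect_true(any(empty))
  touched <- rowSums(unclass(sim$D)) > 0
  # background may only add signal on empty rows; occupied rows keep signal
  base <- simulate_dataset(sim_config(n_families = 400, n_strains = 3,
                                      n_samples = 5, noise_model = "none",
                                      background_rate = 0, seed = 6))
  diff <- unclass(sim$D) - unclass(base$D)
  expect_true(all(diff[!empty, ] == 0))
  expect_true(any(diff[empty, ] > 0))
})

test_that("simulation files round-trip through a directory", {
  cfg <- sim_config(n_families = 150, n_strains = 2, n_samples = 4,
                    min_pairwise_jaccard = 0.1, seed = 8)
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir, n_decoys = 2)
  expect_true(all(file.exists(file.path(dir, c(
    "D.tsv", "truth_P.tsv", "truth_S.tsv", "membership.tsv",
    "sim_config.json")))))
  st <- read_pangenome(file.path(dir, "membership.tsv"))
  expect_equal(length(st$genome_ids), 4)  # 2 true + 2 decoys
  tr <- read_simulation_truth(dir)
  expect_equal(tr$true_content, sim$truth$true_content, ignore_attr = TRUE)
  expect_equal(tr$true_composition, sim$truth$true_composition,
               tolerance = 1e-6, ignore_attr = TRUE)
})
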