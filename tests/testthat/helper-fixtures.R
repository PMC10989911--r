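# Shared fixtures, built in code at test time.

# tiny labeled gene-family matrix
tiny_gfm <- function(values = matrix(c(1, 2, 3, 4, 5, 6), nrow = 3),
                     units = "rpkm") {
  dimnames(values) <- list(paste0("gf", seq_len(nrow(values))),
                           paste0("s", seq_len(ncol(values))))
  gene_family_matrix(values, units = units)
}

# small pangenome with known column sums
tiny_stats <- function(colsums = c(100, 120, 110), n_families = 150) {
  m <- vapply(colsums, function(k) {
    v <- integer(n_families); v[seq_len(k)] <- 1L; v
  }, integer(n_families))
  dimnames(m) <- list(paste0("gf", seq_len(n_families)),
                      paste0("g", seq_along(colsums)))
  pangenome_stats(m)
}

# small but realistic simulated dataset shared across decomposition tests
small_sim <- function(seed = 7, n_strains = 3, noise = "none",
                      n_families = 600, n_samples = 12) {
  cfg <- sim_config(n_families = n_families, n_strains = n_strains,
                    n_samples = n_samples, noise_model = noise, seed = seed)
  simulate_dataset(cfg)
}

# preprocessed matrix from a small simulation (drops all-zero rows)
small_pre <- function(sim) {
  st <- pangenome_stats(sim$truth$true_content)
  trim_and_filter(sim$D, st)$matrix
}

# independent brute-force PR curve: precision/recall at every distinct
# score cut, trapezoidal area anchored at recall 0
bruteforce_auprc <- function(score, truth) {
  truth <- truth > 0
  ths <- sort(unique(score), decreasing = TRUE)
  pr <- t(vapply(ths, function(t) {
    called <- score >= t
    c(sum(called & truth) / sum(called), sum(called & truth) / sum(truth))
  }, numeric(2)))
  r <- c(0, pr[, 2]); p <- c(pr[1, 1], pr[, 1])
  sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
}

# independent JSD oracle via direct base-2 KL evaluation
bruteforce_jsd <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a) sum(ifelse(a > 0, a * log2(a / m), 0))
  0.5 * kl(p) + 0.5 * kl(q)
}

expect_composition_matrix <- function(S) {
  expect_true(all(S >= 0))
  expect_equal(unname(colSums(S)), rep(1, ncol(S)), tolerance = 1e-9)
}
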