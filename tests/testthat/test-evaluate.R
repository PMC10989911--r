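test_that("jsd is zero on identical compositions and handles padding", {
  expect_equal(jsd(c(0.6, 0.4), c(0.6, 0.4)), 0)
  expect_equal(jsd(c(0.6, 0.3, 0.1), c(0.6, 0.3, 0.1)), 0)
  expect_equal(jsd(1, c(1, 0)), 0)                 # zero-padding identity
  # order must not matter: compositions compared as sorted distributions
  expect_equal(jsd(c(0.3, 0.7), c(0.7, 0.3)), 0)
})

test_that("jsd matches a hand-evaluated base-2 value and is symmetric/bounded", {
  # pred (1, 0) vs truth (0.5, 0.5): mixture (0.75, 0.25)
  hand <- bruteforce_jsd(c(1, 0), c(0.5, 0.5))
  expect_equal(jsd(c(1, 0), c(0.5, 0.5)), hand, tolerance = 1e-9)
  expect_equal(round(hand, 4), 0.3113)

  set.seed(42)
  for (i in 1:50) {
    k1 <- sample(1:8, 1); k2 <- sample(1:8, 1)
    a <- rgamma(k1, 1); a <- a / sum(a)
    b <- rgamma(k2, 1); b <- b / sum(b)
    d1 <- jsd(a, b); d2 <- jsd(b, a)
    expect_equal(d1, d2, tolerance = 1e-12)
    expect_gte(d1, 0); expect_lte(d1, 1)
  }
  expect_error(jsd(c(0.5, 0.4), c(0.5, 0.5)), "sum to 1")
})

test_that("raw base-2 divergence attains 1 on disjoint support", {
  expect_equal(js_divergence(c(1, 0), c(0, 1)), 1)
  expect_equal(js_divergence(c(0.5, 0.5, 0), c(0, 0, 1)), 1)
})

test_that("mcc matches the closed-form corners and the sign-swap invariance", {
  expect_equal(mcc(tp = 3, tn = 5, fp = 0, fn = 0), 1)
  expect_equal(mcc(tp = 0, tn = 0, fp = 4, fn = 4), -1)
  expect_equal(mcc(tp = 1, tn = 1, fp = 1, fn = 1), 0)
  expect_equal(mcc(tp = 5, tn = 0, fp = 0, fn = 0), 0)  # degenerate table
  set.seed(1)
  for (i in 1:25) {
    cc <- as.list(rpois(4, 5)); names(cc) <- c("tp", "tn", "fp", "fn")
    if (sum(unlist(cc)) == 0) next
    m1 <- mcc(cc)
    m2 <- mcc(tp = cc$tn, tn = cc$tp, fp = cc$fn, fn = cc$fp)
    expect_equal(m1, m2, tolerance = 1e-12)
    expect_gte(m1, -1); expect_lte(m1, 1)
  }
})

test_that("jaccard distance follows 1 - |intersection| / |union|", {
  expect_equal(jaccard_distance(c(1, 1, 0), c(1, 1, 0)), 0)
  expect_equal(jaccard_distance(c(1, 0, 0), c(0, 1, 1)), 1)
  expect_equal(jaccard_distance(c(1, 2, 3), c(2, 3, 4), is_set = TRUE), 0.5)
  expect_error(jaccard_distance(c(0, 0), c(0, 0)), "empty")
})

test_that("strain annotation picks the nearest reference genome with tie rule", {
  st <- tiny_stats(c(100, 120, 110))
  # strain identical to genome 2's column
  P <- st$membership[, c(2, 1), drop = FALSE]
  colnames(P) <- c("strain1", "strain2")
  ann <- annotate_strains(P, st)
  expect_equal(ann$genome[1], "g2")
  expect_equal(ann$distance[1], 0)

  # profile at different distances: brute-force cross-check
  set.seed(3)
  Pp <- st$membership[, 1, drop = FALSE]
  flip <- sample(seq_len(nrow(Pp)), 8)
  Pp[flip, 1] <- 1 - Pp[flip, 1]
  colnames(Pp) <- "strainX"
  d_brute <- apply(st$membership, 2, function(g) jaccard_distance(Pp[, 1], g))
  annX <- annotate_strains(Pp, st)
  expect_equal(annX$genome, names(which.min(d_brute)))
  expect_equal(annX$distance, min(d_brute))

  # exact tie: identical duplicate genomes -> lexicographically smallest id
  M <- cbind(g2 = c(1, 1, 0), g1 = c(1, 1, 0), g3 = c(0, 1, 1))
  rownames(M) <- paste0("gf", 1:3)
  stt <- pangenome_stats(M)
  Pt <- matrix(c(1, 1, 0), 3, 1, dimnames = list(paste0("gf", 1:3), "s"))
  annT <- annotate_strains(Pt, stt)
  expect_equal(annT$genome, "g1")
  expect_equal(annT$ties, "g1,g2")

  Pe <- matrix(0, 3, 1, dimnames = list(paste0("gf", 1:3), "s"))
  expect_error(annotate_strains(Pe, stt), "empty")
})

test_that("strain matching recovers permutations and groups extras", {
  set.seed(5)
  Tm <- matrix(rbinom(40 * 4, 1, 0.5), 40, 4,
               dimnames = list(paste0("gf", 1:40), paste0("t", 1:4)))
  P <- Tm[, c(3, 1, 4, 2)]
  colnames(P) <- paste0("p", 1:4)
  m <- match_strains(P, Tm)
  expect_equal(m$true_strain, c("t3", "t1", "t4", "t2"))
  expect_equal(m$distance, rep(0, 4))

  # 5 predicted vs 4 true: one extra
  P5 <- cbind(P, p5 = rbinom(40, 1, 0.5))
  m5 <- match_strains(P5, Tm)
  expect_equal(sum(m5$true_strain == "Extras"), 1)
  expect_equal(sum(m5$true_strain != "Extras"), 4)

  # symmetric tie: both predictions equidistant from the one true strain;
  # the lowest predicted index wins
  Tm1 <- matrix(c(1, 1, 0, 0), 4, 1, dimnames = list(paste0("gf", 1:4), "t1"))
  Pt <- matrix(c(1, 0, 1, 0,
                 0, 1, 0, 1), 4, 2,
               dimnames = list(paste0("gf", 1:4), c("p1", "p2")))
  mt <- match_strains(Pt, Tm1)
  expect_equal(mt$true_strain, c("t1", "Extras"))
})

test_that("hungarian assignment agrees with brute force on random instances", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n), n, n)
    h <- pandec:::assignment_hungarian(cost)
    b <- pandec:::assignment_bruteforce(cost)
    expect_equal(sum(cost[cbind(seq_len(n), h)]),
                 sum(cost[cbind(seq_len(n), b)]), tolerance = 1e-10)
  }
})

test_that("pr curve equals brute-force enumeration on small instances", {
  # worked 4-family case: signed scores (1.0, 0.4, -0.2, -1.0), truth (1,1,0,1)
  conf <- c(1.0, 0.4, 0.2, 1.0)
  calls <- c(1, 1, 0, 0)
  truth <- c(1, 1, 0, 1)
  pr <- pr_auprc(conf, calls, truth)
  score <- ifelse(calls > 0, conf, -conf)
  expect_equal(pr$auprc, bruteforce_auprc(score, truth), tolerance = 1e-12)
  expect_equal(pr$auprc, 0.9027778, tolerance = 1e-6)
  expect_true(all(diff(pr$recall) >= 0))

  set.seed(9)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    conf <- round(runif(n), 2)
    calls <- rbinom(n, 1, 0.5)
    truth <- rbinom(n, 1, 0.5)
    if (sum(truth) == 0) truth[1] <- 1
    pr <- pr_auprc(conf, calls, truth)
    expect_equal(pr$auprc,
                 bruteforce_auprc(ifelse(calls > 0, conf, -conf), truth),
                 tolerance = 1e-12)
    expect_gte(pr$auprc, 0); expect_lte(pr$auprc, 1)
  }
})

test_that("perfect confident calls give auprc 1 and all-zero truth errors", {
  truth <- c(1, 0, 1, 1, 0)
  pr <- pr_auprc(rep(1, 5), truth, truth)
  expect_equal(pr$auprc, 1)
  expect_error(pr_auprc(rep(1, 3), c(1, 0, 0), c(0, 0, 0)), "all-zero")
})

test_that("random profile baseline is reproducible and centers on prevalence", {
  st <- tiny_stats(c(100, 120, 110), n_families = 400)
  truth <- setNames(integer(400), st$family_ids)
  truth[sample(400, 160)] <- 1L   # prevalence 0.4
  b1 <- random_profile_baseline(st, truth, n_draws = 50, seed = 4)
  b2 <- random_profile_baseline(st, truth, n_draws = 50, seed = 4)
  expect_identical(b1, b2)
  expect_length(b1, 50)
  prevalence <- mean(truth)
  expect_lt(abs(mean(b1) - prevalence), 0.05)
})

test_that("composition reporting filter drops trace strains and rescales", {
  v <- c(0.6, 0.3, 0.095, 0.005)
  f <- filter_composition(v)
  expect_equal(sum(f), 1)
  expect_length(f, 3)
  expect_equal(f, c(0.6, 0.3, 0.095) / 0.995)
  expect_error(filter_composition(c(0.004, 0.996), min_abundance = 2), "floor")
})
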