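test_that("ANOSIM attains R = 1 under complete separation", {
  # all between-distances exceed all within-distances
  D <- dist_from_upper(c(1, 2, 2, 2, 2, 1), 4)
  a <- anosim(D, c(1, 1, 2, 2), n_permutations = 199, seed = 1)
  expect_equal(a$R, 1)
  # hand-ranked example: ranks 1.5, 1.5 within; 4.5 x4 between
  expect_equal(a$mean_rank_within, 1.5)
  expect_equal(a$mean_rank_between, 4.5)
  expect_equal(a$M, 6)
})

test_that("ANOSIM R is invariant under monotone distance transforms", {
  withr::with_seed(7, {
    xy <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 2), 10, 2))
    D <- as.matrix(dist(xy))
    dimnames(D) <- list(paste0("i", 1:20), paste0("i", 1:20))
  })
  g <- rep(1:2, each = 10)
  a1 <- anosim(D, g, n_permutations = 99, seed = 5)
  a2 <- anosim(sqrt(D), g, n_permutations = 99, seed = 5)
  a3 <- anosim(D^3, g, n_permutations = 99, seed = 5)
  expect_equal(a1$R, a2$R)
  expect_equal(a1$R, a3$R)
  expect_equal(a1$p, a2$p) # same seed, same ranks -> same permutations
})

test_that("ANOSIM agrees with vegan on random data", {
  withr::with_seed(8, {
    xy <- matrix(rnorm(60), 30, 2)
    D <- as.matrix(dist(xy))
    dimnames(D) <- list(paste0("i", 1:30), paste0("i", 1:30))
    g <- sample(rep(1:3, each = 10))
  })
  ours <- anosim(D, g, n_permutations = 99, seed = 1)
  ref <- vegan::anosim(stats::as.dist(D), g, permutations = 19)
  expect_equal(ours$R, unname(ref$statistic), tolerance = 1e-12)
})

test_that("pairwise ANOSIM separates disjoint clouds more than overlapping ones", {
  withr::with_seed(9, {
    a <- cbind(runif(8, 0, 1), runif(8, 0, 1))
    b <- cbind(runif(8, 10, 11), runif(8, 0, 1)) # disjoint from a
    c_ <- cbind(runif(8, 0.5, 1.5), runif(8, 0, 1)) # overlaps a
    xy <- rbind(a, b, c_)
    D <- as.matrix(dist(xy))
    dimnames(D) <- list(paste0("i", 1:24), paste0("i", 1:24))
  })
  g <- rep(1:3, each = 8)
  pw <- anosim_pairwise(D, g, n_permutations = 199, seed = 2)
  R_ab <- pw$R[pw$group_a == 1 & pw$group_b == 2]
  R_ac <- pw$R[pw$group_a == 1 & pw$group_b == 3]
  expect_equal(R_ab, 1)
  expect_lt(R_ac, R_ab)
  expect_true(all(pw$p_corrected >= pw$p, na.rm = TRUE))
})

test_that("random labels rarely yield significant pairwise ANOSIM", {
  withr::with_seed(10, {
    fp <- replicate(60, {
      xy <- matrix(rnorm(60), 30, 2)
      D <- as.matrix(dist(xy))
      dimnames(D) <- list(paste0("i", 1:30), paste0("i", 1:30))
      g <- sample(rep(1:3, each = 10))
      pw <- anosim_pairwise(D, g, n_permutations = 199,
                            seed = sample.int(1e6, 1))
      any(pw$p_corrected < 0.05, na.rm = TRUE)
    })
  })
  expect_lte(mean(fp), 0.1)
})

test_that("dbRDA equals the OLS oracle on a univariate Euclidean embedding", {
  y <- c(0, 1, 2, 4)
  D <- as.matrix(dist(y))
  dimnames(D) <- list(paste0("i", 1:4), paste0("i", 1:4))
  x <- matrix(c(0, 1, 2, 3), 4, 1)
  r <- dbrda(D, x, n_permutations = 99, seed = 1)
  ols <- summary(lm(y ~ x))
  expect_equal(r$pseudo_F, unname(ols$fstatistic[1]), tolerance = 1e-8)
  expect_equal(r$proportion_explained, ols$r.squared, tolerance = 1e-8)
})

test_that("dbRDA matches classical RDA on multivariate Euclidean data", {
  withr::with_seed(11, {
    Y <- matrix(rnorm(60), 20, 3)
    X <- matrix(rnorm(40), 20, 2)
    Z <- matrix(rnorm(20), 20, 1)
  })
  D <- as.matrix(dist(Y))
  dimnames(D) <- list(paste0("i", 1:20), paste0("i", 1:20))
  r <- dbrda(D, X, n_permutations = 99, seed = 1)
  ref <- anova(vegan::rda(Y ~ X), permutations = 19)
  expect_equal(r$pseudo_F, ref$F[1], tolerance = 1e-8)
  rp <- dbrda(D, X, Z = Z, n_permutations = 99, seed = 1)
  refp <- anova(vegan::rda(Y ~ X + Condition(Z)), permutations = 19)
  expect_equal(rp$pseudo_F, refp$F[1], tolerance = 1e-8)
})

test_that("dbRDA trace additivity holds and permutation p is reproducible", {
  sim <- simulate_dataset(sim_config(n_individuals = 30, n_loci = 60, seed = 21))
  D <- jaccard_matrix(sim$markers)
  XY <- cbind(sim$samples$latitude, sim$samples$longitude)
  r1 <- dbrda(D, XY, n_permutations = 199, seed = 4)
  r2 <- dbrda(D, XY, n_permutations = 199, seed = 4)
  expect_identical(r1$p, r2$p)
  expect_equal(r1$trace_fitted + (r1$trace_total - r1$trace_fitted),
               r1$trace_total, tolerance = 1e-8)
  expect_gte(r1$proportion_explained, 0)
  expect_lte(r1$proportion_explained, 1)
  expect_error(dbrda(D, cbind(XY, XY[, 1])), "rank-deficient")
})

test_that("dbRDA permutation test is calibrated under the null", {
  withr::with_seed(12, {
    rej <- replicate(200, {
      y <- rnorm(40)
      D <- as.matrix(dist(y))
      dimnames(D) <- list(paste0("i", 1:40), paste0("i", 1:40))
      X <- matrix(rnorm(80), 40, 2)
      dbrda(D, X, n_permutations = 99, seed = sample.int(1e6, 1))$p <= 0.05
    })
  })
  expect_lte(mean(rej), 0.085)
})

test_that("IBD report distinguishes gradient-only from island-only structure", {
  # pure IBD, one cluster: spatial dbRDA explains much, no cluster term
  cfg <- sim_config(n_clusters = 1, n_individuals = 40, n_loci = 80,
                    ibd_gradient_strength = 0.004, admixture_zone_width = 0,
                    seed = 31)
  sim <- simulate_dataset(cfg)
  rep1 <- suppressWarnings(
    ibd_cluster_report(jaccard_matrix(sim$markers), sim$samples,
                       rep(1, 40), n_permutations = 199, seed = 1))
  expect_false("clusters_partial" %in% rep1$analysis)
  expect_lt(rep1$p[rep1$analysis == "ibd"], 0.05)

  # islands with no internal structure: cluster term dominates space
  cfg2 <- sim_config(n_clusters = 3, n_individuals = 45, n_loci = 120,
                     ibd_gradient_strength = 0, admixture_zone_width = 0,
                     ldd_rate = 0, seed = 32)
  sim2 <- simulate_dataset(cfg2)
  rep2 <- suppressWarnings(
    ibd_cluster_report(jaccard_matrix(sim2$markers), sim2$samples,
                       sim2$truth$cluster, n_permutations = 199, seed = 1))
  prop_cl <- rep2$proportion[rep2$analysis == "clusters_partial"]
  prop_ibd <- rep2$proportion[rep2$analysis == "ibd"]
  expect_gt(prop_cl, prop_ibd)
  within <- rep2[rep2$analysis == "ibd_within_cluster", ]
  expect_true(all(within$proportion < prop_cl))
  # small clusters are skipped, larger ones reported with their own n
  expect_true(all(within$n >= 4))
})
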