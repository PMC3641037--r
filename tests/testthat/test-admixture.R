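test_that("K = 1 collapses to the posterior-mean band frequency", {
  x <- random_marker_matrix(15, 40, seed = 2)
  fit <- fit_admixture(x, 1, burn_in = 100, sweeps = 400, seed = 1)
  expect_true(all(fit$q == 1))
  # Beta(1,1) prior => posterior mean (count + 1) / (n + 2)
  expect_equal(as.numeric(fit$p), unname((colSums(x) + 1) / (nrow(x) + 2)),
               tolerance = 0.05)
  expect_error(fit_admixture(x, 20), "exceed")
})

test_that("well-separated clusters are recovered and runs are reproducible", {
  x <- two_cluster_markers(20, 100, seed = 3)
  truth <- rep(1:2, each = 20)
  fit <- fit_admixture(x, 2, burn_in = 150, sweeps = 150, seed = 11)
  lab <- assign_clusters(fit)$cluster
  acc <- max(mean(lab == truth), mean(lab == 3 - truth))
  expect_gte(acc, 0.95)
  expect_true(all(abs(rowSums(fit$q) - 1) < 1e-9))
  fit2 <- fit_admixture(x, 2, burn_in = 150, sweeps = 150, seed = 11)
  expect_identical(fit$q, fit2$q)
  expect_identical(fit$lnl_trace, fit2$lnl_trace)
})

test_that("missing marker cells are tolerated by the sampler", {
  x <- two_cluster_markers(10, 60, seed = 4)
  x[sample(length(x), 100)] <- NA
  fit <- fit_admixture(x, 2, burn_in = 100, sweeps = 100, seed = 5)
  expect_true(all(is.finite(fit$lnl_trace)))
  lab <- assign_clusters(fit)$cluster
  truth <- rep(1:2, each = 10)
  acc <- max(mean(lab == truth), mean(lab == 3 - truth))
  expect_gte(acc, 0.9)
})

test_that("delta-K reproduces the hand-worked example", {
  runs <- tibble::tibble(
    K = rep(2:4, each = 2),
    model_lnP = c(-101, -99, -82, -78, -76, -74)
  )
  # means: -100, -80, -75; sd at K = 3 is sqrt(8); numerator |-75+160-100| = 15
  tab <- delta_k(runs)
  expect_equal(tab$delta_K[tab$K == 3], 15 / sd(c(-82, -78)))
  # exact spec arithmetic: means (-100, -80, -75), s[L(3)] = 2 -> 7.5
  runs2 <- tibble::tibble(
    K = rep(2:4, each = 3),
    model_lnP = c(-100, -100, -100, -82, -80, -78, -75, -75, -75)
  )
  expect_equal(delta_k(runs2)$delta_K[2], 15 / 2)
})

test_that("delta-K handles degenerate variance and linear profiles", {
  # linear L(K) with zero curvature at interior K
  runs <- tibble::tibble(K = rep(2:4, each = 2),
                         model_lnP = c(-30, -20, -25, -15, -20, -10))
  tab <- delta_k(runs)
  expect_equal(tab$delta_K[tab$K == 3], 0)
  expect_true(is.na(tab$delta_K[tab$K == 2]))
  expect_true(is.na(tab$delta_K[tab$K == 4]))
  # zero SD with non-zero curvature -> Inf sentinel + warning
  runs2 <- tibble::tibble(K = rep(2:4, each = 2),
                          model_lnP = c(-30, -30, -20, -20, -18, -18))
  expect_warning(tab2 <- delta_k(runs2), "Inf")
  expect_true(is.infinite(tab2$delta_K[2]))
  # non-consecutive grid -> error
  runs3 <- tibble::tibble(K = rep(c(2, 4, 5), each = 2), model_lnP = rnorm(6))
  expect_error(delta_k(runs3), "consecutive")
})

test_that("delta-K matches a brute-force recomputation on random tables", {
  brute <- function(runs) {
    Ks <- sort(unique(runs$K))
    means <- sapply(Ks, function(k) mean(runs$model_lnP[runs$K == k]))
    sds <- sapply(Ks, function(k) sd(runs$model_lnP[runs$K == k]))
    out <- rep(NA_real_, length(Ks))
    for (i in 2:(length(Ks) - 1)) {
      out[i] <- abs(means[i + 1] - 2 * means[i] + means[i - 1]) / sds[i]
    }
    out
  }
  for (seed in 1:20) {
    runs <- withr::with_seed(seed, tibble::tibble(
      K = rep(2:7, each = 5),
      model_lnP = rnorm(30, mean = -1000 + 20 * rep(2:7, each = 5), sd = 10)
    ))
    expect_equal(delta_k(runs)$delta_K, brute(runs), tolerance = 1e-10)
  }
})

test_that("label permutation leaves the model log-probability unchanged", {
  # model_lnP depends on q and p only through the mixture likelihood,
  # which is invariant to relabelling clusters: same seed + permuted-label
  # initialisation is not observable from the runs log, so check the
  # likelihood identity directly on a fitted object
  x <- two_cluster_markers(10, 50, seed = 6)
  fit <- fit_admixture(x, 2, burn_in = 100, sweeps = 100, seed = 7)
  perm <- c(2, 1)
  lik <- function(q, p) {
    s <- 0
    for (i in seq_len(nrow(x))) for (l in seq_len(ncol(x))) {
      mix <- sum(q[i, ] * (if (x[i, l] == 1) p[, l] else 1 - p[, l]))
      s <- s + log(mix)
    }
    s
  }
  expect_equal(lik(fit$q, fit$p), lik(fit$q[, perm], fit$p[perm, ]),
               tolerance = 1e-9)
})

test_that("NMDS embeds exactly embeddable configurations with ~zero stress", {
  withr::with_seed(13, {
    pts <- matrix(rnorm(20), 10, 2)
  })
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(paste0("p", 1:10), paste0("p", 1:10))
  nm <- nmds(D, dims = 2, n_restarts = 5, seed = 3)
  expect_lt(nm$stress, 0.01)
  # stress-1 is invariant to a global rescaling of the distances
  nm2 <- nmds(2 * D, dims = 2, n_restarts = 5, seed = 3)
  expect_equal(nm$stress, nm2$stress, tolerance = 1e-6)
  expect_error(nmds(matrix(0, 4, 4)), "all-zero")
})

test_that("Gaussian mixture clustering finds well-separated blobs by BIC", {
  withr::with_seed(14, {
    X <- rbind(matrix(rnorm(40, 0, 0.5), 20, 2),
               matrix(rnorm(40, 8, 0.5), 20, 2))
  })
  rownames(X) <- sprintf("i%02d", 1:40)
  g <- gaussian_mixture_clusters(X, K_max = 6, seed = 2)
  expect_equal(g$K, 2)
  truth <- rep(1:2, each = 20)
  tab <- table(g$assignment$cluster, truth)
  expect_equal(max(tab[1, ]) + max(tab[2, ]), 40) # label-swap-safe purity
  g1 <- gaussian_mixture_clusters(X, K_max = 1, seed = 2)
  expect_equal(g1$K, 1)
  expect_length(unique(g1$assignment$cluster), 1)
})

test_that("admixture and Gaussian clustering agree on synthetic clusters", {
  sim <- simulate_dataset(sim_config(n_individuals = 60, n_loci = 150, seed = 41))
  D <- jaccard_matrix(sim$markers)
  ord <- nmds(D, dims = 2, n_restarts = 5, seed = 2)
  gm <- gaussian_mixture_clusters(ord, K_max = 8, seed = 3)
  expect_equal(gm$K, 5)
})
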