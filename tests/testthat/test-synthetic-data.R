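test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_clusters = 0), "n_clusters")
  expect_error(sim_config(seq_length = 100), "codon")
  expect_error(sim_config(ldd_rate = 1.2), "ldd_rate")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("landscape generation is deterministic and tiles the map", {
  cfg <- sim_config(seed = 71)
  l1 <- simulate_landscape(cfg)
  l2 <- simulate_landscape(cfg)
  expect_identical(l1$localities, l2$localities)
  expect_identical(l1$env, l2$env)
  # one cluster, no barriers
  l3 <- simulate_landscape(sim_config(n_clusters = 1, seed = 71))
  expect_length(unique(l3$localities$region), 1)
  expect_length(l3$barriers, 0)
  # five default clusters: contiguous regions, centroids farther apart than
  # the admixture zone
  cent <- dplyr::summarise(dplyr::group_by(l1$localities, .data$region),
                           x = mean(x), y = mean(y))
  dmin <- min(dist(cent[, c("x", "y")]))
  expect_gt(dmin, cfg$admixture_zone_width)
  expect_length(unique(l1$localities$region), 5)
  # overcrowded map -> explicit error
  expect_error(simulate_landscape(sim_config(n_clusters = 40)), "tile")
})

test_that("simulated markers are deterministic with separable clusters", {
  cfg <- sim_config(n_individuals = 50, n_loci = 120,
                    ibd_gradient_strength = 0, admixture_zone_width = 0,
                    ldd_rate = 0, n_env_selected_loci = 0, seed = 72)
  sim1 <- simulate_aflp(simulate_landscape(cfg), cfg)
  sim2 <- simulate_aflp(simulate_landscape(cfg), cfg)
  expect_identical(sim1$markers, sim2$markers)
  D <- jaccard_matrix(sim1$markers)
  cl <- sim1$truth$cluster
  same <- outer(cl, cl, "==")[upper.tri(D)]
  expect_lt(mean(D[upper.tri(D)][same]), mean(D[upper.tri(D)][!same]))
})

test_that("latent band frequencies are recovered in a large single cluster", {
  cfg <- sim_config(n_clusters = 1, n_individuals = 500, n_loci = 120,
                    ibd_gradient_strength = 0, admixture_zone_width = 0,
                    ldd_rate = 0, n_env_selected_loci = 0, seed = 73)
  sim <- simulate_aflp(simulate_landscape(cfg), cfg)
  p <- sim$truth$p_latent[1, ]
  obs <- colMeans(sim$markers)
  se <- sqrt(p * (1 - p) / nrow(sim$markers))
  expect_gte(mean(abs(obs - p) <= 3 * se), 0.95)
})

test_that("zero-effect env loci look like neutral loci to the regression", {
  # selected loci with env_effect_size = 0: the logistic slope CI covers 0
  # at the nominal rate
  withr::with_seed(74, {
    cover <- replicate(100, {
      e <- rnorm(100)
      x <- rbinom(100, 1, plogis(0 * e + qlogis(runif(1, 0.2, 0.8))))
      if (length(unique(x)) < 2) return(NA)
      r <- logistic_assoc(x, e)
      abs(r$beta) <= 1.96 * r$se
    })
  })
  cover <- cover[!is.na(cover)]
  expect_gte(mean(cover), 0.90)
})

test_that("LDD relocations move genotypes without changing them", {
  cfg <- sim_config(n_individuals = 80, n_loci = 60, ldd_rate = 0.3, seed = 75)
  cfg0 <- sim_config(n_individuals = 80, n_loci = 60, ldd_rate = 0, seed = 75)
  land <- simulate_landscape(cfg)
  sim <- simulate_aflp(land, cfg)
  sim0 <- simulate_aflp(simulate_landscape(cfg0), cfg0)
  expect_identical(sim$markers, sim0$markers) # same seed => same genotypes
  moved <- sim$samples$locality_id != sim0$samples$locality_id
  expect_identical(sort(sim$samples$individual_id[moved]),
                   sort(sim$truth$relocated))
  expect_gt(sum(moved), 0)
})

test_that("higher LDD rates inflate the dispersal screen", {
  counts <- sapply(c(0, 0.1), function(r) {
    sum(sapply(1:4, function(s) {
      cfg <- sim_config(ldd_rate = r, seed = 760 + s)
      sim <- simulate_dataset(cfg)
      screen_pairs(jaccard_matrix(sim$markers),
                   geographic_matrix(sim$samples), "ldd")$n_flagged
    }))
  })
  expect_lt(counts[1], 0.2 * counts[2])
})

test_that("sequence simulation respects its degenerate limits", {
  # theta -> 0 with one lineage: identical sequences
  cfg <- sim_config(n_clusters = 1, n_individuals = 6, theta = 1e-9,
                    cluster_divergence = 0, seed = 77)
  aln <- simulate_sequences(simulate_landscape(cfg), cfg)
  ing <- aln$seq[!aln$is_outgroup, ]
  expect_equal(length(unique(apply(ing, 1, paste, collapse = ""))), 1)
  expect_error(
    simulate_sequences(simulate_landscape(cfg), sim_config(theta = 0, seed = 1)),
    "theta"
  )
  # gap-free coding alignment without internal stops in ingroup consensus
  cfg2 <- sim_config(n_individuals = 10, seed = 78)
  aln2 <- simulate_sequences(simulate_landscape(cfg2), cfg2)
  expect_false(any(aln2$seq == "-"))
  expect_equal(ncol(aln2$seq), cfg2$seq_length)
  expect_equal(sum(aln2$is_outgroup), 2)
})

test_that("strong growth produces significantly negative Fs", {
  sig <- sapply(1:20, function(s) {
    cfg <- sim_config(n_clusters = 1, n_individuals = 60, n_loci = 5,
                      growth_factor = 50, theta = 60, seed = 790 + s)
    aln <- simulate_sequences(simulate_landscape(cfg), cfg)
    r <- fu_fs(aln, n_simulations = 200, seed = s)
    isTRUE(r$Fs < 0 && r$p_value < 0.05)
  })
  expect_gte(mean(sig), 0.9)
})

test_that("constant-size genealogies give Fs centred on zero", {
  fs <- suppressWarnings(sapply(1:150, function(s) {
    cfg <- sim_config(n_clusters = 1, n_individuals = 25, n_loci = 5,
                      growth_factor = 0, theta = 3, seq_length = 6000,
                      omega = 1, seed = 800 + s)
    aln <- simulate_sequences(simulate_landscape(cfg), cfg)
    fu_fs(aln, n_simulations = 0)$Fs
  }))
  fs <- fs[is.finite(fs)]
  expect_lt(abs(mean(fs)), 2 * sd(fs) / sqrt(length(fs)))
})

test_that("MK test keeps its nominal size on simulated alignments", {
  ps <- sapply(1:100, function(s) {
    cfg <- sim_config(n_individuals = 30, n_loci = 5, seed = 810 + s)
    aln <- simulate_sequences(simulate_landscape(cfg), cfg)
    mcdonald_kreitman(aln)$p_value
  })
  expect_lte(mean(ps < 0.05), 0.06)
})

test_that("the written bundle round-trips through the loaders", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(sim_config(n_individuals = 15, n_loci = 25,
                                     n_localities = 12, seed = 82))
  write_simulation(sim, dir)
  expect_true(all(file.exists(file.path(dir,
    c("markers.tsv", "samples.tsv", "env.tsv", "alignment.fasta",
      "truth.tsv", "config.yaml")))))
  ds <- load_dataset(file.path(dir, "markers.tsv"),
                     file.path(dir, "samples.tsv"),
                     file.path(dir, "alignment.fasta"),
                     file.path(dir, "env.tsv"),
                     outgroups = c("OUT1", "OUT2"))
  expect_identical(unname(ds$markers), unname(sim$markers))
  expect_identical(ds$alignment$seq, sim$alignment$seq)
  cfg2 <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg2$n_loci, 25)
})
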