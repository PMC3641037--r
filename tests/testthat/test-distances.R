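test_that("Jaccard distance matches hand counts and handles missing loci", {
  x <- rbind(a = c(1L, 1L, 0L, 0L), b = c(1L, 0L, 1L, 0L))
  colnames(x) <- paste0("l", 1:4)
  D <- jaccard_matrix(x)
  expect_equal(D["a", "b"], 1 - 1 / 3, tolerance = 1e-12)

  # identical rows -> 0; disjoint non-empty band sets -> 1
  y <- rbind(a = c(1L, 1L, 0L), b = c(1L, 1L, 0L), c = c(0L, 0L, 1L))
  colnames(y) <- paste0("l", 1:3)
  Dy <- jaccard_matrix(y)
  expect_equal(Dy["a", "b"], 0)
  expect_equal(Dy["a", "c"], 1)

  # loci missing in either member are excluded from the counts
  z <- rbind(a = c(1L, 1L, NA, 0L), b = c(1L, 0L, 1L, NA))
  colnames(z) <- paste0("l", 1:4)
  # comparable loci: 1 (both 1), 2 (a only) -> a=1, b=1, c=0
  expect_equal(jaccard_matrix(z)["a", "b"], 1 - 1 / 2)
})

test_that("Jaccard agrees with a set-based oracle on random matrices", {
  oracle <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    a <- sum(x[ok] == 1 & y[ok] == 1)
    u <- sum(ok & (x == 1 | y == 1))
    if (u == 0) 0 else 1 - a / u
  }
  for (seed in 1:100) {
    m <- random_marker_matrix(10, 20, seed = seed)
    D <- jaccard_matrix(m)
    for (pair in list(c(1, 2), c(3, 9), c(5, 10))) {
      expect_equal(D[pair[1], pair[2]], oracle(m[pair[1], ], m[pair[2], ]),
                   tolerance = 1e-12)
    }
    expect_true(isSymmetric(unclass(D)))
    expect_true(all(diag(D) == 0))
  }
})

test_that("great-circle distances use the 6371.0088 km sphere", {
  s <- tibble::tibble(individual_id = c("a", "b"),
                      locality_id = c("x", "y"),
                      latitude = c(35, 36), longitude = c(24, 24))
  D <- geographic_matrix(s, "great_circle")
  expect_equal(D["a", "b"], 6371.0088 * pi / 180, tolerance = 1e-5)
  expect_equal(D["a", "a"], 0)
  expect_error(
    geographic_matrix(tibble::tibble(individual_id = "a", locality_id = "x",
                                     latitude = 91, longitude = 0)),
    "latitude"
  )
})

test_that("equirectangular and great-circle agree within 0.5% at island scale", {
  withr::with_seed(5, {
    s <- tibble::tibble(
      individual_id = sprintf("i%02d", 1:30),
      locality_id = sprintf("L%02d", 1:30),
      latitude = runif(30, 34.8, 35.6),
      longitude = runif(30, 23.5, 25.9) # all pairs within ~250 km
    )
  })
  gc <- geographic_matrix(s, "great_circle")
  eq <- geographic_matrix(s, "equirectangular")
  off <- abs(gc - eq)[upper.tri(gc)] / gc[upper.tri(gc)]
  expect_lt(max(off), 0.005)
})

test_that("GTR+Gamma distance has the Jukes-Cantor closed form as limit", {
  withr::with_seed(4, {
    n <- 1500
    anc <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    mut <- function(s, k) {
      i <- sample(length(s), k)
      s[i] <- vapply(s[i], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      s
    }
    der <- mut(anc, 160)
    aln <- coding_alignment(rbind(a = anc, b = der, c = mut(anc, 120)))
  })
  jc_model <- structure(list(
    exchangeabilities = setNames(rep(1, 6), aflpscape:::EXCH_NAMES),
    freqs = setNames(rep(0.25, 4), c("A", "C", "G", "T")),
    alpha = 500, n_rate_categories = 4
  ), class = "substitution_model")
  D <- gtr_gamma_matrix(aln, jc_model)
  p <- mean(anc != der)
  expect_equal(D["a", "b"], -3 / 4 * log(1 - 4 / 3 * p), tolerance = 1e-3)
  # identical sequences -> 0; symmetry in the pair
  aln2 <- coding_alignment(rbind(a = anc, b = anc))
  expect_equal(gtr_gamma_matrix(aln2, jc_model)["a", "b"], 0)
  expect_equal(D["a", "b"], D["b", "a"])
})

test_that("adding mismatches never decreases the GTR distance", {
  withr::with_seed(6, {
    n <- 900
    anc <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    seqs <- list(anc)
    cur <- anc
    for (step in 1:6) {
      i <- sample(which(cur == anc), 30) # only untouched sites: mismatches accumulate
      cur[i] <- vapply(cur[i], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      seqs[[step + 1]] <- cur
    }
  })
  m <- do.call(rbind, seqs)
  rownames(m) <- paste0("s", seq_len(nrow(m)))
  model <- structure(list(
    exchangeabilities = setNames(c(1, 2, 1, 1, 2, 1), aflpscape:::EXCH_NAMES),
    freqs = setNames(c(0.3, 0.2, 0.2, 0.3), c("A", "C", "G", "T")),
    alpha = 1, n_rate_categories = 4
  ), class = "substitution_model")
  D <- gtr_gamma_matrix(coding_alignment(m), model)
  d_to_anc <- D[1, -1]
  expect_true(all(diff(d_to_anc) > -1e-8))
})

test_that("fitted GTR+Gamma recovers simple generating models", {
  withr::with_seed(9, {
    n <- 1200
    anc <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    jc_mut <- function(s, k) {
      i <- sample(length(s), k)
      s[i] <- vapply(s[i], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      s
    }
    seqs <- rbind(a = anc, b = jc_mut(anc, 110), c = jc_mut(anc, 130),
                  d = jc_mut(jc_mut(anc, 60), 70))
  })
  fit <- fit_gtr_gamma(coding_alignment(seqs))
  r <- fit$exchangeabilities
  expect_true(max(r) / min(r) < 4) # near-equal under JC data
  expect_true(all(abs(fit$freqs - 0.25) < 0.03))

  # transition-biased data: r_AG, r_CT exceed the transversion rates
  withr::with_seed(10, {
    ti <- c(A = "G", G = "A", C = "T", T = "C")
    ti_mut <- function(s, k) {
      i <- sample(length(s), k)
      s[i] <- vapply(s[i], function(b) {
        if (runif(1) < 0.8) ti[[b]] else sample(setdiff(c("A", "C", "G", "T"), c(b, ti[[b]])), 1)
      }, "")
      s
    }
    seqs2 <- rbind(a = anc, b = ti_mut(anc, 150), c = ti_mut(anc, 170),
                   d = ti_mut(ti_mut(anc, 80), 90))
  })
  fit2 <- fit_gtr_gamma(coding_alignment(seqs2))
  r2 <- fit2$exchangeabilities
  expect_gt(min(r2["r_AG"], r2["r_CT"]),
            max(r2["r_AC"], r2["r_AT"], r2["r_CG"], r2["r_GT"]))

  # identical sequences: no information -> error
  same <- coding_alignment(rbind(a = anc, b = anc, c = anc))
  expect_error(fit_gtr_gamma(same), "identical")
})

test_that("GTR distances cross-check against phangorn on clean data", {
  skip_if_not_installed("phangorn")
  withr::with_seed(11, {
    n <- 1200
    anc <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    mut <- function(s, k) {
      i <- sample(length(s), k)
      s[i] <- vapply(s[i], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      s
    }
    seqs <- rbind(a = anc, b = mut(anc, 100), c = mut(anc, 140))
  })
  jc_model <- structure(list(
    exchangeabilities = setNames(rep(1, 6), aflpscape:::EXCH_NAMES),
    freqs = setNames(rep(0.25, 4), c("A", "C", "G", "T")),
    alpha = 500, n_rate_categories = 1
  ), class = "substitution_model")
  ours <- gtr_gamma_matrix(coding_alignment(seqs), jc_model)
  pd <- phangorn::dist.ml(phangorn::phyDat(seqs), model = "JC69")
  expect_equal(ours["a", "b"], as.matrix(pd)["a", "b"], tolerance = 1e-3)
  expect_equal(ours["a", "c"], as.matrix(pd)["a", "c"], tolerance = 1e-3)
})
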