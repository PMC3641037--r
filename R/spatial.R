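# Geographic concordance and variance partitioning: rank-based analysis of
# similarities (ANOSIM) and distance-based redundancy analysis (dbRDA) with
# McArdle-Anderson trace pseudo-F and Freedman-Lane permutation for the
# partial (covariate) design.

anosim_stat <- function(ranks, within) {
  M <- length(ranks)
  (mean(ranks[!within]) - mean(ranks[within])) / (M / 2)
}

#' Analysis of similarities (ANOSIM)
#'
#' Ranks all pairwise distances (ties get mean ranks) and compares mean
#' between-group with mean within-group rank: R = (rB - rW) / (M/2),
#' M = n(n-1)/2. Significance by permutation of group labels with the +1
#' correction: p = (1 + #\{R_perm >= R_obs\}) / (1 + n_permutations).
#'
#' @param D A `dist_matrix`.
#' @param labels Cluster assignment: tibble with `individual_id`, `cluster`,
#'   or a vector aligned with the rows of `D`.
#' @param n_permutations Label permutations.
#' @param seed Integer seed.
#' @return An `anosim_result`: `R`, `p`, `mean_rank_between`,
#'   `mean_rank_within`, `M`, `n_permutations`, `groups`.
#' @export
anosim <- function(D, labels, n_permutations = 10000, seed = 1L) {
  D <- check_square_labelled(D)
  g <- resolve_labels(labels, rownames(D))
  sizes <- table(g)
  if (length(sizes) < 2) abort("need at least 2 groups")
  if (any(sizes < 2)) abort("every group needs at least 2 members")
  idx <- which(upper.tri(D))
  ranks <- rank(D[idx])
  arr <- which(upper.tri(D), arr.ind = TRUE)
  within <- g[arr[, 1]] == g[arr[, 2]]
  R_obs <- anosim_stat(ranks, within)
  R_perm <- with_seed(seed, vapply(seq_len(n_permutations), function(b) {
    gp <- sample(g)
    anosim_stat(ranks, gp[arr[, 1]] == gp[arr[, 2]])
  }, numeric(1)))
  p <- (1 + sum(R_perm >= R_obs)) / (1 + n_permutations)
  structure(
    list(
      R = R_obs, p = p,
      mean_rank_between = mean(ranks[!within]),
      mean_rank_within = mean(ranks[within]),
      M = length(ranks),
      n_permutations = n_permutations,
      groups = sort(unique(g))
    ),
    class = "anosim_result"
  )
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("<anosim_result> R = %.4f, p = %.4g (%d permutations, %d groups)\n",
              x$R, x$p, x$n_permutations, length(x$groups)))
  invisible(x)
}

resolve_labels <- function(labels, ids) {
  if (is.data.frame(labels)) {
    i <- match(ids, labels$individual_id)
    if (anyNA(i)) abort("labels missing for some individuals in D")
    labels$cluster[i]
  } else {
    if (length(labels) != length(ids)) abort("labels length must match D")
    labels
  }
}

#' Pairwise ANOSIM over all group pairs
#'
#' One ANOSIM per unordered group pair on the corresponding sub-matrix,
#' with Bonferroni correction over the number of comparisons. Pairs
#' involving a singleton group are skipped with a warning.
#'
#' @inheritParams anosim
#' @param correction Only `"bonferroni"` is implemented.
#' @return A tibble `group_a`, `group_b`, `R`, `p`, `p_corrected`.
#' @export
anosim_pairwise <- function(D, labels, n_permutations = 10000,
                            correction = "bonferroni", seed = 1L) {
  stopifnot(correction == "bonferroni")
  D <- check_square_labelled(D)
  g <- resolve_labels(labels, rownames(D))
  groups <- sort(unique(g))
  combos <- combn(groups, 2)
  out <- purrr::map_dfr(seq_len(ncol(combos)), function(j) {
    ga <- combos[1, j]; gb <- combos[2, j]
    sel <- g %in% c(ga, gb)
    if (sum(g == ga) < 2 || sum(g == gb) < 2) {
      warn(sprintf("group pair (%s, %s) skipped: singleton group", ga, gb))
      return(tibble::tibble(group_a = ga, group_b = gb, R = NA_real_,
                            p = NA_real_))
    }
    a <- anosim(D[sel, sel, drop = FALSE], g[sel], n_permutations,
                seed = stage_seed(seed, paste0("pair", ga, "_", gb)))
    tibble::tibble(group_a = ga, group_b = gb, R = a$R, p = a$p)
  })
  n_comp <- sum(!is.na(out$p))
  out$p_corrected <- pmin(1, out$p * n_comp)
  out
}

# --- dbRDA --------------------------------------------------------------

gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  C <- diag(n) - matrix(1 / n, n, n)
  C %*% A %*% C
}

hat_matrix <- function(X) {
  X <- as.matrix(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qrX <- qr(Xc)
  if (qrX$rank == 0) return(list(H = matrix(0, nrow(X), nrow(X)), rank = 0))
  Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  list(H = Q %*% t(Q), rank = qrX$rank)
}

#' Distance-based redundancy analysis (McArdle-Anderson)
#'
#' Gower-centres G = C(-d^2/2)C and regresses it on the column-centred
#' predictors X: pseudo-F = \[tr(HGH)/m\] / \[tr((I-H)G(I-H))/(n-m-1)\],
#' proportion explained = tr(HGH)/tr(G). With covariates Z, X is first
#' residualised on Z; the numerator uses the hat matrix of the residualised
#' predictors, the denominator the residual of \[Z X\], and permutation is
#' Freedman-Lane style (permute rows of the residualised predictors,
#' re-residualise, recompute F). Without covariates, rows of X are permuted.
#' Negative eigenvalues of G (possible for non-Euclidean distances) stay in
#' the traces; their share is reported as a diagnostic.
#'
#' @param D_response A `dist_matrix` (response).
#' @param X Predictor table (data frame or matrix) aligned with `D` rows.
#' @param Z Optional covariate table.
#' @param n_permutations Permutations for the p-value (+1 correction).
#' @param permutation `"freedman_lane"` (default, used when `Z` given) or
#'   `"raw"` (permute raw predictor rows even in the partial design).
#' @param seed Integer seed.
#' @return A `dbrda_result`: `pseudo_F`, `proportion_explained`, `p`, `m`,
#'   `df_residual`, `trace_total`, `trace_fitted`, `negative_eigen_share`,
#'   `n_permutations`.
#' @export
dbrda <- function(D_response, X, Z = NULL, n_permutations = 9999,
                  permutation = c("freedman_lane", "raw"), seed = 1L) {
  permutation <- match.arg(permutation)
  D <- check_square_labelled(D_response)
  n <- nrow(D)
  X <- as.matrix(X)
  if (nrow(X) != n) abort("X rows must align with D labels")
  Gc <- gower_center(unclass(D))
  ev <- eigen(Gc, symmetric = TRUE, only.values = TRUE)$values
  neg_share <- sum(abs(ev[ev < -1e-10])) / sum(abs(ev))
  trace_total <- sum(diag(Gc))

  if (is.null(Z)) {
    hx <- hat_matrix(X)
    if (hx$rank < ncol(X)) {
      abort(sprintf("rank-deficient predictors: rank %d < %d columns",
                    hx$rank, ncol(X)))
    }
    m <- hx$rank
    stat <- function(Xp) {
      h <- hat_matrix(Xp)
      num <- sum(h$H * Gc)
      den <- trace_total - num
      (num / m) / (den / (n - m - 1))
    }
    F_obs <- stat(X)
    trace_fitted <- sum(hat_matrix(X)$H * Gc)
    df_res <- n - m - 1
    perm_stat <- function() stat(X[sample.int(n), , drop = FALSE])
  } else {
    Z <- as.matrix(Z)
    hz <- hat_matrix(Z)
    Zc <- scale(Z, center = TRUE, scale = FALSE)
    Xc <- scale(X, center = TRUE, scale = FALSE)
    resid_on_z <- function(M) M - hz$H %*% M
    Xres <- resid_on_z(Xc)
    hx <- hat_matrix(Xres)
    m <- hx$rank
    if (m == 0) abort("predictors are collinear with the covariates")
    rank_full <- hat_matrix(cbind(Zc, Xc))$rank
    df_res <- n - rank_full - 1
    stat <- function(Xr) {
      h <- hat_matrix(Xr)
      hfull <- hat_matrix(cbind(Zc, Xr))
      num <- sum(h$H * Gc)
      den <- trace_total - sum(hfull$H * Gc)
      (num / m) / (den / (n - hfull$rank - 1))
    }
    F_obs <- stat(Xres)
    trace_fitted <- sum(hx$H * Gc)
    perm_stat <- if (permutation == "freedman_lane") {
      function() stat(resid_on_z(Xres[sample.int(n), , drop = FALSE]))
    } else {
      function() stat(resid_on_z(Xc[sample.int(n), , drop = FALSE]))
    }
  }
  F_perm <- with_seed(seed, vapply(seq_len(n_permutations), function(b) perm_stat(),
                                   numeric(1)))
  p <- (1 + sum(F_perm >= F_obs)) / (1 + n_permutations)
  structure(
    list(
      pseudo_F = F_obs,
      proportion_explained = trace_fitted / trace_total,
      p = p, m = m, df_residual = df_res,
      trace_total = trace_total, trace_fitted = trace_fitted,
      negative_eigen_share = neg_share,
      n_permutations = n_permutations,
      partial = !is.null(Z)
    ),
    class = "dbrda_result"
  )
}

#' @export
print.dbrda_result <- function(x, ...) {
  cat(sprintf(
    "<dbrda_result>%s pseudo-F = %.3f (m = %d, df = %d), proportion = %.3f, p = %.4g\n",
    if (x$partial) " partial" else "", x$pseudo_F, x$m, x$df_residual,
    x$proportion_explained, x$p))
  if (x$negative_eigen_share > 0.01) {
    cat(sprintf("  note: %.1f%% of |eigenvalue| mass is negative (non-Euclidean distances)\n",
                100 * x$negative_eigen_share))
  }
  invisible(x)
}

#' Isolation-by-distance vs cluster-subdivision report
#'
#' Runs (i) dbRDA of the genetic distances on latitude + longitude
#' (isolation by distance over the whole sample), (ii) partial dbRDA on
#' n-1 cluster dummy variables with the spatial variables as covariates
#' (cluster subdivision beyond space), and (iii) dbRDA on latitude +
#' longitude within each cluster separately. Clusters with fewer than
#' `min_n` members are skipped with a warning (residual df exhaustion).
#'
#' @param D A `dist_matrix` of genetic distances.
#' @param samples Sample table with coordinates.
#' @param labels Cluster assignment (tibble or vector).
#' @param n_permutations Permutations per test.
#' @param min_n Smallest cluster analysed separately.
#' @param seed Integer seed.
#' @return An `ibd_report`: tibble with one row per analysis
#'   (`analysis`, `cluster`, `n`, `m`, `pseudo_F`, `p`, `proportion`).
#' @export
ibd_cluster_report <- function(D, samples, labels, n_permutations = 999,
                               min_n = 4, seed = 1L) {
  D <- check_square_labelled(D)
  ids <- rownames(D)
  samples <- samples[match(ids, samples$individual_id), ]
  g <- resolve_labels(labels, ids)
  XY <- cbind(latitude = samples$latitude, longitude = samples$longitude)
  rows <- list()
  ibd <- dbrda(D, XY, n_permutations = n_permutations,
               seed = stage_seed(seed, "ibd_all"))
  rows[[1]] <- tibble::tibble(analysis = "ibd", cluster = NA_integer_,
                              n = nrow(D), m = ibd$m, pseudo_F = ibd$pseudo_F,
                              p = ibd$p, proportion = ibd$proportion_explained)
  ug <- sort(unique(g))
  if (length(ug) > 1) {
    dummies <- sapply(head(ug, -1), function(k) as.numeric(g == k))
    cl <- dbrda(D, dummies, Z = XY, n_permutations = n_permutations,
                seed = stage_seed(seed, "clusters_partial"))
    rows[[2]] <- tibble::tibble(analysis = "clusters_partial",
                                cluster = NA_integer_, n = nrow(D), m = cl$m,
                                pseudo_F = cl$pseudo_F, p = cl$p,
                                proportion = cl$proportion_explained)
  }
  for (k in ug) {
    sel <- g == k
    if (sum(sel) < min_n) {
      warn(sprintf("cluster %s skipped in per-cluster dbRDA (n = %d < %d)",
                   k, sum(sel), min_n))
      next
    }
    wk <- tryCatch(
      dbrda(D[sel, sel, drop = FALSE], XY[sel, , drop = FALSE],
            n_permutations = n_permutations,
            seed = stage_seed(seed, paste0("within", k))),
      error = function(e) {
        warn(sprintf("cluster %s skipped in per-cluster dbRDA: %s",
                     k, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(wk)) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      analysis = "ibd_within_cluster", cluster = as.integer(k), n = sum(sel),
      m = wk$m, pseudo_F = wk$pseudo_F, p = wk$p,
      proportion = wk$proportion_explained)
  }
  structure(dplyr::bind_rows(rows), class = c("ibd_report", "tbl_df", "tbl", "data.frame"))
}
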