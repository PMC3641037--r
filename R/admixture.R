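# Genetic-cluster inference from the binary marker matrix: a Bayesian
# admixture model fitted by Gibbs sampling, the Evanno delta-K statistic for
# choosing K, an NMDS embedding of Jaccard distances, and Gaussian-mixture
# clustering of the embedding as an assumption-free cross-check.

#' Fit the Bayesian admixture model to a binary marker matrix
#'
#' Bands are modelled as haploid Bernoulli characters: x_il ~
#' Bernoulli(p\[z_il, l\]) with latent per-band source z_il ~
#' Categorical(q_i), q_i ~ Dirichlet(alpha), p\[k, l\] ~ Beta(1, 1).
#' All updates are conjugate; `q` and `p` are posterior means over the
#' post-burn-in sweeps. The model log-probability reported for the
#' delta-K table is `mean(lnL) - var(lnL)/2` over the post-burn-in
#' log-likelihood trace (the trace is recorded after burn-in).
#'
#' @param markers Binary marker matrix (`NA` = missing).
#' @param K Number of clusters.
#' @param burn_in,sweeps Gibbs sweeps to discard / keep.
#' @param alpha Dirichlet concentration for ancestry proportions.
#' @param seed Integer seed (R RNG).
#' @return An `admixture_fit`: `q` (n x K), `p` (K x L), `lnl_trace`,
#'   `model_lnP`, `K`, `alpha`, `seed`.
#' @export
fit_admixture <- function(markers, K, burn_in = 200, sweeps = 200,
                          alpha = 1.0, seed = 1L) {
  markers <- validate_marker_matrix(markers)
  if (K < 1) abort("K must be >= 1")
  if (K > nrow(markers)) abort("K cannot exceed the number of individuals")
  if (sweeps < 1) abort("need at least one post-burn-in sweep")
  res <- with_seed(seed, admixture_gibbs_cpp(markers, K, burn_in, sweeps, alpha))
  if (any(!is.finite(res$lnl_trace))) abort("non-finite likelihood in Gibbs trace")
  post <- res$lnl_trace # post-burn-in sweeps
  model_lnP <- if (sweeps == 1) post else mean(post) - var(post) / 2
  rownames(res$q) <- rownames(markers)
  colnames(res$p) <- colnames(markers)
  structure(
    list(
      K = K, q = res$q, p = res$p, alpha = alpha,
      lnl_trace = res$lnl_trace, model_lnP = model_lnP, seed = seed,
      individual_ids = rownames(markers)
    ),
    class = "admixture_fit"
  )
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("<admixture_fit> K=%d, %d individuals, %d loci, model lnP = %.2f\n",
              x$K, nrow(x$q), ncol(x$p), x$model_lnP))
  invisible(x)
}

#' Hard cluster assignment from an admixture fit
#'
#' @param fit An `admixture_fit`.
#' @return A tibble `individual_id`, `cluster`, `source`.
#' @export
assign_clusters <- function(fit) {
  lab <- max.col(fit$q)
  tibble::tibble(
    individual_id = fit$individual_ids,
    cluster = as.integer(factor(lab)), # contiguous from 1
    source = "admixture_argmax"
  )
}

#' Run the admixture model over a K grid
#'
#' @param markers Binary marker matrix.
#' @param K_values Consecutive integers to scan.
#' @param n_runs Independent runs per K.
#' @param seed Master seed; run seeds are derived deterministically.
#' @inheritParams fit_admixture
#' @return A tibble `(K, run, seed, model_lnP)` — the delta-K input, in the
#'   same layout used to import externally produced run logs.
#' @export
admixture_run_grid <- function(markers, K_values = 2:8, n_runs = 4,
                               burn_in = 150, sweeps = 150, alpha = 1.0,
                               seed = 1L) {
  purrr::map_dfr(K_values, function(K) {
    purrr::map_dfr(seq_len(n_runs), function(r) {
      s <- stage_seed(seed, sprintf("admix_K%d_run%d", K, r))
      fit <- fit_admixture(markers, K, burn_in, sweeps, alpha, seed = s)
      tibble::tibble(K = K, run = r, seed = s, model_lnP = fit$model_lnP)
    })
  })
}

#' Evanno delta-K table from admixture run logs
#'
#' delta-K(K) = |L(K+1) - 2 L(K) + L(K-1)| / s\[L(K)\], with L(K) the mean
#' model log-probability over runs at K and s the across-run standard
#' deviation. Undefined at the smallest and largest K. If s = 0 at an
#' interior K with a non-zero numerator the statistic is reported as `Inf`
#' with a warning.
#'
#' @param runs Tibble with columns `K`, `model_lnP` (one row per run), e.g.
#'   from [admixture_run_grid()] or an imported STRUCTURE log.
#' @param per_run_numerator If `TRUE`, use the mean of per-run absolute
#'   second differences instead of the second difference of per-K means.
#' @return A `delta_k_table` tibble: `K`, `n_runs`, `mean_lnP`, `sd_lnP`,
#'   `second_diff`, `delta_K`, with the chosen optimum in attribute
#'   `best_K`.
#' @export
delta_k <- function(runs, per_run_numerator = FALSE) {
  stopifnot(all(c("K", "model_lnP") %in% names(runs)))
  tab <- runs |>
    dplyr::group_by(K = .data$K) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      mean_lnP = mean(.data$model_lnP),
      sd_lnP = sd(.data$model_lnP),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$K)
  if (nrow(tab) < 3) abort("need at least 3 consecutive K values")
  if (!all(diff(tab$K) == 1)) abort("K grid must be consecutive integers")
  if (any(tab$n_runs < 2)) abort("need at least 2 runs per K")
  m <- nrow(tab)
  second <- rep(NA_real_, m)
  if (per_run_numerator) {
    wide <- split(runs$model_lnP, runs$K)
    for (i in 2:(m - 1)) {
      nr <- min(lengths(wide[c(i - 1, i, i + 1)]))
      second[i] <- mean(abs(wide[[i + 1]][seq_len(nr)] -
                              2 * wide[[i]][seq_len(nr)] +
                              wide[[i - 1]][seq_len(nr)]))
    }
  } else {
    second[2:(m - 1)] <- abs(tab$mean_lnP[3:m] - 2 * tab$mean_lnP[2:(m - 1)] +
                               tab$mean_lnP[1:(m - 2)])
  }
  dK <- second / tab$sd_lnP
  zero_sd <- !is.na(second) & tab$sd_lnP == 0
  if (any(zero_sd)) {
    dK[zero_sd] <- ifelse(second[zero_sd] == 0, 0, Inf)
    if (any(is.infinite(dK[zero_sd]))) {
      warn("zero across-run SD with non-zero curvature: delta-K reported as Inf")
    }
  }
  tab$second_diff <- second
  tab$delta_K <- dK
  best <- tab$K[which.max(dK)]
  structure(tab, class = c("delta_k_table", class(tab)), best_K = best)
}

#' Optimal K from a delta-K table
#' @param tab A `delta_k_table`.
#' @return Integer K at the delta-K maximum.
#' @export
best_k <- function(tab) attr(tab, "best_K")

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Minimises Kruskal stress-1 (monotone regression alternating with
#' configuration updates, as implemented in \code{vegan::monoMDS}), starting
#' from classical scaling plus jittered random restarts; the best-stress
#' solution is returned.
#'
#' @param D A `dist_matrix`.
#' @param dims Embedding dimension.
#' @param n_restarts Random restarts beyond the classical-scaling start.
#' @param seed Integer seed.
#' @return An `nmds_result`: `coordinates` (n x dims, row-named), `stress`
#'   (stress-1, in \[0,1\]), `n_restarts`.
#' @export
nmds <- function(D, dims = 2, n_restarts = 10, seed = 1L) {
  D <- check_square_labelled(D)
  if (all(D == 0)) abort("all-zero distance matrix")
  if (dims >= nrow(D)) abort("dims must be smaller than n")
  d <- stats::as.dist(D)
  with_seed(seed, {
    best <- NULL
    init <- cmdscale(d, k = dims)
    if (ncol(init) < dims) {
      init <- cbind(init, matrix(rnorm(nrow(D) * (dims - ncol(init)), sd = 1e-4),
                                 nrow(D)))
    }
    for (r in seq_len(n_restarts + 1)) {
      start <- if (r == 1) init else init + rnorm(length(init), sd = stats::sd(init) * 0.25 + 1e-8)
      fit <- vegan::monoMDS(d, y = start, k = dims, model = "global")
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
    structure(
      list(
        coordinates = structure(best$points,
                                dimnames = list(attr(d, "Labels"),
                                                paste0("dim", seq_len(dims)))),
        stress = best$stress,
        n_restarts = n_restarts
      ),
      class = "nmds_result"
    )
  })
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("<nmds_result> %d points in %d dims, stress-1 = %.4f\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress))
  invisible(x)
}

#' Gaussian-mixture clustering of an ordination
#'
#' Fits full-covariance Gaussian mixtures by EM for K = 1..K_max
#' (\code{mclust}), selects K by BIC, and returns hard labels.
#'
#' @param coords An `nmds_result` or a numeric coordinate matrix.
#' @param K_max Largest number of components considered.
#' @param seed Integer seed (EM initialisation).
#' @return List with `assignment` (tibble: individual_id, cluster, source),
#'   `K`, `bic` (tibble of K vs BIC).
#' @export
gaussian_mixture_clusters <- function(coords, K_max = 8, seed = 1L) {
  X <- if (inherits(coords, "nmds_result")) coords$coordinates else as.matrix(coords)
  if (any(!is.finite(X))) abort("non-finite coordinates")
  if (K_max < 1) abort("K_max must be >= 1")
  fit <- with_seed(seed, Mclust(X, G = seq_len(K_max),
                                        modelNames = "VVV", verbose = FALSE))
  if (is.null(fit)) {
    # VVV can fail on tiny n; fall back to equal-covariance family
    fit <- with_seed(seed, Mclust(X, G = seq_len(K_max), verbose = FALSE))
  }
  bic_best <- apply(fit$BIC, 1, function(row) {
    if (all(is.na(row))) NA_real_ else max(row, na.rm = TRUE)
  })
  bic <- tibble::tibble(K = as.integer(rownames(fit$BIC)), BIC = bic_best)
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("ind%03d", seq_len(nrow(X)))
  list(
    assignment = tibble::tibble(
      individual_id = ids,
      cluster = as.integer(factor(fit$classification)),
      source = "gaussian"
    ),
    K = fit$G,
    bic = bic
  )
}
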