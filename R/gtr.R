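# GTR+Gamma pairwise maximum-likelihood distances.
#
# The rate matrix is Q[x,y] = r_xy * pi_y (x != y), normalised to one
# expected substitution per site per unit branch length. Among-site rate
# variation uses the discrete gamma approximation with mean-per-category
# rates. Transition probabilities come from the eigendecomposition of the
# symmetrised rate matrix (reversibility), so P(t) is exact for any t.

BASES <- c("A", "C", "G", "T")
EXCH_NAMES <- c("r_AC", "r_AG", "r_AT", "r_CG", "r_CT", "r_GT")

gtr_rate_matrix <- function(exch, freqs) {
  Q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in seq_len(6)) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    Q[i, j] <- exch[k] * freqs[j]
    Q[j, i] <- exch[k] * freqs[i]
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  Q / scale
}

gtr_eigen <- function(exch, freqs) {
  Q <- gtr_rate_matrix(exch, freqs)
  rp <- sqrt(freqs)
  S <- diag(rp) %*% Q %*% diag(1 / rp)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  list(
    values = e$values,
    left = diag(1 / rp) %*% e$vectors,   # P(t) = left %*% diag(exp(l t)) %*% right
    right = t(e$vectors) %*% diag(rp)
  )
}

# Mean-per-category discrete gamma rates (Yang 1994), mean 1.
discrete_gamma_rates <- function(alpha, k = 4) {
  if (k == 1) return(1)
  b <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  p <- stats::pgamma(b, shape = alpha + 1, rate = alpha)
  k * diff(p)
}

gtr_transition <- function(eg, t) {
  eg$left %*% (exp(eg$values * t) * eg$right)
}

# 4x4 pattern-count table for one sequence pair; gap/N sites dropped.
pair_pattern_counts <- function(s1, s2) {
  ok <- s1 %in% BASES & s2 %in% BASES
  table(factor(s1[ok], BASES), factor(s2[ok], BASES))
}

pair_loglik <- function(counts, t, eg, freqs, rates) {
  M <- matrix(0, 4, 4)
  for (r in rates) M <- M + gtr_transition(eg, t * r) / length(rates)
  lik <- freqs * M
  lik[lik < 1e-300] <- 1e-300
  sum(counts * log(lik))
}

optimize_pair_t <- function(counts, eg, freqs, rates, t_max = 20) {
  if (sum(counts) - sum(diag(counts)) == 0) {
    return(list(t = 0, lnL = pair_loglik(counts, 1e-9, eg, freqs, rates)))
  }
  o <- optimize(function(t) pair_loglik(counts, t, eg, freqs, rates),
                interval = c(1e-8, t_max), maximum = TRUE, tol = 1e-7)
  list(t = o$maximum, lnL = o$objective)
}

empirical_base_freqs <- function(aln) {
  tab <- table(factor(aln$seq[aln$seq %in% BASES], BASES))
  f <- as.numeric(tab) / sum(tab)
  setNames(f, BASES)
}

#' Fit a GTR+Gamma substitution model by pairwise likelihood
#'
#' Base frequencies are fixed at empirical counts. The five free
#' exchangeabilities (r_GT = 1) and the gamma shape maximise the sum over
#' sequence pairs of pairwise log-likelihoods, each pair with its own branch
#' length (profiled by 1-D optimisation inside the objective). Deterministic
#' given the alignment: optimisation starts from equal exchangeabilities and
#' shape 1.
#'
#' @param alignment A `coding_alignment` (ingroup and outgroup alike inform
#'   the model).
#' @param n_rate_categories Number of discrete gamma categories.
#' @param max_iter Function-evaluation cap for the outer optimiser.
#' @param max_fit_sequences Cap on the number of sequences whose pairs enter
#'   the fitting objective (the first ones in alignment order, so the choice
#'   is deterministic); model parameters stabilise well before all pairs of
#'   a large alignment are used.
#' @return A `substitution_model`: list with `exchangeabilities`, `freqs`,
#'   `alpha`, `n_rate_categories`, `logLik`, `convergence`.
#' @export
fit_gtr_gamma <- function(alignment, n_rate_categories = 4, max_iter = 2000,
                          max_fit_sequences = 30) {
  seqs <- alignment$seq
  if (nrow(seqs) > max_fit_sequences) {
    keep <- unique(round(seq(1, nrow(seqs), length.out = max_fit_sequences)))
    seqs <- seqs[keep, , drop = FALSE]
  }
  if (nrow(seqs) < 3) abort("need at least 3 sequences to fit a model")
  if (sum(apply(seqs, 2, function(col) all(col %in% BASES))) < 100) {
    abort("need at least 100 ungapped columns")
  }
  freqs <- empirical_base_freqs(alignment)
  if (any(freqs == 0)) freqs <- (freqs + 1e-4) / sum(freqs + 1e-4)
  idx <- combn(nrow(seqs), 2)
  counts <- lapply(seq_len(ncol(idx)), function(k) {
    pair_pattern_counts(seqs[idx[1, k], ], seqs[idx[2, k], ])
  })
  informative <- vapply(counts, function(N) sum(N) - sum(diag(N)) > 0, logical(1))
  if (!any(informative)) abort("all sequences identical: no divergence to fit")
  counts <- counts[informative]

  # branch lengths start at Jukes-Cantor estimates, then alternate:
  # optimise (exchangeabilities, alpha) with branch lengths fixed, update
  # each pair's ML branch length under the new parameters, repeat. This
  # profiles the per-pair branch lengths out of the objective at a fraction
  # of the cost of a nested optimisation, and is deterministic.
  t_hat <- vapply(counts, function(N) {
    p <- (sum(N) - sum(diag(N))) / sum(N)
    p <- min(p, 0.70)
    -3 / 4 * log(1 - 4 / 3 * p)
  }, numeric(1))

  obj_fixed_t <- function(par) {
    exch <- c(exp(par[1:5]), 1)
    alpha <- exp(par[6])
    if (alpha < 1e-3 || alpha > 1e3) return(1e10)
    eg <- gtr_eigen(exch, freqs)
    rates <- discrete_gamma_rates(alpha, n_rate_categories)
    -sum(vapply(seq_along(counts), function(j) {
      pair_loglik(counts[[j]], t_hat[j], eg, freqs, rates)
    }, numeric(1)))
  }

  par <- c(rep(0, 5), 0)
  fit <- NULL
  for (cycle in 1:3) {
    fit <- optim(par, obj_fixed_t, method = "Nelder-Mead",
                 control = list(maxit = max_iter, reltol = 1e-7))
    par <- fit$par
    eg <- gtr_eigen(c(exp(par[1:5]), 1), freqs)
    rates <- discrete_gamma_rates(exp(par[6]), n_rate_categories)
    t_hat <- vapply(counts, function(N) optimize_pair_t(N, eg, freqs, rates)$t,
                    numeric(1))
  }
  model <- structure(
    list(
      exchangeabilities = setNames(c(exp(fit$par[1:5]), 1), EXCH_NAMES),
      freqs = freqs,
      alpha = exp(fit$par[6]),
      n_rate_categories = n_rate_categories,
      logLik = -fit$value,
      convergence = fit$convergence
    ),
    class = "substitution_model"
  )
  if (fit$convergence != 0) {
    abort("GTR+Gamma optimisation did not converge within the evaluation cap",
          model = model)
  }
  model
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("<substitution_model> GTR+Gamma\n")
  cat("  exchangeabilities:", paste(sprintf("%s=%.3f", EXCH_NAMES, x$exchangeabilities), collapse = " "), "\n")
  cat("  base freqs:", paste(sprintf("%s=%.3f", BASES, x$freqs), collapse = " "), "\n")
  cat(sprintf("  gamma shape %.3f (%d categories), pairwise lnL %.2f\n",
              x$alpha, x$n_rate_categories, x$logLik))
  invisible(x)
}

#' Pairwise GTR+Gamma maximum-likelihood distance matrix
#'
#' Each entry is the ML branch length (expected substitutions per site)
#' between a sequence pair under a fixed substitution model, with pairwise
#' deletion of gap/N sites. Pairs with fewer than `min_sites` comparable
#' sites are reported as `NA`.
#'
#' @param alignment A `coding_alignment`.
#' @param model A `substitution_model` from [fit_gtr_gamma()]; if `NULL`,
#'   one is fitted first.
#' @param min_sites Minimum comparable sites per pair.
#' @return A `dist_matrix` of kind `"gtr_gamma"`.
#' @export
gtr_gamma_matrix <- function(alignment, model = NULL, min_sites = 50) {
  if (is.null(model)) model <- fit_gtr_gamma(alignment)
  seqs <- alignment$seq
  n <- nrow(seqs)
  eg <- gtr_eigen(model$exchangeabilities, model$freqs)
  rates <- discrete_gamma_rates(model$alpha, model$n_rate_categories)
  D <- matrix(0, n, n, dimnames = list(rownames(seqs), rownames(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      N <- pair_pattern_counts(seqs[i, ], seqs[j, ])
      if (sum(N) < min_sites) {
        D[i, j] <- D[j, i] <- NA_real_
      } else {
        D[i, j] <- D[j, i] <- optimize_pair_t(N, eg, model$freqs, rates)$t
      }
    }
  }
  if (anyNA(D)) warn("pairs with too few comparable sites reported as NA")
  new_dist_matrix(D, "gtr_gamma")
}
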