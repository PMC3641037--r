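# Neutrality and demographic tests on the coding mitochondrial alignment:
# Fu's Fs built on the Ewens sampling formula with a coalescent null, and
# the McDonald-Kreitman test with codon-pathway counting and an exact
# Fisher test by hypergeometric enumeration.

#' Mean pairwise nucleotide differences (theta-pi)
#'
#' Mean over ingroup sequence pairs of the per-pair count of differing
#' sites, with pairwise deletion of gap/N sites.
#'
#' @param alignment A `coding_alignment`.
#' @return A single number.
#' @export
theta_pi <- function(alignment) {
  seqs <- ingroup_seqs(alignment)
  if (nrow(seqs) < 2) abort("need at least 2 ingroup sequences")
  n <- nrow(seqs)
  valid <- seqs %in% c("A", "C", "G", "T")
  dim(valid) <- dim(seqs)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- valid[i, ] & valid[j, ]
      total <- total + sum(seqs[i, ok] != seqs[j, ok])
    }
  }
  total / choose(n, 2)
}

#' Ewens sampling distribution of the number of distinct alleles
#'
#' P(K = k) = |S(n, k)| theta^k / (theta (theta+1) ... (theta+n-1)), with
#' unsigned Stirling numbers of the first kind built by the standard
#' recurrence in log space (overflow-safe for large n).
#'
#' @param n Sample size.
#' @param theta Scaled mutation rate (> 0).
#' @return An `ewens_distribution`: `n`, `theta`, `prob` (length n,
#'   P(K = k) for k = 1..n), `log_stirling`.
#' @export
ewens_k_distribution <- function(n, theta) {
  if (theta <= 0) abort("theta must be > 0")
  if (n < 1) abort("n must be >= 1")
  ls <- log_stirling_first(n)
  logp <- ls + seq_len(n) * log(theta) - sum(log(theta + 0:(n - 1)))
  prob <- exp(logp)
  structure(
    list(n = n, theta = theta, prob = prob, log_stirling = ls),
    class = "ewens_distribution"
  )
}

# log |S(n, k)| for k = 1..n via |S(n+1,k)| = n |S(n,k)| + |S(n,k-1)|.
log_stirling_first <- function(n) {
  ls <- 0 # n = 1: |S(1,1)| = 1
  if (n == 1) return(ls)
  for (m in seq_len(n - 1)) {
    # ls holds row m (k = 1..m); build row m+1 (k = 1..m+1)
    prev <- c(-Inf, ls)          # |S(m, k-1)|
    cur <- c(ls, -Inf) + log(m)  # m |S(m, k)|
    hi <- pmax(prev, cur)
    ls <- hi + log(exp(prev - hi) + exp(cur - hi))
    ls[is.nan(ls)] <- -Inf
  }
  ls
}

#' Fu's Fs statistic with a coalescent p-value
#'
#' Counts distinct haplotypes k (exact sequence identity after removing
#' alignment columns containing any gap; ambiguity codes count as
#' mismatches), estimates theta from mean pairwise differences, and sets
#' S' = P(K >= k | theta) under the Ewens sampling formula;
#' Fs = ln(S' / (1 - S')). The p-value is the left-tail proportion of
#' neutral constant-size coalescent simulations (same n, theta = theta-pi,
#' infinite-sites haplotype counting) with simulated Fs <= observed,
#' with the +1 correction.
#'
#' @param alignment A `coding_alignment` (ingroup only is used).
#' @param n_simulations Coalescent replicates for the p-value; 0 skips it.
#' @param seed Integer seed.
#' @return A `fu_fs_result`: `n`, `k_obs`, `theta_pi`, `S_prime`, `Fs`,
#'   `p_value`, `n_simulations`.
#' @export
fu_fs <- function(alignment, n_simulations = 1000, seed = 1L) {
  seqs <- ingroup_seqs(alignment)
  if (nrow(seqs) < 2) abort("need at least 2 ingroup sequences")
  gap_cols <- apply(seqs, 2, function(col) any(col == "-"))
  seqs <- seqs[, !gap_cols, drop = FALSE]
  n <- nrow(seqs)
  haps <- apply(seqs, 1, paste, collapse = "")
  k_obs <- length(unique(haps))
  tp <- theta_pi(alignment)
  if (k_obs == 1 || tp == 0) {
    warn("single haplotype: Fs undefined")
    return(structure(
      list(n = n, k_obs = k_obs, theta_pi = tp, S_prime = 1, Fs = NA_real_,
           p_value = NA_real_, n_simulations = 0L),
      class = "fu_fs_result"
    ))
  }
  obs <- fs_from_k_theta(k_obs, n, tp)
  p <- NA_real_
  if (n_simulations > 0) {
    sim <- with_seed(stage_seed(seed, "fs_null"),
                     coalescent_kpi_cpp(n, tp, n_simulations))
    fs_sim <- vapply(seq_len(n_simulations), function(r) {
      if (sim[r, 1] == 1 || sim[r, 2] == 0) return(Inf) # monomorphic sample
      fs_from_k_theta(sim[r, 1], n, sim[r, 2])$Fs
    }, numeric(1))
    p <- (1 + sum(fs_sim <= obs$Fs)) / (1 + n_simulations)
  }
  structure(
    list(n = n, k_obs = k_obs, theta_pi = tp, S_prime = obs$S_prime,
         Fs = obs$Fs, p_value = p, n_simulations = n_simulations),
    class = "fu_fs_result"
  )
}

fs_from_k_theta <- function(k, n, theta) {
  ew <- ewens_k_distribution(n, theta)
  S_prime <- sum(ew$prob[k:n])
  S_prime <- min(max(S_prime, 1e-300), 1)
  Fs <- if (S_prime == 1) Inf else log(S_prime / (1 - S_prime))
  list(S_prime = S_prime, Fs = Fs)
}

#' @export
print.fu_fs_result <- function(x, ...) {
  cat(sprintf("<fu_fs_result> n=%d, k=%d, theta_pi=%.3f, Fs=%.3f, p=%s\n",
              x$n, x$k_obs, x$theta_pi,
              ifelse(is.na(x$Fs), NA, x$Fs),
              format(x$p_value)))
  invisible(x)
}

# --- McDonald-Kreitman --------------------------------------------------

# Average synonymous/nonsynonymous change counts over minimal mutational
# pathways between two codons (all orderings of the differing positions,
# paths through stop codons discarded; if all paths hit stops, fall back to
# counting over all paths).
codon_path_counts <- function(c1, c2) {
  diff_pos <- which(c1 != c2)
  d <- length(diff_pos)
  if (d == 0) return(c(syn = 0, nonsyn = 0))
  perms <- if (d == 1) list(diff_pos) else {
    if (d == 2) lapply(list(c(1, 2), c(2, 1)), function(o) diff_pos[o])
    else lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
                function(o) diff_pos[o])
  }
  tally <- function(order, allow_stop) {
    cur <- c1
    syn <- 0; nonsyn <- 0
    for (pos in order) {
      nxt <- cur
      nxt[pos] <- c2[pos]
      aa1 <- GENETIC_CODE[[paste(cur, collapse = "")]]
      aa2 <- GENETIC_CODE[[paste(nxt, collapse = "")]]
      if (!allow_stop && aa2 == "*" && !identical(nxt, c2)) return(NULL)
      if (aa1 == aa2) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  res <- purrr::compact(lapply(perms, tally, allow_stop = FALSE))
  if (!length(res)) res <- lapply(perms, tally, allow_stop = TRUE)
  colMeans(do.call(rbind, res))
}

#' McDonald-Kreitman test
#'
#' Classifies coding changes as polymorphic (variable within the ingroup)
#' or fixed (monomorphic within ingroup and within outgroup, but different
#' between them) and as synonymous or nonsynonymous by averaging over
#' minimal mutational pathways between codon states. Codons containing
#' gaps or N, codons with more than two states in a group, sites
#' polymorphic in the outgroup, and codons mixing polymorphic and fixed
#' differences are excluded and logged. Neutrality is tested with a
#' two-sided Fisher exact test computed by hypergeometric enumeration.
#'
#' @param alignment A `coding_alignment` with at least 2 ingroup and 1
#'   outgroup sequences.
#' @return An `mk_result`: `counts` (2x2 matrix), `p_value`,
#'   `excluded` (tibble: codon index, reason).
#' @export
mcdonald_kreitman <- function(alignment) {
  seqs <- alignment$seq
  ing <- seqs[!alignment$is_outgroup, , drop = FALSE]
  out <- seqs[alignment$is_outgroup, , drop = FALSE]
  if (nrow(ing) < 2 || nrow(out) < 1) {
    abort("need >= 2 ingroup and >= 1 outgroup sequences")
  }
  off <- alignment$frame_offset
  L <- ncol(seqs)
  n_codons <- (L - off) %/% 3
  # frame check: internal stops in the first ingroup sequence
  ref <- ing[1, ]
  for (ci in seq_len(n_codons - 1)) {
    cd <- ref[(off + (ci - 1) * 3 + 1):(off + ci * 3)]
    if (all(cd %in% c("A", "C", "G", "T")) &&
        GENETIC_CODE[[paste(cd, collapse = "")]] == "*") {
      abort(sprintf("internal stop codon at codon %d: frame violation", ci))
    }
  }
  Ps <- 0; Pn <- 0; Ds <- 0; Dn <- 0
  excluded <- list()
  note <- function(ci, reason) {
    excluded[[length(excluded) + 1]] <<- tibble::tibble(codon = ci, reason = reason)
  }
  for (ci in seq_len(n_codons)) {
    cols <- (off + (ci - 1) * 3 + 1):(off + ci * 3)
    icod <- ing[, cols, drop = FALSE]
    ocod <- out[, cols, drop = FALSE]
    if (any(!(rbind(icod, ocod) %in% c("A", "C", "G", "T")))) {
      note(ci, "gap_or_N"); next
    }
    iu <- unique(apply(icod, 1, paste, collapse = ""))
    ou <- unique(apply(ocod, 1, paste, collapse = ""))
    if (length(ou) > 1) { note(ci, "outgroup_polymorphic"); next }
    if (length(iu) > 2) { note(ci, "more_than_two_ingroup_states"); next }
    per_site_states <- apply(rbind(icod, ocod), 2, function(col) length(unique(col)))
    if (any(per_site_states > 2)) { note(ci, "more_than_two_states_at_site"); next }
    if (length(iu) == 2) {
      c1 <- strsplit(iu[1], "")[[1]]
      c2 <- strsplit(iu[2], "")[[1]]
      # a codon both polymorphic within the ingroup and different from the
      # outgroup at other sites mixes classes: excluded
      poly_sites <- which(c1 != c2)
      fixed_sites <- which(c1 == c2 & c1 != strsplit(ou, "")[[1]])
      if (length(fixed_sites) > 0) { note(ci, "mixed_polymorphic_fixed"); next }
      cnt <- codon_path_counts(c1, c2)
      Ps <- Ps + cnt["syn"]; Pn <- Pn + cnt["nonsyn"]
    } else if (iu != ou) {
      cnt <- codon_path_counts(strsplit(iu, "")[[1]], strsplit(ou, "")[[1]])
      Ds <- Ds + cnt["syn"]; Dn <- Dn + cnt["nonsyn"]
    }
  }
  counts <- matrix(c(Ps, Pn, Ds, Dn), 2, 2,
                   dimnames = list(c("synonymous", "nonsynonymous"),
                                   c("polymorphic", "fixed")))
  p <- fisher_exact_2x2(round(counts))
  structure(
    list(counts = counts, p_value = p,
         excluded = if (length(excluded)) dplyr::bind_rows(excluded)
                    else tibble::tibble(codon = integer(), reason = character())),
    class = "mk_result"
  )
}

#' @export
print.mk_result <- function(x, ...) {
  cat("<mk_result> McDonald-Kreitman 2x2 counts:\n")
  print(x$counts)
  cat(sprintf("Fisher exact (two-sided) p = %.4g; %d codons excluded\n",
              x$p_value, nrow(x$excluded)))
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Enumerates all tables with the observed margins, computes each table's
#' hypergeometric probability, and sums the probabilities not exceeding the
#' observed table's (with a small relative tolerance for ties).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(dim(tab) == c(2, 2), all(tab >= 0))
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  if (N == 0) return(1)
  a_range <- max(0, r1 + c1 - N):min(r1, c1)
  logp <- lchoose(c1, a_range) + lchoose(N - c1, r1 - a_range) - lchoose(N, r1)
  p_obs <- logp[a_range == tab[1, 1]]
  sum(exp(logp[logp <= p_obs + 1e-7]))
}
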