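# Internal helpers shared across modules.

# Derive a reproducible child seed from a master seed and a stage tag.
# Keeps all derived seeds inside the 32-bit integer range.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729 + 13) %% 2147483647L)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Nearest-rank empirical percentile: smallest value with cdf >= prob.
nearest_rank_quantile <- function(x, prob) {
  x <- sort(x)
  x[max(1L, ceiling(prob * length(x)))]
}

# Empirical percentile under either convention used by the pair screen.
screen_quantile <- function(x, prob, convention = c("nearest-rank", "interpolated")) {
  convention <- match.arg(convention)
  if (convention == "nearest-rank") {
    nearest_rank_quantile(x, prob)
  } else {
    unname(stats::quantile(x, prob, type = 7))
  }
}

# Long (unordered-pair) view of a square distance matrix.
pairs_of <- function(D) {
  labs <- rownames(D)
  idx <- which(upper.tri(D), arr.ind = TRUE)
  tibble::tibble(
    id_a = labs[idx[, 1]],
    id_b = labs[idx[, 2]],
    value = D[idx]
  )
}

check_square_labelled <- function(m, arg = "D") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort(sprintf("`%s` must be a square matrix", arg))
  }
  if (is.null(rownames(m))) rownames(m) <- colnames(m)
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("ind", seq_len(nrow(m)))
  m
}
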