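# Landscape-genetic association scan: univariate logistic regression of
# each locus's band presence on each environmental variable, gated on BOTH
# the likelihood-ratio (G) and Wald tests passing a Bonferroni-corrected
# threshold.

#' Univariate logistic association between a locus and an environmental variable
#'
#' Fits presence ~ env by maximum likelihood (IRLS via `stats::glm`) and
#' reports the likelihood-ratio statistic G against the intercept-only
#' model and the Wald statistic W = (beta / SE)^2, each referred to
#' chi-square(1). Complete or quasi-complete separation (monotone
#' likelihood) is detected and flagged; no p-values are reported for
#' flagged or skipped fits.
#'
#' @param presence 0/1 vector.
#' @param env Numeric vector, same length.
#' @return A one-row tibble: `beta`, `se`, `G`, `W`, `p_G`, `p_W`,
#'   `status` ("ok", "separation", "skipped_constant", "skipped_short").
#' @export
logistic_assoc <- function(presence, env) {
  ok <- !is.na(presence) & !is.na(env)
  presence <- presence[ok]; env <- env[ok]
  empty <- tibble::tibble(beta = NA_real_, se = NA_real_, G = NA_real_,
                          W = NA_real_, p_G = NA_real_, p_W = NA_real_)
  if (length(presence) < 10) return(dplyr::mutate(empty, status = "skipped_short"))
  if (length(unique(env)) < 2 || length(unique(presence)) < 2) {
    return(dplyr::mutate(empty, status = "skipped_constant"))
  }
  fit <- suppressWarnings(glm(presence ~ env, family = binomial()))
  co <- summary(fit)$coefficients
  beta <- co["env", "Estimate"]; se <- co["env", "Std. Error"]
  mu <- fit$fitted.values
  separated <- !fit$converged || any(mu > 1 - 1e-8) || any(mu < 1e-8) ||
    abs(beta) > 15 || se > 50
  G <- max(0, fit$null.deviance - fit$deviance)
  W <- (beta / se)^2
  if (separated) {
    return(tibble::tibble(beta = beta, se = se, G = G, W = W,
                          p_G = NA_real_, p_W = NA_real_, status = "separation"))
  }
  tibble::tibble(
    beta = beta, se = se, G = G, W = W,
    p_G = pchisq(G, 1, lower.tail = FALSE),
    p_W = pchisq(W, 1, lower.tail = FALSE),
    status = "ok"
  )
}

#' Genome-wide locus-by-environment association scan
#'
#' Runs [logistic_assoc()] for every locus x variable combination. A locus
#' is called significant only if both the G and Wald p-values fall below
#' the Bonferroni threshold (1 - confidence) / n_tests for at least one
#' variable. By default n_tests counts all attempted locus x variable
#' pairs; `threshold_on_completed` recomputes it on completed (non-skipped)
#' tests only — both counts are reported.
#'
#' @param markers Binary marker matrix.
#' @param env Environment table (locality_id + numeric variables).
#' @param samples Sample table linking individuals to localities.
#' @param confidence Family-wise confidence level (paper-style 0.99).
#' @param threshold_on_completed Use completed tests in the denominator.
#' @return A `sam_scan_result`: `associations` (tibble), `n_loci`,
#'   `n_variables`, `n_tests_attempted`, `n_tests_completed`, `threshold`,
#'   `significant` (tibble locus/variable), `dropped_loci`.
#' @export
sam_scan <- function(markers, env, samples, confidence = 0.99,
                     threshold_on_completed = FALSE) {
  markers <- validate_marker_matrix(markers)
  loc <- samples$locality_id[match(rownames(markers), samples$individual_id)]
  if (anyNA(loc)) abort("every marker individual needs sample metadata")
  has_env <- loc %in% env$locality_id
  if (!all(has_env)) {
    warn(sprintf("%d individuals without environmental data excluded", sum(!has_env)))
  }
  markers <- markers[has_env, , drop = FALSE]
  loc <- loc[has_env]
  vars <- setdiff(names(env), "locality_id")
  if (!length(vars)) abort("no usable environmental variables")
  E <- as.matrix(env[match(loc, env$locality_id), vars])
  mono <- apply(markers, 2, function(x) length(unique(x[!is.na(x)])) < 2)
  dropped <- colnames(markers)[mono]
  markers <- markers[, !mono, drop = FALSE]
  grid <- expand.grid(locus = colnames(markers), variable = vars,
                      stringsAsFactors = FALSE)
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    logistic_assoc(markers[, grid$locus[i]], E[, grid$variable[i]])
  })
  assoc <- dplyr::bind_cols(tibble::as_tibble(grid), res)
  n_attempted <- nrow(assoc)
  n_completed <- sum(assoc$status == "ok")
  n_tests <- if (threshold_on_completed) n_completed else n_attempted
  threshold <- (1 - confidence) / n_tests
  assoc$significant <- !is.na(assoc$p_G) & !is.na(assoc$p_W) &
    assoc$p_G < threshold & assoc$p_W < threshold
  structure(
    list(
      associations = assoc,
      n_loci = ncol(markers),
      n_variables = length(vars),
      n_tests_attempted = n_attempted,
      n_tests_completed = n_completed,
      threshold = threshold,
      confidence = confidence,
      significant = dplyr::filter(assoc, .data$significant) |>
        dplyr::select("locus", "variable", "beta", "G", "W", "p_G", "p_W"),
      dropped_loci = dropped
    ),
    class = "sam_scan_result"
  )
}

#' @export
print.sam_scan_result <- function(x, ...) {
  cat(sprintf(
    "<sam_scan_result> %d loci x %d variables: %d significant loci at threshold %.3g (confidence %.2f)\n",
    x$n_loci, x$n_variables, length(unique(x$significant$locus)),
    x$threshold, x$confidence))
  invisible(x)
}
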