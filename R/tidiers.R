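# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @export
tidy.admixture_fit <- function(x, ...) {
  tibble::as_tibble(x$q, .name_repair = ~ sprintf("q%d", seq_along(.x))) |>
    dplyr::mutate(individual_id = x$individual_ids, .before = 1) |>
    tidyr::pivot_longer(-"individual_id", names_to = "cluster",
                        values_to = "proportion") |>
    dplyr::mutate(cluster = as.integer(sub("^q", "", .data$cluster)))
}

#' @export
glance.admixture_fit <- function(x, ...) {
  tibble::tibble(K = x$K, model_lnP = x$model_lnP, alpha = x$alpha,
                 n_individuals = nrow(x$q), n_loci = ncol(x$p), seed = x$seed)
}

#' @export
tidy.anosim_result <- function(x, ...) {
  tibble::tibble(R = x$R, p = x$p,
                 mean_rank_between = x$mean_rank_between,
                 mean_rank_within = x$mean_rank_within,
                 M = x$M, n_permutations = x$n_permutations)
}

#' @export
glance.anosim_result <- tidy.anosim_result

#' @export
tidy.dbrda_result <- function(x, ...) {
  tibble::tibble(pseudo_F = x$pseudo_F,
                 proportion_explained = x$proportion_explained,
                 p = x$p, m = x$m, df_residual = x$df_residual,
                 negative_eigen_share = x$negative_eigen_share)
}

#' @export
glance.dbrda_result <- tidy.dbrda_result

#' @export
tidy.pair_screen <- function(x, ...) x$pairs

#' @export
glance.pair_screen <- function(x, ...) {
  tibble::tibble(mode = x$mode, n_flagged = x$n_flagged, n_pairs = x$n_pairs,
                 threshold_gen = x$threshold_gen, threshold_geo = x$threshold_geo,
                 quartile = x$quartile)
}

#' @export
tidy.fu_fs_result <- function(x, ...) {
  tibble::tibble(n = x$n, k_obs = x$k_obs, theta_pi = x$theta_pi,
                 S_prime = x$S_prime, Fs = x$Fs, p_value = x$p_value,
                 n_simulations = x$n_simulations)
}

#' @export
glance.fu_fs_result <- tidy.fu_fs_result

#' @export
tidy.mk_result <- function(x, ...) {
  tibble::tibble(
    class = rep(rownames(x$counts), 2),
    category = rep(colnames(x$counts), each = 2),
    count = as.vector(x$counts)
  )
}

#' @export
glance.mk_result <- function(x, ...) {
  tibble::tibble(
    syn_polymorphic = x$counts[1, 1], nonsyn_polymorphic = x$counts[2, 1],
    syn_fixed = x$counts[1, 2], nonsyn_fixed = x$counts[2, 2],
    p_value = x$p_value, n_excluded_codons = nrow(x$excluded)
  )
}

#' @export
tidy.sam_scan_result <- function(x, ...) x$associations

#' @export
glance.sam_scan_result <- function(x, ...) {
  tibble::tibble(n_loci = x$n_loci, n_variables = x$n_variables,
                 n_tests_attempted = x$n_tests_attempted,
                 n_tests_completed = x$n_tests_completed,
                 threshold = x$threshold, confidence = x$confidence,
                 n_significant_loci = length(unique(x$significant$locus)))
}

#' @export
tidy.delta_k_table <- function(x, ...) tibble::as_tibble(x)

#' Admixture bar plot (STRUCTURE-style)
#' @param object An `admixture_fit`.
#' @param ... Unused.
#' @export
autoplot.admixture_fit <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(individual_id = factor(.data$individual_id,
                                         levels = object$individual_ids))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$individual_id,
                                   y = .data$proportion,
                                   fill = factor(.data$cluster))) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "ancestry proportion", fill = "cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Delta-K profile plot
#' @param object A `delta_k_table`.
#' @param ... Unused.
#' @export
autoplot.delta_k_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$K, y = .data$delta_K)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(y = expression(Delta * K)) +
    ggplot2::theme_minimal()
}

#' NMDS ordination plot
#' @param object An `nmds_result`.
#' @param labels Optional cluster assignment to colour points.
#' @param ... Unused.
#' @export
autoplot.nmds_result <- function(object, labels = NULL, ...) {
  df <- tibble::as_tibble(object$coordinates, rownames = "individual_id")
  if (!is.null(labels)) {
    df$cluster <- factor(resolve_labels(labels, df$individual_id))
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(caption = sprintf("stress-1 = %.3f", object$stress))
  if (is.null(df$cluster)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$cluster))
}

#' Map of flagged pairs
#' @param object A `pair_screen`.
#' @param samples Sample table with coordinates.
#' @param ... Unused.
#' @export
autoplot.pair_screen <- function(object, samples, ...) {
  seg <- object$pairs |>
    dplyr::left_join(dplyr::select(samples, "individual_id",
                                   lon_a = "longitude", lat_a = "latitude"),
                     by = c(id_a = "individual_id")) |>
    dplyr::left_join(dplyr::select(samples, "individual_id",
                                   lon_b = "longitude", lat_b = "latitude"),
                     by = c(id_b = "individual_id"))
  ggplot2::ggplot(samples, ggplot2::aes(x = .data$longitude, y = .data$latitude)) +
    ggplot2::geom_point(size = 0.8, colour = "grey40") +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$lon_a, y = .data$lat_a,
                                       xend = .data$lon_b, yend = .data$lat_b),
                          colour = "firebrick", alpha = 0.5) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(title = sprintf("%s pairs (n = %d)", object$mode, object$n_flagged)) +
    ggplot2::theme_minimal()
}
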