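# Quartile-intersection screen for barriers to gene flow and long-distance
# dispersal: flag individual pairs jointly extreme in genetic and geographic
# distance.

#' Screen individual pairs for barriers or long-distance dispersal
#'
#' Over all n(n-1)/2 unordered pairs, computes the empirical 25th and 75th
#' percentiles of each distance vector. Barrier pairs combine high genetic
#' with low geographic distance (d_gen >= Q3_gen and d_geo <= Q1_geo);
#' long-distance-dispersal (ldd) pairs combine low genetic with high
#' geographic distance (d_gen <= Q1_gen and d_geo >= Q3_geo). Comparisons
#' are inclusive; the default quartile is the nearest-rank percentile
#' (deterministic under ties), with linear interpolation as an option.
#'
#' @param D_gen,D_geo `dist_matrix` objects over the same individuals.
#' @param mode `"barrier"` or `"ldd"`.
#' @param quartile Percentile convention, `"nearest-rank"` or
#'   `"interpolated"`.
#' @return A `pair_screen`: `mode`, `threshold_gen`, `threshold_geo`,
#'   `pairs` (tibble: id_a, id_b, d_gen, d_geo, mode), `n_flagged`,
#'   `n_pairs`, `ties` (counts of pairs exactly at either threshold).
#' @export
screen_pairs <- function(D_gen, D_geo, mode = c("barrier", "ldd"),
                         quartile = c("nearest-rank", "interpolated")) {
  mode <- match.arg(mode)
  quartile <- match.arg(quartile)
  D_gen <- check_square_labelled(D_gen, "D_gen")
  D_geo <- check_square_labelled(D_geo, "D_geo")
  if (nrow(D_gen) < 4) abort("need at least 4 individuals")
  if (!identical(rownames(D_gen), rownames(D_geo))) {
    common <- intersect(rownames(D_gen), rownames(D_geo))
    if (length(common) != nrow(D_gen) || length(common) != nrow(D_geo)) {
      abort("D_gen and D_geo label sets differ")
    }
    D_geo <- D_geo[rownames(D_gen), rownames(D_gen)]
  }
  pg <- pairs_of(D_gen)
  pe <- pairs_of(D_geo)
  tab <- tibble::tibble(id_a = pg$id_a, id_b = pg$id_b,
                        d_gen = pg$value, d_geo = pe$value)
  keep <- stats::complete.cases(tab)
  tab <- tab[keep, ]
  if (mode == "barrier") {
    thr_gen <- screen_quantile(tab$d_gen, 0.75, quartile)
    thr_geo <- screen_quantile(tab$d_geo, 0.25, quartile)
    flag <- tab$d_gen >= thr_gen & tab$d_geo <= thr_geo
  } else {
    thr_gen <- screen_quantile(tab$d_gen, 0.25, quartile)
    thr_geo <- screen_quantile(tab$d_geo, 0.75, quartile)
    flag <- tab$d_gen <= thr_gen & tab$d_geo >= thr_geo
  }
  flagged <- tab[flag, ]
  flagged$mode <- mode
  structure(
    list(
      mode = mode,
      threshold_gen = thr_gen,
      threshold_geo = thr_geo,
      quartile = quartile,
      pairs = flagged,
      n_flagged = nrow(flagged),
      n_pairs = nrow(tab),
      ties = c(gen = sum(tab$d_gen == thr_gen), geo = sum(tab$d_geo == thr_geo))
    ),
    class = "pair_screen"
  )
}

#' @export
print.pair_screen <- function(x, ...) {
  cat(sprintf(
    "<pair_screen> mode=%s: %d of %d pairs flagged (gen %s %.4g, geo %s %.4g)\n",
    x$mode, x$n_flagged, x$n_pairs,
    if (x$mode == "barrier") ">=" else "<=", x$threshold_gen,
    if (x$mode == "barrier") "<=" else ">=", x$threshold_geo))
  invisible(x)
}
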