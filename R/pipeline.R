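# End-to-end orchestration: simulate (or load) -> distances -> admixture +
# delta-K -> NMDS/Gaussian cross-check -> ANOSIM -> dbRDA partitioning ->
# barrier/LDD screens -> sequence tests -> environmental scan, with every
# stage seeded from one master seed and all outputs written to a directory.

#' Pipeline configuration
#'
#' @param simulation A [sim_config()] to generate inputs, or `NULL` to use
#'   file paths.
#' @param markers_path,metadata_path,fasta_path,env_path Input files (used
#'   when `simulation` is `NULL`).
#' @param outgroups Outgroup sequence ids for the alignment.
#' @param k_min,k_max Consecutive K grid for the admixture scan.
#' @param n_runs Runs per K (the delta-K denominator needs >= 2).
#' @param burn_in,sweeps Gibbs sweeps per run.
#' @param alpha Dirichlet concentration used in the admixture scan; the
#'   default 0.2 favours near-pure ancestry, appropriate for distinct
#'   clusters with narrow contact zones.
#' @param n_permutations Permutations for ANOSIM and dbRDA.
#' @param quartile Pair-screen percentile convention.
#' @param confidence Confidence level of the association scan.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            markers_path = NULL, metadata_path = NULL,
                            fasta_path = NULL, env_path = NULL,
                            outgroups = character(),
                            k_min = 2, k_max = 8, n_runs = 6,
                            burn_in = 300, sweeps = 200, alpha = 0.2,
                            n_permutations = 999,
                            quartile = "nearest-rank",
                            confidence = 0.99,
                            seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_permutations < 99) abort("use at least 99 permutations")
  if (cfg$k_max < cfg$k_min + 2) abort("K grid needs at least 3 consecutive values")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `simulation` mapping is passed to [sim_config()].
#'
#' @param path YAML (or JSON) file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulation)) {
    raw$simulation <- do.call(sim_config, raw$simulation)
  }
  do.call(pipeline_config, raw)
}

#' Run the full phylogeographic analysis pipeline
#'
#' Executes every stage on simulated or loaded inputs and writes distance
#' matrices, the admixture run log and delta-K table, cluster assignments,
#' ANOSIM tables, the dbRDA report, barrier/LDD pair lists (TSV + GeoJSON),
#' sequence-test results, association-scan tables, and `summary.json` with
#' the headline statistics. Stages whose inputs are absent are marked
#' "skipped" in the summary.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return The summary list, invisibly; side effect: files in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    inform(msg)
  }
  summary <- list(seed = config$seed, stages = list())
  t0 <- Sys.time()
  logf("pipeline start, master seed %d", config$seed)

  # --- inputs ---
  if (!is.null(config$simulation)) {
    sim <- simulate_dataset(config$simulation)
    markers <- sim$markers; samples <- sim$samples
    alignment <- sim$alignment; env <- sim$env
    write_simulation(sim, file.path(out_dir, "inputs"))
    logf("simulated %d individuals x %d loci (seed %d)",
         nrow(markers), ncol(markers), config$simulation$seed)
  } else {
    ds <- load_dataset(config$markers_path, config$metadata_path,
                       config$fasta_path, config$env_path,
                       outgroups = config$outgroups)
    markers <- ds$markers; samples <- ds$samples
    alignment <- ds$alignment; env <- ds$env
    if (length(ds$env_missing)) {
      keep_env <- !samples$individual_id %in% ds$env_missing
      logf("%d individuals lack env data (kept for non-env stages)", sum(!keep_env))
    }
  }

  # --- distances ---
  D_jac <- jaccard_matrix(markers)
  D_geo <- geographic_matrix(samples)
  write_table(tibble::as_tibble(unclass(D_jac), rownames = "individual_id"),
              file.path(out_dir, "dist_jaccard.tsv"))
  write_table(tibble::as_tibble(unclass(D_geo), rownames = "individual_id"),
              file.path(out_dir, "dist_geographic.tsv"))
  summary$stages$distances <- "done"

  # --- admixture + delta-K ---
  runs <- admixture_run_grid(markers, config$k_min:config$k_max,
                             n_runs = config$n_runs, burn_in = config$burn_in,
                             sweeps = config$sweeps, alpha = config$alpha,
                             seed = stage_seed(config$seed, "admixture"))
  write_table(runs, file.path(out_dir, "admixture_runs.tsv"))
  dk <- delta_k(runs)
  write_table(tibble::as_tibble(dk), file.path(out_dir, "delta_k.tsv"))
  K_best <- best_k(dk)
  logf("delta-K optimum: K = %d", K_best)
  fit <- fit_admixture(markers, K_best, burn_in = 2 * config$burn_in,
                       sweeps = 2 * config$sweeps, alpha = config$alpha,
                       seed = stage_seed(config$seed, "admixture_final"))
  clusters <- assign_clusters(fit)
  write_table(clusters, file.path(out_dir, "clusters.tsv"))
  write_table(dplyr::bind_cols(
    tibble::tibble(individual_id = fit$individual_ids),
    tibble::as_tibble(fit$q, .name_repair = ~ sprintf("q%d", seq_along(.x)))
  ), file.path(out_dir, "admixture_q.tsv"))
  summary$stages$admixture <- "done"
  summary$delta_k_optimum <- K_best

  # --- NMDS + Gaussian cross-check ---
  ord <- nmds(D_jac, dims = 2, seed = stage_seed(config$seed, "nmds"))
  gm <- gaussian_mixture_clusters(ord, K_max = config$k_max,
                                  seed = stage_seed(config$seed, "gmm"))
  write_table(gm$assignment, file.path(out_dir, "clusters_gaussian.tsv"))
  summary$gaussian_K <- gm$K
  summary$nmds_stress <- ord$stress
  summary$stages$ordination <- "done"

  # --- ANOSIM: geographic separation of genetic clusters ---
  an <- anosim(D_geo, clusters, n_permutations = config$n_permutations,
               seed = stage_seed(config$seed, "anosim"))
  an_pw <- anosim_pairwise(D_geo, clusters, n_permutations = config$n_permutations,
                           seed = stage_seed(config$seed, "anosim_pw"))
  write_table(glance(an), file.path(out_dir, "anosim_global.tsv"))
  write_table(an_pw, file.path(out_dir, "anosim_pairwise.tsv"))
  summary$anosim_global_R <- an$R
  summary$anosim_global_p <- an$p
  summary$stages$anosim <- "done"

  # --- dbRDA partitioning ---
  rep_tab <- ibd_cluster_report(D_jac, samples, clusters,
                                n_permutations = config$n_permutations,
                                seed = stage_seed(config$seed, "dbrda"))
  write_table(tibble::as_tibble(rep_tab), file.path(out_dir, "dbrda_report.tsv"))
  summary$dbrda_ibd_proportion <-
    rep_tab$proportion[rep_tab$analysis == "ibd"][1]
  summary$dbrda_ibd_pseudo_F <-
    rep_tab$pseudo_F[rep_tab$analysis == "ibd"][1]
  summary$dbrda_cluster_proportion <-
    rep_tab$proportion[rep_tab$analysis == "clusters_partial"][1]
  summary$dbrda_cluster_pseudo_F <-
    rep_tab$pseudo_F[rep_tab$analysis == "clusters_partial"][1]
  summary$stages$dbrda <- "done"

  # --- barrier / LDD screens (marker distances) ---
  for (mode in c("barrier", "ldd")) {
    sc <- screen_pairs(D_jac, D_geo, mode = mode, quartile = config$quartile)
    write_table(sc$pairs, file.path(out_dir, sprintf("pairs_%s.tsv", mode)))
    write_geojson_pairs(sc, samples, file.path(out_dir, sprintf("pairs_%s.geojson", mode)))
    summary[[sprintf("%s_pair_count", mode)]] <- sc$n_flagged
  }
  summary$stages$screen <- "done"

  # --- sequence distances + screens ---
  if (!is.null(alignment) && sum(!alignment$is_outgroup) >= 4) {
    ing_ids <- alignment$ids[!alignment$is_outgroup]
    sub <- coding_alignment(alignment$seq[!alignment$is_outgroup, , drop = FALSE])
    model <- fit_gtr_gamma(sub)
    D_gtr <- gtr_gamma_matrix(sub, model)
    write_table(tibble::as_tibble(unclass(D_gtr), rownames = "individual_id"),
                file.path(out_dir, "dist_gtr.tsv"))
    common <- intersect(ing_ids, rownames(D_geo))
    for (mode in c("barrier", "ldd")) {
      sc <- screen_pairs(D_gtr[common, common], D_geo[common, common],
                         mode = mode, quartile = config$quartile)
      write_table(sc$pairs, file.path(out_dir, sprintf("pairs_%s_gtr.tsv", mode)))
      summary[[sprintf("%s_pair_count_gtr", mode)]] <- sc$n_flagged
    }
    summary$gtr_alpha <- model$alpha
    summary$stages$sequence_distances <- "done"
  } else {
    summary$stages$sequence_distances <- "skipped"
  }

  # --- sequence tests ---
  if (!is.null(alignment) && sum(!alignment$is_outgroup) >= 3) {
    fs <- fu_fs(alignment, n_simulations = 500,
                seed = stage_seed(config$seed, "fufs"))
    write_table(glance(fs), file.path(out_dir, "fu_fs.tsv"))
    summary$fu_fs <- fs$Fs
    summary$fu_fs_p <- fs$p_value
    if (any(alignment$is_outgroup)) {
      mk <- mcdonald_kreitman(alignment)
      write_table(glance(mk), file.path(out_dir, "mk_test.tsv"))
      write_table(mk$excluded, file.path(out_dir, "mk_excluded_codons.tsv"))
      summary$mk_fisher_p <- mk$p_value
    }
    summary$stages$sequence_tests <- "done"
  } else {
    summary$stages$sequence_tests <- "skipped"
    logf("sequence tests skipped: no usable alignment")
  }

  # --- environmental association scan ---
  if (!is.null(env)) {
    scan <- sam_scan(markers, env, samples, confidence = config$confidence)
    write_table(scan$associations, file.path(out_dir, "sam_associations.tsv"))
    write_table(scan$significant, file.path(out_dir, "sam_significant.tsv"))
    summary$sam_significant_loci <- length(unique(scan$significant$locus))
    summary$sam_threshold <- scan$threshold
    summary$stages$env_scan <- "done"
  } else {
    summary$stages$env_scan <- "skipped"
    logf("environmental scan skipped: no env table")
  }

  summary$elapsed_seconds <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("pipeline done in %.1f s", summary$elapsed_seconds)
  invisible(summary)
}
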