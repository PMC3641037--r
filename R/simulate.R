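# Spatially explicit synthetic data with the statistical structure the
# downstream analyses assume: genetic clusters separated by linear barriers,
# admixed cluster boundaries, isolation by distance within clusters, rare
# long-distance relocations, post-expansion sequence genealogies, and a few
# loci tracking an environmental gradient. Every stage draws its randomness
# from a seed derived deterministically from the single master seed.

#' Simulation configuration
#'
#' Defaults describe an elongated island of 250 x 60 km carved into
#' `n_clusters` longitudinal bands by linear barriers, sampled at
#' `n_localities` sites.
#'
#' @param n_clusters Number of genetic clusters (map bands).
#' @param n_individuals Individuals genotyped.
#' @param n_loci Dominant marker loci.
#' @param map_extent `c(width, height)` in km.
#' @param n_localities Sampling localities scattered over the map.
#' @param ibd_gradient_strength Per-km drift of band frequency away from the
#'   cluster centroid.
#' @param admixture_zone_width Width (km) of the mixed-ancestry band along
#'   each barrier.
#' @param ldd_rate Probability that an individual is relocated to a distant
#'   locality (genotype travels unchanged).
#' @param n_env_variables Environmental surfaces sampled at localities.
#' @param n_env_selected_loci Loci whose band probability is logistic in the
#'   first environmental variable.
#' @param env_effect_size Log-odds of band presence per unit (SD) of the
#'   environmental variable at selected loci.
#' @param seq_length Alignment length in bp; must be a codon multiple.
#' @param theta Scaled whole-sequence mutation rate of the coalescent.
#' @param growth_factor Exponential growth intensity of the within-cluster
#'   coalescent (0 = constant size).
#' @param cluster_divergence Expected substitutions/site on the deep branch
#'   leading to each cluster's root sequence.
#' @param outgroup_divergence Expected substitutions/site to the outgroups.
#' @param omega Acceptance probability of a nonsynonymous mutation, applied
#'   identically on every branch so the McDonald-Kreitman null holds.
#' @param drop_monomorphic Drop loci without band variation (marker
#'   ascertainment switch).
#' @param seed Master seed; all stages derive from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_clusters = 5,
                       n_individuals = 100,
                       n_loci = 300,
                       map_extent = c(250, 60),
                       n_localities = 84,
                       ibd_gradient_strength = 0.001,
                       admixture_zone_width = 8,
                       ldd_rate = 0.02,
                       n_env_variables = 5,
                       n_env_selected_loci = 4,
                       env_effect_size = 2,
                       seq_length = 633,
                       theta = 5,
                       growth_factor = 5,
                       cluster_divergence = 0.02,
                       outgroup_divergence = 0.15,
                       omega = 0.2,
                       drop_monomorphic = FALSE,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_clusters < 1) abort("n_clusters must be >= 1")
  if (cfg$seq_length %% 3 != 0) abort("seq_length must be a codon multiple")
  for (r in c("ldd_rate", "omega")) {
    if (cfg[[r]] < 0 || cfg[[r]] > 1) abort(paste(r, "must lie in [0, 1]"))
  }
  if (cfg$n_individuals < 1 || cfg$n_loci < 1) abort("need at least one individual and one locus")
  structure(cfg, class = "sim_config")
}

#' Simulate the sampling landscape
#'
#' The map is cut into `n_clusters` equal-width longitudinal bands; band
#' boundaries are the barrier segments. Localities fall uniformly over the
#' map; each belongs to exactly one band. Environmental surfaces are
#' low-order polynomials in the map coordinates plus noise, standardised
#' over localities. Geographic coordinates place the map at Mediterranean
#' latitudes (lat 35, lon 23.5 origin).
#'
#' @param config A [sim_config()].
#' @return A `landscape`: list with `localities` (tibble: locality_id, x, y,
#'   latitude, longitude, region), `env` (tibble), `barriers` (list of 2x2
#'   segment matrices), `band_width`, `config`.
#' @export
simulate_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  W <- config$map_extent[1]; H <- config$map_extent[2]
  band <- W / config$n_clusters
  if (band <= max(2, config$admixture_zone_width)) {
    abort(sprintf(
      "map cannot tile %d clusters: band width %.1f km <= admixture zone %.1f km",
      config$n_clusters, band, config$admixture_zone_width))
  }
  with_seed(stage_seed(config$seed, "landscape"), {
    x <- runif(config$n_localities, 0, W)
    y <- runif(config$n_localities, 0, H)
    region <- pmin(config$n_clusters, floor(x / band) + 1L)
    lat0 <- 35; lon0 <- 23.5
    latitude <- lat0 + y / 111.195
    longitude <- lon0 + x / (111.195 * cos(lat0 * pi / 180))
    loc <- tibble::tibble(
      locality_id = sprintf("L%02d", seq_len(config$n_localities)),
      x = x, y = y, latitude = latitude, longitude = longitude,
      region = as.integer(region)
    )
    # environmental gradients run along the island's short (north-south)
    # axis, orthogonal to the barrier-delimited bands, so neutral loci are
    # not spatially confounded with the environmental surfaces
    env <- matrix(NA_real_, config$n_localities, config$n_env_variables)
    for (v in seq_len(config$n_env_variables)) {
      co <- rnorm(3)
      w <- y / H
      raw <- co[1] + co[2] * w + co[3] * w^2 +
        rnorm(config$n_localities, sd = 0.2)
      env[, v] <- as.numeric(scale(raw))
    }
    colnames(env) <- sprintf("env_%02d", seq_len(config$n_env_variables))
    barriers <- lapply(seq_len(config$n_clusters - 1), function(k) {
      rbind(c(k * band, 0), c(k * band, H))
    })
    structure(
      list(
        localities = loc,
        env = dplyr::bind_cols(tibble::tibble(locality_id = loc$locality_id),
                               tibble::as_tibble(env)),
        barriers = barriers,
        band_width = band,
        config = config
      ),
      class = "landscape"
    )
  })
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d localities, %d regions, %d env variables\n",
              nrow(x$localities), length(unique(x$localities$region)),
              ncol(x$env) - 1))
  invisible(x)
}

# Ancestry proportions for an individual at map position x: pure inside a
# band, linearly mixed with the neighbouring band within the admixture zone.
ancestry_at <- function(x, band, K, zone) {
  q <- numeric(K)
  k <- min(K, floor(x / band) + 1)
  q[k] <- 1
  if (zone > 0 && K > 1) {
    for (b in seq_len(K - 1)) {
      d <- x - b * band # signed distance to boundary b
      if (abs(d) < zone) {
        other <- if (d >= 0) b else b + 1L
        mix <- 0.5 * (1 - abs(d) / zone)
        q <- q * (1 - mix)
        q[other] <- q[other] + mix
      }
    }
  }
  q / sum(q)
}

#' Simulate a binary dominant-marker dataset
#'
#' Cluster band frequencies are drawn from the U-shaped Beta(0.5, 0.5)
#' (clamped to (0.01, 0.99)), drift linearly with distance from the cluster
#' centroid (isolation by distance), and individuals near a barrier carry
#' mixed ancestry: each band is drawn from the frequency of a cluster
#' sampled from the individual's ancestry vector. A fraction `ldd_rate` of
#' individuals is then relocated to a distant locality (beyond half the map
#' diagonal) with genotype unchanged. Selected loci ignore cluster structure:
#' their band probability is logistic in the first environmental variable.
#'
#' @param landscape A [simulate_landscape()] result.
#' @param config The same [sim_config()].
#' @return List with `markers` (binary matrix), `samples` (tibble),
#'   `truth` (list: `q` ancestry matrix, `cluster` origin labels,
#'   `selected_loci` indices, `relocated` ids, `p_latent` K x L matrix).
#' @export
simulate_aflp <- function(landscape, config = landscape$config) {
  stopifnot(inherits(landscape, "landscape"))
  if (config$n_loci < 1 || config$n_individuals < 1) {
    abort("need at least one locus and one individual")
  }
  K <- config$n_clusters; L <- config$n_loci; n <- config$n_individuals
  loc <- landscape$localities
  band <- landscape$band_width
  with_seed(stage_seed(config$seed, "aflp"), {
    # geographically stratified sampling: individuals spread evenly over the
    # map bands, mirroring a survey design that covers every subregion
    per_band <- table(factor(rep_len(seq_len(K), n), seq_len(K)))
    home <- unlist(lapply(seq_len(K), function(k) {
      in_band <- which(loc$region == k)
      if (!length(in_band)) in_band <- seq_len(nrow(loc))
      sample(rep(in_band, 2), per_band[k], replace = TRUE)
    }))
    home <- home[sample.int(length(home))]
    p_latent <- matrix(pmin(0.99, pmax(0.01, rbeta(K * L, 0.5, 0.5))), K, L)
    ibd_dir <- sample(c(-1, 1), L, replace = TRUE)
    centroids <- cbind((seq_len(K) - 0.5) * band, config$map_extent[2] / 2)
    selected <- integer(0)
    if (config$n_env_selected_loci > 0) {
      selected <- sample(L, min(L, config$n_env_selected_loci))
    }
    env1 <- landscape$env[[2]][home] # first env variable at home locality
    q <- t(vapply(loc$x[home], ancestry_at, numeric(K),
                  band = band, K = K, zone = config$admixture_zone_width))
    if (K == 1) q <- matrix(1, n, 1)
    markers <- matrix(0L, n, L)
    for (i in seq_len(n)) {
      z <- sample.int(K, L, replace = TRUE, prob = q[i, ])
      d_cent <- sqrt((loc$x[home[i]] - centroids[z, 1])^2 +
                       (loc$y[home[i]] - centroids[z, 2])^2)
      p <- pmin(0.99, pmax(0.01, p_latent[cbind(z, seq_len(L))] +
                             config$ibd_gradient_strength * d_cent * ibd_dir))
      if (length(selected)) {
        p[selected] <- plogis(config$env_effect_size * env1[i])
      }
      markers[i, ] <- rbinom(L, 1L, p)
    }
    # long-distance relocation: genotype travels, position changes
    reloc_try <- which(runif(n) < config$ldd_rate)
    half_diag <- 0.5 * sqrt(sum(config$map_extent^2))
    reloc <- integer(0)
    for (i in reloc_try) {
      d <- sqrt((loc$x - loc$x[home[i]])^2 + (loc$y - loc$y[home[i]])^2)
      far <- which(d > half_diag)
      if (length(far)) {
        home[i] <- far[sample.int(length(far), 1)]
        reloc <- c(reloc, i)
      }
    }
    ids <- sprintf("ind%03d", seq_len(n))
    rownames(markers) <- ids
    colnames(markers) <- sprintf("locus%04d", seq_len(L))
    truth_cluster <- max.col(q) # origin ancestry before relocation
    keep <- rep(TRUE, L)
    if (config$drop_monomorphic) {
      keep <- colSums(markers) > 0 & colSums(markers) < n
    }
    samples <- tibble::tibble(
      individual_id = ids,
      locality_id = loc$locality_id[home],
      latitude = loc$latitude[home],
      longitude = loc$longitude[home],
      cluster_label = truth_cluster
    )
    list(
      markers = markers[, keep, drop = FALSE],
      samples = samples,
      truth = list(
        q = q,
        cluster = truth_cluster,
        selected_loci = match(which(seq_len(L) %in% selected & keep),
                              which(keep)),
        relocated = ids[reloc],
        p_latent = p_latent[, keep, drop = FALSE]
      )
    )
  })
}

# --- coalescent sequence simulation ------------------------------------

STOP_CODONS <- c("TAA", "TAG", "TGA")

GENETIC_CODE <- {
  b <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  g <- expand.grid(b3 = b, b2 = b, b1 = b, stringsAsFactors = FALSE)
  codons <- paste0(g$b1, g$b2, g$b3) # third base cycles fastest
  setNames(aa, codons)
}

random_sense_codons <- function(n_codons) {
  sense <- setdiff(names(GENETIC_CODE)[GENETIC_CODE != "*"], STOP_CODONS)
  sample(sense, n_codons, replace = TRUE)
}

# Apply `n_mut` proposed mutations to a base vector; transitions weighted
# kappa : 1, nonsynonymous proposals accepted with probability omega, stop
# codons always rejected. Applied identically everywhere so that the
# synonymous/nonsynonymous composition of polymorphism and divergence match.
mutate_sequence <- function(seq, n_mut, omega, kappa = 4) {
  if (n_mut == 0) return(seq)
  L <- length(seq)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  for (m in seq_len(n_mut)) {
    s <- sample.int(L, 1)
    cur <- seq[s]
    others <- setdiff(c("A", "C", "G", "T"), cur)
    wts <- ifelse(others == transition[[cur]], kappa, 1)
    new <- sample(others, 1, prob = wts)
    cpos <- (s - 1) %/% 3
    codon <- seq[(cpos * 3 + 1):(cpos * 3 + 3)]
    newcodon <- codon
    newcodon[(s - 1) %% 3 + 1] <- new
    cs <- paste(newcodon, collapse = "")
    if (GENETIC_CODE[[cs]] == "*") next
    syn <- GENETIC_CODE[[paste(codon, collapse = "")]] == GENETIC_CODE[[cs]]
    if (!syn && runif(1) > omega) next
    seq[s] <- new
  }
  seq
}

# Kingman coalescent with exponential growth; returns per-node parent and
# branch lengths for n tips (nodes 1..n tips, n+1..2n-1 internal, root last).
coalescent_tree <- function(n, growth = 0) {
  parent <- integer(2 * n - 1)
  blen <- numeric(2 * n - 1)
  times <- numeric(2 * n - 1)
  active <- seq_len(n)
  t_cur <- 0
  nxt <- n + 1L
  while (length(active) > 1) {
    k <- length(active)
    E <- rexp(1)
    tau <- if (growth > 0) {
      log1p(growth * E * exp(-growth * t_cur) / choose(k, 2)) / growth
    } else {
      E / choose(k, 2)
    }
    t_cur <- t_cur + tau
    pick <- sample.int(k, 2)
    ch <- active[pick]
    parent[ch] <- nxt
    times[nxt] <- t_cur
    blen[ch] <- t_cur - times[ch]
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  list(parent = parent, blen = blen, root = 2L * n - 1L, n = n)
}

evolve_tips <- function(tree, root_seq, theta, omega) {
  n_nodes <- length(tree$parent)
  seqs <- vector("list", n_nodes)
  seqs[[tree$root]] <- root_seq
  # children-major traversal: process nodes in decreasing index (root last)
  for (node in rev(seq_len(n_nodes - 1))) {
    p <- tree$parent[node]
    n_mut <- rpois(1, theta / 2 * tree$blen[node])
    seqs[[node]] <- mutate_sequence(seqs[[p]], n_mut, omega)
  }
  do.call(rbind, seqs[seq_len(tree$n)])
}

#' Simulate a coding mitochondrial alignment
#'
#' Each cluster gets its own coalescent genealogy with exponential growth
#' (`growth_factor`); cluster root sequences sit on deep branches from a
#' common ancestor, and two outgroup sequences branch off even deeper.
#' Mutations carry a 4:1 transition bias; nonsynonymous changes are thinned
#' by `omega` identically on every branch, and stop codons never arise, so
#' the alignment is gap-free coding sequence under a McDonald-Kreitman null.
#'
#' @param landscape A [simulate_landscape()] result.
#' @param config The matching [sim_config()].
#' @param samples Optional sample table (with `cluster_label`) so sequence
#'   ids match the marker individuals; defaults to a fresh set of
#'   `n_individuals` split over clusters.
#' @return A [coding_alignment()] with outgroups `OUT1`, `OUT2`.
#' @export
simulate_sequences <- function(landscape, config = landscape$config, samples = NULL) {
  if (config$theta <= 0) abort("theta must be > 0")
  with_seed(stage_seed(config$seed, "sequences"), {
    K <- config$n_clusters
    if (is.null(samples)) {
      cl <- rep(seq_len(K), length.out = config$n_individuals)
      ids <- sprintf("ind%03d", seq_len(config$n_individuals))
    } else {
      cl <- samples$cluster_label
      ids <- samples$individual_id
    }
    L <- config$seq_length
    anc <- unlist(strsplit(random_sense_codons(L / 3), ""))
    # outgroup lineage
    out_anc <- mutate_sequence(anc, rpois(1, config$outgroup_divergence * L), config$omega)
    outs <- rbind(
      mutate_sequence(out_anc, rpois(1, 0.01 * L), config$omega),
      mutate_sequence(out_anc, rpois(1, 0.01 * L), config$omega)
    )
    seq_rows <- matrix(NA_character_, length(ids), L)
    for (k in seq_len(K)) {
      members <- which(cl == k)
      if (!length(members)) next
      root_k <- mutate_sequence(anc, rpois(1, config$cluster_divergence * L), config$omega)
      if (length(members) == 1) {
        seq_rows[members, ] <- root_k
      } else {
        tree <- coalescent_tree(length(members), config$growth_factor)
        seq_rows[members, ] <- evolve_tips(tree, root_k, config$theta, config$omega)
      }
    }
    all_seq <- rbind(seq_rows, outs)
    rownames(all_seq) <- c(ids, "OUT1", "OUT2")
    coding_alignment(all_seq, outgroups = c("OUT1", "OUT2"), frame_offset = 0L)
  })
}

#' Simulate a complete dataset bundle
#'
#' Runs [simulate_landscape()], [simulate_aflp()] and
#' [simulate_sequences()] under one configuration.
#'
#' @param config A [sim_config()].
#' @return List with `landscape`, `markers`, `samples`, `env`, `alignment`,
#'   `truth`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  landscape <- simulate_landscape(config)
  aflp <- simulate_aflp(landscape, config)
  aln <- simulate_sequences(landscape, config, samples = aflp$samples)
  list(
    landscape = landscape,
    markers = aflp$markers,
    samples = aflp$samples,
    env = landscape$env,
    alignment = aln,
    truth = aflp$truth,
    config = config
  )
}

#' Write a simulated dataset as the standard input bundle
#'
#' Produces `markers.tsv`, `samples.tsv`, `env.tsv`, `alignment.fasta`,
#' `truth.tsv` and `config.yaml` in `dir`.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mk <- tibble::as_tibble(sim$markers, rownames = "individual_id")
  readr::write_tsv(mk, file.path(dir, "markers.tsv"), progress = FALSE)
  readr::write_tsv(sim$samples, file.path(dir, "samples.tsv"), progress = FALSE)
  readr::write_tsv(sim$env, file.path(dir, "env.tsv"), progress = FALSE)
  seqs <- apply(sim$alignment$seq, 1, paste, collapse = "")
  writeLines(paste0(">", names(seqs), "\n", seqs), file.path(dir, "alignment.fasta"))
  truth <- dplyr::bind_cols(
    tibble::tibble(
      individual_id = sim$samples$individual_id,
      true_cluster = sim$truth$cluster,
      relocated = sim$samples$individual_id %in% sim$truth$relocated
    ),
    tibble::as_tibble(sim$truth$q, .name_repair = ~ sprintf("q%d", seq_along(.x)))
  )
  truth$selected_loci <- paste(sim$truth$selected_loci, collapse = ",")
  readr::write_tsv(truth, file.path(dir, "truth.tsv"), progress = FALSE)
  yaml::write_yaml(unclass(sim$config), file.path(dir, "config.yaml"))
  invisible(dir)
}
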