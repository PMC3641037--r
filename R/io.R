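#' Read a binary marker (band presence/absence) matrix
#'
#' Reads a tab-separated table of dominant-marker scores, one row per
#' individual and one column per locus, with an `individual_id` column first.
#' Cells must be 0, 1 or the missing code `"?"` (stored as `NA`).
#'
#' @param path Path to a TSV file with a header row.
#' @return An integer matrix with individual ids as row names and locus ids
#'   as column names; missing scores are `NA`.
#' @export
read_marker_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!"individual_id" %in% names(df)) {
    abort("marker table must have an `individual_id` column")
  }
  ids <- df$individual_id
  if (anyDuplicated(ids)) abort("duplicate individual ids in marker table")
  m <- as.matrix(df[setdiff(names(df), "individual_id")])
  bad <- which(matrix(!(m %in% c("0", "1", "?", NA)), nrow(m)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "non-binary marker cell at individual '%s', locus '%s': value '%s'",
      ids[bad[1, 1]], colnames(m)[bad[1, 2]], m[bad[1, 1], bad[1, 2]]
    ))
  }
  m[m == "?"] <- NA
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  validate_marker_matrix(m)
}

validate_marker_matrix <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("marker matrix needs individual row names and locus column names")
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    abort("duplicate ids in marker matrix")
  }
  vals <- m[!is.na(m)]
  if (length(vals) && !all(vals %in% c(0L, 1L))) {
    abort("marker matrix entries must be 0, 1 or missing")
  }
  m
}

#' Read a sample metadata table
#'
#' @param path TSV with columns `individual_id`, `locality_id`, `latitude`,
#'   `longitude` and optionally `cluster_label`, `haplotype_group`.
#' @return A tibble, one row per individual.
#' @export
read_sample_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  req <- c("individual_id", "locality_id", "latitude", "longitude")
  miss <- setdiff(req, names(df))
  if (length(miss)) abort(paste("sample table missing columns:", paste(miss, collapse = ", ")))
  validate_sample_table(tibble::as_tibble(df))
}

validate_sample_table <- function(df) {
  if (anyDuplicated(df$individual_id)) abort("duplicate individual ids in sample table")
  if (any(abs(df$latitude) > 90, na.rm = TRUE)) abort("latitude out of [-90, 90]")
  if (any(abs(df$longitude) > 180, na.rm = TRUE)) abort("longitude out of [-180, 180]")
  df
}

#' Read an environmental-variable table per locality
#'
#' @param path TSV with a `locality_id` column and one numeric column per
#'   environmental variable.
#' @return A tibble.
#' @export
read_env_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!"locality_id" %in% names(df)) abort("env table must have a `locality_id` column")
  num <- df[setdiff(names(df), "locality_id")]
  if (!all(vapply(num, is.numeric, logical(1)))) abort("env variables must be numeric")
  if (any(!is.finite(as.matrix(num)))) abort("non-finite environmental value")
  tibble::as_tibble(df)
}

#' Read an aligned coding sequence FASTA
#'
#' Sequences must be equal length. Outgroup sequences are recognised by id
#' (the `outgroups` argument) and flagged; the reading frame offset says how
#' many leading bases to skip before the first complete codon.
#'
#' @param path FASTA file of aligned sequences (A, C, G, T, `-`, N).
#' @param outgroups Character vector of sequence ids that are outgroups.
#' @param frame_offset Integer 0, 1 or 2.
#' @return A `coding_alignment`: list with `seq` (character matrix, one row
#'   per sequence), `ids`, `is_outgroup`, `frame_offset`.
#' @export
read_coding_alignment <- function(path, outgroups = character(), frame_offset = 0L) {
  dna <- ape::read.FASTA(path)
  mat <- toupper(do.call(rbind, lapply(as.character(dna), identity)))
  rownames(mat) <- names(dna)
  coding_alignment(mat, outgroups = outgroups, frame_offset = frame_offset)
}

#' Construct a coding alignment object
#'
#' @param seq Character matrix of single bases (rows = sequences, named).
#' @param outgroups Ids flagged as outgroup sequences.
#' @param frame_offset Integer 0, 1 or 2.
#' @return A `coding_alignment` object.
#' @export
coding_alignment <- function(seq, outgroups = character(), frame_offset = 0L) {
  if (is.null(rownames(seq))) abort("alignment rows must be named")
  ok <- seq %in% c("A", "C", "G", "T", "-", "N")
  if (!all(ok)) abort("alignment may contain only A, C, G, T, '-', N")
  if (!frame_offset %in% 0:2) abort("frame offset must be 0, 1 or 2")
  unknown <- setdiff(outgroups, rownames(seq))
  if (length(unknown)) abort(paste("outgroup ids absent from alignment:", paste(unknown, collapse = ", ")))
  structure(
    list(
      seq = seq,
      ids = rownames(seq),
      is_outgroup = rownames(seq) %in% outgroups,
      frame_offset = as.integer(frame_offset)
    ),
    class = "coding_alignment"
  )
}

#' @export
print.coding_alignment <- function(x, ...) {
  cat(sprintf(
    "<coding_alignment> %d sequences (%d outgroup) x %d bp, frame offset %d\n",
    length(x$ids), sum(x$is_outgroup), ncol(x$seq), x$frame_offset
  ))
  invisible(x)
}

ingroup_seqs <- function(aln) aln$seq[!aln$is_outgroup, , drop = FALSE]

#' Load a full analysis dataset
#'
#' Reads and cross-references the marker matrix, sample metadata and the
#' optional sequence alignment and environment table. Every marker row must
#' have metadata; individuals whose locality lacks environmental values are
#' flagged (not dropped) in `$env_missing`.
#'
#' @param markers_path,metadata_path Required TSV paths.
#' @param fasta_path,env_path Optional paths.
#' @param outgroups,frame_offset Passed to [read_coding_alignment()].
#' @return A list with elements `markers`, `samples`, `alignment` (or NULL),
#'   `env` (or NULL), `env_missing` (character vector of individual ids).
#' @export
load_dataset <- function(markers_path, metadata_path, fasta_path = NULL,
                         env_path = NULL, outgroups = character(),
                         frame_offset = 0L) {
  markers <- read_marker_matrix(markers_path)
  samples <- read_sample_table(metadata_path)
  missing_meta <- setdiff(rownames(markers), samples$individual_id)
  if (length(missing_meta)) {
    abort(paste("marker individuals missing from metadata:",
                paste(missing_meta, collapse = ", ")))
  }
  samples <- samples[match(rownames(markers), samples$individual_id), ]
  aln <- if (!is.null(fasta_path)) {
    read_coding_alignment(fasta_path, outgroups = outgroups, frame_offset = frame_offset)
  }
  env <- if (!is.null(env_path)) read_env_table(env_path)
  env_missing <- character()
  if (!is.null(env)) {
    env_missing <- samples$individual_id[!samples$locality_id %in% env$locality_id]
    if (length(env_missing)) {
      warn(sprintf("%d individuals lack environmental data and will be excluded from the association scan",
                   length(env_missing)))
    }
  }
  list(markers = markers, samples = samples, alignment = aln, env = env,
       env_missing = env_missing)
}

#' Write a rectangular result to TSV
#'
#' Numeric columns are written with 6 significant digits.
#'
#' @param result A data frame, or an object with a [tidy()] method.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(result, path) {
  if (!is.data.frame(result)) result <- tidy(result)
  out <- result
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write flagged pairs as GeoJSON LineStrings
#'
#' One LineString per flagged pair, coordinates in RFC 7946
#' (longitude, latitude) order, with properties `id_a`, `id_b`,
#' `genetic_distance`, `geographic_distance`, `mode`.
#'
#' @param pairs A [screen_pairs()] result (or its `$pairs` tibble).
#' @param samples Sample table with coordinates for every paired id.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geojson_pairs <- function(pairs, samples, path) {
  tab <- if (inherits(pairs, "pair_screen")) pairs$pairs else tibble::as_tibble(pairs)
  need <- unique(c(tab$id_a, tab$id_b))
  missing <- setdiff(need, samples$individual_id)
  if (length(missing)) abort(paste("pair ids absent from samples:", paste(missing, collapse = ", ")))
  coord <- function(id) {
    i <- match(id, samples$individual_id)
    c(samples$longitude[i], samples$latitude[i])
  }
  features <- purrr::pmap(tab, function(id_a, id_b, d_gen, d_geo, mode, ...) {
    list(
      type = "Feature",
      geometry = list(
        type = "LineString",
        coordinates = list(coord(id_a), coord(id_b))
      ),
      properties = list(
        id_a = id_a, id_b = id_b,
        genetic_distance = d_gen, geographic_distance = d_geo,
        mode = mode
      )
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
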