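# Readers/writers for the tabular formats the pipeline touches. All files
# are plain TSV; numeric output keeps 15 significant digits so that a
# write/read round trip preserves values to >= 12 significant digits.

#' Read a taxa-by-samples composition table
#'
#' Reads a TSV whose first column holds taxon names and whose remaining
#' column headers are sample ids, joins each column against a metadata
#' table, and returns one normalized [community_profile()] per sample.
#' Cells may be percentages or fractions; the dialect is auto-detected per
#' column (column sum above `percent_threshold` means percent) and is
#' irrelevant after normalization, so mixed tables are handled too.
#'
#' @param path Path to the TSV file.
#' @param meta Data frame with columns `sample_id`, `salt_pct`,
#'   `sample_type`, `organism_group` and optionally `line_id`.
#' @param transposed Set `TRUE` for samples-by-taxa orientation.
#' @param percent_threshold Column-sum threshold above which a column is
#'   considered percent-encoded (default 1.5). Only affects error messages
#'   and the returned `dialect` attribute, since profiles are normalized.
#' @return Named list of [community_profile()] objects, one per sample
#'   column.
#' @export
read_composition_table <- function(path, meta, transposed = FALSE,
                                   percent_threshold = 1.5) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("composition table needs a taxon column and at least one sample column", call. = FALSE)
  taxa <- trimws(as.character(raw[[1]]))
  mat <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- taxa
  if (transposed) {
    mat <- t(mat)
  }
  samples <- colnames(mat)

  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative abundance at row \"%s\", column \"%s\"",
                 rownames(mat)[neg[1, 1]], colnames(mat)[neg[1, 2]]),
         call. = FALSE)
  }

  meta <- as.data.frame(meta)
  unknown <- setdiff(samples, meta$sample_id)
  if (length(unknown)) {
    stop("sample ids absent from metadata: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!"line_id" %in% names(meta)) meta$line_id <- meta$sample_id

  profiles <- lapply(samples, function(sid) {
    row <- meta[match(sid, meta$sample_id), ]
    community_profile(
      mat[, sid],
      meta = sample_metadata(sid, row$salt_pct, row$sample_type,
                             row$organism_group, line_id = row$line_id)
    )
  })
  names(profiles) <- samples
  attr(profiles, "dialect") <-
    ifelse(colSums(mat) > percent_threshold, "percent", "fraction")
  profiles
}

#' Write community profiles as a taxa-by-samples TSV
#'
#' @param profiles List of [community_profile()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_composition_table <- function(profiles, path) {
  taxa <- sort(unique(unlist(lapply(profiles, function(p) names(p$abundances)))))
  ids <- vapply(seq_along(profiles), function(i) {
    id <- profile_id(profiles[[i]])
    if (is.na(id)) paste0("sample", i) else id
  }, character(1))
  mat <- vapply(profiles, function(p) {
    v <- stats::setNames(numeric(length(taxa)), taxa)
    v[names(p$abundances)] <- p$abundances
    v
  }, numeric(length(taxa)))
  mat <- matrix(mat, nrow = length(taxa), dimnames = list(taxa, ids))
  df <- data.frame(taxon = taxa, signif(mat, 15), check.names = FALSE)
  write_results(df, path)
}

#' Write a result table to TSV with round-trip precision
#'
#' Writes any stage output (a data frame, or an object with an
#' `as.data.frame` method such as a similarity or screen result) as a
#' tab-separated file with 15 significant digits, so that
#' `read_results(write_results(x))` reproduces all numbers to at least 12
#' significant digits. An empty table yields a header-only file.
#'
#' @param x Data frame (or coercible) to write.
#' @param path Output file path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  x <- as.data.frame(x)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  out <- x
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    s <- sprintf("%.15g", v)
    s[is.na(v)] <- NA_character_
    s
  })
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write to ", path, call. = FALSE)
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path Path to the TSV file.
#' @return A data frame with numeric columns restored.
#' @export
read_results <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a sample metadata table
#'
#' @param path TSV with columns `sample_id`, `salt_pct`, `sample_type`,
#'   `organism_group` and optionally `line_id`.
#' @return A data frame.
#' @export
read_metadata_table <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "salt_pct", "sample_type", "organism_group")
  miss <- setdiff(required, names(meta))
  if (length(miss)) {
    stop("metadata is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  meta
}

#' Read a plate-count table
#'
#' One row per plate: `sample_id`, `dilution_factor`, `plated_volume_ml`,
#' `colonies`, `replicate`. Returns one [plate_count_set()] per sample,
#' joined against metadata.
#'
#' @param path TSV path.
#' @param meta Metadata data frame (see [read_metadata_table()]).
#' @param homogenate_volume_ml,n_units Plating context applied to every
#'   sample unless the table carries its own columns of the same names.
#' @return Named list of [plate_count_set()] objects.
#' @export
read_plate_counts <- function(path, meta, homogenate_volume_ml = 3,
                              n_units = 30) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"line_id" %in% names(meta)) meta$line_id <- meta$sample_id
  sets <- lapply(split(tab, tab$sample_id), function(d) {
    sid <- d$sample_id[1]
    row <- meta[match(sid, meta$sample_id), ]
    if (is.na(row$sample_id)) stop("plate counts reference unknown sample ", sid, call. = FALSE)
    hv <- if ("homogenate_volume_ml" %in% names(d)) d$homogenate_volume_ml[1] else homogenate_volume_ml
    nu <- if ("n_units" %in% names(d)) d$n_units[1] else n_units
    plate_count_set(
      d[, c("dilution_factor", "plated_volume_ml", "colonies", "replicate")],
      meta = sample_metadata(sid, row$salt_pct, row$sample_type,
                             row$organism_group, line_id = row$line_id),
      homogenate_volume_ml = hv, n_units = nu
    )
  })
  sets
}

#' Read a growth-assay table
#'
#' @param path TSV with columns `isolate`, `nacl_pct`, `replicate`,
#'   `od600`.
#' @return A data frame of class `growth_assays`.
#' @export
read_growth_assays <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("isolate", "nacl_pct", "replicate", "od600")
  miss <- setdiff(required, names(tab))
  if (length(miss)) {
    stop("assay table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(tab$od600 < 0)) stop("od600 must be non-negative", call. = FALSE)
  class(tab) <- c("growth_assays", "data.frame")
  tab
}

#' Read an analysis configuration file
#'
#' YAML file holding the knobs of the pipeline (excluded taxa, rare-taxon
#' threshold, Shannon base, similarity form/combiner, screen exclusions,
#' significance levels, normalization tolerance). Missing keys fall back
#' to package defaults.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A named list of options.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(
    eps = 1e-9,
    percent_threshold = 1.5,
    excluded_taxa = "Wolbachia",
    rare_threshold = 0.05,
    lump_for_stats = FALSE,
    shannon_base = exp(1),
    ks_form = "sorensen",
    combiner = "product",
    detection_floor = 0,
    salt_levels = c(0, 2, 4, 7),
    cfu_window = c(30, 300),
    screen_method = "spearman",
    screen_exclude = character(),
    sig_levels = c(p5 = 0.05, p10 = 0.10)
  )
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  utils::modifyList(defaults, user)
}
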