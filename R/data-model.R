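# Shared domain types. Lightweight S3: a community profile is a named
# abundance vector plus sample metadata; everything downstream consumes these.

#' Sample metadata
#'
#' Describes one sample of the study: which host line it came from, the NaCl
#' concentration of the substrate the line was reared on, whether the sample
#' is a fly homogenate or processed substrate, and which organism group
#' (bacteria or yeast) the associated measurements refer to.
#'
#' @param sample_id Unique sample identifier (e.g. `"4a"`, `"s4a"`).
#' @param salt_pct NaCl concentration of the rearing substrate, percent w/v
#'   (non-negative).
#' @param sample_type `"fly"` or `"substrate"`.
#' @param organism_group `"bacteria"` or `"yeast"`.
#' @param line_id Host line identifier; defaults to `sample_id`.
#' @return An object of class `sample_metadata`.
#' @export
sample_metadata <- function(sample_id, salt_pct,
                            sample_type = c("fly", "substrate"),
                            organism_group = c("bacteria", "yeast"),
                            line_id = sample_id) {
  sample_type <- match.arg(sample_type)
  organism_group <- match.arg(organism_group)
  stopifnot(is.character(sample_id), length(sample_id) == 1L, nzchar(sample_id))
  salt_pct <- as.numeric(salt_pct)
  if (!is.finite(salt_pct) || salt_pct < 0) {
    stop("salt_pct must be a finite non-negative number", call. = FALSE)
  }
  structure(
    list(sample_id = sample_id, line_id = line_id, salt_pct = salt_pct,
         sample_type = sample_type, organism_group = organism_group),
    class = "sample_metadata"
  )
}

#' Community profile
#'
#' One sample's taxon-to-relative-abundance mapping. Abundances are
#' normalized to sum to one on construction (percent or fraction input is
#' therefore equivalent); zero-abundance taxa are retained as explicit zeros
#' so profiles can share a taxon universe.
#'
#' @param abundances Named non-negative numeric vector of taxon abundances
#'   (fractions or percentages; any positive total is accepted and
#'   normalized).
#' @param meta A [sample_metadata()] object, or `NULL` for anonymous
#'   profiles.
#' @param n_replicates Number of sequencing replicates this profile
#'   summarizes.
#' @param normalize Normalize to sum one (default). Disable only for
#'   intermediate objects.
#' @return An object of class `community_profile` with elements `meta`,
#'   `abundances`, `n_replicates`.
#' @export
community_profile <- function(abundances, meta = NULL, n_replicates = 1L,
                              normalize = TRUE) {
  if (is.null(names(abundances)) || any(!nzchar(names(abundances)))) {
    stop("abundances must be a fully named numeric vector", call. = FALSE)
  }
  names(abundances) <- trimws(names(abundances))
  if (anyDuplicated(names(abundances))) {
    stop("duplicated taxon names: ",
         paste(unique(names(abundances)[duplicated(names(abundances))]),
               collapse = ", "), call. = FALSE)
  }
  abundances <- as.numeric(abundances) |> stats::setNames(names(abundances))
  if (any(!is.finite(abundances)) || any(abundances < 0)) {
    bad <- names(abundances)[!is.finite(abundances) | abundances < 0]
    stop("negative or non-finite abundance for taxa: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (normalize) {
    total <- sum(abundances)
    if (total <= 0) stop("profile has zero total abundance", call. = FALSE)
    abundances <- abundances / total
  }
  structure(
    list(meta = meta, abundances = abundances,
         n_replicates = as.integer(n_replicates)),
    class = "community_profile"
  )
}

#' @export
print.community_profile <- function(x, ...) {
  id <- if (!is.null(x$meta)) x$meta$sample_id else "<anonymous>"
  cat("community_profile:", id, "(", x$n_replicates, "replicate(s) )\n")
  print(round(sort(x$abundances, decreasing = TRUE), 4))
  invisible(x)
}

#' Sample id of a profile
#' @param profile A [community_profile()].
#' @return Character scalar, `NA` for anonymous profiles.
#' @export
profile_id <- function(profile) {
  if (is.null(profile$meta)) NA_character_ else profile$meta$sample_id
}

# Internal: validate the sum-to-one invariant (tolerance 1e-9).
assert_normalized <- function(profile, eps = 1e-9) {
  if (abs(sum(profile$abundances) - 1) > eps) {
    stop("profile is not normalized (sum = ",
         format(sum(profile$abundances), digits = 15), ")", call. = FALSE)
  }
  invisible(profile)
}

#' Abundance record
#'
#' Total viable count of one organism group in one sample, expressed per
#' fly (fly samples) or per mg of substrate (substrate samples), with its
#' standard deviation across plates.
#'
#' @param meta A [sample_metadata()] object.
#' @param cfu_per_unit Non-negative CFU per fly or per mg substrate.
#' @param sd Non-negative standard deviation of the per-unit estimate.
#' @param flag Optional quality flag (e.g. `"below_detection"`).
#' @param n_plates_used Number of plates the estimate is based on.
#' @return An object of class `abundance_record`.
#' @export
abundance_record <- function(meta, cfu_per_unit, sd = 0, flag = NA_character_,
                             n_plates_used = NA_integer_) {
  stopifnot(is.finite(cfu_per_unit), cfu_per_unit >= 0, sd >= 0 || is.na(sd))
  structure(
    list(meta = meta, cfu_per_unit = as.numeric(cfu_per_unit),
         sd = as.numeric(sd), flag = flag,
         n_plates_used = as.integer(n_plates_used)),
    class = "abundance_record"
  )
}

#' Plate count set
#'
#' Raw colony counts from a serial-dilution plating experiment for one
#' sample, plus the context needed to convert counts to per-unit titers:
#' homogenate volume and the number of host units (flies, or mg of
#' substrate) that went into it.
#'
#' @param counts Data frame with columns `dilution_factor` (>= 1),
#'   `plated_volume_ml` (> 0), `colonies` (non-negative integer),
#'   `replicate` (integer).
#' @param meta A [sample_metadata()] object.
#' @param homogenate_volume_ml Volume the sample was homogenized in
#'   (default 3 mL).
#' @param n_units Number of flies, or mg of substrate, homogenized
#'   (default 30).
#' @return An object of class `plate_count_set`.
#' @export
plate_count_set <- function(counts, meta, homogenate_volume_ml = 3,
                            n_units = 30) {
  required <- c("dilution_factor", "plated_volume_ml", "colonies", "replicate")
  missing_cols <- setdiff(required, names(counts))
  if (length(missing_cols)) {
    stop("counts is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(counts$dilution_factor >= 1),
            all(counts$plated_volume_ml > 0),
            all(counts$colonies >= 0),
            homogenate_volume_ml > 0, n_units > 0)
  structure(
    list(counts = as.data.frame(counts), meta = meta,
         homogenate_volume_ml = homogenate_volume_ml, n_units = n_units),
    class = "plate_count_set"
  )
}

#' Study table
#'
#' Container bundling all per-sample results of one study: community
#' profiles, abundance records and Shannon diversities, keyed by sample id.
#'
#' @param profiles List of [community_profile()] objects.
#' @param abundances List of [abundance_record()] objects.
#' @param diversities Named numeric vector, sample id to Shannon index.
#' @param metadata_only Character vector of sample ids that legitimately
#'   have measurements but no sequencing profile.
#' @return An object of class `study_table`.
#' @export
study_table <- function(profiles = list(), abundances = list(),
                        diversities = numeric(), metadata_only = character()) {
  profile_ids <- vapply(profiles, profile_id, character(1))
  profile_keys <- vapply(profiles, function(p) {
    if (is.null(p$meta)) NA_character_
    else paste(p$meta$sample_id, p$meta$organism_group, sep = ".")
  }, character(1))
  known <- c(profile_ids, profile_keys, metadata_only)
  ref_ids <- c(vapply(abundances, function(a) a$meta$sample_id, character(1)),
               names(diversities))
  unknown <- setdiff(ref_ids, known)
  if (length(unknown)) {
    stop("sample ids without a profile or metadata-only declaration: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  structure(
    list(profiles = profiles, abundances = abundances,
         diversities = diversities, metadata_only = metadata_only),
    class = "study_table"
  )
}
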