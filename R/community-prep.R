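# Preprocessing of sequencing-derived genus tables: replicate averaging,
# exclusion of the intracellular endosymbiont, and lumping of consistently
# rare taxa into "Other". Averaging precedes exclusion, so the excluded
# taxon's share is measured on the averaged table.

#' Average sequencing replicates of one sample
#'
#' Takes the replicates of a single sample (profiles sharing a sample id),
#' averages the per-taxon relative abundances arithmetically over the
#' union taxon set (a taxon missing from a replicate counts as zero), and
#' renormalizes.
#'
#' @param profiles Non-empty list of [community_profile()] objects sharing
#'   one sample id.
#' @return A single [community_profile()] with `n_replicates` set to the
#'   number of inputs.
#' @export
average_replicates <- function(profiles) {
  if (length(profiles) == 0L) stop("no replicates supplied", call. = FALSE)
  ids <- unique(stats::na.omit(vapply(profiles, profile_id, character(1))))
  if (length(ids) > 1L) {
    stop("replicates belong to different samples: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  taxa <- sort(unique(unlist(lapply(profiles, function(p) names(p$abundances)))))
  acc <- stats::setNames(numeric(length(taxa)), taxa)
  for (p in profiles) acc[names(p$abundances)] <- acc[names(p$abundances)] + p$abundances
  community_profile(acc / length(profiles), meta = profiles[[1]]$meta,
                    n_replicates = length(profiles))
}

#' Exclude a taxon from a profile and renormalize
#'
#' Removes one taxon (typically the intracellular endosymbiont
#' *Wolbachia*, which reflects host tissue rather than the gut community)
#' and renormalizes the remainder to sum one. Removing an absent taxon is
#' a no-op, which makes the operation idempotent.
#'
#' @param profile A [community_profile()].
#' @param taxon Taxon name to drop (default `"Wolbachia"`).
#' @return The renormalized [community_profile()].
#' @export
exclude_taxon <- function(profile, taxon = "Wolbachia") {
  keep <- setdiff(names(profile$abundances), trimws(taxon))
  remaining <- profile$abundances[keep]
  if (length(remaining) == 0L || sum(remaining) <= 0) {
    stop("profile became empty after excluding \"", taxon, "\"", call. = FALSE)
  }
  community_profile(remaining, meta = profile$meta,
                    n_replicates = profile$n_replicates)
}

#' Lump consistently rare taxa into "Other"
#'
#' A taxon is lumped iff its relative abundance does not exceed
#' `threshold` in *every* profile of the set (the rule is joint across
#' samples: a taxon above the threshold in even one sample is kept
#' everywhere). Per-profile sums are unchanged, so lumping can only
#' decrease Shannon diversity.
#'
#' @param profiles List of [community_profile()] objects.
#' @param threshold Abundance threshold in (0, 1); the comparison is
#'   inclusive (`<= threshold` lumps). Default 0.05.
#' @param other_label Name of the pooled category (default `"Other"`).
#' @return List of [community_profile()] objects with rare taxa pooled.
#' @export
lump_rare_taxa <- function(profiles, threshold = 0.05, other_label = "Other") {
  stopifnot(threshold > 0, threshold < 1)
  taxa <- sort(unique(unlist(lapply(profiles, function(p) names(p$abundances)))))
  max_ab <- stats::setNames(numeric(length(taxa)), taxa)
  for (p in profiles) {
    max_ab[names(p$abundances)] <- pmax(max_ab[names(p$abundances)], p$abundances)
  }
  rare <- names(max_ab)[max_ab <= threshold & names(max_ab) != other_label]
  if (length(rare) == 0L) return(profiles)
  lapply(profiles, function(p) {
    ab <- p$abundances
    pooled <- sum(ab[intersect(rare, names(ab))])
    ab <- ab[setdiff(names(ab), rare)]
    prior <- if (other_label %in% names(ab)) ab[[other_label]] else 0
    ab[other_label] <- prior + pooled
    community_profile(ab, meta = p$meta, n_replicates = p$n_replicates,
                      normalize = FALSE)
  })
}

#' Full preparation of a set of replicate profiles
#'
#' Convenience wrapper applying the standard order: average replicates per
#' sample, exclude configured taxa, and (optionally, for reporting) lump
#' rare taxa.
#'
#' @param profiles List of [community_profile()] replicates (several per
#'   sample id allowed).
#' @param excluded_taxa Character vector of taxa to exclude after
#'   averaging (default `"Wolbachia"`).
#' @param rare_threshold Threshold for [lump_rare_taxa()], or `NULL` to
#'   skip lumping.
#' @return Named list of prepared [community_profile()] objects, one per
#'   sample id.
#' @export
prepare_profiles <- function(profiles, excluded_taxa = "Wolbachia",
                             rare_threshold = NULL) {
  ids <- vapply(profiles, profile_id, character(1))
  groups <- vapply(profiles, function(p) {
    if (is.null(p$meta)) "" else p$meta$organism_group
  }, character(1))
  # replicates are grouped per sample AND organism group; names stay plain
  # sample ids unless a sample carries both groups
  key <- paste(ids, groups, sep = ".")
  averaged <- lapply(split(profiles, key), average_replicates)
  key_ids <- vapply(averaged, profile_id, character(1))
  if (!anyDuplicated(key_ids)) names(averaged) <- key_ids
  cleaned <- lapply(averaged, function(p) {
    for (tx in excluded_taxa) {
      if (tx %in% names(p$abundances)) p <- exclude_taxon(p, tx)
    }
    p
  })
  if (!is.null(rare_threshold)) cleaned <- lump_rare_taxa(cleaned, rare_threshold)
  cleaned
}
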