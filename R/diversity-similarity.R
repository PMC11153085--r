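# Shannon diversity and the biocenotic similarity coefficient K, which
# combines a species-composition component Ks (shared-species overlap)
# with a relative-abundance component Ku (Renkonen / percentage
# similarity, the summed minima of shared relative abundances).

#' Shannon diversity of a community profile
#'
#' H = -sum over positive p_i of p_i * log(p_i), in the chosen log base
#' (nats by default). Zero-abundance taxa contribute nothing; S is the
#' number of taxa with positive abundance.
#'
#' @param profile A normalized [community_profile()].
#' @param base Logarithm base: `exp(1)` (default), 2 or 10.
#' @return An object of class `diversity_result`: list with `sample_id`,
#'   `H`, `S`.
#' @export
shannon <- function(profile, base = exp(1)) {
  assert_normalized(profile)
  p <- profile$abundances[profile$abundances > 0]
  if (length(p) == 0L) stop("empty profile: no taxa with positive abundance", call. = FALSE)
  H <- -sum(p * log(p, base = base))
  structure(
    list(sample_id = profile_id(profile), H = max(H, 0), S = length(p)),
    class = "diversity_result"
  )
}

#' Shannon diversity for a set of profiles
#'
#' @param profiles List of [community_profile()] objects.
#' @param base Logarithm base, as in [shannon()].
#' @return Data frame with columns `sample_id`, `H`, `S`.
#' @export
diversity_table <- function(profiles, base = exp(1)) {
  rows <- lapply(profiles, function(p) {
    d <- shannon(p, base = base)
    data.frame(sample_id = d$sample_id, H = d$H, S = d$S,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Taxa counted as present: abundance strictly above the detection floor
# (floor 0 means any positive abundance counts).
present_taxa <- function(profile, detection_floor = 0) {
  names(profile$abundances)[profile$abundances > detection_floor]
}

#' Species-composition similarity Ks
#'
#' Overlap of the species (taxon) sets of two samples. The default form
#' is the Sorensen coefficient 2*Su / (S1 + S2), where S1 and S2 are the
#' species counts of the two samples and Su the number of species common
#' to both. Alternative forms from the same coefficient family are
#' available.
#'
#' @param a,b [community_profile()] objects sharing a taxon namespace.
#' @param form `"sorensen"` (default), `"overlap"` (Su / min(S1, S2)) or
#'   `"jaccard"` (Su / (S1 + S2 - Su)).
#' @param detection_floor Abundance below or at which a taxon is treated
#'   as absent (default 0: any positive abundance counts).
#' @return Ks in \[0, 1\].
#' @export
ks_species <- function(a, b, form = c("sorensen", "overlap", "jaccard"),
                       detection_floor = 0) {
  form <- match.arg(form)
  ta <- present_taxa(a, detection_floor)
  tb <- present_taxa(b, detection_floor)
  s1 <- length(ta); s2 <- length(tb)
  if (s1 == 0L && s2 == 0L) stop("both profiles are empty", call. = FALSE)
  su <- length(intersect(ta, tb))
  switch(form,
         sorensen = 2 * su / (s1 + s2),
         overlap  = if (min(s1, s2) == 0L) 0 else su / min(s1, s2),
         jaccard  = su / (s1 + s2 - su))
}

#' Relative-abundance similarity Ku (Renkonen / percentage similarity)
#'
#' For the species common to both samples, take the smaller of the two
#' relative abundances and sum: Ku = sum over shared i of
#' min(p_i^(1), p_i^(2)). On normalized profiles this equals
#' 1 - L1(p, q) / 2 over the union taxon set.
#'
#' @param a,b Normalized [community_profile()] objects.
#' @return Ku in \[0, 1\].
#' @export
ku_abundance <- function(a, b) {
  assert_normalized(a); assert_normalized(b)
  shared <- intersect(present_taxa(a), present_taxa(b))
  if (length(shared) == 0L) return(0)
  sum(pmin(a$abundances[shared], b$abundances[shared]))
}

#' Biocenotic similarity coefficient K
#'
#' Combined similarity of two communities accounting for both species
#' composition ([ks_species()]) and relative abundance
#' ([ku_abundance()]). The default combiner is the product K = Ks * Ku;
#' arithmetic and geometric means are provided as alternatives. Any
#' combiner maps (1, 1) to 1 (self-similarity) and (0, 0) to 0 (disjoint
#' communities).
#'
#' @param a,b Normalized [community_profile()] objects.
#' @param combiner `"product"` (default), `"arithmetic_mean"` or
#'   `"geometric_mean"`.
#' @param ks_form,detection_floor Passed to [ks_species()].
#' @return An object of class `similarity_result`: list with `pair`,
#'   `Ks`, `Ku`, `K`, `Su`, `m` (`Su == m`, the shared-taxon count).
#' @export
biocenotic_k <- function(a, b,
                         combiner = c("product", "arithmetic_mean",
                                      "geometric_mean"),
                         ks_form = "sorensen", detection_floor = 0) {
  combiner <- match.arg(combiner)
  ks <- ks_species(a, b, form = ks_form, detection_floor = detection_floor)
  ku <- ku_abundance(a, b)
  k <- switch(combiner,
              product = ks * ku,
              arithmetic_mean = (ks + ku) / 2,
              geometric_mean = sqrt(ks * ku))
  su <- length(intersect(present_taxa(a, detection_floor),
                         present_taxa(b, detection_floor)))
  structure(
    list(pair = c(profile_id(a), profile_id(b)),
         Ks = ks, Ku = ku, K = k, Su = su, m = su, combiner = combiner),
    class = "similarity_result"
  )
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("similarity %s ~ %s: Ks = %.4f, Ku = %.4f, K = %.4f (%s, %d shared taxa)\n",
              x$pair[1], x$pair[2], x$Ks, x$Ku, x$K, x$combiner, x$Su))
  invisible(x)
}

#' @export
as.data.frame.similarity_result <- function(x, ...) {
  data.frame(sample_a = x$pair[1], sample_b = x$pair[2],
             Ks = x$Ks, Ku = x$Ku, K = x$K, Su = x$Su,
             combiner = x$combiner, stringsAsFactors = FALSE)
}

#' Pairwise similarity for declared sample pairs
#'
#' @param profiles Named list of [community_profile()] objects.
#' @param pairs Data frame with columns `sample_a`, `sample_b` (e.g. each
#'   fly line against its substrate).
#' @param ... Passed to [biocenotic_k()].
#' @return Data frame, one row per pair, with Ks, Ku, K, Su.
#' @export
similarity_table <- function(profiles, pairs, ...) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- profiles[[pairs$sample_a[i]]]
    b <- profiles[[pairs$sample_b[i]]]
    if (is.null(a) || is.null(b)) {
      stop("pair references unknown sample: ", pairs$sample_a[i], " / ",
           pairs$sample_b[i], call. = FALSE)
    }
    as.data.frame(biocenotic_k(a, b, ...))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
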