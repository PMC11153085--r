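# Bundled study data: the published per-sample total counts of bacteria
# and yeasts (CFU per fly or per mg of substrate, with SD) for the 11 fly
# lines and 5 substrate samples reared at 0/2/4/7% NaCl, plus the
# single-species yeast communities of the salt-free fly/substrate pair.

#' Published CFU table of the salinity-adaptation study
#'
#' Total counts of aerobic/aerotolerant bacteria and of yeasts per fly
#' (fly samples) or per mg of substrate (substrate samples), with
#' standard deviations, for the 11 fly lines (0a-0c, 2a-2c, 4a-4c,
#' 7a-7b) and 5 substrate samples (s0b, s0c, s2a, s4a, s7a).
#'
#' @return Data frame with columns `salt_pct`, `sample_id`,
#'   `sample_type`, `bacteria_cfu`, `bacteria_sd`, `yeast_cfu`,
#'   `yeast_sd`.
#' @export
salt_study_cfu <- function() {
  path <- system.file("extdata", "table1_cfu.tsv", package = "holobiome",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Screen-ready variable table for the study's fly samples
#'
#' The five-variable table used by the pairwise correlation screen: salt
#' concentration and bacterial/yeast abundance from the published CFU
#' table for the 11 fly lines. The two diversity variables are included
#' as all-missing columns: the per-sample Shannon values were published
#' only as a figure, so diversity-involving cells cannot be recomputed
#' from printed numbers and are flagged absent by [run_screen()].
#'
#' @return Data frame with columns `sample_id`, `salt_pct`,
#'   `bacterial_abundance`, `yeast_abundance`, `bacterial_diversity`,
#'   `yeast_diversity`.
#' @export
salt_study_variables <- function() {
  tab <- salt_study_cfu()
  fly <- tab[tab$sample_type == "fly", ]
  data.frame(
    sample_id = fly$sample_id,
    salt_pct = fly$salt_pct,
    bacterial_abundance = fly$bacteria_cfu,
    yeast_abundance = fly$yeast_cfu,
    bacterial_diversity = NA_real_,
    yeast_diversity = NA_real_,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Yeast communities of the salt-free fly/substrate pair
#'
#' The salt-free line 0b hosted a single yeast species (*Pichia
#' occidentalis*) while its substrate s0b was inhabited only by
#' *Zygosaccharomyces bailii*: two disjoint single-species communities,
#' the canonical zero-similarity case.
#'
#' @return Named list of two [community_profile()] objects (`"0b"`,
#'   `"s0b"`).
#' @export
salt_study_yeast_zero_pair <- function() {
  list(
    `0b` = community_profile(
      c(`Pichia occidentalis` = 1),
      meta = sample_metadata("0b", 0, "fly", "yeast")),
    s0b = community_profile(
      c(`Zygosaccharomyces bailii` = 1),
      meta = sample_metadata("s0b", 0, "substrate", "yeast"))
  )
}
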