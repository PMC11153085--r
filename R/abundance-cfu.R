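# CFU quantification from serial-dilution plating, and the derived
# per-fly / per-mg comparisons (fly-to-substrate and yeast-to-bacteria
# ratios).

#' Estimate CFU per unit from a dilution-plating series
#'
#' Each plate yields a titer estimate colonies * dilution_factor /
#' plated_volume_mL (CFU per mL of homogenate). Plates whose raw colony
#' count lies inside the countable window (default 30-300) are used; if
#' none do, the plate(s) nearest the window are used and the result is
#' flagged. The per-mL titer is scaled to CFU per unit (per fly or per mg
#' of substrate) by homogenate_volume / n_units. The reported SD is taken
#' across the per-plate titers pooled over dilutions and replicates.
#'
#' @param plates A [plate_count_set()].
#' @param window Countable colony window, default `c(30, 300)`.
#' @return An [abundance_record()]; `flag` is `"below_detection"` when
#'   all plates are empty and `"outside_countable_window"` when no plate
#'   fell inside the window.
#' @export
estimate_cfu <- function(plates, window = c(30, 300)) {
  stopifnot(inherits(plates, "plate_count_set"))
  cnt <- plates$counts
  per_unit_scale <- plates$homogenate_volume_ml / plates$n_units

  if (all(cnt$colonies == 0)) {
    return(abundance_record(plates$meta, 0, 0, flag = "below_detection",
                            n_plates_used = nrow(cnt)))
  }

  in_window <- cnt$colonies >= window[1] & cnt$colonies <= window[2]
  flag <- NA_character_
  if (any(in_window)) {
    usable <- cnt[in_window, ]
  } else {
    dist <- pmin(abs(cnt$colonies - window[1]), abs(cnt$colonies - window[2]))
    dist[cnt$colonies == 0] <- Inf  # empty plates carry no titer information
    usable <- cnt[dist == min(dist), ]
    flag <- "outside_countable_window"
  }

  titer_ml <- usable$colonies * usable$dilution_factor / usable$plated_volume_ml
  per_unit <- titer_ml * per_unit_scale
  abundance_record(plates$meta,
                   cfu_per_unit = mean(per_unit),
                   sd = if (length(per_unit) > 1) stats::sd(per_unit) else 0,
                   flag = flag, n_plates_used = nrow(usable))
}

# Accept either an abundance_record or a bare CFU number.
as_cfu <- function(x) {
  if (inherits(x, "abundance_record")) x$cfu_per_unit else as.numeric(x)
}

#' Ratio of fly abundance to substrate abundance
#'
#' CFU per fly divided by CFU per mg of substrate for the same organism
#' group, with the order of magnitude floor(log10 ratio) alongside.
#'
#' @param fly,substrate [abundance_record()] objects (or bare CFU
#'   numbers) for the fly sample and its substrate.
#' @return List with `ratio`, `log10_floor` and `flag` (set when the
#'   substrate count is zero, making the ratio infinite).
#' @export
fly_substrate_ratio <- function(fly, substrate) {
  f <- as_cfu(fly); s <- as_cfu(substrate)
  if (inherits(fly, "abundance_record") && inherits(substrate, "abundance_record") &&
      fly$meta$organism_group != substrate$meta$organism_group) {
    stop("fly and substrate records are for different organism groups", call. = FALSE)
  }
  if (s <= 0) {
    return(list(ratio = Inf, log10_floor = Inf, flag = "substrate_zero"))
  }
  ratio <- f / s
  list(ratio = ratio,
       log10_floor = if (ratio > 0) floor(log10(ratio)) else -Inf,
       flag = NA_character_)
}

#' Ratio of yeast to bacterial abundance in one sample
#'
#' @param yeast,bacteria [abundance_record()] objects (or bare CFU
#'   numbers) for the same sample.
#' @return The ratio yeast CFU / bacterial CFU per unit.
#' @export
yeast_bacteria_ratio <- function(yeast, bacteria) {
  y <- as_cfu(yeast); b <- as_cfu(bacteria)
  if (b <= 0) stop("bacterial abundance is zero; ratio undefined", call. = FALSE)
  y / b
}

#' Tabulate abundance records
#'
#' @param records List of [abundance_record()] objects.
#' @return Data frame with sample metadata, CFU per unit, SD and flags.
#' @export
abundance_table <- function(records) {
  rows <- lapply(records, function(r) {
    data.frame(sample_id = r$meta$sample_id, salt_pct = r$meta$salt_pct,
               sample_type = r$meta$sample_type,
               organism_group = r$meta$organism_group,
               cfu_per_unit = r$cfu_per_unit, sd = r$sd, flag = r$flag,
               n_plates_used = r$n_plates_used, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
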