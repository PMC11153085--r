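# Seed-deterministic generator of study-shaped datasets with known ground
# truth. Emulates the sampling design (11 fly lines + 5 substrates over
# NaCl 0/2/4/7%, two sequencing replicates per sample, 3 dilutions x 3
# replicate plates, 4 growth-assay replicates) and the observed regime
# structure: Acetobacter declining with salt, Lactiplantibacillus peaking
# at 4%, Leuconostoc/Providencia dominant at 7%, a yeast community shift
# at 7%, salt-dependent CFU magnitudes, and a latent antagonism between
# bacterial and yeast diversity. It provides statistical structure only,
# not a model of fly biology.

# One Dirichlet draw: normalized independent gamma variates. Zero
# centroid entries stay exactly zero.
rdirichlet_one <- function(alpha) {
  pos <- alpha > 0
  g <- numeric(length(alpha))
  g[pos] <- stats::rgamma(sum(pos), shape = alpha[pos], rate = 1)
  if (sum(g) == 0) g[pos] <- 1  # pathological underflow guard
  stats::setNames(g / sum(g), names(alpha))
}

#' Default synthetic-study configuration
#'
#' The configuration encodes the study conditions: sample layout, per-salt
#' community centroids for bacteria and yeasts, Dirichlet concentration
#' (50, reflecting the visible between-line variability), a ~15%
#' endosymbiont (*Wolbachia*) component in fly bacterial samples, CFU
#' magnitudes per salt level on the log10 scale spanning roughly 1e3-1e8,
#' plating design (3 dilutions x 3 replicates, 0.1 mL plated, 3 mL
#' homogenate, 30 units), isolate tolerance curves (ratios at 2% NaCl of
#' about 10%, 60% and 75% for the acetic-acid bacterium, the
#' lactobacillus and the leuconostoc respectively), and the strength of
#' the latent bacteria-yeast diversity antagonism.
#'
#' @return Named list of generator parameters.
#' @export
default_sim_config <- function() {
  bact_taxa <- c("Acetobacter", "Lactiplantibacillus", "Levilactobacillus",
                 "Leuconostoc", "Providencia", "Enterococcus",
                 "Fructilactobacillus", "Gilliamella", "Commensalibacter",
                 "Dysgonomonas")
  bc <- function(...) {
    v <- stats::setNames(numeric(length(bact_taxa)), bact_taxa)
    upd <- c(...)
    v[names(upd)] <- upd
    v / sum(v)
  }
  yeast_taxa <- c("Pichia occidentalis", "Zygosaccharomyces bailii",
                  "Candida californica", "Pichia membranifaciens",
                  "Starmerella bacillaris", "Starmerella etchellsii",
                  "Geotrichum candidum")
  yc <- function(...) {
    v <- stats::setNames(numeric(length(yeast_taxa)), yeast_taxa)
    upd <- c(...)
    v[names(upd)] <- upd
    v / sum(v)
  }
  list(
    salt_levels = c(0, 2, 4, 7),
    fly_lines = list(`0` = c("0a", "0b", "0c"), `2` = c("2a", "2b", "2c"),
                     `4` = c("4a", "4b", "4c"), `7` = c("7a", "7b")),
    substrates = list(`0` = c("s0b", "s0c"), `2` = "s2a", `4` = "s4a",
                      `7` = "s7a"),
    bacteria_centroids = list(
      `0` = bc(Acetobacter = 0.30, Lactiplantibacillus = 0.42,
               Levilactobacillus = 0.05, Leuconostoc = 0.04,
               Fructilactobacillus = 0.05, Gilliamella = 0.06,
               Commensalibacter = 0.03, Providencia = 0.02,
               Enterococcus = 0.02, Dysgonomonas = 0.01),
      `2` = bc(Acetobacter = 0.08, Lactiplantibacillus = 0.68,
               Levilactobacillus = 0.09, Commensalibacter = 0.05,
               Leuconostoc = 0.04, Fructilactobacillus = 0.03,
               Providencia = 0.01, Enterococcus = 0.01,
               Gilliamella = 0.01),
      `4` = bc(Acetobacter = 0.03, Lactiplantibacillus = 0.80,
               Leuconostoc = 0.09, Levilactobacillus = 0.04,
               Commensalibacter = 0.02, Providencia = 0.01,
               Enterococcus = 0.01),
      `7` = bc(Lactiplantibacillus = 0.06, Leuconostoc = 0.31,
               Providencia = 0.39, Enterococcus = 0.13,
               Dysgonomonas = 0.07, Levilactobacillus = 0.04)
    ),
    yeast_centroids = list(
      `0` = yc(`Pichia occidentalis` = 0.90, `Zygosaccharomyces bailii` = 0.07,
               `Candida californica` = 0.03),
      `2` = yc(`Pichia occidentalis` = 0.84, `Candida californica` = 0.07,
               `Zygosaccharomyces bailii` = 0.05,
               `Pichia membranifaciens` = 0.04),
      `4` = yc(`Pichia occidentalis` = 0.87, `Candida californica` = 0.06,
               `Zygosaccharomyces bailii` = 0.04,
               `Pichia membranifaciens` = 0.03),
      `7` = yc(`Starmerella bacillaris` = 0.58, `Pichia occidentalis` = 0.16,
               `Starmerella etchellsii` = 0.14, `Geotrichum candidum` = 0.12)
    ),
    concentration = 50,
    replicate_concentration = 300,
    wolbachia_mean = 0.15,
    wolbachia_kappa = 60,    # Beta(kappa*mean, kappa*(1-mean)) sampling
    antagonism = 0.45,       # latent coupling of bacterial vs yeast evenness
    # log10 CFU per unit by salt level (means mimic the observed pattern:
    # bacteria dip at 2% and recover at 4%; yeast lowest without salt,
    # highest at 2-4%, intermediate at 7%)
    cfu_log10_mean = list(
      bacteria = c(`0` = 6.3, `2` = 4.3, `4` = 6.7, `7` = 6.3),
      yeast    = c(`0` = 3.0, `2` = 5.0, `4` = 5.7, `7` = 4.3)
    ),
    cfu_log10_sd = c(bacteria = 0.5, yeast = 0.35),
    cfu_log10_range = c(3.5, 7.5),
    plated_volume_ml = 0.1,
    homogenate_volume_ml = 3,
    n_units = 30,
    n_dilutions = 3,
    n_plate_replicates = 3,
    # growth assays: planted tolerance curves, percent of 0% reference OD
    isolates = list(
      `Acetobacter pasteurianus` = list(base_od = 1.2,
        curve = c(`0` = 100, `2` = 10, `4` = 2, `7` = 0.5)),
      `Lactiplantibacillus plantarum` = list(base_od = 1.5,
        curve = c(`0` = 100, `2` = 60, `4` = 30, `7` = 5)),
      `Leuconostoc pseudomesenteroides` = list(base_od = 1.0,
        curve = c(`0` = 100, `2` = 75, `4` = 50, `7` = 12))
    ),
    assay_noise_sd = 0.03,
    n_assay_replicates = 4
  )
}

# All (sample_id, salt, type) rows of the design.
sim_design <- function(config) {
  rows <- list()
  for (lvl in names(config$fly_lines)) {
    for (id in config$fly_lines[[lvl]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = id, salt_pct = as.numeric(lvl), sample_type = "fly",
        stringsAsFactors = FALSE)
    }
  }
  for (lvl in names(config$substrates)) {
    for (id in config$substrates[[lvl]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = id, salt_pct = as.numeric(lvl), sample_type = "substrate",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate synthetic community profiles
#'
#' For every sample and organism group, draws a true composition from a
#' Dirichlet distribution centred on the salt-level centroid, then emits
#' two sequencing replicates by Dirichlet resampling around the true
#' composition. Fly bacterial replicates carry an additional
#' endosymbiont (*Wolbachia*) component (Beta-distributed around 15%) so
#' the exclusion step is exercised. A per-sample latent factor u tempers
#' the two centroids in opposite directions before drawing (exponent
#' exp(+a*u) for bacteria, exp(-a*u) for yeasts; exponents above one
#' sharpen a composition and lower its evenness, below one flatten it),
#' planting a negative association between bacterial and yeast
#' diversity.
#'
#' @param config Generator configuration ([default_sim_config()]).
#' @param seed Integer seed, or `NULL` to continue the current RNG
#'   stream.
#' @return List with `replicates` (list of [community_profile()]
#'   objects, two per sample x organism group, each tagged with a
#'   `replicate` attribute), and `truth` (true compositions and latent
#'   factors).
#' @export
generate_compositions <- function(config = default_sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  design <- sim_design(config)
  reps <- list()
  truth <- list()
  for (i in seq_len(nrow(design))) {
    sid <- design$sample_id[i]
    lvl <- as.character(design$salt_pct[i])
    u <- stats::rnorm(1)
    for (group in c("bacteria", "yeast")) {
      centroid <- if (group == "bacteria") config$bacteria_centroids[[lvl]]
                  else config$yeast_centroids[[lvl]]
      if (abs(sum(centroid) - 1) > 1e-9) {
        stop("centroid for salt level ", lvl, " does not sum to 1", call. = FALSE)
      }
      temper <- exp(if (group == "bacteria") config$antagonism * u
                    else -config$antagonism * u)
      shaped <- centroid^temper
      shaped <- shaped / sum(shaped)
      true_comp <- rdirichlet_one(config$concentration * shaped)
      truth[[paste(sid, group, sep = ".")]] <-
        list(composition = true_comp, u = u, temper = temper)
      for (r in seq_len(2L)) {
        obs <- rdirichlet_one(config$replicate_concentration * true_comp)
        if (group == "bacteria" && design$sample_type[i] == "fly") {
          w <- stats::rbeta(1, config$wolbachia_kappa * config$wolbachia_mean,
                            config$wolbachia_kappa * (1 - config$wolbachia_mean))
          obs <- c(Wolbachia = w, obs * (1 - w))
        }
        prof <- community_profile(
          obs,
          meta = sample_metadata(sid, design$salt_pct[i],
                                 design$sample_type[i], group),
          n_replicates = 1L)
        attr(prof, "replicate") <- r
        reps[[length(reps) + 1L]] <- prof
      }
    }
  }
  list(replicates = reps, truth = truth)
}

#' Generate synthetic plate counts for a known titer
#'
#' Colonies on each plate are Poisson with mean
#' titer * n_units / homogenate_volume * plated_volume / dilution. The
#' three dilution factors are powers of ten chosen so that the middle
#' dilution expects about 100 colonies (clamped at 1).
#'
#' @param true_titer True CFU per unit (per fly or per mg); 0 yields
#'   all-zero plates.
#' @param config Generator configuration.
#' @param seed Integer seed, or `NULL`.
#' @param meta Optional [sample_metadata()] attached to the set.
#' @return A [plate_count_set()] with a `true_titer` attribute.
#' @export
generate_plate_counts <- function(true_titer, config = default_sim_config(),
                                  seed = NULL, meta = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(true_titer >= 0)
  titer_ml <- true_titer * config$n_units / config$homogenate_volume_ml
  mid <- max(0, round(log10(max(titer_ml * config$plated_volume_ml, 1) / 100)))
  dils <- 10^(mid + seq_len(config$n_dilutions) - 2)  # mid/10, mid, mid*10
  dils <- pmax(dils, 1)
  rows <- expand.grid(dilution_factor = dils,
                      replicate = seq_len(config$n_plate_replicates))
  lambda <- titer_ml * config$plated_volume_ml / rows$dilution_factor
  rows$colonies <- stats::rpois(nrow(rows), lambda)
  rows$plated_volume_ml <- config$plated_volume_ml
  if (is.null(meta)) {
    meta <- sample_metadata("synthetic", 0, "fly", "bacteria")
  }
  out <- plate_count_set(rows[, c("dilution_factor", "plated_volume_ml",
                                  "colonies", "replicate")],
                         meta = meta,
                         homogenate_volume_ml = config$homogenate_volume_ml,
                         n_units = config$n_units)
  attr(out, "true_titer") <- true_titer
  out
}

#' Generate synthetic growth assays
#'
#' Endpoint OD600 per isolate x NaCl level x replicate: the planted
#' tolerance curve (percent of the salt-free reference) times the
#' isolate's baseline OD, plus Gaussian noise, truncated at zero.
#'
#' @param config Generator configuration.
#' @param seed Integer seed, or `NULL`.
#' @param noise_sd Replicate noise SD on the OD scale; defaults to the
#'   configured value (set 0 for the noise-free limit).
#' @return Assay data frame (`isolate`, `nacl_pct`, `replicate`,
#'   `od600`) with the planted curves as a `truth` attribute.
#' @export
generate_assays <- function(config = default_sim_config(), seed = NULL,
                            noise_sd = config$assay_noise_sd) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (iso in names(config$isolates)) {
    iso_cfg <- config$isolates[[iso]]
    for (lvl in names(iso_cfg$curve)) {
      mu <- iso_cfg$base_od * iso_cfg$curve[[lvl]] / 100
      od <- pmax(0, mu + stats::rnorm(config$n_assay_replicates, 0, noise_sd))
      rows[[length(rows) + 1L]] <- data.frame(
        isolate = iso, nacl_pct = as.numeric(lvl),
        replicate = seq_len(config$n_assay_replicates), od600 = od,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "truth") <- lapply(config$isolates, `[[`, "curve")
  out
}

#' Generate a full synthetic study
#'
#' Wires all generators consistently: compositions (with replicates and
#' the latent diversity antagonism), CFU truths drawn per sample and
#' organism group from the salt-level log-normal means (clamped to the
#' configured log10 range), plate counts simulated from those truths and
#' re-estimated with [estimate_cfu()], Shannon diversities computed from
#' the prepared (replicate-averaged, endosymbiont-excluded) profiles,
#' growth assays, and the screen-ready variable table for fly samples.
#'
#' @param config Generator configuration ([default_sim_config()]).
#' @param seed Integer seed; the same seed reproduces the study
#'   bit-for-bit.
#' @return An object of class `synthetic_study`: list with `study`
#'   ([study_table()]), `profiles` (prepared), `replicates` (raw),
#'   `plate_counts`, `abundance` (estimated records), `assays`,
#'   `variables` (fly-sample screen table) and `truth`.
#' @export
generate_study <- function(config = default_sim_config(), seed = 1L) {
  set.seed(seed)
  comp <- generate_compositions(config, seed = NULL)
  prepared <- prepare_profiles(comp$replicates,
                               excluded_taxa = "Wolbachia")

  design <- sim_design(config)
  plate_counts <- list()
  abundance <- list()
  truth_cfu <- list()
  for (i in seq_len(nrow(design))) {
    sid <- design$sample_id[i]
    lvl <- as.character(design$salt_pct[i])
    for (group in c("bacteria", "yeast")) {
      mu <- config$cfu_log10_mean[[group]][[lvl]]
      lg <- stats::rnorm(1, mu, config$cfu_log10_sd[[group]])
      lg <- min(max(lg, config$cfu_log10_range[1]), config$cfu_log10_range[2])
      titer <- 10^lg
      meta <- sample_metadata(sid, design$salt_pct[i], design$sample_type[i],
                              group)
      pcs <- generate_plate_counts(titer, config, seed = NULL, meta = meta)
      key <- paste(sid, group, sep = ".")
      truth_cfu[[key]] <- titer
      plate_counts[[key]] <- pcs
      abundance[[key]] <- estimate_cfu(pcs)
    }
  }

  div <- vapply(prepared, function(p) shannon(p)$H, numeric(1))
  assays <- generate_assays(config, seed = NULL)

  fly <- design[design$sample_type == "fly", ]
  variables <- data.frame(
    sample_id = fly$sample_id,
    salt_pct = fly$salt_pct,
    bacterial_abundance = vapply(paste(fly$sample_id, "bacteria", sep = "."),
                                 function(k) abundance[[k]]$cfu_per_unit,
                                 numeric(1)),
    yeast_abundance = vapply(paste(fly$sample_id, "yeast", sep = "."),
                             function(k) abundance[[k]]$cfu_per_unit,
                             numeric(1)),
    bacterial_diversity = vapply(fly$sample_id, function(s)
      shannon(prepared[[paste(s, "bacteria", sep = ".")]])$H, numeric(1)),
    yeast_diversity = vapply(fly$sample_id, function(s)
      shannon(prepared[[paste(s, "yeast", sep = ".")]])$H, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )

  structure(
    list(
      study = study_table(profiles = unname(prepared),
                          abundances = unname(abundance),
                          diversities = div),
      profiles = prepared, replicates = comp$replicates,
      plate_counts = plate_counts, abundance = abundance,
      assays = assays, variables = variables,
      truth = list(compositions = comp$truth, cfu = truth_cfu,
                   tolerance_curves = attr(assays, "truth"),
                   config = config, seed = seed)
    ),
    class = "synthetic_study"
  )
}
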