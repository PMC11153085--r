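# End-to-end orchestration: run the enabled stages against input tables
# declared in a YAML config, write one TSV per stage plus a manifest, and
# render a plain-markdown summary report from a results directory.

stage_file <- function(out_dir, name) file.path(out_dir, paste0(name, ".tsv"))

#' Run the analysis pipeline end to end
#'
#' Stages (each switchable via the config's `stages` list, all on by
#' default): `prep` (replicate averaging, taxon exclusion, optional
#' rare-taxon lumping), `diversity` (Shannon), `similarity` (biocenotic
#' K for declared pairs), `abundance` (CFU estimation from plate
#' counts), `screen` (pairwise correlations), `tolerance` (growth-assay
#' ANOVA + Tukey). Inputs are TSV paths under the config's `inputs` key:
#' `composition`, `metadata`, `pairs`, `plate_counts`, `assays`,
#' `variables`. Alternatively `simulate: true` generates a synthetic
#' study with the configured seed and runs on it. A `manifest.json`
#' (package version, config hash, seed, stages run) is written last;
#' outputs of completed stages are preserved if a later stage fails.
#'
#' @param config Path to a YAML configuration file, or a configuration
#'   list.
#' @param out Output directory (created if needed).
#' @param seed Integer seed used for the synthetic branch and recorded in
#'   the manifest.
#' @return Invisibly, 0 on success (errors propagate as conditions).
#' @export
run_pipeline <- function(config, out, seed = 1L) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    cfg <- utils::modifyList(read_config(NULL), yaml::read_yaml(config))
  } else {
    cfg <- utils::modifyList(read_config(NULL), config)
  }
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stages_run <- character()
  on_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop("stage \"", name, "\" failed: ", conditionMessage(e), call. = FALSE)
    })
    stages_run <<- c(stages_run, name)
    res
  }
  enabled <- function(name) is.null(cfg$stages) || !isFALSE(cfg$stages[[name]])

  profiles <- NULL; variables <- NULL; assays <- NULL
  plate_sets <- NULL; pairs <- NULL

  if (isTRUE(cfg$simulate)) {
    sim <- generate_study(utils::modifyList(default_sim_config(),
                                            cfg$sim_config %||% list()),
                          seed = seed)
    profiles <- sim$profiles
    variables <- sim$variables
    assays <- sim$assays
    plate_sets <- sim$plate_counts
  } else {
    inp <- cfg$inputs
    if (!is.null(inp$composition)) {
      for (f in c(inp$composition, inp$metadata)) {
        if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
      }
      meta <- read_metadata_table(inp$metadata)
      raw <- read_composition_table(inp$composition, meta,
                                    percent_threshold = cfg$percent_threshold)
      profiles <- on_stage("prep", prepare_profiles(
        raw, excluded_taxa = cfg$excluded_taxa,
        rare_threshold = if (isTRUE(cfg$lump_for_stats)) cfg$rare_threshold else NULL))
    }
    if (!is.null(inp$plate_counts)) {
      if (!file.exists(inp$plate_counts)) stop("input file not found: ", inp$plate_counts, call. = FALSE)
      meta <- read_metadata_table(inp$metadata)
      plate_sets <- read_plate_counts(inp$plate_counts, meta)
    }
    if (!is.null(inp$assays)) {
      if (!file.exists(inp$assays)) stop("input file not found: ", inp$assays, call. = FALSE)
      assays <- read_growth_assays(inp$assays)
    }
    if (!is.null(inp$variables)) {
      if (!file.exists(inp$variables)) stop("input file not found: ", inp$variables, call. = FALSE)
      variables <- read_results(inp$variables)
    }
    if (!is.null(inp$pairs)) pairs <- read_results(inp$pairs)
  }

  if (!is.null(profiles)) {
    write_composition_table(profiles, stage_file(out, "profiles"))
    if (enabled("diversity")) {
      div <- on_stage("diversity",
                      diversity_table(profiles, base = cfg$shannon_base))
      write_results(div, stage_file(out, "diversity"))
    }
    if (enabled("similarity") && !is.null(pairs)) {
      sim_tab <- on_stage("similarity", similarity_table(
        profiles, pairs, combiner = cfg$combiner, ks_form = cfg$ks_form,
        detection_floor = cfg$detection_floor))
      write_results(sim_tab, stage_file(out, "similarity"))
    }
  }
  if (!is.null(plate_sets) && enabled("abundance")) {
    recs <- on_stage("abundance", lapply(plate_sets, estimate_cfu,
                                         window = cfg$cfu_window))
    write_results(abundance_table(recs), stage_file(out, "abundance"))
  }
  if (!is.null(variables) && enabled("screen")) {
    scr <- on_stage("screen", run_screen(
      variables, exclude = as.character(cfg$screen_exclude),
      method = cfg$screen_method, sig_levels = unlist(cfg$sig_levels)))
    write_results(as.data.frame(scr), stage_file(out, "screen"))
    write_results(data.frame(variable = rownames(scr$rho), scr$rho,
                             check.names = FALSE),
                  stage_file(out, "screen_matrix"))
  }
  if (!is.null(assays) && enabled("tolerance")) {
    tol <- on_stage("tolerance", tolerance_table(assays))
    write_results(tol, stage_file(out, "tolerance"))
    write_results(two_way_anova(assays), stage_file(out, "tolerance_anova"))
    write_results(tukey_hsd(assays, grouping = "interaction"),
                  stage_file(out, "tolerance_tukey"))
  }

  manifest <- list(
    package = "holobiome",
    version = as.character(utils::packageVersion("holobiome")),
    seed = seed,
    config_hash = if (!is.null(cfg_path)) unname(tools::md5sum(cfg_path))
                  else jsonlite::base64_enc(serialize(cfg, NULL)) |>
                       substr(1, 24),
    stages = stages_run
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Render a data frame as a markdown pipe table (values pre-formatted).
md_table <- function(df, digits = 4) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = digits, format = "g"))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, body), collapse = "\n")
}

#' Summarize a results directory as a markdown report
#'
#' Collects whatever stage outputs are present (composition table,
#' diversity, similarity, abundance, correlation screen, tolerance) into
#' a single `report.md` with significance stars on correlation cells
#' (`*` for 5%, `**` for 10%, following the two-level convention).
#' The report carries no timestamp, so rerunning on the same directory
#' is byte-identical.
#'
#' @param results_dir Directory written by [run_pipeline()].
#' @return Path to `report.md`, invisibly.
#' @export
report <- function(results_dir) {
  files <- list.files(results_dir, pattern = "\\.tsv$")
  if (!dir.exists(results_dir) || length(files) == 0L) {
    stop("no stage outputs found in ", results_dir, call. = FALSE)
  }
  sections <- c("# Holobiome pipeline report", "")
  grab <- function(name) {
    f <- stage_file(results_dir, name)
    if (file.exists(f)) read_results(f) else NULL
  }
  if (!is.null(p <- grab("profiles"))) {
    sections <- c(sections, "## Community composition", "", md_table(p), "")
  }
  if (!is.null(d <- grab("diversity"))) {
    sections <- c(sections, "## Shannon diversity", "", md_table(d), "")
  }
  if (!is.null(s <- grab("similarity"))) {
    sections <- c(sections, "## Biocenotic similarity", "", md_table(s), "")
  }
  if (!is.null(a <- grab("abundance"))) {
    sections <- c(sections, "## Abundance (CFU per unit)", "", md_table(a), "")
  }
  if (!is.null(scr <- grab("screen"))) {
    stars <- ifelse(scr$sig == "p5", "*", ifelse(scr$sig == "p10", "**", ""))
    scr$rho_2dp <- paste0(sprintf("%+.2f", scr$rho_2dp), stars)
    vars <- sort(unique(c(scr$var_a, scr$var_b)))
    m <- matrix("", length(vars), length(vars), dimnames = list(vars, vars))
    diag(m) <- "1"
    for (i in seq_len(nrow(scr))) {
      m[scr$var_a[i], scr$var_b[i]] <- m[scr$var_b[i], scr$var_a[i]] <- scr$rho_2dp[i]
    }
    mdf <- data.frame(variable = vars, m, check.names = FALSE)
    sections <- c(sections, "## Correlation screen", "", md_table(mdf), "",
                  "`*` 5% significance level; `**` 10% significance level.", "")
  }
  if (!is.null(tol <- grab("tolerance"))) {
    sections <- c(sections, "## Salt tolerance (% of 0% NaCl growth)", "",
                  md_table(tol), "")
  }
  out <- file.path(results_dir, "report.md")
  writeLines(sections, out)
  invisible(out)
}
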