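# Growth-tolerance quantification of isolates across NaCl levels:
# OD600 tolerance ratios relative to the salt-free reference, two-way
# ANOVA (isolate x NaCl, both categorical, Type-II sums of squares for
# unbalanced designs) and Tukey HSD multiple comparisons.

# Coerce and validate an assay table.
as_assays <- function(assays) {
  assays <- as.data.frame(assays)
  required <- c("isolate", "nacl_pct", "replicate", "od600")
  miss <- setdiff(required, names(assays))
  if (length(miss)) {
    stop("assays missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(assays$od600 < 0)) stop("od600 must be non-negative", call. = FALSE)
  assays
}

#' Growth-tolerance ratio of one isolate at one NaCl level
#'
#' The ratio (percent) of the mean endpoint OD600 of cultures grown with
#' NaCl to the mean OD600 of the same isolate grown without NaCl. 100
#' means unimpaired growth; 10 means a 90% growth decrease. Per-replicate
#' ratios (each replicate OD over the reference mean) are returned for
#' downstream ANOVA.
#'
#' @param assays Assay data frame with columns `isolate`, `nacl_pct`,
#'   `replicate`, `od600`.
#' @param isolate Isolate name.
#' @param nacl NaCl level (percent) to evaluate.
#' @return List with `ratio_pct` and `per_replicate` (numeric vector).
#' @export
tolerance_ratio <- function(assays, isolate, nacl) {
  assays <- as_assays(assays)
  ref <- assays$od600[assays$isolate == isolate & assays$nacl_pct == 0]
  if (length(ref) == 0L || mean(ref) <= 0) {
    stop("no growth at reference (0% NaCl) for isolate ", isolate, call. = FALSE)
  }
  at <- assays$od600[assays$isolate == isolate & assays$nacl_pct == nacl]
  if (length(at) == 0L) {
    stop("no assays for isolate ", isolate, " at ", nacl, "% NaCl", call. = FALSE)
  }
  per_rep <- 100 * at / mean(ref)
  list(ratio_pct = 100 * mean(at) / mean(ref), per_replicate = per_rep)
}

#' Tolerance ratios for all isolate x NaCl combinations
#'
#' @param assays Assay data frame (see [tolerance_ratio()]).
#' @return Data frame with columns `isolate`, `nacl_pct`, `ratio_pct`,
#'   `n_replicates`.
#' @export
tolerance_table <- function(assays) {
  assays <- as_assays(assays)
  cells <- unique(assays[, c("isolate", "nacl_pct")])
  cells <- cells[order(cells$isolate, cells$nacl_pct), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    tr <- tolerance_ratio(assays, cells$isolate[i], cells$nacl_pct[i])
    data.frame(isolate = cells$isolate[i], nacl_pct = cells$nacl_pct[i],
               ratio_pct = tr$ratio_pct,
               n_replicates = length(tr$per_replicate),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Response vector used by the ANOVA/Tukey layer: per-replicate tolerance
# ratios (default) or raw OD.
assay_response <- function(assays, response = c("ratio", "od")) {
  response <- match.arg(response)
  assays <- as_assays(assays)
  if (response == "od") {
    y <- assays$od600
  } else {
    ref_means <- tapply(assays$od600[assays$nacl_pct == 0],
                        assays$isolate[assays$nacl_pct == 0], mean)
    if (any(is.na(ref_means[unique(assays$isolate)])) ||
        any(ref_means[unique(assays$isolate)] <= 0)) {
      stop("every isolate needs a positive 0% NaCl reference", call. = FALSE)
    }
    y <- 100 * assays$od600 / as.numeric(ref_means[assays$isolate])
  }
  data.frame(y = y,
             isolate = factor(assays$isolate),
             nacl = factor(assays$nacl_pct))
}

#' Two-way ANOVA of growth tolerance
#'
#' Factors: isolate, NaCl level (categorical) and their interaction, on
#' per-replicate tolerance ratios by default (so the isolate main effect
#' reflects tolerance rather than baseline growth; `response = "od"`
#' analyses raw OD600). Type-II sums of squares are used, which coincide
#' with the sequential decomposition on balanced designs.
#'
#' @param assays Assay data frame with >= 2 isolates, >= 2 NaCl levels and
#'   >= 2 replicates per cell; every isolate x level cell must be
#'   occupied.
#' @param response `"ratio"` (default) or `"od"`.
#' @return Data frame with columns `factor`, `SS`, `df`, `F`, `p`
#'   (rows: isolate, nacl, isolate:nacl, Residuals).
#' @export
two_way_anova <- function(assays, response = c("ratio", "od")) {
  d <- assay_response(assays, response)
  tab <- table(d$isolate, d$nacl)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)
    stop("empty design cells: ",
         paste(sprintf("%s x %s%%", rownames(tab)[empty[, 1]],
                       colnames(tab)[empty[, 2]]), collapse = ", "),
         call. = FALSE)
  }
  if (nlevels(d$isolate) < 2 || nlevels(d$nacl) < 2) {
    stop("need at least 2 isolates and 2 NaCl levels", call. = FALSE)
  }
  # Type-II sums of squares by model comparison (each main effect
  # adjusted for the other, interaction adjusted for both). This is the
  # car::Anova(type = 2) decomposition, computed via lm fits so that
  # degenerate zero-residual designs still return well-defined SS.
  fit_full <- stats::lm(y ~ isolate * nacl, data = d)
  fit_add  <- stats::lm(y ~ isolate + nacl, data = d)
  fit_iso  <- stats::lm(y ~ isolate, data = d)
  fit_nacl <- stats::lm(y ~ nacl, data = d)
  rss <- function(m) sum(stats::residuals(m)^2)
  ss <- c(isolate = max(rss(fit_nacl) - rss(fit_add), 0),
          nacl = max(rss(fit_iso) - rss(fit_add), 0),
          `isolate:nacl` = max(rss(fit_add) - rss(fit_full), 0))
  df <- c(nlevels(d$isolate) - 1L, nlevels(d$nacl) - 1L,
          (nlevels(d$isolate) - 1L) * (nlevels(d$nacl) - 1L))
  df_res <- stats::df.residual(fit_full)
  ss_res <- rss(fit_full)
  ms_res <- ss_res / df_res
  tol <- 1e-12 * max(sum((d$y - mean(d$y))^2), 1)
  Fval <- if (ms_res > tol) (ss / df) / ms_res else ifelse(ss <= tol, 0, Inf)
  pval <- ifelse(is.infinite(Fval), 0,
                 stats::pf(Fval, df, df_res, lower.tail = FALSE))
  data.frame(
    factor = c(names(ss), "Residuals"),
    SS = c(unname(ss), ss_res),
    df = c(df, df_res),
    F = c(unname(Fval), NA),
    p = c(unname(pval), NA),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Tukey HSD multiple comparisons of growth tolerance
#'
#' All pairwise comparisons among the levels of one grouping factor
#' (isolate, NaCl level, or the isolate x NaCl cells), with studentized-
#' range adjusted p-values. The model is a one-way ANOVA on the chosen
#' grouping, matching the usual presentation of per-group bars.
#'
#' @param assays Assay data frame.
#' @param grouping `"isolate"`, `"nacl"` or `"interaction"` (isolate x
#'   NaCl cells).
#' @param response `"ratio"` (default) or `"od"`.
#' @return Data frame with columns `comparison`, `diff`, `lwr`, `upr`,
#'   `q`, `p_adj`. Empty (zero rows) when the grouping has a single
#'   level.
#' @export
tukey_hsd <- function(assays, grouping = c("isolate", "nacl", "interaction"),
                      response = c("ratio", "od")) {
  grouping <- match.arg(grouping)
  d <- assay_response(assays, response)
  d$group <- switch(grouping,
                    isolate = d$isolate,
                    nacl = d$nacl,
                    interaction = interaction(d$isolate, d$nacl, sep = ":"))
  d$group <- droplevels(d$group)
  empty_cols <- c("comparison", "diff", "lwr", "upr", "q", "p_adj")
  if (nlevels(d$group) < 2) {
    return(stats::setNames(
      data.frame(character(0), numeric(0), numeric(0), numeric(0),
                 numeric(0), numeric(0), stringsAsFactors = FALSE),
      empty_cols))
  }
  fit <- stats::aov(y ~ group, data = d)
  hsd <- stats::TukeyHSD(fit)$group
  mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  sizes <- table(d$group)
  pairs <- strsplit(rownames(hsd), "-", fixed = TRUE)
  q <- vapply(seq_len(nrow(hsd)), function(i) {
    ni <- sizes[[pairs[[i]][1]]]; nj <- sizes[[pairs[[i]][2]]]
    se <- sqrt(mse / 2 * (1 / ni + 1 / nj))
    if (se == 0) return(0)
    abs(hsd[i, "diff"]) / se
  }, numeric(1))
  data.frame(comparison = rownames(hsd),
             diff = hsd[, "diff"], lwr = hsd[, "lwr"], upr = hsd[, "upr"],
             q = q, p_adj = hsd[, "p adj"],
             row.names = NULL, stringsAsFactors = FALSE)
}
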