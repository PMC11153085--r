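# Pairwise correlation screen over study variables (salt concentration,
# bacterial/yeast abundance, bacterial/yeast diversity) with tie-aware
# Spearman and Kendall coefficients, t-test significance, and
# sample-exclusion sensitivity. Spearman is computed as the Pearson
# correlation of tie-averaged ranks; the d^2 shortcut formula is invalid
# under the heavy ties of the salt variable and is deliberately not used.

#' Average (fractional) ranks with ties
#'
#' Assigns each value its rank; members of a tied group all receive the
#' arithmetic mean of the ranks the group spans, so that the rank sum is
#' always n(n+1)/2.
#'
#' @param values Numeric vector without missing values.
#' @return Numeric vector of average ranks.
#' @export
rank_with_ties <- function(values) {
  n <- length(values)
  if (n == 0L) return(numeric(0))
  if (anyNA(values)) stop("rank_with_ties: missing values not allowed", call. = FALSE)
  o <- order(values)
  sorted <- values[o]
  ranks_sorted <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && sorted[j + 1L] == sorted[i]) j <- j + 1L
    ranks_sorted[i:j] <- (i + j) / 2
    i <- j + 1L
  }
  ranks <- numeric(n)
  ranks[o] <- ranks_sorted
  ranks
}

# Pearson correlation by explicit sums (kept free of stats::cor so the
# test suite can use stats::cor as an independent cross-check).
pearson_sum <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  dx <- x - mx; dy <- y - my
  denom <- sqrt(sum(dx^2) * sum(dy^2))
  if (denom == 0) return(NA_real_)
  sum(dx * dy) / denom
}

# Pairwise completion: drop positions missing in either vector.
complete_pairs <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  list(x = x[keep], y = y[keep], n = sum(keep))
}

#' Spearman rank correlation (tie-safe)
#'
#' Pearson correlation of tie-averaged ranks. Pairs with a missing value
#' in either vector are dropped first.
#'
#' @param x,y Paired numeric vectors; at least 3 complete pairs.
#' @return Correlation in \[-1, 1\], or `NA` (with a warning) when either
#'   vector is constant after pairwise deletion.
#' @export
spearman <- function(x, y) {
  cp <- complete_pairs(x, y)
  if (cp$n < 3L) stop("spearman needs at least 3 complete pairs", call. = FALSE)
  rho <- pearson_sum(rank_with_ties(cp$x), rank_with_ties(cp$y))
  if (is.na(rho)) warning("undefined correlation: zero rank variance")
  rho
}

#' Kendall rank correlation tau-b (tie-corrected)
#'
#' Explicit enumeration of all C(n, 2) pairs: tau_b =
#' (C - D) / sqrt((n0 - t_x)(n0 - t_y)) with n0 = n(n-1)/2 and t the
#' tied-pair counts within each vector.
#'
#' @param x,y Paired numeric vectors; at least 3 complete pairs.
#' @return tau-b in \[-1, 1\], or `NA` when a vector is constant.
#' @export
kendall <- function(x, y) {
  cp <- complete_pairs(x, y)
  if (cp$n < 3L) stop("kendall needs at least 3 complete pairs", call. = FALSE)
  x <- cp$x; y <- cp$y; n <- cp$n
  conc <- 0; disc <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
      if (sx == 0 && sy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (sx == 0) tx <- tx + 1
      else if (sy == 0) ty <- ty + 1
      else if (sx == sy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  denom <- sqrt((n0 - tx) * (n0 - ty))
  if (denom == 0) { warning("undefined correlation: constant vector"); return(NA_real_) }
  (conc - disc) / denom
}

#' t-test for a correlation coefficient
#'
#' t = rho * sqrt((n - 2) / (1 - rho^2)), two-sided p from Student's t
#' with n - 2 degrees of freedom.
#'
#' @param rho Correlation coefficient.
#' @param n Number of paired observations (>= 3).
#' @return List with `t`, `p` and `exact` (`TRUE` when |rho| = 1, where
#'   p = 0 exactly).
#' @export
correlation_significance <- function(rho, n) {
  stopifnot(n >= 3)
  if (is.na(rho)) return(list(t = NA_real_, p = NA_real_, exact = FALSE))
  if (abs(rho) >= 1) {
    return(list(t = sign(rho) * Inf, p = 0, exact = TRUE))
  }
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 2), exact = FALSE)
}

# Round half away from zero to `digits` decimals (matches the convention
# used for reported coefficients; base round() rounds half to even).
round_half_away <- function(x, digits = 2) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}

#' Pairwise correlation screen with exclusion sensitivity
#'
#' Computes all pairwise correlations among the variables of a study
#' table (columns other than `sample_id`), optionally after excluding
#' samples, with t-test significance at the 5% and 10% levels. Missing
#' values are dropped pairwise. A variable with fewer than 3 complete
#' pairs against another is reported as `NA` for that cell; a variable
#' that is entirely missing is flagged absent.
#'
#' @param table Data frame with a `sample_id` column and numeric variable
#'   columns.
#' @param exclude Character vector of sample ids to drop before
#'   computing.
#' @param method `"spearman"` (default) or `"kendall"`.
#' @param sig_levels Named numeric vector of significance levels,
#'   default `c(p5 = 0.05, p10 = 0.10)`.
#' @param holm Apply Holm correction across the off-diagonal tests before
#'   flagging (default `FALSE`, mirroring raw per-test levels).
#' @return An object of class `correlation_screen`: list with matrices
#'   `rho`, `rho_rounded` (2 d.p., half away from zero), `t_stat`,
#'   `p_value`, `n_used`, character matrix `sig_level` (`"ns"`, `"p10"`,
#'   `"p5"`), `method`, `excluded`, `absent` (variables with no data).
#' @export
run_screen <- function(table, exclude = character(),
                       method = c("spearman", "kendall"),
                       sig_levels = c(p5 = 0.05, p10 = 0.10),
                       holm = FALSE) {
  method <- match.arg(method)
  stopifnot("sample_id" %in% names(table))
  keep <- !(table$sample_id %in% exclude)
  if (sum(keep) < 3L) {
    stop("fewer than 3 samples remain after exclusion", call. = FALSE)
  }
  dat <- table[keep, setdiff(names(table), "sample_id"), drop = FALSE]
  vars <- names(dat)
  nv <- length(vars)
  absent <- vars[vapply(dat, function(v) all(is.na(v)), logical(1))]

  rho <- t_stat <- p_value <- matrix(NA_real_, nv, nv, dimnames = list(vars, vars))
  n_used <- matrix(0L, nv, nv, dimnames = list(vars, vars))
  diag(rho) <- 1; diag(p_value) <- 0
  diag(n_used) <- as.integer(colSums(!is.na(dat)))

  estimator <- if (method == "spearman") spearman else kendall
  for (i in seq_len(nv - 1L)) {
    for (j in (i + 1L):nv) {
      cp <- complete_pairs(dat[[i]], dat[[j]])
      n_used[i, j] <- n_used[j, i] <- cp$n
      if (cp$n < 3L || vars[i] %in% absent || vars[j] %in% absent) next
      r <- suppressWarnings(estimator(dat[[i]], dat[[j]]))
      rho[i, j] <- rho[j, i] <- r
      sig <- correlation_significance(r, cp$n)
      t_stat[i, j] <- t_stat[j, i] <- sig$t
      p_value[i, j] <- p_value[j, i] <- sig$p
    }
  }

  p_flag <- p_value
  if (holm) {
    up <- upper.tri(p_value)
    adj <- stats::p.adjust(p_value[up], method = "holm")
    p_flag[up] <- adj
    p_flag[lower.tri(p_flag)] <- t(p_flag)[lower.tri(p_flag)]
  }
  lv <- sort(sig_levels)  # strictest first
  sig_level <- matrix("ns", nv, nv, dimnames = list(vars, vars))
  for (k in rev(seq_along(lv))) {
    sig_level[!is.na(p_flag) & p_flag < lv[k]] <- names(lv)[k]
  }
  diag(sig_level) <- ""

  structure(
    list(method = method, rho = rho,
         rho_rounded = round_half_away(rho, 2),
         t_stat = t_stat, p_value = p_value, n_used = n_used,
         sig_level = sig_level, excluded = exclude, absent = absent,
         holm = holm),
    class = "correlation_screen"
  )
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat("correlation screen (", x$method, ")",
      if (length(x$excluded)) paste0(", excluding ", paste(x$excluded, collapse = ", ")),
      "\n", sep = "")
  stars <- ifelse(x$sig_level == "p5", "*", ifelse(x$sig_level == "p10", "**", ""))
  shown <- matrix(paste0(sprintf("%+.2f", x$rho_rounded), stars),
                  nrow(x$rho), dimnames = dimnames(x$rho))
  shown[is.na(x$rho)] <- "."
  diag(shown) <- "1"
  print(shown, quote = FALSE)
  cat("* 5% significance level; ** 10% significance level\n")
  if (length(x$absent)) cat("absent variables:", paste(x$absent, collapse = ", "), "\n")
  invisible(x)
}

#' Long-format view of a correlation screen
#'
#' @param x A `correlation_screen` object.
#' @param ... Unused.
#' @return Data frame with one row per variable pair: rho (full and 2
#'   d.p.), t, p, n and significance flag.
#' @export
as.data.frame.correlation_screen <- function(x, ...) {
  vars <- rownames(x$rho)
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  data.frame(
    var_a = vars[idx[, 1]], var_b = vars[idx[, 2]],
    rho = x$rho[idx], rho_2dp = x$rho_rounded[idx],
    t = x$t_stat[idx], p = x$p_value[idx],
    n = x$n_used[idx], sig = x$sig_level[idx],
    stringsAsFactors = FALSE
  )
}
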