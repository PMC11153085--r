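test_that("average ranks handle tie groups and sum to n(n+1)/2", {
  expect_equal(rank_with_ties(c(0, 0, 0, 2, 2, 2, 4, 4, 4)),
               c(2, 2, 2, 5, 5, 5, 8, 8, 8))
  expect_equal(rank_with_ties(c(3, 1, 2)), c(3, 1, 2))
  expect_equal(rank_with_ties(rep(7, 5)), rep(3, 5))

  set.seed(5)
  for (i in 1:50) {
    v <- sample(1:6, 20, replace = TRUE)
    r <- rank_with_ties(v)
    expect_equal(sum(r), 20 * 21 / 2)
    expect_equal(r, rank(v, ties.method = "average"))
  }
})

test_that("Spearman equals the Pearson-on-average-ranks oracle with ties", {
  set.seed(29)
  for (i in 1:1000) {
    n <- sample(5:25, 1)
    x <- sample(1:6, n, replace = TRUE) + stats::rnorm(n, 0, 0.01 * (i %% 2))
    y <- sample(1:4, n, replace = TRUE) + stats::rnorm(n, 0, 0.01 * (i %% 3 == 0))
    if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) next
    oracle <- stats::cor(rank(x, ties.method = "average"),
                         rank(y, ties.method = "average"))
    expect_equal(spearman(x, y), oracle, tolerance = 1e-12)
    expect_equal(spearman(x, y), stats::cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
})

test_that("Spearman honours identity, antisymmetry and its contracts", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(spearman(x, x), 1)
  expect_equal(spearman(x, -x), -1)
  expect_error(spearman(1:2, 1:2), "at least 3")
  expect_warning(out <- spearman(c(1, 1, 1), c(1, 2, 3)), "zero rank variance")
  expect_true(is.na(out))
  # missing values are dropped pairwise
  expect_equal(spearman(c(1, 2, NA, 4), c(2, 4, 9, 8)),
               spearman(c(1, 2, 4), c(2, 4, 8)))
})

test_that("Kendall tau-b matches brute-force enumeration and the reference", {
  # brute-force oracle over all C(n,2) pairs, written independently
  tau_oracle <- function(x, y) {
    n <- length(x); num <- 0; tiex <- 0; tiey <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      num <- num + sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (x[i] == x[j]) tiex <- tiex + 1
      if (y[i] == y[j]) tiey <- tiey + 1
    }
    n0 <- choose(n, 2)
    num / sqrt((n0 - tiex) * (n0 - tiey))
  }

  x4 <- c(1, 2, 3, 4); y4 <- c(1, 2, 4, 3)  # one discordant pair
  expect_equal(kendall(x4, y4), tau_oracle(x4, y4))
  expect_equal(kendall(x4, y4), (5 - 1) / 6)

  expect_equal(kendall(x4, x4), 1)

  set.seed(31)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    x <- sample(1:5, n, replace = TRUE)
    y <- sample(1:5, n, replace = TRUE)
    if (stats::var(x) == 0 || stats::var(y) == 0) next
    expect_equal(kendall(x, y), tau_oracle(x, y), tolerance = 1e-12)
    expect_equal(kendall(x, y), stats::cor(x, y, method = "kendall"),
                 tolerance = 1e-12)
  }

  # monotone consistency of the two coefficients
  x <- c(1, 3, 7, 9, 12); y <- exp(x)
  expect_equal(sign(kendall(x, y)), sign(spearman(x, y)))
})

test_that("correlation t-test matches the t-distribution oracle", {
  s <- correlation_significance(0.74, 9)
  expect_equal(s$t, 0.74 * sqrt(7 / (1 - 0.74^2)), tolerance = 1e-12)
  expect_equal(s$t, 2.91, tolerance = 1e-2)
  expect_equal(s$p, 2 * stats::pt(-s$t, 7), tolerance = 1e-12)
  expect_lt(abs(s$p - 0.023), 1e-3)
  expect_lt(s$p, 0.05)

  s <- correlation_significance(0.33, 11)
  expect_equal(s$t, 1.05, tolerance = 1e-2)
  expect_equal(s$p, 0.32, tolerance = 1e-2)
  expect_gt(s$p, 0.10)

  s <- correlation_significance(0, 10)
  expect_equal(s$t, 0); expect_equal(s$p, 1)

  s <- correlation_significance(1, 5)
  expect_equal(s$p, 0); expect_true(s$exact)
})

test_that("the screen reproduces the recomputable published correlation cells", {
  vars <- salt_study_variables()
  scr <- run_screen(vars)
  expect_equal(scr$rho_rounded["salt_pct", "bacterial_abundance"], 0.30)
  expect_equal(scr$rho_rounded["salt_pct", "yeast_abundance"], 0.33)
  expect_equal(scr$rho_rounded["bacterial_abundance", "yeast_abundance"], -0.25)
  expect_equal(scr$n_used["salt_pct", "bacterial_abundance"], 11L)

  scr9 <- run_screen(vars, exclude = c("7a", "7b"))
  # full-precision values; the salt x bacterial-abundance cell is 0.158,
  # i.e. 0.16 at 2 d.p. (the published table prints 0.15 for it)
  expect_equal(scr9$rho["salt_pct", "bacterial_abundance"], 0.1581139,
               tolerance = 1e-6)
  expect_equal(scr9$rho_rounded["salt_pct", "yeast_abundance"], 0.74)
  expect_equal(scr9$rho_rounded["bacterial_abundance", "yeast_abundance"], -0.27)
  expect_equal(scr9$n_used["salt_pct", "yeast_abundance"], 9L)

  # significance flags at the two published levels
  expect_equal(scr9$sig_level["salt_pct", "yeast_abundance"], "p5")
  expect_equal(scr$sig_level["salt_pct", "yeast_abundance"], "ns")

  # all-missing diversity columns are flagged absent, not correlated
  expect_setequal(scr$absent, c("bacterial_diversity", "yeast_diversity"))
  expect_true(is.na(scr$rho["salt_pct", "yeast_diversity"]))
})

test_that("screen bookkeeping: symmetry, exclusion accounting, contracts", {
  set.seed(37)
  vars <- data.frame(sample_id = paste0("s", 1:12),
                     a = rnorm(12), b = rnorm(12), c = sample(1:3, 12, TRUE))
  scr <- run_screen(vars)
  expect_equal(scr$rho, t(scr$rho))
  expect_equal(scr$p_value, t(scr$p_value))
  expect_equal(unname(diag(scr$rho)), rep(1, 3))

  scr2 <- run_screen(vars, exclude = c("s1", "s2", "zz"))
  expect_equal(scr2$n_used["a", "b"], scr$n_used["a", "b"] - 2L)

  expect_error(run_screen(vars, exclude = paste0("s", 1:10)),
               "fewer than 3")

  # kendall route and holm option run end to end
  scrk <- run_screen(vars, method = "kendall", holm = TRUE)
  expect_equal(scrk$method, "kendall")
  expect_true(all(scrk$rho[upper.tri(scrk$rho)] >= -1 &
                  scrk$rho[upper.tri(scrk$rho)] <= 1))

  # rounding convention: half rounds away from zero
  expect_equal(holobiome:::round_half_away(0.125, 2), 0.13)
  expect_equal(holobiome:::round_half_away(-0.125, 2), -0.13)
})
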