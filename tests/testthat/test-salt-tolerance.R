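test_that("tolerance ratios express growth relative to the salt-free reference", {
  m <- matrix(c(1.0, 0.10,
                1.0, 0.60), nrow = 2, byrow = TRUE,
              dimnames = list(c("acet", "lacto"), c("0", "2")))
  assays <- toy_assays(m, n_rep = 4, noise = 0)

  expect_equal(tolerance_ratio(assays, "acet", 2)$ratio_pct, 10)   # 90% decrease
  expect_equal(tolerance_ratio(assays, "lacto", 2)$ratio_pct, 60)  # 40% decrease
  expect_equal(tolerance_ratio(assays, "acet", 0)$ratio_pct, 100)
  expect_length(tolerance_ratio(assays, "acet", 2)$per_replicate, 4)

  zero_ref <- toy_assays(matrix(c(0, 0.1), 1, dimnames = list("z", c("0", "2"))))
  expect_error(tolerance_ratio(zero_ref, "z", 2), "no growth at reference")

  # scale invariance: multiplying an isolate's ODs leaves ratios unchanged
  scaled <- assays
  scaled$od600[scaled$isolate == "acet"] <- scaled$od600[scaled$isolate == "acet"] * 7
  expect_equal(tolerance_ratio(scaled, "acet", 2)$ratio_pct, 10, tolerance = 1e-12)
})

test_that("two-way ANOVA decomposes variance with isolate, salt and interaction", {
  # all observations equal -> F = 0 everywhere
  flat <- toy_assays(matrix(1, 2, 2, dimnames = list(c("a", "b"), c("0", "2"))),
                     n_rep = 3, noise = 0)
  an <- two_way_anova(flat, response = "od")
  expect_equal(an$F[an$factor != "Residuals"], c(0, 0, 0))

  # additive cell means, zero noise -> interaction SS = 0
  means <- outer(c(a = 1, b = 2), c(`0` = 0, `2` = 0.5), `+`)
  addit <- toy_assays(means, n_rep = 3, noise = 0)
  an <- two_way_anova(addit, response = "od")
  expect_equal(an$SS[an$factor == "isolate:nacl"], 0, tolerance = 1e-20)

  # balanced 2x2x(n=3): SS match the direct mean-decomposition oracle
  set.seed(41)
  d <- toy_assays(matrix(c(1, .4, 1.2, .9), 2, dimnames = list(c("a", "b"), c("0", "2"))),
                  n_rep = 3, noise = 0.05)
  an <- two_way_anova(d, response = "od")
  y <- d$od600
  iso <- factor(d$isolate); salt <- factor(d$nacl_pct)
  gm <- mean(y)
  ss_iso <- sum(tapply(y, iso, length) * (tapply(y, iso, mean) - gm)^2)
  ss_salt <- sum(tapply(y, salt, length) * (tapply(y, salt, mean) - gm)^2)
  cellm <- tapply(y, interaction(iso, salt), mean)
  ss_cells <- sum(tapply(y, interaction(iso, salt), length) * (cellm - gm)^2)
  ss_int <- ss_cells - ss_iso - ss_salt
  ss_res <- sum((y - cellm[interaction(iso, salt)])^2)
  expect_equal(an$SS[an$factor == "isolate"], ss_iso, tolerance = 1e-9)
  expect_equal(an$SS[an$factor == "nacl"], ss_salt, tolerance = 1e-9)
  expect_equal(an$SS[an$factor == "isolate:nacl"], ss_int, tolerance = 1e-9)
  expect_equal(an$SS[an$factor == "Residuals"], ss_res, tolerance = 1e-9)

  # balanced SS identity: components add to the total sum of squares
  expect_equal(sum(an$SS), sum((y - gm)^2), tolerance = 1e-9)

  # empty design cells are rejected with the cell named
  broken <- d[!(d$isolate == "a" & d$nacl_pct == 2), ]
  expect_error(two_way_anova(broken, response = "od"), "a x 2%")
})

test_that("the Type-II decomposition matches car::Anova on unbalanced data", {
  skip_if_not_installed("car")
  set.seed(53)
  d <- toy_assays(matrix(c(1, .4, 1.2, .9, .8, .5), 2,
                         dimnames = list(c("a", "b"), c("0", "2", "4"))),
                  n_rep = 4, noise = 0.08)
  d <- d[-c(2, 7, 15), ]  # unbalance the design
  an <- two_way_anova(d, response = "od")
  fit <- stats::lm(od600 ~ factor(isolate) * factor(nacl_pct), data = d)
  ref <- car::Anova(fit, type = 2)
  expect_equal(an$SS, ref[["Sum Sq"]], tolerance = 1e-9)
  expect_equal(an$F[1:3], ref[["F value"]][1:3], tolerance = 1e-9)
  expect_equal(an$p[1:3], ref[["Pr(>F)"]][1:3], tolerance = 1e-9)
})

test_that("Tukey HSD flags separated groups and matches the q-statistic oracle", {
  # two identical groups -> diff 0, p_adj 1
  same <- toy_assays(matrix(c(1, 1), 1, dimnames = list("a", c("0", "2"))),
                     n_rep = 4, noise = 0)
  same$od600 <- rep(c(1, 1.001), 4)  # tiny jitter so MSE > 0
  out <- tukey_hsd(same, grouping = "nacl", response = "od")
  expect_equal(nrow(out), 1L)
  expect_lt(abs(out$diff), 1e-9)
  expect_equal(out$p_adj, 1, tolerance = 1e-6)

  # three groups, one shifted far beyond the within-group SD
  set.seed(43)
  m <- matrix(c(1, 1.02, 5), 3, 1, dimnames = list(c("g1", "g2", "g3"), "0"))
  d <- toy_assays(m, n_rep = 4, noise = 0.02)
  out <- tukey_hsd(d, grouping = "isolate", response = "od")
  far <- grepl("g3", out$comparison)
  expect_true(all(out$p_adj[far] < 0.0005))

  # q statistics equal the direct mean-difference / SE computation (k=3, n=4)
  y <- d$od600; g <- factor(d$isolate)
  mse <- sum(stats::resid(stats::aov(y ~ g))^2) / (length(y) - 3)
  for (i in seq_len(nrow(out))) {
    gs <- strsplit(out$comparison[i], "-")[[1]]
    diff <- mean(y[g == gs[1]]) - mean(y[g == gs[2]])
    se <- sqrt(mse / 2 * (1 / 4 + 1 / 4))
    expect_equal(out$q[i], abs(diff) / se, tolerance = 1e-9)
  }

  # single group -> empty table
  single <- toy_assays(matrix(c(1, 0.5), 1, dimnames = list("a", c("0", "2"))),
                       n_rep = 3)
  expect_equal(nrow(tukey_hsd(single, grouping = "isolate")), 0L)
})

test_that("planted isolate differences surface through ratios, ANOVA and Tukey", {
  cfg <- default_sim_config()
  assays <- generate_assays(cfg, seed = 47, noise_sd = 0)
  # noise-free limit returns the planted curves exactly
  for (iso in names(cfg$isolates)) {
    for (lvl in c(0, 2, 4, 7)) {
      expect_equal(tolerance_ratio(assays, iso, lvl)$ratio_pct,
                   cfg$isolates[[iso]]$curve[[as.character(lvl)]],
                   tolerance = 1e-9)
    }
  }

  # the planted interaction is detected at default effect sizes
  hits <- 0
  for (i in 1:200) {
    a <- generate_assays(cfg, seed = 5000 + i)
    an <- two_way_anova(a)
    if (an$p[an$factor == "isolate:nacl"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.90)

  # planted tolerance ordering at 2% NaCl is recovered
  ord <- 0
  for (i in 1:200) {
    a <- generate_assays(cfg, seed = 7000 + i)
    t2 <- vapply(names(cfg$isolates),
                 function(iso) tolerance_ratio(a, iso, 2)$ratio_pct, numeric(1))
    if (t2[["Acetobacter pasteurianus"]] < t2[["Lactiplantibacillus plantarum"]] &&
        t2[["Lactiplantibacillus plantarum"]] < t2[["Leuconostoc pseudomesenteroides"]]) {
      ord <- ord + 1
    }
  }
  expect_gte(ord / 200, 0.95)
})
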