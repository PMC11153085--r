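test_that("Shannon index matches closed forms and the summation oracle", {
  expect_equal(shannon(prof(A = 1))$H, 0)
  expect_equal(shannon(prof(A = 1))$S, 1L)

  u4 <- prof(A = 1, B = 1, C = 1, D = 1)
  expect_equal(shannon(u4)$H, log(4), tolerance = 1e-12)
  expect_equal(shannon(u4, base = 2)$H, 2, tolerance = 1e-12)

  p <- c(0.5, 0.3, 0.2)
  oracle <- -sum(p * log(p))
  expect_equal(shannon(prof(A = 0.5, B = 0.3, C = 0.2))$H, oracle,
               tolerance = 1e-12)
  expect_equal(oracle, 1.02965, tolerance = 1e-4)

  # zero-abundance taxa contribute nothing
  zp <- community_profile(c(A = 0.5, B = 0.5, C = 0))
  expect_equal(shannon(zp)$H, log(2), tolerance = 1e-12)
  expect_equal(shannon(zp)$S, 2L)

  # degenerate input: no positive mass
  empty <- structure(list(meta = NULL, abundances = c(A = 0),
                          n_replicates = 1L), class = "community_profile")
  expect_error(shannon(empty), "not normalized|empty")
})

test_that("Shannon is permutation-invariant and maximal at the uniform profile", {
  set.seed(3)
  for (i in 1:30) {
    p <- random_profile()
    ab <- p$abundances
    shuffled <- community_profile(sample(ab))
    expect_equal(shannon(shuffled)$H, shannon(p)$H, tolerance = 1e-12)
    S <- shannon(p)$S
    expect_lte(shannon(p)$H, log(S) + 1e-12)
  }
})

test_that("species-composition similarity Ks follows the chosen form", {
  a <- prof(A = 0.5, B = 0.5)
  expect_equal(ks_species(a, a), 1)
  expect_equal(ks_species(a, prof(C = 0.5, D = 0.5)), 0)

  # S1 = 2, S2 = 3, Su = 2 -> Sorensen 2*2/5
  b <- prof(A = 0.4, B = 0.3, C = 0.3)
  expect_equal(ks_species(a, b), 0.8)
  expect_equal(ks_species(a, b, form = "overlap"), 1)
  expect_equal(ks_species(a, b, form = "jaccard"), 2 / 3)

  expect_equal(ks_species(a, b), ks_species(b, a))
  expect_error(ks_species(community_profile(c(A = 1), normalize = FALSE),
                          community_profile(c(A = 1), normalize = FALSE))
               , NA)
})

test_that("abundance similarity Ku is the summed minimum over shared taxa", {
  a <- prof(A = 0.7, B = 0.3)
  expect_equal(ku_abundance(a, a), 1)
  expect_equal(ku_abundance(a, prof(A = 0.2, B = 0.8)), 0.5)

  pair <- salt_study_yeast_zero_pair()
  expect_equal(ku_abundance(pair$`0b`, pair$s0b), 0)
})

test_that("Ku equals the 1 - L1/2 oracle on 1,000 random profile pairs", {
  set.seed(11)
  for (i in 1:1000) {
    a <- random_profile()
    b <- random_profile()
    taxa <- union(names(a$abundances), names(b$abundances))
    pa <- pb <- stats::setNames(numeric(length(taxa)), taxa)
    pa[names(a$abundances)] <- a$abundances
    pb[names(b$abundances)] <- b$abundances
    oracle <- 1 - sum(abs(pa - pb)) / 2
    expect_equal(ku_abundance(a, b), oracle, tolerance = 1e-12)
    expect_equal(ku_abundance(b, a), ku_abundance(a, b))
    expect_gte(ku_abundance(a, b), 0)
    expect_lte(ku_abundance(a, b), 1)
  }
})

test_that("adding an equal shared taxon never decreases Ku", {
  set.seed(13)
  for (i in 1:100) {
    a <- random_profile()
    b <- random_profile()
    before <- ku_abundance(a, b)
    eps <- stats::runif(1, 0.05, 0.5)
    grow <- function(p) {
      ab <- c(p$abundances * (1 - eps), new_taxon = eps)
      community_profile(ab)
    }
    expect_gte(ku_abundance(grow(a), grow(b)), before - 1e-12)
  }
})

test_that("biocenotic K combines Ks and Ku and honours its identities", {
  a <- prof(A = 0.5, B = 0.3, C = 0.2)
  for (comb in c("product", "arithmetic_mean", "geometric_mean")) {
    r <- biocenotic_k(a, a, combiner = comb)
    expect_equal(r$K, 1)
    expect_equal(r$Ks, 1); expect_equal(r$Ku, 1)
    expect_equal(r$Su, r$m)
  }

  pair <- salt_study_yeast_zero_pair()
  for (comb in c("product", "arithmetic_mean", "geometric_mean")) {
    r <- biocenotic_k(pair$`0b`, pair$s0b, combiner = comb)
    expect_equal(r$K, 0)
    expect_equal(r$Su, 0L)
  }

  # Ks = 0.8, Ku known -> combiner arithmetic
  b <- prof(A = 0.4, B = 0.3, C = 0.3)
  ks <- ks_species(a, b); ku <- ku_abundance(a, b)
  expect_equal(biocenotic_k(a, b)$K, ks * ku, tolerance = 1e-12)
  expect_equal(biocenotic_k(a, b, combiner = "arithmetic_mean")$K,
               (ks + ku) / 2, tolerance = 1e-12)
  expect_equal(biocenotic_k(a, b, combiner = "geometric_mean")$K,
               sqrt(ks * ku), tolerance = 1e-12)

  # fixed arithmetic case: Ks = 0.8, Ku = 0.5
  x <- prof(A = 0.5, B = 0.5)
  y <- prof(A = 0.15, B = 0.35, C = 0.5)
  expect_equal(ks_species(x, y), 0.8)
  expect_equal(ku_abundance(x, y), 0.5)
  expect_equal(biocenotic_k(x, y)$K, 0.4, tolerance = 1e-12)
  expect_equal(biocenotic_k(x, y, combiner = "arithmetic_mean")$K, 0.65,
               tolerance = 1e-12)
})

test_that("similarity components are symmetric and bounded on random profiles", {
  set.seed(17)
  for (i in 1:200) {
    a <- random_profile(); b <- random_profile()
    r1 <- biocenotic_k(a, b); r2 <- biocenotic_k(b, a)
    expect_equal(r1$Ks, r2$Ks, tolerance = 1e-12)
    expect_equal(r1$Ku, r2$Ku, tolerance = 1e-12)
    expect_equal(r1$K, r2$K, tolerance = 1e-12)
    for (v in c(r1$Ks, r1$Ku, r1$K)) {
      expect_gte(v, 0); expect_lte(v, 1)
    }
  }
})

test_that("Shannon agrees with an independent reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(19)
  for (i in 1:20) {
    p <- random_profile()
    expect_equal(shannon(p)$H,
                 unname(vegan::diversity(p$abundances, index = "shannon")),
                 tolerance = 1e-10)
  }
})
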