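test_that("two-way ANOVA matches the closed-form balanced oracle", {
  set.seed(101)
  soil <- rep(c("natural", "sterilized"), each = 6)
  striga <- rep(rep(c("control", "infected"), each = 3), 2)
  y <- rnorm(12, mean = 2 * (soil == "natural") + (striga == "infected"))
  res <- twoWayAnova(y, soil, striga)
  ora <- oracleTwoWayAnova(y, soil, striga)
  expect_equal(res["Soil", "sumsq"], ora$ss[["Soil"]], tolerance = 1e-10)
  expect_equal(res["Striga", "sumsq"], ora$ss[["Striga"]], tolerance = 1e-10)
  expect_equal(res["Soil:Striga", "sumsq"], ora$ss[["Int"]],
               tolerance = 1e-10)
  expect_equal(res["Soil", "statistic"], ora$F[["Soil"]], tolerance = 1e-10)
  expect_equal(res["Soil", "p.value"], ora$p[["Soil"]], tolerance = 1e-10)
  expect_equal(res["Soil:Striga", "p.value"], ora$p[["Int"]],
               tolerance = 1e-10)
  # SS decomposition is exact on balanced data
  expect_equal(sum(res$sumsq), sum((y - mean(y))^2), tolerance = 1e-10)
  # location shift changes nothing
  res2 <- twoWayAnova(y + 100, soil, striga)
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-12)
  expect_equal(res2$p.value, res$p.value, tolerance = 1e-12)
  # permutation of sample order changes nothing
  perm <- sample(12)
  res3 <- twoWayAnova(y[perm], soil[perm], striga[perm])
  expect_equal(res3$sumsq, res$sumsq, tolerance = 1e-10)
})

test_that("pure soil contrast yields zero striga and interaction F", {
  soil <- rep(c("natural", "natural", "sterilized", "sterilized"), 2)
  striga <- rep(c("control", "infected"), each = 4)
  y <- c(10, 12, 20, 22, 10, 12, 20, 22)
  res <- twoWayAnova(y, soil, striga)
  expect_equal(res["Striga", "statistic"], 0)
  expect_equal(res["Soil:Striga", "statistic"], 0)
  expect_gt(res["Soil", "statistic"], 0)
})

test_that("degenerate and incomplete designs are handled", {
  soil <- rep(c("natural", "sterilized"), each = 4)
  striga <- rep(c("control", "infected"), 4)
  expect_error(twoWayAnova(rep(1, 8), soil, striga), "degenerate")
  # empty cell falls back to main effects with a warning
  soil2 <- c("natural", "natural", "natural", "natural",
             "sterilized", "sterilized", "sterilized", "sterilized")
  striga2 <- c("control", "control", "infected", "infected",
               "control", "control", "control", "control")
  expect_warning(res <- twoWayAnova(rnorm(8), soil2, striga2), "empty")
  expect_false("Soil:Striga" %in% rownames(res))
})

test_that("trait classification follows the screening rule", {
  fake <- function(pS, pT, pI) {
    d <- data.frame(p.value = c(pS, pT, pI, NA),
                    row.names = c("Soil", "Striga", "Soil:Striga",
                                  "Residuals"))
    d
  }
  expect_equal(classifyTrait(fake(0.01, 0.8, 0.9))$label, "soil_only")
  expect_equal(classifyTrait(fake(0.01, 0.2, 0.01))$label, "interaction")
  expect_equal(classifyTrait(fake(0.9, 0.9, 0.9))$label, "none")
  expect_equal(classifyTrait(fake(0.9, 0.01, 0.9))$label, "striga_only")
  # soil_only even when striga main effect is also significant
  expect_equal(classifyTrait(fake(0.01, 0.01, 0.9))$label, "soil_only")
  # alpha is respected
  expect_equal(classifyTrait(fake(0.04, 0.8, 0.9), alpha = 0.01)$label,
               "none")
})

test_that("Shannon diversity matches hand computations", {
  expect_equal(shannonDiversity(c(10, 10, 10, 10)), log(4))
  expect_equal(shannonDiversity(42), 0)
  expect_equal(shannonDiversity(c(5, 3, 2)),
               -sum(c(.5, .3, .2) * log(c(.5, .3, .2))))
  expect_equal(round(shannonDiversity(c(5, 3, 2)), 4), 1.0297)
  # maximized at uniform composition for fixed taxon count
  set.seed(1)
  for (i in 1:5) {
    x <- rmultinom(1, 1000, runif(6))[, 1]
    expect_lte(shannonDiversity(x), log(6) + 1e-12)
  }
  expect_error(shannonDiversity(c(0, 0)), "all-zero")
})

test_that("Welch t test matches hand formulas and edge conventions", {
  r <- welchTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  r2 <- welchTTest(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(r2$t, -1.0954, tolerance = 1e-4)
  expect_equal(r2$df, 6)
  # scale invariance
  r3 <- welchTTest(2 * c(1, 2, 3, 4), 2 * c(2, 3, 4, 5))
  expect_equal(r3$t, r2$t, tolerance = 1e-12)
  # constant groups, equal means -> defined as no difference
  expect_equal(welchTTest(c(2, 2), c(2, 2))$p, 1)
  expect_error(welchTTest(c(1, 1), c(2, 2)), "zero variance")
})

test_that("hypergeometric enrichment equals brute-force enumeration", {
  expect_equal(hypergeometricEnrichment(4, 5, 4, 10), 5 / 210)
  expect_equal(hypergeometricEnrichment(0, 5, 4, 10), 1)
  expect_equal(hypergeometricEnrichment(6, 6, 6, 6), 1)
  set.seed(3)
  for (i in 1:20) {
    N <- sample(4:12, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeometricEnrichment(k, K, n, N),
                 oracleHyperEnum(k, K, n, N), tolerance = 1e-12,
                 info = sprintf("k=%d K=%d n=%d N=%d", k, K, n, N))
  }
  expect_error(hypergeometricEnrichment(5, 4, 4, 10), "inconsistent")
})

test_that("seed assay rates follow their defining ratios", {
  expect_equal(germinationRate(Ngs = 50, Nts = 100), 50)
  expect_equal(haustoriumRate(NHs = 0, Ngs = 10), 0)
  expect_equal(haustoriumRate(NHs = 7, Ngs = 10), 70)
  expect_warning(h <- haustoriumRate(NHs = 0, Ngs = 0), "undefined")
  expect_true(is.na(h))
})

test_that("root porosity implements the pycnometer formula", {
  expect_equal(rootPorosity(Pw = 150, Pr = 155, Pv = 157, rootMass = 10), 0.4)
  expect_equal(rootPorosity(Pw = 100, Pr = 104, Pv = 104, rootMass = 5), 0)
  expect_warning(p <- rootPorosity(Pw = 100, Pr = 104, Pv = 103,
                                   rootMass = 5), "negative")
  expect_lt(p, 0)
  expect_error(rootPorosity(Pw = 100, Pr = 105, Pv = 106, rootMass = 5),
               "denominator")
})

test_that("suberin odds ratio uses cross product with Haldane correction", {
  r <- suberinOddsRatio(8, 2, 2, 8)
  expect_equal(r$or, 16)
  expect_true(r$p < 0.05)
  expect_equal(suberinOddsRatio(5, 5, 5, 5)$or, 1)
  rz <- suberinOddsRatio(10, 0, 2, 8)
  expect_true(is.finite(rz$or))
  expect_error(suberinOddsRatio(0, 0, 0, 0), "all-zero")
})
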