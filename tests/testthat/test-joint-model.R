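test_that("design matrix uses sterilized/control as reference cell", {
  md <- data.frame(soil = c("sterilized", "natural", "sterilized", "natural"),
                   striga = c("control", "control", "infected", "infected"))
  X <- buildDesign(md)
  expect_equal(unname(X[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(X[2, ]), c(1, 1, 0, 0))
  expect_equal(unname(X[3, ]), c(1, 0, 1, 0))
  expect_equal(unname(X[4, ]), c(1, 1, 1, 1))
  expect_equal(qr(X)$rank, 4)
  expect_equal(X[, "interaction"],
               X[, "soil_natural"] * X[, "striga_infected"])
  expect_error(buildDesign(data.frame(soil = "loamy", striga = "control")),
               "unknown soil")
})

test_that("CLR transform matches its definition and sums to zero", {
  expect_equal(unname(clrTransform(matrix(c(7, 7, 7), 1))), rbind(c(0, 0, 0)))
  x <- clrTransform(matrix(c(3, 1), 1), pseudocount = 0.5)
  expect_equal(unname(x[1, ]), c(log(3.5 / sqrt(3.5 * 1.5)),
                                 log(1.5 / sqrt(3.5 * 1.5))))
  expect_equal(round(unname(x[1, 1]), 4), 0.4236)
  set.seed(2)
  m <- matrix(rpois(50, 20), 5)
  expect_lt(max(abs(rowSums(clrTransform(m)))), 1e-12)
  expect_error(clrTransform(m, pseudocount = 0), "pseudocount")
})

test_that("taxa filter applies prevalence, abundance and id tie-breaks", {
  counts <- matrix(0L, 4, 10,
                   dimnames = list(c("OTU_a", "OTU_b", "OTU_c", "OTU_d"),
                                   paste0("s", 1:10)))
  counts["OTU_a", ] <- 50L           # everywhere, abundant
  counts["OTU_b", ] <- 50L           # tied with OTU_a
  counts["OTU_c", 1:5] <- 10L        # half the samples
  counts["OTU_d", 1] <- 5L           # one sample only
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts))
  expect_equal(rownames(filterTaxa(se, 0, 10)), rownames(counts))  # identity
  expect_false("OTU_d" %in% rownames(filterTaxa(se, 0.25, 10)))
  # two taxa tied at the cutoff: lexicographically smaller id kept
  kept <- rownames(filterTaxa(se, 0, 1))
  expect_equal(kept, "OTU_a")
  expect_error(filterTaxa(se, 1.1, 10), "prevalence")
})

test_that("intercept-only fit recovers the sample correlation", {
  set.seed(21)
  n <- 200
  r <- 0.55
  Y <- matrix(rnorm(2 * n), n, 2) %*% chol(matrix(c(1, r, r, 1), 2))
  colnames(Y) <- c("a", "b")
  X <- cbind(intercept = rep(1, n))
  fit <- gibbsFit(Y, X, nIter = 1200, burnIn = 200, thin = 2, seed = 4)
  rc <- residualCorrelations(fit)
  expect_lt(abs(rc["a", "b"] - cor(Y[, 1], Y[, 2])), 0.05)
  expect_equal(diag(rc), c(a = 1, b = 1))
  expect_identical(rc, t(rc))
})

test_that("vague-prior posterior mean of B matches least squares", {
  set.seed(31)
  md <- data.frame(soil = rep(c("natural", "sterilized"), each = 30),
                   striga = rep(c("control", "infected"), 30))
  X <- buildDesign(md)
  B <- rbind(c(1, 0.5), c(2, -1), c(0, 0.8), c(-0.5, 0))
  Y <- X %*% B + matrix(rnorm(120, sd = 0.7), 60, 2)
  colnames(Y) <- c("y1", "y2")
  fit <- suppressWarnings(gibbsFit(Y, X, prior = list(tau = 1e-8),
                                   nIter = 3000, burnIn = 500, thin = 2,
                                   seed = 9))
  Bls <- solve(crossprod(X), crossprod(X, Y))   # normal-equations oracle
  Bhat <- apply(fit@Bdraws, c(1, 2), mean)
  expect_lt(max(abs(Bhat - Bls)), 0.15)
})

test_that("chains are reproducible and draws are SPD", {
  set.seed(1)
  Y <- matrix(rnorm(150), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  X <- cbind(intercept = rep(1, 50))
  # a ~5%-false-positive Geweke flag on a 500-draw chain is expected noise
  f1 <- suppressWarnings(gibbsFit(Y, X, nIter = 600, burnIn = 100, thin = 1,
                                  seed = 7))
  f2 <- suppressWarnings(gibbsFit(Y, X, nIter = 600, burnIn = 100, thin = 1,
                                  seed = 7))
  expect_identical(f1@SigmaDraws, f2@SigmaDraws)
  expect_identical(f1@Bdraws, f2@Bdraws)
  for (i in seq(1, 500, by = 50)) {
    ev <- eigen(f1@SigmaDraws[, , i], symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
  expect_error(gibbsFit(Y[1:3, 1:2, drop = FALSE],
                        cbind(1, diag(3))[, 1:4], seed = 1),
               "too few samples")
})

test_that("residual correlations agree with the plain residual oracle", {
  set.seed(77)
  md <- data.frame(soil = rep(rep(c("natural", "sterilized"), each = 25), 2),
                   striga = rep(c("control", "infected"), each = 50))
  X <- buildDesign(md)
  Sig <- matrix(c(1, 0.5, 0, 0.5, 1, -0.3, 0, -0.3, 1), 3)
  B <- matrix(rnorm(12), 4, 3)
  Y <- X %*% B + matrix(rnorm(300), 100, 3) %*% chol(Sig)
  colnames(Y) <- c("a", "b", "c")
  fit <- suppressWarnings(gibbsFit(Y, X, prior = list(tau = 1e-8),
                                   nIter = 2000, burnIn = 400, thin = 2,
                                   seed = 3))
  rc <- residualCorrelations(fit)
  Bls <- solve(crossprod(X), crossprod(X, Y))
  rOracle <- cor(Y - X %*% Bls)
  expect_lt(max(abs(rc - rOracle)), 0.05)
})

test_that("H1/H2 contrasts recover planted simple effects", {
  set.seed(55)
  md <- data.frame(soil = rep(rep(c("natural", "sterilized"), each = 50), 2),
                   striga = rep(c("control", "infected"), each = 100))
  X <- buildDesign(md)
  # response 1: pure soil effect +2; response 2: nothing
  B <- rbind(c(0, 0), c(2, 0), c(0, 0), c(0, 0))
  Y <- X %*% B + matrix(rnorm(400), 200, 2)
  colnames(Y) <- c("hit", "null")
  fit <- gibbsFit(Y, X, colRoles = c("trait", "trait"),
                  nIter = 2000, burnIn = 400, thin = 2, seed = 12)
  ct <- contrastH1H2(fit)
  h2 <- ct[ct$contrast == "H2_control" & ct$response == "hit", ]
  expect_lt(abs(h2$mean - 2), 0.3)
  expect_true(h2$lower <= h2$mean && h2$mean <= h2$upper)
  # null response: credible intervals cover zero
  nulls <- ct[ct$response == "null", ]
  expect_true(all(nulls$lower < 0 & nulls$upper > 0))
  # H1 in sterilized soil equals the marginal striga coefficient draw-by-draw
  bS <- fit@Bdraws["striga_infected", "hit", ]
  h1s <- ct[ct$contrast == "H1_sterilized" & ct$response == "hit", ]
  expect_equal(h1s$mean, mean(bS), tolerance = 1e-12)
  expect_equal(h1s$lower, unname(quantile(bS, 0.025)), tolerance = 1e-12)
})
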