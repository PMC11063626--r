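# Independent oracles used to verify the package implementations.
# Deliberately written with different machinery than the functions they check.

# Closed-form balanced two-way ANOVA from cell means (textbook SS formulas).
oracleTwoWayAnova <- function(values, soil, striga) {
  soil <- as.character(soil); striga <- as.character(striga)
  n <- length(values)
  grand <- mean(values)
  sLev <- sort(unique(soil)); tLev <- sort(unique(striga))
  nPerCell <- n / (length(sLev) * length(tLev))
  sMean <- vapply(sLev, function(l) mean(values[soil == l]), 0)
  tMean <- vapply(tLev, function(l) mean(values[striga == l]), 0)
  ssSoil <- sum(vapply(sLev, function(l) sum(soil == l), 0) *
                  (sMean - grand)^2)
  ssStriga <- sum(vapply(tLev, function(l) sum(striga == l), 0) *
                    (tMean - grand)^2)
  ssCells <- 0
  for (a in sLev) for (b in tLev) {
    cell <- values[soil == a & striga == b]
    ssCells <- ssCells + length(cell) * (mean(cell) - grand)^2
  }
  ssInt <- ssCells - ssSoil - ssStriga
  ssTot <- sum((values - grand)^2)
  ssRes <- ssTot - ssCells
  dfS <- length(sLev) - 1; dfT <- length(tLev) - 1; dfI <- dfS * dfT
  dfR <- n - length(sLev) * length(tLev)
  Fs <- (ssSoil / dfS) / (ssRes / dfR)
  Ft <- (ssStriga / dfT) / (ssRes / dfR)
  Fi <- (ssInt / dfI) / (ssRes / dfR)
  list(ss = c(Soil = ssSoil, Striga = ssStriga, Int = ssInt, Res = ssRes),
       F = c(Soil = Fs, Striga = Ft, Int = Fi),
       p = c(Soil = pf(Fs, dfS, dfR, lower.tail = FALSE),
             Striga = pf(Ft, dfT, dfR, lower.tail = FALSE),
             Int = pf(Fi, dfI, dfR, lower.tail = FALSE)))
}

# Hypergeometric upper tail by full enumeration of all C(N, n) draws.
oracleHyperEnum <- function(k, K, n, N) {
  draws <- combn(N, n)
  inCat <- colSums(draws <= K)          # items 1..K are the category
  mean(inCat >= k)
}

# BH step-up computed literally from the definition.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Sort-based re-implementation of the full sign-filter / rank / combined-rank
# scheme, using explicit position averaging instead of rank().
oracleRanking <- function(corr, desiredSign) {
  keep <- if (desiredSign == "negative") corr < 0 else corr > 0
  v <- corr[keep]
  if (!length(v)) return(setNames(numeric(0), character(0)))
  key <- if (desiredSign == "negative") -v else v
  o <- order(key, method = "radix")
  pos <- seq_along(v)
  rk <- numeric(length(v)); rk[o] <- pos
  for (u in unique(key)) {            # average tied positions
    idx <- which(key == u)
    rk[idx] <- mean(rk[idx])
  }
  setNames(rk, names(v))
}

oracleCombined <- function(rs, rt) {
  common <- sort(intersect(names(rs), names(rt)))
  if (!length(common)) return(setNames(numeric(0), character(0)))
  sums <- rs[common] + rt[common]
  o <- order(sums, method = "radix")
  rk <- numeric(length(sums)); rk[o] <- seq_along(sums)
  for (u in unique(sums)) {
    idx <- which(sums == u)
    rk[idx] <- mean(rk[idx])
  }
  setNames(rk, common)
}

# Empirical residual correlation: correlation after removing design-cell means.
oracleResidCorr <- function(Z, cellId) {
  resid <- Z
  for (cl in unique(cellId)) {
    idx <- cellId == cl
    resid[idx, ] <- scale(Z[idx, , drop = FALSE], scale = FALSE)
  }
  stats::cor(resid)
}

# Small simulated dataset shared by several tests.
smallSimConfig <- function(seed = 11, ...) {
  simConfig(nTaxa = 15, nReplicates = 4, subCategories = "rhizosphere",
            timepoints = "2wpi", librarySize = 5000, seed = seed, ...)
}
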