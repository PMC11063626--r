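test_that("sign filter keeps only the desirable direction, strictly", {
  kS <- traitKind("striga_attachments")
  kSub <- traitKind("suberin")
  corr <- c(A = 0.3, B = -0.3, C = 0, D = -0.01)
  expect_equal(names(filterBySign(corr, kS)), c("B", "D"))
  expect_equal(names(filterBySign(corr, kSub)), "A")
  expect_error(traitKind("root_length"), "unknown trait kind")
  expect_equal(traitKind("hif_vanillic")$desiredSign, "negative")
  expect_equal(traitKind("aerenchyma")$desiredSign, "positive")
})

test_that("desirability ranks point the right way and average ties", {
  kS <- traitKind("striga_attachments")
  expect_equal(rankDesirability(c(A = -0.5, B = -0.1), kS), c(A = 2, B = 1))
  kSub <- traitKind("suberin")
  expect_equal(rankDesirability(c(A = 0.4, B = 0.1, C = 0.3), kSub),
               c(A = 3, B = 1, C = 2))
  expect_equal(rankDesirability(c(A = -0.2, B = -0.2), kS),
               c(A = 1.5, B = 1.5))
  expect_length(rankDesirability(setNames(numeric(0), character(0)), kS), 0)
})

test_that("combined rank is the rank of the rank sum on shared taxa", {
  expect_equal(combinedRank(c(A = 2, B = 1), c(A = 2, B = 1)),
               c(A = 2, B = 1))
  expect_equal(combinedRank(c(A = 1), c(A = 1)), c(A = 1))
  expect_warning(out <- combinedRank(c(A = 1), c(B = 1)), "no taxa")
  expect_length(out, 0)
  # restriction to the intersection
  expect_equal(names(combinedRank(c(A = 2, B = 1, C = 3), c(B = 1, C = 2))),
               c("B", "C"))
  # permuting input order changes nothing
  rs <- c(A = 3, B = 1, C = 2); rt <- c(C = 1, A = 2, B = 3)
  expect_equal(combinedRank(rs, rt), combinedRank(rev(rs), rt[c(2, 3, 1)]))
})

test_that("filter/rank/combine equals the brute-force oracle exactly", {
  set.seed(99)
  for (i in 1:100) {
    m <- sample(5:50, 1)
    taxa <- sprintf("t%02d", seq_len(m))
    corrS <- setNames(round(runif(m, -1, 1), 2), taxa)  # rounding makes ties
    corrT <- setNames(round(runif(m, -1, 1), 2), taxa)
    kS <- traitKind("striga_attachments")
    kT <- traitKind("suberin")
    rS <- rankDesirability(filterBySign(corrS, kS), kS)
    rT <- rankDesirability(filterBySign(corrT, kT), kT)
    expect_identical(rS, oracleRanking(corrS, "negative"))
    expect_identical(rT, oracleRanking(corrT, "positive"))
    if (length(rS) && length(rT)) {
      comb <- suppressWarnings(combinedRank(rS, rT))
      expect_identical(comb, oracleCombined(rS, rT))
    }
  }
})

test_that("more negative striga correlation never lowers the combined rank", {
  set.seed(17)
  taxa <- sprintf("t%02d", 1:20)
  corrS <- setNames(-runif(20, 0.01, 0.9), taxa)
  corrT <- setNames(runif(20, 0.01, 0.9), taxa)
  kS <- traitKind("striga_attachments"); kT <- traitKind("aerenchyma")
  base <- combinedRank(rankDesirability(corrS, kS),
                       rankDesirability(corrT, kT))
  for (j in c(1, 7, 13)) {
    corr2 <- corrS
    corr2[j] <- corr2[j] - 0.5            # strictly more suppressive
    new <- combinedRank(rankDesirability(corr2, kS),
                        rankDesirability(corrT, kT))
    expect_gte(new[taxa[j]], base[taxa[j]])
  }
})

test_that("top-k summary counts taxonomy and keeps boundary ties", {
  taxonomy <- data.frame(
    class = c("Actinobacteria", "Actinobacteria", "Gammaproteobacteria"),
    row.names = c("t1", "t2", "t3"))
  comb <- c(t1 = 3, t2 = 2, t3 = 1)
  ts <- topTaxaSummary(comb, taxonomy, k = 3)
  expect_equal(as.integer(ts[c("Actinobacteria", "Gammaproteobacteria")]),
               c(2L, 1L))
  # k larger than m: everything counted
  expect_equal(sum(topTaxaSummary(comb, taxonomy, k = 100)), 3)
  # tie straddling the boundary: all tied taxa included, k exceeded
  comb2 <- c(t1 = 3, t2 = 2, t3 = 2)
  expect_equal(sum(topTaxaSummary(comb2, taxonomy, k = 2)), 3)
  # missing taxonomy -> unclassified
  ts3 <- topTaxaSummary(c(t1 = 2, tX = 1), taxonomy, k = 5)
  expect_equal(as.integer(ts3["unclassified"]), 1L)
})

test_that("candidate genera require the striga gate plus a mechanism", {
  taxonomy <- data.frame(genus = c("Arthrobacter", "Pseudomonas", "Nocardia"),
                         row.names = c("o1", "o2", "o3"))
  rc <- rbind(o1 = c(striga_attachments = -0.25, suberin = 0.25,
                     aerenchyma = 0.1, hif_syringic = 0.0),
              o2 = c(striga_attachments = -0.15, suberin = 0.4,
                     aerenchyma = 0.5, hif_syringic = -0.5),
              o3 = c(striga_attachments = -0.3, suberin = 0.0,
                     aerenchyma = 0.25, hif_syringic = -0.21))
  cand <- selectCandidateGenera(rc, taxonomy, thr = 0.2)
  # o1 qualifies via suberin
  expect_true(any(cand$genus == "Arthrobacter" & cand$mechanism == "suberin"))
  # o2 fails the striga gate despite strong trait correlations
  expect_false("Pseudomonas" %in% cand$genus)
  # o3 qualifies for two mechanisms, unioned under one genus
  mechs <- sort(unique(cand$mechanism[cand$genus == "Nocardia"]))
  expect_equal(mechs, c("aerenchyma", "hif_degradation"))
  # exact threshold is strict
  rcEdge <- rbind(oE = c(striga_attachments = -0.2, suberin = 0.3))
  expect_equal(nrow(selectCandidateGenera(
    rcEdge, data.frame(genus = "X", row.names = "oE"))), 0)
})

test_that("rankTable assembles per-trait combined ranks deterministically", {
  rc <- rbind(
    o1 = c(striga_attachments = -0.6, suberin = 0.5, aerenchyma = 0.4),
    o2 = c(striga_attachments = -0.3, suberin = 0.2, aerenchyma = -0.1),
    o3 = c(striga_attachments = 0.2, suberin = 0.6, aerenchyma = 0.6),
    o4 = c(striga_attachments = -0.1, suberin = -0.2, aerenchyma = 0.2))
  rt <- rankTable(rc)
  # o3 is excluded everywhere (positive striga correlation)
  expect_false("o3" %in% rt$taxon)
  # suberin panel: o1 and o2 survive both filters; o1 wins
  sub <- rt[rt$trait == "suberin", ]
  expect_equal(sub$taxon[sub$combined_rank == max(sub$combined_rank)], "o1")
  # rank values within a trait are a permutation of 1..m (no ties here)
  expect_setequal(sub$combined_rank, seq_len(nrow(sub)))
  expect_identical(rt, rankTable(rc[c(3, 1, 4, 2), ]))  # order invariance
})
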