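#' Two-way soil x Striga ANOVA for a single trait
#'
#' Fits \code{value ~ soil + striga + soil:striga} and returns the per-term
#' sums of squares, F statistics and p values used to screen which root
#' traits the soil microbiome changes. On balanced designs the sequential
#' (type I) decomposition equals the classical closed-form two-way ANOVA; on
#' unbalanced designs hierarchical (type II) sums of squares are used
#' instead. When a design cell is empty the interaction is inestimable and
#' the model falls back to main effects only, with a warning.
#'
#' @param values numeric trait vector.
#' @param soil factor/character with levels natural / sterilized.
#' @param striga factor/character with levels infected / control.
#' @return object of class \code{AnovaResult}: data.frame with rows Soil,
#'   Striga, Soil:Striga (when estimable) and Residuals; columns df, sumsq,
#'   meansq, statistic, p.value.
#' @examples
#' soil <- rep(c("natural", "sterilized"), each = 6)
#' striga <- rep(rep(c("control", "infected"), each = 3), 2)
#' twoWayAnova(rnorm(12, ave(seq(12), soil)), soil, striga)
#' @export
twoWayAnova <- function(values, soil, striga) {
  soil <- factor(soil); striga <- factor(striga)
  stopifnot(length(values) == length(soil), length(soil) == length(striga))
  tab <- table(soil, striga)
  if (sum(tab >= 2) < 3)
    stop("need >= 2 observations in at least 3 of the 4 design cells")
  d <- data.frame(value = values, soil = soil, striga = striga)
  emptyCell <- any(tab == 0)
  if (emptyCell) {
    warning("empty design cell: interaction inestimable, ",
            "falling back to main-effects-only model")
    fit <- stats::lm(value ~ soil + striga, data = d)
  } else {
    fit <- stats::lm(value ~ soil * striga, data = d)
  }
  if (stats::df.residual(fit) < 1)
    stop("degenerate design: no residual degrees of freedom")
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((values - mean(values))^2)
  if (rss <= .Machine$double.eps * max(1, tss))
    stop("degenerate design: zero residual variance")
  balanced <- length(unique(tab)) == 1 && !emptyCell
  if (balanced) {
    a <- stats::anova(fit)                      # type I == closed form
  } else {
    a <- car::Anova(fit, type = 2)              # hierarchical type II
  }
  out <- data.frame(
    term = sub("^soil:striga$", "Soil:Striga",
               sub("^striga$", "Striga", sub("^soil$", "Soil", rownames(a)))),
    df = a$Df, sumsq = a$`Sum Sq`, meansq = a$`Sum Sq` / a$Df,
    statistic = a$`F value`, p.value = a$`Pr(>F)`)
  rownames(out) <- out$term
  class(out) <- c("AnovaResult", "data.frame")
  out
}

#' Classify a trait by which design factors affect it
#'
#' Applies the screening rule used to pick traits for the joint model: only
#' traits the microbiome changes independently of Striga infection
#' (\code{soil_only}) are forwarded. The interaction dominates: any trait
#' with a significant soil:striga interaction is labeled \code{interaction}
#' regardless of the main effects.
#'
#' @param res an \code{AnovaResult} from [twoWayAnova()].
#' @param alpha significance level (default 0.05).
#' @return list with \code{label} in \{soil_only, striga_only, interaction,
#'   none\} and \code{alpha}.
#' @export
classifyTrait <- function(res, alpha = 0.05) {
  p <- setNames(res$p.value, rownames(res))
  pInt <- if ("Soil:Striga" %in% names(p)) p[["Soil:Striga"]] else 1
  label <- if (pInt < alpha) "interaction"
           else if (p[["Soil"]] < alpha) "soil_only"
           else if (p[["Striga"]] < alpha) "striga_only"
           else "none"
  list(label = label, alpha = alpha)
}

#' Shannon alpha diversity (natural log)
#'
#' H = -sum p_i ln p_i over positive-count taxa, the convention used to
#' compare bulk-soil communities between natural and sterilized soil.
#'
#' @param counts nonnegative integer vector (one sample).
#' @return Shannon index in nats.
#' @examples
#' shannonDiversity(c(10, 10, 10, 10))  # ln 4
#' @export
shannonDiversity <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (sum(counts) == 0) stop("all-zero count vector has no diversity")
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Welch two-sample t test
#'
#' Unequal-variance t test with Satterthwaite degrees of freedom, the default
#' comparison for alpha diversity and exudate abundance between soils. The
#' degenerate all-constant case (both groups zero variance, equal means) is
#' defined as no evidence of difference (t = 0, p = 1) rather than an error.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list(t, df, p).
#' @export
welchTTest <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    stop("zero variance in both groups with unequal means: t undefined")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' One-sided hypergeometric enrichment test
#'
#' P(X >= k) for drawing k category members when selecting n items from a
#' universe of N containing K category members; equivalent to a one-sided
#' Fisher exact test on the 2x2 table. Used for ortholog-set enrichment among
#' microbiome-regulated genes.
#'
#' @param k observed overlap.
#' @param K category size in the universe.
#' @param n selection size.
#' @param N universe size.
#' @return one-sided upper-tail p value.
#' @examples
#' hypergeometricEnrichment(4, 5, 4, 10)  # 5/210
#' @export
hypergeometricEnrichment <- function(k, K, n, N) {
  if (k > min(K, n) || K > N || n > N || any(c(k, K, n, N) < 0))
    stop("inconsistent counts: need k <= min(K, n) and K, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Striga seed assay rates
#'
#' Germination rate GR\% = (Ngs / Nts) x 100 and haustorium formation rate
#' HFR\% = (NHs / Ngs) x 100, from counts of total (Nts), germinated (Ngs)
#' and haustorium-bearing (NHs) seeds per well.
#'
#' @param Ngs germinated seeds.
#' @param Nts total seeds.
#' @param NHs seeds with (pre-)haustoria.
#' @return percentage; \code{haustoriumRate} returns \code{NA} with a warning
#'   when no seeds germinated.
#' @examples
#' germinationRate(Ngs = 50, Nts = 100)
#' haustoriumRate(NHs = 7, Ngs = 10)
#' @export
germinationRate <- function(Ngs, Nts) {
  stopifnot(Nts > 0, Ngs >= 0, Ngs <= Nts)
  Ngs / Nts * 100
}

#' @rdname germinationRate
#' @export
haustoriumRate <- function(NHs, Ngs) {
  stopifnot(NHs >= 0)
  if (Ngs == 0) {
    warning("no germinated seeds: haustorium formation rate undefined")
    return(NA_real_)
  }
  stopifnot(NHs <= Ngs)
  NHs / Ngs * 100
}

#' Whole-root-system porosity from pycnometer weights
#'
#' porosity = (Pv - Pr) / (Pw + R - Pr), where Pw is the water-filled
#' pycnometer mass, Pr the mass with the root system added, Pv the mass after
#' vacuum infiltration of the roots, and R the fresh root mass. Used as the
#' aerenchyma proportion of the whole root system. Slightly negative values
#' (Pv < Pr) can arise from weighing noise and are returned as-is with a
#' warning.
#'
#' @param Pw,Pr,Pv pycnometer masses (g); see details.
#' @param rootMass fresh root-system mass R (g).
#' @return porosity fraction.
#' @examples
#' rootPorosity(Pw = 150, Pr = 155, Pv = 157, rootMass = 10)  # 0.40
#' @export
rootPorosity <- function(Pw, Pr, Pv, rootMass) {
  den <- Pw + rootMass - Pr
  if (den == 0) stop("zero denominator: Pw + rootMass - Pr must be nonzero")
  if (Pv < Pr) warning("Pv < Pr: negative porosity, likely measurement noise")
  (Pv - Pr) / den
}

#' Odds ratio and Fisher p for suberization 2x2 tables
#'
#' Cross-product odds ratio comparing e.g. fully-suberized plant counts
#' between an inoculated and a mock treatment, with the Haldane-Anscombe 0.5
#' correction applied (to all cells) only when a zero cell would make the
#' ratio degenerate, plus the two-sided Fisher exact p value on the
#' uncorrected table.
#'
#' @param aYes,aNo successes / failures in the first (treated) group.
#' @param bYes,bNo successes / failures in the second (mock) group.
#' @return list(or, p).
#' @examples
#' suberinOddsRatio(8, 2, 2, 8)  # OR = 16
#' @export
suberinOddsRatio <- function(aYes, aNo, bYes, bNo) {
  cells <- c(aYes, aNo, bYes, bNo)
  if (any(cells < 0)) stop("table cells must be nonnegative")
  if (sum(cells) == 0) stop("all-zero 2x2 table")
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  tab <- matrix(c(aYes, aNo, bYes, bNo), 2, 2)
  p <- stats::fisher.test(tab)$p.value
  list(or = or, p = p)
}
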