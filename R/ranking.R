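#' Trait kinds and their desirable correlation sign
#'
#' A taxon is a suppression candidate when it correlates negatively with
#' Striga attachment number and HIF (syringic / vanillic acid) abundance, and
#' positively with the defensive traits suberin and aerenchyma.
#'
#' @param label one of striga_attachments, hif_syringic, hif_vanillic,
#'   suberin, aerenchyma.
#' @return list(label, desiredSign) with desiredSign "negative" or "positive".
#' @export
traitKind <- function(label) {
  neg <- c("striga_attachments", "hif_syringic", "hif_vanillic")
  pos <- c("suberin", "aerenchyma")
  if (!label %in% c(neg, pos)) stop("unknown trait kind: ", label)
  list(label = label,
       desiredSign = if (label %in% neg) "negative" else "positive")
}

#' Keep taxa whose correlation has the desirable sign
#'
#' Strict inequality against zero: a correlation of exactly 0 is excluded in
#' either direction.
#'
#' @param corr named numeric vector of residual correlations (names = taxa).
#' @param kind a [traitKind()].
#' @return the retained subvector.
#' @export
filterBySign <- function(corr, kind) {
  if (kind$desiredSign == "negative") corr[corr < 0] else corr[corr > 0]
}

#' Desirability rank values for one trait
#'
#' Assigns rank value m to the most desirable taxon and 1 to the least: for
#' negative-desired traits (Striga attachments, HIFs) the lowest correlation
#' gets the highest rank value; for positive-desired traits (suberin,
#' aerenchyma) the highest correlation does. Ties receive the average of the
#' covered positions.
#'
#' @param corr named numeric vector, already sign-filtered.
#' @param kind a [traitKind()].
#' @return named numeric vector of rank values.
#' @examples
#' rankDesirability(c(A = -0.5, B = -0.1), traitKind("striga_attachments"))
#' @export
rankDesirability <- function(corr, kind) {
  if (!length(corr)) return(setNames(numeric(0), character(0)))
  v <- if (kind$desiredSign == "negative") -corr else corr
  r <- rank(v, ties.method = "average")
  setNames(as.numeric(r), names(corr))
}

#' Combined rank across Striga attachments and one focal trait
#'
#' Restricts to taxa ranked for both traits, sums the two rank values, and
#' ranks the sums so that the largest sum receives the highest combined rank
#' value; tied sums are averaged.
#'
#' @param rankStriga,rankTrait named rank-value vectors from
#'   [rankDesirability()].
#' @return named numeric vector of combined rank values over the key
#'   intersection (empty, with a warning, when the intersection is empty).
#' @export
combinedRank <- function(rankStriga, rankTrait) {
  common <- sort(intersect(names(rankStriga), names(rankTrait)))
  if (!length(common)) {
    warning("no taxa ranked for both traits")
    return(setNames(numeric(0), character(0)))
  }
  sums <- rankStriga[common] + rankTrait[common]
  setNames(as.numeric(rank(sums, ties.method = "average")), common)
}

#' Taxonomic summary of the top-ranked taxa
#'
#' Selects the k taxa with the highest combined rank value (all tied taxa at
#' the boundary are included, so more than k may be returned) and counts
#' their taxonomy at the requested level. Taxa missing from the taxonomy are
#' counted as "unclassified".
#'
#' @param combined named combined-rank vector.
#' @param taxonomy data.frame with taxa as rownames and taxonomy columns.
#' @param k number of top taxa to summarise (default 100).
#' @param level taxonomy column used for counting (default "class").
#' @return named integer vector of counts, decreasing.
#' @export
topTaxaSummary <- function(combined, taxonomy, k = 100L, level = "class") {
  if (!length(combined)) return(integer(0))
  if (length(combined) > k) {
    thr <- sort(combined, decreasing = TRUE)[k]
    sel <- names(combined)[combined >= thr]    # ties at the boundary stay
  } else sel <- names(combined)
  lab <- rep("unclassified", length(sel))
  hit <- sel %in% rownames(taxonomy)
  lab[hit] <- as.character(taxonomy[sel[hit], level])
  lab[is.na(lab)] <- "unclassified"
  sort(table(lab), decreasing = TRUE)
}

#' Select candidate genera by residual-correlation thresholds
#'
#' An OTU qualifies for a mechanism when its Striga-attachment residual
#' correlation is below -thr and the mechanism trait passes its own
#' threshold: above +thr for suberin and aerenchyma, below -thr for the HIFs
#' (syringic and vanillic acid, pooled as mechanism "hif_degradation"). A
#' genus is selected when at least one member OTU qualifies; mechanisms are
#' unioned across OTUs.
#'
#' @param residCorr matrix or data.frame of residual correlations, taxa in
#'   rows, with a \code{striga_attachments} column and at least one mechanism
#'   column among aerenchyma, suberin, hif_syringic, hif_vanillic.
#' @param taxonomy data.frame with taxa rownames and a \code{genus} column.
#' @param thr threshold magnitude (default 0.2).
#' @return data.frame(genus, mechanism, otu, corr_striga, corr_trait),
#'   one row per qualifying OTU x mechanism, sorted by genus then otu.
#' @export
selectCandidateGenera <- function(residCorr, taxonomy, thr = 0.2) {
  rc <- as.matrix(residCorr)
  if (!"striga_attachments" %in% colnames(rc))
    stop("residCorr must include a striga_attachments column")
  mechMap <- list(aerenchyma = "aerenchyma", suberin = "suberin",
                  hif_syringic = "hif_degradation",
                  hif_vanillic = "hif_degradation")
  traitsHere <- intersect(names(mechMap), colnames(rc))
  if (!length(traitsHere)) stop("no mechanism trait column in residCorr")
  rows <- list()
  for (otu in rownames(rc)) {
    if (!(rc[otu, "striga_attachments"] < -thr)) next
    for (tr in traitsHere) {
      ok <- if (tr %in% c("suberin", "aerenchyma")) rc[otu, tr] > thr
            else rc[otu, tr] < -thr
      if (ok) {
        genus <- if (otu %in% rownames(taxonomy))
          as.character(taxonomy[otu, "genus"]) else "unclassified"
        rows[[length(rows) + 1L]] <- data.frame(
          genus = genus, mechanism = mechMap[[tr]], otu = otu,
          corr_striga = unname(rc[otu, "striga_attachments"]),
          corr_trait = unname(rc[otu, tr]))
      }
    }
  }
  if (!length(rows))
    return(data.frame(genus = character(), mechanism = character(),
                      otu = character(), corr_striga = numeric(),
                      corr_trait = numeric()))
  out <- unique(do.call(rbind, rows))
  out[order(out$genus, out$otu, out$mechanism), , drop = FALSE]
}

#' Full ranking table for one sub-category x timepoint
#'
#' Applies sign filtering, per-trait desirability ranking and the combined
#' (Striga + focal trait) ranking to a residual-correlation matrix.
#'
#' @param residCorr taxa x traits residual-correlation matrix (must include
#'   \code{striga_attachments}).
#' @param traits focal traits to combine with Striga attachments; defaults to
#'   every recognised trait column present.
#' @return data.frame(taxon, trait, corr_striga, corr_trait, rank_striga,
#'   rank_trait, rank_sum, combined_rank), sorted by trait then decreasing
#'   combined rank then taxon id.
#' @export
rankTable <- function(residCorr, traits = NULL) {
  rc <- as.matrix(residCorr)
  if (is.null(traits))
    traits <- intersect(c("aerenchyma", "suberin", "hif_syringic",
                          "hif_vanillic"), colnames(rc))
  kS <- traitKind("striga_attachments")
  corrS <- setNames(rc[, "striga_attachments"], rownames(rc))
  rS <- rankDesirability(filterBySign(corrS, kS), kS)
  out <- lapply(traits, function(tr) {
    kT <- traitKind(tr)
    corrT <- setNames(rc[, tr], rownames(rc))
    rT <- rankDesirability(filterBySign(corrT, kT), kT)
    comb <- suppressWarnings(combinedRank(rS, rT))
    if (!length(comb)) return(NULL)
    taxa <- names(comb)
    data.frame(taxon = taxa, trait = tr,
               corr_striga = unname(corrS[taxa]),
               corr_trait = unname(corrT[taxa]),
               rank_striga = unname(rS[taxa]),
               rank_trait = unname(rT[taxa]),
               rank_sum = unname(rS[taxa] + rT[taxa]),
               combined_rank = unname(comb))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(taxon = character(), trait = character(),
                      corr_striga = numeric(), corr_trait = numeric(),
                      rank_striga = numeric(), rank_trait = numeric(),
                      rank_sum = numeric(), combined_rank = numeric()))
  out <- out[order(out$trait, -out$combined_rank, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}
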