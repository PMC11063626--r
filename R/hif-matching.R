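#' Relative mass error in parts per million
#'
#' (m_obs - m_ref) / m_ref * 1e6.
#'
#' @param mObs observed neutral monoisotopic mass (Da).
#' @param mRef reference exact mass (Da), > 0.
#' @return signed ppm error (vectorised).
#' @examples
#' ppmError(200.0050, 200.0000)  # +25
#' @export
ppmError <- function(mObs, mRef) {
  stopifnot(all(mRef > 0))
  (mObs - mRef) / mRef * 1e6
}

#' Match metabolomics features to predicted degradation-product masses
#'
#' Reports every (feature, product) pair whose neutral-mass deviation is
#' within the ppm tolerance (boundary inclusive). Matching is many-to-many:
#' a feature within tolerance of several products yields several rows, and
#' vice versa. Retention time is carried through but not used. Output is
#' sorted by (feature_id, product_id).
#'
#' @param features data.frame with columns feature_id, neutral_mass (and
#'   optionally rt plus per-sample areas).
#' @param products data.frame with columns product_id, exact_mass (and
#'   optionally parent, level).
#' @param tolPpm tolerance in ppm (default 25).
#' @return data.frame(feature_id, product_id, parent, ppm_error).
#' @export
matchFeatures <- function(features, products, tolPpm = 25) {
  stopifnot(tolPpm > 0)
  if (!nrow(features) || !nrow(products))
    return(data.frame(feature_id = character(), product_id = character(),
                      parent = character(), ppm_error = numeric()))
  parent <- if ("parent" %in% names(products)) products$parent
            else rep(NA_character_, nrow(products))
  grid <- expand.grid(fi = seq_len(nrow(features)),
                      pi = seq_len(nrow(products)))
  err <- ppmError(features$neutral_mass[grid$fi], products$exact_mass[grid$pi])
  keep <- abs(err) <= tolPpm
  out <- data.frame(feature_id = features$feature_id[grid$fi[keep]],
                    product_id = products$product_id[grid$pi[keep]],
                    parent = parent[grid$pi[keep]],
                    ppm_error = err[keep])
  out <- out[order(out$feature_id, out$product_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Log2 fold change between soil groups with a stabilising offset
#'
#' log2((meanNatural + epsilon) / (meanSterilized + epsilon)); epsilon keeps
#' the ratio finite when a group mean is zero.
#'
#' @param meanNatural,meanSterilized nonnegative group means.
#' @param epsilon positive offset.
#' @return log2 fold change (natural over sterilized).
#' @export
log2FoldChange <- function(meanNatural, meanSterilized, epsilon) {
  stopifnot(epsilon > 0, all(meanNatural >= 0), all(meanSterilized >= 0))
  log2((meanNatural + epsilon) / (meanSterilized + epsilon))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonisation, capped at 1,
#' in the original input order.
#'
#' @param p vector of p values in [0, 1].
#' @return adjusted p values.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Differential abundance of matched features between soils
#'
#' For each matched feature, tests the per-sample peak areas between natural-
#' and sterilized-soil samples (Welch by default; \code{test = "student"}
#' gives the equal-variance version), adjusts p values with
#' Benjamini-Hochberg across the matched features only, and flags features
#' significant at adjusted p < alpha with |log2 fold change| > lfc. The fold
#' change offset epsilon is half the smallest positive area in the table.
#'
#' @param features feature table (feature_id, neutral_mass, rt, sample
#'   columns).
#' @param matches result of [matchFeatures()]; only its feature ids are
#'   tested.
#' @param groups named character vector mapping sample column names to
#'   "natural"/"sterilized".
#' @param test "welch" (default) or "student".
#' @param alpha adjusted-p threshold (default 0.05).
#' @param lfc absolute log2-fold-change threshold (default 1).
#' @return data.frame per matched feature: feature_id, mean_natural,
#'   mean_sterilized, log2fc, p, padj, significant, direction.
#' @export
differentialFeatures <- function(features, matches, groups,
                                 test = c("welch", "student"),
                                 alpha = 0.05, lfc = 1) {
  test <- match.arg(test)
  ids <- sort(unique(matches$feature_id))
  if (!length(ids))
    return(data.frame(feature_id = character(), mean_natural = numeric(),
                      mean_sterilized = numeric(), log2fc = numeric(),
                      p = numeric(), padj = numeric(),
                      significant = logical(), direction = character()))
  sampleCols <- names(groups)
  stopifnot(all(sampleCols %in% names(features)))
  nat <- sampleCols[groups == "natural"]
  ster <- sampleCols[groups == "sterilized"]
  if (length(nat) < 2 || length(ster) < 2)
    stop("need >= 2 samples per soil group")
  areas <- as.matrix(features[, sampleCols, drop = FALSE])
  rownames(areas) <- features$feature_id
  posAreas <- areas[areas > 0]
  eps <- if (length(posAreas)) min(posAreas) / 2 else 1e-8

  res <- lapply(ids, function(id) {
    x <- areas[id, nat]; y <- areas[id, ster]
    p <- if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (mean(x) == mean(y)) 1 else 0
    } else {
      stats::t.test(x, y, var.equal = (test == "student"))$p.value
    }
    data.frame(feature_id = id, mean_natural = mean(x),
               mean_sterilized = mean(y),
               log2fc = log2FoldChange(mean(x), mean(y), eps), p = p)
  })
  out <- do.call(rbind, res)
  out$padj <- bhAdjust(out$p)
  out$significant <- out$padj < alpha & abs(out$log2fc) > lfc
  out$direction <- ifelse(out$log2fc > 0, "higher_in_natural",
                          ifelse(out$log2fc < 0, "higher_in_sterilized",
                                 "equal"))
  rownames(out) <- NULL
  out
}
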