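#' @import methods
#' @importFrom stats setNames
NULL

#' Simulation configuration for synthetic soil-microbiome datasets
#'
#' Holds every parameter of the synthetic-data generator: the 2 soils x
#' 2 Striga treatments factorial design replicated within sub-categories and
#' timepoints, the planted taxon-trait residual correlations, per-factor
#' effect sizes, the sterilized-soil diversity drop, sequencing depth, and the
#' metabolite-feature planting scheme. All randomness downstream flows from
#' \code{seed}.
#'
#' @slot nTaxa number of OTUs simulated.
#' @slot nReplicates biological replicates per soil x Striga cell.
#' @slot subCategories character vector of compartment labels.
#' @slot timepoints character vector, e.g. \code{c("2wpi", "3wpi")}.
#' @slot traits trait labels simulated alongside the taxa.
#' @slot plantedCorr data.frame with columns \code{taxon}, \code{trait},
#'   \code{rho}: residual correlations planted into the latent covariance.
#' @slot soilEffects,strigaEffects,interactionEffects named numeric vectors of
#'   treatment effects on the latent scale (names are taxa or trait labels;
#'   unnamed responses get effect 0).
#' @slot sterilizedDiversityDrop fraction of taxa zeroed out in sterilized-soil
#'   samples (models the gamma-irradiation diversity loss).
#' @slot librarySize multinomial sequencing depth per sample.
#' @slot featurePlant data.frame describing planted metabolomics features
#'   (columns \code{product_id}, \code{parent}, \code{exact_mass},
#'   \code{offset_ppm}, \code{log2fc}).
#' @slot seed integer master seed.
#'
#' @seealso [simConfig()] for the validated constructor,
#'   [simulateDataset()], [simulateFeatureTable()].
#' @export
setClass("SimConfig", representation(
  nTaxa = "integer",
  nReplicates = "integer",
  subCategories = "character",
  timepoints = "character",
  traits = "character",
  plantedCorr = "data.frame",
  soilEffects = "numeric",
  strigaEffects = "numeric",
  interactionEffects = "numeric",
  sterilizedDiversityDrop = "numeric",
  librarySize = "integer",
  featurePlant = "data.frame",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nReplicates < 2L)
    msg <- c(msg, "nReplicates must be >= 2")
  if (object@nTaxa < 2L)
    msg <- c(msg, "nTaxa must be >= 2")
  if (nrow(object@plantedCorr) > 0) {
    if (!all(c("taxon", "trait", "rho") %in% names(object@plantedCorr)))
      msg <- c(msg, "plantedCorr needs columns taxon, trait, rho")
    else if (any(abs(object@plantedCorr$rho) >= 1))
      msg <- c(msg, "planted rho magnitudes must be < 1")
  }
  if (object@sterilizedDiversityDrop < 0 || object@sterilizedDiversityDrop > 1)
    msg <- c(msg, "sterilizedDiversityDrop must be in [0, 1]")
  if (object@librarySize < 1L)
    msg <- c(msg, "librarySize must be positive")
  if (length(msg)) msg else TRUE
})

#' Posterior fit of the joint taxa-trait model
#'
#' Container for the Gibbs-sampler output of the Bayesian multivariate
#' regression of responses (CLR-transformed taxa plus traits) on the soil,
#' Striga and interaction design. Retained draws of the coefficient matrix B
#' (p x q) and residual covariance Sigma (q x q) are stored along with the
#' posterior-mean residual correlation matrix and Geweke convergence
#' diagnostics.
#'
#' @slot Bdraws array p x q x nDraw of coefficient draws.
#' @slot SigmaDraws array q x q x nDraw of residual covariance draws.
#' @slot residCorr posterior-mean residual correlation matrix (q x q).
#' @slot colRoles character vector, one of "taxon"/"trait" per response.
#' @slot design the design matrix used (with factor-coding attributes).
#' @slot mcmc list with nIter, burnIn, thin, seed.
#' @slot geweke named numeric vector of Geweke z-scores.
#'
#' @seealso [gibbsFit()], [residualCorrelations()], [contrastH1H2()]
#' @export
setClass("JointFit", representation(
  Bdraws = "array",
  SigmaDraws = "array",
  residCorr = "matrix",
  colRoles = "character",
  design = "matrix",
  mcmc = "list",
  geweke = "numeric"
))

setValidity("JointFit", function(object) {
  msg <- character()
  q <- dim(object@SigmaDraws)[1]
  if (dim(object@Bdraws)[2] != q)
    msg <- c(msg, "Bdraws and SigmaDraws disagree on q")
  if (!isTRUE(all.equal(unname(diag(object@residCorr)), rep(1, q))))
    msg <- c(msg, "residCorr diagonal must be 1")
  if (max(abs(object@residCorr)) > 1 + 1e-8)
    msg <- c(msg, "residCorr entries must lie in [-1, 1]")
  if (length(object@colRoles) != q)
    msg <- c(msg, "colRoles must label every response column")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimConfig-class compact display
#' @param object a \code{SimConfig}
#' @export
setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nTaxa, "taxa,", length(object@traits), "traits,",
      object@nReplicates, "reps/cell\n")
  cat("  sub-categories:", paste(object@subCategories, collapse = ", "), "\n")
  cat("  timepoints:", paste(object@timepoints, collapse = ", "), "\n")
  cat("  planted correlations:", nrow(object@plantedCorr),
      "| diversity drop:", object@sterilizedDiversityDrop,
      "| library size:", object@librarySize, "\n")
  cat("  seed:", object@seed, "\n")
})

#' @describeIn JointFit-class compact display
#' @param object a \code{JointFit}
#' @export
setMethod("show", "JointFit", function(object) {
  d <- dim(object@SigmaDraws)
  cat("JointFit:", d[1], "responses (",
      sum(object@colRoles == "taxon"), "taxa /",
      sum(object@colRoles == "trait"), "traits ),",
      d[3], "retained draws\n")
  cat("  MCMC: nIter", object@mcmc$nIter, "burnIn", object@mcmc$burnIn,
      "thin", object@mcmc$thin, "seed", object@mcmc$seed, "\n")
  bad <- sum(abs(object@geweke) > 2, na.rm = TRUE)
  cat("  Geweke |z| > 2:", bad, "of", length(object@geweke), "monitored chains\n")
})
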