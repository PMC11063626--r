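#' Construct a validated simulation configuration
#'
#' Builds a [SimConfig-class] describing the synthetic study: a 2 soils
#' (natural / sterilized) x 2 Striga treatments (infected / control) factorial
#' replicated within each sub-category and timepoint, latent Gaussian
#' responses for taxa and root traits with planted residual correlations, and
#' a logistic-normal-multinomial read-count layer.
#'
#' Default effect sizes encode the study conditions the generator emulates:
#' the natural-soil microbiome lowers Striga attachments and
#' haustorium-inducing-factor (HIF) exudation while raising aerenchyma and
#' endodermal suberin, independently of Striga infection; infection itself
#' raises attachment counts.
#'
#' @param nTaxa number of OTUs.
#' @param nReplicates replicates per soil x Striga cell (>= 2).
#' @param subCategories compartment labels.
#' @param timepoints timepoint labels.
#' @param traits trait labels; defaults to the five screened traits.
#' @param plantedCorr data.frame(taxon, trait, rho) of planted residual
#'   correlations on the latent scale; rho magnitudes must be < 1 and the
#'   implied covariance must be positive definite.
#' @param soilEffects,strigaEffects,interactionEffects named numeric vectors
#'   of latent-scale effects (positive soil effect = higher in natural soil;
#'   positive striga effect = higher when infected). Unnamed responses get 0.
#' @param sterilizedDiversityDrop fraction of taxa zeroed in sterilized-soil
#'   samples.
#' @param librarySize multinomial sequencing depth per sample.
#' @param featurePlant data.frame(product_id, parent, exact_mass, offset_ppm,
#'   log2fc) of planted metabolomics features; see [defaultFeaturePlant()].
#' @param seed integer master seed; all randomness derives from it.
#' @return a validated \code{SimConfig}.
#' @examples
#' cfg <- simConfig(nTaxa = 20, nReplicates = 4, seed = 1)
#' cfg
#' @export
simConfig <- function(nTaxa = 50L,
                      nReplicates = 6L,
                      subCategories = c("bulk_soil", "rhizosphere",
                                        "soilplug_roots", "sand_roots"),
                      timepoints = c("2wpi", "3wpi"),
                      traits = c("striga_attachments", "aerenchyma",
                                 "suberin", "hif_syringic", "hif_vanillic"),
                      plantedCorr = data.frame(taxon = character(),
                                               trait = character(),
                                               rho = numeric()),
                      soilEffects = c(striga_attachments = -1.5,
                                      aerenchyma = 1.2, suberin = 1.2,
                                      hif_syringic = -1.2, hif_vanillic = -1.2),
                      strigaEffects = c(striga_attachments = 2.0),
                      interactionEffects = numeric(),
                      sterilizedDiversityDrop = 0.3,
                      librarySize = 30000L,
                      featurePlant = defaultFeaturePlant(),
                      seed = 1L) {
  cfg <- new("SimConfig",
             nTaxa = as.integer(nTaxa),
             nReplicates = as.integer(nReplicates),
             subCategories = as.character(subCategories),
             timepoints = as.character(timepoints),
             traits = as.character(traits),
             plantedCorr = plantedCorr,
             soilEffects = soilEffects,
             strigaEffects = strigaEffects,
             interactionEffects = interactionEffects,
             sterilizedDiversityDrop = as.numeric(sterilizedDiversityDrop),
             librarySize = as.integer(librarySize),
             featurePlant = featurePlant,
             seed = as.integer(seed))
  validObject(cfg)
  # fail fast on a non-positive-definite implied covariance
  invisible(.buildSigma(cfg))
  cfg
}

.taxonIds <- function(nTaxa) sprintf("OTU%04d", seq_len(nTaxa))

# Implied latent residual covariance: identity plus planted correlations.
# Rejects (with the offending eigenvalue) when the planted set is globally
# inconsistent, i.e. the matrix is not positive definite.
.buildSigma <- function(config) {
  taxa <- .taxonIds(config@nTaxa)
  ids <- c(taxa, config@traits)
  q <- length(ids)
  Sigma <- diag(q)
  dimnames(Sigma) <- list(ids, ids)
  pc <- config@plantedCorr
  if (nrow(pc)) {
    bad <- setdiff(c(pc$taxon, pc$trait), ids)
    if (length(bad))
      stop("plantedCorr references unknown responses: ",
           paste(bad, collapse = ", "))
    for (i in seq_len(nrow(pc))) {
      Sigma[pc$taxon[i], pc$trait[i]] <- pc$rho[i]
      Sigma[pc$trait[i], pc$taxon[i]] <- pc$rho[i]
    }
  }
  ev <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10)
    stop("implied residual covariance is not positive definite ",
         "(min eigenvalue ", signif(ev, 3), "); reduce or rebalance plantedCorr")
  Sigma
}

# Deterministic per-purpose substream seeds from the single master seed.
.subSeed <- function(seed, index) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(index)) %% (2^31 - 1))
}

# Latent coefficient matrix B (4 x q): intercept row holds seeded baseline
# log-abundances for taxa (spread over ~2 log units) and 0 for traits;
# treatment rows come from the configured effect vectors.
.buildB <- function(config, ids) {
  q <- length(ids)
  B <- matrix(0, 4, q, dimnames = list(
    c("intercept", "soil_natural", "striga_infected", "interaction"), ids))
  nt <- config@nTaxa
  B["intercept", seq_len(nt)] <- seq(-1, 1, length.out = nt)
  fill <- function(v) {
    out <- setNames(numeric(q), ids)
    if (length(v)) out[intersect(names(v), ids)] <- v[intersect(names(v), ids)]
    out
  }
  B["soil_natural", ] <- fill(config@soilEffects)
  B["striga_infected", ] <- fill(config@strigaEffects)
  B["interaction", ] <- fill(config@interactionEffects)
  B
}

#' Simulate a taxa count table and trait table with planted ground truth
#'
#' Latent responses are drawn as Z = XB + E with E ~ MVN(0, Sigma), where
#' Sigma is the identity overwritten with the planted correlations. Taxa
#' latents are mapped to read counts via a softmax-weighted multinomial at the
#' configured library size; trait latents are reported directly. Samples from
#' sterilized soil have a configured fraction of taxa zeroed (dropout),
#' emulating the diversity loss after soil sterilization. One independent
#' bundle is generated per sub-category x timepoint, sharing taxa identities.
#'
#' Taxa planted in \code{plantedCorr} are excluded from the sterilization
#' dropout set: a residual association is only estimable for a taxon observed
#' across the whole design.
#'
#' @param config a [SimConfig-class].
#' @return list with elements
#'   \describe{
#'     \item{se}{\code{SummarizedExperiment}: taxa x samples counts, taxonomy
#'       in \code{rowData} (phylum, class, genus), sample factors in
#'       \code{colData} (soil, striga, timepoint, sub_category, replicate).}
#'     \item{traits}{long data.frame: sample_id, trait, timepoint, value.}
#'     \item{truth}{ground truth: planted correlations, true B and Sigma,
#'       planted suppressive taxon ids, the dropout set, and the latent
#'       response matrix per sub-category x timepoint (for validation).}
#'   }
#' @examples
#' cfg <- simConfig(nTaxa = 12, nReplicates = 3,
#'                  subCategories = "rhizosphere", timepoints = "2wpi",
#'                  seed = 7)
#' sim <- simulateDataset(cfg)
#' dim(SummarizedExperiment::assay(sim$se))
#' @export
simulateDataset <- function(config) {
  stopifnot(is(config, "SimConfig"))
  taxa <- .taxonIds(config@nTaxa)
  ids <- c(taxa, config@traits)
  q <- length(ids)
  Sigma <- .buildSigma(config)
  B <- .buildB(config, ids)
  cholS <- chol(Sigma)

  set.seed(.subSeed(config@seed, 0))
  nDrop <- floor(config@sterilizedDiversityDrop * config@nTaxa)
  plantedTaxa <- unique(intersect(config@plantedCorr$taxon, taxa))
  droppable <- setdiff(taxa, plantedTaxa)
  dropout <- sort(sample(droppable, min(nDrop, length(droppable))))
  taxonomy <- .simTaxonomy(taxa)

  combos <- expand.grid(sub_category = config@subCategories,
                        timepoint = config@timepoints,
                        stringsAsFactors = FALSE)
  cells <- expand.grid(striga = c("control", "infected"),
                       soil = c("sterilized", "natural"),
                       stringsAsFactors = FALSE)
  countList <- list(); metaList <- list(); latents <- list()
  for (k in seq_len(nrow(combos))) {
    set.seed(.subSeed(config@seed, k))
    meta <- cells[rep(seq_len(4), each = config@nReplicates), ]
    meta$replicate <- rep(seq_len(config@nReplicates), times = 4)
    meta$timepoint <- combos$timepoint[k]
    meta$sub_category <- combos$sub_category[k]
    meta$sample_id <- sprintf("%s_%s_%s_%s_r%02d", meta$sub_category,
                              meta$timepoint, meta$soil, meta$striga,
                              meta$replicate)
    n <- nrow(meta)
    X <- buildDesign(meta)
    E <- matrix(rnorm(n * q), n, q) %*% cholS
    Z <- X %*% B + E
    colnames(Z) <- ids
    rownames(Z) <- meta$sample_id
    counts <- matrix(0L, config@nTaxa, n, dimnames = list(taxa, meta$sample_id))
    for (i in seq_len(n)) {
      w <- exp(Z[i, taxa])
      if (meta$soil[i] == "sterilized") w[dropout] <- 0
      counts[, i] <- as.integer(rmultinom(1, config@librarySize, w / sum(w)))
    }
    countList[[k]] <- counts
    metaList[[k]] <- meta
    latents[[paste(combos$sub_category[k], combos$timepoint[k], sep = ".")]] <- Z
  }
  meta <- do.call(rbind, metaList)
  rownames(meta) <- meta$sample_id
  counts <- do.call(cbind, countList)

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = taxonomy,
    colData = S4Vectors::DataFrame(
      meta[, c("soil", "striga", "timepoint", "sub_category", "replicate")]))

  traitLong <- do.call(rbind, lapply(names(latents), function(nm) {
    Z <- latents[[nm]]
    tp <- sub("^.*\\.", "", nm)
    do.call(rbind, lapply(config@traits, function(tr)
      data.frame(sample_id = rownames(Z), trait = tr, timepoint = tp,
                 value = unname(Z[, tr]))))
  }))
  rownames(traitLong) <- NULL

  suppressive <- unique(config@plantedCorr$taxon[
    config@plantedCorr$trait == "striga_attachments" & config@plantedCorr$rho < 0])

  list(se = se,
       traits = traitLong,
       truth = list(plantedCorr = config@plantedCorr,
                    B = B, Sigma = Sigma,
                    suppressiveTaxa = suppressive,
                    dropoutTaxa = dropout,
                    latents = latents))
}

# Round-robin taxonomy over the dominant classes seen in rhizosphere surveys.
.simTaxonomy <- function(taxa) {
  classes <- data.frame(
    phylum = c("Proteobacteria", "Proteobacteria", "Proteobacteria",
               "Bacteroidota", "Actinobacteriota"),
    class = c("Gammaproteobacteria", "Deltaproteobacteria",
              "Alphaproteobacteria", "Bacteroidia", "Actinobacteria"))
  genera <- c("Pseudomonas", "Myxococcus", "Bradyrhizobium", "Flavobacterium",
              "Arthrobacter", "Aeromicrobium", "Mesorhizobium", "Nocardia",
              "Paenibacillus", "Phenylobacterium")
  i <- (seq_along(taxa) - 1L) %% nrow(classes) + 1L
  g <- (seq_along(taxa) - 1L) %% length(genera) + 1L
  S4Vectors::DataFrame(phylum = classes$phylum[i], class = classes$class[i],
                       genus = genera[g], row.names = taxa)
}

#' Default planted metabolite features
#'
#' A small panel of predicted HIF conversion products (demethylation /
#' oxidation derivatives of syringic acid, vanillic acid, vanillin, DMBQ and
#' acetosyringone; synthetic demo masses, not tool output) with ppm offsets
#' and natural-vs-sterilized log2 fold changes used by
#' [simulateFeatureTable()]. One feature sits deliberately outside the 25 ppm
#' window and several are planted non-differential.
#'
#' @return data.frame(product_id, parent, exact_mass, offset_ppm, log2fc).
#' @export
defaultFeaturePlant <- function() {
  data.frame(
    product_id = c("P_gallic", "P_protocat", "P_catechol", "P_hydroxyq",
                   "P_syringol", "P_acetovan", "P_far", "P_null1", "P_null2"),
    parent = c("syringic acid", "vanillic acid", "vanillic acid", "DMBQ",
               "syringic acid", "acetosyringone", "vanillin", "DMBQ",
               "vanillin"),
    exact_mass = c(170.0215, 154.0266, 110.0368, 126.0317,
                   154.0630, 166.0630, 138.0317, 140.0473, 124.0160),
    offset_ppm = c(5, -8, 2, 12, -20, 0, 30, 4, -6),
    log2fc = c(-3, -2.5, -2, -1.8, -2.2, 0, -2, 0.3, 0))
}

#' Simulate an untargeted metabolomics feature table
#'
#' Places one feature per planted product at mass
#' \code{exact_mass * (1 + offset_ppm / 1e6)}, plus background features at
#' random masses, and draws per-sample peak areas lognormally around group
#' means that realize the configured natural-vs-sterilized fold changes.
#' Negative planted log2 fold changes encode HIF-derived compounds depleted by
#' the natural-soil microbiome's degradation activity being products detected
#' there (degradation products are *higher* in natural soil when log2fc > 0;
#' the default panel plants both directions of interest).
#'
#' @param config a [SimConfig-class]; \code{featurePlant} supplies the panel
#'   and \code{nReplicates} the per-soil sample count.
#' @param nBackground number of unplanted background features at random masses.
#' @param sdlog lognormal noise on peak areas (sd on the log scale).
#' @return list with \code{features} (data.frame: feature_id, neutral_mass,
#'   rt, one column per sample), \code{products} (data.frame: parent,
#'   product_id, exact_mass, level), \code{groups} (named soil group per
#'   sample) and \code{truth} (per-feature within-25ppm-window and
#'   truly-differential flags).
#' @export
simulateFeatureTable <- function(config, nBackground = 20L, sdlog = 0.25) {
  stopifnot(is(config, "SimConfig"))
  fp <- config@featurePlant
  stopifnot(all(c("product_id", "parent", "exact_mass", "offset_ppm",
                  "log2fc") %in% names(fp)))
  set.seed(.subSeed(config@seed, 104729))
  nRep <- config@nReplicates
  samples <- c(sprintf("natural_r%02d", seq_len(nRep)),
               sprintf("sterilized_r%02d", seq_len(nRep)))
  groups <- setNames(rep(c("natural", "sterilized"), each = nRep), samples)

  plantedMass <- fp$exact_mass * (1 + fp$offset_ppm / 1e6)
  bgMass <- runif(nBackground, 100, 400)
  mass <- c(plantedMass, bgMass)
  nFeat <- length(mass)
  featId <- sprintf("F%03d", seq_len(nFeat))
  lfc <- c(fp$log2fc, rep(0, nBackground))

  base <- 10^runif(nFeat, 4, 6)               # sterilized-group mean area
  meanNat <- base * 2^lfc
  areas <- matrix(0, nFeat, length(samples), dimnames = list(featId, samples))
  for (i in seq_len(nFeat)) {
    mu <- ifelse(groups == "natural", meanNat[i], base[i])
    areas[i, ] <- rlnorm(length(samples), meanlog = log(mu) - sdlog^2 / 2,
                         sdlog = sdlog)
  }

  features <- data.frame(feature_id = featId, neutral_mass = mass,
                         rt = round(runif(nFeat, 30, 900), 1))
  features <- cbind(features, as.data.frame(areas))
  rownames(features) <- NULL

  products <- data.frame(parent = fp$parent, product_id = fp$product_id,
                         exact_mass = fp$exact_mass,
                         level = rep_len(c(1L, 2L), nrow(fp)))

  within <- vapply(mass, function(m)
    any(abs((m - products$exact_mass) / products$exact_mass * 1e6) <= 25),
    logical(1))
  truth <- data.frame(feature_id = featId,
                      withinWindow = within,
                      trulyDifferential = abs(lfc) > 1,
                      log2fc = lfc)

  list(features = features, products = products, groups = groups,
       truth = truth)
}
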