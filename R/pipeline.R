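#' Read a taxa count table with metadata and taxonomy
#'
#' Counts TSV: first column \code{taxon_id}, then one column per sample.
#' Metadata TSV: sample_id, soil, striga, timepoint, sub_category, replicate.
#' Taxonomy TSV: taxon_id plus taxonomy columns (phylum, class, genus).
#' Validation failures (missing columns, duplicated ids, negative or
#' non-integer counts) raise errors naming the offending column or cell.
#'
#' @param countsPath,metadataPath,taxonomyPath file paths.
#' @return \code{SummarizedExperiment} (taxa x samples).
#' @export
readTaxaTable <- function(countsPath, metadataPath, taxonomyPath) {
  counts <- utils::read.delim(countsPath, check.names = FALSE)
  if (names(counts)[1] != "taxon_id")
    stop("counts table must start with a taxon_id column")
  if (anyDuplicated(counts$taxon_id))
    stop("duplicated taxon_id in counts table")
  mat <- as.matrix(counts[, -1, drop = FALSE])
  rownames(mat) <- counts$taxon_id
  bad <- which(is.na(mat) | mat < 0 | mat != floor(mat), arr.ind = TRUE)
  if (nrow(bad))
    stop("invalid count at row '", rownames(mat)[bad[1, 1]], "', column '",
         colnames(mat)[bad[1, 2]], "': counts must be nonnegative integers")
  storage.mode(mat) <- "integer"

  meta <- utils::read.delim(metadataPath)
  need <- c("sample_id", "soil", "striga", "timepoint", "sub_category",
            "replicate")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicated sample_id in metadata")
  if (!setequal(colnames(mat), meta$sample_id))
    stop("sample ids differ between counts table and metadata")
  rownames(meta) <- meta$sample_id
  meta <- meta[colnames(mat), ]

  taxo <- utils::read.delim(taxonomyPath)
  if (!"taxon_id" %in% names(taxo))
    stop("taxonomy is missing column: taxon_id")
  rownames(taxo) <- taxo$taxon_id
  taxo <- taxo[rownames(mat), setdiff(names(taxo), "taxon_id"), drop = FALSE]

  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = mat),
    rowData = S4Vectors::DataFrame(taxo),
    colData = S4Vectors::DataFrame(meta[, setdiff(need, "sample_id")]))
}

#' Write a taxa SummarizedExperiment as the three pipeline TSVs
#'
#' @param se the \code{SummarizedExperiment}.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
writeTaxaTable <- function(se, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- SummarizedExperiment::assay(se, "counts")
  cp <- file.path(dir, "counts.tsv")
  utils::write.table(data.frame(taxon_id = rownames(counts), counts,
                                check.names = FALSE),
                     cp, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- as.data.frame(SummarizedExperiment::colData(se))
  mp <- file.path(dir, "metadata.tsv")
  utils::write.table(cbind(sample_id = rownames(meta), meta), mp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  taxo <- as.data.frame(SummarizedExperiment::rowData(se))
  tp <- file.path(dir, "taxonomy.tsv")
  utils::write.table(cbind(taxon_id = rownames(taxo), taxo), tp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(counts = cp, metadata = mp, taxonomy = tp))
}

#' Read / write the long trait table
#'
#' Columns: sample_id, trait, timepoint, value.
#' @param path TSV path.
#' @return data.frame.
#' @export
readTraitTable <- function(path) {
  tr <- utils::read.delim(path)
  need <- c("sample_id", "trait", "timepoint", "value")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    stop("trait table is missing column(s): ", paste(miss, collapse = ", "))
  tr
}

#' @rdname readTraitTable
#' @param traits trait data.frame to write.
#' @export
writeTraitTable <- function(traits, path) {
  utils::write.table(traits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a metabolomics feature table and a product mass list
#'
#' Features CSV: feature_id, neutral_mass, rt, then one column per sample.
#' Products CSV: parent, product_id, exact_mass, level (a formula column is
#' carried through if present).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readFeatureTable <- function(path) {
  ft <- utils::read.csv(path, check.names = FALSE)
  need <- c("feature_id", "neutral_mass", "rt")
  miss <- setdiff(need, names(ft))
  if (length(miss))
    stop("feature table is missing column(s): ", paste(miss, collapse = ", "))
  if (any(ft$neutral_mass <= 0)) stop("neutral_mass must be positive")
  ft
}

#' @rdname readFeatureTable
#' @export
readProductMassList <- function(path) {
  pr <- utils::read.csv(path)
  need <- c("parent", "product_id", "exact_mass")
  miss <- setdiff(need, names(pr))
  if (length(miss))
    stop("product list is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(pr$product_id)) stop("duplicated product_id")
  if (any(pr$exact_mass <= 0)) stop("exact_mass must be positive")
  pr
}

#' Assemble a pipeline configuration
#'
#' @param sim a [SimConfig-class] to simulate inputs, or NULL to read them
#'   from \code{paths}.
#' @param paths named list (counts, metadata, taxonomy, traits, features,
#'   products) when not simulating.
#' @param alpha significance level for the trait screen.
#' @param mcmc list(nIter, burnIn, thin) for the joint model.
#' @param minPrevalence,maxTaxa taxa filter settings.
#' @param thr residual-correlation threshold for candidate selection.
#' @param k top-k size for taxonomy summaries.
#' @param tolPpm,test,lfc,alphaDiff matching / differential settings.
#' @param outDir output directory.
#' @param seed master seed.
#' @param logLevel "debug", "info" or "warn".
#' @return validated config list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(sim = NULL, paths = NULL, alpha = 0.05,
                           mcmc = list(nIter = 10000L, burnIn = 2000L,
                                       thin = 5L),
                           minPrevalence = 0.25, maxTaxa = 100L,
                           thr = 0.2, k = 100L, tolPpm = 25,
                           test = "welch", lfc = 1, alphaDiff = 0.05,
                           outDir = tempfile("strigasieve_run_"),
                           seed = 1L, logLevel = "info") {
  stopifnot(thr > 0, k > 0, tolPpm > 0, lfc > 0, alpha > 0, alphaDiff > 0)
  if (is.null(sim)) {
    need <- c("counts", "metadata", "taxonomy", "traits", "features",
              "products")
    miss <- setdiff(need, names(paths))
    if (length(miss))
      stop("paths must name: ", paste(miss, collapse = ", "))
    absent <- unlist(paths[need])[!file.exists(unlist(paths[need]))]
    if (length(absent))
      stop("input file(s) not found: ", paste(absent, collapse = ", "))
  } else stopifnot(is(sim, "SimConfig"))
  structure(list(sim = sim, paths = paths, alpha = alpha, mcmc = mcmc,
                 minPrevalence = minPrevalence, maxTaxa = maxTaxa, thr = thr,
                 k = k, tolPpm = tolPpm, test = test, lfc = lfc,
                 alphaDiff = alphaDiff, outDir = outDir,
                 seed = as.integer(seed), logLevel = logLevel),
            class = "PipelineConfig")
}

.plog <- function(config, level, ...) {
  lv <- c(debug = 1, info = 2, warn = 3)
  if (lv[[level]] >= lv[[config$logLevel]])
    message("[", level, "] ", ...)
}

#' Run the full screening pipeline
#'
#' Stages, in order: (1) simulate or read inputs; (2) two-way ANOVA trait
#' screen and soil-only classification per timepoint; (3) per sub-category x
#' timepoint joint model fit on CLR taxa plus Striga attachments and the
#' soil-only traits of that timepoint, with residual-correlation extraction;
#' (4) sign filtering, desirability ranking, combined ranking, top-k
#' taxonomy summaries and candidate-genus selection; (5) ppm matching of
#' predicted HIF degradation products and the natural-vs-sterilized
#' differential screen. All stage outputs are written as TSV/JSON under
#' \code{config$outDir} together with a machine-readable run report and a
#' manifest. With no soil-only trait beyond Striga attachments the pipeline
#' stops after the screen with an explanatory report.
#'
#' @param config a [pipelineConfig()].
#' @return the run report (list), invisibly also written as
#'   \code{report.json}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  report <- list(parameters = list(
    alpha = config$alpha, mcmc = config$mcmc, thr = config$thr, k = config$k,
    tolPpm = config$tolPpm, test = config$test, lfc = config$lfc,
    minPrevalence = config$minPrevalence, maxTaxa = config$maxTaxa,
    seed = config$seed, simulated = !is.null(config$sim)))

  ## stage 1: inputs -------------------------------------------------------
  if (!is.null(config$sim)) {
    .plog(config, "info", "simulating dataset (seed ", config$sim@seed, ")")
    sim <- simulateDataset(config$sim)
    feat <- simulateFeatureTable(config$sim)
    se <- sim$se; traits <- sim$traits
    features <- feat$features; products <- feat$products
    featGroups <- feat$groups
    truth <- sim$truth
    writeTaxaTable(se, file.path(config$outDir, "input"))
    writeTraitTable(traits, file.path(config$outDir, "input", "traits.tsv"))
  } else {
    .plog(config, "info", "reading input tables")
    se <- readTaxaTable(config$paths$counts, config$paths$metadata,
                        config$paths$taxonomy)
    traits <- readTraitTable(config$paths$traits)
    features <- readFeatureTable(config$paths$features)
    products <- readProductMassList(config$paths$products)
    sampleCols <- setdiff(names(features), c("feature_id", "neutral_mass",
                                             "rt"))
    featGroups <- setNames(ifelse(grepl("natural", sampleCols), "natural",
                                  "sterilized"), sampleCols)
    truth <- NULL
  }
  meta <- as.data.frame(SummarizedExperiment::colData(se))
  meta$sample_id <- rownames(meta)

  ## stage 2: trait screen -------------------------------------------------
  .plog(config, "info", "trait screen (two-way soil x Striga ANOVA)")
  screen <- list(); soilOnly <- list()
  for (tp in unique(traits$timepoint)) {
    for (tr in unique(traits$trait)) {
      sub <- traits[traits$trait == tr & traits$timepoint == tp, ]
      if (!nrow(sub)) next
      m <- meta[sub$sample_id, ]
      a <- twoWayAnova(sub$value, m$soil, m$striga)
      cls <- classifyTrait(a, config$alpha)
      screen[[length(screen) + 1L]] <- data.frame(
        trait = tr, timepoint = tp, label = cls$label,
        p_soil = a["Soil", "p.value"], p_striga = a["Striga", "p.value"],
        p_interaction = if ("Soil:Striga" %in% rownames(a))
          a["Soil:Striga", "p.value"] else NA_real_)
      if (cls$label == "soil_only")
        soilOnly[[tp]] <- c(soilOnly[[tp]], tr)
    }
  }
  screen <- do.call(rbind, screen)
  utils::write.table(screen, file.path(config$outDir, "trait_screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$trait_screen <- screen
  # attachments always enter the joint model as the infection response
  modelTraits <- lapply(unique(traits$timepoint), function(tp)
    unique(c("striga_attachments",
             intersect(soilOnly[[tp]], unique(traits$trait)))))
  names(modelTraits) <- unique(traits$timepoint)
  if (all(vapply(modelTraits, length, 1L) < 2)) {
    report$status <- "stopped_after_screen"
    report$reason <- paste("no trait classified soil_only: nothing to pair",
                           "with Striga attachments in the joint model")
    .writeReport(report, config)
    return(invisible(report))
  }

  ## stage 3 + 4: joint fits and ranking per sub-category x timepoint ------
  allRanks <- list(); allCand <- list(); topSummaries <- list()
  convergenceWarnings <- character()
  combos <- unique(meta[, c("sub_category", "timepoint")])
  taxonomy <- as.data.frame(SummarizedExperiment::rowData(se))
  for (i in seq_len(nrow(combos))) {
    sc <- combos$sub_category[i]; tp <- combos$timepoint[i]
    tag <- paste(sc, tp, sep = ".")
    useTraits <- modelTraits[[tp]]
    if (length(useTraits) < 2) next
    sel <- meta$sub_category == sc & meta$timepoint == tp
    seSub <- se[, rownames(meta)[sel]]
    seSub <- filterTaxa(seSub, config$minPrevalence, config$maxTaxa)
    counts <- t(SummarizedExperiment::assay(seSub, "counts"))
    Yt <- clrTransform(counts)
    wide <- traits[traits$timepoint == tp & traits$trait %in% useTraits &
                     traits$sample_id %in% rownames(counts), ]
    Ytr <- matrix(NA_real_, nrow(counts), length(useTraits),
                  dimnames = list(rownames(counts), useTraits))
    for (tr in useTraits) {
      v <- wide[wide$trait == tr, ]
      Ytr[v$sample_id, tr] <- v$value
    }
    if (anyNA(Ytr)) stop("missing trait values for sub-category ", tag)
    Y <- cbind(Yt, Ytr)
    roles <- c(rep("taxon", ncol(Yt)), rep("trait", ncol(Ytr)))
    X <- buildDesign(meta[sel, ])
    .plog(config, "info", "joint fit: ", tag, " (", ncol(Y), " responses, ",
          nrow(Y), " samples)")
    fit <- gibbsFit(Y, X, colRoles = roles,
                    nIter = config$mcmc$nIter, burnIn = config$mcmc$burnIn,
                    thin = config$mcmc$thin,
                    seed = .subSeed(config$seed, 500 + i))
    if (any(abs(fit@geweke) >= 2, na.rm = TRUE))
      convergenceWarnings <- c(convergenceWarnings, tag)
    rc <- residualCorrelations(fit)
    taxaIds <- rownames(seSub)
    rcTT <- rc[taxaIds, useTraits, drop = FALSE]
    utils::write.table(
      data.frame(taxon = rownames(rcTT), rcTT, check.names = FALSE),
      file.path(config$outDir, paste0("resid_corr_", tag, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    rt <- rankTable(rcTT)
    if (nrow(rt)) {
      rt$sub_category <- sc; rt$timepoint <- tp
      allRanks[[tag]] <- rt
      for (tr in setdiff(useTraits, "striga_attachments")) {
        comb <- setNames(rt$combined_rank[rt$trait == tr],
                         rt$taxon[rt$trait == tr])
        ts <- topTaxaSummary(comb, taxonomy, k = config$k)
        topSummaries[[paste(tag, tr, sep = ".")]] <- as.list(ts)
      }
    }
    cand <- selectCandidateGenera(rcTT, taxonomy, thr = config$thr)
    if (nrow(cand)) {
      cand$sub_category <- sc; cand$timepoint <- tp
      allCand[[tag]] <- cand
    }
  }
  rankTab <- do.call(rbind, allRanks)
  if (!is.null(rankTab)) {
    rownames(rankTab) <- NULL
    utils::write.table(rankTab, file.path(config$outDir, "rank_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  candTab <- do.call(rbind, allCand)
  if (!is.null(candTab)) rownames(candTab) <- NULL
  else candTab <- data.frame()
  utils::write.table(candTab, file.path(config$outDir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # genus-level union of mechanisms across OTUs and sub-categories
  candGenera <- if (nrow(candTab))
    lapply(split(candTab$mechanism, candTab$genus),
           function(m) sort(unique(m)))
  else list()
  jsonlite::write_json(candGenera,
                       file.path(config$outDir, "candidates.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  report$convergence_warnings <- convergenceWarnings
  report$candidate_genera <- candGenera
  report$top_taxa_summaries <- topSummaries

  ## stage 5: HIF degradation-product matching -----------------------------
  .plog(config, "info", "HIF product matching (", config$tolPpm, " ppm)")
  matches <- matchFeatures(features, products, tolPpm = config$tolPpm)
  diffRes <- differentialFeatures(features, matches, featGroups,
                                  test = config$test,
                                  alpha = config$alphaDiff, lfc = config$lfc)
  utils::write.table(matches, file.path(config$outDir, "hif_matches.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(diffRes,
                     file.path(config$outDir, "hif_differential.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$hif <- list(n_products = nrow(products),
                     n_features = nrow(features),
                     n_matched_features = length(unique(matches$feature_id)),
                     n_match_pairs = nrow(matches),
                     n_significant = sum(diffRes$significant))

  ## planted-truth comparison when simulating ------------------------------
  if (!is.null(truth) && length(truth$suppressiveTaxa) && !is.null(rankTab)) {
    recov <- vapply(split(rankTab, paste(rankTab$sub_category,
                                         rankTab$timepoint, rankTab$trait)),
                    function(d) {
                      top <- d$taxon[order(-d$combined_rank)][
                        seq_len(min(10, nrow(d)))]
                      mean(truth$suppressiveTaxa %in% top)
                    }, numeric(1))
    report$truth_comparison <- list(
      suppressive_taxa = truth$suppressiveTaxa,
      frac_planted_in_top10 = recov)
  }
  report$status <- "ok"
  .writeReport(report, config)
  invisible(report)
}

.writeReport <- function(report, config) {
  path <- file.path(config$outDir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = 10, dataframe = "rows")
  manifest <- sort(setdiff(list.files(config$outDir, recursive = TRUE),
                           "manifest.txt"))
  writeLines(manifest, file.path(config$outDir, "manifest.txt"))
  invisible(path)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file holds the same fields as [pipelineConfig()]; a \code{sim} block
#' (fields of [simConfig()]) requests simulation instead of file inputs.
#' Command-line overrides for \code{seed} and \code{outDir} take precedence.
#'
#' @param path .yaml/.yml or .json file.
#' @param seed,outDir optional overrides.
#' @return a \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path, seed = NULL, outDir = NULL) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (!is.null(seed)) raw$seed <- seed
  if (!is.null(outDir)) raw$outDir <- outDir
  if (!is.null(raw$sim)) {
    simArgs <- raw$sim
    if (is.null(simArgs$seed)) simArgs$seed <- raw$seed
    raw$sim <- do.call(simConfig, simArgs)
  }
  do.call(pipelineConfig, raw[!vapply(raw, is.null, logical(1))])
}
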