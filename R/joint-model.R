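#' Build the treatment design matrix
#'
#' Treatment (dummy) coding of the 2 x 2 factorial with sterilized soil and
#' Striga-free control as the reference cell: columns intercept,
#' soil_natural, striga_infected, interaction, with the interaction column
#' the elementwise product of the two dummies.
#'
#' @param metadata data.frame with columns \code{soil} (natural/sterilized)
#'   and \code{striga} (infected/control).
#' @return n x 4 binary design matrix.
#' @examples
#' buildDesign(data.frame(soil = c("sterilized", "natural"),
#'                        striga = c("control", "infected")))
#' @export
buildDesign <- function(metadata) {
  soil <- as.character(metadata$soil)
  striga <- as.character(metadata$striga)
  if (!all(soil %in% c("natural", "sterilized")))
    stop("unknown soil level: ",
         paste(setdiff(soil, c("natural", "sterilized")), collapse = ", "))
  if (!all(striga %in% c("infected", "control")))
    stop("unknown striga level: ",
         paste(setdiff(striga, c("infected", "control")), collapse = ", "))
  X <- cbind(intercept = 1,
             soil_natural = as.numeric(soil == "natural"),
             striga_infected = as.numeric(striga == "infected"))
  X <- cbind(X, interaction = X[, "soil_natural"] * X[, "striga_infected"])
  rownames(X) <- if (!is.null(metadata$sample_id)) metadata$sample_id
                 else rownames(metadata)
  X
}

#' Centered log-ratio transform of count compositions
#'
#' x_i = ln((c_i + pseudocount) / g(c + pseudocount)) with g the geometric
#' mean; each transformed row sums to zero. This is how OTU counts enter the
#' joint model as Gaussian responses.
#'
#' @param counts matrix of nonnegative counts, samples in rows.
#' @param pseudocount positive offset added before taking logs (default 0.5).
#' @return matrix of the same shape; rows sum to 0.
#' @examples
#' clrTransform(matrix(c(3, 1), 1, 2), pseudocount = 0.5)
#' @export
clrTransform <- function(counts, pseudocount = 0.5) {
  stopifnot(pseudocount > 0)
  x <- log(as.matrix(counts) + pseudocount)
  sweep(x, 1, rowMeans(x))
}

#' Filter taxa by prevalence and abundance
#'
#' Keeps taxa present (count > 0) in at least \code{minPrevalence} of the
#' samples, then the \code{maxTaxa} most abundant by mean relative abundance.
#' Ties at the abundance cutoff are broken lexicographically by taxon id, so
#' the result is deterministic.
#'
#' @param se \code{SummarizedExperiment} with a \code{counts} assay
#'   (taxa x samples).
#' @param minPrevalence fraction of samples a taxon must appear in.
#' @param maxTaxa maximum number of taxa retained.
#' @return the subsetted \code{SummarizedExperiment}.
#' @export
filterTaxa <- function(se, minPrevalence = 0.25, maxTaxa = 100L) {
  counts <- SummarizedExperiment::assay(se, "counts")
  prev <- rowMeans(counts > 0)
  keep <- prev >= minPrevalence
  if (!any(keep)) stop("no taxa pass the prevalence filter")
  rel <- sweep(counts, 2, pmax(colSums(counts), 1), "/")
  meanRel <- rowMeans(rel)[keep]
  ids <- rownames(counts)[keep]
  ord <- order(-meanRel, ids)           # abundance desc, then id asc
  kept <- sort(ids[ord[seq_len(min(maxTaxa, length(ids)))]])
  se[kept, ]
}

#' Fit the joint taxa-trait model by Gibbs sampling
#'
#' Bayesian multivariate regression Y = XB + E, E rows iid MVN(0, Sigma),
#' with a ridge (independent normal, precision \code{tau}) prior on B and an
#' inverse-Wishart(\code{nu0}, \code{S0}) prior on Sigma. Both full
#' conditionals are conjugate: vec(B) | Sigma is multivariate normal with
#' precision \code{kron(solve(Sigma), X'X) + tau I}, and Sigma | B is
#' inverse-Wishart(nu0 + n, S0 + E'E). Draws after burn-in are thinned and
#' retained. Convergence is monitored with Geweke z-scores on the residual
#' log-determinant trace and on ten randomly chosen Sigma entries; |z| >= 2
#' triggers a warning, not an error.
#'
#' @param Y n x q response matrix (CLR-transformed taxa columns followed by
#'   trait columns), no missing values.
#' @param X n x p design from [buildDesign()].
#' @param colRoles character vector ("taxon"/"trait") labelling Y's columns;
#'   defaults to all "taxon".
#' @param prior list(tau, nu0, S0); defaults tau = 1e-3, nu0 = q + 2,
#'   S0 = identity.
#' @param nIter,burnIn,thin MCMC schedule (defaults 10000 / 2000 / 5).
#' @param seed integer seed for the chain.
#' @return a [JointFit-class].
#' @examples
#' X <- cbind(intercept = rep(1, 60))
#' Y <- matrix(rnorm(120), 60, 2, dimnames = list(NULL, c("a", "b")))
#' fit <- gibbsFit(Y, X, nIter = 600, burnIn = 100, thin = 1, seed = 1)
#' residualCorrelations(fit)[1, 2]
#' @export
gibbsFit <- function(Y, X, colRoles = NULL, prior = list(),
                     nIter = 10000L, burnIn = 2000L, thin = 5L, seed = 1L) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y); q <- ncol(Y); p <- ncol(X)
  if (!all(is.finite(Y))) stop("Y contains non-finite values")
  if (n <= p) stop("n <= p: too few samples; apply stronger taxa filtering")
  if (q < 2) stop("joint model needs at least two response columns")
  if (is.null(colRoles)) colRoles <- rep("taxon", q)
  stopifnot(length(colRoles) == q)
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("y%03d", seq_len(q))

  tau <- if (is.null(prior$tau)) 1e-3 else prior$tau
  nu0 <- if (is.null(prior$nu0)) q + 2 else prior$nu0
  S0 <- if (is.null(prior$S0)) diag(q) else prior$S0

  set.seed(seed)
  XtX <- crossprod(X)
  XtY <- crossprod(X, Y)
  # ridge start for B; sample residual covariance as Sigma start
  B <- solve(XtX + tau * diag(p), XtY)
  E <- Y - X %*% B
  Sigma <- crossprod(E) / max(n - p, 1) + 1e-6 * diag(q)

  keep <- seq(burnIn + 1L, nIter)
  keep <- keep[(keep - burnIn - 1L) %% thin == 0L]
  nKeep <- length(keep)
  if (nKeep < 100)
    stop("fewer than 100 retained draws; increase nIter or reduce thin")
  Bdraws <- array(NA_real_, c(p, q, nKeep),
                  dimnames = list(colnames(X), colnames(Y), NULL))
  SigmaDraws <- array(NA_real_, c(q, q, nKeep),
                      dimnames = list(colnames(Y), colnames(Y), NULL))
  logdetTrace <- numeric(nIter)
  # monitor up to 10 distinct Sigma entries (sampled from the lower triangle)
  lowTri <- which(lower.tri(diag(q), diag = TRUE), arr.ind = TRUE)
  monIdx <- lowTri[sample.int(nrow(lowTri), min(10, nrow(lowTri))), ,
                   drop = FALSE]
  monTrace <- matrix(NA_real_, nIter, nrow(monIdx))

  Ipq <- diag(p * q)
  slot_i <- 0L
  for (it in seq_len(nIter)) {
    # Sigma | B ~ IW(nu0 + n, S0 + E'E)
    E <- Y - X %*% B
    Sscale <- S0 + crossprod(E)
    W <- stats::rWishart(1, df = nu0 + n, Sigma = chol2inv(chol(Sscale)))[, , 1]
    Sigma <- chol2inv(chol(W))

    # B | Sigma: vec(B) ~ N(mu, Omega^-1),
    # Omega = kron(Sigma^-1, X'X) + tau I, rhs = vec(X'Y Sigma^-1)
    SigInv <- chol2inv(chol(Sigma))
    Omega <- kronecker(SigInv, XtX) + tau * Ipq
    rhs <- as.vector(XtY %*% SigInv)
    ch <- chol(Omega)
    mu <- backsolve(ch, forwardsolve(t(ch), rhs))
    b <- mu + backsolve(ch, stats::rnorm(p * q))
    B <- matrix(b, p, q)

    if (!all(is.finite(B)) || !all(is.finite(Sigma)))
      stop("non-finite draw at iteration ", it, "; check response scaling")

    logdetTrace[it] <- 2 * sum(log(diag(chol(Sigma))))
    monTrace[it, ] <- Sigma[monIdx]
    if (it > burnIn && (it - burnIn - 1L) %% thin == 0L) {
      slot_i <- slot_i + 1L
      Bdraws[, , slot_i] <- B
      SigmaDraws[, , slot_i] <- Sigma
    }
  }

  post <- seq(burnIn + 1L, nIter)
  gz <- c(logdet = .gewekeZ(logdetTrace[post]),
          setNames(apply(monTrace[post, , drop = FALSE], 2, .gewekeZ),
                   sprintf("sigma_%d_%d", monIdx[, 1], monIdx[, 2])))
  if (any(abs(gz) >= 2, na.rm = TRUE))
    warning("Geweke |z| >= 2 on ", sum(abs(gz) >= 2, na.rm = TRUE),
            " monitored chains; consider more iterations")

  residCorr <- .meanResidCorr(SigmaDraws)
  new("JointFit", Bdraws = Bdraws, SigmaDraws = SigmaDraws,
      residCorr = residCorr, colRoles = colRoles, design = X,
      mcmc = list(nIter = nIter, burnIn = burnIn, thin = thin, seed = seed),
      geweke = gz)
}

# Geweke z: mean of first 10% vs last 50%, variances from an AR spectral
# density estimate at frequency zero.
.gewekeZ <- function(x) {
  n <- length(x)
  a <- x[seq_len(max(2, floor(0.1 * n)))]
  b <- x[seq.int(floor(0.5 * n) + 1, n)]
  s0 <- function(v) {
    if (stats::var(v) == 0) return(0)
    fit <- try(stats::ar(v, aic = TRUE, order.max = min(20, length(v) - 1)),
               silent = TRUE)
    if (inherits(fit, "try-error") || length(fit$ar) == 0)
      return(stats::var(v))
    fit$var.pred / (1 - sum(fit$ar))^2
  }
  se2 <- s0(a) / length(a) + s0(b) / length(b)
  if (se2 == 0) return(0)
  (mean(a) - mean(b)) / sqrt(se2)
}

.meanResidCorr <- function(SigmaDraws) {
  q <- dim(SigmaDraws)[1]
  acc <- matrix(0, q, q)
  for (i in seq_len(dim(SigmaDraws)[3]))
    acc <- acc + stats::cov2cor(SigmaDraws[, , i])
  out <- acc / dim(SigmaDraws)[3]
  out <- (out + t(out)) / 2
  diag(out) <- 1
  dimnames(out) <- dimnames(SigmaDraws)[1:2]
  out
}

#' @rdname residualCorrelations
#' @export
setMethod("residualCorrelations", "JointFit", function(fit) {
  if (dim(fit@SigmaDraws)[3] < 100)
    stop("need at least 100 retained draws")
  fit@residCorr
})

#' @rdname contrastH1H2
#' @export
setMethod("contrastH1H2", "JointFit", function(fit) {
  cn <- dimnames(fit@Bdraws)[[1]]
  need <- c("soil_natural", "striga_infected", "interaction")
  if (!all(need %in% cn))
    stop("design must include both factors and their interaction")
  bSoil <- fit@Bdraws["soil_natural", , , drop = TRUE]
  bStriga <- fit@Bdraws["striga_infected", , , drop = TRUE]
  bInt <- fit@Bdraws["interaction", , , drop = TRUE]
  defs <- list(
    H1_sterilized = bStriga,          # striga effect in the reference soil
    H1_natural = bStriga + bInt,
    H2_control = bSoil,               # soil effect in the reference treatment
    H2_infected = bSoil + bInt)
  resp <- dimnames(fit@Bdraws)[[2]]
  do.call(rbind, lapply(names(defs), function(nm) {
    d <- defs[[nm]]                   # q x nDraw
    data.frame(response = resp, role = fit@colRoles, contrast = nm,
               mean = rowMeans(d),
               lower = apply(d, 1, stats::quantile, 0.025),
               upper = apply(d, 1, stats::quantile, 0.975),
               probPositive = rowMeans(d > 0),
               row.names = NULL)
  }))
})
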