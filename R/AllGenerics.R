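#' Extract posterior-mean residual correlations
#'
#' The residual correlation between two responses measures how strongly they
#' covary after the modeled soil and Striga treatment effects are removed; it
#' is the quantity used to associate bacterial taxa with Striga-suppressive
#' root traits.
#'
#' @param fit a [JointFit-class] object.
#' @return symmetric q x q correlation matrix with unit diagonal, computed as
#'   the posterior mean of the per-draw correlation conversion of Sigma.
#' @export
setGeneric("residualCorrelations", function(fit) standardGeneric("residualCorrelations"))

#' Within-factor treatment contrasts (H1 / H2)
#'
#' For each response summarises the two families of simple effects in the
#' 2 x 2 design: H1, the Striga effect within each soil type (sterilized:
#' beta_striga; natural: beta_striga + beta_interaction), and H2, the soil
#' effect within each Striga treatment (control: beta_soil; infected:
#' beta_soil + beta_interaction).
#'
#' @param fit a [JointFit-class] object.
#' @return data.frame with columns \code{response}, \code{role},
#'   \code{contrast}, \code{mean}, \code{lower}, \code{upper} (95% credible
#'   interval) and \code{probPositive}.
#' @export
setGeneric("contrastH1H2", function(fit) standardGeneric("contrastH1H2"))
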