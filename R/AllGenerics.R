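#' Probe identifiers of an object
#'
#' @param x a \linkS4class{BetaSet}, \linkS4class{ClockModel} or
#'   \linkS4class{ReferenceSignature}.
#' @return Character vector of CpG probe identifiers.
#' @export
setGeneric("probeIds", function(x) standardGeneric("probeIds"))

#' Beta-value matrix of an object
#'
#' @param x a \linkS4class{BetaSet}.
#' @return Numeric probes x samples matrix of methylation fractions.
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' Predict DNA methylation age
#'
#' Applies a CpG clock to a beta-value matrix: per sample the linear
#' predictor \code{intercept + sum(coef_j * beta_j)} is evaluated on the
#' calibrated (transformed-age) scale and mapped back to years with
#' \code{\link{inverseTransformAge}}.
#'
#' @param betas a \linkS4class{BetaSet} or a numeric probes x samples matrix
#'   with probe IDs as rownames and sample IDs as colnames.
#' @param model a \linkS4class{ClockModel}.
#' @param minProbeFraction minimum fraction of the model's probes that must
#'   be observed (non-missing) for a sample; samples below it get \code{NA}
#'   with a warning rather than a silently wrong age.
#' @param missingPolicy how missing clock-probe betas are filled before the
#'   weighted sum: \code{"mean"} uses that probe's cohort mean (0.5 when the
#'   probe is missing in every sample), \code{"error"} refuses.
#' @return Named numeric vector of DNAm ages in years (names = sample IDs);
#'   failed samples are \code{NA}.
#' @export
setGeneric("applyClock", function(betas, model, minProbeFraction = 0.8,
                                  missingPolicy = c("mean", "error"))
  standardGeneric("applyClock"))

#' Estimate blood cell-type fractions from methylation
#'
#' Reference-based deconvolution: each sample's beta profile is projected
#' onto the pure cell-type signature matrix by nonnegative least squares,
#' minimising \eqn{||beta - R w||^2} subject to \eqn{w \ge 0} and, in the
#' default \code{"sum1"} mode, \eqn{\sum w = 1}.
#'
#' @param betas a \linkS4class{BetaSet} or probes x samples matrix.
#' @param reference a \linkS4class{ReferenceSignature}.
#' @param mode \code{"sum1"} (fractions on the simplex, the seven blood types
#'   treated as exhaustive) or \code{"free"} (nonnegative abundances only).
#' @return A \linkS4class{CellFractions} object.
#' @export
setGeneric("deconvolveCells", function(betas, reference,
                                       mode = c("sum1", "free"))
  standardGeneric("deconvolveCells"))
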