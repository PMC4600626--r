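#' @include AllGenerics.R
#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom S4Vectors DataFrame
#' @importFrom stats median mad sd qlogis plogis rnorm runif rexp rgamma
#'   rbinom lm.fit pt pchisq qnorm complete.cases
NULL

## Seven blood leukocyte types the IEAA adjustment uses, in a fixed order.
.BLOOD_CELL_TYPES <- c("CD8T_naive", "CD8T_exhausted", "PlasmaB",
                       "CD4T", "NK", "Mono", "Gran")

## -------------------------------------------------------------------------
## BetaSet
## -------------------------------------------------------------------------

#' BetaSet: a methylation beta-value container
#'
#' Thin \linkS4class{SummarizedExperiment} subclass holding one assay
#' \code{"beta"}: a probes x samples matrix of methylation fractions in
#' [0,1] (the classic Illumina beta value). Missing entries are \code{NA}.
#'
#' @slot ... inherited from \linkS4class{SummarizedExperiment}.
#' @export
setClass("BetaSet", contains = "SummarizedExperiment")

setValidity("BetaSet", function(object) {
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    return("assay 'beta' is required")
  b <- SummarizedExperiment::assay(object, "beta")
  if (!is.numeric(b)) return("beta values must be numeric")
  v <- b[!is.na(b)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    return("non-missing beta values must lie in [0, 1]")
  if (anyDuplicated(rownames(b))) return("probe IDs must be unique")
  if (anyDuplicated(colnames(b))) return("sample IDs must be unique")
  TRUE
})

#' Construct a BetaSet
#'
#' @param beta numeric probes x samples matrix, probe IDs as rownames and
#'   sample IDs as colnames, values in [0,1] or NA.
#' @param sampleData optional data.frame of per-sample covariates
#'   (one row per column of \code{beta}).
#' @return A \linkS4class{BetaSet}.
#' @examples
#' b <- matrix(runif(6), 3, 2,
#'             dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' BetaSet(b)
#' @export
BetaSet <- function(beta, sampleData = NULL) {
  beta <- as.matrix(beta)
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("beta matrix needs probe rownames and sample colnames")
  args <- list(assays = list(beta = beta))
  if (!is.null(sampleData)) args$colData <- S4Vectors::DataFrame(sampleData)
  se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
  new("BetaSet", se)
}

#' @rdname probeIds
#' @export
setMethod("probeIds", "BetaSet", function(x) rownames(x))

#' @rdname betaValues
#' @export
setMethod("betaValues", "BetaSet",
          function(x) SummarizedExperiment::assay(x, "beta"))

## -------------------------------------------------------------------------
## ClockModel
## -------------------------------------------------------------------------

#' ClockModel: a CpG methylation clock
#'
#' A linear predictor over CpG beta values on the calibrated age scale.
#' DNAm age = \code{inverseTransformAge(intercept + sum(coef * beta))}.
#'
#' @slot probeIds CpG identifiers entering the predictor.
#' @slot coefficients per-probe weights (transformed-age units per beta unit).
#' @slot intercept intercept on the transformed-age scale.
#' @slot adultAge calibration knot of the age transform, in years
#'   (the published constant is 20).
#' @export
setClass("ClockModel",
         representation(probeIds = "character", coefficients = "numeric",
                        intercept = "numeric", adultAge = "numeric"))

setValidity("ClockModel", function(object) {
  if (length(object@probeIds) != length(object@coefficients))
    return("coefficient count must equal probe-ID count")
  if (anyDuplicated(object@probeIds)) return("duplicate probe IDs")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    return("intercept must be a single finite number")
  if (length(object@adultAge) != 1L || object@adultAge <= -1)
    return("adultAge must be > -1")
  if (any(!is.finite(object@coefficients)))
    return("coefficients must be finite")
  TRUE
})

#' Construct a ClockModel
#'
#' @param probeIds character vector of CpG IDs.
#' @param coefficients numeric weights, one per probe.
#' @param intercept intercept on the transformed-age scale.
#' @param adultAge calibration knot in years (default 20).
#' @return A \linkS4class{ClockModel}.
#' @examples
#' ClockModel(c("cg01", "cg02"), c(0.5, -0.2), intercept = 0.3)
#' @export
ClockModel <- function(probeIds, coefficients, intercept, adultAge = 20) {
  new("ClockModel", probeIds = as.character(probeIds),
      coefficients = as.numeric(coefficients),
      intercept = as.numeric(intercept), adultAge = as.numeric(adultAge))
}

#' @rdname probeIds
#' @export
setMethod("probeIds", "ClockModel", function(x) x@probeIds)

#' Clock coefficients, intercept and calibration knot
#'
#' @param model a \linkS4class{ClockModel}.
#' @return \code{clockCoefficients}: named numeric vector of per-probe
#'   weights; \code{clockIntercept}, \code{clockAdultAge}: single numbers.
#' @export
clockCoefficients <- function(model) {
  stats::setNames(model@coefficients, model@probeIds)
}

#' @rdname clockCoefficients
#' @export
clockIntercept <- function(model) model@intercept

#' @rdname clockCoefficients
#' @export
clockAdultAge <- function(model) model@adultAge

setMethod("show", "ClockModel", function(object) {
  cat("ClockModel with", length(object@probeIds), "CpG probes\n",
      " intercept:", format(object@intercept, digits = 4),
      "(transformed-age units), adultAge:", object@adultAge, "years\n")
})

## -------------------------------------------------------------------------
## ReferenceSignature
## -------------------------------------------------------------------------

#' ReferenceSignature: pure cell-type methylation profiles
#'
#' Probes x cell-types matrix of mean beta values of sorted (pure) cell
#' populations, used as the design matrix of reference-based deconvolution.
#' When produced by the cohort simulator, the designated discriminative
#' (marker) probes, clock probes and the generating logit-scale age slopes
#' are carried along so tests can check against the architecture.
#'
#' @slot values probes x cell-types matrix of betas in [0,1].
#' @slot discProbes IDs of the designated discriminative probe subset.
#' @slot clockProbes IDs of the probes carrying the age signal.
#' @slot clockSlopes logit-scale slope per clock probe (per year).
#' @export
setClass("ReferenceSignature",
         representation(values = "matrix", discProbes = "character",
                        clockProbes = "character", clockSlopes = "numeric"))

setValidity("ReferenceSignature", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("signature values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("signature needs probe rownames and cell-type colnames")
  if (anyDuplicated(colnames(v))) return("cell-type names must be unique")
  if (anyDuplicated(rownames(v))) return("probe IDs must be unique")
  if (min(v) < 0 || max(v) > 1) return("signature values must lie in [0, 1]")
  if (length(object@clockSlopes) != length(object@clockProbes))
    return("one slope per clock probe required")
  TRUE
})

#' Construct a ReferenceSignature
#'
#' @param values probes x cell-types beta matrix with dimnames.
#' @param discProbes,clockProbes,clockSlopes optional generator metadata.
#' @return A \linkS4class{ReferenceSignature}.
#' @export
ReferenceSignature <- function(values, discProbes = character(),
                               clockProbes = character(),
                               clockSlopes = numeric()) {
  new("ReferenceSignature", values = as.matrix(values),
      discProbes = as.character(discProbes),
      clockProbes = as.character(clockProbes),
      clockSlopes = as.numeric(clockSlopes))
}

#' @rdname probeIds
#' @export
setMethod("probeIds", "ReferenceSignature", function(x) rownames(x@values))

#' Accessors for ReferenceSignature
#'
#' @param x a \linkS4class{ReferenceSignature}.
#' @return \code{signatureValues}: the probes x cell-types matrix;
#'   \code{cellTypes}: cell-type names; \code{discriminativeProbes},
#'   \code{clockProbeIds}, \code{clockProbeSlopes}: generator metadata.
#' @export
signatureValues <- function(x) x@values

#' @rdname signatureValues
#' @export
cellTypes <- function(x) colnames(x@values)

#' @rdname signatureValues
#' @export
discriminativeProbes <- function(x) x@discProbes

#' @rdname signatureValues
#' @export
clockProbeIds <- function(x) x@clockProbes

#' @rdname signatureValues
#' @export
clockProbeSlopes <- function(x) stats::setNames(x@clockSlopes, x@clockProbes)

setMethod("show", "ReferenceSignature", function(object) {
  cat("ReferenceSignature:", nrow(object@values), "probes x",
      ncol(object@values), "cell types\n  cell types:",
      paste(colnames(object@values), collapse = ", "), "\n")
  if (length(object@discProbes))
    cat(" ", length(object@discProbes), "discriminative probes,",
        length(object@clockProbes), "clock probes\n")
})

## -------------------------------------------------------------------------
## CellFractions
## -------------------------------------------------------------------------

#' CellFractions: per-sample blood composition estimates
#'
#' @slot fractions samples x cell-types matrix of nonnegative weights
#'   (rows on the simplex in \code{"sum1"} mode).
#' @slot residualNorm per-sample Euclidean norm of the deconvolution
#'   residual (dimensionless, on the beta scale).
#' @slot mode constraint mode used, \code{"sum1"} or \code{"free"}.
#' @export
setClass("CellFractions",
         representation(fractions = "matrix", residualNorm = "numeric",
                        mode = "character"))

setValidity("CellFractions", function(object) {
  f <- object@fractions
  if (is.null(rownames(f)) || is.null(colnames(f)))
    return("fractions need sample rownames and cell-type colnames")
  if (min(f) < 0) return("fractions must be nonnegative")
  if (length(object@residualNorm) != nrow(f))
    return("one residual norm per sample required")
  if (identical(object@mode, "sum1") &&
      any(abs(rowSums(f) - 1) > 1e-8))
    return("sum1 mode requires row sums of 1 (within 1e-8)")
  TRUE
})

#' @rdname cellFractions
#' @export
CellFractions <- function(fractions, residualNorm, mode = "sum1") {
  new("CellFractions", fractions = as.matrix(fractions),
      residualNorm = as.numeric(residualNorm), mode = mode)
}

#' Accessors for CellFractions
#'
#' @param x a \linkS4class{CellFractions}.
#' @param fractions,residualNorm,mode constructor arguments.
#' @return \code{cellFractions}: samples x cell-types matrix;
#'   \code{residualNorms}: named numeric vector.
#' @export
cellFractions <- function(x) x@fractions

#' @rdname cellFractions
#' @export
residualNorms <- function(x) {
  stats::setNames(x@residualNorm, rownames(x@fractions))
}

setMethod("show", "CellFractions", function(object) {
  cat("CellFractions:", nrow(object@fractions), "samples x",
      ncol(object@fractions), "cell types (mode:", object@mode, ")\n",
      " mean fractions:", paste(colnames(object@fractions),
      round(colMeans(object@fractions), 3), sep = "=", collapse = ", "),
      "\n")
})

## -------------------------------------------------------------------------
## IEAAResult
## -------------------------------------------------------------------------

#' IEAAResult: intrinsic epigenetic age acceleration
#'
#' Residuals from regressing DNAm age on chronological age and blood
#' cell-type fractions, plus the cohort-standardized (z-scored) form.
#' Positive values mean methylation-older than expected.
#'
#' @slot sampleIds analyzed sample IDs (after listwise exclusions).
#' @slot dnamAge DNAm age in years.
#' @slot rawResidual IEAA in years.
#' @slot standardized cohort z-score of the residual (mean 0, SD 1).
#' @slot coefficients OLS coefficients (intercept, age, cell fractions).
#' @slot rSquared R-squared of the adjustment regression.
#' @slot droppedColumn cell-fraction column dropped to break the
#'   sum-to-one collinearity (empty if none).
#' @slot nExcluded samples excluded for missing DNAm age.
#' @export
setClass("IEAAResult",
         representation(sampleIds = "character", dnamAge = "numeric",
                        rawResidual = "numeric", standardized = "numeric",
                        coefficients = "numeric", rSquared = "numeric",
                        droppedColumn = "character", nExcluded = "integer"))

setValidity("IEAAResult", function(object) {
  n <- length(object@sampleIds)
  if (length(object@rawResidual) != n || length(object@standardized) != n ||
      length(object@dnamAge) != n)
    return("per-sample slots must have equal length")
  TRUE
})

#' Accessors for IEAAResult
#'
#' @param x an \linkS4class{IEAAResult}.
#' @return \code{ieaa}: named standardized IEAA; \code{rawResiduals}: named
#'   residuals in years; \code{ieaaCoefficients}: the adjustment-regression
#'   coefficients.
#' @export
ieaa <- function(x) stats::setNames(x@standardized, x@sampleIds)

#' @rdname ieaa
#' @export
rawResiduals <- function(x) stats::setNames(x@rawResidual, x@sampleIds)

#' @rdname ieaa
#' @export
ieaaCoefficients <- function(x) x@coefficients

setMethod("show", "IEAAResult", function(object) {
  cat("IEAAResult for", length(object@sampleIds), "samples",
      sprintf("(%d excluded)\n", object@nExcluded),
      sprintf(" raw residual SD: %.2f years; adjustment R^2: %.3f\n",
              stats::sd(object@rawResidual), object@rSquared))
  if (length(object@droppedColumn))
    cat("  dropped collinear cell-fraction column:",
        object@droppedColumn, "\n")
})

## -------------------------------------------------------------------------
## CoxModelFit
## -------------------------------------------------------------------------

#' CoxModelFit: a summarized Cox proportional-hazards fit
#'
#' @slot fit the underlying \code{survival::coxph} object (or NULL when the
#'   stratum was unestimable).
#' @slot coefTable data.frame with term, logHR, se, HR, z, p.
#' @slot baselineCumhaz data.frame (time, hazard): Breslow cumulative
#'   baseline hazard at covariate values 0, stepping at event times.
#' @slot n,nEvents,personYears cohort accounting.
#' @slot rSquared Cox-Snell-family index 1 - exp(2(ll0 - ll1)/n).
#' @slot converged FALSE flags monotone-likelihood / unestimable fits.
#' @slot label stratum label ("" for the full cohort).
#' @export
setClass("CoxModelFit",
         representation(fit = "ANY", coefTable = "data.frame",
                        baselineCumhaz = "data.frame", n = "integer",
                        nEvents = "integer", personYears = "numeric",
                        rSquared = "numeric", converged = "logical",
                        label = "character"))

setValidity("CoxModelFit", function(object) {
  if (object@nEvents > object@n) return("nEvents cannot exceed n")
  h <- object@baselineCumhaz
  if (nrow(h) && (is.unsorted(h$hazard) || any(h$hazard < 0)))
    return("baseline cumulative hazard must be nonnegative nondecreasing")
  TRUE
})

#' Accessors for CoxModelFit
#'
#' @param x a \linkS4class{CoxModelFit}.
#' @return \code{coxTable}: term/logHR/se/HR/z/p data.frame;
#'   \code{baselineCumhaz}: (time, hazard) data.frame;
#'   \code{hazardRatios}: named HR vector.
#' @export
coxTable <- function(x) x@coefTable

#' @rdname coxTable
#' @export
baselineCumhaz <- function(x) x@baselineCumhaz

#' @rdname coxTable
#' @export
hazardRatios <- function(x) {
  stats::setNames(x@coefTable$HR, x@coefTable$term)
}

setMethod("show", "CoxModelFit", function(object) {
  lab <- if (nzchar(object@label)) paste0(" [", object@label, "]") else ""
  cat(sprintf("CoxModelFit%s: n=%d, events=%d, person-years=%.0f, R^2=%.3f\n",
              lab, object@n, object@nEvents, object@personYears,
              object@rSquared))
  if (!object@converged) cat("  ** did not converge / unestimable **\n")
  if (nrow(object@coefTable)) {
    tab <- object@coefTable
    tab$HR <- round(tab$HR, 3)
    tab$p <- signif(tab$p, 2)
    print(tab[, c("term", "HR", "p")], row.names = FALSE)
  }
})
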