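## DNA methylation age: beta values, the calibrated age transform, clock
## application and elastic-net clock training.

#' Beta value from methylated/unmethylated intensities
#'
#' The Illumina beta value: \code{Max(M,0) / (Max(M,0) + Max(U,0) + 100)}.
#' The +100 offset regularizes low-intensity probes, which makes the value
#' deliberately scale-sensitive.
#'
#' @param M methylated-allele signal intensity (vectorized; negatives clamp
#'   to 0).
#' @param U unmethylated-allele signal intensity.
#' @return Beta values in [0, 1).
#' @examples
#' betaFromIntensities(900, 0)   # 0.9
#' betaFromIntensities(-50, 300) # 0
#' @export
betaFromIntensities <- function(M, U) {
  .stop_if(any(!is.finite(M)) || any(!is.finite(U)),
           "intensities must be finite")
  m <- pmax(M, 0)
  u <- pmax(U, 0)
  m / (m + u + 100)
}

#' Calibrated age transform and its inverse
#'
#' The clock is fit on a transformed age scale that is logarithmic below a
#' calibration knot (\code{adultAge}, default 20 years) and linear above
#' it: \code{log(age+1) - log(adultAge+1)} for \code{age <= adultAge},
#' else \code{(age - adultAge)/(adultAge+1)}. It is continuous, strictly
#' increasing and 0 at the knot; \code{inverseTransformAge} is the exact
#' functional inverse.
#'
#' @param age age in years, must be > -1.
#' @param t value on the transformed scale.
#' @param adultAge calibration knot in years (> -1).
#' @return \code{transformAge}: dimensionless transformed age;
#'   \code{inverseTransformAge}: age in years.
#' @examples
#' transformAge(41, 20)          # 1
#' inverseTransformAge(0, 20)    # 20
#' @export
transformAge <- function(age, adultAge = 20) {
  .stop_if(any(!is.finite(age)) || any(age <= -1),
           "age must be finite and > -1")
  .stop_if(adultAge <= -1, "adultAge must be > -1")
  ifelse(age <= adultAge,
         log(age + 1) - log(adultAge + 1),
         (age - adultAge) / (adultAge + 1))
}

#' @rdname transformAge
#' @export
inverseTransformAge <- function(t, adultAge = 20) {
  .stop_if(any(!is.finite(t)), "transformed value must be finite")
  ifelse(t <= 0, exp(t) * (adultAge + 1) - 1, t * (adultAge + 1) + adultAge)
}

.apply_clock_matrix <- function(betas, model, minProbeFraction = 0.8,
                                missingPolicy = c("mean", "error")) {
  missingPolicy <- match.arg(missingPolicy)
  probes <- probeIds(model)
  present <- probes %in% rownames(betas)
  .stop_if(!any(present),
           "no overlap between clock probes and beta-matrix probes")
  coef <- clockCoefficients(model)

  # model-probe submatrix in model order; absent probes become NA rows
  sub <- matrix(NA_real_, length(probes), ncol(betas),
                dimnames = list(probes, colnames(betas)))
  sub[probes[present], ] <- betas[probes[present], , drop = FALSE]

  obsFrac <- colMeans(!is.na(sub))
  failed <- obsFrac < minProbeFraction
  nMissing <- sum(is.na(sub))
  if (nMissing > 0) {
    if (missingPolicy == "error")
      stop(nMissing, " missing clock-probe beta values (missingPolicy = ",
           "\"error\")", call. = FALSE)
    probeMean <- rowMeans(sub, na.rm = TRUE)
    probeMean[!is.finite(probeMean)] <- 0.5
    idx <- which(is.na(sub), arr.ind = TRUE)
    sub[idx] <- probeMean[idx[, 1]]
  }

  lp <- clockIntercept(model) + as.numeric(crossprod(sub, coef))
  ages <- inverseTransformAge(lp, clockAdultAge(model))
  if (any(failed)) {
    warning(sum(failed), " sample(s) below the ", minProbeFraction,
            " observed clock-probe fraction; DNAm age set to NA",
            call. = FALSE)
    ages[failed] <- NA_real_
  }
  stats::setNames(ages, colnames(betas))
}

#' @rdname applyClock
#' @export
setMethod("applyClock", signature(betas = "matrix", model = "ClockModel"),
          .apply_clock_matrix)

#' @rdname applyClock
#' @export
setMethod("applyClock", signature(betas = "BetaSet", model = "ClockModel"),
          function(betas, model, minProbeFraction = 0.8,
                   missingPolicy = c("mean", "error")) {
            .apply_clock_matrix(betaValues(betas), model, minProbeFraction,
                                missingPolicy)
          })

#' Train a methylation clock by elastic-net regression
#'
#' Fits a penalized linear regression of transformed age on beta values
#' (mixing parameter \code{alpha}, default 0.5; penalty chosen by 10-fold
#' cross-validation unless \code{lambda} is given) and returns the probes
#' with nonzero coefficients as a \linkS4class{ClockModel}. Fold
#' assignment is seeded, so training is reproducible.
#'
#' @param betas a \linkS4class{BetaSet} or probes x samples matrix.
#' @param ages chronological ages in years, one per sample.
#' @param alpha elastic-net mixing parameter in [0,1] (1 = lasso).
#' @param lambda optional fixed penalty; skips cross-validation.
#' @param nfolds cross-validation folds.
#' @param adultAge calibration knot passed to \code{\link{transformAge}}.
#' @param seed integer seed for fold assignment.
#' @return A \linkS4class{ClockModel}.
#' @export
trainClock <- function(betas, ages, alpha = 0.5, lambda = NULL, nfolds = 10,
                       adultAge = 20, seed = 1) {
  b <- if (is(betas, "BetaSet")) betaValues(betas) else as.matrix(betas)
  .stop_if(ncol(b) != length(ages),
           "one age per sample (beta-matrix column) required")
  .stop_if(ncol(b) < 20, "need at least 20 samples to train a clock")
  y <- transformAge(ages, adultAge)
  .stop_if(stats::sd(y) < 1e-12, "degenerate fit: constant response")
  x <- t(b)
  if (is.null(lambda)) {
    set.seed(as.integer(seed))
    foldid <- sample(rep_len(seq_len(nfolds), nrow(x)))
    cv <- glmnet::cv.glmnet(x, y, alpha = alpha, foldid = foldid,
                            family = "gaussian")
    lambda <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    fit <- glmnet::glmnet(x, y, alpha = alpha, lambda = lambda,
                          family = "gaussian")
  }
  co <- as.matrix(stats::coef(fit, s = lambda))
  keep <- which(co[-1, 1] != 0)
  ClockModel(rownames(co)[-1][keep], co[-1, 1][keep],
             intercept = co[1, 1], adultAge = adultAge)
}

#' Construct betas that a given clock inverts exactly
#'
#' Builds a beta matrix whose clock linear predictor equals
#' \code{transformAge(age)} exactly for each requested age, so
#' \code{\link{applyClock}} recovers the ages to machine precision. Used
#' to validate clock application independently of the cohort generator
#' (whose age signal lives on the logit scale and is therefore not exactly
#' linear in beta). Betas are spread around \code{base} along the
#' coefficient direction; an error is raised if any required beta would
#' leave [0,1].
#'
#' @param model a \linkS4class{ClockModel}.
#' @param ages ages in years to encode.
#' @param base baseline beta level (default 0.5).
#' @return probes x samples beta matrix with the model's probes as rows.
#' @export
simulateClockBetas <- function(model, ages, base = 0.5) {
  coef <- clockCoefficients(model)
  t0 <- transformAge(ages, clockAdultAge(model))
  delta <- t0 - clockIntercept(model) - sum(coef * base)
  b <- outer(unname(coef) / sum(coef^2), delta) + base
  .stop_if(min(b) < 0 || max(b) > 1,
           "requested ages need betas outside [0,1]; rescale the model or ",
           "choose a different base")
  dimnames(b) <- list(probeIds(model),
                      sprintf("S%05d", seq_along(ages)))
  b
}
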