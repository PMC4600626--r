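## Intrinsic epigenetic age acceleration (IEAA): the residual from
## regressing DNAm age on chronological age and blood cell composition.

#' Compute intrinsic epigenetic age acceleration
#'
#' Ordinary least squares of DNAm age on an intercept, chronological age
#' and the cell-type fractions; IEAA is the per-sample residual (years), a
#' positive value meaning DNA methylation age higher than expected given
#' age and blood composition. When the fractions sum to one (the
#' \code{"sum1"} deconvolution mode) the granulocyte column - the majority
#' fraction - is dropped to break the exact collinearity with the
#' intercept. Standardization (z-score) uses the analyzed cohort after
#' listwise exclusion of samples with missing DNAm age.
#'
#' @param dnamAges named numeric vector of DNAm ages (years), names =
#'   sample IDs; NAs are excluded listwise with a message.
#' @param chronAges named numeric vector of chronological ages (years).
#' @param cells a \linkS4class{CellFractions} or samples x cell-types
#'   matrix with sample rownames.
#' @param sdType \code{"sample"} (n-1 denominator, default) or
#'   \code{"population"} for the standardization.
#' @return An \linkS4class{IEAAResult}.
#' @examples
#' \dontrun{
#' res <- computeIEAA(dnamAges, pheno$age, fractions)
#' summary(ieaa(res))
#' }
#' @export
computeIEAA <- function(dnamAges, chronAges, cells,
                        sdType = c("sample", "population")) {
  sdType <- match.arg(sdType)
  frac <- if (is(cells, "CellFractions")) cellFractions(cells)
          else as.matrix(cells)
  ids <- names(dnamAges)
  if (is.null(ids)) ids <- rownames(frac)
  .stop_if(is.null(ids), "sample IDs required (names on dnamAges or ",
           "rownames on the fraction matrix)")
  .stop_if(length(chronAges) != length(dnamAges),
           "dnamAges and chronAges must have equal length")
  frac <- frac[ids, , drop = FALSE]

  keep <- is.finite(dnamAges) & is.finite(chronAges) &
    stats::complete.cases(frac)
  nExcluded <- sum(!keep)
  if (nExcluded > 0)
    message(nExcluded, " sample(s) excluded from the IEAA regression ",
            "(missing DNAm age or covariates)")
  .stop_if(sum(keep) < 10, "need at least 10 analyzable samples")

  y <- dnamAges[keep]
  age <- chronAges[keep]
  F <- frac[keep, , drop = FALSE]

  dropped <- character()
  if (max(abs(rowSums(F) - 1)) < 1e-6) {
    dc <- if ("Gran" %in% colnames(F)) "Gran"
          else colnames(F)[which.max(colMeans(F))]
    dropped <- dc
    F <- F[, setdiff(colnames(F), dc), drop = FALSE]
  }
  X <- cbind(`(Intercept)` = 1, age = age, F)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear regressors in the IEAA adjustment: ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  s <- stats::sd(res)
  if (sdType == "population") s <- s * sqrt((length(res) - 1) / length(res))
  .stop_if(s < 1e-12,
           "zero-variance residuals: DNAm age is an exact function of the ",
           "regressors, standardization undefined")
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  new("IEAAResult", sampleIds = ids[keep], dnamAge = unname(y),
      rawResidual = unname(res), standardized = unname((res - mean(res)) / s),
      coefficients = fit$coefficients, rSquared = r2,
      droppedColumn = dropped, nExcluded = as.integer(nExcluded))
}

#' Age-only (extrinsic-style) acceleration residuals
#'
#' Residuals of DNAm age on chronological age alone - the simple variant
#' that is not adjusted for blood composition and can therefore still
#' track cell-type shifts. Provided for comparison with IEAA.
#'
#' @param dnamAges DNAm ages in years.
#' @param chronAges chronological ages in years.
#' @return Named numeric vector of residuals in years.
#' @export
eeaaResiduals <- function(dnamAges, chronAges) {
  keep <- is.finite(dnamAges) & is.finite(chronAges)
  .stop_if(sum(keep) < 3, "need at least 3 analyzable samples")
  .stop_if(stats::sd(chronAges[keep]) < 1e-12,
           "rank error: constant chronological age")
  fit <- stats::lm.fit(cbind(1, chronAges[keep]), dnamAges[keep])
  out <- rep(NA_real_, length(dnamAges))
  out[keep] <- fit$residuals
  names(out) <- names(dnamAges)
  out[keep]
}
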