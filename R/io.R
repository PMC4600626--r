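## Plain-text readers/writers for the pipeline's standard formats.

#' Read / write a beta matrix as TSV
#'
#' Tab-separated, probes as rows: first column \code{probe_id}, header row
#' of sample IDs, \code{NA} for missing values.
#'
#' @param path file path.
#' @param betas a \linkS4class{BetaSet} or probes x samples matrix.
#' @return \code{readBetaMatrix}: a \linkS4class{BetaSet}.
#' @export
readBetaMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  BetaSet(m)
}

#' @rdname readBetaMatrix
#' @export
writeBetaMatrix <- function(betas, path) {
  m <- if (is(betas, "BetaSet")) betaValues(betas) else as.matrix(betas)
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write clock coefficients as CSV
#'
#' Two columns (\code{CpG}, \code{coefficient}) with the intercept encoded
#' as a row with the reserved ID \code{"(Intercept)"} - the published
#' coefficient-table format. Read-write round-trips are identity on all
#' fields; a missing intercept row or duplicated probe IDs are format
#' errors.
#'
#' @param path CSV file path.
#' @param model a \linkS4class{ClockModel}.
#' @param adultAge calibration knot to attach on read (the format does not
#'   carry it; default 20).
#' @return \code{readClockModel}: a \linkS4class{ClockModel}.
#' @export
readClockModel <- function(path, adultAge = 20) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .stop_if(ncol(df) < 2, "format error: need CpG and coefficient columns")
  ids <- as.character(df[[1]])
  co <- as.numeric(df[[2]])
  isInt <- ids == "(Intercept)"
  .stop_if(sum(isInt) != 1, "format error: exactly one '(Intercept)' row ",
           "required")
  probes <- ids[!isInt]
  .stop_if(anyDuplicated(probes) > 0, "format error: duplicate probe IDs")
  ClockModel(probes, co[!isInt], intercept = co[isInt], adultAge = adultAge)
}

#' @rdname readClockModel
#' @export
writeClockModel <- function(model, path) {
  df <- data.frame(CpG = c("(Intercept)", probeIds(model)),
                   coefficient = c(clockIntercept(model),
                                   unname(clockCoefficients(model))),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a reference signature as TSV
#'
#' Probes x cell types; first column \code{probe_id}, header = cell-type
#' names.
#'
#' @param path file path.
#' @param reference a \linkS4class{ReferenceSignature}.
#' @return \code{readReference}: a \linkS4class{ReferenceSignature} (the
#'   generator metadata probe subsets are not part of the format).
#' @export
readReference <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  ReferenceSignature(m)
}

#' @rdname readReference
#' @export
writeReference <- function(reference, path) {
  m <- signatureValues(reference)
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write cell fractions / IEAA results as CSV
#'
#' @param x a \linkS4class{CellFractions} or \linkS4class{IEAAResult}.
#' @param path file path.
#' @return The path, invisibly.
#' @export
writeCellFractions <- function(x, path) {
  df <- data.frame(sample_id = rownames(cellFractions(x)),
                   cellFractions(x), residual_norm = residualNorms(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCellFractions
#' @export
writeIEAA <- function(x, path) {
  df <- data.frame(sample_id = x@sampleIds, dnam_age = x@dnamAge,
                   raw_residual = x@rawResidual,
                   ieaa_standardized = x@standardized,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
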