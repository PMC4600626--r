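## Reference-based cell-type deconvolution by constrained least squares.

## Equality-constrained least squares on a support: minimize ||b - R w||^2
## subject to sum(w) = 1 over the columns in `support`, via the KKT system;
## columns turning negative are dropped (active-set) and the system resolved.
.sum1_polish <- function(R, b, support) {
  K <- ncol(R)
  w <- numeric(K)
  S <- which(support)
  if (!length(S)) S <- seq_len(K)
  repeat {
    Rs <- R[, S, drop = FALSE]
    k <- length(S)
    A <- rbind(cbind(2 * crossprod(Rs), rep(1, k)), c(rep(1, k), 0))
    rhs <- c(2 * crossprod(Rs, b), 1)
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    ws <- sol[seq_len(k)]
    if (all(ws >= -1e-12) || k == 1L) {
      w[S] <- pmax(ws, 0)
      w <- w / sum(w)
      return(w)
    }
    S <- S[-which.min(ws)]
  }
}

## NNLS with the sum-to-one constraint imposed through an augmented penalty
## row of weight 1e4 (determines the support), then an exact
## equality-constrained refit on that support.
.nnls_sum1 <- function(R, b, penalty = 1e4) {
  ## fast path: if the equality-only solution is already nonnegative it is
  ## the constrained optimum (KKT)
  K <- ncol(R)
  A <- rbind(cbind(2 * crossprod(R), rep(1, K)), c(rep(1, K), 0))
  sol <- tryCatch(solve(A, c(2 * crossprod(R, b), 1)),
                  error = function(e) NULL)
  if (!is.null(sol) && all(sol[seq_len(K)] >= -1e-12)) {
    w <- pmax(sol[seq_len(K)], 0)
    return(w / sum(w))
  }
  Aa <- rbind(R, rep(penalty, K))
  y <- c(b, penalty)
  w0 <- tryCatch(pracma::lsqnonneg(Aa, y)$x, error = function(e) NULL)
  w <- if (is.null(w0)) .sum1_polish(R, b, rep(TRUE, K))
       else .sum1_polish(R, b, w0 > 1e-10)
  if (is.null(w)) w <- w0 / sum(w0)
  w
}

.deconvolve_matrix <- function(betas, reference, mode = c("sum1", "free")) {
  mode <- match.arg(mode)
  R <- signatureValues(reference)
  shared <- intersect(rownames(betas), rownames(R))
  .stop_if(length(shared) == 0,
           "no shared probes between beta matrix and reference")
  nExtra <- nrow(betas) - length(shared)
  if (nExtra > 0)
    message(nExtra, " probe(s) absent from the reference were ignored")
  Rs <- R[shared, , drop = FALSE]
  .stop_if(length(shared) < 2 * ncol(Rs),
           "too few shared probes for a stable deconvolution")
  qrR <- qr(Rs)
  if (qrR$rank < ncol(Rs)) {
    dep <- colnames(Rs)[qrR$pivot[(qrR$rank + 1):ncol(Rs)]]
    stop("degenerate reference: collinear cell types on shared probes: ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  B <- betas[shared, , drop = FALSE]
  n <- ncol(B)
  K <- ncol(Rs)
  W <- matrix(0, n, K, dimnames = list(colnames(B), colnames(Rs)))
  rn <- numeric(n)
  for (i in seq_len(n)) {
    ok <- !is.na(B[, i])
    .stop_if(sum(ok) < K,
             "sample ", colnames(B)[i], ": too few non-missing shared probes")
    b <- B[ok, i]
    Ri <- Rs[ok, , drop = FALSE]
    w <- if (mode == "sum1") .nnls_sum1(Ri, b)
         else pracma::lsqnonneg(Ri, b)$x
    W[i, ] <- w
    rn[i] <- sqrt(sum((b - Ri %*% w)^2))
  }
  CellFractions(W, rn, mode = mode)
}

#' @rdname deconvolveCells
#' @export
setMethod("deconvolveCells",
          signature(betas = "matrix", reference = "ReferenceSignature"),
          .deconvolve_matrix)

#' @rdname deconvolveCells
#' @export
setMethod("deconvolveCells",
          signature(betas = "BetaSet", reference = "ReferenceSignature"),
          function(betas, reference, mode = c("sum1", "free")) {
            .deconvolve_matrix(betaValues(betas), reference, mode)
          })

## Vectorized one-way ANOVA F statistic per probe (rows of x) across groups.
.probe_f_stat <- function(x, groups) {
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  n <- length(groups)
  gm <- rowMeans(x)
  ssb <- 0
  ssw <- 0
  for (lev in levels(groups)) {
    xi <- x[, groups == lev, drop = FALSE]
    mi <- rowMeans(xi)
    ssb <- ssb + ncol(xi) * (mi - gm)^2
    ssw <- ssw + rowSums((xi - mi)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Build a reference signature from sorted pure-cell profiles
#'
#' Averages the beta profiles of sorted (pure) samples within each cell
#' type. Optionally keeps only the \code{topK} probes most discriminative
#' between cell types by one-way ANOVA F statistic (requires replicate
#' samples per type).
#'
#' @param pureSamples a \linkS4class{BetaSet} or probes x samples matrix of
#'   sorted-cell methylation.
#' @param labels cell-type label per sample (column).
#' @param cellTypes cell types that must be present; defaults to
#'   \code{unique(labels)}. A listed type with no sample is an error.
#' @param topK optional number of most discriminative probes to keep.
#' @return A \linkS4class{ReferenceSignature} (with \code{discProbes} set
#'   to the selection when \code{topK} is used).
#' @export
buildReference <- function(pureSamples, labels, cellTypes = NULL,
                           topK = NULL) {
  x <- if (is(pureSamples, "BetaSet")) betaValues(pureSamples)
       else as.matrix(pureSamples)
  .stop_if(ncol(x) != length(labels), "one label per sample required")
  labels <- as.character(labels)
  if (is.null(cellTypes)) cellTypes <- unique(labels)
  missing <- setdiff(cellTypes, labels)
  .stop_if(length(missing) > 0, "no samples provided for cell type(s): ",
           paste(missing, collapse = ", "))
  means <- vapply(cellTypes,
                  function(ct) rowMeans(x[, labels == ct, drop = FALSE]),
                  numeric(nrow(x)))
  disc <- character()
  if (!is.null(topK)) {
    .stop_if(all(table(labels) < 2),
             "probe selection needs replicate samples per cell type")
    f <- .probe_f_stat(x, labels)
    disc <- rownames(x)[order(f, decreasing = TRUE)[seq_len(topK)]]
    means <- means[disc, , drop = FALSE]
  }
  ReferenceSignature(means, discProbes = disc)
}
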