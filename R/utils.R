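## Internal numerical helpers.

## logit with clamping away from {0,1}; the generator keeps mixtures well
## inside (0,1) so the clamp is a guard, not a modelling device.
.logit <- function(p, eps = 1e-12) stats::qlogis(pmin(pmax(p, eps), 1 - eps))

.expit <- function(x) stats::plogis(x)

## Dirichlet draws via normalized gammas; alpha is a matrix (n x K) or vector.
.rdirichlet <- function(n, alpha) {
  if (is.matrix(alpha)) {
    stopifnot(nrow(alpha) == n)
    g <- matrix(stats::rgamma(length(alpha), shape = alpha), nrow = n)
  } else {
    g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
                nrow = n)
  }
  g / rowSums(g)
}

.stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)
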