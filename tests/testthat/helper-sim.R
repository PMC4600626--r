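# Shared fixtures: small simulation configs and a mini end-to-end runner.

tiny_config <- function(...) {
  defaults <- list(nSubjects = 80, nProbes = 60, nClockProbes = 15,
                   nDiscProbes = 21, betaNoiseSd = 0.05, seed = 1)
  args <- utils::modifyList(defaults, list(...))
  do.call(simConfig, args)
}

# simulate -> train clock on a leading split -> apply -> deconvolve -> IEAA
run_mini_pipeline <- function(cfg, nTrain = 300, signatures = NULL) {
  coh <- simulateCohort(cfg, signatures = signatures)
  b <- betaValues(coh$betas)
  tr <- seq_len(nTrain)
  an <- setdiff(seq_len(ncol(b)), tr)
  model <- trainClock(b[, tr, drop = FALSE], coh$phenotypes$age[tr],
                      seed = cfg@seed)
  dnam <- applyClock(b[, an, drop = FALSE], model)
  cells <- deconvolveCells(b[, an, drop = FALSE], coh$signatures)
  ieaaRes <- computeIEAA(dnam, coh$phenotypes$age[an], cells)
  ph <- coh$phenotypes[an, , drop = FALSE]
  ph$ieaa <- unname(ieaa(ieaaRes))
  list(cohort = coh, model = model, dnam = dnam, cells = cells,
       ieaa = ieaaRes, pheno = ph, analysisIdx = an)
}

# hand-written Breslow partial log-likelihood for a single covariate
# (distinct event times), evaluated on a grid of coefficients
cox_loglik_grid <- function(time, event, x, grid) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  sapply(grid, function(b) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
    ll
  })
}

# tie-free Kruskal-Wallis H from precomputed ranks (label shuffles reuse it)
kw_H_from_ranks <- function(r, g) {
  N <- length(r)
  Ri <- tapply(r, g, sum)
  ni <- tabulate(as.integer(as.factor(g)))
  12 / (N * (N + 1)) * sum(Ri^2 / ni) - 3 * (N + 1)
}
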