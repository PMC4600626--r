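## Synthetic methylation cohort generator.
##
## Emulates a prospective cohort of postmenopausal women aged 50-79 with
## ~2% cumulative lung-cancer incidence over <=20 years: beta values are
## cell-type mixtures plus a logit-scale age trend on designated clock
## probes plus a per-subject latent age-acceleration variable; event times
## follow a proportional-hazards (exponential) model in which standardized
## acceleration has a configurable log hazard ratio.

#' SimulationConfig: parameters of the synthetic cohort generator
#'
#' @slot nSubjects,nProbes,nClockProbes,nDiscProbes,nCellTypes counts; the
#'   clock and discriminative (cell-type marker) probe subsets are disjoint
#'   and must fit inside \code{nProbes}.
#' @slot ageRange baseline age range in years, uniform draw.
#' @slot accelerationSd SD (years) of the latent, time-constant
#'   age-acceleration variable.
#' @slot betaNoiseSd SD of logit-scale (M-value-like) measurement noise.
#' @slot trueLogHrPerSd planted log hazard ratio per SD of acceleration.
#' @slot strataLogHrPerSd optional length-3 vector of planted log HRs by
#'   age decade ([50,60), [60,70), 70+); overrides \code{trueLogHrPerSd}.
#' @slot baselineRate baseline hazard, events per person-year.
#' @slot followupMax administrative censoring time in years.
#' @slot smokingPrevalence never/former/current probabilities.
#' @slot packYearsMean mean pack-years for former and current smokers
#'   (gamma draws, shape 2); never smokers have exactly 0.
#' @slot chdPrevalence Bernoulli probability of prevalent CHD.
#' @slot raceProbs white/black/hispanic probabilities.
#' @slot cellMeans mean cell-type fractions (length \code{nCellTypes}).
#' @slot cellConcentration Dirichlet concentration scale (higher = less
#'   between-subject variation in composition).
#' @slot cellAgeEffect 0 for age-independent composition; positive values
#'   shift granulocytes up and naive CD8 T cells down with age, to let
#'   tests plant cell-composition confounding.
#' @slot covariateLogHr named log hazard ratios (age per year centered at
#'   65, former, current, pack_years per pack-year, chd).
#' @slot clockSlopeRange range of |logit-scale slope| per year on clock
#'   probes; slopes get random signs.
#' @slot seed integer; every generator stage derives its stream from it.
#' @export
setClass("SimulationConfig",
  representation(nSubjects = "integer", nProbes = "integer",
                 nClockProbes = "integer", nDiscProbes = "integer",
                 nCellTypes = "integer", ageRange = "numeric",
                 accelerationSd = "numeric", betaNoiseSd = "numeric",
                 trueLogHrPerSd = "numeric", strataLogHrPerSd = "numeric",
                 baselineRate = "numeric", followupMax = "numeric",
                 smokingPrevalence = "numeric", packYearsMean = "numeric",
                 chdPrevalence = "numeric", raceProbs = "numeric",
                 cellMeans = "numeric", cellConcentration = "numeric",
                 cellAgeEffect = "numeric", covariateLogHr = "numeric",
                 clockSlopeRange = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@nCellTypes < 2L) return("nCellTypes must be >= 2")
  if (object@nClockProbes > object@nProbes)
    return("nClockProbes cannot exceed nProbes")
  if (object@nClockProbes + object@nDiscProbes > object@nProbes)
    return("clock + discriminative probes cannot exceed nProbes")
  if (object@ageRange[1] >= object@ageRange[2])
    return("ageRange must satisfy min < max")
  if (abs(sum(object@smokingPrevalence) - 1) > 1e-12)
    return("smoking prevalences must sum to 1 (within 1e-12)")
  if (abs(sum(object@raceProbs) - 1) > 1e-12)
    return("race probabilities must sum to 1 (within 1e-12)")
  rates <- c(object@accelerationSd, object@betaNoiseSd, object@baselineRate,
             object@followupMax, object@cellConcentration,
             object@chdPrevalence, object@packYearsMean)
  if (any(!is.finite(rates)) || any(rates < 0))
    return("rates and SDs must be finite and >= 0")
  if (length(object@cellMeans) != object@nCellTypes)
    return("cellMeans must have one entry per cell type")
  if (any(object@cellMeans <= 0))
    return("cellMeans must be positive")
  if (!length(object@strataLogHrPerSd) %in% c(0L, 3L))
    return("strataLogHrPerSd must be empty or length 3 (age decades)")
  need <- c("age", "former", "current", "pack_years", "chd")
  if (!all(need %in% names(object@covariateLogHr)))
    return(paste("covariateLogHr needs entries:",
                 paste(need, collapse = ", ")))
  TRUE
})

#' Build a simulation configuration
#'
#' Defaults reproduce the study conditions of a WHI-like cohort: ages
#' uniform on 50-79, smoking prevalences 54.4/35.2/10.4%, pack-year means
#' 19.4 (former) and 25.9 (current), CHD prevalence 31%, race mix
#' 48/32/20%, 20-year administrative censoring, a baseline hazard
#' calibrated to ~2% cumulative incidence, and a planted hazard ratio of
#' 1.5 per SD of age acceleration.
#'
#' @param nSubjects,nProbes,nClockProbes,nDiscProbes,nCellTypes counts.
#' @param ageRange,accelerationSd,betaNoiseSd,trueLogHrPerSd,strataLogHrPerSd
#'   see \linkS4class{SimulationConfig}.
#' @param baselineRate,followupMax,smokingPrevalence,packYearsMean see
#'   \linkS4class{SimulationConfig}.
#' @param chdPrevalence,raceProbs,cellMeans,cellConcentration,cellAgeEffect
#'   see \linkS4class{SimulationConfig}.
#' @param covariateLogHr,clockSlopeRange,seed see
#'   \linkS4class{SimulationConfig}.
#' @return A validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simConfig(nSubjects = 100, nProbes = 60, nClockProbes = 20,
#'                  nDiscProbes = 21, seed = 7)
#' @export
simConfig <- function(nSubjects = 2000, nProbes = 500, nClockProbes = 100,
                      nDiscProbes = 70, nCellTypes = 7,
                      ageRange = c(50, 79), accelerationSd = 5,
                      betaNoiseSd = 0.1, trueLogHrPerSd = log(1.5),
                      strataLogHrPerSd = numeric(),
                      baselineRate = 2.3e-4, followupMax = 20,
                      smokingPrevalence = c(never = 0.544, former = 0.352,
                                            current = 0.104),
                      packYearsMean = c(former = 19.4, current = 25.9),
                      chdPrevalence = 0.31,
                      raceProbs = c(white = 0.48, black = 0.32,
                                    hispanic = 0.20),
                      cellMeans = NULL, cellConcentration = 40,
                      cellAgeEffect = 0,
                      covariateLogHr = c(age = log(1.09), former = log(2.2),
                                         current = log(6.2),
                                         pack_years = log(1.03),
                                         chd = log(0.8)),
                      clockSlopeRange = c(0.012, 0.03), seed = 1) {
  if (is.null(cellMeans)) {
    cellMeans <- if (nCellTypes == 7L ||
                     as.integer(nCellTypes) == 7L) {
      c(CD8T_naive = 0.05, CD8T_exhausted = 0.03, PlasmaB = 0.05,
        CD4T = 0.15, NK = 0.07, Mono = 0.08, Gran = 0.57)
    } else {
      k <- as.integer(nCellTypes)
      stats::setNames(rep(1 / k, k), paste0("cell", seq_len(k)))
    }
  }
  new("SimulationConfig", nSubjects = as.integer(nSubjects),
      nProbes = as.integer(nProbes), nClockProbes = as.integer(nClockProbes),
      nDiscProbes = as.integer(nDiscProbes),
      nCellTypes = as.integer(nCellTypes), ageRange = as.numeric(ageRange),
      accelerationSd = accelerationSd, betaNoiseSd = betaNoiseSd,
      trueLogHrPerSd = trueLogHrPerSd,
      strataLogHrPerSd = as.numeric(strataLogHrPerSd),
      baselineRate = baselineRate, followupMax = followupMax,
      smokingPrevalence = smokingPrevalence, packYearsMean = packYearsMean,
      chdPrevalence = chdPrevalence, raceProbs = raceProbs,
      cellMeans = cellMeans, cellConcentration = cellConcentration,
      cellAgeEffect = cellAgeEffect, covariateLogHr = covariateLogHr,
      clockSlopeRange = as.numeric(clockSlopeRange), seed = as.integer(seed))
}

.cell_type_names <- function(config) {
  if (!is.null(names(config@cellMeans))) return(names(config@cellMeans))
  if (config@nCellTypes == 7L) return(.BLOOD_CELL_TYPES)
  paste0("cell", seq_len(config@nCellTypes))
}

#' Simulate pure cell-type reference signatures
#'
#' Generates one mean-methylation profile per cell type over all probes.
#' The designated discriminative subset consists of marker probes: each is
#' owned by one cell type (beta in [0.82, 0.90]) and low (in [0.10, 0.18])
#' in all others, so every pair of cell types is separated by at least 0.3
#' on each of their marker probes. Clock probes share a common baseline
#' across cell types (small jitter) with their age slope offset baked in so
#' betas stay mid-range over the cohort age span; background probes get a
#' random base level with small cell-type jitter.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{ReferenceSignature} carrying the discriminative
#'   and clock probe sets and the generating logit-scale slopes.
#' @export
simulateReferenceSignatures <- function(config) {
  validObject(config)
  .stop_if(config@nCellTypes < 2L, "invalid config: nCellTypes must be >= 2")
  set.seed(config@seed + 1L)
  P <- config@nProbes; K <- config@nCellTypes
  probes <- sprintf("cg%06d", seq_len(P))
  types <- .cell_type_names(config)
  vals <- matrix(NA_real_, P, K, dimnames = list(probes, types))

  idx_disc <- seq_len(config@nDiscProbes)
  idx_clock <- config@nDiscProbes + seq_len(config@nClockProbes)
  idx_bg <- setdiff(seq_len(P), c(idx_disc, idx_clock))

  if (length(idx_disc)) {
    owner <- rep_len(seq_len(K), length(idx_disc))
    low <- matrix(runif(length(idx_disc) * K, 0.10, 0.18),
                  length(idx_disc), K)
    low[cbind(seq_along(idx_disc), owner)] <-
      runif(length(idx_disc), 0.82, 0.90)
    vals[idx_disc, ] <- low
  }

  ageMid <- mean(config@ageRange)
  slopes <- numeric(0)
  if (length(idx_clock)) {
    slopes <- runif(length(idx_clock), config@clockSlopeRange[1],
                    config@clockSlopeRange[2]) *
      sample(c(-1, 1), length(idx_clock), replace = TRUE)
    base <- rnorm(length(idx_clock), 0, 0.4) - slopes * ageMid
    jit <- matrix(rnorm(length(idx_clock) * K, 0, 0.05),
                  length(idx_clock), K)
    vals[idx_clock, ] <- pmin(pmax(.expit(base + jit), 0.02), 0.98)
  }

  if (length(idx_bg)) {
    base <- runif(length(idx_bg), 0.15, 0.85)
    jit <- matrix(rnorm(length(idx_bg) * K, 0, 0.03), length(idx_bg), K)
    vals[idx_bg, ] <- pmin(pmax(base + jit, 0.02), 0.98)
  }

  ReferenceSignature(vals, discProbes = probes[idx_disc],
                     clockProbes = probes[idx_clock], clockSlopes = slopes)
}

#' Simulate subject-level covariates and ground truth
#'
#' Ages uniform on the configured range; latent acceleration
#' Normal(0, accelerationSd^2); smoking multinomial with pack-years 0 for
#' never smokers and gamma draws otherwise; CHD Bernoulli; cell fractions
#' Dirichlet (optionally age-dependent via \code{cellAgeEffect}).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{phenotypes} (sample_id, age, race, smoking,
#'   pack_years, chd; event/time NA until \code{\link{simulateEvents}}) and
#'   \code{truth} (true_age, true_acceleration, frac_* columns).
#' @export
simulateSubjects <- function(config) {
  validObject(config)
  set.seed(config@seed + 2L)
  n <- config@nSubjects
  ids <- sprintf("S%05d", seq_len(n))
  age <- runif(n, config@ageRange[1], config@ageRange[2])
  acc <- if (config@accelerationSd > 0)
    rnorm(n, 0, config@accelerationSd) else rep(0, n)
  smoking <- factor(sample(c("never", "former", "current"), n, TRUE,
                           prob = config@smokingPrevalence),
                    levels = c("never", "former", "current"))
  py <- numeric(n)
  isF <- smoking == "former"; isC <- smoking == "current"
  py[isF] <- rgamma(sum(isF), shape = 2,
                    scale = config@packYearsMean[["former"]] / 2)
  py[isC] <- rgamma(sum(isC), shape = 2,
                    scale = config@packYearsMean[["current"]] / 2)
  race <- factor(sample(c("white", "black", "hispanic"), n, TRUE,
                        prob = config@raceProbs),
                 levels = c("white", "black", "hispanic"))
  chd <- rbinom(n, 1, config@chdPrevalence)

  types <- .cell_type_names(config)
  means <- config@cellMeans
  if (config@cellAgeEffect != 0) {
    shift <- config@cellAgeEffect * (age - mean(config@ageRange)) /
      (diff(config@ageRange) / 2)
    up <- if ("Gran" %in% types) "Gran" else types[length(types)]
    dn <- if ("CD8T_naive" %in% types) "CD8T_naive" else types[1]
    m <- matrix(rep(means, each = n), n, length(types),
                dimnames = list(NULL, types))
    m[, up] <- pmax(means[[up]] * (1 + shift), 0.01)
    m[, dn] <- pmax(means[[dn]] * (1 - shift), 0.01)
    m <- m / rowSums(m)
    alpha <- config@cellConcentration * m
  } else {
    alpha <- config@cellConcentration * means
  }
  frac <- .rdirichlet(n, alpha)
  colnames(frac) <- paste0("frac_", types)

  phenotypes <- data.frame(sample_id = ids, age = age, race = race,
                           smoking = smoking, pack_years = py, chd = chd,
                           event = NA_integer_, time = NA_real_,
                           stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = ids, true_age = age,
                      true_acceleration = acc, stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(frac))
  list(phenotypes = phenotypes, truth = truth)
}

#' Simulate the beta-value matrix
#'
#' Each sample's beta vector is the cell-fraction-weighted mixture of the
#' reference signatures; clock probes are additionally shifted on the logit
#' scale by slope x (true_age + true_acceleration); logit-scale Gaussian
#' noise is added and the logistic map takes everything back to (0,1).
#'
#' @param subjects output of \code{\link{simulateSubjects}} (the
#'   \code{phenotypes} data.frame).
#' @param truth ground-truth data.frame with frac_* columns.
#' @param signatures a \linkS4class{ReferenceSignature} from
#'   \code{\link{simulateReferenceSignatures}}.
#' @param config the \linkS4class{SimulationConfig}.
#' @return A \linkS4class{BetaSet} (probes x samples), values strictly in
#'   (0,1).
#' @export
simulateBetas <- function(subjects, truth, signatures, config) {
  validObject(config)
  set.seed(config@seed + 3L)
  R <- signatureValues(signatures)
  .stop_if(nrow(R) != config@nProbes,
           "shape error: signature probes do not match configured probe set")
  types <- .cell_type_names(config)
  fcols <- paste0("frac_", types)
  .stop_if(!all(fcols %in% names(truth)),
           "shape error: truth lacks fraction columns for the signature's ",
           "cell types")
  W <- as.matrix(truth[, fcols])
  .stop_if(ncol(W) != ncol(R),
           "shape error: cell-type dimension mismatch")
  n <- nrow(W)
  L <- .logit(R %*% t(W))                      # probes x samples
  cp <- clockProbeIds(signatures)
  if (length(cp)) {
    sl <- clockProbeSlopes(signatures)
    L[cp, ] <- L[cp, ] + outer(unname(sl),
                               truth$true_age + truth$true_acceleration)
  }
  if (config@betaNoiseSd > 0)
    L <- L + matrix(rnorm(length(L), 0, config@betaNoiseSd), nrow(L))
  beta <- .expit(L)
  rownames(beta) <- rownames(R)
  colnames(beta) <- truth$sample_id
  BetaSet(beta)
}

#' Simulate event times under proportional hazards
#'
#' Event time is Exponential with rate \code{baselineRate *
#' exp(logHR * z + covariate effects)} where \code{z} is the standardized
#' true acceleration; observed time is censored administratively at
#' \code{followupMax} years.
#'
#' @param subjects the \code{phenotypes} data.frame.
#' @param truth the ground-truth data.frame (acceleration, ages).
#' @param config the \linkS4class{SimulationConfig}.
#' @return list with \code{phenotypes} (event, time filled) and
#'   \code{truth} (true_event_time, censored filled).
#' @export
simulateEvents <- function(subjects, truth, config) {
  validObject(config)
  .stop_if(!is.finite(config@baselineRate) || config@baselineRate < 0,
           "invalid config: baselineRate must be finite and >= 0")
  .stop_if(!all(is.finite(config@trueLogHrPerSd)),
           "invalid config: trueLogHrPerSd must be finite")
  set.seed(config@seed + 4L)
  n <- nrow(subjects)
  z <- if (config@accelerationSd > 0)
    truth$true_acceleration / config@accelerationSd else rep(0, n)
  lhr <- if (length(config@strataLogHrPerSd) == 3L) {
    config@strataLogHrPerSd[findInterval(subjects$age, c(60, 70)) + 1L]
  } else rep(config@trueLogHrPerSd, n)
  cv <- config@covariateLogHr
  lp <- lhr * z +
    cv[["age"]] * (subjects$age - mean(config@ageRange)) +
    cv[["former"]] * (subjects$smoking == "former") +
    cv[["current"]] * (subjects$smoking == "current") +
    cv[["pack_years"]] * subjects$pack_years +
    cv[["chd"]] * subjects$chd
  rate <- config@baselineRate * exp(lp)
  e <- rexp(n)
  tEvent <- ifelse(rate > 0, e / rate, Inf)
  subjects$time <- pmin(tEvent, config@followupMax)
  subjects$event <- as.integer(tEvent <= config@followupMax)
  truth$true_event_time <- tEvent
  truth$censored <- subjects$event == 0L
  list(phenotypes = subjects, truth = truth)
}

#' Simulate a complete cohort
#'
#' Runs signatures, subjects, events and betas in order with seeds derived
#' from \code{config@seed}; identical config gives bit-identical output.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param signatures optional pre-built \linkS4class{ReferenceSignature};
#'   lets replicate studies fix the methylome architecture while varying
#'   the cohort.
#' @return list: \code{config}, \code{signatures}, \code{phenotypes},
#'   \code{truth}, \code{betas}.
#' @examples
#' coh <- simulateCohort(simConfig(nSubjects = 50, nProbes = 60,
#'                                 nClockProbes = 20, nDiscProbes = 21,
#'                                 seed = 3))
#' dim(betaValues(coh$betas))
#' @export
simulateCohort <- function(config, signatures = NULL) {
  validObject(config)
  if (is.null(signatures)) signatures <- simulateReferenceSignatures(config)
  subj <- simulateSubjects(config)
  ev <- simulateEvents(subj$phenotypes, subj$truth, config)
  betas <- simulateBetas(ev$phenotypes, ev$truth, signatures, config)
  list(config = config, signatures = signatures,
       phenotypes = ev$phenotypes, truth = ev$truth, betas = betas)
}
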