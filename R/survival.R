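## Inferential stage: person-time accounting, Kruskal-Wallis screens,
## biweight midcorrelation, Cox proportional-hazards models (full and
## stratified), Breslow baseline hazards with covariate-profile incidence
## curves, landmark exclusions and a logistic sensitivity analysis.

#' Convert person-days to person-years
#'
#' \code{days / 365.25}, rounded to four decimal places (the convention
#' used for follow-up accounting).
#'
#' @param days nonnegative number of person-days (vectorized).
#' @return Person-years at 4-decimal precision.
#' @examples
#' personYearsFromDays(365)   # 0.9993
#' personYearsFromDays(7305)  # 20
#' @export
personYearsFromDays <- function(days) {
  .stop_if(any(!is.finite(days)) || any(days < 0),
           "days must be finite and >= 0")
  round(days / 365.25, 4)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' k-1 degrees of freedom (wraps \code{stats::kruskal.test}).
#'
#' @param values numeric per-sample statistic (e.g. standardized IEAA).
#' @param groups grouping factor (e.g. case/control).
#' @return list with \code{statistic} (H), \code{p_value}, \code{df} and
#'   \code{group_sizes}.
#' @export
kruskalWallis <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  .stop_if(nlevels(groups) < 2, "need at least 2 non-empty groups")
  .stop_if(length(values) < 3, "need at least 3 observations")
  .stop_if(stats::sd(values) < 1e-15,
           "degenerate data: all values identical")
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter),
       group_sizes = as.integer(table(groups)))
}

#' Biweight midcorrelation
#'
#' Robust correlation using median/MAD-based Tukey biweights
#' \eqn{(1-u^2)^2} for \eqn{|u|<1}, \eqn{u = (x - med)/(9 \cdot MAD)},
#' which downweight outliers. The p-value uses the t approximation with
#' n-2 degrees of freedom. When a vector has zero MAD the weights are
#' undefined; with \code{fallbackPearson = TRUE} the Pearson correlation
#' is returned with a warning, otherwise an error is raised.
#'
#' @param x,y numeric vectors of equal length, n >= 5.
#' @param fallbackPearson fall back to Pearson when a MAD is zero.
#' @return list with \code{estimate} (in [-1,1]), \code{p_value}, \code{n}
#'   and \code{method}.
#' @export
bicor <- function(x, y, fallbackPearson = TRUE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  .stop_if(n < 5, "need at least 5 complete observations")
  madx <- stats::mad(x, constant = 1)
  mady <- stats::mad(y, constant = 1)
  if (madx == 0 || mady == 0) {
    .stop_if(!fallbackPearson,
             "zero median absolute deviation: biweights undefined")
    warning("zero MAD; falling back to Pearson correlation", call. = FALSE)
    r <- stats::cor(x, y)
    method <- "pearson (MAD fallback)"
  } else {
    wx <- .biweight_deviation(x, madx)
    wy <- .biweight_deviation(y, mady)
    r <- sum(wx * wy) / sqrt(sum(wx^2) * sum(wy^2))
    method <- "bicor"
  }
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), n - 2)
  }
  list(estimate = r, p_value = p, n = n, method = method)
}

.biweight_deviation <- function(x, madx) {
  u <- (x - stats::median(x)) / (9 * madx)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  (x - stats::median(x)) * w
}

## Relevel phenotype factors to the analysis reference categories.
.prep_pheno <- function(ph) {
  if (is.factor(ph$smoking) || is.character(ph$smoking)) {
    lev <- intersect(c("never", "former", "current"), unique(ph$smoking))
    ph$smoking <- factor(ph$smoking, levels = lev)
  }
  if (is.factor(ph$race) || is.character(ph$race)) {
    lev <- intersect(c("white", "black", "hispanic"), unique(ph$race))
    ph$race <- factor(ph$race, levels = lev)
  }
  ph
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood with Breslow tie handling (Efron
#' available behind the \code{ties} flag) for the event indicator and
#' follow-up time in \code{phenotypes}, and extracts the Breslow
#' cumulative baseline hazard at covariate values zero. The reported
#' \code{rSquared} is the Cox-Snell-family index
#' \code{1 - exp(2 (ll0 - ll1) / n)}.
#'
#' @param phenotypes data.frame with columns \code{time} (> 0 person-years),
#'   \code{event} (0/1) and the covariates.
#' @param covariates character vector of covariate column names; factors
#'   (race, smoking) expand to dummies against the reference categories
#'   never smoker / white.
#' @param ties \code{"breslow"} (default) or \code{"efron"}.
#' @param label optional stratum label carried into the result.
#' @return A \linkS4class{CoxModelFit}.
#' @export
coxFit <- function(phenotypes, covariates, ties = c("breslow", "efron"),
                   label = "") {
  ties <- match.arg(ties)
  ph <- .prep_pheno(phenotypes)
  .stop_if(!all(c("time", "event") %in% names(ph)),
           "phenotypes need 'time' and 'event' columns")
  .stop_if(any(ph$time <= 0), "follow-up time must be positive")
  .stop_if(!all(ph$event %in% c(0, 1)), "event must be 0/1")
  .stop_if(sum(ph$event) < 1, "no events: model unestimable")
  missing <- setdiff(covariates, names(ph))
  .stop_if(length(missing) > 0, "unknown covariates: ",
           paste(missing, collapse = ", "))

  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  mm <- stats::model.matrix(stats::as.formula(
    paste("~", paste(covariates, collapse = " + "))), data = ph)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    dep <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("rank-deficient design (constant or collinear covariates): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }

  fit <- withCallingHandlers(
    survival::coxph(fml, data = ph, ties = ties, x = TRUE,
                    control = survival::coxph.control(eps = 1e-10,
                                                      iter.max = 50)),
    warning = function(w) invokeRestart("muffleWarning"))
  s <- summary(fit)
  monotone <- any(abs(stats::coef(fit)) > 12 |
                    !is.finite(sqrt(diag(fit$var))))
  if (monotone) {
    bad <- names(stats::coef(fit))[abs(stats::coef(fit)) > 12 |
                                     !is.finite(sqrt(diag(fit$var)))]
    warning("possible monotone likelihood (covariate separating events): ",
            paste(bad, collapse = ", "), call. = FALSE)
  }
  ct <- data.frame(term = rownames(s$coefficients),
                   logHR = s$coefficients[, "coef"],
                   se = s$coefficients[, "se(coef)"],
                   HR = s$coefficients[, "exp(coef)"],
                   z = s$coefficients[, "z"],
                   p = s$coefficients[, "Pr(>|z|)"],
                   row.names = NULL, stringsAsFactors = FALSE)
  bh <- survival::basehaz(fit, centered = FALSE)
  ll <- fit$loglik
  n <- nrow(ph)
  new("CoxModelFit", fit = fit, coefTable = ct,
      baselineCumhaz = data.frame(time = bh$time, hazard = bh$hazard),
      n = as.integer(n), nEvents = as.integer(sum(ph$event)),
      personYears = sum(ph$time),
      rSquared = 1 - exp(2 * (ll[1] - ll[2]) / n),
      converged = !monotone, label = label)
}

#' Age- and smoking-stratified Cox models
#'
#' Refits the Cox model within strata. Age strata are the left-closed
#' decades [50,60), [60,70), 70+ with covariates IEAA, age, race, CHD,
#' smoking and pack-years; smoking strata (never/former/current) use IEAA,
#' age, race, CHD and pack-years, with pack-years omitted for never
#' smokers (identically zero there). Strata without events are reported as
#' unestimable rather than dropped.
#'
#' @param phenotypes phenotype data.frame (see \code{\link{coxFit}}).
#' @param ieaaValues an \linkS4class{IEAAResult} or named numeric vector of
#'   standardized IEAA; the full-cohort standardization is reused across
#'   strata so hazard ratios stay on one scale.
#' @param strata \code{"age"} or \code{"smoking"}.
#' @return Named list of \linkS4class{CoxModelFit} (unestimable strata are
#'   \code{CoxModelFit} shells with \code{converged = FALSE}).
#' @export
stratifiedAnalysis <- function(phenotypes, ieaaValues,
                               strata = c("age", "smoking")) {
  strata <- match.arg(strata)
  ph <- .prep_pheno(phenotypes)
  z <- if (is(ieaaValues, "IEAAResult")) ieaa(ieaaValues) else ieaaValues
  .stop_if(is.null(names(z)), "ieaaValues must be named by sample ID")
  ph <- ph[ph$sample_id %in% names(z), , drop = FALSE]
  ph$ieaa <- unname(z[ph$sample_id])

  if (strata == "age") {
    grp <- cut(ph$age, c(-Inf, 60, 70, Inf), right = FALSE,
               labels = c("50-59", "60-69", "70+"))
    covs <- c("ieaa", "age", "race", "chd", "smoking", "pack_years")
    covList <- stats::setNames(rep(list(covs), 3), levels(grp))
  } else {
    grp <- ph$smoking
    covList <- list(never = c("ieaa", "age", "race", "chd"),
                    former = c("ieaa", "age", "race", "chd", "pack_years"),
                    current = c("ieaa", "age", "race", "chd", "pack_years"))
    covList <- covList[levels(grp)]
  }

  out <- list()
  for (lev in levels(grp)) {
    sub <- ph[grp == lev, , drop = FALSE]
    covs <- covList[[lev]]
    covs <- covs[vapply(covs, function(cl) {
      v <- sub[[cl]]
      if (is.factor(v)) nlevels(droplevels(v)) > 1
      else length(unique(v)) > 1
    }, logical(1))]
    out[[lev]] <- if (nrow(sub) == 0 || sum(sub$event) < 1) {
      new("CoxModelFit", fit = NULL, coefTable = data.frame(),
          baselineCumhaz = data.frame(time = numeric(), hazard = numeric()),
          n = as.integer(nrow(sub)), nEvents = as.integer(sum(sub$event)),
          personYears = sum(sub$time), rSquared = NA_real_,
          converged = FALSE, label = paste0(lev, " (unestimable)"))
    } else {
      sub$race <- droplevels(sub$race)
      if (is.factor(sub$smoking)) sub$smoking <- droplevels(sub$smoking)
      coxFit(sub, covs, label = lev)
    }
  }
  out
}

## Step-function evaluation of the Breslow cumulative hazard: value at the
## largest event time <= t, 0 before the first event, flat beyond the last.
.eval_cumhaz <- function(bh, times) {
  if (!nrow(bh)) return(rep(0, length(times)))
  idx <- findInterval(times, bh$time)
  c(0, bh$hazard)[idx + 1L]
}

#' Predicted cumulative incidence for a covariate profile
#'
#' Evaluates \eqn{1 - exp(-H_0(t) e^{x'\beta})} on a time grid, with
#' \eqn{H_0} the Breslow cumulative baseline hazard of the fit (at
#' covariate values 0). Used to draw incidence curves for reference
#' profiles, e.g. a 75-year-old white current smoker with 30 pack-years at
#' standardized IEAA -1 / 0 / +1.
#'
#' @param fit a converged \linkS4class{CoxModelFit}.
#' @param profile named numeric vector of covariate values on the
#'   model-matrix scale; every term of the fit must be covered (dummy
#'   terms like \code{smokingcurrent} set to 0/1).
#' @param times nonnegative time grid in years; times beyond the last
#'   observed event time extend the curve flat with a warning.
#' @return data.frame with \code{time} and \code{incidence}, nondecreasing,
#'   0 at time 0.
#' @export
predictIncidence <- function(fit, profile, times) {
  .stop_if(!fit@converged, "fit did not converge")
  .stop_if(any(times < 0), "times must be >= 0")
  terms <- fit@coefTable$term
  missing <- setdiff(terms, names(profile))
  .stop_if(length(missing) > 0, "profile must cover all fit covariates; ",
           "missing: ", paste(missing, collapse = ", "))
  lp <- sum(fit@coefTable$logHR * profile[terms])
  bh <- fit@baselineCumhaz
  if (nrow(bh) && any(times > max(bh$time)))
    warning("times beyond the last observed event time; curve extended flat",
            call. = FALSE)
  H <- .eval_cumhaz(bh, times)
  data.frame(time = times, incidence = 1 - exp(-H * exp(lp)))
}

#' Landmark exclusion of early events
#'
#' Sensitivity filter against reverse causation: removes subjects whose
#' event occurred within \code{excludeWithin} years of baseline; censored
#' subjects are retained regardless of their follow-up time.
#'
#' @param phenotypes phenotype data.frame with \code{event} and \code{time}.
#' @param excludeWithin years (>= 0).
#' @return Filtered data.frame; the number removed is in
#'   \code{attr(, "nExcluded")}.
#' @export
landmarkExclusion <- function(phenotypes, excludeWithin) {
  .stop_if(excludeWithin < 0, "excludeWithin must be >= 0")
  drop <- phenotypes$event == 1 & phenotypes$time < excludeWithin
  out <- phenotypes[!drop, , drop = FALSE]
  attr(out, "nExcluded") <- sum(drop)
  out
}

#' Logistic-regression sensitivity analysis
#'
#' Maximum-likelihood logistic regression of the event indicator on the
#' Cox covariate set, ignoring follow-up time. Under a rare outcome the
#' odds ratios approximate the hazard ratios, which makes this a check on
#' survival-sampling artifacts.
#'
#' @param phenotypes phenotype data.frame.
#' @param covariates covariate column names (include \code{"ieaa"} after
#'   merging standardized IEAA into the table).
#' @return data.frame with term, logOR, se, OR, z, p.
#' @export
logisticSensitivity <- function(phenotypes, covariates) {
  ph <- .prep_pheno(phenotypes)
  .stop_if(length(unique(ph$event)) < 2,
           "both outcome classes must be present")
  fml <- stats::as.formula(paste("event ~",
                                 paste(covariates, collapse = " + ")))
  fit <- withCallingHandlers(
    stats::glm(fml, data = ph, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  co <- stats::coef(summary(fit))
  sep <- abs(co[, "Estimate"]) > 15
  if (any(sep[-1]))
    stop("perfect separation suspected for: ",
         paste(rownames(co)[-1][sep[-1]], collapse = ", "), call. = FALSE)
  data.frame(term = rownames(co), logOR = co[, "Estimate"],
             se = co[, "Std. Error"], OR = exp(co[, "Estimate"]),
             z = co[, "z value"], p = co[, "Pr(>|z|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}
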