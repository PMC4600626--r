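# methylAging

Does blood look *epigenetically older* than it should — and does that
predict who develops disease? `methylAging` is an R package for analysts
working with Illumina 450K-style DNA methylation from prospective cohorts.
It implements the full chain from beta values to a survival statement:

1. **DNAm age** — apply (or train, via elastic net) a CpG clock: DNAm age
   `= F^{-1}(intercept + Σ coef_j β_j)`, where `F` is the calibrated age
   transform `F(age) = log(age+1) − log(adultAge+1)` below the knot and
   `(age − adultAge)/(adultAge+1)` above it.
2. **Blood composition** — impute seven leukocyte fractions (naive CD8 T,
   exhausted CD8 T, plasma B, CD4 T, NK, monocytes, granulocytes) per
   sample by constrained least squares against a reference signature:
   `min ‖β − R w‖²` s.t. `w ≥ 0`, `Σw = 1`.
3. **IEAA** — intrinsic epigenetic age acceleration: the residual of DNAm
   age regressed on chronological age *and* the seven cell fractions,
   z-scored over the cohort. Positive = methylation-older than expected,
   unconfounded by blood composition.
4. **Risk models** — Cox proportional hazards (Breslow ties) for incident
   disease on standardized IEAA adjusted for age, race/ethnicity, CHD,
   smoking and pack-years; age- and smoking-stratified refits;
   Breslow-baseline incidence curves for covariate profiles; landmark
   exclusions; a logistic sensitivity check; Kruskal–Wallis screens and
   biweight midcorrelation; person-time at `days/365.25` to 4 decimals.
5. **Synthetic cohorts** — a seeded generator (cell mixtures + logit-scale
   aging signal + latent acceleration + exponential proportional-hazards
   event times, ~2% cumulative incidence over 20 years) so every stage is
   validated against planted ground truth.

## Worked example

Simulate a cohort of 2,500 women aged 50–79 with a planted hazard ratio of
1.5 per SD of age acceleration, train a clock on the first 500, analyze
the remaining 2,000:

```r
library(methylAging)

cfg <- simConfig(nSubjects = 2500, seed = 42)
coh <- simulateCohort(cfg)
b   <- betaValues(coh$betas)

model <- trainClock(b[, 1:500], coh$phenotypes$age[1:500], seed = 42)
dnam  <- applyClock(b[, 501:2500], model)
cells <- deconvolveCells(b[, 501:2500], coh$signatures)
res   <- computeIEAA(dnam, coh$phenotypes$age[501:2500], cells)
res
#> IEAAResult for 2000 samples (0 excluded)
#>   raw residual SD: 3.71 years; adjustment R^2: 0.714
#>   dropped collinear cell-fraction column: Gran

ph <- coh$phenotypes[501:2500, ]
ph$ieaa <- unname(ieaa(res))
fit <- coxFit(ph, c("ieaa", "age", "race", "chd", "smoking", "pack_years"))
fit
#> CoxModelFit: n=2000, events=43, person-years=39579, R^2=0.045
#>            term    HR       p
#>            ieaa 1.357 4.4e-02
#>             age 1.125 3.3e-07
#>       raceblack 0.295 7.5e-03
#>    racehispanic 0.792 5.2e-01
#>             chd 1.391 3.1e-01
#>   smokingformer 1.938 1.8e-01
#>  smokingcurrent 4.011 1.2e-02
#>      pack_years 1.037 1.4e-05
```

The IEAA row is the headline: a hazard ratio of 1.36 per SD (planted truth
1.5; single-replicate Wald CI covers it — over replicates the estimator
centers on the planted value, see the acceptance script). The estimated
IEAA itself tracks the latent acceleration closely:

```r
cor(rawResiduals(res), coh$truth$true_acceleration[501:2500])
#> [1] 0.974
```

Predicted 10/20-year incidence for a reference profile (age 75, white,
current smoker, 30 pack-years) at standardized IEAA +1:

```r
predictIncidence(fit, c(ieaa = 1, age = 75, raceblack = 0, racehispanic = 0,
                        chd = 0, smokingformer = 0, smokingcurrent = 1,
                        pack_years = 30), times = c(10, 20))
#>   time incidence
#> 1   10     0.125
#> 2   20     0.247
```

`runPipeline()` wraps all stages behind one YAML-able config and writes
every artifact plus a checksummed manifest. Real coefficient tables load
with `readClockModel()` (two-column CSV with an `"(Intercept)"` row); real
beta matrices with `readBetaMatrix()` (TSV, probes × samples).

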