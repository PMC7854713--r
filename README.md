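# ernaclock

Decay kinetics of environmental DNA and RNA, and the eRNA:eDNA age clock.

## The problem

Environmental DNA (eDNA) surveys detect organisms from genetic material shed
into water, but a positive qPCR detection carries no timestamp: eDNA persists
for days to weeks and can be transported, so "legacy" material can mimic a
living population. Environmental RNA (eRNA) decays measurably faster than
eDNA. The eRNA:eDNA concentration ratio of a gene region therefore starts at
a transcription-determined baseline at release and declines predictably with
age — a molecular clock for environmental genetic material.

`ernaclock` implements the quantitative pipeline around that idea for
mesocosm degradation experiments (the motivating system is invasive
*Dreissena* mussels in replicated tanks, with markers spanning the
mitochondrial and nuclear genomes, two amplicon lengths, and both nucleic
acids):

* **Concentration model.** First-order decay, C_t = C_0 e^(−kt)
  (k in /h), fitted on normalised series log_e(C_t/C_0) over the initial
  log-linear phase (default 0–72 h), with qPCR non-detects (Cq > 35)
  excluded as censored. Half-life ln(2)/k with confidence bounds obtained
  by inverting the Wald interval for k.
* **Estimators.** A linear mixed-effect model (time × gene target,
  time × abundance, gene × abundance, tank random intercepts; marginal
  trends with Tukey-adjusted contrasts via emmeans/lme4), and a two-stage
  estimator (per-tank OLS slopes combined by a Hartung–Knapp weighted t
  procedure) whose small-sample interval is exact on balanced designs.
* **Ratio clock.** Pooled OLS of log10 RNA:DNA (or short:long) ratio on
  time, with slope −(k_num − k_den)/ln 10, and the inverse estimator
  t̂ = ln(10)(baseline − observed)/(k_RNA − k_DNA) with a parametric
  bootstrap interval.
* **Synthetic mesocosm generator.** A `SummarizedExperiment`-based
  simulator reproducing the reference design (5 abundance treatments × 3
  tanks, 8 sampling times over 240 h, 10 gene × nucleic-acid targets with
  reported initial concentrations and decay constants, tank random
  effects, lognormal noise, detection-limit censoring) so every estimator
  is validated against known truth.

## A worked example

```r
library(ernaclock)

cfg <- defaultSimConfig(seed = 1)        # the reference tank design
de  <- simulateExperiment(cfg)           # 10 targets x 120 water samples
de  <- excludeTanks(de, c("A06_B", "A24_B"))  # compromised replicates

fit <- fitDecay(de, method = "two-stage")
subset(resultsTable(fit), gene == "16S_141",
       select = c(target, k, se, half_life_h,
                  half_life_lower_h, half_life_upper_h))
#>        target          k         se half_life_h half_life_lower_h half_life_upper_h
#> 1 16S_141_DNA 0.03893112 0.00170260    17.80445          16.25550          19.67968
#> 7 16S_141_RNA 0.05830052 0.00231036    11.88921          10.94425          13.01277

rr <- regressRatio(buildRatioSeries(de, "RD", genes = "16S_141"))
rr
#> RatioRegression: slope -0.009682 +/- 0.001031 log10/h, intercept 2.835,
#>   R2 = 0.527, p = 1.69e-14, n = 81

estimateAge(observed = 1, baseline = 3, kRna = 0.0561, kDna = 0.0378,
            seKRna = 0.002, seKDna = 0.002, seObserved = 0.3)
#> AgeEstimate: 251.65 h since release (95% CI 164.49-410.53)
```

The fitted decay constants sit within about one standard error of their
simulated truths (0.0378 and 0.0561 /h for 16S DNA and rRNA), the RNA:DNA
ratio declines significantly with the theoretical expectation
−(k_RNA − k_DNA)/ln 10 ≈ −0.0079 log10 units per hour under the simulated
constants, and a sample whose ratio has dropped 100-fold from baseline dates
to roughly ten days — the horizon of the reference experiment.

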