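---
title: "Decay kinetics of environmental DNA and RNA and the eRNA:eDNA age clock"
author: "ernaclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decay kinetics of environmental DNA and RNA and the eRNA:eDNA age clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ernaclock)
options(ernaclock.verbose = FALSE)
```

## The problem

Environmental DNA (eDNA) monitoring detects organisms from the genetic
material they shed into water. A positive qPCR detection, however, carries no
timestamp: eDNA can persist for days to weeks and can be transported far from
its source, so "legacy" material can mimic a living population. Environmental
RNA (eRNA) decays faster than eDNA, which makes the eRNA:eDNA concentration
ratio of a gene region a candidate clock: it starts at a
transcription-determined baseline at release and declines predictably as the
material ages.

`ernaclock` implements the quantitative machinery around this idea for
mesocosm degradation experiments of the kind used with invasive dreissenid
mussels: tanks holding known numbers of animals accumulate genetic material
for 24 h, the animals are removed, and water is sampled repeatedly
(0–240 h) for qPCR quantification of multiple markers spanning the
mitochondrial and nuclear genomes (16S, COI, 18S, H2B), two amplicon lengths
per gene where available, and both nucleic acids.

## The decay model

Concentrations follow first-order exponential decay,

$$C_t = C_0\, e^{-k t},$$

with $C_t$ in copies/mL and $k$ in per hour. Internally `k` is stored as a
positive magnitude; display conventions that print negative decay constants
are a formatting concern only. The half-life is $\ln(2)/k$, and a Wald
interval for $k$ inverts into a half-life interval
$(\ln 2/(k + z\,\mathrm{se}),\ \ln 2/(k - z\,\mathrm{se}))$
(`halfLifeInterval()`). The default quantile is the exact Normal 97.5% point
$z = 1.959964$. Published half-life tables for this design largely agree
with that convention to two decimals; a minority of rows differ in the
second decimal, suggesting rounding or a slightly different quantile in the
original software, so a `z` argument (e.g. `qt(0.975, df)`) is provided
rather than a silent switch.

Decay is fitted on the *normalised* series $C' = C_t/C_0$, i.e. on
$\log_e(C_t/C_0)$ against time, which removes tank-level release
differences (any multiplicative tank effect cancels exactly). Only the
0–72 h window is fitted by default: empirical eDNA decay is frequently
biphasic (fast first phase, slower tail), and restricting to the initial
log-linear phase keeps the first-order model honest. The window is a
parameter (`windowH`), not a constant.

### Censoring

qPCR non-detects (quantification cycle above 35 by the standard rule,
`applyDetectionLimit()`) are stored as *absent* concentrations with a
censoring flag — never as zeros — so each stage can own its censoring
policy. Decay fitting follows the source experiment's convention: censored
points are excluded from the fit (`censorPolicy = "drop"`). This induces an
upward bias in $k$ when series truncate at the detection limit inside the
fitting window, because the faintest (slowest-looking) tail observations
are the ones lost; the package documents this rather than correcting it,
and a censored-likelihood (Tobit-type) model is deliberately out of scope.
`censorPolicy = "refuse"` is available for workflows that must not silently
drop data. In the default simulated design the 0–72 h window sits far above
the detection limit for every quantifiable marker, so the bias is
negligible there.

## Two estimation routes

`fitDecay()` offers two estimators with one contract:

* **Mixed model** (default): one lme4 fit of $\log_e(C_t/C_0)$ with time as
  a continuous fixed effect, gene target (categorical) and mussel abundance
  (quantitative) with their two-way interactions with time, a
  gene × abundance interaction, and a random intercept per tank. Per-target
  decay constants are the negated marginal time trends at the mean
  abundance (emmeans), with Tukey-adjusted pairwise comparisons. Degrees of
  freedom are Satterthwaite when `lmerTest` is available. The experimental
  design nests water samples within replicate tanks; with one water sample
  per tank per timepoint — the default design — the tank intercept is the
  nesting level that remains identifiable, and ratio-normalisation absorbs
  most of it.
* **Two-stage**: an OLS slope per (tank, target), combined across the $m$
  tanks by a Hartung–Knapp weighted $t$ procedure with $m-1$ degrees of
  freedom. Weights are *design-based* inverse variances
  ($w_i = \sum_j (t_{ij}-\bar t_i)^2$, the OLS precision factor under a
  common residual variance). Residual-based weights were rejected: with
  ~4 residual degrees of freedom per tank they correlate with the slope
  estimates and visibly degrade interval coverage, whereas design-based
  weights are fixed by the sampling grid and reduce to equal weights on
  balanced designs, where the interval is the exact unweighted $t$
  interval for the mean tank slope.

The mixed route is the analysis model of record; the two-stage route is the
calibration workhorse (it is what the Monte-Carlo recovery and age-clock
studies use, precisely because its small-sample interval is exact on
balanced designs) and the automatic fallback when the mixed fit fails on
degenerate inputs (e.g. zero-noise data). On balanced designs the two agree
within sampling error, which the test suite checks at the 2-SE level.

Group comparisons beyond per-target Tukey contrasts — fragment length,
genomic origin, nucleic acid, RNA class, abundance treatment — use pooled
per-target estimates with pairwise $z$ tests under Holm adjustment
(`pairwiseContrasts()`). Exact Tukey HSD machinery for these derived
groupings is intentionally not reimplemented; exact ties are defined as
$p = 1$ so that noiseless identity checks behave sensibly.

`fitInitialConcentration()` applies the same structure to
$\log_e C_0$: gene × abundance fixed effects, tank random intercept,
marginal means per target at the mean abundance.

## The ratio clock

For two markers measured in the same water samples, the pointwise log10
ratio removes everything the two share — tank effects, abundance effects on
release, volume bridges — and retains only differential decay:

$$\log_{10} R(t) = \log_{10} R(0) - \frac{k_{num} - k_{den}}{\ln 10}\, t.$$

`buildRatioSeries()` constructs RNA:DNA (`"RD"`) and short:long (`"SL"`)
series using only timepoints where both members are detections;
`regressRatio()` pools tanks into one OLS line. Two consequences are used
as exact identities in the tests: on noiseless data the fitted RD slope
equals $-(k_{RNA}-k_{DNA})/\ln 10$ to machine precision, and an equal-$k$
fragment pair has a flat SL ratio (the null under which the observed
short:long stability of the 16S pair is reproduced).

`estimateAge()` inverts the line:
$\hat t = \ln(10)\,(\mathrm{baseline} - \mathrm{observed})/(k_{RNA}-k_{DNA})$,
with $\hat t$ clamped at 0 when the observed ratio exceeds baseline (fresh
material within noise). Uncertainty comes from a parametric bootstrap
(default 2000 draws, fixed seed): Normal draws of $k_{RNA}$, $k_{DNA}$, the
baseline and the observed ratio from their standard errors, draws with
$\Delta k \le 0$ discarded, percentile interval. The observed ratio's own
measurement error must be supplied (`seObserved`) — in practice from
replicate field samples, in simulation from the known noise model — and it
dominates the error budget at young ages, because a log10 ratio read with
SE $\sigma$ converts to an age error of $\sigma \ln(10)/\Delta k$ hours
regardless of age. The estimator assumes a single release pulse; in real
water bodies material of mixed ages shifts the ratio toward the freshest
component, which is the main caveat for field use.

The baseline can be the fitted intercept of a calibration regression or a
known-at-release value. `ageRecoveryStudy()` validates the whole loop under
the second convention (calibrated clock, independent test sample), which
keeps the propagated error sources independent; using the same experiment's
fitted intercept as baseline couples it to the fitted slopes and is offered
for diagnostics rather than validation.

## The synthetic mesocosm generator

`simulateExperiment()` generates data under exactly the model the
estimators assume — by design, since its purpose is ground-truth
validation, not realism. For tank $i$ (abundance $A_i$) and target $g$:

$$c_{0,ig} = c_{0,g} + \beta_{C0}(\ln A_i - \overline{\ln A}) + u_i,
\qquad u_i \sim N(0, \sigma^2_{tank}),$$
$$k_{ig} = \max\{0,\ k_g + \beta_k (A_i - \bar A)\},$$

latent concentration $\exp(c_{0,ig})e^{-k_{ig}t}$, lognormal measurement
noise $\exp(N(0, \sigma^2_{noise}))$, and censoring below a fixed
copies/mL detection limit. Abundance effects are **centred on the design
means**, so the configured per-target $c_{0,g}$ and $k_g$ are the
all-abundances marginal values — the scale on which the reference
experiment reports them — and recovery tests can compare marginal
estimates to configured truth directly.

`defaultSimConfig()` encodes the reference design: abundances
{2, 6, 12, 24, 48} × 3 replicate tanks, sampling at
{0, 5, 12, 24, 48, 72, 144, 240} h, and ten targets with the reported
initial log concentrations and decay constants (16S 141/341 bp DNA, COI
128 bp DNA, 18S 169 bp DNA, H2B 75/250 bp DNA, 16S/COI/18S RNA, H2B
250 bp RNA). The H2B messenger RNA — a mitosis-associated transcript
essentially absent from shed material — was too scarce for a measured
decay constant; it is simulated with a user-suppliable `fallbackK`
defaulting to 0.0735 /h, the fastest measured rRNA constant, which
reproduces its qualitative behaviour (undetectable within roughly a day).

Quantities the reference experiment does not report are fixed here as
stated assumptions, chosen once: tank intercept SD 0.3 and measurement
noise SD 0.5 (log_e scale — typical qPCR replicate scatter of a factor
~1.6), release slope $\beta_{C0} = 0.5$ per unit $\ln A$ (sublinear
per-capita shedding), decay slope $\beta_k = 2\times10^{-4}$ /h per mussel
(a modest monotone abundance effect), and a detection limit of 0.6
copies/mL — one template copy per reaction at the default volume bridge of
`copiesPerReactionToPerMl()` (100 mL filtered, half filter extracted,
75 µL eluate, 2.5 µL template: 5/3 mL per reaction). Biphasic decay is off
by default (the fitted window is the first phase); when enabled, $k$ is
multiplied by a factor in (0, 1] past a breakpoint.

Randomness is reproducible and modular: one root seed spawns a child
stream per tank and per tank × target, so adding a target perturbs no
other draws, and raising the detection limit can only remove detections
(the underlying draws are identical) — a property the test suite checks
exactly, alongside bit-reproducibility and preservation of the caller's
RNG state.

What the generator deliberately does **not** emulate: mechanistic shedding
dynamics during the accumulation phase (release is folded into $c_0$),
temperature/pH/UV covariates on $k$, microbial community effects,
multi-source mixing, and mortality events (tank exclusion is a user
action, mirroring the removal of two compromised replicates in the
reference design, not a simulated process). Passing recovery tests
therefore demonstrate estimator correctness under the stated model, not
robustness to field conditions.

## Numerical conventions and edge cases

* Decay and release are analysed in log_e; ratios in log10 (the field's
  plotting convention). The conversion constant $\ln 10$ lives in one
  place to avoid drift.
* Units are fixed internally: copies/mL and hours.
* Exact-fit degeneracies are defined, not propagated: a zero-residual
  contrast with zero estimate has $p = 1$ (a tie), with nonzero estimate
  $p = 0$; a constant ratio series regresses to slope 0, $r^2 = 0$,
  $p = 1$.
* A Wald half-life interval is refused when $k - z\,\mathrm{se} \le 0$
  (the inversion is invalid there) with advice to use a profile or
  bootstrap interval.
* Series without a detected $t = 0$ point cannot be normalised and are
  skipped with a count; targets with no usable series are reported
  not-estimable rather than erroring, so one dark marker does not kill a
  ten-marker analysis.
* CSV round trips print numbers with 17 significant digits, so written
  datasets re-read bit-identically.

## Problem sizes used in validation

The shipped studies use the design sizes of the reference experiment:
13 analysed tanks (15 simulated, two excluded), 6 in-window timepoints,
500 replicate experiments for decay-constant recovery (bias within
Monte-Carlo error, interval coverage checked against a 92–98% band), and
age-clock calibration runs at 120–500 replicates with 400–500 bootstrap
draws. These sizes give Monte-Carlo standard errors comfortably below the
effects being checked while keeping the full validation suite in the
minutes range on a single core.

## A worked example

```{r example, eval = FALSE}
cfg <- defaultSimConfig(seed = 1)
de <- simulateExperiment(cfg)
de <- excludeTanks(de, c("A06_B", "A24_B"))   # compromised replicates

fit <- fitDecay(de, method = "mixed")
resultsTable(fit)[, c("target", "k", "se", "half_life_h")]
pairwiseContrasts(fit, "nucleic_acid")

rs <- buildRatioSeries(de, "RD", genes = "16S_141")
rr <- regressRatio(rs)

estimateAge(observed = 1, baseline = rr@intercept,
            kRna = 0.0561, kDna = 0.0378,
            seKRna = 0.0025, seKDna = 0.0025,
            seBaseline = rr@interceptSe, seObserved = 0.3)
```

## Known limitations

* No censored-likelihood decay model; the drop-non-detects convention is
  faithful to practice but biased near the detection limit.
* The clock is single-pulse; mixtures are out of scope.
* Standard curves are always user- or simulator-supplied; multi-plate
  calibration and LOD/LOQ modelling beyond the fixed Cq threshold are not
  implemented.
* Markers are labels with attributes, not sequences; no primer design or
  melting-temperature logic.
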