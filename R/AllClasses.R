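#' @import methods
#' @importFrom S4Vectors SimpleList DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

.GENOMES <- c("mt", "nu")
.RNA_CLASSES <- c("rRNA", "mRNA")
.NUCLEIC_ACIDS <- c("DNA", "RNA")

#' Gene target descriptor
#'
#' Identity of a qPCR marker assayed in the degradation experiment: the gene
#' fragment (e.g. a 141-bp stretch of mitochondrial 16S), its genomic origin,
#' the RNA class of its transcript, the amplicon length and whether the
#' measured molecule is DNA or RNA (cDNA).
#'
#' @slot name Short marker label, e.g. `"16S_141"`; unique within a dataset
#'   together with the nucleic acid.
#' @slot genome `"mt"` (mitochondrial) or `"nu"` (nuclear).
#' @slot rnaClass `"rRNA"` (ribosomal) or `"mRNA"` (messenger); describes the
#'   transcript of the gene region regardless of the assayed nucleic acid.
#' @slot ampliconLength Amplicon length in base pairs (positive integer).
#' @slot nucleicAcid `"DNA"` or `"RNA"`: the molecule that was quantified.
#'
#' @seealso [GeneTarget()]
#' @exportClass GeneTarget
setClass("GeneTarget",
  representation(
    name = "character",
    genome = "character",
    rnaClass = "character",
    ampliconLength = "integer",
    nucleicAcid = "character"
  )
)

setValidity("GeneTarget", function(object) {
  msg <- character()
  for (s in c("name", "genome", "rnaClass", "ampliconLength", "nucleicAcid"))
    if (length(slot(object, s)) != 1L)
      msg <- c(msg, sprintf("slot '%s' must have length 1", s))
  if (length(msg)) return(msg)
  if (is.na(object@name) || !nzchar(object@name))
    msg <- c(msg, "'name' must be a non-empty string")
  if (!object@genome %in% .GENOMES)
    msg <- c(msg, sprintf("'genome' must be one of %s",
                          paste(.GENOMES, collapse = ", ")))
  if (!object@rnaClass %in% .RNA_CLASSES)
    msg <- c(msg, sprintf("'rnaClass' must be one of %s",
                          paste(.RNA_CLASSES, collapse = ", ")))
  if (is.na(object@ampliconLength) || object@ampliconLength <= 0L)
    msg <- c(msg, "'ampliconLength' must be a positive integer")
  if (!object@nucleicAcid %in% .NUCLEIC_ACIDS)
    msg <- c(msg, sprintf("'nucleicAcid' must be one of %s",
                          paste(.NUCLEIC_ACIDS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Container for a mesocosm degradation experiment
#'
#' `DecayExperiment` extends [SummarizedExperiment::SummarizedExperiment] with
#' two assays of identical dimension: `copies` (qPCR-quantified concentration
#' in copies/mL; `NA` where the reaction failed to amplify) and `censored`
#' (`TRUE` for non-detects, `FALSE` for quantified detections, `NA` where the
#' cell was never measured). Rows are gene x nucleic-acid targets described by
#' `rowData` columns `gene`, `genome`, `rna_class`, `amplicon_length`,
#' `nucleic_acid`; columns are individual water samples described by `colData`
#' columns `tank_id`, `abundance`, `replicate`, `time_h` and `sample_id`.
#'
#' @seealso [readMeasurements()], [simulateExperiment()],
#'   [concentrationSeries()]
#' @exportClass DecayExperiment
setClass("DecayExperiment", contains = "SummarizedExperiment")

.REQ_ROWDATA <- c("gene", "genome", "rna_class", "amplicon_length",
                  "nucleic_acid")
.REQ_COLDATA <- c("tank_id", "abundance", "replicate", "time_h", "sample_id")

setValidity("DecayExperiment", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("copies", "censored") %in% an))
    return("assays 'copies' and 'censored' are required")
  miss <- setdiff(.REQ_ROWDATA, colnames(rowData(object)))
  if (length(miss))
    msg <- c(msg, paste("missing rowData column(s):",
                        paste(miss, collapse = ", ")))
  miss <- setdiff(.REQ_COLDATA, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste("missing colData column(s):",
                        paste(miss, collapse = ", ")))
  if (length(msg)) return(msg)
  cp <- assay(object, "copies")
  cn <- assay(object, "censored")
  measured <- !is.na(cn)
  if (any(cn[measured] & !is.na(cp[measured])))
    msg <- c(msg, "censored cells must have NA copies")
  if (any(!cn[measured] & is.na(cp[measured])))
    msg <- c(msg, "detected cells must have non-missing copies")
  if (any(cp[!is.na(cp)] < 0))
    msg <- c(msg, "'copies' must be non-negative")
  tm <- colData(object)$time_h
  if (any(is.na(tm)) || any(tm < 0))
    msg <- c(msg, "'time_h' must be non-negative and non-missing")
  ab <- colData(object)$abundance
  if (any(is.na(ab)) || any(ab < 0))
    msg <- c(msg, "'abundance' must be a non-negative count")
  al <- rowData(object)$amplicon_length
  if (any(is.na(al)) || any(al <= 0))
    msg <- c(msg, "'amplicon_length' must be positive")
  if (!all(rowData(object)$genome %in% .GENOMES))
    msg <- c(msg, "rowData 'genome' must be 'mt' or 'nu'")
  if (!all(rowData(object)$rna_class %in% .RNA_CLASSES))
    msg <- c(msg, "rowData 'rna_class' must be 'rRNA' or 'mRNA'")
  if (!all(rowData(object)$nucleic_acid %in% .NUCLEIC_ACIDS))
    msg <- c(msg, "rowData 'nucleic_acid' must be 'DNA' or 'RNA'")
  if (length(msg)) msg else TRUE
})

#' One tank x target concentration time course
#'
#' An ordered qPCR time series of copies/mL for a single marker in a single
#' mesocosm tank, with censoring flags for non-detects. This is the unit on
#' which normalisation and per-tank decay slopes operate.
#'
#' @slot tankId Tank label.
#' @slot abundance Mussel count of the tank.
#' @slot replicate Replicate label within the abundance group.
#' @slot target A [GeneTarget-class].
#' @slot timeH Hours since organism removal, strictly increasing.
#' @slot copiesPerMl Concentration in copies/mL; `NA` where censored.
#' @slot censored Logical non-detect flags.
#'
#' @exportClass ConcentrationSeries
setClass("ConcentrationSeries",
  representation(
    tankId = "character",
    abundance = "numeric",
    replicate = "character",
    target = "GeneTarget",
    timeH = "numeric",
    copiesPerMl = "numeric",
    censored = "logical"
  )
)

setValidity("ConcentrationSeries", function(object) {
  msg <- character()
  n <- length(object@timeH)
  if (length(object@copiesPerMl) != n || length(object@censored) != n)
    msg <- c(msg, "timeH, copiesPerMl and censored must have equal length")
  if (n > 1 && any(diff(object@timeH) <= 0))
    msg <- c(msg, "timeH must be strictly increasing")
  if (any(object@timeH < 0))
    msg <- c(msg, "timeH must be non-negative")
  ok <- !is.na(object@censored)
  if (any(object@censored[ok] & !is.na(object@copiesPerMl[ok])))
    msg <- c(msg, "censored points must have NA copiesPerMl")
  if (any(!object@censored[ok] & is.na(object@copiesPerMl[ok])))
    msg <- c(msg, "detections must have non-missing copiesPerMl")
  if (any(object@copiesPerMl < 0, na.rm = TRUE))
    msg <- c(msg, "copiesPerMl must be non-negative")
  if (length(msg)) msg else TRUE
})

#' qPCR standard curve
#'
#' Ordinary least-squares calibration of quantification cycle (Cq) against
#' log10 template copies per reaction from a serial dilution, with the
#' amplification efficiency implied by the slope:
#' `efficiency = 10^(-1/slope) - 1` (1 = 100%; a slope of -3.321928 cycles
#' per decade doubles the template each cycle).
#'
#' @slot slope Cq change per log10(copies); negative for a valid curve.
#' @slot intercept Cq at 1 copy/reaction.
#' @slot r2 Coefficient of determination of the calibration fit.
#' @slot efficiency Amplification efficiency as a fraction.
#'
#' @seealso [fitStandardCurve()], [cqToCopies()]
#' @exportClass StandardCurve
setClass("StandardCurve",
  representation(slope = "numeric", intercept = "numeric",
                 r2 = "numeric", efficiency = "numeric")
)

setValidity("StandardCurve", function(object) {
  msg <- character()
  if (length(object@slope) != 1L || is.na(object@slope) || object@slope >= 0)
    msg <- c(msg, "'slope' must be a single negative number")
  if (length(object@r2) != 1L || is.na(object@r2) ||
      object@r2 < 0 || object@r2 > 1)
    msg <- c(msg, "'r2' must lie in [0, 1]")
  if (length(object@efficiency) != 1L || is.na(object@efficiency))
    msg <- c(msg, "'efficiency' must be a single number")
  if (length(msg)) msg else TRUE
})

#' First-order decay fit for one target
#'
#' Decay constant of the model `C_t = C_0 * exp(-k t)` estimated from the
#' log-linear phase of a concentration time course, with its standard error,
#' half-life `ln(2)/k` and the half-life interval obtained by inverting the
#' confidence bounds of `k`.
#'
#' @slot target Target label the fit belongs to.
#' @slot kHat Estimated decay constant (per hour, stored as magnitude).
#' @slot seK Standard error of `kHat` (per hour).
#' @slot df Degrees of freedom of the interval (Inf for a Normal z interval).
#' @slot ciLevel Confidence level, default 0.95.
#' @slot halfLifeH Half-life `ln(2)/kHat` in hours.
#' @slot halfLifeCiH Two-sided half-life interval (hours), lower bound first.
#' @slot nObs Number of detections used in the fit.
#' @slot windowH Fitted time window (start, end), hours.
#' @slot estimable `FALSE` when too few usable detections were available.
#'
#' @seealso [fitDecay()], [halfLifeInterval()]
#' @exportClass DecayFit
setClass("DecayFit",
  representation(
    target = "character",
    kHat = "numeric",
    seK = "numeric",
    df = "numeric",
    ciLevel = "numeric",
    halfLifeH = "numeric",
    halfLifeCiH = "numeric",
    nObs = "integer",
    windowH = "numeric",
    estimable = "logical"
  ),
  prototype(ciLevel = 0.95, estimable = TRUE)
)

setValidity("DecayFit", function(object) {
  msg <- character()
  if (!object@estimable) return(TRUE)
  if (object@kHat < 0) msg <- c(msg, "'kHat' must be >= 0 (magnitude)")
  if (length(object@halfLifeCiH) != 2L)
    msg <- c(msg, "'halfLifeCiH' must have length 2")
  else if (!any(is.na(object@halfLifeCiH)) && is.finite(object@halfLifeH) &&
           (object@halfLifeH < object@halfLifeCiH[1] - 1e-12 ||
            object@halfLifeH > object@halfLifeCiH[2] + 1e-12))
    msg <- c(msg, "'halfLifeCiH' must contain 'halfLifeH'")
  if (object@nObs < 2L) msg <- c(msg, "'nObs' must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Fitted decay analysis across targets
#'
#' Result of [fitDecay()]: per-target [DecayFit-class] objects, a summary
#' table mirroring the usual decay-constant/half-life reporting, the abundance
#' effect on the decay constant, and multiplicity-adjusted pairwise contrasts
#' between target decay constants.
#'
#' @slot fits `SimpleList` of [DecayFit-class], one per target.
#' @slot table `data.frame` with one row per target (k, SE, half-life, CI, n).
#' @slot abundanceEffect Named numeric: `estimate` and `se` of the change in
#'   k per additional mussel (per hour).
#' @slot contrasts `data.frame` of pairwise target contrasts on k.
#' @slot method `"mixed"` or `"two-stage"`.
#' @slot windowH Fitted window in hours.
#' @slot nDropped Named integer counts of excluded points
#'   (`censored`, `outside_window`, `unusable_series`).
#' @slot perTank `data.frame` of per-tank OLS slopes (tank_id, abundance,
#'   target, slope, se, n), the first stage of the two-stage estimator;
#'   also populated under the mixed route for diagnostics and
#'   abundance-group contrasts.
#'
#' @exportClass DecayAnalysis
setClass("DecayAnalysis",
  representation(
    fits = "SimpleList",
    table = "data.frame",
    abundanceEffect = "numeric",
    contrasts = "data.frame",
    method = "character",
    windowH = "numeric",
    nDropped = "integer",
    perTank = "data.frame"
  )
)

#' Initial-concentration analysis
#'
#' Result of [fitInitialConcentration()]: per-target marginal mean log_e
#' concentration at time 0, the abundance effect on log_e initial
#' concentration, and pairwise target contrasts.
#'
#' @slot table `data.frame`: target, estimate (log_e copies/mL), se, df.
#' @slot abundanceEffect Named numeric `estimate`/`se` (log_e copies/mL per
#'   unit ln abundance as modelled, see [fitInitialConcentration()]).
#' @slot contrasts `data.frame` of pairwise contrasts.
#' @slot method `"mixed"` or `"fixed"` (lm fallback).
#'
#' @exportClass InitialConcAnalysis
setClass("InitialConcAnalysis",
  representation(
    table = "data.frame",
    abundanceEffect = "numeric",
    contrasts = "data.frame",
    method = "character"
  )
)

#' Ratio time series for one tank
#'
#' Pointwise log10 ratio of two markers measured in the same water samples:
#' short:long amplicons of one gene (`"SL"`) or RNA:DNA for one gene region
#' (`"RD"`). Only timepoints at which both members were detections contribute
#' points; censored timepoints are omitted and counted.
#'
#' @slot tankId Tank label.
#' @slot kind `"RD"` or `"SL"`.
#' @slot numerator,denominator Target labels of the pair.
#' @slot timeH Hours of the common detections.
#' @slot log10Ratio log10(numerator/denominator) at those times.
#' @slot nOmitted Number of timepoints dropped because either member was
#'   censored or unmeasured.
#'
#' @seealso [buildRatioSeries()]
#' @exportClass RatioSeries
setClass("RatioSeries",
  representation(
    tankId = "character",
    kind = "character",
    numerator = "character",
    denominator = "character",
    timeH = "numeric",
    log10Ratio = "numeric",
    nOmitted = "integer"
  )
)

setValidity("RatioSeries", function(object) {
  msg <- character()
  if (!object@kind %in% c("RD", "SL"))
    msg <- c(msg, "'kind' must be 'RD' or 'SL'")
  if (length(object@timeH) != length(object@log10Ratio))
    msg <- c(msg, "timeH and log10Ratio must have equal length")
  # nested water samples may contribute several points at one timepoint
  if (length(object@timeH) > 1 && any(diff(object@timeH) < 0))
    msg <- c(msg, "timeH must be sorted ascending")
  if (length(msg)) msg else TRUE
})

#' Pooled log-ratio regression
#'
#' Ordinary least-squares regression of log10 marker ratio on time, pooled
#' across tanks. Under first-order decay of both pair members the expected
#' slope is `-(k_num - k_den)/ln(10)` log10 units per hour.
#'
#' @slot slope,slopeSe Slope (log10/h) and its standard error.
#' @slot intercept,interceptSe Intercept (log10 ratio at t = 0) and SE.
#' @slot r2 Coefficient of determination.
#' @slot pValue Two-sided p-value of the slope.
#' @slot n Number of pooled points.
#'
#' @seealso [regressRatio()]
#' @exportClass RatioRegression
setClass("RatioRegression",
  representation(slope = "numeric", slopeSe = "numeric",
                 intercept = "numeric", interceptSe = "numeric",
                 r2 = "numeric", pValue = "numeric", n = "integer")
)

setValidity("RatioRegression", function(object) {
  msg <- character()
  if (object@r2 < -1e-12 || object@r2 > 1 + 1e-12)
    msg <- c(msg, "'r2' must lie in [0, 1]")
  if (object@n < 3L) msg <- c(msg, "'n' must be >= 3")
  if (length(msg)) msg else TRUE
})

#' Age estimate from the eRNA:eDNA ratio clock
#'
#' Time since release inferred by inverting the first-order differential
#' decay of RNA versus DNA:
#' `t = ln(10) * (baseline - observed) / (k_RNA - k_DNA)`, where baseline and
#' observed are log10 RNA:DNA ratios at release and at sampling. Uncertainty
#' comes from a parametric bootstrap propagating the standard errors of both
#' decay constants, the baseline and the observed ratio.
#'
#' @slot tHat Estimated hours since release (>= 0).
#' @slot ciH Bootstrap percentile interval (hours).
#' @slot level Confidence level of `ciH`.
#' @slot inputs Named list of the inputs and bootstrap bookkeeping.
#'
#' @seealso [estimateAge()]
#' @exportClass AgeEstimate
setClass("AgeEstimate",
  representation(tHat = "numeric", ciH = "numeric",
                 level = "numeric", inputs = "list")
)

setValidity("AgeEstimate", function(object) {
  msg <- character()
  if (object@tHat < 0) msg <- c(msg, "'tHat' must be >= 0")
  if (length(object@ciH) != 2L) msg <- c(msg, "'ciH' must have length 2")
  else if (!any(is.na(object@ciH)) &&
           (object@tHat < object@ciH[1] - 1e-9 ||
            object@tHat > object@ciH[2] + 1e-9))
    msg <- c(msg, "'ciH' must contain 'tHat'")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration for the synthetic mesocosm generator
#'
#' Complete description of a simulated tank degradation experiment: design
#' (abundance treatments, replicate tanks, sampling times, targets with their
#' true initial log concentrations and decay constants), abundance effects,
#' variance components, detection limit and an optional biphasic decay switch.
#'
#' @slot seed Root random seed (integer).
#' @slot abundances Mussel counts of the abundance treatments.
#' @slot replicatesPerAbundance Replicate tanks per treatment.
#' @slot timepointsH Sampling times in hours, ascending, starting at 0.
#' @slot targets `data.frame` with columns `gene`, `genome`, `rna_class`,
#'   `amplicon_length`, `nucleic_acid`, `c0_log` (log_e copies/mL at t = 0)
#'   and `k` (per hour; `NA` allowed, filled by `fallbackK`).
#' @slot abundanceC0Slope Change in log_e C0 per unit ln(abundance), applied
#'   centred on the design mean of ln(abundance).
#' @slot abundanceKSlope Change in k (per hour) per mussel, applied centred
#'   on the design mean abundance; realized k floored at 0.
#' @slot tankSd SD of the tank-level random intercept (log_e scale).
#' @slot noiseSd SD of lognormal measurement noise (log_e scale).
#' @slot lodCopiesPerMl Detection limit in copies/mL.
#' @slot samplesPerTimepoint Water samples per tank per timepoint.
#' @slot fallbackK Decay constant used for targets with `k = NA`.
#' @slot biphasic Empty list (off) or `list(breakpoint_h=, k_multiplier_after=)`
#'   with the multiplier in (0, 1].
#'
#' @seealso [SimConfig()], [defaultSimConfig()], [simulateExperiment()]
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    seed = "integer",
    abundances = "numeric",
    replicatesPerAbundance = "integer",
    timepointsH = "numeric",
    targets = "data.frame",
    abundanceC0Slope = "numeric",
    abundanceKSlope = "numeric",
    tankSd = "numeric",
    noiseSd = "numeric",
    lodCopiesPerMl = "numeric",
    samplesPerTimepoint = "integer",
    fallbackK = "numeric",
    biphasic = "list"
  )
)

.REQ_TARGET_COLS <- c("gene", "genome", "rna_class", "amplicon_length",
                      "nucleic_acid", "c0_log", "k")

setValidity("SimConfig", function(object) {
  msg <- character()
  if (nrow(object@targets) == 0L)
    msg <- c(msg, "at least one target is required")
  miss <- setdiff(.REQ_TARGET_COLS, colnames(object@targets))
  if (length(miss))
    msg <- c(msg, paste("targets is missing column(s):",
                        paste(miss, collapse = ", ")))
  if (length(object@timepointsH) == 0L)
    msg <- c(msg, "at least one timepoint is required")
  else {
    if (object@timepointsH[1] != 0)
      msg <- c(msg, "timepoints must start at 0")
    if (any(diff(object@timepointsH) <= 0))
      msg <- c(msg, "timepoints must be strictly ascending")
  }
  if (length(object@abundances) == 0L || any(object@abundances < 0))
    msg <- c(msg, "abundances must be non-negative counts")
  if (object@replicatesPerAbundance < 1L)
    msg <- c(msg, "replicatesPerAbundance must be >= 1")
  if (object@tankSd < 0 || object@noiseSd < 0)
    msg <- c(msg, "standard deviations must be >= 0")
  if (object@lodCopiesPerMl < 0)
    msg <- c(msg, "lodCopiesPerMl must be >= 0")
  if (object@samplesPerTimepoint < 1L)
    msg <- c(msg, "samplesPerTimepoint must be >= 1")
  if (length(object@biphasic)) {
    need <- c("breakpoint_h", "k_multiplier_after")
    if (!all(need %in% names(object@biphasic)))
      msg <- c(msg, "biphasic needs 'breakpoint_h' and 'k_multiplier_after'")
    else {
      m <- object@biphasic$k_multiplier_after
      if (m <= 0 || m > 1)
        msg <- c(msg, "biphasic k_multiplier_after must lie in (0, 1]")
      if (object@biphasic$breakpoint_h <= 0)
        msg <- c(msg, "biphasic breakpoint_h must be > 0")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated experiment
#'
#' Ledger of the latent quantities a simulation realized, for parameter
#' recovery studies: per tank x target the realized initial log concentration
#' (baseline + abundance effect + tank intercept) and realized decay constant,
#' and per measurement the latent pre-noise concentration.
#'
#' @slot params `data.frame`: tank_id, target, abundance, tank_intercept,
#'   c0_log (realized), k (realized).
#' @slot latent Matrix of latent copies/mL (targets x samples), pre-noise and
#'   pre-censoring.
#'
#' @seealso [simulateExperiment()], [simTruth()]
#' @exportClass SimTruth
setClass("SimTruth",
  representation(params = "data.frame", latent = "matrix")
)
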