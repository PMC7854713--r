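#' @include AllClasses.R
NULL

#' Extract per-tank concentration time courses
#'
#' Splits a [DecayExperiment-class] into one [ConcentrationSeries-class] per
#' (tank, target) combination, each sorted by time. The split is a partition:
#' every measured cell of the experiment appears in exactly one series.
#'
#' @param x A `DecayExperiment`.
#' @param ... Unused.
#' @return A [S4Vectors::SimpleList] of `ConcentrationSeries`, named
#'   `"<tank_id>.<target>"`.
#' @examples
#' de <- simulateExperiment(defaultSimConfig(seed = 1))
#' cs <- concentrationSeries(de)
#' cs[[1]]
#' @export
setGeneric("concentrationSeries",
           function(x, ...) standardGeneric("concentrationSeries"))

#' Tidy long measurement table
#'
#' Flattens an experiment (or a single series) into the package's tidy
#' interchange format: one row per measurement with columns `tank_id`,
#' `abundance`, `replicate`, `gene`, `genome`, `rna_class`,
#' `amplicon_length`, `nucleic_acid`, `time_h`, `copies_per_ml`, `censored`.
#'
#' @param x A `DecayExperiment` or `ConcentrationSeries`.
#' @param ... Unused.
#' @return A `data.frame` in tidy long format.
#' @export
setGeneric("measurementTable",
           function(x, ...) standardGeneric("measurementTable"))

#' Remove tanks from an experiment
#'
#' Drops all water samples belonging to the listed tanks, mirroring the
#' exclusion of compromised replicates (e.g. tanks in which a mussel died)
#' from analysis. The operation is idempotent.
#'
#' @param x A `DecayExperiment`.
#' @param tankIds Character vector of tank labels to remove; must all be
#'   present in `x`.
#' @param ... Unused.
#' @return `x` without the excluded tanks. Removing every tank yields an
#'   empty experiment with a warning.
#' @export
setGeneric("excludeTanks",
           function(x, tankIds, ...) standardGeneric("excludeTanks"))

#' Normalise a concentration series to its initial value
#'
#' Computes the relative concentration C' = C_t / C_0 used to put tanks with
#' different starting concentrations on a common decay scale. The value at
#' t = 0 is exactly 1; censored points stay censored. A censored or missing
#' t = 0 detection makes the series unusable for decay fitting and is an
#' error.
#'
#' @param x A `ConcentrationSeries` (or `DecayExperiment`, normalised
#'   series-wise; series lacking a detected t = 0 are dropped with a message).
#' @param ... Unused.
#' @return Object of the same class with copies replaced by unitless ratios.
#' @export
setGeneric("normalizeSeries",
           function(x, ...) standardGeneric("normalizeSeries"))

#' Ground truth of a simulated experiment
#'
#' @param x A `DecayExperiment` produced by [simulateExperiment()].
#' @param ... Unused.
#' @return The [SimTruth-class] stored in the object metadata, or `NULL` for
#'   experiments read from disk.
#' @export
setGeneric("simTruth", function(x, ...) standardGeneric("simTruth"))

#' Summary table of a fitted analysis
#'
#' @param x A [DecayAnalysis-class] or [InitialConcAnalysis-class].
#' @param ... Unused.
#' @return A `data.frame` with one row per target.
#' @export
setGeneric("resultsTable", function(x, ...) standardGeneric("resultsTable"))

#' Pairwise contrast table of a fitted analysis
#'
#' @param x A [DecayAnalysis-class] or [InitialConcAnalysis-class].
#' @param ... Unused.
#' @return A `data.frame` of pairwise contrasts with adjusted p-values.
#' @export
setGeneric("contrastTable", function(x, ...) standardGeneric("contrastTable"))

#' @describeIn DecayFit-class Estimated decay constant (per hour).
#' @param object A `DecayFit`.
#' @export
setGeneric("kHat", function(object) standardGeneric("kHat"))

#' @describeIn DecayFit-class Standard error of the decay constant.
#' @export
setGeneric("seK", function(object) standardGeneric("seK"))

#' @describeIn DecayFit-class Half-life in hours.
#' @export
setGeneric("halfLifeH", function(object) standardGeneric("halfLifeH"))

#' @describeIn DecayFit-class Half-life confidence interval in hours.
#' @export
setGeneric("halfLifeCiH", function(object) standardGeneric("halfLifeCiH"))

#' @describeIn StandardCurve-class Amplification efficiency as a fraction.
#' @param object A `StandardCurve`.
#' @export
setGeneric("efficiency", function(object) standardGeneric("efficiency"))

#' @describeIn AgeEstimate-class Estimated hours since release.
#' @param object An `AgeEstimate`.
#' @export
setGeneric("tHat", function(object) standardGeneric("tHat"))
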