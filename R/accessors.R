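#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname DecayFit-class
#' @export
setMethod("kHat", "DecayFit", function(object) object@kHat)

#' @rdname DecayFit-class
#' @export
setMethod("seK", "DecayFit", function(object) object@seK)

#' @rdname DecayFit-class
#' @export
setMethod("halfLifeH", "DecayFit", function(object) object@halfLifeH)

#' @rdname DecayFit-class
#' @export
setMethod("halfLifeCiH", "DecayFit", function(object) object@halfLifeCiH)

#' @rdname StandardCurve-class
#' @export
setMethod("efficiency", "StandardCurve", function(object) object@efficiency)

#' @rdname AgeEstimate-class
#' @export
setMethod("tHat", "AgeEstimate", function(object) object@tHat)

#' @rdname resultsTable
#' @export
setMethod("resultsTable", "DecayAnalysis", function(x, ...) x@table)

#' @rdname resultsTable
#' @export
setMethod("resultsTable", "InitialConcAnalysis", function(x, ...) x@table)

#' @rdname contrastTable
#' @export
setMethod("contrastTable", "DecayAnalysis", function(x, ...) x@contrasts)

#' @rdname contrastTable
#' @export
setMethod("contrastTable", "InitialConcAnalysis", function(x, ...) x@contrasts)

setMethod("show", "GeneTarget", function(object) {
  cat(sprintf("GeneTarget %s [%s, %s, %d bp, %s]\n",
              object@name, object@genome, object@rnaClass,
              object@ampliconLength, object@nucleicAcid))
})

setMethod("show", "ConcentrationSeries", function(object) {
  cat(sprintf("ConcentrationSeries: tank %s, target %s_%s\n",
              object@tankId, object@target@name, object@target@nucleicAcid))
  cat(sprintf("  %d timepoints (%s h), %d censored\n",
              length(object@timeH),
              paste(range(object@timeH), collapse = "-"),
              sum(object@censored)))
})

setMethod("show", "DecayExperiment", function(object) {
  callNextMethod()
  cn <- assay(object, "censored")
  cat(sprintf("tanks: %d | measurements: %d (%d censored)\n",
              length(unique(colData(object)$tank_id)),
              sum(!is.na(cn)), sum(cn, na.rm = TRUE)))
})

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf(
    "StandardCurve: Cq = %.4f + %.4f * log10(copies)\n  efficiency %.1f%%, R2 = %.4f\n",
    object@intercept, object@slope, 100 * object@efficiency, object@r2))
})

setMethod("show", "DecayFit", function(object) {
  if (!object@estimable) {
    cat(sprintf("DecayFit [%s]: not estimable\n", object@target))
    return(invisible(NULL))
  }
  cat(sprintf(
    "DecayFit [%s]: k = %.4f +/- %.4f /h, half-life %.2f h (%.0f%% CI %.2f-%.2f), n = %d\n",
    object@target, object@kHat, object@seK, object@halfLifeH,
    100 * object@ciLevel, object@halfLifeCiH[1], object@halfLifeCiH[2],
    object@nObs))
})

setMethod("show", "DecayAnalysis", function(object) {
  cat(sprintf("DecayAnalysis (%s), window %g-%g h\n", object@method,
              object@windowH[1], object@windowH[2]))
  print(object@table, digits = 4)
  if (length(object@abundanceEffect))
    cat(sprintf("abundance effect on k: %.5f +/- %.5f per mussel per h\n",
                object@abundanceEffect[["estimate"]],
                object@abundanceEffect[["se"]]))
})

setMethod("show", "InitialConcAnalysis", function(object) {
  cat(sprintf("InitialConcAnalysis (%s)\n", object@method))
  print(object@table, digits = 4)
})

setMethod("show", "RatioSeries", function(object) {
  cat(sprintf("RatioSeries [%s] tank %s: %s / %s, %d points (%d omitted)\n",
              object@kind, object@tankId, object@numerator,
              object@denominator, length(object@timeH), object@nOmitted))
})

setMethod("show", "RatioRegression", function(object) {
  cat(sprintf(
    "RatioRegression: slope %.6f +/- %.6f log10/h, intercept %.3f, R2 = %.3f, p = %.3g, n = %d\n",
    object@slope, object@slopeSe, object@intercept, object@r2,
    object@pValue, object@n))
})

setMethod("show", "AgeEstimate", function(object) {
  cat(sprintf("AgeEstimate: %.2f h since release (%.0f%% CI %.2f-%.2f)\n",
              object@tHat, 100 * object@level, object@ciH[1], object@ciH[2]))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d abundance treatments x %d replicates, %d timepoints, %d targets\n",
    length(object@abundances), object@replicatesPerAbundance,
    length(object@timepointsH), nrow(object@targets)))
  cat(sprintf(
    "  tank_sd %.2f, noise_sd %.2f, LOD %.3g copies/mL, seed %d%s\n",
    object@tankSd, object@noiseSd, object@lodCopiesPerMl, object@seed,
    if (length(object@biphasic)) ", biphasic" else ""))
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: %d tank x target parameter sets, latent %d x %d\n",
              nrow(object@params), nrow(object@latent), ncol(object@latent)))
})
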