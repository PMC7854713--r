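#' @include AllClasses.R
NULL

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of quantification cycle (Cq) on log10 template
#' copies per reaction across a serial dilution (conventionally 10^6 down to
#' 1 copy/reaction). The amplification efficiency implied by the slope is
#' `10^(-1/slope) - 1`; a perfectly efficient reaction doubles template each
#' cycle, i.e. slope `-log2(10) = -3.321928` and efficiency 1.
#'
#' @param copies Template copies per reaction at each dilution point (> 0).
#' @param cq Measured Cq at each point.
#' @return A [StandardCurve-class].
#' @examples
#' sc <- fitStandardCurve(10^(0:5), 40 - 3.321928 * (0:5))
#' efficiency(sc)  # 1
#' @export
fitStandardCurve <- function(copies, cq) {
  if (length(copies) != length(cq))
    stop("'copies' and 'cq' must have equal length")
  keep <- !is.na(copies) & !is.na(cq)
  copies <- copies[keep]; cq <- cq[keep]
  if (any(copies <= 0)) stop("'copies' must be positive")
  if (length(unique(copies)) < 3L)
    stop("insufficient data: need >= 3 distinct dilution levels")
  lc <- log10(copies)
  fit <- stats::lm(cq ~ lc)
  slope <- unname(stats::coef(fit)[2])
  if (is.na(slope) || slope >= 0)
    stop("invalid curve: slope must be negative (more template, earlier Cq)")
  r2 <- suppressWarnings(summary(fit))$r.squared  # exact curves warn
  new("StandardCurve", slope = slope,
      intercept = unname(stats::coef(fit)[1]),
      r2 = r2, efficiency = 10^(-1 / slope) - 1)
}

#' Convert Cq values to copies per reaction
#'
#' Inverts the standard curve: `copies = 10^((cq - intercept)/slope)`.
#' Strictly decreasing in Cq; a Cq lower by one slope magnitude corresponds
#' to tenfold more template. Absent Cq values (no amplification) give `NA`,
#' the censored marker, not a number.
#'
#' @param cq Numeric Cq values; `NA` = no amplification.
#' @param curve A [StandardCurve-class].
#' @return Copies per reaction, `NA` where censored.
#' @export
cqToCopies <- function(cq, curve) {
  stopifnot(is(curve, "StandardCurve"))
  validObject(curve)
  10^((cq - curve@intercept) / curve@slope)
}

#' Convert copies per reaction to Cq
#'
#' Forward evaluation of the standard curve,
#' `cq = intercept + slope * log10(copies)`; inverse of [cqToCopies()].
#'
#' @param copies Copies per reaction (> 0).
#' @param curve A [StandardCurve-class].
#' @return Predicted Cq values.
#' @export
copiesToCq <- function(copies, curve) {
  stopifnot(is(curve, "StandardCurve"))
  if (any(copies <= 0, na.rm = TRUE)) stop("'copies' must be positive")
  curve@intercept + curve@slope * log10(copies)
}

#' Apply the detection-limit censoring rule
#'
#' Flags as censored every record whose Cq exceeds the detection threshold
#' (default 35 cycles) and every record with no amplification (absent Cq).
#' Quantifiable detections are left untouched; the flags propagate so that
#' the decay-fitting stage owns the exclusion decision. Idempotent.
#'
#' @param records `data.frame` with at least a `cq` column (`NA` = no
#'   amplification); typically also `sample` and `gene`.
#' @param thresholdCq Censoring threshold in cycles (> 0), default 35.
#' @return `records` with a logical `censored` column added (or overwritten),
#'   with the censored/retained counts logged.
#' @examples
#' rec <- data.frame(sample = c("a", "b", "c"), cq = c(34.9, 35.1, NA))
#' applyDetectionLimit(rec)$censored  # FALSE TRUE TRUE
#' @export
applyDetectionLimit <- function(records, thresholdCq = 35) {
  if (!is.data.frame(records) || !"cq" %in% colnames(records))
    stop("'records' must be a data.frame with a 'cq' column")
  if (thresholdCq <= 0) stop("'thresholdCq' must be positive")
  if (any(records$cq <= 0, na.rm = TRUE))
    stop("Cq values must be positive where present")
  records$censored <- is.na(records$cq) | records$cq > thresholdCq
  .log("detection limit Cq > %g: %d censored, %d retained", thresholdCq,
       sum(records$censored), sum(!records$censored))
  records
}

#' Bridge copies per reaction to copies per mL of sampled water
#'
#' `copies_per_ml = copies_per_reaction / volumeFactor`, where `volumeFactor`
#' is the mL-equivalents of filtered water represented in one reaction. The
#' default 5/3 mL/reaction encodes the documented processing chain: 100 mL of
#' water filtered, half the filter extracted (50 mL), eluted in 75 uL, of
#' which 2.5 uL template per reaction: 50 * 2.5 / 75 = 5/3.
#'
#' @param copies Copies per reaction.
#' @param volumeFactor mL of water per reaction (> 0).
#' @return Copies per mL.
#' @export
copiesPerReactionToPerMl <- function(copies, volumeFactor = 5 / 3) {
  if (!is.numeric(volumeFactor) || length(volumeFactor) != 1L ||
      is.na(volumeFactor) || volumeFactor <= 0)
    stop("'volumeFactor' must be a single positive number")
  copies / volumeFactor
}
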