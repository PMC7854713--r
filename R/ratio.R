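#' @include constructors.R simulate.R inference.R
NULL

.LN10 <- log(10)

# pairing rules: RD matches RNA over DNA for the same gene fragment;
# SL matches the shorter over the longer amplicon within a gene family
# (label prefix before "_") and nucleic acid
.ratioPairs <- function(rd, kind) {
  rd <- as.data.frame(rd)
  rd$label <- rownames(rd)
  pairs <- list()
  if (kind == "RD") {
    for (g in unique(rd$gene)) {
      num <- rd$label[rd$gene == g & rd$nucleic_acid == "RNA"]
      den <- rd$label[rd$gene == g & rd$nucleic_acid == "DNA"]
      if (length(num) == 1L && length(den) == 1L)
        pairs[[g]] <- c(num = num, den = den)
    }
  } else {
    fam <- sub("_.*$", "", rd$gene)
    for (f in unique(fam)) for (na in unique(rd$nucleic_acid)) {
      sel <- rd[fam == f & rd$nucleic_acid == na, , drop = FALSE]
      if (nrow(sel) < 2L) next
      sel <- sel[order(sel$amplicon_length), , drop = FALSE]
      for (i in seq_len(nrow(sel) - 1L)) for (j in seq(i + 1L, nrow(sel)))
        pairs[[sprintf("%s_%s_%dv%d", f, na, sel$amplicon_length[i],
                       sel$amplicon_length[j])]] <-
          c(num = sel$label[i], den = sel$label[j])
    }
  }
  pairs
}

#' Build marker-ratio time series
#'
#' Computes, per tank, the pointwise log10 ratio of two markers measured in
#' the same water samples: `kind = "RD"` pairs eRNA over eDNA for each gene
#' fragment assayed as both nucleic acids; `kind = "SL"` pairs the short over
#' the long amplicon within a gene family and nucleic acid. A timepoint
#' contributes a point only when both pair members are quantified detections
#' in the same sample; timepoints lost to censoring (or missing measurement)
#' of either member are omitted and counted in `nOmitted`.
#'
#' @param de A [DecayExperiment-class].
#' @param kind `"RD"` (RNA:DNA) or `"SL"` (short:long).
#' @param genes Optional character vector restricting the gene fragments (for
#'   `"RD"`) or families (for `"SL"`) that are paired.
#' @return A [S4Vectors::SimpleList] of [RatioSeries-class], one per
#'   (tank, pair) with the pair in the name; tanks with no common detections
#'   yield an empty series with a warning.
#' @examples
#' de <- simulateExperiment(defaultSimConfig(seed = 1))
#' rs <- buildRatioSeries(de, "RD", genes = "16S_141")
#' rs[[1]]
#' @export
buildRatioSeries <- function(de, kind = c("RD", "SL"), genes = NULL) {
  stopifnot(is(de, "DecayExperiment"))
  kind <- match.arg(kind)
  pairs <- .ratioPairs(rowData(de), kind)
  if (!is.null(genes)) {
    keepers <- vapply(names(pairs), function(nm)
      any(startsWith(nm, genes)), logical(1))
    pairs <- pairs[keepers]
  }
  if (!length(pairs)) stop("no ", kind, " pairs available in this experiment")
  cp <- assay(de, "copies")
  cn <- assay(de, "censored")
  cd <- colData(de)
  out <- list()
  for (pn in names(pairs)) {
    ri <- match(pairs[[pn]][["num"]], rownames(de))
    rj <- match(pairs[[pn]][["den"]], rownames(de))
    for (tk in unique(cd$tank_id)) {
      js <- which(cd$tank_id == tk)
      js <- js[order(cd$time_h[js])]
      measured <- js[!is.na(cn[ri, js]) | !is.na(cn[rj, js])]
      both <- js[!is.na(cn[ri, js]) & !cn[ri, js] &
                 !is.na(cn[rj, js]) & !cn[rj, js]]
      if (!length(both))
        warning(sprintf("tank %s, pair %s: no common detections", tk, pn))
      out[[paste(tk, pn, sep = ".")]] <- new(
        "RatioSeries", tankId = tk, kind = kind,
        numerator = pairs[[pn]][["num"]], denominator = pairs[[pn]][["den"]],
        timeH = unname(cd$time_h[both]),
        log10Ratio = unname(log10(cp[ri, both] / cp[rj, both])),
        nOmitted = length(measured) - length(both))
    }
  }
  S4Vectors::SimpleList(out)
}

#' Pooled regression of log10 marker ratio on time
#'
#' Ordinary least squares of the log10 ratio on time, pooled across tanks
#' (the convention used when the degradation trend itself is the estimand).
#' For markers following first-order decay with constants `k_num` and
#' `k_den`, the expected slope is `-(k_num - k_den)/ln(10)` log10 units per
#' hour, so an RNA:DNA ratio declines and its slope measures the
#' differential decay rate.
#'
#' @param rs A [RatioSeries-class], a list/`SimpleList` of them, or a
#'   `data.frame` with columns `time_h` and `log10_ratio`.
#' @return A [RatioRegression-class]. Requires at least 3 pooled points
#'   spanning at least 2 distinct times. On an exact fit (zero residual) the
#'   slope p-value is 0 by convention (1 if the slope is also 0), and a
#'   constant response gives r2 = 0.
#' @export
regressRatio <- function(rs) {
  if (is(rs, "RatioSeries")) rs <- list(rs)
  if (is.data.frame(rs)) {
    dat <- data.frame(time_h = rs$time_h, y = rs$log10_ratio)
  } else {
    dat <- do.call(rbind, lapply(rs, function(s)
      data.frame(time_h = s@timeH, y = s@log10Ratio)))
  }
  dat <- dat[is.finite(dat$y) & is.finite(dat$time_h), , drop = FALSE]
  if (nrow(dat) < 3L)
    stop("need at least 3 pooled ratio points")
  if (length(unique(dat$time_h)) < 2L)
    stop("degenerate time span: need at least 2 distinct times")
  if (stats::sd(dat$y) <= 1e-12) {
    # exactly constant ratio (equal decay constants, no noise)
    return(new("RatioRegression", slope = 0, slopeSe = 0,
               intercept = mean(dat$y), interceptSe = 0, r2 = 0,
               pValue = 1, n = nrow(dat)))
  }
  fit <- stats::lm(y ~ time_h, data = dat)
  sm <- suppressWarnings(summary(fit))  # exact fits trip a summary.lm warning
  co <- sm$coefficients
  slope <- co["time_h", "Estimate"]
  slope_se <- co["time_h", "Std. Error"]
  p <- co["time_h", "Pr(>|t|)"]
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- 0           # constant response
  if (!is.finite(p)) p <- if (slope == 0) 1 else 0  # exact fit
  new("RatioRegression", slope = slope, slopeSe = slope_se,
      intercept = co["(Intercept)", "Estimate"],
      interceptSe = co["(Intercept)", "Std. Error"],
      r2 = r2, pValue = p, n = nrow(dat))
}

#' Age of genomic material from the eRNA:eDNA ratio
#'
#' Inverts first-order differential decay into time since release. If RNA
#' and DNA copies of the same gene region decay with constants `kRna > kDna`,
#' the log10 RNA:DNA ratio falls linearly at rate `(kRna - kDna)/ln(10)` per
#' hour, so an observed ratio dates the material:
#' \deqn{\hat t = \ln(10) (baseline - observed) / (k_{RNA} - k_{DNA})}
#' Uncertainty is propagated by a parametric bootstrap: Normal draws of the
#' two decay constants, the baseline and the observed ratio from their
#' standard errors, with draws violating `kRna > kDna` discarded and ages
#' clamped at 0; the interval is the percentile interval of the resampled
#' ages. The estimator assumes a single release pulse; mixtures of material
#' of different ages shift the ratio toward the freshest component.
#'
#' @param observed Observed log10 RNA:DNA ratio of the sample.
#' @param baseline log10 RNA:DNA ratio at release (from a calibration
#'   experiment, e.g. the intercept of [regressRatio()]).
#' @param kRna,kDna Decay constants (per hour); `kRna > kDna` required.
#' @param seKRna,seKDna,seBaseline,seObserved Standard errors; zero (the
#'   default) treats the input as known.
#' @param level Confidence level of the interval.
#' @param nboot Bootstrap draws, default 2000.
#' @param seed Seed for the bootstrap; the caller's RNG state is preserved.
#' @return An [AgeEstimate-class]. An observed ratio above baseline (fresh
#'   material within noise) returns age 0 with a warning.
#' @examples
#' estimateAge(observed = 1, baseline = 3, kRna = 0.0561, kDna = 0.0378)
#' @export
estimateAge <- function(observed, baseline, kRna, kDna,
                        seKRna = 0, seKDna = 0, seBaseline = 0,
                        seObserved = 0, level = 0.95, nboot = 2000,
                        seed = 1) {
  observed <- unname(observed); baseline <- unname(baseline)
  kRna <- unname(kRna); kDna <- unname(kDna)
  dk <- kRna - kDna
  if (!is.finite(dk) || dk <= 0)
    stop("clock undefined: kRna must exceed kDna")
  if (observed > baseline) {
    warning("observed ratio above baseline; returning age 0 ",
            "(fresh material within noise)")
    t_hat <- 0
  } else {
    t_hat <- .LN10 * (baseline - observed) / dk
  }
  ses <- c(seKRna, seKDna, seBaseline, seObserved)
  if (any(ses < 0)) stop("standard errors must be >= 0")
  n_dropped <- 0L
  if (any(ses > 0)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      old_seed <- get(".Random.seed", globalenv())
      on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    }
    set.seed(seed)
    kr <- stats::rnorm(nboot, kRna, seKRna)
    kd <- stats::rnorm(nboot, kDna, seKDna)
    bb <- stats::rnorm(nboot, baseline, seBaseline)
    oo <- stats::rnorm(nboot, observed, seObserved)
    dkb <- kr - kd
    keep <- dkb > 0
    n_dropped <- sum(!keep)
    tb <- pmax(0, .LN10 * (bb[keep] - oo[keep]) / dkb[keep])
    ci <- unname(stats::quantile(tb, c((1 - level) / 2, 1 - (1 - level) / 2)))
    # numeric guard: the point estimate must sit inside its own interval
    ci <- c(min(ci[1], t_hat), max(ci[2], t_hat))
  } else {
    ci <- c(t_hat, t_hat)
  }
  new("AgeEstimate", tHat = t_hat, ciH = ci, level = level,
      inputs = list(observed = observed, baseline = baseline, kRna = kRna,
                    kDna = kDna, deltaK = dk, seKRna = seKRna,
                    seKDna = seKDna, seBaseline = seBaseline,
                    seObserved = seObserved, nboot = nboot,
                    nDropped = n_dropped))
}

#' Monte-Carlo validation of the ratio age clock
#'
#' Repeatedly simulates a calibration experiment, fits the RNA and DNA decay
#' constants of one gene region with the two-stage estimator, then dates a
#' fresh water sample of known age drawn from the same generative model and
#' scores the age estimate. The release-time baseline ratio is taken as
#' known (the prospective-use calibration; within the generative model it is
#' abundance- and tank-invariant because shared effects cancel in the
#' ratio), while the observed sample ratio carries measurement noise whose
#' standard error is propagated through the bootstrap together with the
#' decay-constant standard errors.
#'
#' @param config A [SimConfig-class] containing both nucleic acids of
#'   `gene`, with `kRna > kDna`.
#' @param sampleTimes True ages (hours) at which test samples are drawn.
#' @param reps Simulated calibration experiments.
#' @param seed Root seed; the study is deterministic given it.
#' @param gene Gene fragment label of the RNA/DNA pair, default `"16S_141"`.
#' @param excludeTankIds Tanks removed before each calibration fit.
#' @param nboot Bootstrap draws per age estimate.
#' @param level Confidence level scored for coverage.
#' @return A `data.frame` with one row per true age: `true_age_h`, `bias_h`,
#'   `rmse_h`, `coverage`, `reps`.
#' @export
ageRecoveryStudy <- function(config, sampleTimes = c(12, 24, 48, 72),
                             reps = 200, seed = 1, gene = "16S_141",
                             excludeTankIds = character(), nboot = 500,
                             level = 0.95) {
  stopifnot(is(config, "SimConfig"))
  tg <- config@targets
  sel <- tg$gene == gene
  if (sum(sel & tg$nucleic_acid == "RNA") != 1L ||
      sum(sel & tg$nucleic_acid == "DNA") != 1L)
    stop("config must contain exactly one RNA and one DNA target for gene ",
         gene)
  cfg <- config
  cfg@targets <- tg[sel, , drop = FALSE]
  kr_true <- cfg@targets$k[cfg@targets$nucleic_acid == "RNA"]
  kd_true <- cfg@targets$k[cfg@targets$nucleic_acid == "DNA"]
  if (is.na(kr_true)) kr_true <- cfg@fallbackK
  dk_true <- kr_true - kd_true
  if (dk_true <= 0) stop("config pair has no differential decay (delta k <= 0)")
  c0r <- cfg@targets$c0_log[cfg@targets$nucleic_acid == "RNA"]
  c0d <- cfg@targets$c0_log[cfg@targets$nucleic_acid == "DNA"]
  baseline_true <- (c0r - c0d) / .LN10
  se_obs <- sqrt(2) * cfg@noiseSd / .LN10
  rna_lab <- .targetLabel(gene, "RNA")
  dna_lab <- .targetLabel(gene, "DNA")

  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  op <- options(ernaclock.verbose = FALSE)
  on.exit(options(op), add = TRUE)

  res <- vector("list", reps)
  for (i in seq_len(reps)) {
    cfg_i <- cfg
    cfg_i@seed <- as.integer(.childSeed(seed, i) %% .Machine$integer.max)
    de <- simulateExperiment(cfg_i)
    if (length(excludeTankIds)) de <- excludeTanks(de, excludeTankIds)
    fit <- fitDecay(de, method = "two-stage", ciLevel = level)
    tb <- fit@table
    kr <- tb$k[tb$target == rna_lab]; ser <- tb$se[tb$target == rna_lab]
    kd <- tb$k[tb$target == dna_lab]; sed <- tb$se[tb$target == dna_lab]
    if (!length(kr) || !length(kd) || anyNA(c(kr, kd))) next
    set.seed(.childSeed(seed, 10^6 + i) %% .Machine$integer.max)
    eps <- stats::rnorm(2 * length(sampleTimes), 0, cfg@noiseSd)
    obs <- baseline_true - dk_true * sampleTimes / .LN10 +
      (eps[seq_along(sampleTimes)] -
         eps[length(sampleTimes) + seq_along(sampleTimes)]) / .LN10
    est <- lapply(seq_along(sampleTimes), function(a) {
      ae <- suppressWarnings(estimateAge(
        obs[a], baseline_true, kr, kd, seKRna = ser, seKDna = sed,
        seBaseline = 0, seObserved = se_obs, level = level, nboot = nboot,
        seed = .childSeed(seed, 10^7 + i * 17 + a) %% .Machine$integer.max))
      data.frame(true_age_h = sampleTimes[a], t_hat = ae@tHat,
                 covered = ae@ciH[1] - 1e-9 <= sampleTimes[a] &
                   sampleTimes[a] <= ae@ciH[2] + 1e-9)
    })
    res[[i]] <- do.call(rbind, est)
  }
  all <- do.call(rbind, res)
  if (is.null(all)) stop("no replicate produced an estimable pair")
  out <- do.call(rbind, lapply(split(all, all$true_age_h), function(d)
    data.frame(true_age_h = d$true_age_h[1],
               bias_h = mean(d$t_hat - d$true_age_h),
               rmse_h = sqrt(mean((d$t_hat - d$true_age_h)^2)),
               coverage = mean(d$covered), reps = nrow(d))))
  rownames(out) <- NULL
  out[order(out$true_age_h), , drop = FALSE]
}
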