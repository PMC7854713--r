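#' @include constructors.R kinetics.R
NULL

#' @rdname normalizeSeries
#' @export
setMethod("normalizeSeries", "ConcentrationSeries", function(x, ...) {
  i0 <- which(x@timeH == 0 & !x@censored)
  if (!length(i0))
    stop("series unusable for decay fitting: no detected t = 0 measurement")
  c0 <- x@copiesPerMl[i0[1]]
  if (!is.finite(c0) || c0 <= 0)
    stop("series unusable for decay fitting: C_0 must be positive")
  x@copiesPerMl <- x@copiesPerMl / c0
  validObject(x)
  x
})

#' @rdname normalizeSeries
#' @export
setMethod("normalizeSeries", "DecayExperiment", function(x, ...) {
  cs <- concentrationSeries(x)
  usable <- vapply(cs, function(s) any(s@timeH == 0 & !s@censored), logical(1))
  if (any(!usable))
    .log("dropping %d series without a detected t = 0 point", sum(!usable))
  S4Vectors::SimpleList(lapply(cs[usable], normalizeSeries))
})

# Long table of normalised log-ratios for decay fitting.
# For each (target, tank): requires a detected t = 0 point; log C0 is the
# mean log concentration over t = 0 detections (one sample per timepoint in
# the standard design). Censored points and points outside the window are
# excluded with counts.
.decayData <- function(de, windowH) {
  cp <- assay(de, "copies")
  cn <- assay(de, "censored")
  cd <- colData(de)
  tanks <- unique(cd$tank_id)
  rows <- list()
  dropped <- c(censored = 0L, outside_window = 0L, unusable_series = 0L)
  n_cens_win <- 0L
  for (r in seq_len(nrow(de))) {
    for (tk in tanks) {
      js <- which(cd$tank_id == tk & !is.na(cn[r, ]))
      if (!length(js)) next
      js <- js[order(cd$time_h[js])]
      tmj <- cd$time_h[js]
      det <- !cn[r, js]
      j0 <- js[tmj == 0 & det]
      inwin <- tmj >= windowH[1] & tmj <= windowH[2]
      n_cens_win <- n_cens_win + sum(!det & inwin)
      if (!length(j0)) {
        dropped["unusable_series"] <- dropped["unusable_series"] + 1L
        next
      }
      use <- det & inwin
      if (sum(use) < 2L) {
        dropped["unusable_series"] <- dropped["unusable_series"] + 1L
        next
      }
      dropped["censored"] <- dropped["censored"] + sum(!det & inwin)
      dropped["outside_window"] <- dropped["outside_window"] + sum(det & !inwin)
      logc0 <- mean(log(cp[r, j0]))
      sel <- js[use]
      rows[[length(rows) + 1L]] <- data.frame(
        tank_id = tk, abundance = cd$abundance[sel][1],
        gene = rownames(de)[r], time_h = cd$time_h[sel],
        y = log(cp[r, sel]) - logc0, stringsAsFactors = FALSE)
    }
  }
  list(data = if (length(rows)) do.call(rbind, rows) else
         data.frame(tank_id = character(), abundance = numeric(),
                    gene = character(), time_h = numeric(), y = numeric()),
       dropped = dropped, n_censored_in_window = n_cens_win)
}

# per-(tank, target) OLS slopes of log(Ct/C0) on time: stage one of the
# two-stage estimator
.perTankSlopes <- function(dd) {
  sp <- split(dd, list(dd$tank_id, dd$gene), drop = TRUE)
  out <- lapply(sp, function(d) {
    fit <- stats::lm(y ~ time_h, data = d)
    sm <- suppressWarnings(summary(fit))  # exact fits trip a summary warning
    data.frame(tank_id = d$tank_id[1], abundance = d$abundance[1],
               target = d$gene[1], slope = unname(stats::coef(fit)[2]),
               se = sm$coefficients[2, 2], n = nrow(d),
               sxx = sum((d$time_h - mean(d$time_h))^2),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Hartung-Knapp combination of per-tank slopes for one target: weighted mean
# with a scale estimated from the weighted slope dispersion and a t_{m-1}
# reference distribution. Weights are design-based inverse variances,
# w_i = sum((t - tbar)^2) for tank i (the OLS precision factor under a
# common residual variance): deterministic given the sampling grid, so they
# cannot correlate with the slope estimates the way residual-based weights
# do in small samples, and they reduce to equal weights on balanced designs,
# where the interval is the exact unweighted t interval.
.combineSlopes <- function(s, v, w = NULL) {
  m <- length(s)
  if (m == 1L) return(list(est = s, se = sqrt(v), df = NA_real_))
  if (is.null(w) || !all(is.finite(w)) || !all(w > 0)) w <- rep(1, m)
  est <- sum(w * s) / sum(w)
  se <- sqrt(sum(w * (s - est)^2) / ((m - 1) * sum(w)))
  list(est = est, se = se, df = m - 1)
}

.makeDecayFit <- function(target, k, se, df, level, n_obs, windowH) {
  z <- if (is.finite(df)) stats::qt(1 - (1 - level) / 2, df)
       else stats::qnorm(1 - (1 - level) / 2)
  if (!is.finite(k) || k <= 0) {
    hl <- Inf
    ci <- c(NA_real_, NA_real_)
    k <- max(k, 0)
  } else {
    hl <- halfLife(k)
    ci <- tryCatch(halfLifeInterval(k, se, z),
                   error = function(e) c(NA_real_, NA_real_))
  }
  new("DecayFit", target = target, kHat = k, seK = se,
      df = if (is.finite(df)) df else Inf, ciLevel = level, halfLifeH = hl,
      halfLifeCiH = ci, nObs = as.integer(n_obs), windowH = windowH)
}

.notEstimableFit <- function(target, windowH, level) {
  new("DecayFit", target = target, kHat = NA_real_, seK = NA_real_,
      df = NA_real_, ciLevel = level, halfLifeH = NA_real_,
      halfLifeCiH = c(NA_real_, NA_real_), nObs = 0L, windowH = windowH,
      estimable = FALSE)
}

# clean up an emmeans contrast summary into the package's contrast table.
# Zero-residual fits make p-values 0/0: exact ties are defined as p = 1,
# exact non-zero differences as p = 0.
.tidyContrasts <- function(cs, flip_sign = FALSE, adjustment = "tukey") {
  df <- as.data.frame(cs)
  est <- if (flip_sign) -df$estimate else df$estimate
  p <- df$p.value
  degenerate <- !is.finite(p) & df$SE <= 1e-10
  p[degenerate & abs(est) <= 1e-10] <- 1
  p[degenerate & abs(est) > 1e-10] <- 0
  parts <- strsplit(as.character(df$contrast), " - ", fixed = TRUE)
  data.frame(
    group_a = vapply(parts, `[`, character(1), 1),
    group_b = vapply(parts, `[`, character(1), 2),
    estimate = est, se = df$SE, adjusted_p = p,
    adjustment = adjustment, stringsAsFactors = FALSE)
}

# pairwise z contrasts with Holm adjustment from per-group (estimate, var)
.pairwiseZ <- function(groups, est, var) {
  ix <- utils::combn(seq_along(groups), 2)
  d <- est[ix[1, ]] - est[ix[2, ]]
  se <- sqrt(var[ix[1, ]] + var[ix[2, ]])
  tied <- abs(d) <= 1e-12 & se <= 1e-12   # exact ties from noiseless fits
  z <- ifelse(tied, 0, d / se)
  p <- ifelse(tied, 1, 2 * stats::pnorm(-abs(z)))
  data.frame(group_a = groups[ix[1, ]], group_b = groups[ix[2, ]],
             estimate = d, se = se,
             adjusted_p = stats::p.adjust(p, "holm"),
             adjustment = "holm", stringsAsFactors = FALSE)
}

#' Estimate initial concentrations at time zero
#'
#' Fits the release model: log_e concentration at t = 0 as a function of
#' gene target (categorical), mussel abundance (quantitative) and their
#' interaction, with a random intercept per tank ("samples nested within
#' replicate tanks"; with one water sample per tank the tank level is the
#' nesting that remains). Per-target marginal means are evaluated at the
#' mean abundance via estimated marginal means, and all pairwise target
#' contrasts are Tukey-adjusted. If the mixed fit fails (e.g. zero residual
#' variance in noiseless data), a fixed-effects linear model is used and the
#' downgrade is logged.
#'
#' @param de A [DecayExperiment-class].
#' @param ciLevel Confidence level for intervals, default 0.95.
#' @return An [InitialConcAnalysis-class]. Targets censored in every tank at
#'   t = 0 are reported as not estimable (NA rows), not as errors.
#' @export
fitInitialConcentration <- function(de, ciLevel = 0.95) {
  stopifnot(is(de, "DecayExperiment"))
  cp <- assay(de, "copies")
  cn <- assay(de, "censored")
  cd <- colData(de)
  j0 <- which(cd$time_h == 0)
  if (length(unique(cd$tank_id[j0])) < 2L)
    stop("need t = 0 samples from at least 2 tanks")
  rows <- list()
  for (r in seq_len(nrow(de))) {
    jj <- j0[!is.na(cn[r, j0]) & !cn[r, j0]]
    if (!length(jj)) next
    rows[[length(rows) + 1L]] <- data.frame(
      tank_id = cd$tank_id[jj], abundance = cd$abundance[jj],
      gene = rownames(de)[r], y = log(cp[r, jj]), stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no detected t = 0 measurements")
  dat <- do.call(rbind, rows)
  dat$gene <- factor(dat$gene, levels = rownames(de))
  multi_gene <- nlevels(droplevels(dat$gene)) > 1L
  has_ab <- length(unique(dat$abundance)) > 1L

  fe <- if (multi_gene && has_ab) "gene * abundance"
        else if (multi_gene) "gene" else if (has_ab) "abundance" else "1"
  # marginal means and Tukey contrasts for a fitted model; any failure on
  # the mixed route (degenerate variance structures) downgrades to lm
  marginals <- function(fit) {
    if (multi_gene) {
      em <- suppressMessages(
        emmeans::emmeans(fit, "gene", lmer.df = "satterthwaite"))
      es <- as.data.frame(em)
      ct <- .tidyContrasts(suppressWarnings(
        summary(emmeans::contrast(em, "pairwise", adjust = "tukey"))))
    } else {
      em <- suppressMessages(
        emmeans::emmeans(fit, "1", lmer.df = "satterthwaite"))
      es <- as.data.frame(em)
      es$gene <- levels(droplevels(dat$gene))
      ct <- data.frame()
    }
    list(es = es, contrasts = ct, fit = fit)
  }
  method <- "mixed"
  res <- tryCatch({
    fit <- suppressWarnings(suppressMessages(lme4::lmer(
      stats::as.formula(paste("y ~", fe, "+ (1 | tank_id)")), data = dat)))
    suppressWarnings(marginals(fit))
  }, error = function(e) NULL)
  if (is.null(res)) {
    method <- "fixed"
    .log("mixed model failed at t = 0; falling back to fixed-effects lm")
    fit <- stats::lm(stats::as.formula(paste("y ~", fe)), data = dat)
    res <- suppressWarnings(marginals(fit))
  }
  fit <- res$fit
  es <- res$es
  contrasts <- res$contrasts
  rdm <- as.data.frame(rowData(de))
  m <- match(as.character(es$gene), rownames(de))
  tab <- data.frame(
    target = as.character(es$gene), gene = rdm$gene[m],
    genome = rdm$genome[m], rna_class = rdm$rna_class[m],
    amplicon_length = rdm$amplicon_length[m],
    nucleic_acid = rdm$nucleic_acid[m],
    estimate = es$emmean, se = es$SE, df = es$df,
    estimable = TRUE, stringsAsFactors = FALSE)
  # targets with no detected t = 0 measurement anywhere: not estimable
  missing_t <- setdiff(rownames(de), tab$target)
  if (length(missing_t)) {
    m2 <- match(missing_t, rownames(de))
    tab <- rbind(tab, data.frame(
      target = missing_t, gene = rdm$gene[m2], genome = rdm$genome[m2],
      rna_class = rdm$rna_class[m2],
      amplicon_length = rdm$amplicon_length[m2],
      nucleic_acid = rdm$nucleic_acid[m2], estimate = NA_real_,
      se = NA_real_, df = NA_real_, estimable = FALSE,
      stringsAsFactors = FALSE))
  }
  tab <- tab[match(rownames(de), tab$target), , drop = FALSE]
  rownames(tab) <- NULL

  abEff <- c(estimate = NA_real_, se = NA_real_)
  if (has_ab) {
    co <- if (method == "mixed") lme4::fixef(fit) else stats::coef(fit)
    vc <- suppressWarnings(as.matrix(stats::vcov(fit)))  # exact-fit warning
    if ("abundance" %in% names(co))
      abEff <- c(estimate = unname(co[["abundance"]]),
                 se = sqrt(vc["abundance", "abundance"]))
  }
  new("InitialConcAnalysis", table = tab, abundanceEffect = abEff,
      contrasts = contrasts, method = method)
}

#' Fit first-order decay constants from censored concentration series
#'
#' Estimates per-target decay constants from the log-linear phase of
#' normalised concentration series, `log_e(C_t/C_0)` regressed on time. Two
#' estimation routes are available:
#'
#' * `method = "mixed"` (default): one linear mixed-effect model across all
#'   targets with time as a continuous fixed effect, gene target and mussel
#'   abundance (quantitative) as fixed effects, the two-way interactions of
#'   time with gene and with abundance, the gene x abundance interaction, and
#'   a random intercept per tank. Per-target decay constants are the negated
#'   marginal time trends (evaluated at the mean abundance) with
#'   Tukey-adjusted pairwise comparisons. Falls back to `"two-stage"` with a
#'   logged downgrade if the mixed fit fails.
#' * `method = "two-stage"`: an ordinary least-squares slope per tank and
#'   target, combined across tanks by a Hartung-Knapp weighted t procedure
#'   (inverse-variance weights, dispersion-based scale, t with m - 1 degrees
#'   of freedom). On balanced designs this is the exact unweighted t
#'   interval for the mean tank slope, which gives it known small-sample
#'   calibration.
#'
#' Censoring policy follows the source experiment: non-detects are excluded
#' from the fit (`censorPolicy = "drop"`), which biases k upward when the
#' series truncates at the detection limit within the window; no correction
#' is applied. `censorPolicy = "refuse"` errors on any censored point in the
#' window instead. Series without a detected t = 0 point, or with fewer than
#' 2 usable detections in the window, are skipped; targets with no usable
#' series are reported not-estimable.
#'
#' @param de A [DecayExperiment-class].
#' @param windowH Fitted time window in hours, default `c(0, 72)` (the
#'   log-linear phase; later times often show biphasic slowing).
#' @param censorPolicy `"drop"` (default) or `"refuse"`.
#' @param method `"mixed"` (default) or `"two-stage"`.
#' @param ciLevel Confidence level, default 0.95.
#' @return A [DecayAnalysis-class].
#' @examples
#' cfg <- defaultSimConfig(seed = 3)
#' de <- simulateExperiment(cfg)
#' fit <- fitDecay(de, method = "two-stage")
#' resultsTable(fit)
#' @export
fitDecay <- function(de, windowH = c(0, 72),
                     censorPolicy = c("drop", "refuse"),
                     method = c("mixed", "two-stage"), ciLevel = 0.95) {
  stopifnot(is(de, "DecayExperiment"))
  censorPolicy <- match.arg(censorPolicy)
  method <- match.arg(method)
  stopifnot(length(windowH) == 2L, windowH[1] < windowH[2])

  dd <- .decayData(de, windowH)
  if (censorPolicy == "refuse" && dd$n_censored_in_window > 0L)
    stop(sprintf(
      "censorPolicy = 'refuse': %d censored point(s) inside the window",
      dd$n_censored_in_window))
  dat <- dd$data
  if (nrow(dat) == 0L) stop("no usable series in the window")
  .log("decay fit: %d points, dropped %d censored / %d outside window / %d unusable series",
       nrow(dat), dd$dropped["censored"], dd$dropped["outside_window"],
       dd$dropped["unusable_series"])

  targets <- rownames(de)
  dat$gene <- factor(dat$gene, levels = targets)
  per_tank <- .perTankSlopes(dat)
  level <- ciLevel
  n_by_target <- table(factor(dat$gene, levels = targets))

  est_tab <- NULL
  contrasts <- data.frame()
  abEff <- c(estimate = NA_real_, se = NA_real_)
  has_ab <- length(unique(dat$abundance)) > 1L
  multi_gene <- nlevels(droplevels(dat$gene)) > 1L

  if (method == "mixed") {
    fe <- c("time_h")
    if (multi_gene) fe <- c(fe, "gene", "time_h:gene")
    if (has_ab) fe <- c(fe, "abundance", "time_h:abundance")
    if (multi_gene && has_ab) fe <- c(fe, "gene:abundance")
    form <- stats::as.formula(
      paste("y ~", paste(fe, collapse = " + "), "+ (1 | tank_id)"))
    mixed <- tryCatch({
      fit <- suppressWarnings(suppressMessages(lme4::lmer(form, data = dat)))
      if (multi_gene) {
        et <- suppressWarnings(suppressMessages(emmeans::emtrends(
          fit, "gene", var = "time_h", lmer.df = "satterthwaite")))
        es <- as.data.frame(et)
        ct <- .tidyContrasts(suppressWarnings(
          summary(emmeans::contrast(et, "pairwise", adjust = "tukey"))),
          flip_sign = TRUE)
      } else {
        et <- suppressWarnings(suppressMessages(emmeans::emtrends(
          fit, "1", var = "time_h", lmer.df = "satterthwaite")))
        es <- as.data.frame(et)
        es$gene <- levels(droplevels(dat$gene))
        ct <- data.frame()
      }
      list(fit = fit, es = es, contrasts = ct)
    }, error = function(e) NULL)
    if (is.null(mixed)) {
      .log("mixed decay model failed; downgrading to the two-stage estimator")
      method <- "two-stage"
    } else {
      contrasts <- mixed$contrasts
      est_tab <- data.frame(target = as.character(mixed$es$gene),
                            k = -mixed$es$time_h.trend, se = mixed$es$SE,
                            df = mixed$es$df, stringsAsFactors = FALSE)
      if (has_ab) {
        co <- lme4::fixef(mixed$fit)
        vc <- suppressWarnings(as.matrix(stats::vcov(mixed$fit)))
        nm <- intersect(c("time_h:abundance", "abundance:time_h"), names(co))
        if (length(nm))
          abEff <- c(estimate = -unname(co[[nm[1]]]),
                     se = sqrt(vc[nm[1], nm[1]]))
      }
    }
  }

  if (method == "two-stage") {
    est_tab <- do.call(rbind, lapply(
      split(per_tank, factor(per_tank$target, levels = targets), drop = TRUE),
      function(g) {
        cmb <- .combineSlopes(g$slope, g$se^2, w = g$sxx)
        data.frame(target = g$target[1], k = -cmb$est, se = cmb$se,
                   df = if (is.na(cmb$df)) g$n[1] - 2 else cmb$df,
                   stringsAsFactors = FALSE)
      }))
    rownames(est_tab) <- NULL
    if (multi_gene) {
      v <- est_tab$se^2
      contrasts <- .pairwiseZ(est_tab$target, est_tab$k, v)
    }
    if (has_ab) {
      pt <- per_tank
      pt$neg_slope <- -pt$slope
      ab_form <- if (multi_gene) neg_slope ~ target + abundance
                 else neg_slope ~ abundance
      af <- stats::lm(ab_form, data = pt)
      sm <- suppressWarnings(summary(af))$coefficients
      if ("abundance" %in% rownames(sm))
        abEff <- c(estimate = sm["abundance", 1], se = sm["abundance", 2])
    }
  }

  fits <- lapply(targets, function(tg) {
    row <- est_tab[est_tab$target == tg, , drop = FALSE]
    if (nrow(row) == 0L || !is.finite(row$k))
      .notEstimableFit(tg, windowH, level)
    else .makeDecayFit(tg, row$k, row$se, row$df, level,
                       n_by_target[[tg]], windowH)
  })
  names(fits) <- targets

  rdm <- as.data.frame(rowData(de))
  tab <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(
      target = f@target, gene = rdm$gene[i], genome = rdm$genome[i],
      rna_class = rdm$rna_class[i], amplicon_length = rdm$amplicon_length[i],
      nucleic_acid = rdm$nucleic_acid[i],
      k = if (f@estimable) f@kHat else NA_real_,
      se = if (f@estimable) f@seK else NA_real_,
      df = if (f@estimable) f@df else NA_real_,
      half_life_h = if (f@estimable) f@halfLifeH else NA_real_,
      half_life_lower_h = f@halfLifeCiH[1],
      half_life_upper_h = f@halfLifeCiH[2],
      n_obs = f@nObs, estimable = f@estimable, stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL

  new("DecayAnalysis", fits = S4Vectors::SimpleList(fits), table = tab,
      abundanceEffect = abEff, contrasts = contrasts, method = method,
      windowH = as.numeric(windowH), nDropped = dd$dropped,
      perTank = per_tank)
}

#' Pairwise group contrasts on fitted decay constants or release levels
#'
#' Compares estimates between levels of a target attribute (amplicon
#' fragment length, genomic origin, nucleic acid, RNA class) or between
#' abundance treatments. Attribute groups pool the per-target estimates of
#' their members (mean, with variances propagated assuming independence) and
#' are compared with pairwise z tests under Holm adjustment; results are
#' reported in one direction only (antisymmetric in pair order). Exact ties
#' are defined as p = 1. For `grouping = "abundance"` on a
#' [DecayAnalysis-class], per-tank slopes are grouped by tank abundance and
#' compared the same way.
#'
#' To reproduce a within-gene comparison (e.g. RNA vs DNA for one gene
#' region), fit only the targets of interest or subset before calling.
#'
#' @param x A [DecayAnalysis-class] or [InitialConcAnalysis-class].
#' @param grouping One of `"target"`, `"fragment_length"`, `"genome"`,
#'   `"nucleic_acid"`, `"rna_class"`, `"abundance"`.
#' @return `data.frame` with columns `group_a`, `group_b`, `estimate`
#'   (difference on the analysis scale: per-hour k for decay, log_e
#'   concentration for release), `se`, `adjusted_p`, `adjustment`. A single
#'   group yields an empty result with a warning.
#' @export
pairwiseContrasts <- function(x, grouping = c("target", "fragment_length",
                                              "genome", "nucleic_acid",
                                              "rna_class", "abundance")) {
  grouping <- match.arg(grouping)
  if (!(is(x, "DecayAnalysis") || is(x, "InitialConcAnalysis")))
    stop("'x' must be a DecayAnalysis or InitialConcAnalysis")
  tab <- x@table
  empty <- data.frame(group_a = character(), group_b = character(),
                      estimate = numeric(), se = numeric(),
                      adjusted_p = numeric(), adjustment = character())

  if (grouping == "abundance") {
    if (!is(x, "DecayAnalysis"))
      stop("'abundance' contrasts need per-tank slopes (a DecayAnalysis)")
    pt <- x@perTank
    gs <- split(pt, pt$abundance)
    if (length(gs) < 2L) {
      warning("fewer than 2 abundance groups; nothing to contrast")
      return(empty)
    }
    est <- vapply(gs, function(g) mean(-g$slope), numeric(1))
    varc <- vapply(gs, function(g)
      stats::var(-g$slope) / nrow(g), numeric(1))
    varc[is.na(varc)] <- 0
    return(.pairwiseZ(names(gs), est, varc))
  }

  col <- switch(grouping, target = "target",
                fragment_length = "amplicon_length", genome = "genome",
                nucleic_acid = "nucleic_acid", rna_class = "rna_class")
  est_col <- if (is(x, "DecayAnalysis")) "k" else "estimate"
  ok <- tab$estimable & is.finite(tab[[est_col]])
  tab <- tab[ok, , drop = FALSE]
  gs <- split(tab, tab[[col]])
  if (length(gs) < 2L) {
    warning("fewer than 2 groups under grouping '", grouping,
            "'; nothing to contrast")
    return(empty)
  }
  est <- vapply(gs, function(g) mean(g[[est_col]]), numeric(1))
  varc <- vapply(gs, function(g) sum(g$se^2) / nrow(g)^2, numeric(1))
  .pairwiseZ(names(gs), est, varc)
}

#' Monte-Carlo recovery study for the decay constant
#'
#' Repeatedly simulates an experiment, optionally excludes tanks (mirroring
#' the removal of compromised replicates), fits the decay model and records
#' the estimate and confidence interval for one target, to quantify bias and
#' interval coverage of the estimator under known truth.
#'
#' @param config A [SimConfig-class]; the study re-seeds it per replicate
#'   from `seed`.
#' @param target Target label (rowname) to track; defaults to the first.
#' @param reps Number of simulated experiments.
#' @param seed Root seed of the study.
#' @param excludeTankIds Tanks removed before fitting each replicate.
#' @param windowH,method,ciLevel Passed to [fitDecay()]; the two-stage
#'   estimator is the default here for its exact small-sample t calibration
#'   on balanced designs.
#' @return A list: `reps` (`data.frame` of k_hat, se, ci_lo, ci_hi, covered),
#'   `summary` (truth, mean k_hat, Monte-Carlo SE of the mean, empirical SD,
#'   coverage), and `truth`.
#' @export
decayRecoveryStudy <- function(config, target = NULL, reps = 100,
                               seed = 1, excludeTankIds = character(),
                               windowH = c(0, 72), method = "two-stage",
                               ciLevel = 0.95) {
  stopifnot(is(config, "SimConfig"))
  tg <- config@targets
  tlab <- .targetLabel(tg$gene, tg$nucleic_acid)
  if (is.null(target)) target <- tlab[1]
  gi <- match(target, tlab)
  if (is.na(gi)) stop("unknown target: ", target)
  k_true <- tg$k[gi]
  if (is.na(k_true)) k_true <- config@fallbackK

  out <- matrix(NA_real_, reps, 4,
                dimnames = list(NULL, c("k_hat", "se", "ci_lo", "ci_hi")))
  op <- options(ernaclock.verbose = FALSE); on.exit(options(op))
  for (i in seq_len(reps)) {
    cfg <- config
    cfg@seed <- as.integer(.childSeed(seed, i) %% .Machine$integer.max)
    de <- simulateExperiment(cfg)
    if (length(excludeTankIds)) de <- excludeTanks(de, excludeTankIds)
    fit <- fitDecay(de, windowH = windowH, method = method,
                    ciLevel = ciLevel)
    row <- fit@table[fit@table$target == target, ]
    if (!row$estimable) next
    zq <- stats::qt(1 - (1 - ciLevel) / 2, row$df)
    out[i, ] <- c(row$k, row$se, row$k - zq * row$se, row$k + zq * row$se)
  }
  reps_df <- as.data.frame(out)
  reps_df$covered <- reps_df$ci_lo <= k_true & k_true <= reps_df$ci_hi
  ok <- stats::complete.cases(reps_df)
  summ <- data.frame(
    target = target, truth = k_true, reps = sum(ok),
    mean_k_hat = mean(reps_df$k_hat[ok]),
    mc_se = stats::sd(reps_df$k_hat[ok]) / sqrt(sum(ok)),
    sd_k_hat = stats::sd(reps_df$k_hat[ok]),
    coverage = mean(reps_df$covered[ok]))
  list(reps = reps_df, summary = summ, truth = k_true)
}
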