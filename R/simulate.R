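#' @include constructors.R
NULL

#' Construct a simulation configuration
#'
#' See [SimConfig-class] for the meaning of every field. Defaults describe a
#' small two-target experiment; [defaultSimConfig()] returns the full
#' dreissenid mesocosm design.
#'
#' @param seed Root random seed.
#' @param abundances Mussel counts of the abundance treatments.
#' @param replicatesPerAbundance Replicate tanks per treatment.
#' @param timepointsH Sampling hours, ascending from 0.
#' @param targets `data.frame` with columns `gene`, `genome`, `rna_class`,
#'   `amplicon_length`, `nucleic_acid`, `c0_log`, `k`.
#' @param abundanceC0Slope log_e C0 change per unit ln(abundance), centred.
#' @param abundanceKSlope k change per mussel (per hour), centred.
#' @param tankSd Tank random-intercept SD (log_e).
#' @param noiseSd Lognormal measurement noise SD (log_e).
#' @param lodCopiesPerMl Detection limit (copies/mL).
#' @param samplesPerTimepoint Nested water samples per tank per timepoint.
#' @param fallbackK Decay constant substituted where `targets$k` is `NA`.
#' @param biphasic `list()` (off) or
#'   `list(breakpoint_h =, k_multiplier_after =)`.
#' @return A validated [SimConfig-class].
#' @examples
#' cfg <- SimConfig(seed = 7, targets = data.frame(
#'   gene = "16S_141", genome = "mt", rna_class = "rRNA",
#'   amplicon_length = 141L, nucleic_acid = "DNA",
#'   c0_log = log(100), k = log(2)))
#' @export
SimConfig <- function(seed = 1L,
                      abundances = c(2, 6, 12, 24, 48),
                      replicatesPerAbundance = 3L,
                      timepointsH = c(0, 5, 12, 24, 48, 72, 144, 240),
                      targets,
                      abundanceC0Slope = 0,
                      abundanceKSlope = 0,
                      tankSd = 0,
                      noiseSd = 0,
                      lodCopiesPerMl = 0,
                      samplesPerTimepoint = 1L,
                      fallbackK = 0.0735,
                      biphasic = list()) {
  if (missing(targets) || is.null(targets) || nrow(targets) == 0L)
    stop("config error: at least one target is required")
  if (length(timepointsH) == 0L)
    stop("config error: at least one timepoint is required")
  targets <- as.data.frame(targets, stringsAsFactors = FALSE)
  targets$amplicon_length <- as.integer(targets$amplicon_length)
  new("SimConfig", seed = as.integer(seed),
      abundances = as.numeric(abundances),
      replicatesPerAbundance = as.integer(replicatesPerAbundance),
      timepointsH = as.numeric(timepointsH), targets = targets,
      abundanceC0Slope = as.numeric(abundanceC0Slope),
      abundanceKSlope = as.numeric(abundanceKSlope),
      tankSd = as.numeric(tankSd), noiseSd = as.numeric(noiseSd),
      lodCopiesPerMl = as.numeric(lodCopiesPerMl),
      samplesPerTimepoint = as.integer(samplesPerTimepoint),
      fallbackK = as.numeric(fallbackK), biphasic = biphasic)
}

#' Default mesocosm design: the dreissenid tank experiment
#'
#' Returns the configuration emulating the study design the analysis targets:
#' five abundance treatments of 2, 6, 12, 24 and 48 mussels, three replicate
#' tanks each, water sampled at 0, 5, 12, 24, 48, 72, 144 and 240 h after
#' organism removal, and ten gene x nucleic-acid targets with the reported
#' marginal initial log_e concentrations and first-order decay constants:
#'
#' | target | c0_log | k (/h) |
#' |---|---|---|
#' | 16S_141 DNA | 4.75 | 0.0378 |
#' | 16S_341 DNA | 4.42 | 0.0420 |
#' | COI_128 DNA | 4.23 | 0.0398 |
#' | 18S_169 DNA | 6.43 | 0.0466 |
#' | H2B_75 DNA  | 6.87 | 0.0461 |
#' | H2B_250 DNA | 6.75 | 0.0480 |
#' | 16S_141 RNA | 11.09 | 0.0561 |
#' | COI_128 RNA | 7.31 | 0.0602 |
#' | 18S_169 RNA | 12.61 | 0.0735 |
#' | H2B_250 RNA | 2.03 | (none) |
#'
#' The H2B messenger-RNA marker decayed below detection too quickly for a
#' decay constant to be measured; it is simulated with `fallbackK`
#' (default 0.0735 /h, the fastest measured rRNA constant). Variance
#' components and abundance slopes are not reported quantities; the defaults
#' (`tankSd = 0.3`, `noiseSd = 0.5` on the log_e scale,
#' `abundanceC0Slope = 0.5`, `abundanceKSlope = 2e-4`) are stated modelling
#' assumptions chosen to produce the qualitative abundance trends the
#' experiment showed. The detection limit of 0.6 copies/mL corresponds to a
#' single template copy per reaction at the default volume bridge of
#' [copiesPerReactionToPerMl()].
#'
#' @param seed Root random seed.
#' @param fallbackK Decay constant for the H2B RNA target (per hour).
#' @param ... Further arguments overriding [SimConfig()] defaults.
#' @return A [SimConfig-class].
#' @examples
#' cfg <- defaultSimConfig(seed = 42)
#' cfg
#' @export
defaultSimConfig <- function(seed = 1L, fallbackK = 0.0735, ...) {
  targets <- data.frame(
    gene = c("16S_141", "16S_341", "COI_128", "18S_169", "H2B_75",
             "H2B_250", "16S_141", "COI_128", "18S_169", "H2B_250"),
    genome = c("mt", "mt", "mt", "nu", "nu", "nu", "mt", "mt", "nu", "nu"),
    rna_class = c("rRNA", "rRNA", "mRNA", "rRNA", "mRNA", "mRNA",
                  "rRNA", "mRNA", "rRNA", "mRNA"),
    amplicon_length = c(141L, 341L, 128L, 169L, 75L, 250L,
                        141L, 128L, 169L, 250L),
    nucleic_acid = c(rep("DNA", 6), rep("RNA", 4)),
    c0_log = c(4.75, 4.42, 4.23, 6.43, 6.87, 6.75, 11.09, 7.31, 12.61, 2.03),
    k = c(0.0378, 0.0420, 0.0398, 0.0466, 0.0461, 0.0480,
          0.0561, 0.0602, 0.0735, NA),
    stringsAsFactors = FALSE)
  args <- list(seed = seed, targets = targets,
               abundanceC0Slope = 0.5, abundanceKSlope = 2e-4,
               tankSd = 0.3, noiseSd = 0.5, lodCopiesPerMl = 0.6,
               fallbackK = fallbackK)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(SimConfig, args)
}

# deterministic child seed below 2^31, distinct per (root, stream index)
.childSeed <- function(root, idx) {
  (abs(as.numeric(root)) * 48271 + as.numeric(idx) * 2246822519 + 1013904223) %%
    2147483647
}

#' Simulate a mesocosm degradation experiment
#'
#' Generates a complete synthetic dataset under the generative model the
#' decay analysis assumes. For tank i (abundance A_i) and target g:
#' \deqn{c0_{ig} = c0_g + \beta_{C0} (\ln A_i - \overline{\ln A}) + u_i,
#'       \quad u_i \sim N(0, \sigma_{tank}^2)}
#' \deqn{k_{ig} = \max(0,\; k_g + \beta_k (A_i - \bar A))}
#' The latent concentration at time t is `exp(c0_ig) * exp(-k_ig t)` (with an
#' optional biphasic slowdown after a breakpoint), observed concentrations
#' carry multiplicative lognormal noise `exp(N(0, noiseSd^2))`, and any
#' observation below the detection limit is recorded as a censored non-detect
#' with absent copies. Abundance effects are centred on the design means so
#' the configured `c0_log`/`k` are the all-abundances marginal values.
#'
#' Randomness is fully reproducible: a single root seed spawns one child
#' stream per tank (intercepts) and one per tank x target (noise), so adding
#' a target leaves all other draws untouched, and raising the detection limit
#' can only turn detections into non-detects (the draws themselves are
#' identical). The caller's RNG state is left unchanged.
#'
#' @param config A [SimConfig-class].
#' @return A [DecayExperiment-class]; [simTruth()] on it returns the realized
#'   per-tank parameters and latent pre-noise concentrations.
#' @examples
#' de <- simulateExperiment(defaultSimConfig(seed = 1))
#' de
#' @export
simulateExperiment <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  tg <- config@targets
  tg$k[is.na(tg$k)] <- config@fallbackK
  tlab <- .targetLabel(tg$gene, tg$nucleic_acid)
  if (anyDuplicated(tlab))
    stop("config error: duplicated target (gene, nucleic_acid)")

  # design
  ab <- rep(config@abundances, each = config@replicatesPerAbundance)
  rl <- if (config@replicatesPerAbundance <= 26L)
    LETTERS[seq_len(config@replicatesPerAbundance)]
  else sprintf("R%04d", seq_len(config@replicatesPerAbundance))
  rep_lab <- rep(rl, times = length(config@abundances))
  tank_id <- sprintf("A%02d_%s", as.integer(ab), rep_lab)
  n_tank <- length(tank_id)
  tt <- config@timepointsH
  nspt <- config@samplesPerTimepoint
  mean_lnA <- mean(log(config@abundances[config@abundances > 0]))
  mean_A <- mean(config@abundances)

  # preserve the caller's RNG state
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }

  set.seed(.childSeed(config@seed, 0))
  tank_u <- stats::rnorm(n_tank, 0, config@tankSd)

  rows <- vector("list", n_tank * nrow(tg))
  truth_rows <- vector("list", n_tank * nrow(tg))
  t_rep <- rep(tt, each = nspt)
  r <- 0L
  for (i in seq_len(n_tank)) {
    lnA_eff <- if (ab[i] > 0) log(ab[i]) - mean_lnA else -Inf
    for (g in seq_len(nrow(tg))) {
      r <- r + 1L
      c0_ig <- tg$c0_log[g] + config@abundanceC0Slope * lnA_eff + tank_u[i]
      k_ig <- max(0, tg$k[g] + config@abundanceKSlope * (ab[i] - mean_A))
      # first-order decay, optionally slowed after a breakpoint
      if (length(config@biphasic)) {
        bp <- config@biphasic$breakpoint_h
        mult <- config@biphasic$k_multiplier_after
        dec <- ifelse(t_rep <= bp, k_ig * t_rep,
                      k_ig * bp + mult * k_ig * (t_rep - bp))
      } else {
        dec <- k_ig * t_rep
      }
      latent_log <- c0_ig - dec
      set.seed(.childSeed(config@seed, i * 100003 + g))
      eps <- if (config@noiseSd > 0)
        stats::rnorm(length(t_rep), 0, config@noiseSd) else
        numeric(length(t_rep))
      obs <- exp(latent_log + eps)
      cens <- obs < config@lodCopiesPerMl | !is.finite(latent_log)
      rows[[r]] <- data.frame(
        tank_id = tank_id[i], abundance = ab[i], replicate = rep_lab[i],
        gene = tg$gene[g], genome = tg$genome[g],
        rna_class = tg$rna_class[g],
        amplicon_length = tg$amplicon_length[g],
        nucleic_acid = tg$nucleic_acid[g], time_h = t_rep,
        copies_per_ml = ifelse(cens, NA_real_, obs), censored = cens,
        latent = exp(latent_log), stringsAsFactors = FALSE)
      truth_rows[[r]] <- data.frame(
        tank_id = tank_id[i], target = tlab[g], abundance = ab[i],
        tank_intercept = tank_u[i], c0_log = c0_ig, k = k_ig,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  # target-major input: occurrences per (tank, time) align across targets
  df <- df[order(match(.targetLabel(df$gene, df$nucleic_acid), tlab)), ]
  latent <- df$latent
  df$latent <- NULL

  de <- .buildExperiment(df)
  lat <- matrix(NA_real_, nrow(de), ncol(de), dimnames = dimnames(de))
  tl_df <- .targetLabel(df$gene, df$nucleic_acid)
  occ <- stats::ave(seq_len(nrow(df)), tl_df, df$tank_id, df$time_h,
                    FUN = seq_along)
  skey <- sprintf("%s.t%s.s%d", df$tank_id, format(df$time_h, trim = TRUE),
                  occ)
  lat[cbind(match(tl_df, rownames(de)), match(skey, colnames(de)))] <- latent
  truth <- new("SimTruth", params = do.call(rbind, truth_rows), latent = lat)
  S4Vectors::metadata(de)$truth <- truth
  S4Vectors::metadata(de)$config <- config
  .log("simulated %d tanks x %d targets x %d sampling slots (%d censored)",
       n_tank, nrow(tg), length(t_rep), sum(assay(de, "censored")))
  de
}
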