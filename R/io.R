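#' @include constructors.R
NULL

# stderr logging, silenced via options(ernaclock.verbose = FALSE)
.log <- function(fmt, ...) {
  if (isFALSE(getOption("ernaclock.verbose", TRUE))) return(invisible(NULL))
  message(sprintf(paste0("[ernaclock] ", fmt), ...))
}

.REQ_CSV_COLS <- c("tank_id", "abundance", "gene", "nucleic_acid",
                   "time_h", "copies_per_ml", "censored")
.META_CSV_COLS <- c("replicate", "genome", "rna_class", "amplicon_length")

#' Read qPCR measurements from a tidy long CSV
#'
#' Reads a comma-separated, header-mandatory table with one row per
#' measurement and assembles it into a [DecayExperiment-class]. Required
#' columns: `tank_id`, `abundance`, `gene`, `nucleic_acid`, `time_h`,
#' `copies_per_ml`, `censored`; recognised metadata columns: `replicate`,
#' `genome`, `rna_class`, `amplicon_length` (alternatively supplied through
#' `targets`). Censored rows carry an empty/`NA` (or zero-coded)
#' `copies_per_ml` and `censored = TRUE`; they are stored as missing, never
#' as zeros, so downstream stages own the censoring policy. Malformed rows
#' are rejected with row-indexed diagnostics.
#'
#' @param path CSV file path.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(tank_id = "tank")`.
#' @param targets Optional `data.frame` with columns `gene`, `genome`,
#'   `rna_class`, `amplicon_length` used to annotate targets when the file
#'   lacks those columns.
#' @return A [DecayExperiment-class]. Use [concentrationSeries()] for the
#'   per-(tank, target) series view.
#' @examples
#' de <- simulateExperiment(defaultSimConfig(seed = 1))
#' f <- tempfile(fileext = ".csv")
#' writeMeasurements(de, f)
#' de2 <- readMeasurements(f)
#' @export
readMeasurements <- function(path, schema = NULL, targets = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% colnames(raw))
        stop("schema error: file has no column '", schema[[canon]], "'")
      colnames(raw)[colnames(raw) == schema[[canon]]] <- canon
    }
  }
  miss <- setdiff(.REQ_CSV_COLS, colnames(raw))
  if (length(miss))
    stop("schema error: missing required column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(raw) == 0L) stop("no measurement rows in ", path)

  df <- data.frame(
    tank_id = raw$tank_id,
    abundance = suppressWarnings(as.numeric(raw$abundance)),
    gene = raw$gene,
    nucleic_acid = raw$nucleic_acid,
    time_h = suppressWarnings(as.numeric(raw$time_h)),
    copies_per_ml = suppressWarnings(as.numeric(raw$copies_per_ml)),
    censored = toupper(trimws(raw$censored)) %in% c("TRUE", "T", "1"),
    stringsAsFactors = FALSE)
  df$replicate <- if ("replicate" %in% colnames(raw)) raw$replicate
                  else NA_character_

  meta_in_file <- all(c("genome", "rna_class", "amplicon_length") %in%
                        colnames(raw))
  if (meta_in_file) {
    df$genome <- raw$genome
    df$rna_class <- raw$rna_class
    df$amplicon_length <- suppressWarnings(as.integer(raw$amplicon_length))
  } else if (!is.null(targets)) {
    m <- match(df$gene, targets$gene)
    if (anyNA(m))
      stop("targets table lacks metadata for gene(s): ",
           paste(unique(df$gene[is.na(m)]), collapse = ", "))
    df$genome <- targets$genome[m]
    df$rna_class <- targets$rna_class[m]
    df$amplicon_length <- as.integer(targets$amplicon_length[m])
  } else {
    stop("schema error: missing column(s) genome, rna_class, ",
         "amplicon_length (supply them in the file or via 'targets')")
  }

  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows))
      stop(sprintf("validation error: %s in row(s) %s", what,
                   paste(utils::head(rows, 10), collapse = ", ")))
  }
  bad(is.na(df$time_h) | df$time_h < 0, "negative or unparseable time_h")
  bad(is.na(df$abundance) | df$abundance < 0,
      "negative or unparseable abundance")
  bad(!df$censored & is.na(df$copies_per_ml),
      "uncensored row without copies_per_ml")
  bad(df$copies_per_ml < 0 & !is.na(df$copies_per_ml),
      "negative copies_per_ml")
  bad(!df$nucleic_acid %in% .NUCLEIC_ACIDS, "nucleic_acid not DNA/RNA")
  bad(!df$genome %in% .GENOMES, "genome not mt/nu")
  bad(!df$rna_class %in% .RNA_CLASSES, "rna_class not rRNA/mRNA")
  bad(is.na(df$amplicon_length) | df$amplicon_length <= 0,
      "non-positive amplicon_length")

  # non-detects stored as absent, including zero-coded ones
  df$copies_per_ml[df$censored] <- NA_real_

  de <- .buildExperiment(df)
  .log("read %d measurements (%d censored) into %d targets x %d samples",
       nrow(df), sum(df$censored), nrow(de), ncol(de))
  de
}

#' Write measurements to a tidy long CSV
#'
#' Inverse of [readMeasurements()]: numbers are printed with 17 significant
#' digits so that a write/read round trip reproduces every value bit-exactly.
#' Censored measurements are written with an empty `copies_per_ml` and
#' `censored = TRUE`.
#'
#' @param x A [DecayExperiment-class] with at least one measurement.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeMeasurements <- function(x, path) {
  stopifnot(is(x, "DecayExperiment"))
  df <- measurementTable(x)
  if (nrow(df) == 0L) stop("no measurements to write")
  num <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  out <- data.frame(
    tank_id = df$tank_id, abundance = num(df$abundance),
    replicate = ifelse(is.na(df$replicate), "", df$replicate),
    gene = df$gene, genome = df$genome, rna_class = df$rna_class,
    amplicon_length = df$amplicon_length, nucleic_acid = df$nucleic_acid,
    time_h = num(df$time_h), copies_per_ml = num(df$copies_per_ml),
    censored = df$censored, stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing ", path, ": ",
                        conditionMessage(ok))
  .log("wrote %d measurements to %s", nrow(out), path)
  invisible(path)
}

#' @rdname excludeTanks
#' @export
setMethod("excludeTanks", "DecayExperiment", function(x, tankIds, ...) {
  present <- unique(colData(x)$tank_id)
  unknown <- setdiff(tankIds, present)
  if (length(unknown))
    stop("unknown tank_id(s): ", paste(unknown, collapse = ", "))
  if (!length(tankIds)) return(x)
  keep <- !colData(x)$tank_id %in% tankIds
  n_removed <- sum(!keep)
  .log("excluding %d tank(s) (%d samples removed)",
       length(unique(tankIds)), n_removed)
  out <- x[, keep]
  if (ncol(out) == 0L)
    warning("all tanks excluded; experiment is empty")
  out
})

#' Read a simulation configuration from YAML
#'
#' Keys mirror the [SimConfig-class] slots in snake_case (`seed`,
#' `abundances`, `replicates_per_abundance`, `timepoints_h`, `targets` (a
#' list of records), `abundance_c0_slope`, `abundance_k_slope`, `tank_sd`,
#' `noise_sd`, `lod_copies_per_ml`, `samples_per_timepoint`, `fallback_k`,
#' `biphasic`). Missing keys fall back to the defaults of [SimConfig()].
#'
#' @param path YAML file path.
#' @return A [SimConfig-class].
#' @export
readSimConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  args <- list()
  take <- function(key, slot = key) {
    if (!is.null(y[[key]])) args[[slot]] <<- y[[key]]
  }
  take("seed")
  take("abundances")
  take("replicates_per_abundance", "replicatesPerAbundance")
  take("timepoints_h", "timepointsH")
  take("abundance_c0_slope", "abundanceC0Slope")
  take("abundance_k_slope", "abundanceKSlope")
  take("tank_sd", "tankSd")
  take("noise_sd", "noiseSd")
  take("lod_copies_per_ml", "lodCopiesPerMl")
  take("samples_per_timepoint", "samplesPerTimepoint")
  take("fallback_k", "fallbackK")
  if (!is.null(y$targets))
    args$targets <- do.call(rbind, lapply(y$targets, function(t)
      data.frame(gene = t$gene, genome = t$genome, rna_class = t$rna_class,
                 amplicon_length = as.integer(t$amplicon_length),
                 nucleic_acid = t$nucleic_acid,
                 c0_log = as.numeric(t$c0_log),
                 k = if (is.null(t$k)) NA_real_ else as.numeric(t$k),
                 stringsAsFactors = FALSE)))
  if (!is.null(y$biphasic)) args$biphasic <- y$biphasic
  do.call(SimConfig, args)
}

#' Write a simulation configuration to YAML
#'
#' @param config A [SimConfig-class].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
writeSimConfig <- function(config, path) {
  stopifnot(is(config, "SimConfig"))
  tg <- config@targets
  y <- list(
    seed = config@seed,
    abundances = config@abundances,
    replicates_per_abundance = config@replicatesPerAbundance,
    timepoints_h = config@timepointsH,
    targets = lapply(seq_len(nrow(tg)), function(i) {
      r <- as.list(tg[i, .REQ_TARGET_COLS])
      if (is.na(r$k)) r$k <- NULL
      r
    }),
    abundance_c0_slope = config@abundanceC0Slope,
    abundance_k_slope = config@abundanceKSlope,
    tank_sd = config@tankSd,
    noise_sd = config@noiseSd,
    lod_copies_per_ml = config@lodCopiesPerMl,
    samples_per_timepoint = config@samplesPerTimepoint,
    fallback_k = config@fallbackK)
  if (length(config@biphasic)) y$biphasic <- config@biphasic
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Write a machine-readable run summary
#'
#' Serialises a named list of scalar results (counts, estimates, file paths)
#' to JSON, for pipeline bookkeeping alongside the human-readable log.
#'
#' @param summary Named list.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
writeRunSummary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
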