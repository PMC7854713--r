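options(ernaclock.verbose = FALSE)
suppressPackageStartupMessages(library(SummarizedExperiment))

# one-target configuration with all stochastic components off by default
singleTargetConfig <- function(seed = 1, c0_log = log(100), k = log(2),
                               timepoints = c(0, 1, 2), abundances = 2,
                               replicates = 1L, noise = 0, tank_sd = 0,
                               lod = 0, ...) {
  SimConfig(seed = seed, abundances = abundances,
            replicatesPerAbundance = replicates, timepointsH = timepoints,
            targets = data.frame(gene = "16S_141", genome = "mt",
                                 rna_class = "rRNA", amplicon_length = 141L,
                                 nucleic_acid = "DNA", c0_log = c0_log,
                                 k = k, stringsAsFactors = FALSE),
            tankSd = tank_sd, noiseSd = noise, lodCopiesPerMl = lod, ...)
}

# RNA/DNA pair of one gene fragment (defaults: the 16S pair truths)
pairConfig <- function(seed = 1, kR = 0.0561, kD = 0.0378,
                       c0R = 11.09, c0D = 4.75, noise = 0, tank_sd = 0,
                       lod = 0, abundances = c(2, 6, 12, 24, 48),
                       replicates = 3L,
                       timepoints = c(0, 5, 12, 24, 48, 72, 144, 240), ...) {
  SimConfig(seed = seed, abundances = abundances,
            replicatesPerAbundance = replicates, timepointsH = timepoints,
            targets = data.frame(
              gene = "16S_141", genome = "mt", rna_class = "rRNA",
              amplicon_length = 141L, nucleic_acid = c("DNA", "RNA"),
              c0_log = c(c0D, c0R), k = c(kD, kR), stringsAsFactors = FALSE),
            tankSd = tank_sd, noiseSd = noise, lodCopiesPerMl = lod, ...)
}

# minimal tidy CSV on disk; rows = list of character vectors
writeTidyCsv <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- paste("tank_id", "abundance", "replicate", "gene", "genome",
                  "rna_class", "amplicon_length", "nucleic_acid", "time_h",
                  "copies_per_ml", "censored", sep = ",")
  writeLines(c(header, vapply(rows, paste, character(1), collapse = ",")),
             path)
  path
}

tidyRow <- function(tank = "T1", ab = 2, rep = "A", gene = "16S_141",
                    genome = "mt", rna = "rRNA", len = 141,
                    na = "DNA", t = 0, copies = "100", cens = "FALSE") {
  c(tank, ab, rep, gene, genome, rna, len, na, t, copies, cens)
}

detectionCount <- function(de) sum(!assay(de, "censored"), na.rm = TRUE)
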