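#' @include AllGenerics.R
NULL

#' Create a gene target descriptor
#'
#' @param name Marker label, e.g. `"16S_141"`.
#' @param genome `"mt"` or `"nu"`.
#' @param rnaClass `"rRNA"` or `"mRNA"`.
#' @param ampliconLength Amplicon length in base pairs.
#' @param nucleicAcid `"DNA"` or `"RNA"`.
#' @return A [GeneTarget-class].
#' @examples
#' GeneTarget("16S_141", "mt", "rRNA", 141, "DNA")
#' @export
GeneTarget <- function(name, genome, rnaClass, ampliconLength, nucleicAcid) {
  new("GeneTarget", name = as.character(name), genome = as.character(genome),
      rnaClass = as.character(rnaClass),
      ampliconLength = as.integer(ampliconLength),
      nucleicAcid = as.character(nucleicAcid))
}

#' Create a concentration series
#'
#' @param tankId Tank label.
#' @param target A [GeneTarget-class].
#' @param timeH Hours since removal, strictly increasing.
#' @param copiesPerMl Copies/mL; `NA` where censored.
#' @param censored Logical non-detect flags; defaults to `is.na(copiesPerMl)`.
#' @param abundance Mussel count of the tank.
#' @param replicate Replicate label.
#' @return A [ConcentrationSeries-class].
#' @export
ConcentrationSeries <- function(tankId, target, timeH, copiesPerMl,
                                censored = is.na(copiesPerMl),
                                abundance = NA_real_,
                                replicate = NA_character_) {
  new("ConcentrationSeries", tankId = as.character(tankId),
      abundance = as.numeric(abundance), replicate = as.character(replicate),
      target = target, timeH = as.numeric(timeH),
      copiesPerMl = as.numeric(copiesPerMl), censored = as.logical(censored))
}

# canonical target label: gene fragment + assayed nucleic acid
.targetLabel <- function(gene, nucleicAcid) paste(gene, nucleicAcid, sep = "_")

# Assemble a DecayExperiment from a validated tidy long table. Repeated
# (tank, target, time) rows are interpreted as nested water samples; the i-th
# occurrence for each target is assigned to the i-th sample of that
# (tank, time), so replicate samples must be listed in a consistent order.
.buildExperiment <- function(df, truth = NULL) {
  tl <- .targetLabel(df$gene, df$nucleic_acid)
  ru <- !duplicated(tl)
  rd <- S4Vectors::DataFrame(
    gene = df$gene[ru], genome = df$genome[ru],
    rna_class = df$rna_class[ru],
    amplicon_length = as.integer(df$amplicon_length[ru]),
    nucleic_acid = df$nucleic_acid[ru],
    row.names = tl[ru])

  occ <- stats::ave(seq_len(nrow(df)),
                    tl, df$tank_id, df$time_h, FUN = seq_along)
  skey <- sprintf("%s.t%s.s%d", df$tank_id, format(df$time_h, trim = TRUE),
                  occ)
  su <- !duplicated(skey)
  cd <- S4Vectors::DataFrame(
    tank_id = df$tank_id[su], abundance = as.numeric(df$abundance[su]),
    replicate = as.character(df$replicate[su]),
    time_h = as.numeric(df$time_h[su]), sample_id = skey[su],
    row.names = skey[su])
  ord <- order(cd$tank_id, cd$time_h, cd$sample_id)
  cd <- cd[ord, , drop = FALSE]

  dn <- list(rownames(rd), rownames(cd))
  copies <- matrix(NA_real_, nrow(rd), nrow(cd), dimnames = dn)
  cens <- matrix(NA, nrow(rd), nrow(cd), dimnames = dn)
  idx <- cbind(match(tl, rownames(rd)), match(skey, rownames(cd)))
  copies[idx] <- df$copies_per_ml
  cens[idx] <- df$censored

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(copies = copies, censored = cens),
    rowData = rd, colData = cd)
  de <- new("DecayExperiment", se)
  if (!is.null(truth)) S4Vectors::metadata(de)$truth <- truth
  de
}

#' @rdname measurementTable
#' @export
setMethod("measurementTable", "DecayExperiment", function(x, ...) {
  cp <- assay(x, "copies")
  cn <- assay(x, "censored")
  rd <- as.data.frame(rowData(x))
  cd <- as.data.frame(colData(x))
  nr <- nrow(x); nc <- ncol(x)
  i <- rep(seq_len(nr), times = nc)
  j <- rep(seq_len(nc), each = nr)
  keep <- !is.na(as.vector(cn))
  i <- i[keep]; j <- j[keep]
  out <- data.frame(
    tank_id = cd$tank_id[j], abundance = cd$abundance[j],
    replicate = cd$replicate[j], gene = rd$gene[i], genome = rd$genome[i],
    rna_class = rd$rna_class[i], amplicon_length = rd$amplicon_length[i],
    nucleic_acid = rd$nucleic_acid[i], time_h = cd$time_h[j],
    copies_per_ml = as.vector(cp)[keep], censored = as.vector(cn)[keep],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
})

#' @rdname measurementTable
#' @export
setMethod("measurementTable", "ConcentrationSeries", function(x, ...) {
  tg <- x@target
  data.frame(
    tank_id = x@tankId, abundance = x@abundance, replicate = x@replicate,
    gene = tg@name, genome = tg@genome, rna_class = tg@rnaClass,
    amplicon_length = tg@ampliconLength, nucleic_acid = tg@nucleicAcid,
    time_h = x@timeH, copies_per_ml = x@copiesPerMl, censored = x@censored,
    stringsAsFactors = FALSE)
})

#' @rdname concentrationSeries
#' @export
setMethod("concentrationSeries", "DecayExperiment", function(x, ...) {
  cp <- assay(x, "copies")
  cn <- assay(x, "censored")
  cd <- colData(x)
  rd <- rowData(x)
  out <- list()
  for (tk in unique(cd$tank_id)) {
    js <- which(cd$tank_id == tk)
    js <- js[order(cd$time_h[js])]
    for (r in seq_len(nrow(x))) {
      meas <- js[!is.na(cn[r, js])]
      if (!length(meas)) next
      tg <- GeneTarget(rd$gene[r], rd$genome[r], rd$rna_class[r],
                       rd$amplicon_length[r], rd$nucleic_acid[r])
      nm <- paste(tk, rownames(x)[r], sep = ".")
      # nested samples at one timepoint would make timeH non-strict; keep
      # one series per sample occurrence in that case
      tt <- cd$time_h[meas]
      if (anyDuplicated(tt)) {
        occ <- stats::ave(seq_along(meas), tt, FUN = seq_along)
        for (o in unique(occ)) {
          sel <- meas[occ == o]
          out[[sprintf("%s.s%d", nm, o)]] <- ConcentrationSeries(
            tk, tg, cd$time_h[sel], cp[r, sel], cn[r, sel],
            abundance = cd$abundance[sel][1],
            replicate = cd$replicate[sel][1])
        }
      } else {
        out[[nm]] <- ConcentrationSeries(
          tk, tg, tt, cp[r, meas], cn[r, meas],
          abundance = cd$abundance[meas][1],
          replicate = cd$replicate[meas][1])
      }
    }
  }
  S4Vectors::SimpleList(out)
})

#' @rdname simTruth
#' @export
setMethod("simTruth", "DecayExperiment", function(x, ...) {
  S4Vectors::metadata(x)$truth
})
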