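#' @import methods
#' @importFrom stats lm mad median qnorm rbinom rnorm runif setNames var cor coef
#' @importFrom utils head tail packageVersion
NULL

#' Multiplex melting-curve dPCR panel
#'
#' A \code{DyePanel} describes the assay layout of a multiplex digital-PCR
#' melting-curve experiment: which genotype is read on which dye channel, at
#' which expected melting temperature (Tm) and expected melt-peak width
#' (FWHM), and with which amplicon length.  Two targets may share a dye
#' channel with a small Tm separation if they are registered as a
#' \emph{shared-dye pair}; such pairs are resolved downstream by the FWHM of
#' the (possibly merged) melt peak.
#'
#' Validity rules: six uniquely named channels; unique genotype labels; all
#' expected Tm values inside the thermal ramp (45--80 degrees C); positive
#' FWHM and amplicon lengths; and for any two targets on the same channel,
#' either |delta Tm| >= 2 * \code{tmWindowHalfwidth} or membership of a
#' declared shared-dye pair.
#'
#' @slot targets \code{data.frame} with columns \code{genotype}, \code{gene},
#'   \code{locus_group}, \code{channel}, \code{is_wt}, \code{tm},
#'   \code{fwhm}, \code{amplicon_length}.
#' @slot channels character vector of the six dye-channel names, in filter
#'   index order.
#' @slot tmWindowHalfwidth numeric, half-width (degrees C) of the genotyping
#'   window placed around each target's expected Tm.
#' @slot sharedDyePairs list of character(2) genotype pairs sharing a channel.
#' @slot schemaVersion character, config schema version.
#'
#' @seealso [defaultPanel()], [loadPanel()], [genotypingWindow()]
#' @export
setClass("DyePanel",
  slots = c(
    targets = "data.frame",
    channels = "character",
    tmWindowHalfwidth = "numeric",
    sharedDyePairs = "list",
    schemaVersion = "character"
  )
)

.RAMP_RANGE <- c(45, 80)
.PANEL_COLUMNS <- c("genotype", "gene", "locus_group", "channel", "is_wt",
                    "tm", "fwhm", "amplicon_length")

setValidity("DyePanel", function(object) {
  msgs <- character()
  tg <- object@targets
  if (!all(.PANEL_COLUMNS %in% names(tg)))
    return(paste("targets must have columns:",
                 paste(.PANEL_COLUMNS, collapse = ", ")))
  if (length(object@channels) != 6L)
    msgs <- c(msgs, "a panel must define exactly six dye channels")
  if (anyDuplicated(object@channels))
    msgs <- c(msgs, "channel names must be unique")
  if (anyDuplicated(tg$genotype))
    msgs <- c(msgs, "genotype labels must be unique")
  if (!all(tg$channel %in% object@channels))
    msgs <- c(msgs, sprintf("unknown channel(s): %s",
      paste(setdiff(tg$channel, object@channels), collapse = ", ")))
  if (any(tg$tm < .RAMP_RANGE[1] | tg$tm > .RAMP_RANGE[2]))
    msgs <- c(msgs, sprintf("expected Tm must lie within the ramp [%g, %g] degC",
                            .RAMP_RANGE[1], .RAMP_RANGE[2]))
  if (any(tg$fwhm <= 0))
    msgs <- c(msgs, "expected FWHM must be > 0")
  if (any(tg$amplicon_length <= 0))
    msgs <- c(msgs, "amplicon_length must be > 0")
  if (length(object@tmWindowHalfwidth) != 1L || object@tmWindowHalfwidth <= 0)
    msgs <- c(msgs, "tmWindowHalfwidth must be a single positive number")
  for (pair in object@sharedDyePairs) {
    if (length(pair) != 2L || !all(pair %in% tg$genotype)) {
      msgs <- c(msgs, "each shared-dye pair must name two panel genotypes")
      next
    }
    if (length(unique(tg$channel[match(pair, tg$genotype)])) != 1L)
      msgs <- c(msgs, sprintf("shared-dye pair %s/%s must be on one channel",
                              pair[1], pair[2]))
  }
  # Tm separation on each channel, shared-dye pairs exempt
  hw <- object@tmWindowHalfwidth
  shared_key <- vapply(object@sharedDyePairs,
                       function(p) paste(sort(p), collapse = "|"), character(1))
  for (ch in unique(tg$channel)) {
    sub <- tg[tg$channel == ch, , drop = FALSE]
    if (nrow(sub) < 2L) next
    for (i in seq_len(nrow(sub) - 1L)) for (j in seq(i + 1L, nrow(sub))) {
      key <- paste(sort(c(sub$genotype[i], sub$genotype[j])), collapse = "|")
      if (abs(sub$tm[i] - sub$tm[j]) < 2 * hw && !(key %in% shared_key))
        msgs <- c(msgs, sprintf(
          "genotyping windows of %s and %s overlap on channel %s and the pair is not declared shared-dye",
          sub$genotype[i], sub$genotype[j], ch))
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Ground truth of a simulated chip
#'
#' Records, for every well of a simulated chip, how many detectable copies of
#' each genotype were loaded, which PCR-error false positives were injected,
#' and the realized detectable-copy totals.  Copy conservation holds exactly:
#' \code{colSums(wellCopies(x)) == detectableCopies(x)}.
#'
#' @slot counts integer matrix, wells x genotypes: true copies per well.
#' @slot injected logical matrix, wells x genotypes: PCR-error false-positive
#'   events (presence only, recorded separately from true copies).
#' @slot detectableCopies named numeric, realized detectable copies per
#'   genotype (after the fragmentation-detectability thinning).
#' @slot inputCopies named numeric, requested input copies per genotype.
#' @slot detectionProb named numeric, per-genotype detection probability used.
#' @slot fragmentLength numeric, fragment length in bp (NA for intact DNA).
#'
#' @export
setClass("ChipTruth",
  slots = c(
    counts = "matrix",
    injected = "matrix",
    detectableCopies = "numeric",
    inputCopies = "numeric",
    detectionProb = "numeric",
    fragmentLength = "numeric"
  )
)

setValidity("ChipTruth", function(object) {
  if (!identical(dim(object@counts), dim(object@injected)))
    return("counts and injected matrices must have identical dimensions")
  if (!identical(colnames(object@counts), names(object@detectableCopies)))
    return("column names of counts must match names of detectableCopies")
  if (!isTRUE(all(colSums(object@counts) == object@detectableCopies)))
    return("copy conservation violated: colSums(counts) != detectableCopies")
  TRUE
})

#' Six-channel melt-curve chip
#'
#' A \code{MeltChip} holds the per-well fluorescence-versus-temperature traces
#' of one partitioned chip: one assay matrix per dye channel (rows = wells,
#' columns = temperature points on a common grid).  Simulated chips carry
#' their [ChipTruth-class] in \code{metadata(x)$truth}.
#'
#' @seealso [simulateChip()], [callPeaks()], [temperatures()]
#' @export
setClass("MeltChip", contains = "SummarizedExperiment")

setValidity("MeltChip", function(object) {
  cd <- SummarizedExperiment::colData(object)
  if (!"temperature" %in% names(cd))
    return("colData must contain a 'temperature' column")
  tt <- cd$temperature
  if (is.unsorted(tt, strictly = TRUE))
    return("temperature grid must be strictly increasing")
  if (length(SummarizedExperiment::assayNames(object)) < 1L)
    return("at least one channel assay is required")
  TRUE
})

#' Positive-well counts of an analyzed chip
#'
#' @slot nWellsAnalyzed integer, number of wells that passed trace QC and were
#'   genotyped.
#' @slot positives named integer, positive-well count per panel genotype.  A
#'   multi-positive well contributes to every genotype it contains.
#' @slot nOutOfWindow integer, number of accepted melt peaks falling outside
#'   every genotyping window (flagged, not assigned).
#'
#' @seealso [countChip()], [genotypeChip()], [chipEstimates()]
#' @export
setClass("ChipCounts",
  slots = c(
    nWellsAnalyzed = "integer",
    positives = "integer",
    nOutOfWindow = "integer"
  )
)

setValidity("ChipCounts", function(object) {
  if (length(object@nWellsAnalyzed) != 1L || object@nWellsAnalyzed < 0L)
    return("nWellsAnalyzed must be a single non-negative integer")
  if (is.null(names(object@positives)))
    return("positives must be a named integer vector")
  if (any(object@positives < 0L) ||
      any(object@positives > object@nWellsAnalyzed))
    return("each positive-well count must lie in [0, nWellsAnalyzed]")
  TRUE
})

#' Quantification results for one chip
#'
#' Per-genotype Poisson estimates (lambda, copies, 95\% CI), per-locus variant
#' allele fractions, and copy-number-alteration ratios versus the reference
#' gene, computed from a [ChipCounts-class] object.
#'
#' @slot estimates data.frame, one row per genotype: k, N, p, lambda, copies,
#'   lambda CI bounds.
#' @slot vaf data.frame, one row per (locus, genotype): allele fraction on the
#'   lambda scale.
#' @slot cna data.frame, one row per target gene: ratio to the reference gene
#'   with delta-method 95\% CI.
#' @slot nWells integer, analyzed wells.
#'
#' @seealso [quantifyChip()]
#' @export
setClass("QuantResult",
  slots = c(
    estimates = "data.frame",
    vaf = "data.frame",
    cna = "data.frame",
    nWells = "integer"
  )
)
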