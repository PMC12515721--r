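# Synthetic-chip generator: Poisson partitioning, fragment-length-dependent
# detectability, six-channel logistic melt traces, PCR-error false positives.

.DEFAULT_TEMP_GRID <- function() seq(45, 80, by = 0.25)
.DEFAULT_N_WELLS <- 20000L
.DEFAULT_NOISE_SD <- 0.03
.BASELINE <- 1.0
.AMPLITUDE <- 1.0

#' Probability that a fragmented template is amplifiable
#'
#' Under the fixed-fragment-length, uniform-random-phase model a template
#' molecule is detectable only if one fragment fully contains the amplicon:
#' \eqn{d = \max(0, (F - L + 1)/F)} for amplicon length \eqn{L} and fragment
#' length \eqn{F}.  Intact DNA (\code{fragmentLength = NULL}, \code{NA} or
#' \code{Inf}) gives \eqn{d = 1}.  A vector of fragment lengths is treated as
#' an empirical length distribution and \eqn{d} is averaged over it.
#'
#' This is why dPCR detection rates are higher for shorter amplicons on
#' sheared DNA, biasing copy-number ratios when amplicon sizes are mismatched.
#'
#' @param ampliconLength amplicon length(s), bp (> 0)
#' @param fragmentLength fragment length, bp (> 0); NULL/NA/Inf for intact
#'   DNA; a vector is averaged as an empirical distribution
#' @return detection probability, vectorized over \code{ampliconLength}
#' @examples
#' fragmentDetectionProb(98, 200)   # 103/200 = 0.515
#' fragmentDetectionProb(65, 200)   # 136/200 = 0.680
#' @export
fragmentDetectionProb <- function(ampliconLength, fragmentLength = NULL) {
  if (any(ampliconLength <= 0)) stop("ampliconLength must be > 0")
  if (is.null(fragmentLength) || all(is.na(fragmentLength)) ||
      all(is.infinite(fragmentLength)))
    return(rep(1, length(ampliconLength)))
  if (any(fragmentLength <= 0)) stop("fragmentLength must be > 0")
  vapply(ampliconLength, function(L)
    mean(pmax(0, (fragmentLength - L + 1) / fragmentLength)), numeric(1))
}

.restoreSeed <- function(seed) {
  # Run downstream draws from a caller-supplied seed without clobbering the
  # session RNG state.
  if (is.null(seed)) return(invisible(NULL))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    fn <- function() assign(".Random.seed", old, envir = globalenv())
  } else {
    fn <- function() suppressWarnings(
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  fn
}

.normalizeCopies <- function(copies, panel) {
  if (is.null(names(copies)) || any(!nzchar(names(copies))))
    stop("'copies' must be a named vector of genotype -> input copy number")
  unknown <- setdiff(names(copies), panel@targets$genotype)
  if (length(unknown))
    stop("unknown genotype(s) in 'copies': ", paste(unknown, collapse = ", "))
  if (any(copies < 0)) stop("copies must be >= 0")
  full <- setNames(numeric(nrow(panel@targets)), panel@targets$genotype)
  full[names(copies)] <- copies
  full
}

#' Partition template copies into wells
#'
#' Each genotype's detectable copy count is drawn as
#' Binomial(\code{copies}, \eqn{d}) with \eqn{d} from
#' [fragmentDetectionProb()], then copies are assigned to wells independently
#' and uniformly, so per-well counts are multinomial and marginally
#' approximately Poisson with mean \eqn{\lambda = } detectable copies /
#' \code{nWells}.  Assignment conserves totals exactly and is deterministic
#' given \code{seed}.
#'
#' @param panel a [DyePanel-class]
#' @param copies named vector, genotype -> input copy number
#' @param nWells number of wells on the chip
#' @param fragmentLength see [fragmentDetectionProb()]
#' @param seed optional integer seed
#' @return a [ChipTruth-class]
#' @export
partitionCopies <- function(panel, copies, nWells = .DEFAULT_N_WELLS,
                            fragmentLength = NULL, seed = NULL) {
  stopifnot(methods::is(panel, "DyePanel"))
  nWells <- as.integer(nWells)
  if (nWells <= 0L) stop("nWells must be > 0")
  copies <- .normalizeCopies(copies, panel)
  restore <- .restoreSeed(seed)
  if (!is.null(seed)) on.exit(restore(), add = TRUE)
  d <- setNames(
    fragmentDetectionProb(panel@targets$amplicon_length, fragmentLength),
    panel@targets$genotype)
  gt <- names(copies)
  counts <- matrix(0L, nrow = nWells, ncol = length(gt),
                   dimnames = list(NULL, gt))
  detectable <- setNames(integer(length(gt)), gt)
  for (g in gt) {
    nDet <- rbinom(1L, size = as.integer(round(copies[g])), prob = d[g])
    detectable[g] <- nDet
    if (nDet > 0L) {
      wells <- sample.int(nWells, nDet, replace = TRUE)
      counts[, g] <- tabulate(wells, nbins = nWells)
    }
  }
  methods::new("ChipTruth",
    counts = counts,
    injected = matrix(FALSE, nrow = nWells, ncol = length(gt),
                      dimnames = list(NULL, gt)),
    detectableCopies = as.numeric(detectable) |> setNames(gt),
    inputCopies = copies,
    detectionProb = d,
    fragmentLength = if (is.null(fragmentLength)) NA_real_
                     else as.numeric(fragmentLength)[1])
}

.injectFalsePositives <- function(truth, panel, rate) {
  if (rate < 0 || rate >= 1)
    stop("falsePositiveRate must be in [0, 1)")
  if (rate == 0) return(truth)
  tg <- panel@targets
  inj <- truth@injected
  for (i in which(tg$is_wt)) {
    locus <- tg$locus_group[i]
    muts <- tg$genotype[tg$locus_group == locus & !tg$is_wt]
    if (!length(muts)) next
    wtWells <- which(truth@counts[, tg$genotype[i]] > 0L)
    for (m in muts)
      inj[wtWells, m] <- inj[wtWells, m] |
        (runif(length(wtWells)) < rate)
  }
  truth@injected <- inj
  truth
}

.logisticMelt <- function(tempGrid, tm, w, amplitude = .AMPLITUDE) {
  amplitude * stats::plogis((tm - tempGrid) / w)
}

#' Synthesize the six-channel trace of a single well
#'
#' Per channel, fluorescence(T) = baseline + sum over present genotypes on
#' that channel of \eqn{A\,\sigma((T_m - T)/w)} with
#' \eqn{w = \mathrm{FWHM}/(2 \ln(3+2\sqrt2))}, plus Gaussian noise.  Presence
#' is binary: endpoint PCR saturates, so within-well copy number does not
#' change the amplitude.
#'
#' @param genotypes character vector (multiset) of genotypes present
#' @param panel a [DyePanel-class]
#' @param tempGrid temperature grid, degrees C
#' @param noiseSd Gaussian noise sd, fluorescence a.u.
#' @param baseline,amplitude baseline and per-target amplitude, a.u.
#' @param seed optional integer seed
#' @return numeric matrix, length(tempGrid) x 6 channels
#' @export
synthesizeTrace <- function(genotypes, panel,
                            tempGrid = .DEFAULT_TEMP_GRID(),
                            noiseSd = 0, baseline = .BASELINE,
                            amplitude = .AMPLITUDE, seed = NULL) {
  stopifnot(methods::is(panel, "DyePanel"))
  unknown <- setdiff(genotypes, panel@targets$genotype)
  if (length(unknown))
    stop("unknown genotype(s): ", paste(unknown, collapse = ", "))
  restore <- .restoreSeed(seed)
  if (!is.null(seed)) on.exit(restore(), add = TRUE)
  tg <- panel@targets
  out <- matrix(baseline, nrow = length(tempGrid),
                ncol = length(panel@channels),
                dimnames = list(NULL, panel@channels))
  for (g in unique(genotypes)) {
    i <- match(g, tg$genotype)
    out[, tg$channel[i]] <- out[, tg$channel[i]] +
      .logisticMelt(tempGrid, tg$tm[i], fwhmToScale(tg$fwhm[i]), amplitude)
  }
  if (noiseSd > 0)
    out <- out + matrix(rnorm(length(out), 0, noiseSd), nrow = nrow(out))
  out
}

#' Simulate a partitioned melting-curve chip
#'
#' Composes the full generative model: Binomial thinning by
#' fragment-detectability, uniform partitioning into wells, PCR-error false
#' positives (each well containing a locus wild type gains each of that
#' locus's mutants with probability \code{falsePositiveRate}), and per-well
#' six-channel logistic melt traces with additive Gaussian noise.  The
#' returned chip carries its [ChipTruth-class] in \code{metadata()$truth};
#' injected false positives are recorded there separately from true copies.
#'
#' @param panel a [DyePanel-class]
#' @param copies named vector, genotype -> input copy number
#' @param nWells wells on the chip (default 20000)
#' @param fragmentLength fragment length bp, or NULL for intact DNA
#' @param noiseSd trace noise sd, a.u. (default 0.03)
#' @param falsePositiveRate per-well per-mutant PCR-error probability
#' @param tempGrid temperature grid, degrees C (default 45--80 by 0.25)
#' @param seed optional integer seed (all draws flow from it)
#' @param baseline,amplitude trace baseline and per-target amplitude, a.u.
#' @return a [MeltChip-class]
#' @examples
#' chip <- simulateChip(defaultPanel(),
#'                      c(KRAS_WT_12_13 = 300, KRAS_G12D = 300),
#'                      nWells = 500, seed = 1)
#' detectableCopies(chipTruth(chip))
#' @export
simulateChip <- function(panel, copies, nWells = .DEFAULT_N_WELLS,
                         fragmentLength = NULL, noiseSd = .DEFAULT_NOISE_SD,
                         falsePositiveRate = 0,
                         tempGrid = .DEFAULT_TEMP_GRID(), seed = NULL,
                         baseline = .BASELINE, amplitude = .AMPLITUDE) {
  stopifnot(methods::is(panel, "DyePanel"))
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  restore <- .restoreSeed(seed)
  if (!is.null(seed)) on.exit(restore(), add = TRUE)
  truth <- partitionCopies(panel, copies, nWells = nWells,
                           fragmentLength = fragmentLength, seed = NULL)
  truth <- .injectFalsePositives(truth, panel, falsePositiveRate)
  presence <- truth@counts > 0L | truth@injected
  tg <- panel@targets
  nT <- length(tempGrid)
  assays <- setNames(vector("list", length(panel@channels)), panel@channels)
  for (ch in panel@channels) {
    mat <- matrix(baseline, nrow = nWells, ncol = nT)
    for (i in which(tg$channel == ch)) {
      idx <- which(presence[, tg$genotype[i]])
      if (!length(idx)) next
      curve <- .logisticMelt(tempGrid, tg$tm[i], fwhmToScale(tg$fwhm[i]),
                             amplitude)
      mat[idx, ] <- mat[idx, ] + rep(curve, each = length(idx))
    }
    if (noiseSd > 0)
      mat <- mat + matrix(rnorm(nWells * nT, 0, noiseSd), nrow = nWells)
    assays[[ch]] <- mat
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(well = seq_len(nWells)),
    colData = S4Vectors::DataFrame(temperature = tempGrid),
    metadata = list(truth = truth,
                    params = list(nWells = nWells, noiseSd = noiseSd,
                                  falsePositiveRate = falsePositiveRate,
                                  fragmentLength = fragmentLength,
                                  seed = seed, baseline = baseline,
                                  amplitude = amplitude)))
  methods::new("MeltChip", se)
}

# accessors --------------------------------------------------------------

#' @rdname meltplex-generics
#' @export
setMethod("temperatures", "MeltChip", function(x)
  SummarizedExperiment::colData(x)$temperature)

#' @rdname meltplex-generics
#' @export
setMethod("chipTruth", "MeltChip", function(x)
  S4Vectors::metadata(x)$truth)

#' @rdname meltplex-generics
#' @export
setMethod("wellCopies", "ChipTruth", function(x) x@counts)

#' @rdname meltplex-generics
#' @export
setMethod("injectedPositives", "ChipTruth", function(x) x@injected)

#' @rdname meltplex-generics
#' @export
setMethod("detectableCopies", "ChipTruth", function(x) x@detectableCopies)

#' @rdname meltplex-generics
#' @export
setMethod("occupancyCounts", "ChipTruth", function(x)
  colSums(x@counts > 0L | x@injected))

setMethod("show", "ChipTruth", function(object) {
  cat(sprintf("ChipTruth: %d wells x %d genotypes (fragment length: %s bp)\n",
              nrow(object@counts), ncol(object@counts),
              ifelse(is.na(object@fragmentLength), "intact",
                     format(object@fragmentLength))))
  nz <- object@detectableCopies[object@detectableCopies > 0]
  if (length(nz)) {
    cat("  detectable copies:\n")
    for (g in names(nz)) cat(sprintf("    %-15s %d\n", g, as.integer(nz[g])))
  } else cat("  empty chip\n")
  nInj <- sum(object@injected)
  if (nInj) cat(sprintf("  injected false-positive events: %d\n", nInj))
  invisible(NULL)
})

setMethod("show", "MeltChip", function(object) {
  cat(sprintf("MeltChip: %d wells, %d temperature points (%.2f-%.2f degC), channels: %s\n",
              nrow(object), ncol(object),
              min(temperatures(object)), max(temperatures(object)),
              paste(SummarizedExperiment::assayNames(object), collapse = ", ")))
  if (!is.null(chipTruth(object))) cat("  (simulated; ground truth attached)\n")
  invisible(NULL)
})
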