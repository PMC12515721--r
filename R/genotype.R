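# Well genotyping: map peak calls to genotyping windows, resolve shared-dye
# double positives by FWHM, aggregate positive-well counts.

#' FWHM thresholds for shared-dye double-positive resolution
#'
#' For each shared-dye pair the expected FWHM of a single-positive peak and
#' of the merged double-positive peak are obtained by pushing noiseless
#' synthetic curves through the same derivative pipeline used for calling;
#' the decision threshold is their midpoint.  Residual pipeline broadening
#' therefore cancels out of the classification.
#'
#' @param panel a [DyePanel-class]
#' @param params a [meltParams()] object
#' @param tempGrid temperature grid to evaluate on
#' @return named numeric vector, one threshold per shared pair
#'   (\code{"A|B"}), with the single/merged component widths in
#'   \code{attr(, "components")}
#' @export
fwhmDoubleThresholds <- function(panel, params = meltParams(),
                                 tempGrid = .DEFAULT_TEMP_GRID()) {
  stopifnot(methods::is(panel, "DyePanel"))
  pairs <- panel@sharedDyePairs
  out <- setNames(numeric(length(pairs)),
                  vapply(pairs, paste, "", collapse = "|"))
  comp <- list()
  measure <- function(genotypes) {
    tr <- synthesizeTrace(genotypes, panel, tempGrid, noiseSd = 0)
    ch <- panel@targets$channel[match(genotypes[1], panel@targets$genotype)]
    pk <- callWell(tr[, ch, drop = FALSE], tempGrid, params)
    if (nrow(pk) != 1L)
      stop("shared-dye pair does not merge into a single peak on this grid; ",
           "FWHM discrimination is not applicable")
    pk$fwhm[1]
  }
  for (k in seq_along(pairs)) {
    p <- pairs[[k]]
    single <- mean(c(measure(p[1]), measure(p[2])))
    merged <- measure(p)
    out[k] <- (single + merged) / 2
    comp[[names(out)[k]]] <- c(single = single, merged = merged)
  }
  attr(out, "components") <- comp
  out
}

#' Classify the genotypes present in wells from their melt peaks
#'
#' Each accepted peak whose Tm falls inside a genotyping window assigns that
#' window's genotype to its well (window membership = nearest window center
#' within the halfwidth; tie broken toward the lower Tm).  On a shared-dye
#' channel, a \emph{single} peak inside the pair's combined Tm region whose
#' FWHM reaches the pair's double-positive threshold assigns \emph{both}
#' genotypes (flag \code{merged_shared_dye}); two resolved peaks assign each
#' separately.  Peaks outside every window are flagged, not assigned.
#'
#' @param peaks peak table from [callPeaks()] (or [callWell()] with a
#'   \code{well} column added)
#' @param panel a [DyePanel-class]
#' @param params a [meltParams()] object (used to derive the FWHM
#'   thresholds when \code{thresholds} is NULL)
#' @param thresholds optional precomputed [fwhmDoubleThresholds()]
#' @return data.frame of assignments with columns \code{well},
#'   \code{genotype}, \code{merged_shared_dye}; flag counts are attached as
#'   attributes \code{nOutOfWindow} (peaks outside all windows),
#'   \code{truncatedWells}, and \code{nWells} is carried through
#' @export
classifyWells <- function(peaks, panel, params = meltParams(),
                          thresholds = NULL) {
  stopifnot(methods::is(panel, "DyePanel"))
  if (is.null(thresholds) && length(panel@sharedDyePairs))
    thresholds <- fwhmDoubleThresholds(panel, params)
  tg <- panel@targets
  hw <- panel@tmWindowHalfwidth
  n <- nrow(peaks)
  acc <- list()  # list of data.frames, bound once at the end
  outOfWindow <- 0L

  # nearest window center within halfwidth, vectorized over peaks;
  # tie -> lower Tm (centers pre-sorted ascending, ties resolve to first)
  nearestTargets <- function(tms, centers, genos) {
    ord <- order(centers)
    centers <- centers[ord]; genos <- genos[ord]
    d <- abs(outer(tms, centers, "-"))
    i <- max.col(-d, ties.method = "first")
    ifelse(d[cbind(seq_along(tms), i)] <= hw, genos[i], NA_character_)
  }

  sharedByChannel <- list()
  for (p in panel@sharedDyePairs) {
    ch <- tg$channel[match(p[1], tg$genotype)]
    sharedByChannel[[ch]] <- p
  }

  for (ch in unique(peaks$channel)) {
    sub <- peaks[peaks$channel == ch, , drop = FALSE]
    chTg <- tg[tg$channel == ch, , drop = FALSE]
    if (!nrow(chTg)) { outOfWindow <- outOfWindow + nrow(sub); next }
    pair <- sharedByChannel[[ch]]
    if (!is.null(pair)) {
      pc <- chTg$tm[match(pair, chTg$genotype)]
      lo <- min(pc) - hw; hi <- max(pc) + hw
      thr <- thresholds[[paste(pair, collapse = "|")]]
      inRegion <- sub$tm >= lo & sub$tm <= hi
      rp <- sub[inRegion, , drop = FALSE]
      if (nrow(rp)) {
        nPer <- stats::ave(rp$well, rp$well, FUN = length)
        isMerged <- nPer == 1L & !is.na(rp$fwhm) & rp$fwhm >= thr
        if (any(isMerged))
          acc[[length(acc) + 1L]] <- data.frame(
            well = rep(rp$well[isMerged], each = 2L),
            genotype = rep(pair, times = sum(isMerged)),
            merged_shared_dye = TRUE)
        if (any(!isMerged)) {
          gt <- nearestTargets(rp$tm[!isMerged], chTg$tm, chTg$genotype)
          miss <- is.na(gt)
          outOfWindow <- outOfWindow + sum(miss)
          if (any(!miss))
            acc[[length(acc) + 1L]] <- data.frame(
              well = rp$well[!isMerged][!miss], genotype = gt[!miss],
              merged_shared_dye = FALSE)
        }
      }
      sub <- sub[!inRegion, , drop = FALSE]
      if (!nrow(sub)) next
    }
    gt <- nearestTargets(sub$tm, chTg$tm, chTg$genotype)
    miss <- is.na(gt)
    outOfWindow <- outOfWindow + sum(miss)
    if (any(!miss))
      acc[[length(acc) + 1L]] <- data.frame(
        well = sub$well[!miss], genotype = gt[!miss],
        merged_shared_dye = FALSE)
  }
  res <- if (length(acc)) do.call(rbind, acc) else
    data.frame(well = integer(), genotype = character(),
               merged_shared_dye = logical())
  # deduplicate (a well's genotype set): keep flag if any contributing peak
  if (nrow(res)) {
    key <- paste(res$well, res$genotype)
    merged <- tapply(res$merged_shared_dye, key, any)
    res <- res[!duplicated(key), , drop = FALSE]
    res$merged_shared_dye <- as.logical(merged[paste(res$well, res$genotype)])
    res <- res[order(res$well, res$genotype), , drop = FALSE]
    rownames(res) <- NULL
  }
  attr(res, "nOutOfWindow") <- outOfWindow
  attr(res, "truncatedWells") <-
    if (n) length(unique(peaks$well[peaks$truncated])) else 0L
  attr(res, "nWells") <- attr(peaks, "nWells")
  res
}

#' Classify a single well
#'
#' Convenience wrapper around [classifyWells()] for one well's peak list.
#'
#' @param peaks data.frame from [callWell()]
#' @param panel a [DyePanel-class]
#' @param ... passed to [classifyWells()]
#' @return list with \code{genotypes} (character set) and \code{flags}
#'   (named logical: \code{merged_shared_dye}, \code{out_of_window_peak},
#'   \code{truncated_peak})
#' @export
classifyWell <- function(peaks, panel, ...) {
  peaks$well <- rep(1L, nrow(peaks))
  res <- classifyWells(peaks, panel, ...)
  list(genotypes = res$genotype,
       flags = c(merged_shared_dye = any(res$merged_shared_dye),
                 out_of_window_peak = attr(res, "nOutOfWindow") > 0L,
                 truncated_peak = any(peaks$truncated)))
}

#' Aggregate per-genotype positive-well counts
#'
#' \code{positives[g]} is the number of wells whose genotype set contains
#' \code{g}; a multi-positive well contributes to several genotypes.
#' Counting is permutation-invariant over wells.
#'
#' @param assignments data.frame from [classifyWells()] (columns \code{well},
#'   \code{genotype})
#' @param panel a [DyePanel-class]
#' @param nWells number of analyzed wells (defaults to
#'   \code{attr(assignments, "nWells")})
#' @return a [ChipCounts-class]
#' @export
countChip <- function(assignments, panel, nWells = NULL) {
  stopifnot(methods::is(panel, "DyePanel"))
  if (is.null(nWells)) nWells <- attr(assignments, "nWells")
  if (is.null(nWells)) stop("nWells must be supplied")
  if (nrow(assignments) &&
      anyDuplicated(paste(assignments$well, assignments$genotype)))
    stop("duplicate (well, genotype) entries in assignments")
  gt <- panel@targets$genotype
  unknown <- setdiff(unique(assignments$genotype), gt)
  if (length(unknown))
    stop("assignments contain unknown genotype(s): ",
         paste(unknown, collapse = ", "))
  pos <- table(factor(assignments$genotype, levels = gt))
  methods::new("ChipCounts",
    nWellsAnalyzed = as.integer(nWells),
    positives = setNames(as.integer(pos), gt),
    nOutOfWindow = as.integer(attr(assignments, "nOutOfWindow") %||% 0L))
}

#' Full chip genotyping pipeline
#'
#' [callPeaks()] then [classifyWells()] then [countChip()].
#'
#' @param chip a [MeltChip-class]
#' @param panel a [DyePanel-class]
#' @param params a [meltParams()] object
#' @param thresholds optional precomputed [fwhmDoubleThresholds()]
#' @return a [ChipCounts-class]
#' @export
genotypeChip <- function(chip, panel, params = meltParams(),
                         thresholds = NULL) {
  peaks <- callPeaks(chip, params)
  asg <- classifyWells(peaks, panel, params, thresholds = thresholds)
  countChip(asg, panel)
}

# accessors --------------------------------------------------------------

#' @rdname meltplex-generics
#' @export
setMethod("nWellsAnalyzed", "ChipCounts", function(x) x@nWellsAnalyzed)

#' @rdname meltplex-generics
#' @param genotype optional genotype label(s) to subset the counts
#' @export
setMethod("positiveWells", "ChipCounts", function(x, genotype = NULL) {
  if (is.null(genotype)) return(x@positives)
  miss <- setdiff(genotype, names(x@positives))
  if (length(miss)) stop("unknown genotype(s): ", paste(miss, collapse = ", "))
  x@positives[genotype]
})

#' @rdname meltplex-generics
#' @export
setMethod("outOfWindowPeaks", "ChipCounts", function(x) x@nOutOfWindow)

setMethod("show", "ChipCounts", function(object) {
  cat(sprintf("ChipCounts: %d wells analyzed, %d out-of-window peak(s)\n",
              object@nWellsAnalyzed, object@nOutOfWindow))
  nz <- object@positives[object@positives > 0L]
  if (length(nz))
    for (g in names(nz)) cat(sprintf("  %-15s %6d positive wells\n", g, nz[g]))
  else cat("  no positive wells\n")
  invisible(NULL)
})
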