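# Melt-peak calling: smoothed negative differentiation, peak detection with a
# robust noise floor, parabolic Tm refinement and interpolated half-height
# FWHM with a known-kernel broadening correction.

#' Melt-calling analysis parameters
#'
#' @param smoothHalfwidth moving-average halfwidth (grid points) applied to
#'   the raw melting curve before differentiation.
#' @param derivSmoothHalfwidth moving-average halfwidth (grid points) applied
#'   to the derivative curve used for peak \emph{detection} and Tm.  Kept
#'   mild so that two genuine transitions >= 5 degC apart remain two apexes.
#' @param fwhmSmoothHalfwidth moving-average halfwidth (grid points) of the
#'   second, heavier derivative used only to \emph{measure} peak width.
#'   Width at half height is exquisitely sensitive to in-band noise, so it
#'   is read off a strongly smoothed curve; the systematic broadening is
#'   removed again by the exact kernel calibration in [estimateTmFwhm()].
#' @param kMad peaks must have prominence >= \code{kMad} times the
#'   MAD-based robust noise estimate of the derivative curve.
#' @param minProminence absolute prominence floor, a.u./degC.  Kept small
#'   (6\% of the expected single-target derivative height) so that the
#'   shallow valley between two genuine melt peaks ~6 degC apart, or a peak
#'   whose tail is clipped by the grid edge, does not suppress a real apex;
#'   baseline noise is rejected by \code{minPeakHeight} and the
#'   \code{kMad} rule instead.
#' @param minPeakHeight absolute apex-height floor, a.u./degC.  Default is
#'   50\% of the expected derivative peak height of a single saturated
#'   target (amplitude 1, logistic scale 1.5 degC => height 1/6): endpoint
#'   PCR saturates, so genuine melt peaks sit near full amplitude and the
#'   floor rejects baseline noise outright.
#' @param mergeGridSteps accepted apexes within this many grid steps are
#'   merged, keeping the higher one (tie: lower temperature).
#' @return a list of class \code{MeltParams}
#' @export
meltParams <- function(smoothHalfwidth = 2L, derivSmoothHalfwidth = 3L,
                       fwhmSmoothHalfwidth = 9L, kMad = 5,
                       minProminence = 0.06 / 6,
                       minPeakHeight = 0.5 / 6, mergeGridSteps = 2L) {
  stopifnot(smoothHalfwidth >= 0, derivSmoothHalfwidth >= 0,
            fwhmSmoothHalfwidth >= derivSmoothHalfwidth, kMad >= 0,
            minProminence >= 0, minPeakHeight >= 0, mergeGridSteps >= 0)
  structure(list(smoothHalfwidth = as.integer(smoothHalfwidth),
                 derivSmoothHalfwidth = as.integer(derivSmoothHalfwidth),
                 fwhmSmoothHalfwidth = as.integer(fwhmSmoothHalfwidth),
                 kMad = kMad, minProminence = minProminence,
                 minPeakHeight = minPeakHeight,
                 mergeGridSteps = as.integer(mergeGridSteps)),
            class = "MeltParams")
}

# Cache of FWHM calibration tables, keyed by (kernel halfwidths, grid step).
.calCache <- new.env(parent = emptyenv())

# Exact width calibration for the smoothing/differentiation chain.  The
# kernel is known, so the map from the true FWHM of a logistic melt
# transition to the half-height width measured on the processed derivative
# is computed once (noiseless, same grid step) and inverted by monotone
# interpolation.  This removes the systematic broadening of the smoothing
# chain without any distributional approximation.
.fwhmCalibration <- function(params, h,
                             derivHalfwidth = params$fwhmSmoothHalfwidth) {
  key <- sprintf("%d|%d|%.6g", params$smoothHalfwidth, derivHalfwidth, h)
  hit <- .calCache[[key]]
  if (!is.null(hit)) return(hit)
  kern <- .derivKernel(params, h, derivHalfwidth)
  m <- (length(kern) - 1L) %/% 2L
  tt <- seq(-40, 40, by = h)
  trueF <- seq(0.5, 20, by = 0.25)
  rawOf <- function(f) {
    w <- fwhmToScale(f)
    y <- stats::plogis(-tt / w)
    n <- length(y)
    d <- vapply((m + 1L):(n - m), function(i)
      sum(kern * y[(i - m):(i + m)]), numeric(1))
    i <- which.max(d)
    half <- d[i] / 2
    l <- max(which(d[1:i] <= half))
    r <- i - 1L + min(which(d[i:length(d)] <= half))
    tl <- (l - 1L) * h + (half - d[l]) / (d[l + 1L] - d[l]) * h
    tr <- (r - 2L) * h + (d[r - 1L] - half) / (d[r - 1L] - d[r]) * h
    tr - tl
  }
  raw <- vapply(trueF, rawOf, numeric(1))
  keep <- c(TRUE, diff(raw) > 0)        # enforce strict monotonicity
  cal <- list(raw = raw[keep], true = trueF[keep])
  .calCache[[key]] <- cal
  cal
}

# invert the calibration: measured raw width -> true FWHM
.fwhmFromRaw <- function(raw, cal) {
  n <- length(cal$raw)
  if (raw <= cal$raw[1]) return(cal$true[1])
  if (raw >= cal$raw[n]) return(cal$true[n] + (raw - cal$raw[n]))
  stats::approx(cal$raw, cal$true, xout = raw)$y
}

# Full linear operator (sparse, nT x nOut): moving average, negated central
# difference, moving average.  deriv = trace %*% operator.
.derivKernel <- function(params, h,
                         derivHalfwidth = params$derivSmoothHalfwidth) {
  conv <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1L)
    for (i in seq_along(a))
      out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
    out
  }
  ma <- function(hw) rep(1 / (2 * hw + 1), 2 * hw + 1)
  # negative derivative of a decreasing melt curve is positive:
  # d_j = (F[j-1] - F[j+1]) / (2h)
  conv(ma(params$smoothHalfwidth), conv(c(1, 0, -1) / (2 * h),
                                        ma(derivHalfwidth)))
}

.derivOperator <- function(nT, h, params,
                           derivHalfwidth = params$derivSmoothHalfwidth) {
  kern <- .derivKernel(params, h, derivHalfwidth)
  m <- (length(kern) - 1L) %/% 2L         # margin consumed on each side
  nOut <- nT - 2L * m
  if (nOut < 3L)
    stop("too few temperature points for the smoothing/differentiation chain")
  i <- rep(seq_len(nOut), each = length(kern)) +
    rep(seq_along(kern) - 1L, times = nOut)
  j <- rep(seq_len(nOut), each = length(kern))
  Matrix::sparseMatrix(i = i, j = j, x = rep(kern, times = nOut),
                       dims = c(nT, nOut))
}

.checkGrid <- function(temperature) {
  if (length(temperature) < 5L)
    stop("at least 5 temperature points are required")
  h <- diff(temperature)
  if (any(h <= 0) || diff(range(h)) > 1e-8 * mean(h))
    stop("temperature grid must be uniform and strictly increasing")
  mean(h)
}

#' Negative derivative of a melting curve
#'
#' Applies moving-average smoothing to the raw fluorescence curve, a central
#' difference for \eqn{-dF/dT}, and moving-average smoothing of the
#' derivative, all as one linear operator.  The output lives on the interior
#' of the grid (the margins consumed by the kernels are dropped).
#'
#' @param intensity numeric vector (one curve) or matrix (wells x
#'   temperature) of fluorescence values
#' @param temperature uniform, strictly increasing temperature grid
#' @param params a [meltParams()] object
#' @param derivHalfwidth derivative-smoothing halfwidth: the detection scale
#'   (\code{params$derivSmoothHalfwidth}, default) or the width-measurement
#'   scale (\code{params$fwhmSmoothHalfwidth})
#' @return list with \code{temperature} (interior grid) and
#'   \code{derivative} (vector or matrix, matching the input shape)
#' @export
negativeDerivative <- function(intensity, temperature,
                               params = meltParams(),
                               derivHalfwidth = params$derivSmoothHalfwidth) {
  h <- .checkGrid(temperature)
  vec <- is.null(dim(intensity))
  mat <- if (vec) matrix(intensity, nrow = 1L) else as.matrix(intensity)
  if (ncol(mat) != length(temperature))
    stop("intensity and temperature lengths disagree")
  if (any(!is.finite(mat))) stop("intensity values must be finite")
  D <- .derivOperator(ncol(mat), h, params, derivHalfwidth)
  m <- (ncol(mat) - ncol(D)) %/% 2L
  dv <- as.matrix(mat %*% D)
  list(temperature = temperature[(m + 1L):(length(temperature) - m)],
       derivative = if (vec) dv[1L, ] else dv)
}

# -- reference (pure R) peak machinery ----------------------------------
# The Rcpp scanner in src/peakscan.cpp implements the identical algorithm
# for whole-chip matrices; a test pins the two paths to each other.

# Robust noise estimate of a derivative curve.  The MAD of the first
# differences is used rather than the MAD of the curve itself: melt-peak
# structure is smooth and cancels in the differences, so the estimate
# reflects the high-frequency noise floor and returns ~0 for noiseless
# curves regardless of how much of the channel carries signal.
.robustSigma <- function(y) {
  d <- diff(y)
  1.4826 * median(abs(d - median(d))) / sqrt(2)
}

.localMaxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer())
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

.prominence <- function(y, i) {
  n <- length(y)
  lmin <- y[i]; j <- i - 1L
  while (j >= 1L && y[j] <= y[i]) { lmin <- min(lmin, y[j]); j <- j - 1L }
  if (j < 1L) lmin <- min(lmin, min(y[1:i]))
  rmin <- y[i]; j <- i + 1L
  while (j <= n && y[j] <= y[i]) { rmin <- min(rmin, y[j]); j <- j + 1L }
  if (j > n) rmin <- min(rmin, min(y[i:n]))
  y[i] - max(lmin, rmin)
}

#' Locate melt peaks on a derivative curve
#'
#' Local maxima are accepted when their prominence exceeds both the absolute
#' floor and \code{kMad} times the MAD-based robust noise estimate of the
#' curve, and their height exceeds the height floor.  Accepted apexes within
#' \code{mergeGridSteps} of each other are merged (higher wins; tie: lower
#' temperature).  An empty result is legitimate (negative well).
#'
#' @param derivative numeric vector, \code{-dF/dT} from
#'   [negativeDerivative()]
#' @param temperature matching temperature grid
#' @param params a [meltParams()] object
#' @param sigma optional known noise level of the derivative; estimated
#'   robustly from the curve when NULL
#' @return data.frame with columns \code{index}, \code{temperature},
#'   \code{height}, \code{prominence}, ordered by temperature
#' @export
findPeaks <- function(derivative, temperature, params = meltParams(),
                      sigma = NULL) {
  if (any(!is.finite(derivative))) stop("derivative must be finite")
  if (is.null(sigma)) sigma <- .robustSigma(derivative)
  thr <- max(params$minProminence, params$kMad * sigma)
  cand <- .localMaxima(derivative)
  cand <- cand[derivative[cand] >= params$minPeakHeight]
  prom <- vapply(cand, function(i) .prominence(derivative, i), numeric(1))
  keep <- prom >= thr
  cand <- cand[keep]; prom <- prom[keep]
  # merge apexes within mergeGridSteps
  if (length(cand) > 1L) {
    ord <- order(cand)
    cand <- cand[ord]; prom <- prom[ord]
    keepIdx <- rep(TRUE, length(cand))
    i <- 1L
    while (i < length(cand)) {
      if (keepIdx[i] && cand[i + 1L] - cand[i] <= params$mergeGridSteps) {
        # keep the higher apex; tie -> lower temperature
        drop <- if (derivative[cand[i + 1L]] > derivative[cand[i]]) i else i + 1L
        keepIdx[drop] <- FALSE
        if (drop == i) i <- i + 1L else {
          cand[i + 1L] <- cand[i]; prom[i + 1L] <- prom[i]; i <- i + 1L
        }
      } else i <- i + 1L
    }
    cand <- cand[keepIdx]; prom <- prom[keepIdx]
  }
  data.frame(index = cand, temperature = temperature[cand],
             height = derivative[cand], prominence = prom)
}

#' Refine a melt peak: Tm and FWHM
#'
#' Tm is located by three-point parabolic interpolation around the apex.
#' FWHM is measured by linear interpolation of the half-height crossings on
#' each side and then mapped back to the pre-smoothing scale through the
#' exact kernel calibration (the smoothing chain is a known linear operator,
#' so its broadening of a logistic melt peak is computed once and inverted).
#' A side whose crossing runs off the grid
#' flags the peak as truncated and is mirrored from the other side; if the
#' curve rises again before crossing half height (overlapping neighbour
#' peak) that side is likewise mirrored.
#'
#' The derivative handed in should be computed at the width-measurement
#' scale (\code{derivHalfwidth = params$fwhmSmoothHalfwidth} in
#' [negativeDerivative()]); the calibration assumes that kernel.
#'
#' @param derivative numeric vector, \code{-dF/dT}
#' @param temperature matching temperature grid
#' @param index apex index (a local maximum)
#' @param params a [meltParams()] object
#' @param sigma noise level used for the valley tolerance (default 0)
#' @return list with \code{tm}, \code{fwhm}, \code{height},
#'   \code{truncated}
#' @export
estimateTmFwhm <- function(derivative, temperature, index,
                           params = meltParams(), sigma = 0) {
  n <- length(derivative)
  if (index < 2L || index > n - 1L)
    stop("apex index must be interior to the grid")
  if (derivative[index] < derivative[index - 1L] ||
      derivative[index] < derivative[index + 1L])
    stop("index is not a local maximum")
  h <- .checkGrid(temperature)
  y0 <- derivative[index]
  ym <- derivative[index - 1L]; yp <- derivative[index + 1L]
  den <- ym - 2 * y0 + yp
  delta <- if (den < 0) 0.5 * (ym - yp) / den else 0
  delta <- max(-0.5, min(0.5, delta))
  tm <- temperature[index] + delta * h
  height <- y0 - 0.25 * (ym - yp) * delta
  half <- height / 2
  valleyTol <- max(3 * sigma, 0.05 * height)

  walk <- function(step) {
    j <- index
    runMin <- derivative[index]
    while (TRUE) {
      jn <- j + step
      if (jn < 1L || jn > n) return(list(t = NA_real_, truncated = TRUE))
      yj <- derivative[jn]
      if (yj <= half) {
        frac <- (derivative[j] - half) / (derivative[j] - yj)
        return(list(t = temperature[j] + step * frac * h, truncated = FALSE))
      }
      runMin <- min(runMin, yj)
      if (yj - runMin > valleyTol)           # rose again: overlapping peak
        return(list(t = NA_real_, truncated = FALSE))
      j <- jn
    }
  }
  left <- walk(-1L); right <- walk(1L)
  truncated <- isTRUE(left$truncated) || isTRUE(right$truncated)
  wl <- if (!is.na(left$t)) tm - left$t else NA_real_
  wr <- if (!is.na(right$t)) right$t - tm else NA_real_
  if (is.na(wl)) wl <- wr
  if (is.na(wr)) wr <- wl
  fwhm <- if (is.na(wl)) NA_real_ else
    .fwhmFromRaw(wl + wr, .fwhmCalibration(params, h))
  list(tm = tm, fwhm = fwhm, height = height, truncated = truncated)
}

# Tm + height by three-point parabola at a grid apex (shared by both code
# paths; clamped to half a grid step).
.parabolicApex <- function(y, temperature, i, h) {
  y0 <- y[i]; ym <- y[i - 1L]; yp <- y[i + 1L]
  den <- ym - 2 * y0 + yp
  delta <- if (den < 0) 0.5 * (ym - yp) / den else 0
  delta <- max(-0.5, min(0.5, delta))
  list(tm = temperature[i] + delta * h,
       height = y0 - 0.25 * (ym - yp) * delta)
}

# re-localize a detection-scale apex on the width-measurement derivative:
# the local maximum of `heavy` within +/- steps of index iH0
.relocalizeApex <- function(heavy, iH0, steps = 4L) {
  n <- length(heavy)
  lo <- max(2L, iH0 - steps); hi <- min(n - 1L, iH0 + steps)
  if (lo > hi) return(NA_integer_)
  iH <- (lo:hi)[which.max(heavy[lo:hi])]
  # walk uphill to the true local maximum if the window clipped it
  while (iH > 1L && iH < n &&
         (heavy[iH - 1L] > heavy[iH] || heavy[iH + 1L] > heavy[iH])) {
    iH <- if (heavy[iH - 1L] > heavy[iH]) iH - 1L else iH + 1L
  }
  if (iH <= 1L || iH >= n) NA_integer_ else iH
}

#' Call melt peaks in a single well
#'
#' Runs the full per-channel chain on one well's trace matrix: detection
#' (and Tm) on the mildly smoothed derivative, width measurement on the
#' heavily smoothed derivative with exact kernel calibration.
#' Deterministic.
#'
#' @param trace numeric matrix, temperature points x channels, with channel
#'   column names
#' @param temperature temperature grid matching \code{nrow(trace)}
#' @param params a [meltParams()] object
#' @return data.frame with columns \code{channel}, \code{tm}, \code{fwhm},
#'   \code{height}, \code{prominence}, \code{truncated}
#' @export
callWell <- function(trace, temperature, params = meltParams()) {
  stopifnot(is.matrix(trace), !is.null(colnames(trace)))
  h <- .checkGrid(temperature)
  out <- list()
  for (ch in colnames(trace)) {
    nd <- negativeDerivative(trace[, ch], temperature, params)
    nf <- negativeDerivative(trace[, ch], temperature, params,
                             derivHalfwidth = params$fwhmSmoothHalfwidth)
    off <- (length(nd$derivative) - length(nf$derivative)) %/% 2L
    sigma <- .robustSigma(nd$derivative)
    sigmaF <- .robustSigma(nf$derivative)
    pk <- findPeaks(nd$derivative, nd$temperature, params, sigma = sigma)
    if (!nrow(pk)) next
    ref <- lapply(pk$index, function(i) {
      apex <- .parabolicApex(nd$derivative, nd$temperature, i, h)
      iH <- .relocalizeApex(nf$derivative, i - off)
      wf <- if (is.na(iH)) list(fwhm = NA_real_, truncated = TRUE)
            else estimateTmFwhm(nf$derivative, nf$temperature, iH, params,
                                sigma = sigmaF)
      list(tm = apex$tm, height = apex$height, fwhm = wf$fwhm,
           truncated = wf$truncated)
    })
    out[[ch]] <- data.frame(
      channel = ch,
      tm = vapply(ref, `[[`, numeric(1), "tm"),
      fwhm = vapply(ref, `[[`, numeric(1), "fwhm"),
      height = vapply(ref, `[[`, numeric(1), "height"),
      prominence = pk$prominence,
      truncated = vapply(ref, `[[`, logical(1), "truncated"))
  }
  if (!length(out))
    return(data.frame(channel = character(), tm = numeric(),
                      fwhm = numeric(), height = numeric(),
                      prominence = numeric(), truncated = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call melt peaks across a whole chip
#'
#' Vectorized chip-scale version of [callWell()]: per channel the derivative
#' of all wells is obtained with one sparse-operator multiplication and peaks
#' are scanned in compiled code (identical algorithm to the R reference
#' functions).
#'
#' @param chip a [MeltChip-class]
#' @param params a [meltParams()] object
#' @return data.frame of peak calls: \code{well}, \code{channel}, \code{tm},
#'   \code{fwhm}, \code{height}, \code{prominence}, \code{truncated}; the
#'   number of analyzed wells is attached as \code{attr(, "nWells")}
#' @export
callPeaks <- function(chip, params = meltParams()) {
  stopifnot(methods::is(chip, "MeltChip"))
  temps <- temperatures(chip)
  h <- .checkGrid(temps)
  D <- .derivOperator(length(temps), h, params)
  DF <- .derivOperator(length(temps), h, params,
                       params$fwhmSmoothHalfwidth)
  m <- (length(temps) - ncol(D)) %/% 2L
  tOut <- temps[(m + 1L):(length(temps) - m)]
  off <- (ncol(D) - ncol(DF)) %/% 2L
  cal <- .fwhmCalibration(params, h)
  wells <- SummarizedExperiment::rowData(chip)$well
  out <- list()
  for (ch in SummarizedExperiment::assayNames(chip)) {
    a <- SummarizedExperiment::assay(chip, ch)
    dv <- as.matrix(a %*% D)
    dvF <- as.matrix(a %*% DF)
    pk <- scan_peaks(dv, dvF, tOut, off, params$kMad, params$minProminence,
                     params$minPeakHeight, params$mergeGridSteps,
                     cal$raw, cal$true)
    if (!nrow(pk)) next
    pk$well <- wells[pk$row]
    pk$row <- NULL
    pk$channel <- ch
    out[[ch]] <- pk
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(tm = numeric(), fwhm = numeric(), height = numeric(),
               prominence = numeric(), truncated = logical(),
               well = integer(), channel = character())
  res <- res[, c("well", "channel", "tm", "fwhm", "height", "prominence",
                 "truncated")]
  res <- res[order(res$well, res$channel, res$tm), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "nWells") <- nrow(chip)
  res
}
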