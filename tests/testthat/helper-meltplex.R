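# Shared fixtures and independent numeric oracles.  Oracles deliberately
# avoid the package's derivative/peak machinery: they work on analytic
# curves evaluated on a fine grid.

DEFAULT_GRID <- seq(45, 80, by = 0.25)
LOGISTIC_FWHM <- 2 * log(3 + 2 * sqrt(2))   # FWHM of dlogis-type peak, x w

# negative derivative of a (sum of) logistic melt transition(s)
oracleDeriv <- function(tt, tms, w) {
  rowSums(vapply(tms, function(tm) {
    s <- stats::plogis((tm - tt) / w)
    s * (1 - s) / w
  }, numeric(length(tt))))
}

# FWHM of the analytic derivative peak by fine-grid half-height crossings
oracleFwhm <- function(tms, w, step = 0.001) {
  tt <- seq(min(tms) - 15, max(tms) + 15, by = step)
  y <- oracleDeriv(tt, tms, w)
  i <- which.max(y)
  half <- y[i] / 2
  left <- max(which(y[1:i] <= half))
  right <- i - 1 + min(which(y[i:length(y)] <= half))
  tt[right] - tt[left]
}

# one-channel MeltChip with every well holding the same genotype content
# (built from the simulator's own trace model plus iid noise)
channelChip <- function(panel, content, channel, nWells, noiseSd = 0.03,
                        seed = 1, tempGrid = DEFAULT_GRID) {
  base <- if (length(content))
    synthesizeTrace(content, panel, tempGrid, noiseSd = 0)[, channel]
  else rep(1, length(tempGrid))
  set.seed(seed)
  m <- matrix(rep(base, each = nWells), nrow = nWells)
  if (noiseSd > 0)
    m <- m + matrix(rnorm(nWells * length(tempGrid), 0, noiseSd),
                    nrow = nWells)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = stats::setNames(list(m), channel),
    rowData = S4Vectors::DataFrame(well = seq_len(nWells)),
    colData = S4Vectors::DataFrame(temperature = tempGrid))
  methods::new("MeltChip", se)
}

# per-well genotype sets from a ChipTruth, as a named list keyed by well
truthSets <- function(truth) {
  pres <- wellCopies(truth) > 0L | injectedPositives(truth)
  idx <- which(pres, arr.ind = TRUE)
  split(colnames(pres)[idx[, 2]], idx[, 1])
}
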