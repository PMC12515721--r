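test_that("fragment detectability follows the uniform-phase closed form", {
  expect_equal(fragmentDetectionProb(98, 200), 103 / 200)
  expect_equal(fragmentDetectionProb(65, 200), 136 / 200)
  # amplicon-size bias for the original primer set, cf. the measured
  # KRAS/RPP30 ratio on sheared DNA
  expect_equal(fragmentDetectionProb(98, 200) / fragmentDetectionProb(65, 200),
               0.515 / 0.680, tolerance = 1e-12)
  expect_equal(fragmentDetectionProb(300, 200), 0)
  expect_equal(fragmentDetectionProb(98, NULL), 1)
  expect_equal(fragmentDetectionProb(98, Inf), 1)
  # a vector of fragment lengths is an empirical distribution
  expect_equal(fragmentDetectionProb(98, c(150, 200, 250)),
               mean(c(53 / 150, 103 / 200, 153 / 250)))
  expect_error(fragmentDetectionProb(0, 200), "ampliconLength")
  expect_error(fragmentDetectionProb(98, -5), "fragmentLength")
})

test_that("detectability is monotone in amplicon and fragment length", {
  L <- seq(20, 320, by = 25)
  for (f in c(100, 200, 400)) {
    d <- fragmentDetectionProb(L, f)
    expect_true(all(diff(d) <= 0))       # non-increasing in amplicon length
  }
  for (l in c(65, 96, 98)) {
    d <- vapply(seq(70, 500, by = 10), function(f)
      fragmentDetectionProb(l, f), numeric(1))
    expect_true(all(diff(d) >= 0))       # non-decreasing in fragment length
  }
})

test_that("partitioning conserves copies exactly and is seed-deterministic", {
  p <- defaultPanel()
  tr <- partitionCopies(p, c(KRAS_G12D = 500, RPP30_WT = 900),
                        nWells = 2000, seed = 5)
  expect_equal(colSums(wellCopies(tr)), detectableCopies(tr))
  expect_equal(sum(detectableCopies(tr)), 1400)   # intact DNA: d = 1
  tr2 <- partitionCopies(p, c(KRAS_G12D = 500, RPP30_WT = 900),
                         nWells = 2000, seed = 5)
  expect_identical(wellCopies(tr), wellCopies(tr2))

  # fragmentation thins the totals but conservation still holds
  trf <- partitionCopies(p, c(RPP30_WT = 5000), nWells = 2000,
                         fragmentLength = 200, seed = 6)
  expect_equal(colSums(wellCopies(trf)), detectableCopies(trf))
  expect_lt(detectableCopies(trf)[["RPP30_WT"]], 5000)

  empty <- partitionCopies(p, c(KRAS_G12D = 0), nWells = 100, seed = 1)
  expect_true(all(wellCopies(empty) == 0L))
  expect_error(partitionCopies(p, c(KRAS_G12D = -1), nWells = 10), ">= 0")
  expect_error(partitionCopies(p, c(NOPE = 10), nWells = 10), "unknown")
  expect_error(partitionCopies(p, c(KRAS_G12D = 10), nWells = 0), "nWells")
})

test_that("occupancy matches the Poisson loading model", {
  # 9000 copies into 20000 wells: positive fraction ~ 1 - exp(-0.45)
  p <- defaultPanel()
  tr <- partitionCopies(p, c(RPP30_WT = 9000), nWells = 20000, seed = 7)
  k <- occupancyCounts(tr)[["RPP30_WT"]]
  pExp <- 1 - exp(-0.45)
  se <- sqrt(pExp * (1 - pExp) / 20000)
  expect_lt(abs(k / 20000 - pExp), 3 * se)
  # the Poisson estimator inverts occupancy to the realized detectable copies
  for (seed in 1:5) {
    tr <- partitionCopies(p, c(RPP30_WT = 9000), nWells = 20000, seed = seed)
    k <- occupancyCounts(tr)[["RPP30_WT"]]
    lam <- -log(1 - k / 20000)
    seLam <- sqrt(k / 20000 / ((1 - k / 20000) * 20000))
    expect_lt(abs(lam * 20000 - detectableCopies(tr)[["RPP30_WT"]]),
              3 * seLam * 20000)
  }
})

test_that("single-well traces follow the logistic melt model", {
  p <- defaultPanel()
  grid <- DEFAULT_GRID
  flat <- synthesizeTrace(character(0), p, grid, noiseSd = 0)
  expect_true(all(flat == 1))
  expect_equal(colnames(flat), channelNames(p))

  tr <- synthesizeTrace("KRAS_G12R", p, grid, noiseSd = 0)  # FAM, Tm 58
  expect_true(all(tr[, setdiff(channelNames(p), "FAM")] == 1))
  # independent oracle: raw central difference of the synthetic curve peaks
  # at the expected Tm with the analytic height A/(4w)
  d <- -(tr[-(1:2), "FAM"] - tr[seq_len(nrow(tr) - 2), "FAM"]) / 0.5
  tmid <- grid[-c(1, length(grid))]
  expect_equal(tmid[which.max(d)], 58, tolerance = 0.25)
  w <- fwhmToScale(panelTargets(p)$fwhm[1])
  expect_equal(max(d), 1 / (4 * w), tolerance = 0.01)

  # two same-channel targets 12 degC apart: two distinct derivative maxima
  tr2 <- synthesizeTrace(c("KRAS_G12D", "KRAS_G12V"), p, grid, noiseSd = 0)
  d2 <- -(tr2[-(1:2), "FAM"] - tr2[seq_len(nrow(tr2) - 2), "FAM"]) / 0.5
  locmax <- which(d2[2:(length(d2) - 1)] > d2[1:(length(d2) - 2)] &
                  d2[2:(length(d2) - 1)] > d2[3:length(d2)]) + 1L
  locmax <- locmax[d2[locmax] > 0.05]
  expect_length(locmax, 2L)
  expect_equal(sort(tmid[locmax]), c(52, 64), tolerance = 0.3)

  expect_error(synthesizeTrace("NOPE", p, grid), "unknown genotype")
})

test_that("chip simulation injects PCR-error false positives at the stated rate", {
  p <- defaultPanel()
  chip <- simulateChip(p, c(KRAS_WT_12_13 = 9000), nWells = 20000,
                       falsePositiveRate = 1e-3, noiseSd = 0, seed = 9)
  truth <- chipTruth(chip)
  inj <- colSums(injectedPositives(truth))
  # expected injections per codon-12/13 mutant: (WT-positive wells) * rate
  nWt <- sum(wellCopies(truth)[, "KRAS_WT_12_13"] > 0)
  lamInj <- nWt * 1e-3
  for (m in c("KRAS_G12D", "KRAS_G12V", "KRAS_G13D"))
    expect_lt(abs(inj[[m]] - lamInj), 3 * sqrt(lamInj) + 1)
  # mutants of other loci gain nothing from this wild type
  expect_equal(inj[["KRAS_Q61H"]], 0L)
  expect_equal(inj[["GNAS_R201H"]], 0L)
  # no injection at rate zero
  chip0 <- simulateChip(p, c(KRAS_WT_12_13 = 1000), nWells = 2000,
                        falsePositiveRate = 0, noiseSd = 0, seed = 9)
  expect_equal(sum(injectedPositives(chipTruth(chip0))), 0L)
  expect_error(simulateChip(p, c(KRAS_WT_12_13 = 10), nWells = 10,
                            falsePositiveRate = 1.5), "falsePositiveRate")
})

test_that("chip simulation is reproducible for a fixed seed", {
  p <- defaultPanel()
  a <- simulateChip(p, c(KRAS_G12D = 300, RPP30_WT = 400), nWells = 500,
                    seed = 21)
  b <- simulateChip(p, c(KRAS_G12D = 300, RPP30_WT = 400), nWells = 500,
                    seed = 21)
  expect_identical(wellCopies(chipTruth(a)), wellCopies(chipTruth(b)))
  for (ch in SummarizedExperiment::assayNames(a))
    expect_identical(SummarizedExperiment::assay(a, ch),
                     SummarizedExperiment::assay(b, ch))
  c <- simulateChip(p, c(KRAS_G12D = 300, RPP30_WT = 400), nWells = 500,
                    seed = 22)
  expect_false(identical(SummarizedExperiment::assay(a, "FAM"),
                         SummarizedExperiment::assay(c, "FAM")))
})
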