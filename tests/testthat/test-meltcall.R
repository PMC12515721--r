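test_that("negative differentiation behaves on elementary curves", {
  grid <- DEFAULT_GRID
  par <- meltParams()
  # linearly decreasing fluorescence: constant positive derivative
  lin <- negativeDerivative(5 - 0.1 * grid, grid, par)
  expect_true(all(abs(lin$derivative - 0.1) < 1e-10))
  # constant trace: all-zero derivative
  flat <- negativeDerivative(rep(2, length(grid)), grid, par)
  expect_true(all(abs(flat$derivative) < 1e-12))
  # the interior grid loses the kernel margins symmetrically
  m <- (length(grid) - length(flat$temperature)) / 2
  expect_equal(flat$temperature, grid[(m + 1):(length(grid) - m)])
  # logistic melt: derivative maximum within one grid step of Tm
  w <- fwhmToScale(5.2883)
  y <- 1 + plogis((60 - grid) / w)
  nd <- negativeDerivative(y, grid, par)
  expect_lt(abs(nd$temperature[which.max(nd$derivative)] - 60), 0.25 + 1e-9)
  expect_error(negativeDerivative(c(1, 2, 3), c(45, 45.25, 45.5)),
               "temperature points")
  expect_error(negativeDerivative(y[1:20], grid[1:20] + c(0, runif(19))),
               "uniform")
})

test_that("peak finding counts transitions correctly and ignores pure noise", {
  grid <- DEFAULT_GRID
  par <- meltParams()
  w <- fwhmToScale(5.2883)
  one <- 1 + plogis((60 - grid) / w)
  nd <- negativeDerivative(one, grid, par)
  expect_equal(nrow(findPeaks(nd$derivative, nd$temperature, par)), 1L)
  two <- 1 + plogis((52 - grid) / w) + plogis((68 - grid) / w)
  nd2 <- negativeDerivative(two, grid, par)
  pk2 <- findPeaks(nd2$derivative, nd2$temperature, par)
  expect_equal(nrow(pk2), 2L)
  expect_equal(pk2$temperature, sort(pk2$temperature))  # ordered by Tm

  # false-call rate on noise-only wells stays below 1%
  p <- defaultPanel()
  neg <- callPeaks(channelChip(p, character(0), "FAM", 10000, seed = 31))
  expect_lt(length(unique(neg$well)) / 10000, 0.01)
})

test_that("Tm and FWHM recover the analytic values on noiseless peaks", {
  grid <- DEFAULT_GRID
  par <- meltParams()
  w <- 1.5
  y <- 1 + plogis((60 - grid) / w)
  ndF <- negativeDerivative(y, grid, par,
                            derivHalfwidth = par$fwhmSmoothHalfwidth)
  i <- which.max(ndF$derivative)
  est <- estimateTmFwhm(ndF$derivative, ndF$temperature, i, par)
  expect_equal(est$tm, 60, tolerance = 0.05)
  # closed form: FWHM = 2 ln(3 + 2 sqrt(2)) w ~ 5.2883
  expect_equal(est$fwhm, LOGISTIC_FWHM * w, tolerance = 0.1)
  expect_false(est$truncated)
  # FWHM agrees with an independent fine-grid oracle of the same curve
  expect_equal(est$fwhm, oracleFwhm(60, w), tolerance = 0.02)
  expect_error(estimateTmFwhm(ndF$derivative, ndF$temperature, i + 3, par),
               "local maximum")
})

test_that("merged transitions broaden the peak monotonically with separation", {
  grid <- DEFAULT_GRID
  par <- meltParams()
  w <- 1.5
  single <- NULL
  prev <- 0
  for (dTm in c(0, 1, 2, 3)) {
    y <- 1 + plogis((60 - dTm / 2 - grid) / w) + plogis((60 + dTm / 2 - grid) / w)
    ndF <- negativeDerivative(y, grid, par,
                              derivHalfwidth = par$fwhmSmoothHalfwidth)
    i <- which.max(ndF$derivative)
    est <- estimateTmFwhm(ndF$derivative, ndF$temperature, i, par)
    expect_gte(est$fwhm, prev - 0.02)
    prev <- est$fwhm
    if (dTm == 0) single <- est$fwhm
  }
  expect_gt(prev, single + 1)  # 3 degC apart is clearly broadened
})

test_that("truncation near the grid edge is flagged", {
  grid <- DEFAULT_GRID
  par <- meltParams()
  # Tm close to the ramp start: the apex is detectable but the left
  # half-height crossing falls outside the smoothed grid
  y <- 1 + plogis((49.5 - grid) / 1.5)
  tr <- matrix(y, ncol = 1, dimnames = list(NULL, "FAM"))
  pk <- callWell(tr, grid, par)
  expect_equal(nrow(pk), 1L)
  expect_true(all(pk$truncated))
  # an interior peak is not flagged
  y2 <- 1 + plogis((60 - grid) / 1.5)
  pk2 <- callWell(matrix(y2, ncol = 1, dimnames = list(NULL, "FAM")),
                  grid, par)
  expect_false(any(pk2$truncated))
})

test_that("well-level calls recover channel and Tm of every panel target", {
  p <- defaultPanel()
  tg <- panelTargets(p)
  for (g in tg$genotype) {
    tr <- synthesizeTrace(g, p, DEFAULT_GRID, noiseSd = 0)
    pk <- callWell(tr, DEFAULT_GRID)
    expect_equal(nrow(pk), 1L, label = paste("one peak for", g))
    expect_equal(pk$channel, tg$channel[tg$genotype == g])
    expect_lt(abs(pk$tm - tg$tm[tg$genotype == g]), 0.1)
  }
  # empty well: no calls
  empty <- callWell(synthesizeTrace(character(0), p, DEFAULT_GRID),
                    DEFAULT_GRID)
  expect_equal(nrow(empty), 0L)
  # multi-channel well: one call per occupied channel
  tr3 <- synthesizeTrace(c("KRAS_G12D", "KRAS_Q61H", "RPP30_WT"), p,
                         DEFAULT_GRID, noiseSd = 0)
  pk3 <- callWell(tr3, DEFAULT_GRID)
  expect_setequal(pk3$channel, c("FAM", "CFR610", "Quasar705"))
})

test_that("Tm estimates are invariant to affine transforms of fluorescence", {
  p <- defaultPanel()
  tr <- synthesizeTrace("KRAS_G12V", p, DEFAULT_GRID, noiseSd = 0)
  pk1 <- callWell(tr, DEFAULT_GRID)
  tr2 <- tr * 3 + 0.7          # gain and offset change
  pk2 <- callWell(tr2, DEFAULT_GRID)
  expect_equal(pk2$tm, pk1$tm, tolerance = 1e-9)
  expect_equal(pk2$fwhm, pk1$fwhm, tolerance = 1e-9)
})

test_that("the compiled chip scanner matches the reference implementation", {
  p <- defaultPanel()
  grid <- DEFAULT_GRID
  # a mixed bag of wells: empty, single, shared-dye double, resolved pair
  contents <- list(character(0), "KRAS_WT_12_13", "GNAS_WT",
                   c("KRAS_WT_12_13", "GNAS_WT"),
                   c("KRAS_G12D", "KRAS_G12V"), "KRAS_G12D")
  set.seed(77)
  mats <- lapply(contents, function(ct) {
    base <- if (length(ct)) synthesizeTrace(ct, p, grid, noiseSd = 0)
            else matrix(1, length(grid), 6,
                        dimnames = list(NULL, channelNames(p)))
    base + matrix(rnorm(length(base), 0, 0.03), nrow = nrow(base))
  })
  assays <- lapply(channelNames(p), function(ch)
    t(vapply(mats, function(m) m[, ch], numeric(length(grid)))))
  names(assays) <- channelNames(p)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(well = seq_along(contents)),
    colData = S4Vectors::DataFrame(temperature = grid))
  chip <- methods::new("MeltChip", se)

  fast <- callPeaks(chip)
  slow <- do.call(rbind, lapply(seq_along(contents), function(i) {
    pk <- callWell(mats[[i]], grid)
    if (nrow(pk)) cbind(well = i, pk) else NULL
  }))
  slow <- slow[order(slow$well, slow$channel, slow$tm), ]
  rownames(slow) <- NULL
  expect_equal(nrow(fast), nrow(slow))
  expect_equal(fast$tm, slow$tm, tolerance = 1e-10)
  expect_equal(fast$fwhm, slow$fwhm, tolerance = 1e-10)
  expect_equal(fast$height, slow$height, tolerance = 1e-10)
  expect_equal(fast$prominence, slow$prominence, tolerance = 1e-10)
  expect_equal(fast$truncated, slow$truncated)
})
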