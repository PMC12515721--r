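test_that("Poisson lambda estimation matches closed forms", {
  z <- poissonLambda(0, 20000)
  expect_equal(z$lambda, 0)
  expect_equal(z$copies, 0)
  expect_equal(z$lambda_lower, 0)
  half <- poissonLambda(10000, 20000)
  expect_equal(half$lambda, log(2))
  expect_equal(half$copies, 20000 * log(2), tolerance = 1e-12)  # ~13863
  expect_true(half$lambda_lower < log(2) && log(2) < half$lambda_upper)
  # strictly increasing in k; lambda = 0 iff k = 0
  lam <- poissonLambda(0:19999, 20000)$lambda
  expect_true(all(diff(lam) > 0))
  expect_true(all(lam[-1] > 0))
  expect_error(poissonLambda(20000, 20000), "saturated")
  expect_error(poissonLambda(-1, 100), "0 <= k <= N")
  expect_error(poissonLambda(5, 0), "N must be")
})

test_that("the Wilson interval solves the score equation and tracks the exact interval", {
  # independent oracle: the Wilson bounds are the roots of
  # (p - phat)^2 = z^2 p (1 - p) / N
  k <- 50; N <- 100
  z <- qnorm(0.975)
  phat <- k / N
  rt <- sort(Re(polyroot(c(phat^2, -(2 * phat + z^2 / N),
                           1 + z^2 / N))))
  est <- poissonLambda(k, N)
  expect_equal(-log(1 - rt[1]), est$lambda_lower, tolerance = 1e-9)
  expect_equal(-log(1 - rt[2]), est$lambda_upper, tolerance = 1e-9)
  # and it stays close to the exact Clopper-Pearson interval
  cp <- binom.test(k, N)$conf.int
  expect_lt(abs(rt[1] - cp[1]), 0.025)
  expect_lt(abs(rt[2] - cp[2]), 0.025)
})

test_that("the 95% lambda interval has calibrated coverage at lambda 0.45", {
  lambda <- 0.45
  N <- 20000
  pTrue <- 1 - exp(-lambda)
  set.seed(61)
  k <- rbinom(1000, N, pTrue)
  est <- poissonLambda(k, N)
  cover <- mean(est$lambda_lower <= lambda & lambda <= est$lambda_upper)
  expect_gte(cover, 0.92)
  expect_lte(cover, 0.98)
})

test_that("allele fractions are computed on the lambda scale per locus", {
  p <- defaultPanel()
  gt <- panelTargets(p)$genotype
  mkCounts <- function(pos) {
    full <- setNames(integer(length(gt)), gt)
    full[names(pos)] <- as.integer(pos)
    methods::new("ChipCounts", nWellsAnalyzed = 20000L, positives = full,
                 nOutOfWindow = 0L)
  }
  # equal positives -> equal lambda -> 50/50
  cnt <- mkCounts(c(KRAS_WT_12_13 = 4000, KRAS_G12D = 4000))
  vaf <- locusVaf(cnt, p, "KRAS_12_13")
  expect_equal(vaf$fraction[vaf$genotype == "KRAS_G12D"], 0.5)
  expect_equal(sum(vaf$fraction), 1)
  # at high load the lambda scale corrects multi-copy wells: raw positive
  # fractions would understate the majority component
  cnt2 <- mkCounts(c(KRAS_WT_12_13 = 18000, KRAS_G12D = 4000))
  vaf2 <- locusVaf(cnt2, p, "KRAS_12_13")
  lamWt <- -log(1 - 0.9); lamMut <- -log(1 - 0.2)
  expect_equal(vaf2$fraction[vaf2$is_wt], lamWt / (lamWt + lamMut))
  # pure wild type: every mutant 0
  cnt3 <- mkCounts(c(KRAS_WT_12_13 = 5000))
  vaf3 <- locusVaf(cnt3, p, "KRAS_12_13")
  expect_true(all(vaf3$fraction[!vaf3$is_wt] == 0))
  # an all-zero locus reports NA, not zero
  vafZ <- locusVaf(cnt3, p, "GNAS_201")
  expect_true(all(is.na(vafZ$fraction)))
  # fractions sum to one exactly across random count tables
  set.seed(62)
  for (i in 1:20) {
    pos <- setNames(rbinom(length(gt), 15000, runif(1, 0.01, 0.5)), gt)
    v <- locusVaf(mkCounts(pos), p)
    for (lg in unique(v$locus_group))
      expect_equal(sum(v$fraction[v$locus_group == lg]), 1)
  }
})

test_that("CNA ratios compare the primary locus against the reference gene", {
  p <- defaultPanel()
  gt <- panelTargets(p)$genotype
  full <- setNames(integer(length(gt)), gt)
  full[c("KRAS_WT_12_13", "RPP30_WT")] <- 6000L
  cnt <- methods::new("ChipCounts", nWellsAnalyzed = 20000L,
                      positives = full, nOutOfWindow = 0L)
  r <- cnaRatio(cnt, p, "KRAS")
  expect_equal(r$ratio, 1)
  expect_true(r$lower < 1 && 1 < r$upper)
  # mutants of the codon 12/13 locus join the numerator; the codon 61 locus
  # does not (single amplicon counted once)
  full2 <- full
  full2["KRAS_G12D"] <- 3000L
  full2["KRAS_Q61H"] <- 3000L
  cnt2 <- methods::new("ChipCounts", nWellsAnalyzed = 20000L,
                       positives = full2, nOutOfWindow = 0L)
  r2 <- cnaRatio(cnt2, p, "KRAS")
  lam <- function(k) -log(1 - k / 20000)
  expect_equal(r2$ratio, (lam(6000) + lam(3000)) / lam(6000))
  # undefined without reference-gene signal
  full3 <- full; full3["RPP30_WT"] <- 0L
  cnt3 <- methods::new("ChipCounts", nWellsAnalyzed = 20000L,
                       positives = full3, nOutOfWindow = 0L)
  expect_error(cnaRatio(cnt3, p, "KRAS"), "RPP30")
})

test_that("limit of detection is mean plus three sample deviations", {
  expect_equal(lodFromReplicates(rep(0, 8))$lod, 0)
  expect_equal(lodFromReplicates(rep(0.001, 8))$lod, 0.001)
  x <- c(0, 0.001, 0.002, 0, 0.0005, 0.001, 0, 0.0015)
  l <- lodFromReplicates(x)
  expect_equal(l$lod, mean(x) + 3 * sd(x))   # sd uses the n-1 denominator
  expect_gte(l$lod, l$mean)
  expect_error(lodFromReplicates(0.01), "2 replicates")
})

test_that("linearity fits measured against input fractions", {
  x <- c(0.005, 0.02, 0.1, 0.25, 0.5)
  fit <- linearity(x, 2 * x)
  expect_equal(fit$r.squared, 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(linearity(x, rep(0.1, 5))$r.squared, 0)  # degenerate: 0
  expect_error(linearity(rep(0.1, 5), x), "zero variance")
  expect_error(linearity(x[1:2], x[1:2] * 2), "3 points")
})

test_that("chip quantification bundles estimates, fractions and ratios", {
  p <- defaultPanel()
  chip <- simulateChip(p, c(KRAS_WT_12_13 = 2000, KRAS_G12D = 2000,
                            RPP30_WT = 4000), nWells = 8000,
                       noiseSd = 0, seed = 71)
  res <- quantifyChip(genotypeChip(chip, p), p)
  est <- resultEstimates(res)
  expect_setequal(est$genotype, panelTargets(p)$genotype)
  expect_true(all(est$lambda_lower <= est$lambda &
                  est$lambda <= est$lambda_upper))
  v <- resultVaf(res)
  g12d <- v$fraction[v$genotype == "KRAS_G12D"]
  expect_equal(g12d, 0.5, tolerance = 0.05)
  cna <- resultCna(res)
  expect_setequal(cna$gene, c("KRAS", "GNAS"))
  kras <- cna[cna$gene == "KRAS", ]
  expect_true(kras$lower < kras$ratio & kras$ratio < kras$upper)
  expect_equal(kras$ratio, 1, tolerance = 0.1)
})
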