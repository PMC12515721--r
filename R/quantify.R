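# Poisson quantification: lambda and copies with Wilson-based CIs, per-locus
# allele fractions on the lambda scale, CNA ratios with delta-method CIs,
# limit of detection and linearity.

.wilsonInterval <- function(k, N, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / N
  denom <- 1 + z^2 / N
  center <- (p + z^2 / (2 * N)) / denom
  half <- z * sqrt(p * (1 - p) / N + z^2 / (4 * N^2)) / denom
  # at k = 0 the score lower bound is exactly 0; clear the rounding dust
  cbind(lower = ifelse(k == 0, 0, pmax(0, center - half)),
        upper = pmin(1, center + half))
}

#' Poisson estimate of mean copies per well
#'
#' From \code{k} positive wells out of \code{N}, the mean copies per well is
#' \eqn{\lambda = -\ln(1 - k/N)} and total copies \eqn{\lambda N}.  The 95\%
#' CI is the Wilson score interval on the positive fraction transformed
#' through \eqn{-\ln(1-\cdot)} (monotone, so coverage is preserved).
#'
#' @param k positive-well count(s)
#' @param N analyzed wells
#' @param conf confidence level
#' @return data.frame with columns \code{k}, \code{N}, \code{p},
#'   \code{lambda}, \code{copies}, \code{lambda_lower}, \code{lambda_upper}
#' @examples
#' poissonLambda(10000, 20000)  # lambda = log(2), copies ~ 13863
#' @export
poissonLambda <- function(k, N, conf = 0.95) {
  if (any(N <= 0)) stop("N must be > 0")
  if (any(k < 0) || any(k > N)) stop("k must satisfy 0 <= k <= N")
  if (any(k == N))
    stop("saturated chip: every well positive, lambda is unbounded")
  p <- k / N
  lambda <- -log1p(-p)
  ci <- .wilsonInterval(k, N, conf)
  data.frame(k = k, N = N, p = p, lambda = lambda, copies = lambda * N,
             lambda_lower = -log1p(-ci[, "lower"]),
             lambda_upper = -log1p(-pmin(ci[, "upper"], 1 - 1e-12)))
}

# variance of lambda-hat by the delta method: var(p-hat)/(1-p)^2
.lambdaVar <- function(k, N) {
  p <- k / N
  p / ((1 - p) * N)
}

#' @rdname meltplex-generics
#' @param panel a [DyePanel-class]
#' @param conf confidence level
#' @export
setMethod("chipEstimates", "ChipCounts", function(x, conf = 0.95) {
  est <- poissonLambda(as.numeric(x@positives), x@nWellsAnalyzed, conf)
  cbind(data.frame(genotype = names(x@positives)), est)
})

.lambdaByGenotype <- function(estimates) {
  setNames(estimates$lambda, estimates$genotype)
}

#' Per-locus variant allele fractions
#'
#' Fractions are computed on the \eqn{\lambda} scale (not raw positive-well
#' fractions), which corrects for multi-copy wells at high load:
#' \eqn{\mathrm{VAF}_m = \lambda_m / \sum_{g \in \mathrm{locus}} \lambda_g}.
#' Fractions of one locus sum to 1 exactly; an all-zero locus yields
#' \code{NA} (not available, not 0).
#'
#' @param x a [ChipCounts-class], or a data.frame of estimates from
#'   [chipEstimates()]
#' @param panel a [DyePanel-class]
#' @param locusGroup optional single locus group; default all
#' @return data.frame: \code{locus_group}, \code{genotype}, \code{is_wt},
#'   \code{lambda}, \code{fraction}
#' @export
setMethod("locusVaf", "ChipCounts", function(x, panel, locusGroup = NULL) {
  .locusVaf(chipEstimates(x), panel, locusGroup)
})

#' @rdname locusVaf-ChipCounts-method
#' @export
setMethod("locusVaf", "data.frame", function(x, panel, locusGroup = NULL) {
  .locusVaf(x, panel, locusGroup)
})

.locusVaf <- function(estimates, panel, locusGroup = NULL) {
  stopifnot(methods::is(panel, "DyePanel"))
  tg <- panel@targets
  loci <- locusGroup %||% unique(tg$locus_group)
  lam <- .lambdaByGenotype(estimates)
  out <- lapply(loci, function(lg) {
    genos <- locusGenotypes(panel, lg)
    if (!any(tg$is_wt[match(genos, tg$genotype)]))
      stop("locus ", lg, " has no wild-type target")
    l <- lam[genos]
    if (anyNA(l)) stop("estimates missing genotype(s) of locus ", lg)
    s <- sum(l)
    data.frame(locus_group = lg, genotype = genos,
               is_wt = tg$is_wt[match(genos, tg$genotype)],
               lambda = as.numeric(l),
               fraction = if (s > 0) as.numeric(l) / s else NA_real_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# primary copy-counting locus per CNA target gene: for KRAS only the codon
# 12/13 amplicon is counted (codon 61 is its own VAF locus but excluded from
# the CNA numerator to avoid double counting); GNAS uses codon 201.
.CNA_LOCUS <- c(KRAS = "KRAS_12_13", GNAS = "GNAS_201")
.CNA_REFERENCE <- "RPP30_WT"

#' Copy-number-alteration ratio versus the reference gene
#'
#' Ratio of the target gene's total \eqn{\lambda} (wild type plus mutants of
#' its primary copy-counting locus) to the reference gene RPP30's
#' \eqn{\lambda}, with a 95\% CI by the delta method on the log ratio
#' assuming independent numerator/denominator counts.
#'
#' @param x a [ChipCounts-class] or estimates data.frame
#' @param panel a [DyePanel-class]
#' @param gene \code{"KRAS"} or \code{"GNAS"}
#' @param conf confidence level
#' @return data.frame: \code{gene}, \code{ratio}, \code{lower}, \code{upper}
#' @export
setMethod("cnaRatio", "ChipCounts", function(x, panel, gene = "KRAS",
                                             conf = 0.95) {
  .cnaRatio(chipEstimates(x), panel, gene, conf)
})

#' @rdname cnaRatio-ChipCounts-method
#' @export
setMethod("cnaRatio", "data.frame", function(x, panel, gene = "KRAS",
                                             conf = 0.95) {
  .cnaRatio(x, panel, gene, conf)
})

.cnaRatio <- function(estimates, panel, gene, conf = 0.95) {
  stopifnot(methods::is(panel, "DyePanel"))
  gene <- match.arg(gene, names(.CNA_LOCUS))
  genos <- locusGenotypes(panel, .CNA_LOCUS[[gene]])
  i <- match(genos, estimates$genotype)
  j <- match(.CNA_REFERENCE, estimates$genotype)
  if (anyNA(i) || is.na(j)) stop("estimates missing required genotypes")
  num <- sum(estimates$lambda[i])
  den <- estimates$lambda[j]
  if (den <= 0) stop("reference gene RPP30 has zero lambda; ratio undefined")
  vNum <- sum(.lambdaVar(estimates$k[i], estimates$N[i]))
  vDen <- .lambdaVar(estimates$k[j], estimates$N[j])
  seLog <- sqrt(vNum / num^2 + vDen / den^2)
  z <- qnorm(1 - (1 - conf) / 2)
  ratio <- num / den
  data.frame(gene = gene, ratio = ratio,
             lower = ratio * exp(-z * seLog),
             upper = ratio * exp(z * seLog))
}

#' Limit of detection from wild-type-only replicates
#'
#' LOD = mean + 3 * sample SD (denominator n-1) of the mutant fraction
#' measured over replicate wild-type-only chips.
#'
#' @param fractions numeric vector of replicate mutant fractions (>= 2)
#' @return list with \code{mean}, \code{sd}, \code{lod}
#' @examples
#' lodFromReplicates(rep(0.001, 8))$lod  # 0.001 (SD = 0)
#' @export
lodFromReplicates <- function(fractions) {
  if (length(fractions) < 2L)
    stop("at least 2 replicates are required")
  m <- mean(fractions)
  s <- stats::sd(fractions)
  list(mean = m, sd = s, lod = m + 3 * s)
}

#' Linearity of measured versus input fraction
#'
#' Ordinary least squares of measured on input; R^2 is the squared Pearson
#' correlation (0 by convention when the measured values are constant).
#'
#' @param input input fractions (>= 3 points, non-constant)
#' @param measured measured fractions
#' @return list with \code{slope}, \code{intercept}, \code{r.squared}
#' @export
linearity <- function(input, measured) {
  if (length(input) != length(measured))
    stop("input and measured lengths differ")
  if (length(input) < 3L) stop("at least 3 points are required")
  if (var(input) == 0) stop("input fractions have zero variance")
  fit <- lm(measured ~ input)
  r2 <- if (var(measured) == 0) 0 else cor(input, measured)^2
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r.squared = r2)
}

#' Quantify a counted chip
#'
#' Combines [chipEstimates()], [locusVaf()] for every locus, and
#' [cnaRatio()] for KRAS and GNAS (when the reference gene is positive) into
#' one [QuantResult-class].
#'
#' @param counts a [ChipCounts-class]
#' @param panel a [DyePanel-class]
#' @param conf confidence level
#' @return a [QuantResult-class]
#' @export
quantifyChip <- function(counts, panel, conf = 0.95) {
  stopifnot(methods::is(counts, "ChipCounts"), methods::is(panel, "DyePanel"))
  est <- chipEstimates(counts, conf = conf)
  vaf <- .locusVaf(est, panel)
  refPos <- est$lambda[match(.CNA_REFERENCE, est$genotype)]
  cna <- if (!is.na(refPos) && refPos > 0)
    do.call(rbind, lapply(intersect(names(.CNA_LOCUS),
                                    unique(panel@targets$gene)),
                          function(g) .cnaRatio(est, panel, g, conf)))
  else data.frame(gene = character(), ratio = numeric(),
                  lower = numeric(), upper = numeric())
  methods::new("QuantResult", estimates = est, vaf = vaf, cna = cna,
               nWells = counts@nWellsAnalyzed)
}

#' @rdname quantifyChip
#' @param x a [QuantResult-class]
#' @export
resultEstimates <- function(x) { stopifnot(methods::is(x, "QuantResult")); x@estimates }

#' @rdname quantifyChip
#' @export
resultVaf <- function(x) { stopifnot(methods::is(x, "QuantResult")); x@vaf }

#' @rdname quantifyChip
#' @export
resultCna <- function(x) { stopifnot(methods::is(x, "QuantResult")); x@cna }

setMethod("show", "QuantResult", function(object) {
  cat(sprintf("QuantResult over %d wells\n", object@nWells))
  est <- object@estimates
  pos <- est[est$k > 0, , drop = FALSE]
  cat(sprintf("  %d genotype(s) positive:\n", nrow(pos)))
  for (i in seq_len(nrow(pos)))
    cat(sprintf("    %-15s k=%6d  lambda=%.4f  copies=%9.1f [%.1f, %.1f]\n",
                pos$genotype[i], pos$k[i], pos$lambda[i], pos$copies[i],
                pos$lambda_lower[i] * pos$N[i], pos$lambda_upper[i] * pos$N[i]))
  vaf <- object@vaf[!is.na(object@vaf$fraction) & !object@vaf$is_wt &
                    object@vaf$fraction > 0, , drop = FALSE]
  if (nrow(vaf)) {
    cat("  variant allele fractions:\n")
    for (i in seq_len(nrow(vaf)))
      cat(sprintf("    %-15s %6.2f%%\n", vaf$genotype[i],
                  100 * vaf$fraction[i]))
  }
  if (nrow(object@cna)) {
    cat("  copy-number ratios vs RPP30:\n")
    for (i in seq_len(nrow(object@cna)))
      cat(sprintf("    %-6s %.3f [%.3f, %.3f]\n", object@cna$gene[i],
                  object@cna$ratio[i], object@cna$lower[i],
                  object@cna$upper[i]))
  }
  invisible(NULL)
})
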