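---
title: "Melting-curve multiplex dPCR: models, calibration and design choices"
author: "meltplex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Melting-curve multiplex dPCR: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meltplex)
```

## The measurement problem

Digital PCR (dPCR) quantifies nucleic acids absolutely by partitioning a
sample into thousands of micro-reactions ("wells") and counting which ones
amplify.  Conventional dPCR reads one endpoint intensity per dye, which
caps multiplexing at the number of optical channels.  Adding melting-curve
analysis breaks that cap: molecular-beacon probes survive PCR, so after
thermal cycling the chip can be swept from 45 to 80 degrees C while imaging
all six dye channels, and each probe--target duplex reveals itself as a
melt transition at a characteristic melting temperature (Tm).  A genotype
is then identified by the *pair* (dye colour, Tm), and a single chip can
discriminate 14 targets: the eight common KRAS hotspot mutations (codons
12/13 and 61) with their wild types, the two common GNAS codon-201
mutations with wild type, and the reference gene RPP30 used to express
copy-number alterations (CNA) as a ratio.

This package implements the full analysis chain for such an assay --- and,
because raw chips from the custom instrument are not generally available, a
synthetic-chip generator with exact ground truth that serves as the test
bed for every downstream claim.

## Generative model of a chip

**Partitioning.**  Each genotype $g$ enters with $c_g$ template copies.  A
copy survives fragmentation with probability $d_g$ (below) and is then
assigned to one of $N$ wells uniformly and independently.  Per-well counts
are therefore multinomial, marginally Poisson with mean
$\lambda_g = d_g c_g / N$.  Copy conservation is exact by construction:
the per-well counts of a genotype always sum to its realized detectable
total, which the test suite asserts identically.

**Fragment-length detectability.**  A template is amplifiable only if one
fragment fully contains the amplicon.  With all fragments of length $F$
and a uniformly random cut phase, an amplicon of length $L$ survives with

$$d = \max\!\left(0, \frac{F - L + 1}{F}\right),$$

and $d = 1$ for intact DNA.  A vector of fragment lengths is treated as an
empirical distribution and $d$ is averaged over it.  This one-line model
is what makes amplicon-size matching matter: at $F = 200$ (sheared
genomic DNA of cell-free-DNA size) a 98 bp amplicon gives
$d = 103/200 = 0.515$ while a 65 bp amplicon gives $136/200 = 0.680$, so
the KRAS/RPP30 ratio of an unamplified genome reads
$0.515/0.680 \approx 0.76$ rather than 1 --- reproducing the published
fragmentation bias of the original primer set, and motivating the
redesigned near-matched 98/96/98 bp layout the default panel ships with.

**Melt traces.**  Endpoint PCR saturates, so presence is binary: within a
well, copy number does not change amplitude.  Each present genotype adds a
logistic melt step to its channel,

$$F_{ch}(T) = \text{baseline} + \sum_{g \in ch} A\,\sigma\!\left(\frac{T_{m,g} - T}{w_g}\right) + \varepsilon(T),$$

with $\varepsilon \sim \mathcal N(0, \sigma_n^2)$ i.i.d. per sample.  The
negative derivative of a logistic step is a symmetric peak whose full
width at half maximum is $\mathrm{FWHM} = 2\ln(3 + 2\sqrt 2)\,w \approx
3.5255\,w$; the panel stores expected FWHM and the generator converts to
$w$.  Defaults: baseline 1, amplitude 1, $\sigma_n = 0.03$ (a.u.; tests
are phrased in terms of this signal-to-noise ratio, not absolute units),
temperature grid 45--80 degrees C in 0.25 steps.  The physical ramp rate
fixes the sweep, not the sampling; the sampling density is our choice.

**PCR-error false positives.**  Wild-type templates occasionally
misprime into apparent mutants.  Each well containing a locus wild type
gains each of that locus's mutants with a configurable per-well
probability (default 0); injected events are recorded separately in the
ground truth so sensitivity analyses can distinguish them from real
copies.  The limit-of-detection study uses $10^{-4}$, which places every
mutant's LOD below the published 0.2% bound.

**Input scale.**  Simulated assays default to 9000 copies per target,
the package-wide convention for a 30 ng genomic DNA input, into
$2 \times 10^4$ wells ($\lambda \approx 0.45$).

## Peak calling

Melt calls are made per well and channel by numerical differentiation:

1. moving-average smoothing of the raw curve (halfwidth 2 grid points);
2. central difference $-dF/dT$;
3. moving-average smoothing of the derivative --- at **two scales**, a mild
   one (halfwidth 3) for peak *detection* and Tm, and a heavy one
   (halfwidth 9) used only to *measure* peak width;
4. apex acceptance, three-point parabolic Tm interpolation, and
   interpolated half-height FWHM.

The two scales deserve explanation, because a single compromise scale
fails both of its jobs.  Width at half height is read off two flank
crossings whose position noise is the curve noise divided by the flank
slope; with the default noise this makes FWHM on a mildly smoothed
derivative far too noisy to separate single from merged peaks (below).
Heavy smoothing fixes that, but a moving-average window of ~4.8 degrees C
fuses two genuine transitions 5--6 degrees apart into one apex, which
would break genotyping of wells containing two same-channel targets.
Detecting on the mild scale and measuring on the heavy scale decouples the
two requirements.

**Noise floor.**  The robust noise estimate is the scaled median absolute
deviation of the *first differences* of the derivative curve.  Melt-peak
structure is smooth and cancels in the differences, so the estimate
reflects the high-frequency noise floor, is immune to how much of the
channel carries signal, and returns 0 for noiseless curves.  (The MAD of
the curve itself is badly inflated when peaks occupy a large fraction of
the sweep, which silently suppresses real apexes.)

**Acceptance rules.**  An apex is accepted when its prominence exceeds
$\max(\text{floor}, k \cdot \widehat\sigma)$ with $k = 5$, and its height
exceeds 50% of the expected single-target derivative height.  Endpoint
PCR saturates, so genuine peaks sit near full amplitude and the height
floor rejects baseline noise outright (measured false-call rate on $10^4$
noise-only wells: 0).  The prominence floor is deliberately small (6% of
the expected height): the valley between two real peaks 6 degrees apart is
shallow, and a peak whose tail is clipped by the grid edge loses
prominence; both are real signals that a large floor would discard.
Apexes within 2 grid steps merge (higher wins; tie: lower temperature).

**Exact width calibration.**  Smoothing broadens peaks systematically.
Because the whole chain is one known linear kernel, the map from the true
FWHM of a logistic melt transition to the width measured on the processed
derivative is computed once per (kernel, grid step) --- noiselessly, by
pushing analytic curves through the same kernel --- and inverted by
monotone interpolation.  The reported FWHM of a noiseless single target is
then exact to $\sim 10^{-4}$ degrees C, and, because classification
thresholds are computed through the *same* pipeline, genotyping is
invariant to this (monotone) recalibration.  The calibration assumes the
logistic peak shape; for merged double peaks it is approximate, which is
immaterial for classification (same argument) and is why the merged-width
test tolerances are looser than the single-peak ones.

## Genotyping

Each accepted peak whose Tm falls inside a target's fixed window
(expected Tm $\pm$ 1.5 degrees C on the target's channel; membership by
nearest window centre, ties to the lower Tm) assigns that genotype to its
well.  Peaks outside every window are flagged and excluded from counting
rather than reassigned.

**Shared-dye double positives.**  The panel deliberately places
KRAS wild type (12/13) and GNAS wild type on one channel only
3 degrees C apart --- mirroring the published layout's need to discriminate
the two by peak shape.  At that separation two logistic transitions merge
into a single apex, so a double-positive well shows *one* broadened peak.
The decision statistic is the calibrated FWHM: the threshold is the
midpoint between the expected single-peak width and the numerically
computed width of the merged pair (both measured through the calling
pipeline, so pipeline broadening cancels).  A single peak in the pair's
combined region at or above threshold assigns both genotypes and flags the
well; two resolved peaks assign each separately.  Measured on $10^4$
simulated wells at default noise: 99.96% of true double-positive wells
are assigned both genotypes, 0.5% of single-positive wells are falsely
double-called.

**Panel layout.**  Published figures show the layout qualitatively but no
per-probe Tm values, so the default panel places each channel's targets on
an evenly spaced Tm grid between 50 and 75 degrees C with >= 5 degrees C
separation (any layout satisfying the separation invariant reproduces the
method), keeps the shared-dye pair at 3 degrees C, and uses a window
halfwidth of 1.5 degrees C --- half the shared-pair spacing.  Panel
validation enforces that any two same-channel targets are either
>= 2 halfwidths apart or registered as a shared-dye pair.

## Quantification

With $k$ of $N$ analyzed wells positive for a genotype, the mean copies
per well is $\hat\lambda = -\ln(1 - k/N)$ and total copies
$\hat\lambda N$.  A saturated chip ($k = N$) is an error, not a number.

**Confidence intervals.**  The published description ("95% confidence
intervals calculated from the Poisson probability") does not pin down a
construction.  We use the Wilson score interval on the positive fraction
transformed through $-\ln(1-\cdot)$: the transform is monotone, so
coverage is preserved, and the interval is well-behaved at $k = 0$.
Empirical coverage at $\lambda = 0.45$ over 1000 simulated chips sits
inside [92%, 98%], which the acceptance suite asserts.  Ratio CIs (below)
use the delta method on the log ratio with
$\mathrm{Var}(\hat\lambda) \approx p/((1-p)N)$, assuming independent
numerator and denominator counts.

**Allele fractions.**  Variant allele fractions are computed on the
$\lambda$ scale, $\mathrm{VAF}_m = \lambda_m / \sum_{g} \lambda_g$ over
the locus, not on raw positive fractions: at high load multi-copy wells
compress raw fractions, while $\lambda$ ratios remain unbiased; at low
load the two coincide.  Locus fractions sum to 1 exactly; an all-zero
locus reports NA rather than 0.

**CNA ratios.**  The CNA ratio of a target gene is its total $\lambda$
(wild type plus mutants of its primary copy-counting locus) over the
RPP30 $\lambda$.  For KRAS only the codon 12/13 locus enters the
numerator: the assay amplifies KRAS with a single primer pair (one
98 bp amplicon), so counting the codon 61 locus as well would double-count
molecules.  Codon 61 keeps its own locus for VAF purposes.

**LOD and linearity.**  The limit of detection of each mutant is
mean + 3 sample SD (denominator $n-1$) of its measured fraction over 8
wild-type-only replicate chips; no multiple-testing adjustment is applied
across the ten mutants, matching the published procedure.  Linearity of a
spike-in series is ordinary least squares of measured on input fraction
with $R^2$ the squared Pearson correlation (0 by convention for constant
measurements; constant inputs are an error).

## What the generator does and does not emulate

Emulated: Poisson loading of up to $2\times10^4$ wells, arbitrary
genotype mixtures, fragment-length-dependent detectability (fixed length
or empirical distribution), six-channel logistic melt transitions with
shared-dye superposition, additive Gaussian noise, per-well PCR-error
false positives, and exact ground truth for every well.

Not emulated: chip imaging and image segmentation (the pipeline starts
from per-well traces), optical crosstalk between dye filters, well-to-well
amplitude variation and partial amplification, temperature gradients
across the chip, probe thermodynamics (Tm values are panel parameters, not
sequence predictions), and polymerase-specific error spectra (the
false-positive rate is a single tunable probability).  Passing tests
therefore demonstrate the correctness and statistical calibration of the
*analysis* under the stated physical model --- not instrument-level
performance on real chips, where crosstalk and amplitude dispersion would
first have to be characterized.

## Numerical choices and degenerate inputs

* Temperature grid: uniform, strictly increasing; at least 5 points; the
  kernels consume a fixed margin (3 degrees C at default parameters) at
  each end, and a half-height crossing running off the grid flags the peak
  as truncated and mirrors the other side.
* A side on which the curve rises again before crossing half height
  (overlapping neighbour peak) is likewise mirrored; the rise tolerance is
  $\max(3\widehat\sigma, 5\%\ \text{of height})$.
* Window-boundary peaks go to the nearest centre, ties to the lower Tm;
  all tie-breaks are deterministic, and the whole pipeline is
  reproducible: one seed drives every stochastic draw of a simulated chip,
  and fixed seed + config gives byte-identical outputs.
* Wells with unparseable trace records are dropped (and counted) at read
  time; wells with a missing channel keep their other channels.

## Problem sizes used by the shipped tests

The test and acceptance suites run full-size chips ($2\times10^4$ wells)
where the claim is about chip-scale statistics: 10-seed means for the
three fragmentation-bias ratios, single chips for the four
mixture-genotyping standards, 8 replicates for LOD, 5 chips for the
spike-in series, 1000 binomial replicates for CI coverage, and $10^4$-well
single-channel batteries for the false-call and double-positive error
rates.  Unit tests of the panel, IO and estimator layers use chips of
50--8000 wells, which exercise the same code paths at negligible cost.

## Known limitations

* The FWHM calibration is exact for single logistic transitions only;
  strongly overlapped (but resolved) peaks report widths biased by the
  neighbour's flank.  Classification does not consume those widths.
* Same-channel targets 6 degrees C apart in one well are resolved with
  ~85% efficiency at default noise (the valley between them is shallow);
  such co-occupancies are rare at $\lambda \approx 0.45$ and unbiased
  between the two members, so locus fractions are essentially unaffected,
  but heavy same-channel co-loading would warrant wider Tm spacing.
* The Wilson-transformed interval is per-genotype; chip-to-chip
  variation (pipetting, chip lot) is outside the statistical model.
* CNA ratios assume the reference gene itself is copy-neutral; with an
  amplified or deleted RPP30 the ratio moves for every target, a
  limitation shared with any single-reference design.
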