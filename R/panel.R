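# Panel definition, validation, serialization, genotyping windows.

.PANEL_SCHEMA_VERSION <- "1.0"

# FWHM of the negative derivative of a logistic melt transition with scale w
# is 2*log(3 + 2*sqrt(2)) * w  (the half-maximum points of s(x)(1-s(x))).
.LOGISTIC_FWHM_FACTOR <- 2 * log(3 + 2 * sqrt(2))

#' Convert between melt-peak FWHM and logistic scale
#'
#' The simulator models each melt transition as a logistic step
#' \eqn{A \cdot \sigma((T_m - T)/w)}; the negative derivative is then a
#' symmetric peak whose full width at half maximum is
#' \eqn{2\,\ln(3+2\sqrt2)\,w \approx 3.5255\,w}.
#'
#' @param fwhm peak full width at half maximum, degrees C
#' @param w logistic scale parameter, degrees C
#' @return the corresponding scale \code{w} (for \code{fwhmToScale}) or FWHM
#'   (for \code{scaleToFwhm}).
#' @examples
#' scaleToFwhm(1.5)   # ~5.29 degC
#' @export
fwhmToScale <- function(fwhm) fwhm / .LOGISTIC_FWHM_FACTOR

#' @rdname fwhmToScale
#' @export
scaleToFwhm <- function(w) w * .LOGISTIC_FWHM_FACTOR

.newPanel <- function(targets, channels, tmWindowHalfwidth, sharedDyePairs,
                      schemaVersion = .PANEL_SCHEMA_VERSION) {
  targets <- as.data.frame(targets, stringsAsFactors = FALSE)
  rownames(targets) <- NULL
  methods::new("DyePanel",
    targets = targets[, .PANEL_COLUMNS],
    channels = as.character(channels),
    tmWindowHalfwidth = as.numeric(tmWindowHalfwidth),
    sharedDyePairs = lapply(sharedDyePairs, as.character),
    schemaVersion = as.character(schemaVersion))
}

#' The default 14-target KRAS/GNAS/RPP30 panel
#'
#' Builds the shipped assay layout: the eight most common KRAS hotspot
#' mutations (codons 12/13 and 61) with their wild-type counterparts, the two
#' common GNAS codon-201 mutations with wild type, and the reference gene
#' RPP30, spread over six dye channels.  Targets on one channel sit on an
#' evenly spaced Tm grid (>= 5 degC apart) except for the deliberately close
#' KRAS-WT(12/13) / GNAS-WT pair (delta Tm = 3 degC) registered as a
#' shared-dye pair and resolved by FWHM.
#'
#' Amplicon lengths default to the redesigned assay (KRAS 98 bp, GNAS 96 bp,
#' RPP30 98 bp); pass \code{rpp30AmpliconLength = 65} for the original RPP30
#' primers to study fragmentation bias.
#'
#' @param rpp30AmpliconLength amplicon length (bp) of the RPP30 target
#' @param tmWindowHalfwidth genotyping-window half-width, degrees C
#' @return a validated [DyePanel-class]
#' @examples
#' p <- defaultPanel()
#' nrow(panelTargets(p))  # 14
#' @export
defaultPanel <- function(rpp30AmpliconLength = 98, tmWindowHalfwidth = 1.5) {
  fw <- scaleToFwhm(1.5)  # ~5.2883 degC, shared by all probes by default
  t <- function(genotype, gene, locus, channel, is_wt, tm, amp)
    data.frame(genotype = genotype, gene = gene, locus_group = locus,
               channel = channel, is_wt = is_wt, tm = tm, fwhm = fw,
               amplicon_length = amp, stringsAsFactors = FALSE)
  targets <- rbind(
    t("KRAS_WT_12_13", "KRAS", "KRAS_12_13", "ATTO425",  TRUE,  58, 98),
    t("GNAS_WT",       "GNAS", "GNAS_201",   "ATTO425",  TRUE,  61, 96),
    t("KRAS_G12D",     "KRAS", "KRAS_12_13", "FAM",      FALSE, 52, 98),
    t("KRAS_G12R",     "KRAS", "KRAS_12_13", "FAM",      FALSE, 58, 98),
    t("KRAS_G12V",     "KRAS", "KRAS_12_13", "FAM",      FALSE, 64, 98),
    t("KRAS_G12A",     "KRAS", "KRAS_12_13", "FAM",      FALSE, 70, 98),
    t("KRAS_G13D",     "KRAS", "KRAS_12_13", "HEX",      FALSE, 52, 98),
    t("KRAS_G12S",     "KRAS", "KRAS_12_13", "HEX",      FALSE, 58, 98),
    t("KRAS_G12C",     "KRAS", "KRAS_12_13", "HEX",      FALSE, 64, 98),
    t("KRAS_WT_61",    "KRAS", "KRAS_61",    "CFR610",   TRUE,  55, 98),
    t("KRAS_Q61H",     "KRAS", "KRAS_61",    "CFR610",   FALSE, 62, 98),
    t("GNAS_R201H",    "GNAS", "GNAS_201",   "Cy5",      FALSE, 55, 96),
    t("GNAS_R201C",    "GNAS", "GNAS_201",   "Cy5",      FALSE, 62, 96),
    t("RPP30_WT",      "RPP30","RPP30",      "Quasar705",TRUE,  58,
      rpp30AmpliconLength)
  )
  pan <- .newPanel(targets,
    channels = c("ATTO425", "FAM", "HEX", "CFR610", "Cy5", "Quasar705"),
    tmWindowHalfwidth = tmWindowHalfwidth,
    sharedDyePairs = list(c("KRAS_WT_12_13", "GNAS_WT")))
  methods::validObject(pan)
  pan
}

#' Change the amplicon length of one gene's targets
#'
#' @param panel a [DyePanel-class]
#' @param gene gene symbol (all of its targets are updated)
#' @param length new amplicon length, bp
#' @return the modified panel
#' @export
setAmpliconLength <- function(panel, gene, length) {
  stopifnot(methods::is(panel, "DyePanel"), length > 0)
  hit <- panel@targets$gene == gene
  if (!any(hit)) stop("unknown gene: ", gene)
  panel@targets$amplicon_length[hit] <- length
  methods::validObject(panel)
  panel
}

#' Read a panel configuration file
#'
#' The config is YAML with fields \code{schema_version},
#' \code{tm_window_halfwidth}, \code{channels} (six names),
#' \code{shared_dye_pairs} (list of two-element lists) and \code{targets}
#' (list of records with \code{genotype}, \code{gene}, \code{locus_group},
#' \code{channel}, \code{is_wt}, \code{tm}, \code{fwhm},
#' \code{amplicon_length}).  Validation enforces the Tm-separation invariant;
#' overlapping same-channel windows not declared shared-dye raise an error
#' naming both targets.
#'
#' @param path path to a YAML panel config
#' @return a validated [DyePanel-class]
#' @seealso [writePanel()], [defaultPanel()]
#' @export
loadPanel <- function(path) {
  if (!file.exists(path)) stop("panel config not found: ", path)
  cfg <- yaml::read_yaml(path)
  need <- c("channels", "targets", "tm_window_halfwidth")
  if (!all(need %in% names(cfg)))
    stop("panel config must define: ", paste(need, collapse = ", "))
  targets <- do.call(rbind, lapply(cfg$targets, function(rec) {
    miss <- setdiff(.PANEL_COLUMNS, names(rec))
    if (length(miss))
      stop("target record missing field(s): ", paste(miss, collapse = ", "))
    data.frame(genotype = rec$genotype, gene = rec$gene,
               locus_group = rec$locus_group, channel = rec$channel,
               is_wt = as.logical(rec$is_wt), tm = as.numeric(rec$tm),
               fwhm = as.numeric(rec$fwhm),
               amplicon_length = as.numeric(rec$amplicon_length),
               stringsAsFactors = FALSE)
  }))
  pan <- .newPanel(targets, channels = unlist(cfg$channels),
                   tmWindowHalfwidth = cfg$tm_window_halfwidth,
                   sharedDyePairs = cfg$shared_dye_pairs %||% list(),
                   schemaVersion = cfg$schema_version %||% .PANEL_SCHEMA_VERSION)
  methods::validObject(pan)
  pan
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a panel configuration file
#'
#' @param panel a [DyePanel-class]
#' @param path output YAML path
#' @return \code{path}, invisibly
#' @export
writePanel <- function(panel, path) {
  stopifnot(methods::is(panel, "DyePanel"))
  tg <- panel@targets
  cfg <- list(
    schema_version = panel@schemaVersion,
    tm_window_halfwidth = panel@tmWindowHalfwidth,
    channels = as.list(panel@channels),
    shared_dye_pairs = lapply(panel@sharedDyePairs, as.list),
    targets = lapply(seq_len(nrow(tg)), function(i) list(
      genotype = tg$genotype[i], gene = tg$gene[i],
      locus_group = tg$locus_group[i], channel = tg$channel[i],
      is_wt = tg$is_wt[i], tm = tg$tm[i], fwhm = tg$fwhm[i],
      amplicon_length = tg$amplicon_length[i]))
  )
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' Genotyping window of one target
#'
#' Returns the fixed (channel, Tm interval) window used to assign melt peaks
#' to this genotype: \code{[tm - halfwidth, tm + halfwidth]} on the target's
#' dye channel.  Windows are a property of the panel and do not change
#' between experiments.
#'
#' @param panel a [DyePanel-class]
#' @param genotype genotype label
#' @return list with \code{genotype}, \code{channel}, \code{center},
#'   \code{lower}, \code{upper}
#' @export
genotypingWindow <- function(panel, genotype) {
  stopifnot(methods::is(panel, "DyePanel"))
  i <- match(genotype, panel@targets$genotype)
  if (is.na(i)) stop("unknown genotype: ", genotype)
  hw <- panel@tmWindowHalfwidth
  list(genotype = genotype, channel = panel@targets$channel[i],
       center = panel@targets$tm[i],
       lower = panel@targets$tm[i] - hw, upper = panel@targets$tm[i] + hw)
}

# locus helpers ---------------------------------------------------------

#' Genotypes of one locus group
#'
#' @param panel a [DyePanel-class]
#' @param locusGroup locus group label (e.g. \code{"KRAS_12_13"})
#' @return character vector of genotype labels (wild type first)
#' @export
locusGenotypes <- function(panel, locusGroup) {
  tg <- panel@targets
  sub <- tg[tg$locus_group == locusGroup, , drop = FALSE]
  if (!nrow(sub)) stop("unknown locus group: ", locusGroup)
  c(sub$genotype[sub$is_wt], sub$genotype[!sub$is_wt])
}

#' @rdname locusGenotypes
#' @export
locusGroups <- function(panel) unique(panel@targets$locus_group)

#' @rdname locusGenotypes
#' @export
mutantGenotypes <- function(panel) {
  tg <- panel@targets
  tg$genotype[!tg$is_wt]
}

# accessors --------------------------------------------------------------

#' @rdname meltplex-generics
#' @export
setMethod("panelTargets", "DyePanel", function(x) x@targets)

#' @rdname meltplex-generics
#' @export
setMethod("channelNames", "DyePanel", function(x) x@channels)

#' @rdname meltplex-generics
#' @export
setMethod("tmWindowHalfwidth", "DyePanel", function(x) x@tmWindowHalfwidth)

#' @rdname meltplex-generics
#' @export
setMethod("sharedDyePairs", "DyePanel", function(x) x@sharedDyePairs)

setMethod("show", "DyePanel", function(object) {
  tg <- object@targets
  cat(sprintf("DyePanel: %d targets on %d channels (schema %s)\n",
              nrow(tg), length(object@channels), object@schemaVersion))
  cat(sprintf("  Tm window halfwidth: %.2f degC; shared-dye pairs: %s\n",
              object@tmWindowHalfwidth,
              if (length(object@sharedDyePairs))
                paste(vapply(object@sharedDyePairs, paste, "", collapse = "/"),
                      collapse = ", ") else "none"))
  for (ch in object@channels) {
    sub <- tg[tg$channel == ch, , drop = FALSE]
    cat(sprintf("  %-10s %s\n", ch, paste(
      sprintf("%s (Tm %.1f)", sub$genotype, sub$tm), collapse = ", ")))
  }
  invisible(NULL)
})
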