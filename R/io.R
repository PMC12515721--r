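# Text formats: long-format trace tables, counts tables with a YAML metadata
# sidecar, result reports, and a minimal variant annotation table.

# 32-bit polynomial rolling hash over a canonical string rendering;
# provenance fingerprint for sidecar metadata (not cryptographic).
.fingerprint <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  sprintf("%08x", h)
}

#' Fingerprint of a panel
#'
#' Stable short hash over all panel fields, recorded in output sidecars so
#' every counts/results file can be traced to the exact assay layout.
#'
#' @param panel a [DyePanel-class]
#' @return 8-character hex string
#' @export
panelFingerprint <- function(panel) {
  stopifnot(methods::is(panel, "DyePanel"))
  .fingerprint(list(panel@targets, panel@channels, panel@tmWindowHalfwidth,
                    panel@sharedDyePairs))
}

#' Write and read melt-curve traces
#'
#' The trace format is tab-delimited text with a header and one row per
#' (well, channel, temperature) sample, columns in this order: \code{well}
#' (integer), \code{channel}, \code{temperature} (degrees C),
#' \code{intensity} (a.u.).  Every (well, channel) must repeat one common,
#' sorted temperature grid.
#'
#' On reading, wells whose records are malformed (inconsistent or incomplete
#' temperature grid, duplicated samples) are dropped with a warning and
#' counted in \code{attr(, "nDropped")}; a well missing an entire channel
#' keeps its other channels and the missing channel is treated as absent
#' (zero intensity, hence no peaks), with a warning.
#'
#' @param chip a [MeltChip-class]
#' @param path file path (tab-separated text)
#' @return \code{writeTraces}: \code{path}, invisibly.  \code{readTraces}: a
#'   [MeltChip-class].
#' @export
writeTraces <- function(chip, path) {
  stopifnot(methods::is(chip, "MeltChip"))
  temps <- temperatures(chip)
  wells <- SummarizedExperiment::rowData(chip)$well
  parts <- lapply(SummarizedExperiment::assayNames(chip), function(ch) {
    m <- SummarizedExperiment::assay(chip, ch)
    data.table::data.table(
      well = rep(wells, times = length(temps)),
      channel = ch,
      temperature = rep(temps, each = length(wells)),
      intensity = as.vector(m))
  })
  dt <- data.table::rbindlist(parts)
  data.table::setorder(dt, well, channel, temperature)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname writeTraces
#' @export
readTraces <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  dt <- data.table::fread(path, sep = "\t")
  need <- c("well", "channel", "temperature", "intensity")
  if (!all(need %in% names(dt)))
    stop("trace file must have columns: ", paste(need, collapse = ", "))
  if (!nrow(dt)) stop("trace file is empty")
  if (any(!is.finite(dt$intensity)) || any(!is.finite(dt$temperature)))
    stop("trace file contains non-finite values")
  # reference grid: temperatures carried by (essentially) every
  # (well, channel) record group; stray off-grid samples are rare by
  # construction and excluded here, and the wells carrying them are
  # dropped below
  tcount <- table(dt$temperature)
  grid <- sort(as.numeric(names(tcount)[tcount >= max(tcount) / 2]))
  nT <- length(grid)
  off <- unique(dt$well[!dt$temperature %in% grid])
  dt <- dt[!dt$well %in% off]
  if (length(off))
    warning(length(off), " well(s) dropped: off-grid temperatures")
  if (!nrow(dt)) stop("no wells with a consistent temperature grid")
  channels <- sort(unique(dt$channel))
  counts <- dt[, .N, by = c("well", "channel")]
  bad <- unique(counts$well[counts$N != nT])
  wells <- sort(setdiff(unique(dt$well), bad))
  if (length(bad))
    warning(length(bad), " well(s) dropped: inconsistent temperature grid")
  if (!length(wells)) stop("no wells with a consistent temperature grid")
  dt <- dt[dt$well %in% wells]
  # grid value check on the survivors
  chk <- dt[, list(ok = identical(sort(temperature), grid)),
            by = c("well", "channel")]
  if (!all(chk$ok)) {
    bad2 <- unique(chk$well[!chk$ok])
    warning(length(bad2), " well(s) dropped: off-grid temperatures")
    wells <- setdiff(wells, bad2)
    if (!length(wells)) stop("no wells with a consistent temperature grid")
    dt <- dt[dt$well %in% wells]
  }
  data.table::setorder(dt, channel, temperature, well)
  wIdx <- match(dt$well, wells)
  assays <- setNames(lapply(channels, function(ch) {
    sub <- dt[dt$channel == ch]
    m <- matrix(0, nrow = length(wells), ncol = nT)
    if (nrow(sub) < length(wells) * nT) {
      have <- unique(sub$well)
      if (length(have) < length(wells))
        warning("channel ", ch, " missing for ",
                length(wells) - length(have),
                " well(s); treated as absent (no peaks)")
    }
    m[cbind(match(sub$well, wells), match(sub$temperature, grid))] <-
      sub$intensity
    m
  }), channels)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(well = wells),
    colData = S4Vectors::DataFrame(temperature = grid),
    metadata = list(truth = NULL,
                    nDropped = length(setdiff(unique(c(bad)), wells))))
  chip <- methods::new("MeltChip", se)
  attr(chip, "nDropped") <- length(bad)
  chip
}

.writeSidecar <- function(path, meta) {
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
}

.readSidecar <- function(path) {
  sc <- paste0(path, ".meta.yaml")
  if (!file.exists(sc)) return(NULL)
  yaml::read_yaml(sc)
}

#' Write and read positive-well counts tables
#'
#' Counts are tab-separated (\code{genotype}, \code{positive_wells}) with a
#' YAML sidecar (\code{<path>.meta.yaml}) carrying \code{n_wells_analyzed},
#' \code{n_out_of_window}, the panel fingerprint and any extra metadata
#' (seed, parameters) for provenance.
#'
#' @param counts a [ChipCounts-class]
#' @param path file path
#' @param panel optional [DyePanel-class] whose fingerprint is recorded
#' @param meta named list of extra metadata for the sidecar
#' @return \code{writeCounts}: \code{path}, invisibly; \code{readCounts}: a
#'   [ChipCounts-class]
#' @export
writeCounts <- function(counts, path, panel = NULL, meta = list()) {
  stopifnot(methods::is(counts, "ChipCounts"))
  df <- data.frame(genotype = names(counts@positives),
                   positive_wells = as.integer(counts@positives))
  data.table::fwrite(df, path, sep = "\t")
  side <- c(list(n_wells_analyzed = counts@nWellsAnalyzed,
                 n_out_of_window = counts@nOutOfWindow,
                 package_version = as.character(packageVersion("meltplex"))),
            if (!is.null(panel)) list(panel_fingerprint =
                                        panelFingerprint(panel)),
            meta)
  .writeSidecar(path, side)
  invisible(path)
}

#' @rdname writeCounts
#' @export
readCounts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- data.table::fread(path, sep = "\t")
  if (!all(c("genotype", "positive_wells") %in% names(df)))
    stop("counts file must have columns genotype, positive_wells")
  side <- .readSidecar(path)
  if (is.null(side) || is.null(side$n_wells_analyzed))
    stop("counts sidecar ", path, ".meta.yaml with n_wells_analyzed is required")
  methods::new("ChipCounts",
    nWellsAnalyzed = as.integer(side$n_wells_analyzed),
    positives = setNames(as.integer(df$positive_wells), df$genotype),
    nOutOfWindow = as.integer(side$n_out_of_window %||% 0L))
}

#' Minimal variant annotation table
#'
#' Static VCF-like annotation (GRCh38 chrom/pos/ref/alt) hard-coded per
#' panel mutant genotype.  This is bookkeeping metadata for downstream
#' reporting, not alignment-derived; genotypes without a known annotation
#' are omitted.
#'
#' @param panel a [DyePanel-class]
#' @return data.frame: \code{genotype}, \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}
#' @export
variantAnnotationTable <- function(panel) {
  stopifnot(methods::is(panel, "DyePanel"))
  ann <- data.frame(
    genotype = c("KRAS_G12D", "KRAS_G12V", "KRAS_G12A", "KRAS_G12C",
                 "KRAS_G12S", "KRAS_G12R", "KRAS_G13D", "KRAS_Q61H",
                 "GNAS_R201H", "GNAS_R201C"),
    chrom = c(rep("chr12", 8), rep("chr20", 2)),
    pos = c(25245350, 25245350, 25245350, 25245351, 25245351, 25245351,
            25245347, 25227341, 58909366, 58909365),
    ref = c("C", "C", "C", "C", "C", "C", "C", "T", "G", "C"),
    alt = c("T", "A", "G", "A", "T", "G", "T", "G", "A", "T"),
    stringsAsFactors = FALSE)
  ann[ann$genotype %in% panel@targets$genotype, , drop = FALSE]
}

#' Write a quantification report
#'
#' Writes \code{estimates.tsv}, \code{vaf.tsv}, \code{cna.tsv}, a
#' human-readable \code{report.txt} and (when mutant annotations exist)
#' \code{variants.tsv} into \code{dir}.
#'
#' @param result a [QuantResult-class]
#' @param dir output directory (created if needed)
#' @param panel optional [DyePanel-class] for the annotation table and the
#'   sidecar fingerprint
#' @param meta named list of extra metadata recorded in the sidecar
#' @return \code{dir}, invisibly
#' @export
writeResults <- function(result, dir, panel = NULL, meta = list()) {
  stopifnot(methods::is(result, "QuantResult"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(result@estimates, file.path(dir, "estimates.tsv"),
                     sep = "\t")
  data.table::fwrite(result@vaf, file.path(dir, "vaf.tsv"), sep = "\t")
  data.table::fwrite(result@cna, file.path(dir, "cna.tsv"), sep = "\t")
  if (!is.null(panel)) {
    ann <- variantAnnotationTable(panel)
    if (nrow(ann)) {
      vaf <- result@vaf
      ann$fraction <- vaf$fraction[match(ann$genotype, vaf$genotype)]
      data.table::fwrite(ann, file.path(dir, "variants.tsv"), sep = "\t")
    }
  }
  txt <- utils::capture.output(methods::show(result))
  writeLines(txt, file.path(dir, "report.txt"))
  .writeSidecar(file.path(dir, "results"),
                c(list(n_wells = result@nWells,
                       package_version =
                         as.character(packageVersion("meltplex"))),
                  if (!is.null(panel)) list(panel_fingerprint =
                                              panelFingerprint(panel)),
                  meta))
  invisible(dir)
}
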