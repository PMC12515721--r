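#' @name meltplex-generics
#' @title Accessor generics
#' @description Accessor generics for the panel, chip, truth, counts and
#'   result classes.  Use these rather than reaching into slots.
#' @param x an object of the documented class
#' @param ... passed to methods
NULL

#' @rdname meltplex-generics
#' @export
setGeneric("panelTargets", function(x) standardGeneric("panelTargets"))

#' @rdname meltplex-generics
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname meltplex-generics
#' @export
setGeneric("tmWindowHalfwidth", function(x) standardGeneric("tmWindowHalfwidth"))

#' @rdname meltplex-generics
#' @export
setGeneric("sharedDyePairs", function(x) standardGeneric("sharedDyePairs"))

#' @rdname meltplex-generics
#' @export
setGeneric("temperatures", function(x) standardGeneric("temperatures"))

#' @rdname meltplex-generics
#' @export
setGeneric("chipTruth", function(x) standardGeneric("chipTruth"))

#' @rdname meltplex-generics
#' @export
setGeneric("wellCopies", function(x) standardGeneric("wellCopies"))

#' @rdname meltplex-generics
#' @export
setGeneric("injectedPositives", function(x) standardGeneric("injectedPositives"))

#' @rdname meltplex-generics
#' @export
setGeneric("detectableCopies", function(x) standardGeneric("detectableCopies"))

#' @rdname meltplex-generics
#' @export
setGeneric("occupancyCounts", function(x) standardGeneric("occupancyCounts"))

#' @rdname meltplex-generics
#' @export
setGeneric("nWellsAnalyzed", function(x) standardGeneric("nWellsAnalyzed"))

#' @rdname meltplex-generics
#' @export
setGeneric("positiveWells", function(x, ...) standardGeneric("positiveWells"))

#' @rdname meltplex-generics
#' @export
setGeneric("outOfWindowPeaks", function(x) standardGeneric("outOfWindowPeaks"))

#' @rdname meltplex-generics
#' @export
setGeneric("chipEstimates", function(x, ...) standardGeneric("chipEstimates"))

#' @rdname meltplex-generics
#' @export
setGeneric("locusVaf", function(x, ...) standardGeneric("locusVaf"))

#' @rdname meltplex-generics
#' @export
setGeneric("cnaRatio", function(x, ...) standardGeneric("cnaRatio"))
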