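#' @rdname TrackRegistry-class
#' @param x,object a `TrackRegistry`.
#' @export
setGeneric("staticTracks", function(x) standardGeneric("staticTracks"))

#' @rdname TrackRegistry-class
#' @export
setGeneric("trackGroups", function(x) standardGeneric("trackGroups"))

#' @rdname TrackRegistry-class
#' @export
setGeneric("trackSets", function(x) standardGeneric("trackSets"))

#' @rdname TrackRegistry-class
#' @export
setGeneric("globalMaxVisible", function(x) standardGeneric("globalMaxVisible"))

#' @rdname FeatureIndex-class
#' @param x a `FeatureIndex`.
#' @export
setGeneric("trackUniverse", function(x) standardGeneric("trackUniverse"))

#' Query the feature index for the tracks interesting in a window
#'
#' Returns the ids of all tracks having at least one companion feature
#' overlapping the window by >= 1 bp (half-open arithmetic:
#' `feature.start < window.end && feature.end > window.start`, same
#' chromosome). A track appears at most once; the result is sorted for
#' determinism. Querying a chromosome absent from the index returns an
#' empty set.
#'
#' @param index a [FeatureIndex-class].
#' @param window a [GenomicWindow-class].
#' @return character vector of track ids.
#' @examples
#' reg <- exampleRegistry()
#' idx <- buildIndex(reg)
#' queryWindow(idx, parseWindow("chr1:1-500"))
#' @export
setGeneric("queryWindow", function(index, window) standardGeneric("queryWindow"))

#' @rdname LayoutState-class
#' @param x,object a `LayoutState`.
#' @export
setGeneric("containerEntries", function(x) standardGeneric("containerEntries"))

#' @rdname LayoutState-class
#' @export
setGeneric("carouselOffsets", function(x) standardGeneric("carouselOffsets"))

#' @rdname LayoutState-class
#' @export
setGeneric("overflowFlags", function(x) standardGeneric("overflowFlags"))

#' @rdname LayoutState-class
#' @export
setGeneric("isGlobalOverflow", function(x) standardGeneric("isGlobalOverflow"))

#' @rdname LayoutState-class
#' @export
setGeneric("pendingGroups", function(x) standardGeneric("pendingGroups"))

#' @rdname LayoutState-class
#' @export
setGeneric("stateLog", function(x) standardGeneric("stateLog"))
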