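#' @import methods
NULL

setClassUnion("integerOrNA", "integer")
setClassUnion("characterOrNA", "character")

#' GenomicWindow: a 0-based half-open genomic interval
#'
#' The engine's navigation target. Coordinates are stored 0-based half-open
#' (BED arithmetic); user-facing region strings are 1-based inclusive and
#' converted once, in [parseWindow()].
#'
#' @slot chrom single non-empty sequence name.
#' @slot start 0-based inclusive start offset.
#' @slot end exclusive end offset; `start < end` always holds.
#' @seealso [parseWindow()], [formatWindow()]
#' @export
setClass("GenomicWindow",
  representation(chrom = "character", start = "integer", end = "integer"),
  validity = function(object) {
    if (length(object@chrom) != 1L || is.na(object@chrom) || !nzchar(object@chrom))
      return("chrom must be a single non-empty string")
    if (length(object@start) != 1L || length(object@end) != 1L ||
        is.na(object@start) || is.na(object@end))
      return("start and end must be single integers")
    if (object@start < 0L) return("start must be >= 0")
    if (object@start >= object@end) return("start must be < end")
    TRUE
  })

#' TrackSet: a dependent signal + feature dataset pair
#'
#' A quantitative signal dataset (bedGraph) registered together with its
#' companion feature dataset (BED/GFF3 peak list) describing the regions of
#' significant signal. The companion features are the sole source of
#' "interestingness" for the track.
#'
#' @slot id unique identifier across the registry.
#' @slot signalPath path to the bedGraph signal file.
#' @slot featurePath path to the BED/GFF3 companion feature file.
#' @slot groupId id of the owning [TrackGroup-class].
#' @slot rank non-negative display rank, unique within the group.
#' @export
setClass("TrackSet",
  representation(id = "character", signalPath = "character",
                 featurePath = "character", groupId = "character",
                 rank = "integer"),
  validity = function(object) {
    for (s in c("id", "signalPath", "featurePath", "groupId"))
      if (length(slot(object, s)) != 1L || is.na(slot(object, s)) ||
          !nzchar(slot(object, s)))
        return(sprintf("%s must be a single non-empty string", s))
    if (!isCount(object@rank)) return("rank must be a non-negative integer")
    TRUE
  })

#' StaticTrack: a manually controlled track
#'
#' A track outside dynamic management: never auto-added or auto-removed, it
#' forms the fixed backbone of the track container and the usual anchoring
#' target for managed groups.
#'
#' @slot id unique identifier across the registry.
#' @slot path path to the track's data file (BED).
#' @slot position non-negative rank in the static backbone, unique across
#'   static tracks.
#' @export
setClass("StaticTrack",
  representation(id = "character", path = "character", position = "integer"),
  validity = function(object) {
    if (length(object@id) != 1L || !nzchar(object@id)) return("id must be non-empty")
    if (length(object@path) != 1L || !nzchar(object@path)) return("path must be non-empty")
    if (!isCount(object@position)) return("position must be a non-negative integer")
    TRUE
  })

#' TrackGroup: an ordered set of managed tracks
#'
#' Members are rendered as a contiguous block, in a predefined rank order.
#' The browsing mode is `automatic` (container updated on every navigation
#' step), `manual` (fresh classifications are kept pending until explicitly
#' applied) or `disabled` (the group is ignored). An optional anchor pins the
#' block right below a static track or another group; an optional cap bounds
#' how many interesting members are shown at once.
#'
#' @slot id unique identifier.
#' @slot mode one of `"automatic"`, `"manual"`, `"disabled"`.
#' @slot members TrackSet ids in display-rank order.
#' @slot anchor id of a StaticTrack or TrackGroup, or `NA_character_`.
#' @slot maxVisible positive integer cap, or `NA_integer_` for unlimited.
#' @export
setClass("TrackGroup",
  representation(id = "character", mode = "character", members = "character",
                 anchor = "character", maxVisible = "integer"),
  validity = function(object) {
    if (length(object@id) != 1L || !nzchar(object@id)) return("id must be non-empty")
    if (length(object@mode) != 1L ||
        !object@mode %in% c("automatic", "manual", "disabled"))
      return("mode must be one of automatic, manual, disabled")
    if (length(object@members) < 1L) return("members must be non-empty")
    if (anyDuplicated(object@members)) return("duplicate member ids")
    if (length(object@anchor) != 1L) return("anchor must be length 1 (NA for none)")
    if (length(object@maxVisible) != 1L) return("maxVisible must be length 1 (NA for unlimited)")
    if (!is.na(object@maxVisible) && object@maxVisible < 1L)
      return("maxVisible must be >= 1 when set")
    TRUE
  })

#' TrackRegistry: the validated registry of tracks, sets and groups
#'
#' Loaded from a JSON configuration by [loadRegistry()]. All
#' cross-references (track set to group, group member to track set, anchor
#' target) are resolved and the anchor relation is verified acyclic at load.
#'
#' @slot staticTracks named list of [StaticTrack-class], in declaration order.
#' @slot groups named list of [TrackGroup-class], in declaration order.
#' @slot trackSets named list of [TrackSet-class].
#' @slot globalMaxVisible positive integer bounding the total number of
#'   group-managed tracks on screen, or `NA_integer_` for unlimited. Static
#'   tracks never count against it.
#' @seealso [loadRegistry()], [registryToJSON()]
#' @export
setClass("TrackRegistry",
  representation(staticTracks = "list", groups = "list", trackSets = "list",
                 globalMaxVisible = "integer"),
  validity = function(object) validateRegistry(object))

#' FeatureIndex: the compiled interval index over all companion features
#'
#' All features of all registered track sets, compiled into a single
#' queryable structure (a `GRanges` holding every interval tagged with its
#' owning track id). A window query returns the ids of tracks with at least
#' one feature overlapping the window by >= 1 bp.
#'
#' @slot features `GRanges` of all indexed features (1-based closed, as
#'   GRanges requires), with a `trackId` metadata column.
#' @slot nclists per-chromosome preindexed interval containers
#'   (`IRanges::NCList`), the structure actually hit by window queries.
#' @slot chromTrackIds per-chromosome track-id vector parallel to each
#'   NCList's intervals.
#' @slot trackUniverse ids of all indexed tracks, including tracks whose
#'   feature file holds zero features (they are simply never interesting).
#' @seealso [buildIndex()], [queryWindow()]
#' @export
setClass("FeatureIndex",
  representation(features = "GRanges", nclists = "list",
                 chromTrackIds = "list", trackUniverse = "character"),
  validity = function(object) {
    if (anyDuplicated(object@trackUniverse)) return("duplicate track ids in universe")
    withFeat <- unique(as.character(object@features$trackId))
    if (!all(withFeat %in% object@trackUniverse))
      return("features reference tracks outside the universe")
    if (!identical(sort(names(object@nclists)), sort(names(object@chromTrackIds))))
      return("nclists and chromTrackIds must cover the same chromosomes")
    TRUE
  })

#' Classification: per-group interesting/empty partition for one window
#'
#' For every non-disabled group, members are partitioned into the
#' locus-specific interesting tracks (>= 1 companion feature overlapping the
#' window) and the locus-specific empty tracks, both in display-rank order.
#' Disabled groups are absent.
#'
#' @slot window the [GenomicWindow-class] the classification was computed for.
#' @slot perGroup named list, one entry per classified group:
#'   `list(interesting = <ids>, empty = <ids>)`.
#' @seealso [classify()]
#' @export
setClass("Classification",
  representation(window = "GenomicWindow", perGroup = "list"),
  validity = function(object) {
    for (g in names(object@perGroup)) {
      e <- object@perGroup[[g]]
      if (!is.list(e) || !all(c("interesting", "empty") %in% names(e)))
        return(sprintf("group '%s': entry must have interesting and empty", g))
      if (length(intersect(e$interesting, e$empty)) > 0L)
        return(sprintf("group '%s': interesting and empty overlap", g))
    }
    TRUE
  })

#' LayoutState: the ordered track container and its carousel bookkeeping
#'
#' The engine's central mutable-looking (but value-semantic) object: an
#' ordered sequence of blocks — one per static track and one per group, the
#' latter possibly empty — plus per-group carousel offsets, overflow flags,
#' pending classifications for manual-mode groups, and a diagnostic log.
#' Group blocks are always contiguous; empty blocks keep their slot so that
#' anchoring on a currently-empty group stays stable.
#'
#' @slot blocks ordered list of `list(kind, id, tracks)` where `kind` is
#'   `"static"` or `"group"`.
#' @slot visible named list: group id -> character vector of visible ids.
#' @slot carouselOffset named integer: group id -> ring offset.
#' @slot overflow named logical: group id -> some interesting tracks hidden.
#' @slot truncatedGlobal named logical: group id -> truncated by the global
#'   budget specifically.
#' @slot pending named list of pending classifications (manual groups).
#' @slot globalOverflow `TRUE` when any group was truncated by the global cap.
#' @slot log diagnostics accumulated during composition (e.g. degraded
#'   anchor placement).
#' @seealso [composeLayout()], [containerEntries()], [layoutStateToJSON()]
#' @export
setClass("LayoutState",
  representation(blocks = "list", visible = "list", carouselOffset = "integer",
                 overflow = "logical", truncatedGlobal = "logical",
                 pending = "list", globalOverflow = "logical",
                 log = "character"),
  validity = function(object) {
    ids <- unlist(lapply(object@blocks, `[[`, "tracks"), use.names = FALSE)
    if (anyDuplicated(ids)) return("duplicate track ids in container")
    if (length(object@globalOverflow) != 1L) return("globalOverflow must be length 1")
    if (any(object@carouselOffset < 0L)) return("carousel offsets must be >= 0")
    TRUE
  })

#' LayoutSummary: the per-group counts shown in the control widget
#'
#' What the engine communicates to the user after each step: per group, how
#' many tracks are locus-specific interesting, how many of those are on
#' screen, and how many remain hidden (`nVisible + nHidden = nInteresting`);
#' globally, the total container size and whether anything overflowed.
#'
#' @slot perGroup data.frame with columns `groupId`, `nInteresting`,
#'   `nVisible`, `nHidden`.
#' @slot totalVisible total number of entries in the container.
#' @slot anyOverflow `TRUE` when any group has hidden interesting tracks.
#' @seealso [summarizeLayout()]
#' @export
setClass("LayoutSummary",
  representation(perGroup = "data.frame", totalVisible = "integer",
                 anyOverflow = "logical"),
  validity = function(object) {
    pg <- object@perGroup
    need <- c("groupId", "nInteresting", "nVisible", "nHidden")
    if (!all(need %in% names(pg))) return("perGroup missing columns")
    if (nrow(pg) && any(pg$nVisible + pg$nHidden != pg$nInteresting))
      return("nVisible + nHidden must equal nInteresting")
    TRUE
  })

#' FixtureSpec: parameters of the synthetic fixture generator
#'
#' @slot seed RNG seed; identical seeds give byte-identical output trees.
#' @slot nGroups number of track groups.
#' @slot tracksPerGroup track sets per group.
#' @slot featuresPerTrack features written per companion BED file.
#' @slot chromSizes named integer vector of chromosome lengths (bp).
#' @slot featureLengthRange length-2 integer `(min, max)` feature size in bp.
#' @slot groupMaxVisible per-group cap applied to every generated group, or
#'   `NA` for none.
#' @slot globalMaxVisible global cap written to the registry, or `NA`.
#' @slot modes recycled vector of group modes for the generated groups.
#' @slot anchorFirstGroup when `TRUE` the first group is anchored below the
#'   generated static genes track and each further group below its
#'   predecessor; otherwise groups are unanchored.
#' @seealso [fixtureSpec()], [generateFixtures()]
#' @export
setClass("FixtureSpec",
  representation(seed = "integer", nGroups = "integer", tracksPerGroup = "integer",
                 featuresPerTrack = "integer", chromSizes = "integer",
                 featureLengthRange = "integer", groupMaxVisible = "integer",
                 globalMaxVisible = "integer", modes = "character",
                 anchorFirstGroup = "logical"),
  validity = function(object) {
    if (object@nGroups < 1L || object@tracksPerGroup < 1L ||
        object@featuresPerTrack < 1L)
      return("all counts must be >= 1")
    if (length(object@chromSizes) < 1L || is.null(names(object@chromSizes)))
      return("chromSizes must be a named vector")
    if (any(object@chromSizes < 1L)) return("chromosome lengths must be >= 1")
    r <- object@featureLengthRange
    if (length(r) != 2L || r[1] > r[2] || r[1] < 1L)
      return("featureLengthRange must be (min, max) with 1 <= min <= max")
    if (!all(object@modes %in% c("automatic", "manual", "disabled")))
      return("modes must be automatic/manual/disabled")
    TRUE
  })
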