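## Registry model: loading, validation, serialization, window parsing.

#' Construct a GenomicWindow
#'
#' @param chrom sequence name.
#' @param start 0-based inclusive start.
#' @param end exclusive end.
#' @return a [GenomicWindow-class].
#' @examples
#' GenomicWindow("chr2R", 8794208, 8812865)
#' @export
GenomicWindow <- function(chrom, start, end) {
  new("GenomicWindow", chrom = as.character(chrom),
      start = as.integer(start), end = as.integer(end))
}

#' Parse a browser region string into a GenomicWindow
#'
#' Accepts `"chrom:start-end"` or `"chrom:start..end"`, with optional comma
#' or thin-space thousands separators. Input coordinates follow the genome
#' browser convention (1-based, both ends inclusive) and are converted to
#' the internal 0-based half-open representation: `chr1:1-1` denotes the
#' first base, i.e. the internal window `[0, 1)`.
#'
#' @param text region string.
#' @return a [GenomicWindow-class].
#' @examples
#' parseWindow("chr2R:8,794,209-8,812,865")
#' parseWindow("chr1:1-1")
#' @export
parseWindow <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    dtRegionError("region must be a single string")
  txt <- gsub("[,   ]", "", text)
  m <- regmatches(txt, regexec("^([^:]+):([0-9]+)(?:-|\\.\\.)([0-9]+)$", txt))[[1]]
  if (length(m) != 4L)
    dtRegionError("malformed region '%s' (expected chrom:start-end)", text)
  start1 <- suppressWarnings(as.numeric(m[3]))
  end1 <- suppressWarnings(as.numeric(m[4]))
  if (is.na(start1) || is.na(end1) || start1 < 1)
    dtRegionError("malformed coordinates in region '%s'", text)
  if (start1 > end1)
    dtRegionError("region '%s': start %s > end %s", text, m[3], m[4])
  GenomicWindow(m[2], start1 - 1, end1)
}

#' Format a GenomicWindow as a 1-based region string
#'
#' Inverse of [parseWindow()] (without thousands separators).
#' @param window a [GenomicWindow-class].
#' @return a region string `"chrom:start-end"`, 1-based inclusive.
#' @export
formatWindow <- function(window) {
  stopifnot(is(window, "GenomicWindow"))
  sprintf("%s:%d-%d", window@chrom, window@start + 1L, window@end)
}

setMethod("show", "GenomicWindow", function(object) {
  cat("GenomicWindow ", formatWindow(object),
      " (internal [", object@start, ", ", object@end, "))\n", sep = "")
})

## ---- registry validation -------------------------------------------------

## Anchor graph cycle detection over group->group edges; anchors on static
## tracks are terminal by construction.
detectAnchorCycle <- function(groups) {
  anchorOf <- vapply(groups, function(g) g@anchor, character(1))
  gids <- names(groups)
  color <- setNames(rep(0L, length(gids)), gids)  # 0 white, 1 grey, 2 black
  for (start in gids) {
    if (color[[start]] != 0L) next
    path <- character(0)
    node <- start
    while (!is.na(node) && node %in% gids) {
      if (color[[node]] == 1L) {
        cyc <- c(path[which(path == node):length(path)], node)
        return(paste(cyc, collapse = " -> "))
      }
      if (color[[node]] == 2L) break
      color[[node]] <- 1L
      path <- c(path, node)
      node <- anchorOf[[node]]
    }
    color[path] <- 2L
  }
  NULL
}

validateRegistry <- function(object) {
  st <- object@staticTracks; gr <- object@groups; ts <- object@trackSets
  if (length(st) && !identical(names(st), unname(vapply(st, function(x) x@id, ""))))
    return("staticTracks must be named by id")
  if (length(gr) && !identical(names(gr), unname(vapply(gr, function(x) x@id, ""))))
    return("groups must be named by id")
  if (length(ts) && !identical(names(ts), unname(vapply(ts, function(x) x@id, ""))))
    return("trackSets must be named by id")
  allIds <- c(names(st), names(gr), names(ts))
  dup <- allIds[duplicated(allIds)]
  if (length(dup))
    return(sprintf("duplicate id(s) across the registry: %s",
                   paste(unique(dup), collapse = ", ")))
  pos <- vapply(st, function(x) x@position, integer(1))
  if (anyDuplicated(pos)) return("duplicate static track positions")
  for (t in ts)
    if (!t@groupId %in% names(gr))
      return(sprintf("track set '%s' references unknown group '%s'", t@id, t@groupId))
  for (g in gr) {
    bad <- setdiff(g@members, names(ts))
    if (length(bad))
      return(sprintf("group '%s' references unknown track set(s): %s",
                     g@id, paste(bad, collapse = ", ")))
    owners <- vapply(g@members, function(m) ts[[m]]@groupId, "")
    if (any(owners != g@id))
      return(sprintf("group '%s' lists member(s) owned by another group: %s",
                     g@id, paste(g@members[owners != g@id], collapse = ", ")))
    ranks <- vapply(g@members, function(m) ts[[m]]@rank, integer(1))
    if (anyDuplicated(ranks))
      return(sprintf("group '%s' has duplicate member ranks", g@id))
    if (is.unsorted(ranks))
      return(sprintf("group '%s' members not in rank order", g@id))
    if (!is.na(g@anchor) && !g@anchor %in% c(names(st), names(gr)))
      return(sprintf("group '%s' anchors on unknown target '%s'", g@id, g@anchor))
    if (!is.na(g@anchor) && g@anchor == g@id)
      return(sprintf("group '%s' anchors on itself", g@id))
  }
  ## every track set must be listed by its owning group
  for (t in ts)
    if (!t@id %in% gr[[t@groupId]]@members)
      return(sprintf("track set '%s' missing from member list of group '%s'",
                     t@id, t@groupId))
  cyc <- detectAnchorCycle(gr)
  if (!is.null(cyc)) return(sprintf("anchor cycle: %s", cyc))
  if (length(object@globalMaxVisible) != 1L)
    return("globalMaxVisible must be length 1 (NA for unlimited)")
  if (!is.na(object@globalMaxVisible) && object@globalMaxVisible < 1L)
    return("globalMaxVisible must be >= 1 when set")
  TRUE
}

## ---- configuration I/O ---------------------------------------------------

asScalarChr <- function(x, what, entity) {
  if (is.null(x) || length(x) != 1L || is.na(x) || !nzchar(as.character(x)))
    dtConfigError("%s: missing or empty '%s'", entity, what)
  as.character(x)
}

#' Load a track registry from a JSON configuration
#'
#' The configuration is a single JSON document with top-level keys
#' `static_tracks`, `groups`, `track_sets` and optional
#' `global_max_visible` (see the JSON Schema shipped at
#' `system.file("extdata", "registry.schema.json", package = "dynatrack")`).
#' Group membership and within-group order are derived from each track set's
#' `group_id` and `rank`. Defaults: group mode `automatic`; absent caps mean
#' unlimited. All cross-references are resolved at load time: duplicate ids,
#' dangling group or anchor references, anchor cycles and non-positive caps
#' are configuration errors naming the offending entity. Relative data paths
#' are resolved against the directory of `path`.
#'
#' @param path path to a configuration JSON file.
#' @param text alternatively, the configuration JSON as a string.
#' @return a validated [TrackRegistry-class].
#' @examples
#' cfg <- '{
#'   "static_tracks": [{"id": "genes", "path": "genes.bed", "position": 0}],
#'   "groups": [{"id": "g1", "mode": "automatic", "anchor": "genes"}],
#'   "track_sets": [
#'     {"id": "t1", "signal_path": "t1.bedGraph", "feature_path": "t1.bed",
#'      "group_id": "g1", "rank": 1}
#'   ]
#' }'
#' loadRegistry(text = cfg)
#' @export
loadRegistry <- function(path = NULL, text = NULL) {
  if (is.null(path) == is.null(text))
    dtContractError("supply exactly one of 'path' or 'text'")
  baseDir <- NULL
  if (!is.null(path)) {
    if (!file.exists(path)) dtIOError("configuration file not found: %s", path)
    baseDir <- dirname(normalizePath(path))
    text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  }
  cfg <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e) dtSyntaxError("configuration is not valid JSON: %s",
                                      conditionMessage(e)))
  if (!is.list(cfg)) dtSyntaxError("configuration root must be a JSON object")
  resolve <- function(p) {
    if (is.null(baseDir) || grepl("^(/|[A-Za-z]:)", p)) p
    else file.path(baseDir, p)
  }

  st <- list()
  for (s in (cfg$static_tracks %||% list())) {
    id <- asScalarChr(s$id, "id", "static track")
    if (!isCount(s$position %||% NA))
      dtConfigError("static track '%s': position must be a non-negative integer", id)
    st[[id]] <- new("StaticTrack", id = id,
                    path = resolve(asScalarChr(s$path, "path", sprintf("static track '%s'", id))),
                    position = as.integer(s$position))
  }

  ts <- list()
  for (t in (cfg$track_sets %||% list())) {
    id <- asScalarChr(t$id, "id", "track set")
    if (id %in% names(ts))
      dtConfigError("duplicate track set id '%s'", id)
    if (!isCount(t$rank %||% NA))
      dtConfigError("track set '%s': rank must be a non-negative integer", id)
    ts[[id]] <- new("TrackSet", id = id,
                    signalPath = resolve(asScalarChr(t$signal_path, "signal_path",
                                                     sprintf("track set '%s'", id))),
                    featurePath = resolve(asScalarChr(t$feature_path, "feature_path",
                                                      sprintf("track set '%s'", id))),
                    groupId = asScalarChr(t$group_id, "group_id",
                                          sprintf("track set '%s'", id)),
                    rank = as.integer(t$rank))
  }

  declaredGroups <- vapply(cfg$groups %||% list(), function(g)
    as.character(g$id %||% ""), "")
  orphan <- Filter(function(t) !t@groupId %in% declaredGroups, ts)
  if (length(orphan))
    dtConfigError("track set '%s' references unknown group '%s'",
                  orphan[[1]]@id, orphan[[1]]@groupId)

  gr <- list()
  for (g in (cfg$groups %||% list())) {
    id <- asScalarChr(g$id, "id", "group")
    if (id %in% names(gr)) dtConfigError("duplicate group id '%s'", id)
    mode <- as.character(g$mode %||% "automatic")
    if (!mode %in% c("automatic", "manual", "disabled"))
      dtConfigError("group '%s': invalid mode '%s'", id, mode)
    cap <- g$max_visible %||% NA_integer_
    if (!is.na(cap[1]) && (!isCount(cap) || cap < 1))
      dtConfigError("group '%s': max_visible must be a positive integer", id)
    memberSets <- Filter(function(t) t@groupId == id, ts)
    if (!length(memberSets))
      dtConfigError("group '%s' has no member track sets", id)
    ranks <- vapply(memberSets, function(t) t@rank, integer(1))
    if (anyDuplicated(ranks))
      dtConfigError("group '%s': duplicate ranks among members (%s)",
                    id, paste(names(memberSets)[duplicated(ranks) | duplicated(ranks, fromLast = TRUE)], collapse = ", "))
    members <- names(memberSets)[order(ranks)]
    anchor <- g$anchor %||% NA_character_
    gr[[id]] <- new("TrackGroup", id = id, mode = mode, members = members,
                    anchor = as.character(anchor), maxVisible = as.integer(cap[1]))
  }

  gmax <- cfg$global_max_visible %||% NA_integer_
  if (!is.na(gmax[1]) && (!isCount(gmax) || gmax < 1))
    dtConfigError("global_max_visible must be a positive integer")

  ## the class validity method re-runs the full cross-reference check;
  ## surface its verdict as a configuration error, not a raw S4 failure
  tryCatch(
    new("TrackRegistry", staticTracks = st, groups = gr, trackSets = ts,
        globalMaxVisible = as.integer(gmax[1])),
    error = function(e) {
      if (inherits(e, "dynatrack_error")) stop(e)
      dtConfigError("%s", sub("^invalid class [^:]+: ", "", conditionMessage(e)))
    })
}

#' Serialize a registry back to canonical configuration JSON
#'
#' Round-trips with [loadRegistry()]: re-loading the produced text yields an
#' equal registry (paths are emitted as stored, i.e. as resolved at load).
#'
#' @param registry a [TrackRegistry-class].
#' @return a JSON string.
#' @export
registryToJSON <- function(registry) {
  stopifnot(is(registry, "TrackRegistry"))
  doc <- list(
    global_max_visible = if (is.na(registry@globalMaxVisible)) NULL
                         else registry@globalMaxVisible,
    groups = lapply(unname(registry@groups), function(g) {
      out <- list(id = g@id, mode = g@mode)
      if (!is.na(g@anchor)) out$anchor <- g@anchor
      if (!is.na(g@maxVisible)) out$max_visible <- g@maxVisible
      out
    }),
    static_tracks = lapply(unname(registry@staticTracks), function(s)
      list(id = s@id, path = s@path, position = s@position)),
    track_sets = lapply(unname(registry@trackSets), function(t)
      list(feature_path = t@featurePath, group_id = t@groupId, id = t@id,
           rank = t@rank, signal_path = t@signalPath))
  )
  canonicalJSON(doc)
}

#' Write a registry configuration file
#' @param registry a [TrackRegistry-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRegistry <- function(registry, path) {
  writeLines(registryToJSON(registry), path, useBytes = TRUE)
  invisible(path)
}

## ---- accessors & show ----------------------------------------------------

#' @describeIn TrackRegistry-class static tracks, in declaration order.
#' @export
setMethod("staticTracks", "TrackRegistry", function(x) x@staticTracks)

#' @describeIn TrackRegistry-class track groups, in declaration order.
#' @export
setMethod("trackGroups", "TrackRegistry", function(x) x@groups)

#' @describeIn TrackRegistry-class registered track sets.
#' @export
setMethod("trackSets", "TrackRegistry", function(x) x@trackSets)

#' @describeIn TrackRegistry-class global cap on group-managed visible
#'   tracks (`NA` = unlimited).
#' @export
setMethod("globalMaxVisible", "TrackRegistry", function(x) x@globalMaxVisible)

#' Members of a group, in display-rank order
#' @param registry a [TrackRegistry-class].
#' @param groupId group id.
#' @return character vector of track set ids.
#' @export
groupMembers <- function(registry, groupId) {
  g <- registry@groups[[groupId]]
  if (is.null(g)) dtContractError("unknown group '%s'", groupId)
  g@members
}

setMethod("show", "TrackRegistry", function(object) {
  cat("TrackRegistry with", length(object@staticTracks), "static track(s),",
      length(object@groups), "group(s),",
      length(object@trackSets), "track set(s)\n")
  gm <- object@globalMaxVisible
  cat("  global max visible:", if (is.na(gm)) "unlimited" else gm, "\n")
  for (g in object@groups)
    cat(sprintf("  group '%s' [%s]%s%s: %s\n", g@id, g@mode,
                if (is.na(g@anchor)) "" else paste0(" anchored on '", g@anchor, "'"),
                if (is.na(g@maxVisible)) "" else paste0(" cap ", g@maxVisible),
                paste(g@members, collapse = ", ")))
})

#' A tiny in-memory example registry with on-disk fixtures
#'
#' Builds a three-track single-group registry backed by small temporary BED
#' and bedGraph files; used in examples.
#' @return a [TrackRegistry-class].
#' @export
exampleRegistry <- function() {
  dir <- tempfile("dynatrack_example_")
  dir.create(dir)
  feats <- list(t1 = c("chr1\t0\t100"), t2 = c("chr1\t50\t150", "chr1\t400\t450"),
                t3 = c("chr1\t900\t950"))
  for (id in names(feats)) {
    writeLines(feats[[id]], file.path(dir, paste0(id, ".bed")))
    writeLines(sub("^(\\S+\t\\S+\t\\S+).*", "\\1\t5", feats[[id]]),
               file.path(dir, paste0(id, ".bedGraph")))
  }
  writeLines("chr1\t10\t600\tgeneA", file.path(dir, "genes.bed"))
  cfg <- list(
    static_tracks = list(list(id = "genes", path = "genes.bed", position = 0L)),
    groups = list(list(id = "g1", mode = "automatic", anchor = "genes")),
    track_sets = lapply(seq_along(feats), function(i)
      list(id = names(feats)[i], signal_path = paste0(names(feats)[i], ".bedGraph"),
           feature_path = paste0(names(feats)[i], ".bed"),
           group_id = "g1", rank = i))
  )
  p <- file.path(dir, "registry.json")
  writeLines(canonicalJSON(cfg), p)
  loadRegistry(p)
}
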