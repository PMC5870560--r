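## Shared builders and independent oracles. Oracles deliberately avoid the
## code paths they check: window queries are verified against a plain linear
## scan, container layouts against a recursive re-assembly from the anchor
## graph.

## Build an on-disk registry from explicit BED content.
## features: named list, track id -> character vector of BED lines (possibly
##   empty). groups: named list, group id -> list(tracks, mode, anchor, cap).
## statics: character vector of static track ids (positions follow order).
makeTestRegistry <- function(features, groups, statics = "genes", globalMax = NULL,
                             dir = withr::local_tempdir(.local_envir = parent.frame())) {
  for (id in names(features))
    writeLines(features[[id]], file.path(dir, paste0(id, ".bed")))
  for (id in statics)
    writeLines("chr1\t100\t500\tfeat", file.path(dir, paste0(id, ".bed")))
  trackSets <- list()
  for (g in names(groups)) {
    tr <- groups[[g]]$tracks
    for (i in seq_along(tr)) {
      sigPath <- file.path(dir, paste0(tr[i], ".bedGraph"))
      writeLines(sub("^(\\S+\t\\S+\t\\S+).*$", "\\1\t2",
                     features[[tr[i]]] %||% character(0)), sigPath)
      trackSets[[length(trackSets) + 1L]] <- list(
        id = tr[i], signal_path = paste0(tr[i], ".bedGraph"),
        feature_path = paste0(tr[i], ".bed"), group_id = g, rank = i)
    }
  }
  cfg <- list(
    static_tracks = lapply(seq_along(statics), function(i)
      list(id = statics[i], path = paste0(statics[i], ".bed"), position = i - 1L)),
    groups = lapply(names(groups), function(g) {
      out <- list(id = g, mode = groups[[g]]$mode %||% "automatic")
      if (!is.null(groups[[g]]$anchor)) out$anchor <- groups[[g]]$anchor
      if (!is.null(groups[[g]]$cap)) out$max_visible <- groups[[g]]$cap
      out
    }),
    track_sets = trackSets)
  if (!is.null(globalMax)) cfg$global_max_visible <- globalMax
  p <- file.path(dir, "registry.json")
  writeLines(canonicalJSON(cfg), p)
  loadRegistry(p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## All companion features of a registry as one flat table (0-based half-open).
collectFeatures <- function(registry) {
  parts <- lapply(trackSets(registry), function(t) {
    df <- readFeatures(t@featurePath)
    if (nrow(df)) df$trackId <- t@id
    df
  })
  parts <- Filter(nrow, parts)
  if (!length(parts))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), trackId = character(0)))
  do.call(rbind, c(parts, make.row.names = FALSE))
}

## Linear-scan oracle for queryWindow.
scanOracle <- function(featureTable, window) {
  hit <- featureTable$chrom == window@chrom &
    featureTable$start < window@end & featureTable$end > window@start
  sort(unique(featureTable$trackId[hit]), method = "radix")
}

## Recursive container-assembly oracle: statics in position order, each
## followed by the subtree of groups anchored (transitively) below it, with
## siblings in declaration order; unanchored groups and their subtrees at
## the end.
containerOracle <- function(registry, visible) {
  grs <- trackGroups(registry)
  anchorOf <- vapply(grs, function(g) g@anchor, character(1))
  subtree <- function(target) {
    out <- character(0)
    for (g in names(grs))
      if (!is.na(anchorOf[[g]]) && anchorOf[[g]] == target)
        out <- c(out, visible[[g]] %||% character(0), subtree(g))
    out
  }
  sts <- staticTracks(registry)
  sts <- sts[order(vapply(sts, function(s) s@position, integer(1)))]
  out <- character(0)
  for (s in sts) out <- c(out, s@id, subtree(s@id))
  for (g in names(grs))
    if (is.na(anchorOf[[g]])) out <- c(out, visible[[g]] %||% character(0), subtree(g))
  out
}

stateVisible <- function(state) state@visible

randomWindow <- function(chromSizes, maxLen = 50000L) {
  chrom <- sample(names(chromSizes), 1L)
  len <- sample.int(maxLen, 1L)
  start <- sample.int(max(1L, chromSizes[[chrom]] - len), 1L) - 1L
  GenomicWindow(chrom, start, start + len)
}

## A registry purely in memory (no data files); enough for layout/carousel
## logic, which never touches disk.
inMemoryRegistry <- function(nTracks, cap = NA_integer_, mode = "automatic",
                             globalMax = NA_integer_) {
  ids <- sprintf("t%02d", seq_len(nTracks))
  ts <- setNames(lapply(seq_along(ids), function(i)
    new("TrackSet", id = ids[i], signalPath = "unused.bedGraph",
        featurePath = "unused.bed", groupId = "g", rank = i)), ids)
  g <- new("TrackGroup", id = "g", mode = mode, members = ids,
           anchor = NA_character_, maxVisible = as.integer(cap))
  new("TrackRegistry", staticTracks = list(), groups = list(g = g),
      trackSets = ts, globalMaxVisible = as.integer(globalMax))
}

inMemoryClassification <- function(registry, interesting) {
  perGroup <- list()
  for (g in trackGroups(registry)) {
    if (g@mode == "disabled") next
    perGroup[[g@id]] <- list(interesting = g@members[g@members %in% interesting],
                             empty = g@members[!g@members %in% interesting])
  }
  new("Classification", window = GenomicWindow("chr1", 0L, 1L),
      perGroup = perGroup)
}
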