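## Layout engine: window classification, container composition, anchoring,
## caps, overflow cues, browsing modes.

groupCap <- function(g) if (is.na(g@maxVisible)) Inf else as.numeric(g@maxVisible)

registryBudget <- function(registry)
  if (is.na(registry@globalMaxVisible)) Inf else as.numeric(registry@globalMaxVisible)

## ---- classification ------------------------------------------------------

#' Classify group members as locus-specific interesting or empty
#'
#' For each non-disabled group, partitions its members into tracks with at
#' least one companion feature overlapping the window (interesting) and the
#' rest (empty), both sub-lists kept in display-rank order. Disabled groups
#' are ignored and absent from the result.
#'
#' @param registry a [TrackRegistry-class].
#' @param index a [FeatureIndex-class] built from the same registry.
#' @param window a [GenomicWindow-class].
#' @return a [Classification-class].
#' @export
classify <- function(registry, index, window) {
  stopifnot(is(registry, "TrackRegistry"), is(index, "FeatureIndex"),
            is(window, "GenomicWindow"))
  hits <- queryWindow(index, window)
  perGroup <- list()
  for (g in registry@groups) {
    if (g@mode == "disabled") next
    isIn <- g@members %in% hits
    perGroup[[g@id]] <- list(interesting = g@members[isIn],
                             empty = g@members[!isIn])
  }
  new("Classification", window = window, perGroup = perGroup)
}

## ---- container assembly --------------------------------------------------

## TRUE when the anchor chain starting at group id `b` reaches `target`
## without passing through it more than once (chains are acyclic by load
## validation).
anchorChainReaches <- function(registry, b, target) {
  g <- registry@groups[[b]]
  while (!is.null(g)) {
    a <- g@anchor
    if (is.na(a)) return(FALSE)
    if (a == target) return(TRUE)
    g <- registry@groups[[a]]  # NULL when the anchor is a static track
  }
  FALSE
}

## Deterministic block assembly. Every static track and every group gets a
## block (groups possibly empty, keeping a stable slot for anchors). Groups
## are placed in topological order of the anchor graph, ties broken by
## declaration order; an anchored block is inserted right below its target
## block, after any earlier-placed blocks whose anchor chain leads to the
## same target (siblings stack in declaration order, dependents stay below
## their parent). Unanchored groups are appended at the container end.
assembleBlocks <- function(registry, visible) {
  blocks <- lapply(unname(registry@staticTracks)[
    order(vapply(registry@staticTracks, function(s) s@position, integer(1)))],
    function(s) list(kind = "static", id = s@id, tracks = s@id))
  log <- character(0)
  gids <- names(registry@groups)
  placedGroups <- character(0)
  remaining <- gids
  while (length(remaining)) {
    pick <- NA_character_
    for (g in remaining) {
      a <- registry@groups[[g]]@anchor
      if (is.na(a) || !a %in% gids || a %in% placedGroups) { pick <- g; break }
    }
    if (is.na(pick)) pick <- remaining[1]  # unreachable for valid registries
    remaining <- setdiff(remaining, pick)
    placedGroups <- c(placedGroups, pick)
    newBlock <- list(kind = "group", id = pick,
                     tracks = as.character(visible[[pick]] %||% character(0)))
    anc <- registry@groups[[pick]]@anchor
    blockIds <- vapply(blocks, `[[`, "", "id")
    if (is.na(anc)) {
      blocks[[length(blocks) + 1L]] <- newBlock
    } else if (!anc %in% blockIds) {
      blocks[[length(blocks) + 1L]] <- newBlock
      log <- c(log, sprintf(
        "group '%s': anchor target '%s' not present in container; appended at end",
        pick, anc))
    } else {
      p <- match(anc, blockIds)
      while (p < length(blocks) && blocks[[p + 1L]]$kind == "group" &&
             anchorChainReaches(registry, blocks[[p + 1L]]$id, anc))
        p <- p + 1L
      blocks <- append(blocks, list(newBlock), after = p)
    }
  }
  list(blocks = blocks, log = log)
}

#' Order in which group blocks appear in the assembled container
#'
#' Anchors resolved first (topologically), ties broken by declaration order;
#' this is the order in which the global visibility budget is allocated.
#'
#' @param registry a [TrackRegistry-class].
#' @return character vector of group ids.
#' @export
groupPlacementOrder <- function(registry) {
  blocks <- assembleBlocks(registry, list())$blocks
  ids <- vapply(blocks, `[[`, "", "id")
  kinds <- vapply(blocks, `[[`, "", "kind")
  ids[kinds == "group"]
}

## ---- composition ---------------------------------------------------------

#' The initial layout: static backbone only
#'
#' A valid starting [LayoutState-class] for any registry: every group block
#' empty, all offsets zero, no overflow, no pending changes.
#'
#' @param registry a [TrackRegistry-class].
#' @return a [LayoutState-class].
#' @export
initialLayout <- function(registry) {
  stopifnot(is(registry, "TrackRegistry"))
  gids <- names(registry@groups) %||% character(0)
  visible <- setNames(rep(list(character(0)), length(gids)), gids)
  asm <- assembleBlocks(registry, visible)
  new("LayoutState", blocks = asm$blocks, visible = visible,
      carouselOffset = setNames(integer(length(gids)), gids),
      overflow = setNames(logical(length(gids)), gids),
      truncatedGlobal = setNames(logical(length(gids)), gids),
      pending = list(), globalOverflow = FALSE, log = asm$log)
}

#' Compose the track container for a fresh window classification
#'
#' The central update step, executed on every navigation event:
#' \itemize{
#'   \item Static tracks keep their configured backbone positions.
#'   \item Each \emph{automatic} group shows the first
#'     `min(n interesting, group cap, remaining global budget)` tracks of
#'     its interesting list in rank order; its carousel offset resets to 0
#'     and its block is placed immediately below its resolved anchor (or
#'     appended at the end when unanchored).
#'   \item The global budget (when set) is allocated to automatic groups in
#'     container placement order after accounting for the tracks held by
#'     manual and disabled groups; later groups may receive 0 slots.
#'   \item \emph{Manual} groups keep their previous visible set; the fresh
#'     classification is stored as pending, awaiting [applyPending()].
#'   \item \emph{Disabled} groups are copied verbatim from the previous
#'     state.
#'   \item `overflow[g]` is `TRUE` iff some interesting tracks of `g` are
#'     hidden; `globalOverflow` iff any group was truncated specifically by
#'     the global budget.
#' }
#' Composition is deterministic: identical inputs produce identical states.
#' An anchor target missing from the container degrades to end-of-container
#' placement with a diagnostic in the state log, never an error.
#'
#' @param registry a [TrackRegistry-class].
#' @param classification a [Classification-class] for the target window.
#' @param previous the previous [LayoutState-class]; see [initialLayout()].
#' @return a new [LayoutState-class].
#' @examples
#' reg <- exampleRegistry()
#' idx <- buildIndex(reg)
#' st <- composeLayout(reg, classify(reg, idx, parseWindow("chr1:1-200")),
#'                     initialLayout(reg))
#' containerEntries(st)
#' @export
composeLayout <- function(registry, classification, previous) {
  stopifnot(is(registry, "TrackRegistry"), is(classification, "Classification"),
            is(previous, "LayoutState"))
  groups <- registry@groups
  gids <- names(groups) %||% character(0)
  missing <- setdiff(Filter(function(g) groups[[g]]@mode != "disabled", gids),
                     names(classification@perGroup))
  if (length(missing))
    dtContractError("classification lacks non-disabled group(s): %s",
                    paste(missing, collapse = ", "))

  visible <- setNames(rep(list(character(0)), length(gids)), gids)
  offset <- setNames(integer(length(gids)), gids)
  overflow <- setNames(logical(length(gids)), gids)
  truncGlob <- setNames(logical(length(gids)), gids)
  pending <- list()

  prevVisible <- function(g) as.character(previous@visible[[g]] %||% character(0))
  prevOffset <- function(g) as.integer(previous@carouselOffset[g] %|na|% 0L)

  ## manual and disabled groups first: they hold their tracks and consume
  ## global budget ahead of automatic allocation
  for (g in gids) {
    mode <- groups[[g]]@mode
    if (mode == "manual") {
      visible[[g]] <- prevVisible(g)
      pending[[g]] <- classification@perGroup[[g]]
      int <- classification@perGroup[[g]]$interesting
      overflow[g] <- length(setdiff(int, visible[[g]])) > 0L
      truncGlob[g] <- isTRUE(previous@truncatedGlobal[g] %|na|% FALSE)
      off <- prevOffset(g)
      offset[g] <- if (off >= max(1L, length(int))) 0L else off
    } else if (mode == "disabled") {
      visible[[g]] <- prevVisible(g)
      overflow[g] <- isTRUE(previous@overflow[g] %|na|% FALSE)
      truncGlob[g] <- isTRUE(previous@truncatedGlobal[g] %|na|% FALSE)
      offset[g] <- prevOffset(g)
    }
  }

  budget <- registryBudget(registry) -
    sum(lengths(visible[vapply(gids, function(g) groups[[g]]@mode != "automatic", TRUE)]))
  budget <- max(0, budget)

  for (g in groupPlacementOrder(registry)) {
    if (groups[[g]]@mode != "automatic") next
    ring <- classification@perGroup[[g]]$interesting
    quota <- min(length(ring), groupCap(groups[[g]]), budget)
    visible[[g]] <- head(ring, quota)
    offset[g] <- 0L
    overflow[g] <- quota < length(ring)
    truncGlob[g] <- quota < min(length(ring), groupCap(groups[[g]]))
    budget <- budget - quota
  }

  asm <- assembleBlocks(registry, visible)
  new("LayoutState", blocks = asm$blocks, visible = visible,
      carouselOffset = offset, overflow = overflow, truncatedGlobal = truncGlob,
      pending = pending, globalOverflow = any(truncGlob), log = asm$log)
}

`%|na|%` <- function(x, default) {
  if (length(x) != 1L || is.na(x)) default else x
}

#' Apply the pending classification of a manual-mode group
#'
#' In manual mode, navigation never touches the container; the fresh
#' classification is parked as pending until the user explicitly applies it.
#' Applying rebuilds the group's visible block exactly as [composeLayout()]
#' would for an automatic group (rank-order prefix, group cap, remaining
#' global budget, carousel offset reset) and clears the pending entry. All
#' other groups are untouched. Calling with no pending entry is a no-op;
#' calling for a non-manual group is a contract violation.
#'
#' @param state a [LayoutState-class].
#' @param registry the [TrackRegistry-class] the state derives from.
#' @param groupId id of a manual-mode group.
#' @return a new [LayoutState-class].
#' @export
applyPending <- function(state, registry, groupId) {
  stopifnot(is(state, "LayoutState"), is(registry, "TrackRegistry"))
  g <- registry@groups[[groupId]]
  if (is.null(g)) dtContractError("unknown group '%s'", groupId)
  if (g@mode != "manual")
    dtContractError("applyPending: group '%s' has mode '%s', not manual",
                    groupId, g@mode)
  if (is.null(state@pending[[groupId]])) return(state)
  ring <- state@pending[[groupId]]$interesting
  others <- setdiff(names(state@visible), groupId)
  budget <- max(0, registryBudget(registry) - sum(lengths(state@visible[others])))
  quota <- min(length(ring), groupCap(g), budget)

  visible <- state@visible
  visible[[groupId]] <- head(ring, quota)
  offset <- state@carouselOffset; offset[groupId] <- 0L
  overflow <- state@overflow; overflow[groupId] <- quota < length(ring)
  truncGlob <- state@truncatedGlobal
  truncGlob[groupId] <- quota < min(length(ring), groupCap(g))
  pending <- state@pending; pending[[groupId]] <- NULL

  asm <- assembleBlocks(registry, visible)
  new("LayoutState", blocks = asm$blocks, visible = visible,
      carouselOffset = offset, overflow = overflow, truncatedGlobal = truncGlob,
      pending = pending, globalOverflow = any(truncGlob),
      log = c(state@log, asm$log))
}

## ---- summary -------------------------------------------------------------

#' Summarize a layout for the control widget
#'
#' Per classified group: how many tracks are interesting in the current
#' window, how many of those are on screen, and how many remain hidden
#' (`nVisible + nHidden = nInteresting` always). Globally: the container
#' size and whether any group overflowed.
#'
#' @param classification a [Classification-class].
#' @param state the [LayoutState-class] for the same window.
#' @return a [LayoutSummary-class].
#' @export
summarizeLayout <- function(classification, state) {
  stopifnot(is(classification, "Classification"), is(state, "LayoutState"))
  gids <- names(classification@perGroup) %||% character(0)
  nInt <- integer(length(gids)); nVis <- integer(length(gids))
  for (i in seq_along(gids)) {
    int <- classification@perGroup[[gids[i]]]$interesting
    vis <- as.character(state@visible[[gids[i]]] %||% character(0))
    nInt[i] <- length(int)
    nVis[i] <- length(intersect(vis, int))
  }
  new("LayoutSummary",
      perGroup = data.frame(groupId = gids, nInteresting = nInt,
                            nVisible = nVis, nHidden = nInt - nVis),
      totalVisible = nrow(containerEntries(state)),
      anyOverflow = any(state@overflow) || state@globalOverflow)
}

## ---- accessors & show ----------------------------------------------------

#' @describeIn LayoutState-class the ordered container as a data.frame with
#'   columns `trackId` and `origin` (`"static"` or `"group:<id>"`).
#' @export
setMethod("containerEntries", "LayoutState", function(x) {
  ids <- character(0); origin <- character(0)
  for (b in x@blocks) {
    if (!length(b$tracks)) next
    ids <- c(ids, b$tracks)
    origin <- c(origin, rep(if (b$kind == "static") "static"
                            else paste0("group:", b$id), length(b$tracks)))
  }
  data.frame(trackId = ids, origin = origin)
})

#' @describeIn LayoutState-class per-group carousel offsets.
#' @export
setMethod("carouselOffsets", "LayoutState", function(x) x@carouselOffset)

#' @describeIn LayoutState-class per-group overflow flags.
#' @export
setMethod("overflowFlags", "LayoutState", function(x) x@overflow)

#' @describeIn LayoutState-class `TRUE` when the global cap truncated any
#'   group.
#' @export
setMethod("isGlobalOverflow", "LayoutState", function(x) x@globalOverflow)

#' @describeIn LayoutState-class ids of groups with a pending
#'   classification.
#' @export
setMethod("pendingGroups", "LayoutState", function(x) names(x@pending) %||% character(0))

#' @describeIn LayoutState-class diagnostics recorded during composition.
#' @export
setMethod("stateLog", "LayoutState", function(x) x@log)

setMethod("show", "LayoutState", function(object) {
  ce <- containerEntries(object)
  cat("LayoutState with", nrow(ce), "visible track(s)\n")
  for (b in object@blocks) {
    tag <- if (b$kind == "static") "static" else sprintf("group %s", b$id)
    cat(sprintf("  [%s] %s\n", tag,
                if (length(b$tracks)) paste(b$tracks, collapse = ", ") else "<empty>"))
  }
  if (length(object@pending))
    cat("  pending:", paste(names(object@pending), collapse = ", "), "\n")
  if (object@globalOverflow) cat("  global overflow\n")
})

setMethod("show", "LayoutSummary", function(object) {
  cat("LayoutSummary:", object@totalVisible, "visible track(s);",
      if (object@anyOverflow) "overflow" else "no overflow", "\n")
  if (nrow(object@perGroup)) print(object@perGroup, row.names = FALSE)
})
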