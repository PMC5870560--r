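## Canonical JSON: UTF-8, keys sorted recursively, no insignificant
## whitespace. The golden-file surface for layout states and summaries.

sortKeysRec <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && length(x)) {
      x <- x[order(nm, method = "radix")]
    }
    x <- lapply(x, sortKeysRec)
  }
  x
}

#' Serialize a list to canonical JSON
#'
#' Object keys are sorted recursively (radix/byte order); output carries no
#' insignificant whitespace, so identical inputs give byte-identical text.
#' Vectors wrapped in [I()] always serialize as arrays, unwrapped length-1
#' vectors as scalars. `NULL` entries are dropped.
#'
#' @param x a (possibly nested) named list.
#' @return a single JSON string.
#' @export
canonicalJSON <- function(x) {
  x <- sortKeysRec(x)
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"))
}

emptyObj <- function() structure(list(), names = character(0))

## ---- LayoutState <-> JSON ------------------------------------------------

STATE_SCHEMA_VERSION <- 1L

#' Serialize a LayoutState to canonical JSON
#'
#' The machine interface for front-ends and the golden-file test surface:
#' sorted keys, explicit `version` field, arrays kept as arrays even when
#' length 1. [layoutStateFromJSON()] inverts it exactly.
#'
#' @param state a [LayoutState-class].
#' @return a single JSON string.
#' @export
layoutStateToJSON <- function(state) {
  stopifnot(is(state, "LayoutState"))
  ce <- containerEntries(state)
  namedOrEmpty <- function(v) if (length(v)) as.list(v) else emptyObj()
  pend <- if (length(state@pending))
    lapply(state@pending, function(e) list(interesting = I(e$interesting),
                                           empty = I(e$empty)))
  else emptyObj()
  doc <- list(
    version = STATE_SCHEMA_VERSION,
    blocks = lapply(state@blocks, function(b)
      list(kind = b$kind, id = b$id, tracks = I(b$tracks))),
    container = lapply(seq_len(nrow(ce)), function(i)
      list(track = ce$trackId[i], origin = ce$origin[i])),
    carousel_offset = namedOrEmpty(state@carouselOffset),
    overflow = namedOrEmpty(state@overflow),
    truncated_global = namedOrEmpty(state@truncatedGlobal),
    global_overflow = state@globalOverflow,
    pending = pend,
    log = I(state@log)
  )
  canonicalJSON(doc)
}

#' Deserialize a LayoutState from JSON
#' @param json JSON text produced by [layoutStateToJSON()], or a file path.
#' @return a [LayoutState-class].
#' @export
layoutStateFromJSON <- function(json) {
  if (length(json) == 1L && !grepl("^\\s*\\{", json) && file.exists(json))
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (!identical(as.integer(doc$version %||% -1L), STATE_SCHEMA_VERSION))
    dtFormatError("unsupported layout state version: %s", doc$version %||% "absent")
  blocks <- lapply(doc$blocks, function(b)
    list(kind = b$kind, id = b$id,
         tracks = as.character(unlist(b$tracks, use.names = FALSE))))
  visible <- list()
  for (b in blocks) if (b$kind == "group") visible[[b$id]] <- b$tracks
  toNamed <- function(x, cast) {
    if (!length(x)) return(cast(character(0)))
    setNames(cast(unlist(x, use.names = FALSE)), names(x))
  }
  pend <- lapply(doc$pending %||% list(), function(e)
    list(interesting = as.character(unlist(e$interesting, use.names = FALSE)),
         empty = as.character(unlist(e$empty, use.names = FALSE))))
  new("LayoutState",
      blocks = blocks, visible = visible,
      carouselOffset = toNamed(doc$carousel_offset, as.integer),
      overflow = toNamed(doc$overflow, as.logical),
      truncatedGlobal = toNamed(doc$truncated_global, as.logical),
      pending = pend,
      globalOverflow = as.logical(doc$global_overflow %||% FALSE),
      log = as.character(unlist(doc$log, use.names = FALSE)))
}

#' Serialize a LayoutSummary to canonical JSON
#' @param summary a [LayoutSummary-class].
#' @return a single JSON string.
#' @export
summaryToJSON <- function(summary) {
  stopifnot(is(summary, "LayoutSummary"))
  pg <- summary@perGroup
  doc <- list(
    version = STATE_SCHEMA_VERSION,
    groups = if (nrow(pg)) lapply(seq_len(nrow(pg)), function(i)
      list(group = pg$groupId[i], n_interesting = pg$nInteresting[i],
           n_visible = pg$nVisible[i], n_hidden = pg$nHidden[i]))
      else list(),
    total_visible = summary@totalVisible,
    any_overflow = summary@anyOverflow
  )
  canonicalJSON(doc)
}
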