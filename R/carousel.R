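## Carousel browsing: cyclic rotation through a group's interesting tracks
## when they exceed the visible quota.

#' Rotate a group's carousel by half a window
#'
#' Treats the group's rank-ordered interesting list as a ring of length `N`
#' and its visible block as a cyclic window of `V` slots. Each rotation
#' advances the window start by `ceil(V/2)` positions modulo `N`, so half of
#' the visible tracks are replaced with hidden ones following the predefined
#' order, the other half is retained, and repeated clicks scroll through all
#' interesting tracks with wrap-around ("infinite scrolling"). `ceil` (not
#' `floor`) guarantees progress even at `V = 1`.
#'
#' When `N <= V` nothing is hidden and the state is returned unchanged; a
#' group holding zero slots is likewise left untouched. All other groups and
#' static tracks are never affected, and the overflow flag stays set.
#'
#' @param state a [LayoutState-class].
#' @param registry the [TrackRegistry-class] the state derives from.
#' @param classification the current [Classification-class] (supplies the
#'   ring).
#' @param groupId id of the group to rotate; must be present in the
#'   classification.
#' @return a new [LayoutState-class].
#' @export
rotateCarousel <- function(state, registry, classification, groupId) {
  stopifnot(is(state, "LayoutState"), is(registry, "TrackRegistry"),
            is(classification, "Classification"))
  if (is.null(registry@groups[[groupId]]))
    dtContractError("unknown group '%s'", groupId)
  entry <- classification@perGroup[[groupId]]
  if (is.null(entry))
    dtContractError("group '%s' is not present in the classification", groupId)
  ring <- entry$interesting
  n <- length(ring)
  v <- length(state@visible[[groupId]] %||% character(0))
  if (n <= v || v == 0L) return(state)

  step <- as.integer(ceiling(v / 2))
  offset <- as.integer((state@carouselOffset[groupId] %|na|% 0L + step) %% n)
  window <- ring[((offset + seq_len(v) - 1L) %% n) + 1L]

  visible <- state@visible
  visible[[groupId]] <- window
  offs <- state@carouselOffset; offs[groupId] <- offset
  asm <- assembleBlocks(registry, visible)
  new("LayoutState", blocks = asm$blocks, visible = visible,
      carouselOffset = offs, overflow = state@overflow,
      truncatedGlobal = state@truncatedGlobal, pending = state@pending,
      globalOverflow = state@globalOverflow, log = c(state@log, asm$log))
}

#' Number of rotations until the carousel first returns to its start
#'
#' With ring length `N` and `V` visible slots, each rotation advances the
#' offset by `ceil(V/2)` modulo `N`; the visible window first coincides with
#' the initial one after `N / gcd(N, ceil(V/2))` rotations.
#'
#' @param N ring length (number of interesting tracks); must exceed `V`.
#' @param V number of visible slots, `>= 1`.
#' @return a positive integer.
#' @examples
#' rotationCycleLength(10, 4)  # step 2 -> 5 rotations
#' rotationCycleLength(9, 4)   # step 2, coprime -> 9 rotations
#' @export
rotationCycleLength <- function(N, V) {
  if (!isCount(N) || !isCount(V) || V < 1L)
    dtContractError("N and V must be positive integers")
  if (N <= V)
    dtContractError("rotation cycle undefined for N <= V (N=%d, V=%d): nothing hidden",
                    as.integer(N), as.integer(V))
  step <- as.integer(ceiling(V / 2))
  as.integer(N) %/% gcdInt(as.integer(N), step)
}
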