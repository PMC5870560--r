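## Static SVG rendering of a composed layout: a verification surrogate for
## the browser's track container, not an interactive view. SVG text is
## emitted directly with fixed number formatting so identical inputs give
## byte-identical output, and structural markers (one <g class="track-panel">
## per container entry, <g class="overflow-glyph"> per overflowing group)
## are string-searchable by tests and downstream tooling.

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Read a bedGraph signal file
#'
#' Thin wrapper over `rtracklayer::import(format = "bedGraph")` returning
#' 0-based half-open intervals with their values.
#'
#' @param path path to a bedGraph file.
#' @return data.frame with columns `chrom`, `start`, `end`, `value`.
#' @export
readBedGraph <- function(path) {
  if (!file.exists(path)) dtIOError("signal file not found: %s", path)
  gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                 error = function(e) dtFormatError("cannot parse bedGraph '%s': %s",
                                                   path, conditionMessage(e)))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             value = as.numeric(gr$score))
}

fmt <- function(x) sprintf("%.2f", x)

#' Render a composed layout as a static SVG figure
#'
#' One horizontal panel per container entry, top to bottom in container
#' order: track-set panels show the bedGraph signal as filled bars over the
#' window with the companion features as a box strip underneath; static
#' track panels show their features as filled boxes. A coordinate axis
#' (1-based labels) sits on top, and every group whose overflow flag is set
#' gets a warning glyph (`id="overflow-<group>"`). Output is deterministic:
#' identical inputs yield byte-identical SVG.
#'
#' @param registry a [TrackRegistry-class] or the path of its configuration.
#' @param state a [LayoutState-class], its JSON text, or a state file path.
#' @param window a [GenomicWindow-class] or region string.
#' @param out output SVG path.
#' @return `out`, invisibly.
#' @export
renderView <- function(registry, state, window, out) {
  if (is.character(registry)) registry <- loadRegistry(registry)
  if (is.character(state)) state <- layoutStateFromJSON(state)
  if (is.character(window)) window <- parseWindow(window)
  stopifnot(is(registry, "TrackRegistry"), is(state, "LayoutState"),
            is(window, "GenomicWindow"))

  ce <- containerEntries(state)
  W <- 960; mLeft <- 150; mRight <- 30; mTop <- 46; panelH <- 48; gap <- 8
  plotW <- W - mLeft - mRight
  H <- mTop + max(1L, nrow(ce)) * (panelH + gap) + 10
  wS <- window@start; wE <- window@end
  xOf <- function(pos) mLeft + (pmin(pmax(pos, wS), wE) - wS) / (wE - wS) * plotW

  svg <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                          'height="%d" viewBox="0 0 %d %d">'), W, H, W, H),
           sprintf('<rect x="0" y="0" width="%d" height="%d" fill="white"/>', W, H))

  ## coordinate axis (1-based labels)
  ticks <- pretty(c(wS + 1, wE), n = 5)
  ticks <- ticks[ticks >= wS + 1 & ticks <= wE]
  svg <- c(svg, '<g class="axis">',
           sprintf('<line x1="%s" y1="30" x2="%s" y2="30" stroke="black"/>',
                   fmt(mLeft), fmt(W - mRight)),
           sprintf('<text x="%s" y="14" font-size="12" font-family="monospace">%s</text>',
                   fmt(mLeft), xmlEscape(formatWindow(window))))
  for (t in ticks)
    svg <- c(svg,
             sprintf('<line x1="%s" y1="26" x2="%s" y2="34" stroke="black"/>',
                     fmt(xOf(t - 1)), fmt(xOf(t - 1))),
             sprintf('<text x="%s" y="24" font-size="9" text-anchor="middle">%d</text>',
                     fmt(xOf(t - 1)), as.integer(t)))
  svg <- c(svg, '</g>')

  clipBoxes <- function(df) {
    df <- df[df$chrom == window@chrom & df$start < wE & df$end > wS, , drop = FALSE]
    df
  }
  lastPanelOfGroup <- list()  # group id -> y of its last panel
  y <- mTop
  for (i in seq_len(nrow(ce))) {
    tid <- ce$trackId[i]; origin <- ce$origin[i]
    isStatic <- origin == "static"
    gid <- if (isStatic) NA_character_ else sub("^group:", "", origin)
    svg <- c(svg, sprintf('<g class="track-panel" id="panel-%s">', xmlEscape(tid)),
             sprintf('<rect x="%s" y="%s" width="%s" height="%d" fill="none" stroke="#cccccc"/>',
                     fmt(mLeft), fmt(y), fmt(plotW), panelH),
             sprintf('<text x="6" y="%s" font-size="11" font-family="monospace">%s</text>',
                     fmt(y + panelH / 2 + 4), xmlEscape(tid)))
    if (isStatic) {
      feats <- clipBoxes(readFeatures(registry@staticTracks[[tid]]@path))
      for (j in seq_len(nrow(feats)))
        svg <- c(svg, sprintf('<rect class="feature-box" x="%s" y="%s" width="%s" height="%s" fill="#2b6cb0"/>',
                              fmt(xOf(feats$start[j])), fmt(y + panelH * 0.3),
                              fmt(max(1, xOf(feats$end[j]) - xOf(feats$start[j]))),
                              fmt(panelH * 0.4)))
    } else {
      ts <- registry@trackSets[[tid]]
      if (is.null(ts)) dtIOError("track '%s' is not registered", tid)
      sig <- clipBoxes(readBedGraph(ts@signalPath))
      maxV <- if (nrow(sig)) max(sig$value) else 1
      sigH <- panelH * 0.72
      for (j in seq_len(nrow(sig))) {
        h <- sigH * sig$value[j] / max(maxV, .Machine$double.eps)
        svg <- c(svg, sprintf('<rect class="signal-bar" x="%s" y="%s" width="%s" height="%s" fill="#718096"/>',
                              fmt(xOf(sig$start[j])), fmt(y + sigH - h),
                              fmt(max(1, xOf(sig$end[j]) - xOf(sig$start[j]))),
                              fmt(h)))
      }
      feats <- clipBoxes(readFeatures(ts@featurePath))
      for (j in seq_len(nrow(feats)))
        svg <- c(svg, sprintf('<rect class="feature-box" x="%s" y="%s" width="%s" height="%s" fill="#c05621"/>',
                              fmt(xOf(feats$start[j])), fmt(y + panelH * 0.8),
                              fmt(max(1, xOf(feats$end[j]) - xOf(feats$start[j]))),
                              fmt(panelH * 0.15)))
      lastPanelOfGroup[[gid]] <- y
    }
    svg <- c(svg, '</g>')
    y <- y + panelH + gap
  }

  ## overflow cue: warning triangle at the right edge of the group's block
  ## (or in the header row when the group holds no visible panel)
  for (gid in names(state@overflow)) {
    if (!isTRUE(state@overflow[[gid]])) next
    gy <- lastPanelOfGroup[[gid]] %||% 4
    cx <- W - mRight + 14
    svg <- c(svg, sprintf('<g class="overflow-glyph" id="overflow-%s">', xmlEscape(gid)),
             sprintf('<path d="M %s %s l 10 18 l -20 0 z" fill="#e53e3e"/>',
                     fmt(cx), fmt(gy + 10)),
             sprintf('<title>group %s: interesting tracks hidden</title>', xmlEscape(gid)),
             '</g>')
  }
  svg <- c(svg, '</svg>')
  writeTextFile(svg, out)
  invisible(out)
}
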