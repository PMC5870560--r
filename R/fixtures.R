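## Deterministic synthetic-fixture generation: companion feature BEDs,
## constant-height bedGraph signal, a static genes track and a registry
## configuration wiring them together.

#' Describe a synthetic fixture
#'
#' Defaults emulate a small epigenomics browsing setup on two
#' Drosophila-sized chromosome arms: one seven-track group (signal +
#' companion peak calls per track), 50 peaks per track with typical
#' ChIP-seq peak widths of 200-2000 bp, all modes automatic, the group
#' anchored below a static genes track, no visibility caps.
#'
#' @param seed RNG seed; the whole output tree is a pure function of it.
#' @param nGroups number of track groups.
#' @param tracksPerGroup track sets per group.
#' @param featuresPerTrack features per companion BED.
#' @param chromSizes named integer vector of chromosome lengths (bp).
#' @param featureLengthRange integer `(min, max)` feature length in bp.
#' @param groupMaxVisible per-group visibility cap (`NA` = none).
#' @param globalMaxVisible global visibility cap (`NA` = none).
#' @param modes group browsing modes, recycled over groups.
#' @param anchorFirstGroup anchor the first group below the genes track and
#'   chain each further group below its predecessor.
#' @return a [FixtureSpec-class].
#' @export
fixtureSpec <- function(seed, nGroups = 1L, tracksPerGroup = 7L,
                        featuresPerTrack = 50L,
                        chromSizes = c(chr2L = 1000000L, chr2R = 1000000L),
                        featureLengthRange = c(200L, 2000L),
                        groupMaxVisible = NA_integer_,
                        globalMaxVisible = NA_integer_,
                        modes = "automatic",
                        anchorFirstGroup = TRUE) {
  new("FixtureSpec", seed = as.integer(seed), nGroups = as.integer(nGroups),
      tracksPerGroup = as.integer(tracksPerGroup),
      featuresPerTrack = as.integer(featuresPerTrack),
      chromSizes = setNames(as.integer(chromSizes), names(chromSizes)),
      featureLengthRange = as.integer(featureLengthRange),
      groupMaxVisible = as.integer(groupMaxVisible),
      globalMaxVisible = as.integer(globalMaxVisible),
      modes = as.character(modes),
      anchorFirstGroup = isTRUE(anchorFirstGroup))
}

writeTextFile <- function(lines, path) writeLines(lines, path, useBytes = TRUE)

## n feature intervals on random chromosomes, 0-based half-open, length
## drawn uniformly from [min, max], start uniform over the fitting range.
randomIntervals <- function(n, chromSizes, lenRange) {
  chromIdx <- sample.int(length(chromSizes), n, replace = TRUE)
  len <- if (lenRange[1] == lenRange[2]) rep(lenRange[1], n)
         else lenRange[1] + floor(runif(n) * (lenRange[2] - lenRange[1] + 1L))
  maxStart <- pmax(0L, chromSizes[chromIdx] - len)
  start <- floor(runif(n) * (maxStart + 1))
  data.frame(chrom = names(chromSizes)[chromIdx],
             start = as.integer(start),
             end = as.integer(start + len))
}

#' Generate a complete synthetic fixture tree
#'
#' Writes, deterministically from the seed in `spec`: one companion BED per
#' track (uniformly placed, non-degenerate features), one bedGraph per track
#' (a constant-height rectangle over each feature, zero elsewhere), one
#' static genes BED, and a registry JSON wiring everything into groups.
#' Re-running with the same spec produces a byte-identical directory tree.
#'
#' @param spec a [FixtureSpec-class].
#' @param outDir output directory (created if needed).
#' @return path of the written registry JSON, invisibly.
#' @examples
#' dir <- tempfile()
#' reg <- loadRegistry(generateFixtures(fixtureSpec(seed = 1), dir))
#' reg
#' @export
generateFixtures <- function(spec, outDir) {
  stopifnot(is(spec, "FixtureSpec"))
  ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(outDir, 2L) != 0L)
    dtIOError("output directory not writable: %s", outDir)

  regPath <- withSeed(spec@seed, {
    trackSets <- list()
    for (g in seq_len(spec@nGroups)) {
      for (i in seq_len(spec@tracksPerGroup)) {
        id <- sprintf("g%d_t%d", g, i)
        iv <- randomIntervals(spec@featuresPerTrack, spec@chromSizes,
                              spec@featureLengthRange)
        iv <- iv[order(iv$chrom, iv$start, iv$end), , drop = FALSE]
        writeTextFile(sprintf("%s\t%d\t%d\t%s_f%d", iv$chrom, iv$start, iv$end,
                              id, seq_len(nrow(iv))),
                      file.path(outDir, paste0(id, ".bed")))
        height <- 1L + as.integer(floor(runif(nrow(iv)) * 10))
        writeTextFile(sprintf("%s\t%d\t%d\t%d", iv$chrom, iv$start, iv$end, height),
                      file.path(outDir, paste0(id, ".bedGraph")))
        trackSets[[id]] <- list(id = id,
                                signal_path = paste0(id, ".bedGraph"),
                                feature_path = paste0(id, ".bed"),
                                group_id = sprintf("grp%d", g), rank = i)
      }
    }
    genes <- randomIntervals(20L, spec@chromSizes, c(5000L, 20000L))
    genes <- genes[order(genes$chrom, genes$start, genes$end), , drop = FALSE]
    writeTextFile(sprintf("%s\t%d\t%d\tgene%d", genes$chrom, genes$start,
                          genes$end, seq_len(nrow(genes))),
                  file.path(outDir, "genes.bed"))

    modes <- rep_len(spec@modes, spec@nGroups)
    groups <- lapply(seq_len(spec@nGroups), function(g) {
      out <- list(id = sprintf("grp%d", g), mode = modes[g])
      if (spec@anchorFirstGroup)
        out$anchor <- if (g == 1L) "genes" else sprintf("grp%d", g - 1L)
      if (!is.na(spec@groupMaxVisible)) out$max_visible <- spec@groupMaxVisible
      out
    })
    cfg <- list(static_tracks = list(list(id = "genes", path = "genes.bed",
                                          position = 0L)),
                groups = groups, track_sets = unname(trackSets))
    if (!is.na(spec@globalMaxVisible))
      cfg$global_max_visible <- spec@globalMaxVisible
    regPath <- file.path(outDir, "registry.json")
    writeTextFile(canonicalJSON(cfg), regPath)
    regPath
  })
  invisible(regPath)
}

#' Generate the two-window walkthrough fixture
#'
#' A hand-laid (RNG-free) fixture for the canonical demonstration scenario:
#' a static genes track followed by one automatic seven-track group anchored
#' below it, on Drosophila chr2R. In the first window
#' (`chr2R:8794209-8812865`) every track has at least one companion feature;
#' in a second window 84 kb away (`chr2R:8878094-8896750`) only the tracks
#' ranked 2, 4 and 7 do, so navigating from the first window to the second
#' shrinks the container from `[genes, t1..t7]` to `[genes, t2, t4, t7]`.
#'
#' @param outDir output directory (created if needed).
#' @return a list with `registry` (path to the registry JSON) and `windows`
#'   (the two region strings).
#' @export
generateDemoFixture <- function(outDir) {
  ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) dtIOError("output directory not writable: %s", outDir)
  w1 <- "chr2R:8794209-8812865"
  w2 <- "chr2R:8878094-8896750"
  a <- parseWindow(w1); b <- parseWindow(w2)
  inW2 <- c(2L, 4L, 7L)
  for (i in 1:7) {
    id <- sprintf("t%d", i)
    ## one peak per window, offset per rank so tracks differ visibly
    feats <- sprintf("chr2R\t%d\t%d\t%s_w1", a@start + 1000L * i,
                     a@start + 1000L * i + 600L, id)
    if (i %in% inW2)
      feats <- c(feats, sprintf("chr2R\t%d\t%d\t%s_w2", b@start + 1200L * i,
                                b@start + 1200L * i + 800L, id))
    writeTextFile(feats, file.path(outDir, paste0(id, ".bed")))
    writeTextFile(sub("^(\\S+\t\\S+\t\\S+).*$", paste0("\\1\t", i), feats),
                  file.path(outDir, paste0(id, ".bedGraph")))
  }
  writeTextFile(c(sprintf("chr2R\t%d\t%d\tgeneA", a@start + 2000L, a@end - 2000L),
                  sprintf("chr2R\t%d\t%d\tgeneB", b@start + 2000L, b@end - 2000L)),
                file.path(outDir, "genes.bed"))
  cfg <- list(
    static_tracks = list(list(id = "genes", path = "genes.bed", position = 0L)),
    groups = list(list(id = "grp1", mode = "automatic", anchor = "genes")),
    track_sets = lapply(1:7, function(i)
      list(id = sprintf("t%d", i), signal_path = sprintf("t%d.bedGraph", i),
           feature_path = sprintf("t%d.bed", i), group_id = "grp1", rank = i))
  )
  regPath <- file.path(outDir, "registry.json")
  writeTextFile(canonicalJSON(cfg), regPath)
  list(registry = regPath, windows = c(w1, w2))
}
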