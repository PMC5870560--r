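#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

## ---- reading companion feature files -------------------------------------

guessFeatureFormat <- function(path) {
  p <- sub("\\.gz$", "", path, ignore.case = TRUE)
  ext <- tolower(tools::file_ext(p))
  if (ext == "bed") return("bed")
  if (ext %in% c("gff", "gff3")) return("gff3")
  dtFormatError("cannot guess feature format from extension of '%s'", path)
}

#' Read a companion feature dataset (BED or GFF3)
#'
#' Only genomic location is consumed: BED columns 1-3 (already 0-based
#' half-open) or GFF3 columns 1, 4, 5 (1-based inclusive, converted to
#' 0-based half-open as `(start-1, end)`). Strand, scores, names and all
#' other columns are ignored for indexing. Comment (`#`), `track` and
#' `browser` lines and blank lines are skipped. Plain or gzip-compressed
#' files are accepted; `format = "auto"` dispatches on the file extension.
#'
#' Rows with non-integer coordinates, or with `start >= end` after
#' conversion (including zero-length GFF3 features, which cannot overlap any
#' window under half-open semantics), raise a format error citing the
#' offending line number.
#'
#' @param path path to the feature file.
#' @param format `"bed"`, `"gff3"` or `"auto"`.
#' @return a data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), one row per feature; zero rows for an empty file.
#' @export
readFeatures <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) dtIOError("feature file not found: %s", path)
  if (format == "auto") format <- guessFeatureFormat(path)
  con <- if (grepl("\\.gz$", path, ignore.case = TRUE)) gzfile(path, "rt")
         else file(path, "rt")
  on.exit(close(con))
  lines <- tryCatch(readLines(con, warn = FALSE),
                    error = function(e) dtIOError("cannot read '%s': %s", path,
                                                  conditionMessage(e)))
  skip <- !nzchar(trimws(lines)) | grepl("^#", lines) |
    grepl("^(track|browser)([ \t]|$)", lines)
  keep <- which(!skip)
  if (!length(keep))
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))

  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  minCols <- if (format == "bed") 3L else 5L
  bad <- which(nf < minCols)
  if (length(bad))
    dtFormatError("%s line %d: expected >= %d tab-separated columns, got %d",
                  path, keep[bad[1]], minCols, nf[bad[1]])
  if (format == "bed") {
    chrom <- vapply(fields, `[[`, "", 1L)
    sTxt <- vapply(fields, `[[`, "", 2L)
    eTxt <- vapply(fields, `[[`, "", 3L)
  } else {
    chrom <- vapply(fields, `[[`, "", 1L)
    sTxt <- vapply(fields, `[[`, "", 4L)
    eTxt <- vapply(fields, `[[`, "", 5L)
  }
  badInt <- which(!grepl("^[0-9]+$", sTxt) | !grepl("^[0-9]+$", eTxt))
  if (length(badInt))
    dtFormatError("%s line %d: non-integer coordinates ('%s', '%s')",
                  path, keep[badInt[1]], sTxt[badInt[1]], eTxt[badInt[1]])
  start <- as.integer(sTxt); end <- as.integer(eTxt)
  if (format == "gff3") start <- start - 1L
  badIv <- which(start >= end)
  if (length(badIv))
    dtFormatError("%s line %d: empty or reversed interval [%d, %d)",
                  path, keep[badIv[1]], start[badIv[1]], end[badIv[1]])
  data.frame(chrom = chrom, start = start, end = end)
}

## ---- index construction & query ------------------------------------------

#' Compile all companion features of a registry into a FeatureIndex
#'
#' The compiled index is the single structure queried on every navigation
#' step to decide which tracks are locus-specific interesting. Construction
#' is deterministic; tracks whose feature file is empty stay in the track
#' universe (they are simply never interesting). Reader errors are
#' propagated prefixed with the offending track id.
#'
#' @param registry a [TrackRegistry-class].
#' @return a [FeatureIndex-class].
#' @export
buildIndex <- function(registry) {
  stopifnot(is(registry, "TrackRegistry"))
  ts <- registry@trackSets
  parts <- vector("list", length(ts))
  for (i in seq_along(ts)) {
    t <- ts[[i]]
    df <- tryCatch(readFeatures(t@featurePath),
                   error = function(e) dtStop(class(e)[1], "track '%s': %s",
                                              t@id, conditionMessage(e)))
    if (nrow(df)) df$trackId <- t@id
    parts[[i]] <- df
  }
  nonEmpty <- Filter(nrow, parts)
  nclists <- list(); chromIds <- list()
  if (length(nonEmpty)) {
    all <- do.call(rbind, nonEmpty)
    gr <- GRanges(seqnames = all$chrom,
                  ranges = IRanges(start = all$start + 1L, end = all$end),
                  trackId = all$trackId)
    for (chrom in sort(unique(all$chrom), method = "radix")) {
      sel <- all$chrom == chrom
      nclists[[chrom]] <- IRanges::NCList(
        IRanges(start = all$start[sel] + 1L, end = all$end[sel]))
      chromIds[[chrom]] <- all$trackId[sel]
    }
  } else {
    gr <- GRanges()
    S4Vectors::mcols(gr)$trackId <- character(0)
  }
  new("FeatureIndex", features = gr, nclists = nclists, chromTrackIds = chromIds,
      trackUniverse = unname(names(ts) %||% character(0)))
}

#' @describeIn FeatureIndex-class ids of all indexed tracks.
#' @export
setMethod("trackUniverse", "FeatureIndex", function(x) x@trackUniverse)

#' @rdname queryWindow
#' @export
setMethod("queryWindow", signature("FeatureIndex", "GenomicWindow"),
  function(index, window) {
    ncl <- index@nclists[[window@chrom]]
    if (is.null(ncl)) return(character(0))
    q <- IRanges(start = window@start + 1L, end = window@end)
    hits <- findOverlaps(q, ncl, minoverlap = 1L)
    sort(unique(index@chromTrackIds[[window@chrom]][subjectHits(hits)]),
         method = "radix")
  })

setMethod("show", "FeatureIndex", function(object) {
  cat("FeatureIndex:", length(object@features), "feature(s) across",
      length(object@trackUniverse), "track(s) on",
      length(unique(as.character(GenomicRanges::seqnames(object@features)))),
      "sequence(s)\n")
})
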