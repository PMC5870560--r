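test_that("BED and GFF3 rows map to 0-based half-open coordinates", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "a.bed")
  writeLines(c("track name=peaks", "# comment", "",
               "chr1\t10\t20\tpeakA", "chr2\t0\t5"), bed)
  df <- readFeatures(bed)
  expect_equal(df$start, c(10L, 0L))
  expect_equal(df$end, c(20L, 5L))

  gff <- file.path(dir, "a.gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tpeak\t11\t20\t.\t+\t.\tID=x"), gff)
  dg <- readFeatures(gff)
  expect_equal(dg$chrom, "chr1")
  expect_equal(dg$start, 10L)  # 1-based inclusive -> 0-based half-open
  expect_equal(dg$end, 20L)

  ## gzip-compressed input with auto format dispatch
  gz <- file.path(dir, "b.bed.gz")
  con <- gzfile(gz, "wt"); writeLines("chr1\t5\t9", con); close(con)
  expect_equal(readFeatures(gz)$start, 5L)
})

test_that("malformed feature rows raise format errors citing the line", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.bed")
  writeLines(c("chr1\t0\t10", "chr1\t20\t10"), bad)
  expect_error(readFeatures(bad), "line 2", class = "dt_format_error")
  writeLines(c("chr1\tx\t10"), bad)
  expect_error(readFeatures(bad), "line 1", class = "dt_format_error")
  ## zero-length GFF3 feature (start == end after conversion)
  gff <- file.path(dir, "zero.gff3")
  writeLines("chr1\tsrc\tp\t11\t10\t.\t.\t.\t.", gff)
  expect_error(readFeatures(gff), class = "dt_format_error")
  expect_error(readFeatures(file.path(dir, "absent.bed")), class = "dt_io_error")
})

test_that("the reader agrees with rtracklayer on well-formed files", {
  dir <- withr::local_tempdir()
  withr::with_seed(7, {
    n <- 100L
    start <- sample.int(100000L, n)
    df <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                     start = start, end = start + sample.int(2000L, n))
  })
  bed <- file.path(dir, "r.bed")
  writeLines(sprintf("%s\t%d\t%d\tf%d", df$chrom, df$start, df$end, seq_len(nrow(df))), bed)
  mine <- readFeatures(bed)
  ref <- rtracklayer::import(bed, format = "bed")
  expect_equal(mine$chrom, as.character(GenomicRanges::seqnames(ref)))
  expect_equal(mine$start, GenomicRanges::start(ref) - 1L)
  expect_equal(mine$end, GenomicRanges::end(ref))
})

test_that("window queries match the linear-scan oracle (hand cases)", {
  reg <- makeTestRegistry(
    features = list(t1 = "chr1\t0\t10", t2 = "chr1\t5\t15", t3 = "chr1\t100\t110"),
    groups = list(g1 = list(tracks = c("t1", "t2", "t3"))))
  idx <- buildIndex(reg)
  expect_equal(queryWindow(idx, GenomicWindow("chr1", 6L, 8L)), c("t1", "t2"))
  ## abutting features are excluded under half-open arithmetic
  expect_equal(queryWindow(idx, GenomicWindow("chr1", 15L, 100L)), character(0))
  expect_equal(queryWindow(idx, GenomicWindow("chr1", 14L, 16L)), "t2")
  ## containment
  expect_equal(queryWindow(idx, GenomicWindow("chr1", 101L, 102L)), "t3")
  ## unknown chromosome is a valid, empty query
  expect_equal(queryWindow(idx, GenomicWindow("chrUn", 0L, 1e6)), character(0))
})

test_that("tracks with empty feature files stay in the universe", {
  dir <- withr::local_tempdir()
  reg <- makeTestRegistry(
    features = list(t1 = "chr1\t0\t10", t2 = character(0)),
    groups = list(g1 = list(tracks = c("t1", "t2"))), dir = dir)
  idx <- buildIndex(reg)
  expect_setequal(trackUniverse(idx), c("t1", "t2"))
  expect_equal(queryWindow(idx, GenomicWindow("chr1", 0L, 1000L)), "t1")
  ## reader errors propagate with the track id prefixed
  writeLines("chr1\t9\t3", file.path(dir, "t2.bed"))
  expect_error(buildIndex(reg), "t2", class = "dt_format_error")
})

test_that("queries equal the scan oracle on randomized fixtures", {
  chromSizes <- c(chrA = 200000L, chrB = 100000L)
  for (seed in 1:3) {
    dir <- withr::local_tempdir()
    reg <- loadRegistry(generateFixtures(
      fixtureSpec(seed = seed, nGroups = 2L, tracksPerGroup = 5L,
                  featuresPerTrack = 40L, chromSizes = chromSizes,
                  featureLengthRange = c(50L, 500L)), dir))
    idx <- buildIndex(reg)
    idx2 <- buildIndex(reg)
    feats <- collectFeatures(reg)
    withr::with_seed(1000L + seed, {
      for (i in 1:50) {
        w <- randomWindow(chromSizes)
        expect_identical(queryWindow(idx, w), scanOracle(feats, w))
        ## rebuilding the index does not change query behaviour
        expect_identical(queryWindow(idx2, w), queryWindow(idx, w))
      }
    })
  }
})

test_that("query results are monotone in window containment", {
  dir <- withr::local_tempdir()
  chromSizes <- c(chr1 = 100000L)
  reg <- loadRegistry(generateFixtures(
    fixtureSpec(seed = 11, tracksPerGroup = 6L, featuresPerTrack = 30L,
                chromSizes = chromSizes, featureLengthRange = c(20L, 300L)), dir))
  idx <- buildIndex(reg)
  withr::with_seed(42, {
    for (i in 1:40) {
      w2 <- randomWindow(chromSizes, maxLen = 20000L)
      pad <- sample.int(5000L, 2L)
      inner <- GenomicWindow(w2@chrom,
                             min(w2@start + pad[1], w2@end - 1L), w2@end)
      expect_true(all(queryWindow(idx, inner) %in% queryWindow(idx, w2)))
    }
  })
})
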