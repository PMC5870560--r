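## A seven-track group where only ranks 2, 4 and 7 have features in the
## second window; the canonical walkthrough configuration.
sevenTrackRegistry <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  feats <- list()
  for (i in 1:7) {
    lines <- sprintf("chr1\t%d\t%d", 1000L + i * 10L, 1000L + i * 10L + 5L)
    if (i %in% c(2L, 4L, 7L))
      lines <- c(lines, sprintf("chr1\t%d\t%d", 5000L + i * 10L, 5000L + i * 10L + 5L))
    feats[[paste0("t", i)]] <- lines
  }
  makeTestRegistry(feats,
                   groups = list(g1 = list(tracks = paste0("t", 1:7),
                                           anchor = "genes")),
                   dir = dir)
}

test_that("classification partitions members by rank order", {
  reg <- sevenTrackRegistry()
  idx <- buildIndex(reg)
  cls <- classify(reg, idx, GenomicWindow("chr1", 4900L, 5200L))
  expect_equal(cls@perGroup$g1$interesting, c("t2", "t4", "t7"))
  expect_equal(cls@perGroup$g1$empty, c("t1", "t3", "t5", "t6"))
  ## window on an empty contig: everything empty
  cls0 <- classify(reg, idx, GenomicWindow("chrUn", 0L, 100L))
  expect_equal(cls0@perGroup$g1$interesting, character(0))
  expect_equal(cls0@perGroup$g1$empty, paste0("t", 1:7))
})

test_that("disabled groups are absent from the classification", {
  reg <- makeTestRegistry(
    features = list(a1 = "chr1\t0\t10", b1 = "chr1\t0\t10"),
    groups = list(gA = list(tracks = "a1"),
                  gB = list(tracks = "b1", mode = "disabled")))
  cls <- classify(reg, buildIndex(reg), GenomicWindow("chr1", 0L, 5L))
  expect_named(cls@perGroup, "gA")
})

test_that("navigation removes empty tracks and keeps the anchored block below genes", {
  reg <- sevenTrackRegistry()
  idx <- buildIndex(reg)
  st1 <- composeLayout(reg, classify(reg, idx, GenomicWindow("chr1", 900L, 2000L)),
                       initialLayout(reg))
  expect_equal(containerEntries(st1)$trackId, c("genes", paste0("t", 1:7)))
  st2 <- composeLayout(reg, classify(reg, idx, GenomicWindow("chr1", 4900L, 5200L)), st1)
  expect_equal(containerEntries(st2)$trackId, c("genes", "t2", "t4", "t7"))
  expect_false(any(overflowFlags(st2)))
  ## all-empty classification leaves only the static backbone
  st3 <- composeLayout(reg, classify(reg, idx, GenomicWindow("chrUn", 0L, 10L)), st2)
  expect_equal(containerEntries(st3)$trackId, "genes")
})

test_that("group caps truncate the rank-ordered prefix and set the overflow flag", {
  reg <- makeTestRegistry(
    features = setNames(rep(list("chr1\t0\t100"), 5), paste0("t", 1:5)),
    groups = list(g1 = list(tracks = paste0("t", 1:5), cap = 2L)))
  cls <- classify(reg, buildIndex(reg), GenomicWindow("chr1", 0L, 50L))
  st <- composeLayout(reg, cls, initialLayout(reg))
  expect_equal(st@visible$g1, c("t1", "t2"))
  expect_true(overflowFlags(st)[["g1"]])
  expect_false(isGlobalOverflow(st))  # group cap, not the global budget
  s <- summarizeLayout(cls, st)
  expect_equal(s@perGroup$nInteresting, 5L)
  expect_equal(s@perGroup$nVisible, 2L)
  expect_equal(s@perGroup$nHidden, 3L)
})

test_that("the global budget is allocated in placement order; later groups may get 0", {
  reg <- makeTestRegistry(
    features = setNames(rep(list("chr1\t0\t100"), 6),
                        c("a1", "a2", "a3", "b1", "b2", "b3")),
    groups = list(gA = list(tracks = c("a1", "a2", "a3"), anchor = "genes"),
                  gB = list(tracks = c("b1", "b2", "b3"))),
    globalMax = 4L)
  cls <- classify(reg, buildIndex(reg), GenomicWindow("chr1", 0L, 50L))
  st <- composeLayout(reg, cls, initialLayout(reg))
  expect_equal(st@visible$gA, c("a1", "a2", "a3"))
  expect_equal(st@visible$gB, "b1")
  expect_true(isGlobalOverflow(st))
  expect_true(overflowFlags(st)[["gB"]])
  expect_equal(containerEntries(st)$trackId, c("genes", "a1", "a2", "a3", "b1"))
})

test_that("composition is idempotent and deterministic", {
  reg <- sevenTrackRegistry()
  idx <- buildIndex(reg)
  cls <- classify(reg, idx, GenomicWindow("chr1", 900L, 6000L))
  st1 <- composeLayout(reg, cls, initialLayout(reg))
  st2 <- composeLayout(reg, cls, st1)
  expect_identical(layoutStateToJSON(st2), layoutStateToJSON(st1))
})

test_that("manual groups freeze their block and park the classification as pending", {
  dir <- withr::local_tempdir()
  feats <- list(m1 = "chr1\t0\t100", m2 = "chr1\t0\t100",
                m3 = "chr1\t500\t600")
  reg <- makeTestRegistry(feats,
                          groups = list(gM = list(tracks = c("m1", "m2", "m3"),
                                                  mode = "manual")),
                          dir = dir)
  idx <- buildIndex(reg)
  ## manual mode: first navigation shows nothing (initial block empty)
  st1 <- composeLayout(reg, classify(reg, idx, GenomicWindow("chr1", 0L, 50L)),
                       initialLayout(reg))
  expect_equal(st1@visible$gM, character(0))
  expect_equal(pendingGroups(st1), "gM")
  expect_true(overflowFlags(st1)[["gM"]])  # interesting tracks, none shown
  ## applying the pending classification rebuilds the block
  st2 <- applyPending(st1, reg, "gM")
  expect_equal(st2@visible$gM, c("m1", "m2"))
  expect_length(pendingGroups(st2), 0L)
  ## fixed point: pending equal to what is already visible changes nothing
  st3 <- composeLayout(reg, classify(reg, idx, GenomicWindow("chr1", 0L, 50L)), st2)
  expect_equal(st3@visible$gM, c("m1", "m2"))
  st4 <- applyPending(st3, reg, "gM")
  expect_equal(containerEntries(st4)$trackId, containerEntries(st3)$trackId)
  ## single-group recomposition: pending interesting [m3] replaces the block
  st5 <- composeLayout(reg, classify(reg, idx, GenomicWindow("chr1", 550L, 560L)), st4)
  expect_equal(st5@visible$gM, c("m1", "m2"))  # untouched by navigation
  st6 <- applyPending(st5, reg, "gM")
  expect_equal(st6@visible$gM, "m3")
  ## no pending entry: no-op
  expect_identical(layoutStateToJSON(applyPending(st6, reg, "gM")),
                   layoutStateToJSON(st6))
})

test_that("applyPending on a non-manual group is a contract violation", {
  reg <- makeTestRegistry(features = list(t1 = "chr1\t0\t10"),
                          groups = list(g1 = list(tracks = "t1")))
  st <- initialLayout(reg)
  expect_error(applyPending(st, reg, "g1"), class = "dt_contract_error")
  expect_error(applyPending(st, reg, "ghost"), class = "dt_contract_error")
})

test_that("disabled groups are copied verbatim across navigation", {
  dir <- withr::local_tempdir()
  reg <- makeTestRegistry(
    features = list(d1 = "chr1\t0\t100", a1 = "chr1\t0\t100"),
    groups = list(gD = list(tracks = "d1", mode = "disabled"),
                  gA = list(tracks = "a1")),
    dir = dir)
  idx <- buildIndex(reg)
  st <- composeLayout(reg, classify(reg, idx, GenomicWindow("chr1", 0L, 50L)),
                      initialLayout(reg))
  expect_equal(st@visible$gD, character(0))
  expect_equal(st@visible$gA, "a1")
  ## hand the disabled group a visible track, then navigate again
  st@visible$gD <- "d1"
  st2 <- composeLayout(reg, classify(reg, idx, GenomicWindow("chr1", 200L, 300L)), st)
  expect_equal(st2@visible$gD, "d1")
  expect_equal(st2@visible$gA, character(0))
})

test_that("anchor chains and sibling stacking match the recursive oracle", {
  feats <- setNames(rep(list("chr1\t0\t100"), 6),
                    c("a1", "a2", "b1", "b2", "c1", "u1"))
  reg <- makeTestRegistry(
    feats,
    groups = list(gA = list(tracks = c("a1", "a2"), anchor = "genes"),
                  gB = list(tracks = c("b1", "b2"), anchor = "gA"),
                  gC = list(tracks = "c1", anchor = "genes"),
                  gU = list(tracks = "u1")),
    statics = c("genes", "snps"))
  cls <- classify(reg, buildIndex(reg), GenomicWindow("chr1", 0L, 50L))
  st <- composeLayout(reg, cls, initialLayout(reg))
  got <- containerEntries(st)$trackId
  expect_equal(got, containerOracle(reg, stateVisible(st)))
  ## gA right below genes, gB below gA, sibling gC after gA's subtree,
  ## snps keeps its backbone slot, unanchored gU at the end
  expect_equal(got, c("genes", "a1", "a2", "b1", "b2", "c1", "snps", "u1"))
  ## first entry of the anchored group sits at anchor position + 1
  expect_equal(which(got == "a1"), which(got == "genes") + 1L)
})

test_that("a missing anchor target degrades to end placement with a diagnostic", {
  reg <- makeTestRegistry(features = list(t1 = "chr1\t0\t10"),
                          groups = list(g1 = list(tracks = "t1", anchor = "genes")))
  ## simulate a state whose container lost the anchor target
  reg2 <- reg
  reg2@staticTracks <- list()  # bypasses load validation on purpose
  cls <- inMemoryClassification(reg2, "t1")
  st <- composeLayout(reg2, cls, initialLayout(reg2))
  expect_equal(containerEntries(st)$trackId, "t1")
  expect_match(stateLog(st)[1], "anchor target 'genes' not present")
})
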