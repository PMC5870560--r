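test_that("script validation enforces shape and the leading goto", {
  expect_error(readNavigationScript("[]"), class = "dt_config_syntax_error")
  expect_error(readNavigationScript('[{"rotate": "g1"}]'),
               class = "dt_config_syntax_error")
  expect_error(readNavigationScript('[{"zoom": "chr1:1-2"}]'),
               class = "dt_config_syntax_error")
  steps <- readNavigationScript('[{"goto": "chr1:1-100"}, {"rotate": "g1"}]')
  expect_equal(steps[[2]], list(op = "rotate", arg = "g1"))
})

test_that("the two-window walkthrough reproduces the expected containers", {
  dir <- withr::local_tempdir()
  fx <- generateDemoFixture(dir)
  out <- file.path(dir, "nav")
  script <- sprintf('[{"goto": "%s"}, {"goto": "%s"}]',
                    fx$windows[1], fx$windows[2])
  res <- runNavigation(fx$registry, script, out)
  st1 <- layoutStateFromJSON(res$states[1])
  st2 <- layoutStateFromJSON(res$states[2])
  ## window 1: all 7 managed tracks on screen, right below the genes track
  expect_equal(containerEntries(st1)$trackId, c("genes", paste0("t", 1:7)))
  ## window 2, 84 kb away: only ranks 2, 4 and 7 stay; the rest are hidden
  expect_equal(containerEntries(st2)$trackId, c("genes", "t2", "t4", "t7"))
  summ <- jsonlite::fromJSON(res$summary, simplifyVector = FALSE)
  expect_equal(summ$groups[[1]]$n_interesting, 3L)
  expect_equal(summ$groups[[1]]$n_hidden, 0L)
  expect_equal(summ$total_visible, 4L)
})

test_that("every emitted state re-loads and matches the assembly oracle", {
  dir <- withr::local_tempdir()
  reg <- loadRegistry(generateFixtures(
    fixtureSpec(seed = 5, nGroups = 3L, tracksPerGroup = 4L,
                featuresPerTrack = 30L, groupMaxVisible = 2L,
                chromSizes = c(chr1 = 300000L)), dir))
  idx <- buildIndex(reg)
  withr::with_seed(6, {
    windows <- replicate(8, formatWindow(randomWindow(c(chr1 = 300000L))))
  })
  script <- jsonlite::toJSON(lapply(windows, function(w) list(goto = w)),
                             auto_unbox = TRUE)
  res <- runNavigation(reg, as.character(script), file.path(dir, "nav"))
  for (p in res$states) {
    st <- layoutStateFromJSON(p)
    expect_s4_class(st, "LayoutState")
    expect_equal(containerEntries(st)$trackId,
                 containerOracle(reg, stateVisible(st)))
    ## the serialized form is canonical: reserializing is byte-stable
    expect_identical(layoutStateToJSON(st),
                     paste(readLines(p, warn = FALSE), collapse = "\n"))
  }
})

test_that("invalid steps abort naming the step index", {
  dir <- withr::local_tempdir()
  fx <- generateDemoFixture(dir)
  err <- tryCatch(
    runNavigation(fx$registry,
                  sprintf('[{"goto": "%s"}, {"rotate": "nope"}]', fx$windows[1]),
                  file.path(dir, "nav1")),
    error = identity)
  expect_s3_class(err, "dt_contract_error")
  expect_match(conditionMessage(err), "step 2")
  ## apply on an automatic group
  err2 <- tryCatch(
    runNavigation(fx$registry,
                  sprintf('[{"goto": "%s"}, {"apply": "grp1"}]', fx$windows[1]),
                  file.path(dir, "nav2")),
    error = identity)
  expect_s3_class(err2, "dt_contract_error")
  expect_match(conditionMessage(err2), "step 2")
})

test_that("the CLI drives the full simulate/index/nav/render pipeline", {
  dir <- withr::local_tempdir()
  fxDir <- file.path(dir, "fx")
  expect_equal(dynatrackCLI(c("simulate", "--seed", "9", "--groups", "1",
                              "--tracks-per-group", "3", "--features", "5",
                              "--out", fxDir, "--log-level", "warn")), 0L)
  reg <- file.path(fxDir, "registry.json")
  expect_true(file.exists(reg))
  idxOut <- file.path(dir, "idx.json")
  expect_equal(dynatrackCLI(c("index", "--registry", reg, "--out", idxOut,
                              "--log-level", "warn")), 0L)
  idx <- jsonlite::fromJSON(idxOut)
  expect_equal(idx$n_features, 15L)
  ## craft a window guaranteed to exist: around the first feature of track 1
  f <- readFeatures(file.path(fxDir, "g1_t1.bed"))[1, ]
  w <- sprintf("%s:%d-%d", f$chrom, f$start + 1L, f$end)
  scriptPath <- file.path(dir, "script.json")
  writeLines(sprintf('[{"goto": "%s"}]', w), scriptPath)
  navDir <- file.path(dir, "nav")
  expect_equal(dynatrackCLI(c("nav", "--registry", reg, "--script", scriptPath,
                              "--out", navDir, "--log-level", "warn")), 0L)
  svgOut <- file.path(dir, "view.svg")
  expect_equal(dynatrackCLI(c("render", "--registry", reg, "--state",
                              file.path(navDir, "state_001.json"),
                              "--region", w, "--out", svgOut,
                              "--log-level", "warn")), 0L)
  expect_true(file.exists(svgOut))
  ## errors surface as a non-zero status, not an exception
  expect_equal(suppressMessages(dynatrackCLI(c("nav", "--registry", "missing.json",
                                               "--script", scriptPath,
                                               "--out", navDir))), 1L)
  expect_equal(suppressMessages(dynatrackCLI("frobnicate")), 1L)
})
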