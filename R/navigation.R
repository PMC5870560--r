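## Batch replay of the browser interaction loop: a navigation script is an
## ordered list of goto / rotate / apply steps, executed against a registry,
## emitting one canonical-JSON layout state per step.

#' Read and validate a navigation script
#'
#' A script is a JSON array of single-key objects: `{"goto": "chrom:start-end"}`
#' navigates (classify + compose), `{"rotate": "<group id>"}` rotates a
#' group's carousel, `{"apply": "<group id>"}` applies a manual group's
#' pending classification. The script must be non-empty and start with a
#' `goto` (rotation and application need a current window).
#'
#' @param path path to the script JSON, or the JSON text itself.
#' @return a list of steps, each `list(op = <chr>, arg = <chr>)`.
#' @export
readNavigationScript <- function(path) {
  txt <- if (length(path) == 1L && !grepl("^\\s*\\[", path)) {
    if (!file.exists(path)) dtIOError("script file not found: %s", path)
    paste(readLines(path, warn = FALSE), collapse = "\n")
  } else path
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) dtSyntaxError("script is not valid JSON: %s",
                                                    conditionMessage(e)))
  if (!is.list(doc) || !length(doc))
    dtSyntaxError("navigation script must be a non-empty JSON array")
  steps <- lapply(seq_along(doc), function(i) {
    s <- doc[[i]]
    if (!is.list(s) || length(s) != 1L ||
        !names(s) %in% c("goto", "rotate", "apply"))
      dtSyntaxError("step %d: expected a single goto/rotate/apply key", i)
    list(op = names(s), arg = as.character(s[[1]]))
  })
  if (steps[[1]]$op != "goto")
    dtSyntaxError("step 1: a navigation script must start with a goto")
  steps
}

#' Replay a navigation script and write one layout state per step
#'
#' Loads the registry, builds the feature index once, starts from the
#' static-backbone initial layout, then executes the script in order,
#' writing `state_<step>.json` (canonical JSON) after every step and a
#' final `summary.json` for the last window's classification. Any invalid
#' step (rotate on an unknown group, apply on a non-manual group, malformed
#' region) aborts with an error naming the step index.
#'
#' @param registryPath path to the registry JSON (or a loaded
#'   [TrackRegistry-class]).
#' @param scriptPath path to the navigation script JSON (or parsed steps
#'   from [readNavigationScript()]).
#' @param outDir output directory for the numbered state files.
#' @return invisibly, a list with `states` (paths, one per step),
#'   `summary` (path), and `finalState` (the last [LayoutState-class]).
#' @export
runNavigation <- function(registryPath, scriptPath, outDir) {
  registry <- if (is(registryPath, "TrackRegistry")) registryPath
              else loadRegistry(registryPath)
  steps <- if (is.character(scriptPath)) readNavigationScript(scriptPath)
           else scriptPath
  ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) dtIOError("output directory not writable: %s", outDir)

  index <- buildIndex(registry)
  state <- initialLayout(registry)
  cls <- NULL
  statePaths <- character(length(steps))
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    state <- tryCatch(
      switch(st$op,
        goto = {
          cls <- classify(registry, index, parseWindow(st$arg))
          composeLayout(registry, cls, state)
        },
        rotate = rotateCarousel(state, registry, cls, st$arg),
        apply = applyPending(state, registry, st$arg)),
      dynatrack_error = function(e)
        dtStop(class(e)[1], "step %d (%s %s): %s", i, st$op, st$arg,
               conditionMessage(e)))
    statePaths[i] <- file.path(outDir, sprintf("state_%03d.json", i))
    writeTextFile(layoutStateToJSON(state), statePaths[i])
  }
  summaryPath <- file.path(outDir, "summary.json")
  writeTextFile(summaryToJSON(summarizeLayout(cls, state)), summaryPath)
  invisible(list(states = statePaths, summary = summaryPath, finalState = state))
}
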