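# dynatrack

Genome browsers stack datasets as *tracks* aligned to a reference sequence.
With thousands of public epigenomics datasets available, the bottleneck is no
longer data access but screen space and rendering cost: a set of ChIP-seq or
4C-seq tracks worth displaying at one locus may be entirely flat a few
kilobases away, forcing the user to scroll, swap and drag tracks by hand as
they navigate. `dynatrack` is a headless, fully testable engine for
*dynamic track management*: it decides, for any genomic window, which tracks
are worth showing and exactly where on the screen each one goes.

It is aimed at genome-browser and visualization developers who need the
selection/layout logic as a reusable, deterministic component, and at
computational biologists who want to script or audit that logic outside a
browser.

## The model

Every quantitative signal dataset (bedGraph) is registered together with its
**companion feature dataset** (BED/GFF3 peak list) as a *dependent track
set* — the features declare where the signal rises above background, a
decision made upstream by peak calling. All companion features of all track
sets are compiled into one interval index. For a window *W* = [s, e) a
managed track *t* is **locus-specific interesting** iff it owns at least one
feature *f* with

```
f.start < e  and  f.end > s      (0-based, half-open)
```

and **locus-specific empty** otherwise. On each navigation step the engine
recomposes the ordered track container under these rules:

* static tracks (not managed) keep their configured backbone positions;
* each *automatic* group shows the first
  `min(n_interesting, group_cap, remaining_global_budget)` tracks of its
  interesting list, in predefined rank order, as one contiguous block placed
  immediately below its *anchor* (a static track or another group);
* *manual* groups freeze their block and park the fresh classification as
  pending until the user applies it; *disabled* groups are ignored;
* when interesting tracks exceed the caps, an overflow flag marks the group
  and **carousel rotation** scrolls through the ring of *N* interesting
  tracks with a cyclic window of *V* slots, advancing by `ceil(V/2)` per
  click, so the view first returns to its start after
  `N / gcd(N, ceil(V/2))` rotations.

## Worked example

The bundled generator writes a seven-track walkthrough fixture: every track
has a peak in the first window, only the tracks ranked 2, 4 and 7 have one
in a second window 84 kb downstream.

```r
library(dynatrack)
dir <- file.path(tempdir(), "demo")
fx  <- generateDemoFixture(dir)
reg <- loadRegistry(fx$registry)
reg
#> TrackRegistry with 1 static track(s), 1 group(s), 7 track set(s)
#>   global max visible: unlimited
#>   group 'grp1' [automatic] anchored on 'genes': t1, t2, t3, t4, t5, t6, t7

idx <- buildIndex(reg)
idx
#> FeatureIndex: 10 feature(s) across 7 track(s) on 1 sequence(s)

res <- runNavigation(reg, sprintf('[{"goto": "%s"}, {"goto": "%s"}]',
                                  fx$windows[1], fx$windows[2]),
                     file.path(dir, "nav"))
st2 <- layoutStateFromJSON(res$states[2])
st2
#> LayoutState with 4 visible track(s)
#>   [static] genes
#>   [group grp1] t2, t4, t7

cls <- classify(reg, idx, parseWindow(fx$windows[2]))
summarizeLayout(cls, st2)
#> LayoutSummary: 4 visible track(s); no overflow
#>  groupId nInteresting nVisible nHidden
#>     grp1            3        3       0
```

After the second `goto`, the four tracks with no features in the new window
have been removed from the container; the genes track (static, unmanaged) is
untouched and the surviving block still sits directly below it. The summary
is what a front-end widget would show the user: 3 of 7 managed tracks are
interesting here, all 3 are on screen, none hidden.

`renderView(reg, res$states[2], fx$windows[2], "view.svg")` draws the
composed container as a static SVG — one panel per entry (signal as filled
bars, companion features as a box strip), a coordinate axis, and a red
warning glyph beside any group whose interesting tracks overflow the caps.

The same operations are available from the shell via the installed script
(`exec/dynatrack.R`): `dynatrack simulate | index | nav | render`.

## Methods

See `vignettes/dynatrack-methods.Rmd` for the full account of the layout
algorithm, its tunable parameters, the synthetic-data generator, numerical
and tie-breaking choices, and known limitations.
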