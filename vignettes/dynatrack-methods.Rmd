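---
title: "dynatrack: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dynatrack: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynatrack)
```

# The problem and the model

Co-visualizing hundreds of genomic datasets in a browser fails on two
fronts: rendering cost and screen space. The observation behind dynamic
track management is that relevance is *locus-specific*: a ChIP-seq or
4C-seq track worth a slot at one locus may carry nothing but background a
few kilobases away. `dynatrack` operationalizes this with a priori
knowledge that already exists for essentially every processed dataset: the
peak list. A signal dataset is registered only together with its
**companion feature dataset**, and that companion — not the raw signal — is
the single source of truth for whether the track is interesting in a
window.

## Interestingness

All companion features of all registered track sets are compiled into one
interval index (per-chromosome `IRanges::NCList` containers under a
`GRanges` facade). For a window $[s, e)$, track $t$ is *interesting* iff it
owns a feature $[f_s, f_e)$ on the same chromosome with $f_s < e$ and
$f_e > s$ — i.e. an overlap of at least 1 bp under 0-based half-open
arithmetic.

Assumptions worth making explicit:

* **>= 1 bp is the whole criterion.** There is no minimum-overlap fraction,
  no feature-score threshold, and strand is ignored. Signal/background
  separation is delegated entirely to the upstream peak caller that
  produced the companion dataset; the engine performs no on-the-fly
  thresholding of bedGraph values.
* Zero-length features (GFF3 rows whose converted start equals their end)
  are rejected at read time: they cannot overlap any window under half-open
  semantics, so silently indexing them would create tracks that can never
  be interesting for a reason invisible to the user.

## Container composition

The track container is an ordered list of *blocks*: one per static track
(the fixed backbone, in configured position order) and one per group.
Composition rules, applied on every navigation step:

1. **Contiguity.** A group's tracks always form one consecutive block;
   empty blocks keep their slot, so a group anchored on a currently-empty
   group still lands in a stable position.
2. **Order.** Within a group, visible tracks are the *prefix* of the
   rank-ordered interesting list (at carousel offset 0). A track that stays
   interesting across a step is re-sorted into rank position rather than
   keeping its previous screen slot: the display order is defined as
   predefined, and re-sorting is the only policy that makes the layout a
   pure function of the classification.
3. **Anchoring.** An anchored block is inserted immediately below its
   target's block, after any earlier-placed blocks whose anchor chain leads
   to the same target — so siblings anchored on one target stack in
   declaration order and dependents stay below their parent. Anchor chains
   resolve transitively and are verified acyclic at load. Unanchored groups
   are appended at the container end in declaration order. A target missing
   from the container (reachable only from hand-constructed states, since
   loading validates anchors) degrades to end-of-container placement with a
   logged diagnostic — navigation must never fail mid-session.
4. **Caps.** Each automatic group shows
   $\min(n_\text{interesting}, \text{group cap}, \text{remaining global budget})$
   tracks. The global budget bounds the *managed* tracks only; static
   tracks never count against it, since the cap exists to bound automatic
   additions. When the sum of interesting tracks exceeds the global cap,
   groups are served in container placement order (anchors resolved, ties
   by declaration order) and later groups may receive zero slots: a
   deterministic allocation the user can predict, at the price of a
   declaration-order bias. Manual and disabled groups hold their tracks
   regardless, so their usage is subtracted from the budget before
   automatic allocation.
5. **Overflow.** `overflow[g]` is true iff some interesting tracks of $g$
   are off screen — computed as
   $n_\text{interesting} - |\text{visible} \cap \text{interesting}|> 0$,
   which for automatic groups reduces to truncation, and for manual groups
   keeps the widget's count identity `nVisible + nHidden = nInteresting`
   valid even when the frozen visible set is not a subset of the current
   interesting list. `globalOverflow` marks truncation by the global budget
   specifically.

Composition is a pure function: identical registry, classification and
previous state give byte-identical serialized states, and it is idempotent
(`compose(compose(s)) == compose(s)`).

## Browsing modes

*Automatic* groups recompose on every step. *Manual* groups never change on
navigation; the fresh classification is parked as `pending` and applied
only on explicit request (`applyPending()`), which rebuilds exactly as an
automatic group would — including cap and budget arithmetic at apply time —
and resets the carousel offset. *Disabled* groups are copied verbatim and
excluded from classification. Mode isolation is a tested invariant: no
navigation step alters a manual or disabled block.

## Carousel rotation

A group whose interesting list (length $N$) exceeds its visible quota
($V$) rotates as a cyclic window over the rank-ordered ring: each click
advances the offset by $\lceil V/2 \rceil$ modulo $N$. Choices made where
the behaviour was open:

* **`ceil`, not `floor`.** At $V = 1$, `floor(V/2) = 0` would stall the
  carousel; `ceil` guarantees progress for every $V \ge 1$.
* **The retained half is the tail** of the previous window: the window
  slides forward, so repeated clicks read *downward* through the predefined
  order, and wrap-around supplies the "infinite scrolling".
* **Forward-only.** One control, one direction; the cycle
  $N / \gcd(N, \lceil V/2 \rceil)$ (exposed as `rotationCycleLength()`)
  guarantees eventual return.
* A group allocated zero slots by the global budget does not rotate (the
  step would be 0 anyway); rotation with $N \le V$ is a no-op since
  nothing is hidden.
* Offsets reset to 0 whenever a group is recomposed (the ring only means
  something against a fixed interesting list); manual/disabled groups keep
  their offset across navigation, clamped back to 0 if the ring shrank
  beneath it.

# Configuration and coordinate conventions

The registry is one JSON document (`static_tracks`, `groups`, `track_sets`,
optional `global_max_visible`; schema in `inst/extdata/`). JSON was chosen
over browser-native conf dialects because it is bit-exact, language-neutral
and schema-checkable; loading resolves every cross-reference and rejects
duplicate ids, dangling references, anchor cycles and non-positive caps
with errors naming the offending entity. A track set belongs to exactly one
group; sharing a physical dataset between groups is expressed as two track
sets pointing at the same files.

User-facing region strings are 1-based inclusive (`chr2R:8794209-8812865`,
the browser convention); everything internal is 0-based half-open (BED
arithmetic), converted exactly once in `parseWindow()`. BED rows pass
through unchanged; GFF3 rows map $(start, end) \to (start - 1, end)$.

Tunable parameters, units and defaults:

| parameter | meaning | default |
|---|---|---|
| `mode` (per group) | automatic / manual / disabled | `automatic` |
| `max_visible` (per group) | cap on visible interesting tracks | unlimited |
| `global_max_visible` | cap on all group-managed visible tracks | unlimited |
| `anchor` (per group) | static track or group the block sits below | none (append at end) |
| `rank` (per track set) | display position within the group | required, no default |

Automatic mode and unlimited caps are the defaults because automatic
updating is the primary behaviour; caps are an opt-in guard for limited
hardware.

# The synthetic-data generator

`generateFixtures()` emulates a small epigenomics browsing setup: per
track, uniformly placed features of 200–2000 bp (typical ChIP-seq peak
widths) on Drosophila-arm-sized (1 Mb in tests) chromosomes, a bedGraph
with one constant-height rectangle per feature (zero elsewhere), a static
genes track, and a registry wiring groups with configurable modes, caps and
anchor chains. Defaults are one seven-track automatic group anchored below
the genes track with 50 features per track. Output is a pure function of
the seed — byte-identical trees across runs — which is what makes
golden-file and determinism tests possible. `generateDemoFixture()` is the
RNG-free two-window walkthrough: seven tracks all featured in
`chr2R:8794209-8812865`, only ranks 2, 4 and 7 featured 84 kb away in
`chr2R:8878094-8896750`.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: clustered/overlapping peak landscapes (features are
placed uniformly, real peaks cluster at regulatory elements), realistic
signal shapes (rectangles, not read pileups), contigs absent from the
index, malformed input files in the wild, or datasets large enough to
stress memory. The interval-index contract is nevertheless exercised at
realistic densities, and every reader rejects malformed rows with
line-numbered errors.

# Verification strategy and problem sizes

Every non-trivial rule is checked against an independent oracle rather than
against the implementation's own arithmetic: window queries against a
brute-force linear scan over all features (20 seeded fixtures x 200 random
windows in the acceptance suite), container layouts against a recursive
re-assembly straight from the anchor graph, carousel behaviour against
closed-form cycle lengths over the exhaustive grid $1 \le V < N \le 40$,
and the BED reader against `rtracklayer::import` on well-formed files.
Random navigation traces (3 configurations x 100 steps, mixing goto /
rotate / apply against registries with caps, manual and disabled groups,
and anchor chains) assert contiguity, anchoring, cap safety, overflow
consistency, mode isolation and idempotence after every step. These sizes
keep the full suite in the tens of seconds while covering every branch of
the allocation and placement logic; the fixture scale (tens of tracks,
thousands of features) matches the index's intended regime, and the NCList
query path is logarithmic in practice, so larger registries change
constants, not behaviour.

# Known limitations

* The engine is headless by design: no interactive reordering, no track
  styling, no height autoscaling, no browser integration. The SVG renderer
  is a verification surrogate with fixed panel geometry.
* Interestingness is binary and presence-based; a score- or
  fraction-of-overlap-based ranking would need the companion format to
  carry trusted scores, which it is not assumed to do.
* The global-budget allocation favours earlier-placed groups; a
  proportional allocation would be fairer but non-deterministic to the
  user's eye and is deliberately not implemented.
* bigWig signal input is not supported in this build; bedGraph covers the
  fixture-driven verification loop, and the reader sits behind a single
  function (`readBedGraph()`) where a bigWig path could be added.
* Feature files are read eagerly at index build; there is no lazy or
  incremental re-indexing when files change on disk.
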