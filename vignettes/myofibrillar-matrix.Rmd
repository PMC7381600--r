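---
title: "Quantifying the branching myofibrillar matrix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the branching myofibrillar matrix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myomatrix)
```

## The problem

Striated muscle has long been drawn as bundles of independent, tube-like
myofibrils: sarcomeres stacked end to end, many tubes in parallel. Volume
electron microscopy of labeled muscle shows something different: sarcomeres
branch. Part of a sarcomere's myofilaments can split away to form a second
myofibrillar structure, or detach and join an adjacent, parallel sarcomere
(a *myofilament transfer*; a reciprocal exchange at the same level is a
*trade*). Frequent branching knits the contractile apparatus into a single
connected network — a *myofibrillar matrix* — spanning both the length and
the width of the cell.

`myomatrix` implements the quantitative pipeline behind that observation so
it can be exercised end to end on data with known ground truth:

1. **`sample_network()` / `render_volume()`** — a stochastic generator of
   branching networks and rendered label volumes emulating manual
   one-label-per-segment segmentations;
2. **`build_graph()` / `classify_events()`** — overlap-based reconstruction
   of the sarcomere graph from any label volume, with typed branch events;
3. **`seed_tracks()` / `track_myofibril()` / `fov_filter()`** — the
   myofibril-tracking routine with the membrane-distance continuation rule
   and field-of-view exclusion;
4. **`branch_frequency()` / `percent_branched()` / `transfer_share()` /
   `volume_summary()`** — the per-volume statistics;
5. **`connected_components()` / `minimal_lateral_path()` /
   `width_span_fraction()`** — whole-cell connectivity;
6. **`group_compare()`** — one-way ANOVA with Tukey's HSD across muscle
   types, volumes being the unit of analysis.

## The generative model

A muscle volume is modeled as `n_columns` parallel sarcomere columns laid on
a jittered square grid (pitch `grid_pitch_vox`, default 13 voxels; column
radius 5) inside an elliptical cell cross-section, with z-disks every
`sarcomere_len_slices` slices (default 40, about 2 µm at the default 50 nm
isotropic voxel pitch — a deliberately coarser grid than the 10 nm of the
source imaging, keeping desk-scale volumes while preserving topology).

Per column and per sarcomere interval, at most one branch event is
initiated (a multinomial draw). Three event classes exist:

* **split** — a bridge detaches within the parent's cross-section (the
  parent footprint is partitioned by a chord; the parent keeps its lineage,
  the bridge is a new structure). Packed tissue leaves a detached bridge
  nowhere to go but alongside its neighbours, so after `2*taper + 2` to
  `2*taper + 8` slices it merges into a geometrically adjacent column. A
  static volume records this as **two** branch points — a split at one end
  and a merge at the other — exactly as a tracing of the volume would count
  them, and the two cannot be told apart in fixed material, which is why
  all reporting pools splits and merges into one class.
* **transfer** — a wedge (25% of the donor cross-section) detaches and
  crosses to an adjacent acceptor over `taper_slices` slices.
* **trade** — two reciprocal wedges exchanged between a pair of columns at
  the same level, recorded as a single event.

**Rate calibration.** The configuration probabilities `p_split`,
`p_transfer`, `p_trade` are defined on the scale the field reports: expected
branch events *encountered per sarcomere of a tracked myofibril* (so ten
times their sum is the branches-per-10-sarcomeres frequency). Every
initiated event touches exactly two columns — split end and merge end, or
donor and acceptor — so the generator initiates at half the configured
rates. This makes the tracked branch frequency an unbiased estimator of
`10 * (p_split + p_transfer + p_trade)` by construction, and it is what
lets the published frequencies serve directly as generator presets.

`muscle_preset()` encodes the published per-muscle values: branch frequency
per 10 sarcomeres (fast-twitch 1.6, slow-twitch 4.3, cardiac 2.2, early
postnatal 2.8, late postnatal 1.3, adult human fast 2.4), the transfer
share of all branches (fast 34.8%, slow 15.2%, cardiac 13.8%), and the
per-volume tracking totals (e.g. fast-twitch: 193 myofibrils averaging 18
serial sarcomeres). Two published quantities are not available and are
package assumptions, chosen once: the transfer share of the postnatal
stages (set to 15%, close to the other non-fast muscles) and the fraction
of transfer-class events that are trades (set to 20% everywhere). The
postnatal myofibril/sarcomere totals follow the running text (early
150/1401, late 141/1796); the corresponding figure legend carries the two
readings swapped, and we take no position on which is correct beyond
following the text.

Events are placed uniformly at random within their sarcomere interval
(branch points are observed in all sarcomeric bands, and
`annotate_band()` maps the phase fraction to z-disk-proximal, I-band,
A-band or H-zone using a fixed fractional partition that is a package
convention, not a measured one). Placement is constrained so that every
label transition of a column falls on its own slice and tapers complete
inside the volume; an event that cannot be placed — no adjacent partner
with a free corridor, or three cuts already active on a column — is
re-drawn as no-event and reported in the `suppressed` tally. At the
published rates this affects well under 1% of initiations.

## Rendering and its deliberate simplifications

`render_volume()` rasterizes analytic footprints per slice: disks minus
"cap" cuts for columns, translated caps for crossing wedges. A new label
starts at every branch point (split children, merge products, post-event
continuations), mirroring the segment-per-branch labeling convention of
manual tracing. Cut boundaries coincide exactly with wedge boundaries, so
per-slice labeled area is conserved up to discretization. Boundary noise is
an AR(1) process along z (marginal SD `jitter_sd_vox`, default 0.5; lag-1
correlation 0.85), emulating tracing error smoothed by contour
interpolation; detached wedges ride their donor's jitter track, and the
acceptor's carve rides the incoming wedge's track with one voxel of slack.
Two simplifications are worth naming: events appear as an instant chord
partition at their slice rather than a gradually widening separation, and
columns regain their full cross-section after donating a wedge (no
permanent size bookkeeping). Neither affects any quantity the pipeline
measures.

What the generator does *not* emulate: grayscale EM appearance, Vernier
displacement of z-disk sheets, mitochondria and the sarcotubular systems,
fiber-type differences in cross-sectional shape, or any clustering of
branch events along a myofibril — events are independent across sarcomere
intervals. Passing tests therefore validate the pipeline's bookkeeping and
geometry handling, not the biological realism of manual segmentations.

## Extraction

`build_graph()` links labels across consecutive slices by footprint
overlap (minimum 4 shared voxels at 50 nm pitch, scaled as
`(50/pitch)^2`; links weaker than 35% of the smaller footprint are
discarded as boundary-noise artifacts). Label transitions are grouped into
connected components and classified by signature:

* one-to-one full overlap — a relabeling, treated as a continuation, never
  an event;
* one-to-many — a fission; the child with the largest overlap continues the
  parent's lineage (major-overlap inheritance), every other child detaches;
* many-to-one — a fusion; the product inherits the largest parent's
  lineage.

A detached piece that fuses into a pre-existing adjacent lineage within
`persist_min_slices` (default `2*taper`) is one **transfer**; a
longer-lived piece anchors a **split** at its fission and a **merge** at
its fusion. Reciprocal transfers between the same pair of lineages within
`trade_window_slices` (default `2*taper`) collapse into one **trade**.
Anything else becomes an event of type `"ambiguous"` and is reported,
never dropped. Transfer directionality (donor vs acceptor) is assigned
from slice order — fission side donates, fusion side accepts — which is a
convention forced by static data, not an observation about the biology.

On noiseless renders at default geometry, extraction recovers the
ground-truth event multiset exactly over 50 seeded volumes; with boundary
jitter up to 1 voxel SD, event recall stays above 0.95 (both are enforced
by the test suite).

## Tracking and metrics

`seed_tracks()` starts one track per sarcomere present in the first image,
numbered in raster order of centroids. `track_myofibril()` walks serial
edges interval by interval; at a split it follows the child whose membrane
distance (2D distance from centroid to the nearest cell-boundary point, in
µm) is closest to the track's starting distance — ties break to the lower
node id — and at a merge it continues with the merged lineage. Each
split/merge/transfer/trade touching the current lineage counts once per
track; a trade's two sides are never double-counted within a track, while
two different tracks may legitimately both encounter the same physical
event (that is how the per-sarcomere rate is defined). `fov_filter()`
keeps only tracks that reach the final interval without touching the
lateral volume boundary.

`volume_summary()` reports events per 10 sarcomeres overall and split by
the two distinguishable classes (splits+merges vs transfers+trades),
percent branched, the volume-level transfer share, and the mean track
length that the closed-form check `100*(1-(1-p)^L)` uses. With at most one
event per column-interval, events-per-10 coincides with
sarcomeres-containing-branches-per-10.

One consequence of two-ended branch counting is worth knowing when reading
percent-branched values: a track's per-sarcomere encounters are half its
own initiations (Bernoulli at rate `p/2`) and half incoming ends from
neighbours (approximately Poisson at rate `p/2`), which is slightly
overdispersed relative to a single Bernoulli(`p`) draw. Percent branched
therefore runs a little below the independence closed form — about one
point at fast-twitch rates and track lengths — while the branch frequency
itself stays exactly calibrated. Both effects sit comfortably inside the
binomial bands the tests check.

## Connectivity

`connected_components()` partitions nodes under serial plus branch edges
(igraph). The design choice that matters here is the bridge reintegration
described above: transfers alone are an order of magnitude too rare to
unify a hundred columns, and it is the split bridges anchoring into
neighbours that make mature muscle a single component — which is precisely
the "unified matrix" observation. At slow-twitch rates and the default
network size (100 columns × 25 sarcomeres; the upper end of the ~10–25
sarcomere fields of view the source imaging allows) essentially every
sampled network is one component, while at late-postnatal rates most are
not. `minimal_lateral_path()` returns the fewest-sarcomere path between
the two farthest-apart first-interval sarcomeres (unweighted breadth-first
search; "minimal path" is formalized as fewest nodes since the original
usage was visual), optionally restricted to serial edges only, and
`width_span_fraction()` projects the path's footprints onto the
endpoint axis relative to the cell-mask extent.

## Group comparison

`group_compare()` is one-way ANOVA with Tukey's HSD (family alpha 0.05 by
default, no other correction), computed by `stats::aov` and
`stats::TukeyHSD`, with muscle volumes as the unit of analysis and
mean ± SE (SD/√n) reported per group. Degenerate inputs — fewer than two
groups, singleton groups, all-zero within-group variance — are explicit
errors rather than silent NaNs. The test suite checks the implementation
against an independently coded textbook-formula oracle to 1e-8 on random
tables.

## Numerical choices and problem sizes

All tolerances that govern classification (`min_overlap`,
`persist_min_slices`, `trade_window_slices`, the 0.35 relative-overlap
floor) are arguments with the defaults above. Determinism: a single seeded
RNG stream per sampled network, a derived stream for rendering jitter, and
deterministic tie-breaks everywhere (raster order for track numbering,
lower label/node id at overlap ties), so identical seeds give byte-identical
outputs through the whole pipeline.

The test and acceptance simulations use the published per-volume problem
sizes where a published number exists (193×18, 167×13, 110×13 tracks ×
sarcomeres for the percent-branched checks), 9-column × 3-sarcomere
volumes for the 50-fold render/extract round trip, 60×13 networks for the
rate-consistency grid, and 100×25 for connectivity — sizes chosen so each
check exercises hundreds of events while the whole suite stays a
desk-scale computation.

## Known limitations

* The independence of events across sarcomere intervals is an assumption;
  if real branching clusters along myofibrils, percent-branched at a given
  frequency would be lower than the closed form predicts (the late
  postnatal value hints at this), and the generator cannot reproduce that.
* Merge/split identity and transfer directionality are conventions on
  static data.
* The renderer's circular cross-sections do not imitate the elongated,
  tortuous shapes of slow-twitch sarcomeres; extraction does not depend on
  cross-sectional shape, only on overlap.
* Tracking through time is out of scope: the data model is a single fixed
  volume.
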