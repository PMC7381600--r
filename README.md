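# myomatrix

Quantitative analysis of sarcomere branching and myofibrillar-matrix
connectivity in labeled 3D muscle volumes.

Striated muscle is classically described as many parallel, tube-like
myofibrils. High-resolution volume electron microscopy instead shows
sarcomeres that branch — by **splitting** (part of a sarcomere's
myofilaments separates into a distinct myofibrillar structure), by
**myofilament transfer** (a portion detaches and joins an adjacent,
parallel sarcomere), or by a bidirectional **trade** — knitting the whole
contractile apparatus into a single connected **myofibrillar matrix**.
`myomatrix` is for researchers who want to quantify that connectivity from
segmented (labeled) muscle volumes, and to test such pipelines on
synthetic volumes with known ground truth.

The package provides, end to end:

* a **generator** of ground-truth branching networks and rendered 16-bit
  label volumes (`muscle_preset()`, `sample_network()`,
  `render_volume()`), with per-muscle-type presets calibrated to published
  branch frequencies;
* **graph extraction** from any labeled volume by consecutive-slice
  footprint overlap, with every branch event classified as split, merge,
  transfer or trade (`build_graph()`, `classify_events()`,
  `annotate_band()`);
* **myofibril tracking** with the membrane-distance continuation rule and
  field-of-view filtering (`seed_tracks()`, `track_myofibril()`,
  `fov_filter()`);
* **per-volume metrics** (`branch_frequency()`, `percent_branched()`,
  `transfer_share()`, `volume_summary()`);
* **connectivity** analysis — connected components and the minimal lateral
  path across the cell (`connected_components()`,
  `minimal_lateral_path()`, `width_span_fraction()`);
* **group comparison** by one-way ANOVA with Tukey's HSD
  (`group_compare()`).

The central quantities are the branch frequency per 10 serial sarcomeres,

    f = 10 * (branch events encountered on tracked myofibrils) / (sarcomeres traversed),

the percentage of myofibrils containing at least one branch (for
independent events at per-sarcomere rate *p* over *L* sarcomeres, the
closed form is `100 * (1 - (1 - p)^L)`), and the transfer share,
`100 * (transfers + trades) / all branches`. Published reference values
used by the presets: *f* = 1.6 (fast-twitch), 4.3 (slow-twitch), 2.2
(cardiac), 2.8 / 1.3 (early / late postnatal), 2.4 (adult human
fast-twitch); transfer shares 34.8% / 15.2% / 13.8% for fast / slow /
cardiac.

## Worked example

```r
library(myomatrix)

cfg <- muscle_preset("slow_twitch", n_columns = 20, n_sarcomeres = 5)
net <- sample_network(cfg, seed = 42)
net
#> <myo_network> 20 columns x 5 sarcomeres (200 slices), seed 42
#>   events: 31 (split 14, merge 14, transfer 2, trade 1); 3.40 per 10 sarcomeres

# render to a label volume, re-extract the graph, and track every myofibril
bundle <- render_volume(net)
graph  <- build_graph(bundle)
tracks <- fov_filter(track_all(graph), graph)$retained
volume_summary(tracks, graph$events, volume_id = "demo", group = "slow_twitch")
#>   volume_id       group n_tracks n_sarcomeres mean_track_len branch_freq_per10
#> 1      demo slow_twitch       20          100              5               3.4
#>   split_freq_per10 transfer_freq_per10 pct_branched transfer_share_pct
#> 1                3                 0.4           85               6.25
#>   n_events_volume n_ambiguous n_suppressed
#> 1              32           2            0
```

The 31 recorded ground-truth events are 17 physical branches: each split
bridge anchors a split at one end and a merge at the other, and tracking
encounters 34 branch ends over 100 sarcomeres — 3.4 branches per 10
sarcomeres, an unbiased estimate of the preset's 4.3 at this small size.
85% of the 20 myofibrils contain at least one branch. At the default
boundary jitter a couple of transitions land in the `ambiguous` bucket
rather than being force-classified; on a noiseless render
(`render_volume(net, jitter_sd_vox = 0)`) the extracted events match the
generator's ground truth exactly.

Group comparison across muscle types works on per-volume metric tables:

```r
vals <- c(4.0, 4.4, 4.6, 1.5, 1.7, 1.8, 1.6, 2.1, 2.2, 2.4, 2.0, 2.3)
grp  <- rep(c("slow", "fast", "cardiac"), c(3, 4, 5))
group_compare(vals, grp)
#> <myo_group_comparison> one-way ANOVA + Tukey HSD
#>   F(2, 9) = 179, p = 5.661e-08 (alpha = 0.05)
#>   cardiac          n = 5, mean = 2.200 +/- 0.071 (SE)
#>   fast             n = 4, mean = 1.650 +/- 0.065 (SE)
#>   slow             n = 3, mean = 4.333 +/- 0.176 (SE)
#>   significant pairs: fast-cardiac, slow-cardiac, slow-fast
```

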