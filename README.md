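# polarTrack

Single-cell image analysis of **polar accumulation of periplasmic
fluorophores** in time-lapse microscopy of growing bacterial microcolonies.

Fluorescent *Pseudomonas* siderophores such as pyoverdin are normally
distributed homogeneously through the periplasm of actively dividing cells.
When division stops — at entry into stationary phase, or under iron or
translational stress — the fluorophore condenses into a focus at a cell
pole, preferentially the *new* pole (the end created at the last division).
The process reverses before growth resumes, and cells that accumulated the
siderophore restart division sooner after stress. `polarTrack` provides the
quantitative machinery to measure all of this from multi-channel image
stacks, together with a fully ground-truthed synthetic time-lapse generator
so that every stage of the pipeline is testable without any external
dataset.

## The core statistic

Each segmented cell is divided into three portions along its long
(principal) axis: the outer thirds are the poles, the middle third the
centre. For pole *p* with pixel intensity sum *S(p)* and centre sum *S(c)*,
the **pole/centre ratio**

    r_p = S(p) / S(c)

is ≈ 1 for a homogeneously fluorescent cell and rises steeply when a polar
focus forms. Cells are labelled *polarized* or *homogeneous* by a logistic
discriminant on three features: the maximum of the two pole ratios, the
long-axis profile peak-to-median ratio, and the fraction of total cell
intensity in the brightest pole third. On top of this sit per-cell
long-axis fluorescence profiles, lineage tracking with generation labels
(F0 = inoculum whose birth was not observed, F1 = cells born and divided
during the movie, F2 = final generation), new/old pole identity from
division geometry, per-track elongation rates (slope of log length against
time), and growth-resumption kinetics: lag time (time to first division)
and depolarization time (first sustained homogeneous classification).

## A worked example

Simulate an 18 h microcolony movie (30 min frame interval), measure it with
the full pipeline, and look at the polarization dynamics:

```r
library(polarTrack)

cfg <- simulationConfig(seed = 7, n_frames = 36L, n_initial = 6L,
                        carrying_capacity = 40L)
sim   <- simulateStack(cfg)          # ground truth + rendered frames + labels
cells <- measureStack(sim$labels, sim$stack)
pol   <- quantifyPolarization(sim$labels, sim$stack, cells)
freq  <- polarizedFrequency(pol, frameInterval(sim$stack))
tail(freq, 3)
#>    frame time_h  n n_polarized fraction
#> 34    33   16.5 40          40        1
#> 35    34   17.0 40          40        1
#> 36    35   17.5 40          40        1
```

By the end of this movie every one of the colony's 40 cells is classified
polarized, matching the ground truth exactly (40/40 truly polarized at
that frame). Tracking recovers lineage, generations, and growth:

```r
trk <- trackCells(sim$labels, cells, frame_interval = 0.5)
lin <- assignGenerations(trk$lineage, trk$tracks, nFrames(sim$stack))
table(lin$generation)
#>         F0         F1         F2 unassigned
#>          6         12          8         48

er <- elongationRates(trk$tracks, 0.5)
median(er$rate_per_h[er$track_id %in%
                       lin$track_id[lin$generation == "F1"]], na.rm = TRUE)
#> [1] 0.2788725     # true simulated rate: 0.28 / h
```

The same functions run on real data: read TIFF stacks with
`readFrameStack()`, segment with `segmentStack()` (or supply your own label
images with `readLabelStack()`), then proceed exactly as above.
`runPipeline()` executes everything in order and writes CSV tables, a
provenance record and a plain-text report;
`inst/scripts/polartrack.R` exposes the stages as shell subcommands.

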