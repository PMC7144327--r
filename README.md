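# TriSynapse

Analysis of three-colour 3D dSTORM localisation data of **tripartite
synapses**: presynaptic bassoon and postsynaptic Homer1 scaffold clusters,
and the perisynaptic astrocytic glutamate transporter GLT-1.

Single-molecule localisation microscopy delivers, per colour channel, a
table of localisations (x, y, z in nm, frame, photons, precision). From
such tables TriSynapse

- finds scaffold **clusters** with DBSCAN (3D Euclidean metric, radius
  `eps = 100` nm, minimum `min_pts = 50` localisations per cluster) and
  summarises each cluster's localisation count, centroid, 3D convex-hull
  volume and density;
- identifies **synapses** as opposed bassoon–Homer1 cluster pairs whose
  centroids lie within 500 nm, pairing greedily by ascending centroid
  distance, one-to-one; the synapse centre is the centroid midpoint;
- computes **distance statistics**: per-localisation bassoon→Homer1
  nearest-neighbour distances (500 nm cutoff, 10 nm histogram bins, with
  the modal bin centre as the headline statistic) and distances of GLT-1
  localisations within 500 nm of a synapse centre to that centre and to
  the nearest member of the pre-/postsynaptic clusters;
- supports the surrounding workflow: a CSV dialect for localisation
  tables, affine **channel registration** from multi-colour fiducial
  beads, a minimal **biplane localiser** (Gaussian spot fitting, bead-stack
  PSF calibration, width-ratio z inversion), density-weighted **rendering**
  and constant-diameter (30 nm) point-cloud export;
- ships a **synthetic-data generator** that emulates the whole experiment
  (apposed label discs 120 nm apart, perisynaptic GLT-1 shells, antibody
  displacement, stochastic blinking, anisotropic localisation noise,
  chromatic offsets, spurious localisations) with full ground truth, so
  every stage is testable against known truth.

See the methods vignette (`vignettes/trisynapse-methods.Rmd`) for the
models, parameter defaults and their rationale, and known limitations —
including why the modal nearest-neighbour distance is a biased estimator
of the underlying scaffold separation.

## Worked example

```r
library(TriSynapse)

summary <- runPipeline(
  pipelineConfig(seed = 1, render = list(enabled = FALSE)),
  out_dir = "run1")
```

The run logs each stage:

```
[simulate] generating scene (n_synapses = 50, seed = 1)
[simulate] 31480 localisations in 3 channels
[register] channels aligned to GLT1 (max RMS residual 1.50 nm)
[cluster] bassoon: 52 clusters; Homer1: 51 clusters (eps=100, min_pts=50)
[pair] 50 synapses identified
[summary] run complete: 50 synapses, NN mode 95 nm
```

and writes `localizations.csv`, `truth.csv`, `transforms.json`,
`clusters.csv`, `synapses.csv`, `distances.csv` and `summary.json` into
`run1/`. Reading the summary:

- `n_synapses = 50` — all 50 simulated synapses were recovered as opposed
  cluster pairs (`n_true_synapses = 50`).
- `histogram_modes_nm$pre_post_nn = 95` — the modal bassoon→Homer1
  nearest-neighbour distance. It falls below the generative 120 nm disc
  separation because a nearest-neighbour minimum over noisy candidates
  selects the lower tail of the gap distribution (see the vignette).
- `median_distances_nm$glt1_to_post = 93.8 < glt1_to_pre = 105.0` — GLT-1
  localisations sit closer to the postsynaptic than the presynaptic
  scaffold, reflecting the post-shifted perisynaptic shell.

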