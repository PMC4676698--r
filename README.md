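# smlmtools

Quantitative analysis of molecular position tables from single-molecule
localization microscopy (PALM / STORM / ground-state depletion), for cell
biologists asking two questions of their super-resolution data: *do these
two (or three) labeled species interact?* and *what higher-order structures
do they form?*

SMLM data defeats conventional colocalization analysis twice over: with
~20 nm precision, genuinely interacting proteins are resolved into
*separate*, non-overlapping localizations, and the stochastic blinking that
produces the data guarantees simultaneous oversampling (repeat detections
of one fluorophore) and undersampling (fluorophores never detected).
`smlmtools` answers both questions with spatial statistics designed for
point data and validated against these artefacts.

## What it computes

**Interaction — spatial association analysis (SAA).** Two molecules are
*potentially interacting* when their separation is below the colocalization
distance criterion,

    CDC = m · σ_RMS + I_reg,      σ_RMS = sqrt(Σ_i σ_ci²),

with σ_ci the mean localization precision of channel *i*, m = 1.65 (90%) or
2 (95%), and I_reg the chromatic registration error. `saa_two_colour()`
measures each molecule's nearest-neighbour distance into the other channel,
the fraction below the CDC, and the same fraction after uniformly
randomizing the target channel over the region (simulated random positions,
SRP) — the measured/SRP ratio separates real association from chance
juxtaposition, and is invariant to undersampling. The analysis is
directional (A→B ≠ B→A) and `saa_three_colour()` classifies each reference
molecule against two partner channels at once.

**Clustering — cross-RDF and cross-Ripley.** `cross_rdf()` computes the
pair-correlation function G(r) (annulus density relative to mean density;
1 under randomness, oversampling-robust); `cross_ripley()` computes
K(r), L = √(K/π) and H(r) = L − r, whose single positive peak marks
clustering. Mean cluster radius comes from either calibrated estimator:
`cluster_radius_lagache()` (r_max/1.3) or `cluster_radius_kiskowski()`
(half the radius where H′ crosses −1).

**Segmentation.** `dbscan_locs()` (core/edge/noise labeling with a
parameter sweep helper), `optics_order()` (canonical OPTICS reachability
profiles), `extract_clusters_static_rd()` (valleys under a fixed RD
threshold), `hier_segment_rd()` (recursive reachability-plot segmentation
that handles heterogeneous densities and nested vesicle-in-body
structures), `h_segment()` (static-radius H maps), and
`cluster_hull_density()` (convex-hull content quantification across
channels).

**Synthetic data.** Seeded, bit-reproducible generators emulate the
validation experiments: fluorophore pair fields at exact separations
(`make_pair_field()`), clustered scenes (`make_clustered_scene()`),
the two sampling artefacts in isolation (`apply_undersampling()`,
`apply_oversampling()`), frame-wise acquisition simulation
(`simulate_acquisition()`) and reconstruction autocorrelation with its
0.990 stop point (`reconstruct_autocorrelation()`).

I/O covers the tab-delimited position files of common instruments via
configurable column-map dialects (`read_locs()`, `write_locs()`,
`convert_folder()`), ROI cropping/refinement, density filtering and 16-bit
TIFF rasterization. Results are tibbles (with `tidy()`/`glance()`/
`autoplot()` methods), so everything composes with dplyr and ggplot2.
`run_queue()` and the `exec/smt` script batch-process per-ROI analysis
queues.

## Worked example

Recover a known 10.2 nm pair separation from a synthetic two-channel field
of 5000 annealed pairs under 20 nm-precision localization jitter:

```r
library(smlmtools)

pf <- make_pair_field(5000, separation = 10.2, seed = 1)
a  <- jitter_locs(pf$channels$A, precision = 20, seed = 2)
b  <- jitter_locs(pf$channels$B, precision = 20, seed = 3)
saa_two_colour(a, b, sigma_c = c(10, 10), n_randomizations = 20, seed = 4)
#> Two-colour spatial association analysis
#>   CDC: 23.33 nm (cutoff 1.65, I_reg 0.00)
#>   A -> B: 0.983 below CDC (SRP 0.112), mode 11.0 nm, n = 5000
#>   B -> A: 0.982 below CDC (SRP 0.110), mode 11.0 nm, n = 5000
```

98% of molecules sit below the 23.3 nm CDC against 11% in the randomized
control — a ~9-fold enrichment, i.e. genuine association — and the
histogram mode (11 nm, 2 nm bins) recovers the true 10.2 nm separation
within one bin, half the microscope precision.

Cluster-radius recovery from a field of fifty 50 nm clusters:

```r
sc <- make_clustered_scene(preset = "rdf", seed = 6)
h  <- cross_ripley(sc$channels$A, sc$channels$A,
                   roi_rect(0, 5000, 0, 5000), exclude_self = TRUE)
cluster_radius_lagache(h)
#> [1] 53.84615
```

The H peak sits at r_max = 70 nm; r_max/1.3 ≈ 54 nm estimates the true
50 nm generator radius within 8%.

See `vignettes/smlm-interaction-analysis.Rmd` for the models, parameter
choices, numerical conventions and known limitations.

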