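# payloadSPT

Single-particle tracking (SPT) analysis of fluorescent payload delivery
into live cells, for researchers quantifying whether a targeted
nanocarrier actually releases its cargo in the cytosol rather than
leaving it stuck at the plasma membrane or inside endosomes.

The package implements the full analysis chain for two-channel HILO
time-lapse recordings — and a synthetic microscopy simulator that
generates ground-truth recordings so every stage is quantitatively
testable without any external data:

1. **Simulation** — trajectories from four motion models (Brownian;
   directed, i.e. drift + diffusion; confined in a reflecting disk;
   subdiffusive fractional Brownian motion with α = 2H via exact
   Davies–Harte generation), rendered with a pixel-integrated Gaussian
   PSF, Poisson shot noise and Gaussian read noise on a 428 × 684-px,
   0.117 µm/px, 200 ms/frame, 16-bit field of view. Cleaved payloads
   are single emitters; intact payloads are sub-diffraction four-emitter
   clusters.
2. **Detection** — difference-of-Gaussians band-pass, subpixel
   intensity-weighted centroids, and per-spot shape descriptors: radius
   of gyration Rg = √tr M and eccentricity √(1 − λ_min/λ_max) from the
   second-moment matrix M (Rg = σ√2 for an isotropic Gaussian of width
   σ).
3. **Linking** — minimum-total-distance bipartite assignment per frame
   pair (Jonker–Volgenant-style solver) with gap closing.
4. **Motion analysis** — per-track time-averaged MSD, log–log OLS fit
   of MSD(τ) = 4D τ^α for the anomalous exponent α, and rule-based
   segmentation into normal / directed / confined / subdiffusive
   windows.
5. **Delivery-path classification** — membrane occupancy by distance
   transform, then explicit rules: *fast* (membrane → cytosol, α > 0.8),
   *slow* (α < 0.3), *attached* (membrane residence > 10 frames,
   α < 0.3, never leaves), *temporarily fixed* (residence > 10 frames,
   then moves), *unclassified* otherwise.
6. **Population statistics** — two-sided two-sample Kolmogorov–Smirnov
   and Welch t tests with star significance bands, and native
   Pearson / Manders (M1/M2) colocalization on segmented channels.

See `vignettes/payload-tracking-methods.Rmd` for the models,
parameters, calibration and limitations.

## Worked example

Simulate a ground-truth delivery scenario, run the full pipeline, and
look at the recovered path classes:

```r
library(payloadSPT)

cfg <- pipelineConfig(seed = 11L)       # 16 payloads, 4 per path class
res <- runPipeline(cfg, "run_out")
#> simulate: 16 particles, 50 frames
#> detect: 800 spots in 50 frames
#> link: 16 tracks, 16 kept at min length 20
#> motion: 16 tracks fitted
#> paths: attached=4, fast=4, slow=4, temporarily_fixed=4

table(res$paths$path_class)
#>          attached              fast              slow temporarily_fixed
#>                 4                 4                 4                 4

head(res$paths, 3)
#>   track_id        path_class alpha_post membrane_residence alpha_on_subtrack
#> 1        1 temporarily_fixed     1.9693                 17              TRUE
#> 2        2          attached     0.0524                 50             FALSE
#> 3        3 temporarily_fixed     1.9329                 17              TRUE
```

Every simulated payload is recovered with its scripted delivery path:
the four membrane-attached payloads show long membrane residence and a
near-zero anomalous exponent, the four fast ones show brief membrane
contact followed by directed cytosolic transport (α ≈ 2), and the
output files in `run_out/` (spots, tracks, per-track α table, path
classes, run log) are stamped with the configuration hash and seed —
rerunning with the same configuration reproduces them byte for byte.

Comparing cleaved (single-dye) against intact (four-dye) payload
populations by spot size:

```r
singles  <- simulateSpotPopulation(500, 1, seed = 31L)
clusters <- simulateSpotPopulation(500, 4, seed = 32L)
cmp <- compareSizeEccentricity(singles, clusters)
cmp$rgTest$pValue        # ~0: the size distributions are clearly distinct
cmp$medianShift[["rg"]]  # ~0.47 px: clusters are larger
```

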