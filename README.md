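# nmjquant

Object-based quantification of marker fluorescence at neuromuscular
junctions (NMJs) from multichannel microscopy, for researchers studying
synapse-adjacent innervation (e.g. sympathetic axons marked by tyrosine
hydroxylase) or presynaptic apposition (vesicular acetylcholine
transporter) relative to α-bungarotoxin (BGT)-labelled postsynapses.

The package implements two complementary readouts plus a ground-truthed
synthetic data generator:

1. **Accumulation analysis** (planar sections). The BGT channel is median
   filtered (3×3) and thresholded on 30–255 to outline NMJ regions of
   interest. For each ROI, a paired muscle-fiber reference ring is built by
   square dilation, and the marker channel is scored per NMJ:

   positive ⇔ mean<sub>NMJ</sub> > mean<sub>fiber</sub> + SD<sub>fiber</sub>

   (strict inequality; invariant under positive affine intensity
   transforms). Summaries report percent immunopositive NMJs, and a
   time-course runner reports mean ± SEM over replicate fields per age.

2. **3D proximity analysis** (volumes). Channels are binarized at
   inclusive intensity bounds (BGT 20–255, TH 6–255, NFL 22–255, VAChT
   20–255), labelled as 26-connected components, size-filtered
   (postsynapses 50–2×10⁷ voxels, markers 3–2×10⁹), and BGT objects at
   image edges are excluded. For every retained postsynapse the
   **edge-to-edge distance** to the nearest marker object is the minimum
   anisotropic Euclidean distance between border-voxel centres
   (0 for overlapping objects), in micrometres. The headline statistic is
   the fraction of NMJs at a distance strictly below 2 µm, with a binned
   distribution and empirical CDF.

3. **Synthetic generator**. Plaque-like postsynapses in a synapse band,
   apposed presynaptic boutons with analytically known surface gaps,
   filamentous axons, diffuse receptor signal, PSF blur and
   Poisson + Gaussian noise, on anisotropic voxel grids
   (default 1 × 0.785 × 0.785 µm). Continuous-coordinate ground truth makes
   recovery tolerances explicit.

See `vignettes/nmjquant-methods.Rmd` for the full model description,
parameter defaults and numerical conventions.

## Worked example

```r
library(nmjquant)

p   <- synthetic_params(image_shape = c(10L, 256L, 256L), n_nmjs = 8L, seed = 3L)
cfg <- pipeline_config("proximity", synthetic = p, seed = 3L)
res <- run_proximity_study(cfg)
res
#> proximity_result (VAChT): 8 NMJ objects, 100.0% at < 2 um
res$stage_counts
#> $postsynapse
#>    labeled after_size after_edge
#>         96          8          8
#> $marker
#>    labeled after_size
#>        103          8
head(res$records, 3)
#>   nmj_id nearest_marker_id distance_um
#> 1      1                 1           0
#> 2      2                 2           0
#> 3      3                 3           0
```

All 8 simulated postsynapses survive size filtering and edge exclusion
(the 88 removed "objects" are noise specks below the 50-voxel minimum),
and every NMJ is recovered at distance 0 to its apposed bouton — the
blurred, thresholded surfaces of structures placed 0–0.5 µm apart overlap
after segmentation, hence below the 2 µm cutoff.

A developmental time-course with the bundled per-age positivity defaults:

```r
tc <- run_timecourse_study(pipeline_config("timecourse", marker = "TH",
        ages = c("P0", "P21", "adult"), n_replicates = 3L,
        synthetic = synthetic_params(image_shape = c(1L, 384L, 384L),
                                     n_nmjs = 10L),
        seed = 7L))
tc$summary
#>     age mean_percent sem_percent truth_fraction n_replicates
#> 1    P0           40           0            0.4            3
#> 2   P21           70           0            0.7            3
#> 3 adult           90           0            0.9            3
```

The recovered percent-immunopositive values equal the generator's truth
fractions: at these contrast and noise settings the accumulation
classifier makes no errors.

A thin command-line front end over the same functions is installed as
`exec/nmjquant` (subcommands `simulate`, `accumulate`, `segment`,
`proximity`, `timecourse`).

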