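# rpcavg

Quantifying how en-face OCTA frame registration and averaging changes the
visualization of the radial peripapillary capillary (RPC) network.

## The problem

The RPCs are a planar network of long, nearly parallel capillaries with few
anastomoses inside the retinal nerve fiber layer around the optic disc.
Single en-face OCT angiography (OCTA) frames of this network are noisy:
speckle-like decorrelation noise, motion-artifact lines and discontinuous
vessel segments make quantification unreliable. Registering several scans of
the same eye and averaging them suppresses that noise — but each extra scan
costs patient time, so the practical question is *how many frames are enough
for each quantitative measure*.

`rpcavg` implements the full measurement chain for that question:

1. **Synthetic scenes** — ground-truth capillary fields (spacing, diameter,
   tortuosity, anastomoses) rendered into multi-frame noisy stacks with
   known rigid misalignment, so every stage is testable without image
   downloads.
2. **Rigid registration** — reference-frame selection, windowed
   cross-correlation with an angular search (translation + rotation only),
   and transform transfer between stacks of the same eye.
3. **ROI geometry** — least-squares optic-disc ellipse fit from margin
   points and placement of five ~2x2 degree ROIs (superior, superotemporal,
   temporal, inferotemporal, inferior) centred one degree outside the disc
   margin.
4. **Quantification** per ROI and per number of averaged frames n = 1..10:
   - mask-based signal-to-noise ratio
     `SNR = (mu_signal - mu_background) / sqrt(sigma_signal^2 + sigma_background^2)`,
     where signal is the region inside a 15 um dilation of the vessel
     skeleton (mask fixed from the 10-frame average),
   - number of skeleton **endpoints**,
   - **mean segment length** (total skeleton length / number of segments),
   - **capillary length density** (skeleton length / ROI area, mm^-1),
   - **intercapillary distance** (mean peak-to-peak spacing of an averaged
     intensity profile from a 0.1 x 1 degree box perpendicular to the
     vessels).
5. **Statistics** — one-way repeated-measures ANOVA across frame counts
   with the Greenhouse-Geisser sphericity correction, Bonferroni-adjusted
   sequential post hoc t-tests (1v2, 2v3, ..., 9v10), and the
   *optimal frame count* rule: the smallest n such that no sequential
   comparison from (n vs n+1) onward is significant. Percent differences
   (reference vs 5- and 10-frame averages), the length-density to
   area-coverage conversion (`100 * density * diameter/1000`), and a
   normative box-plot comparison of patient densities against healthy
   controls complete the stage.

## Worked example

Simulate a 10-frame noisy stack of one ROI-sized capillary field (38 um
spacing, 9 um diameter, speckle SD 0.3) and quantify it at several frame
counts:

```r
library(rpcavg)
sc <- scale_model()                       # 30.4 px/deg, ~9.57 um/px
scene <- synthetic_scene(image_size_px = c(60, 60), shift_range_px = 0,
                         rot_range_deg = 0, motion_line_prob = 0, seed = 21)
sim <- simulate_stack(scene, sc, 10)
stack <- sim$stack; stack$registered <- TRUE   # frames are pre-aligned here
roi <- structure(list(label = "T", box = c(r0 = 1, r1 = 60, c0 = 1, c1 = 60),
                      vessel_orientation_deg = 0, excluded = FALSE),
                 class = "roi_spec")
quantify_roi(stack, roi, sc, n_values = c(1, 2, 5, 10))
```

```
 n_frames  snr n_endpoints mean_segment_length_um density_mm_inv icd_um
        1 1.68          89                   79.6           27.3   38.3
        2 1.82          58                  157.2           26.7   38.3
        5 1.97          55                  233.3           26.2   38.3
       10 2.00          59                  225.5           26.0   38.3
```

Averaging raises SNR monotonically, collapses the spurious skeleton
endpoints of the single frame (89 -> ~55) and lengthens the mean skeleton
segment, while density stays near the ground truth (26.9 mm^-1 for this
scene) and the intercapillary distance is essentially invariant in n —
exactly the qualitative behaviour the averaging technique is meant to
deliver. The `analysis/` directory stages the same computation as a
file-based workflow (`01_simulate.R` .. `04_stats.R`) writing its tables
and figures under `results/`.

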