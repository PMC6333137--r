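# tiltmar — tilted-scan CT metal artifact reduction

Metal implants corrupt CT images with streaks, dark bands and
photon-starvation noise, which complicates target delineation and dose
calculation in radiotherapy planning. The most severe artifacts run along
ray directions that traverse *multiple* metallic objects — so a second scan
acquired at a different gantry tilt sees them differently, and regions
corrupted in one scan are often clean in the other.

`tiltmar` implements this two-scan fusion strategy for R, together with the
polychromatic fan-beam CT simulator needed to generate, reconstruct and
quantitatively evaluate metal-artifact-corrupted images:

* **T-MAR** — per-pixel fusion of an ordinary and a tilted reconstruction.
  The difference image `I_art = I_ori − I_tilt` cancels anatomy and keeps
  the superposition of both scans' artifacts. Each scan is correlated with
  that map by a *modified structural similarity index* restricted to the
  contrast and structure factors,

  `SSIM′(x, y) = c(x, y) · s(x, y)`,
  `c = (2σₓσᵧ + c₂)/(σₓ² + σᵧ² + c₂)`, `s = (σₓᵧ + c₃)/(σₓσᵧ + c₃)`,

  on 5×5 patches, giving `C_ori = SSIM′(I_ori, I_art)` and
  `C_tilt = SSIM′(I_tilt, −I_art)`. The fused image takes, per pixel, the
  scan with the **lower** correlation (ties go to the tilted scan). The
  luminance factor is excluded on purpose: artifact maps and CT images
  differ grossly in local intensity while sharing structure, and the
  luminance term flips sign on dark bands, steering the selection toward
  the corrupted scan.
* **AT-MAR** — when the tilt cannot supply enough complementary information
  (both scans corrupted in the same region), a second fusion pass runs the
  same workflow on the T-MAR intermediate and a sinogram-inpainting MAR
  image (NMAR by default; any externally produced MAR image can be plugged
  in).
* **Simulator** — parametric pelvis (bilateral CoCr hip rods) and head
  (Cerrobend dental inserts) voxel phantoms, oblique slicing, equiangular
  fan-beam projection, a six-bin 120 kVp polychromatic beam with bundled
  attenuation tables (beam hardening and photon starvation emerge from the
  physics), Poisson and Gaussian noise, and Hann-apodized fan-beam filtered
  backprojection.
* **Baselines and evaluation** — LI-MAR and NMAR sinogram inpainting,
  metal segmentation and trace computation, ROI-based mean absolute
  percentage error (MAPE) and multi-method comparison reports.

## Worked example

```r
library(tiltmar)

ph   <- make_pelvis_phantom(pelvis_config(n_xy = 256, spacing = 0.2))
geom <- fan_geometry(400, 1100, 720, 365, 170)  # SID/SDD in mm
grid <- recon_grid(256, 0.2)

study <- run_study(ph, tilts = c(0, 10), geom = geom, grid = grid, seed = 7)
study$report
#>     method  mape_pct
#> 1     tmar  3.750057
#> 2   tilted  3.781278
#> 3     nmar  5.030142
#> 4    limar  6.820671
#> 5 original 21.304136
```

The report lists the soft-tissue-ROI MAPE (%) of each image against the
artifact-free reference for one noise realization: the uncorrected
ordinary scan is dominated by the dark band and streaks between the two
implants (~21%), the tilted scan avoids the two-implant overlap (~3.8%),
sinogram inpainting on the ordinary scan's virtual sinogram recovers part
of the damage (NMAR ~5.0%, LI-MAR ~6.8%), and the fused T-MAR image is the
most accurate (~3.75%). `pelvis_replication()` and `head_replication()`
repeat this over several noise realizations and report medians; the head
study is configured with an insufficient tilt, where plain T-MAR stalls
near the inputs (~15%) and the augmented AT-MAR pass recovers (~6%).

A thin command-line front end mirrors the workflow
(`inst/exec/tiltmar run --config cfg.yaml`, plus `simulate`, `mar`,
`baseline` and `evaluate` subcommands).

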