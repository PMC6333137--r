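---
title: "Tilted-scan metal artifact reduction: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tilted-scan metal artifact reduction: model, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the idea

Highly attenuating implants corrupt CT reconstructions through photon
starvation, beam hardening and noise; the worst artifacts — dark bands and
streaks — run along ray directions that traverse more than one metallic
object. Changing the scan plane (a gantry tilt, or rotating the object)
changes which rays are blocked, so a second scan at a different tilt carries
complementary information: regions corrupted in one reconstruction are
often clean in the other. `tiltmar` fuses such a co-registered pair into a
nearly artifact-free image, and ships the full simulation and evaluation
stack used to quantify that claim.

## The fusion model

Let $I_{ori}$ and $I_{tilt}$ be the two co-registered reconstructions.
Because the anatomy is (by assumption) identical, their difference

$$I_{art} = I_{ori} - I_{tilt}$$

contains no anatomy — only the superposition of both scans' artifacts
(`artifact_split()`). Each scan is then scored, pixel by pixel over a 5×5
sliding window, by how strongly it correlates with this artifact map,
using a modified structural similarity index that keeps only the contrast
and structure factors:

$$\mathrm{SSIM}'(x, y) = \underbrace{\frac{2\sigma_x\sigma_y + c_2}
{\sigma_x^2 + \sigma_y^2 + c_2}}_{\text{contrast}} \cdot
\underbrace{\frac{\sigma_{xy} + c_3}{\sigma_x \sigma_y + c_3}}_{\text{structure}},$$

$$C_{ori} = \mathrm{SSIM}'(I_{ori}, I_{art}), \qquad
  C_{tilt} = \mathrm{SSIM}'(I_{tilt}, -I_{art}).$$

The sign flip keeps the tilted scan's own artifacts positively correlated
(the map is ordinary-minus-tilted). A high correlation marks the scan that
*contributes* the local artifact content, so the fused image takes the scan
with the lower value:

$$I_G(p) = \begin{cases} I_{ori}(p) & C_{ori}(p) < C_{tilt}(p) \\
I_{tilt}(p) & \text{otherwise.} \end{cases}$$

Ties go to the tilted scan, exactly as written. Every fused pixel equals
one of the two inputs — the method can suppress artifacts but cannot
invent false structure.

**Why the luminance factor is excluded.** The standard SSIM multiplies in
a luminance factor $l = (2\mu_x\mu_y + c_1)/(\mu_x^2 + \mu_y^2 + c_1)$.
An artifact map has near-zero mean while a CT image is strictly positive,
so $l$ compresses both correlation maps; worse, on *dark* artifact bands
the local map mean is negative, $l$ flips sign, and the full SSIM ranks
the corrupted scan as the less correlated one. The test suite demonstrates
this concretely: on a deterministic streak fixture the modified index
fuses to ~1% MAPE while the full SSIM fuses to ~7%, worse than the better
input.

**AT-MAR.** When the achievable tilt is too small (or the implants too
extensive) both scans are corrupted in the same region and no selection
can help. `atmar_pipeline()` then runs the same workflow a second time on
the stage-1 result and a sinogram-inpainting MAR image — NMAR of the
ordinary scan's virtual sinogram by default; the `augment` argument
accepts any externally produced MAR image, so other inpainting software
can be slotted in.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `patch` | 5 px | SSIM sliding window (uniform weights, reflective borders) |
| `c2`, `c3` | $(0.03R)^2$, $c_2/2$ | SSIM stabilizers; $R$ is the inputs' robust dynamic range |
| `sigma` | 0.5 px | Gaussian pre-denoising of the inputs to the correlation maps |
| `alpha,beta,gamma` | 1 | factor exponents (kept at 1) |
| `metal_threshold` | 1.2 cm⁻¹ / 3000 HU | implant segmentation threshold |

Three of these deserve their rationale:

* **Robust dynamic range.** The SSIM stabilizers follow the standard
  constants, but $R$ is measured as the 0.5–99.5 % quantile span of the two
  images rather than the raw min–max: implant pixels are one to two orders
  of magnitude above tissue, and a min–max range inflates $c_2, c_3$ until
  both correlation maps saturate at 1 and the selection degenerates to
  chance.
* **Light denoising.** Contrast and structure are variance- and
  covariance-based, so noise feeds straight into the maps; a Gaussian
  pre-filter stabilizes them. It is kept deliberately light (σ = 0.5 px)
  because each scan's *own* noise is positively correlated with the
  artifact map — this asymmetry steers the selection toward the less noisy
  scan precisely in regions with no structured artifact, and heavy
  smoothing erases the cue. Measured on the pelvis study, σ = 1 px leaves
  ~30 % of artifact-free pixels picked from the noisier ordinary scan at a
  net cost, σ = 0.5 px drops that to ~6 % at a net gain.
* **Denoised selection, raw output.** The correlation maps are computed on
  denoised images, but the fused image samples the *raw* reconstructions,
  so the deliverable is never blurred. `fuse_denoised = TRUE` switches
  this off; the pipeline stores both denoised inputs for inspection.

Metal pixels themselves are outside the selection logic: the rule is about
artifact regions, not implants, so segmented metal is copied from the
ordinary scan (`exclude_metal`).

Inputs must be co-registered; no registration is performed. A light guard
(correlation of the two bone masks) warns on obvious misuse.

## The simulator

The simulator exists to generate controlled metal-artifact-corrupted
image pairs with a known ground truth.

* **Phantoms.** Parametric voxel phantoms rather than licensed anthropomorphic
  data: a pelvis (soft-tissue ellipse, sacrum/iliac/pubic bones, water
  bladder, bowel-gas pockets, pelvic fat lobules, two lateral implant rods
  of radius 0.85 cm) and a head (tissue ellipse, gypsum skull shell and
  jaw, two 0.6 cm Cerrobend rods in the gingiva region). Generation is
  deterministic; every geometric parameter lives in
  `pelvis_config()`/`head_config()`.
* **Tilt as an oblique cut.** A tilted scan is modelled by cutting the
  voxel grid along a plane tilted about an in-plane axis
  (`oblique_slice()`), with nearest-neighbour label sampling (labels are
  categorical; interpolation would invent materials). The rotation axis
  must be perpendicular to the implant separation to discriminate the
  implants: rotating about the left–right axis changes the plane height
  along the anterior–posterior coordinate, which bilateral implants share,
  so the plane meets both at the same height and nothing separates — hence
  the anterior–posterior axis (`axis = "ap"`) is the default for both
  phantoms. Two sampling modes exist: the metrically exact rotated plane
  (cross-sections foreshorten by $1/\cos\theta$), and a `registered` shear
  mode whose slice of any z-extruded structure is pixel-identical to the
  axial slice. The study workflow uses the registered mode, which realises
  the method's co-registration assumption exactly and isolates artifact
  differences from resampling differences.
* **Rod z-spans select the tilt regime.** Each rod occupies a configurable
  z-interval. The pelvis defaults stagger them so the 10° cut keeps one
  rod and drops the other: the ordinary slice suffers the two-implant
  overlap artifacts, the tilted slice only single-implant artifacts. The
  head replication instead uses long symmetric spans, so both rods stay in
  the 15° slice — the deliberately insufficient-tilt regime that motivates
  AT-MAR.
* **Physics.** An equiangular fan-beam projector (ray-driven, bilinear
  sampling at half a pixel per step, Rcpp) produces per-material path
  lengths; polychromatic counts are
  $i_0 \sum_b w_b e^{-\sum_m \mu_m(E_b) L_m}$ over six bins at
  20–120 keV of a filtered tungsten spectral shape (bundled table; the bin
  weights integrate the shape over ±10 keV). Beam hardening and photon
  starvation are emergent, not injected. Poisson noise is applied to the
  counts ($i_0 = 10^7$), zero counts are clamped to one photon before the
  log transform, and zero-mean Gaussian noise of variance 0.001 is added
  in the log domain. Poisson and Gaussian draws use independent seeds
  derived from one master seed so either source can be toggled without
  disturbing the other.
* **Attenuation tables.** Mass-attenuation tables are bundled as CSV
  (NIST-style values rounded to ~3 significant figures for water, air,
  soft tissue, adipose, bone, titanium, iron/steel; gypsum, Cerrobend and
  CoCrMo as mass-weighted mixtures), interpolated log–log. The pelvis
  default implant is CoCrMo: a titanium rod pair does not fully starve the
  beam at these sizes and produces only mild artifacts, while CoCr
  reproduces the severe bilateral-hip regime the method targets.
* **Reconstruction.** Kak–Slaney equiangular fan-beam FBP: cosine
  weighting, band-limited ramp with the $(\gamma/\sin\gamma)^2$
  correction, Hann apodization (pure ramp by option), inverse-square
  distance weighting; pixels outside the scan FOV see partial coverage and
  are zeroed.

## Evaluation design

The artifact-free reference replays the identical noise-free polychromatic
acquisition with metal voxels replaced by soft tissue — "the same scan
without the implants". A monochromatic effective-energy reference is
available (`mode = "monochromatic"`) but not the default: its cupping-free
values differ from every polychromatic reconstruction by a systematic
~30 % margin that would swamp the artifact signal being measured.

MAPE is evaluated on soft-tissue ROIs excluding implants: the default mask
is the soft-tissue (including fat) label set eroded by 2 px, minus a 3 px
dilation of the metal mask. For the pelvis study the ROIs are disks along
the corridor between the two implant centroids (`roi_between_metals()`),
where the inter-implant artifacts live — whole-mask averaging dilutes the
corridor roughly 2×. The head study evaluates the whole soft-tissue mask,
since the corridor between the dental inserts contains almost no soft
tissue.

The inpainting baselines (LI-MAR, NMAR) consume the *virtual sinogram* of
the corrupted ordinary reconstruction, as they must on clinical systems
that do not export raw data; streaks already baked into out-of-trace bins
therefore persist through inpainting, which is why these methods trail a
well-tilted second scan. The metal trace is the forward projection of the
segmented (threshold + 3×3 closing) mask, widened by two detector channels
— segmentation underestimates the corrupted penumbra. NMAR's prior
flattens the LI-MAR image into air/soft/bone classes (metal to the soft
value) and interpolates in the prior-normalised domain.

## Study conditions and what the tests show

The replication studies run on 256² grids, 720 views, 365 detector
channels (roughly half-pixel pitch at the isocenter), with 10 (pelvis) and
5 (head) noise realizations; medians over realizations are reported.
These sizes keep a full multi-method, multi-realization study in minutes
on one CPU while leaving every artifact mechanism intact.

Passing tests show that, *under the simulator's physics*: the ordinary
scan's corridor error collapses from ~22 % to ~3.9 % with a well-chosen
tilt, the fusion never invents values, improves on the tilted scan in
median, and beats both inpainting baselines; and in the insufficient-tilt
head regime the augmented pass recovers what plain fusion cannot. They do
not show clinical performance: the simulator omits scatter, detector
energy response, bowtie filtration and anatomical motion, uses 2-D fan
geometry rather than helical/cone-beam, and its phantoms are far simpler
than real anatomy. Registration between the two scans is assumed perfect;
with real gantry-tilted acquisitions, resampling and registration errors
would enter the artifact map as structure.

## Numerical choices and degenerate inputs

* Projector rays integrate by the midpoint rule at half-pixel steps
  (configurable); the backprojection adjoint is exact to the same
  discretisation, which the adjoint-consistency test checks at 1 %.
* The discrete Gaussian denoiser truncates at ±⌈4σ⌉ and renormalises;
  boundaries reflect.
* Local variances are clamped at zero before the square root; the SSIM
  map is bounded by 1 + 1e-9 by construction with positive stabilizers.
* σ = 0 denoising, empty metal masks, empty traces, rodless phantoms, and
  identical input pairs are all exact no-ops/identities with tests pinning
  the bitwise behaviour.
* Zero detected counts clamp to one photon, capping log data at
  $\ln i_0 \approx 16.1$; this is the photon-starvation mechanism that
  produces the dark bands.
* Mixing cm⁻¹ and HU images is a hard error, never a silent cast.

## Known limitations

* The shear-registered tilt model is exact only for z-extruded structures;
  real anatomy varies along z, so a clinical tilted scan pair would need
  registration first (out of scope, as is smoothing the fusion-boundary
  seams).
* Fusion operates per pixel; boundaries between regions taken from
  different scans can be visible where the scans' noise levels differ.
* The bundled spectrum is a filtered-Kramers shape without characteristic
  lines; bin weights are therefore approximate, though all comparisons are
  internally consistent.
* LI-MAR/NMAR are implemented in their canonical per-view 1-D form; 2-D
  inpainting variants and iterative/statistical MAR are out of scope.
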