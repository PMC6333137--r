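# End-to-end simulation workflow: phantom slice -> polychromatic counts ->
# noise -> log data -> FBP, plus the artifact-free reference and the full
# multi-method replication study the evaluation tables are built from.
# Material path integrals are computed once per slice and shared between the
# noisy acquisition, the artifact-free reference and repeated noise
# realizations.

#' Per-material path-length sinograms of a slice
#'
#' Forward-projects each material's indicator image once; monochromatic line
#' integrals at any energy are then linear combinations of these paths.
#'
#' @param slice a `material_slice`.
#' @param geom a [fan_geometry()].
#' @param step_frac ray-sampling step, see [forward_project()].
#' @return named list of views x channels matrices (air omitted).
#' @export
material_paths <- function(slice, geom, step_frac = 0.5) {
  paths <- list()
  for (m in seq_along(slice$materials)) {
    nm <- slice$materials[m]
    if (nm == "air") next
    ind <- (slice$labels == m) * 1.0
    if (!any(ind > 0)) next
    paths[[nm]] <- forward_project(ind, geom, pixel_cm = slice$spacing,
                                   step_frac = step_frac)$values
  }
  paths
}

poly_counts_from_paths <- function(paths, sp, i0, geom,
                                   replace = NULL) {
  if (!is.null(replace)) {
    for (from in names(replace)) {
      if (is.null(paths[[from]])) next
      to <- replace[[from]]
      paths[[to]] <- (paths[[to]] %||% 0) + paths[[from]]
      paths[[from]] <- NULL
    }
  }
  counts <- 0
  for (b in seq_along(sp$energies)) {
    L <- 0
    for (nm in names(paths))
      L <- L + attenuation(nm, sp$energies[b]) * paths[[nm]]
    counts <- counts + sp$weights[b] * exp(-L)
  }
  if (identical(counts, 0)) counts <- matrix(1, geom$n_views, geom$n_channels)
  intensity_sinogram(i0 * counts, i0, geom)
}

#' Simulate one noisy CT scan of a material slice
#'
#' Polychromatic photon counts, Poisson counting noise, the log transform
#' (with photon-starvation clamping) and Gaussian log-domain noise, followed
#' by filtered backprojection. Poisson and Gaussian draws use independent
#' seeds derived from `seed` (stages 0 and 1 of [derive_seed()]), so either
#' noise source can be switched off without changing the other's draws.
#'
#' @param slice a `material_slice` (see [oblique_slice()]).
#' @param sp a [make_spectrum()].
#' @param geom a [fan_geometry()].
#' @param grid a [recon_grid()].
#' @param i0 incident photons per channel (default 1e7).
#' @param gaussian_var log-domain Gaussian noise variance (default 0.001).
#' @param seed master seed for this scan.
#' @param poisson,gaussian logical switches for the two noise sources.
#' @param apodization FBP apodization.
#' @return list with `image` ([recon_image()]), `sinogram` and the
#'   noise-free `intensity` sinogram.
#' @export
simulate_scan <- function(slice, sp, geom, grid = recon_grid(), i0 = 1e7,
                          gaussian_var = 0.001, seed = 1, poisson = TRUE,
                          gaussian = TRUE, apodization = "hann") {
  isino <- simulate_polychromatic(slice, sp, geom, i0 = i0)
  noisy <- if (poisson) add_poisson(isino, derive_seed(seed, 0)) else isino
  sino <- log_transform(noisy)
  if (gaussian)
    sino <- add_gaussian(sino, gaussian_var, derive_seed(seed, 1))
  img <- fbp(sino, grid, apodization, tilt_deg = slice$tilt_deg)
  list(image = img, sinogram = sino, intensity = isino)
}

#' Artifact-free reference reconstruction
#'
#' Reconstruction of metal-artifact-free data: the metal voxels are replaced
#' by soft tissue and the same noise-free acquisition model is replayed. The
#' default reuses the polychromatic forward model, so the tissue-induced
#' beam hardening present in every evaluated image is present in the
#' reference too and the error measures metal artifacts, not the shared
#' spectrum effects. `mode = "monochromatic"` instead projects the
#' effective-energy attenuation image (useful as an idealised ground truth,
#' but its cupping-free values differ from every polychromatic
#' reconstruction by a systematic margin).
#'
#' @inheritParams simulate_scan
#' @param mode `"polychromatic"` (default) or `"monochromatic"`.
#' @return a [recon_image()].
#' @export
reference_image <- function(slice, sp, geom, grid = recon_grid(),
                            apodization = "hann",
                            mode = c("polychromatic", "monochromatic")) {
  mode <- match.arg(mode)
  metals <- metal_materials(slice)
  if (mode == "monochromatic") {
    repl <- NULL
    if (length(metals)) repl <- stats::setNames(rep("soft_tissue",
                                                    length(metals)), metals)
    mu <- slice_mu_effective(slice, sp, replace = repl)
    sino <- forward_project(mu, geom, pixel_cm = slice$spacing)
    return(fbp(sino, grid, apodization, tilt_deg = slice$tilt_deg))
  }
  paths <- material_paths(slice, geom)
  repl <- stats::setNames(rep("soft_tissue", length(metals)), metals)
  isino <- poly_counts_from_paths(paths, sp, 1e7, geom, replace = repl)
  fbp(log_transform(isino), grid, apodization, tilt_deg = slice$tilt_deg)
}

#' Noise-independent inputs of a replication study
#'
#' Cuts the ordinary and tilted slices, forward-projects every material
#' once, forms the noise-free polychromatic count data for both scans,
#' the artifact-free reference and the soft-tissue evaluation ROI. The
#' result feeds [study_realization()], which can then be repeated cheaply
#' over noise seeds.
#'
#' @param phantom a [voxel_phantom()].
#' @param tilts two tilt angles, degrees (ordinary first; default `c(0, 10)`).
#' @param axis rotation axis passed to [oblique_slice()].
#' @param sp,geom,grid,i0,apodization as in [simulate_scan()].
#' @param roi evaluation [roi_set()]; `NULL` uses the artifact-corridor
#'   ROIs of [roi_between_metals()].
#' @return a list of class `study_inputs`.
#' @export
study_inputs <- function(phantom, tilts = c(0, 10), axis = "ap",
                         sp = make_spectrum(120, 6), geom = fan_geometry(),
                         grid = recon_grid(), i0 = 1e7,
                         apodization = "hann", roi = NULL) {
  if (length(tilts) != 2)
    stop("two scans at different tilts are required (tilts must have length 2)")
  if (tilts[1] == tilts[2])
    stop("the two scans must use different tilt angles")
  sl_ori <- oblique_slice(phantom, tilts[1], axis = axis, registered = TRUE)
  sl_tlt <- oblique_slice(phantom, tilts[2], axis = axis, registered = TRUE)
  paths_ori <- material_paths(sl_ori, geom)
  paths_tlt <- material_paths(sl_tlt, geom)
  metals <- metal_materials(sl_ori)
  repl <- stats::setNames(rep("soft_tissue", length(metals)), metals)
  ref <- fbp(log_transform(
    poly_counts_from_paths(paths_ori, sp, i0, geom, replace = repl)),
    grid, apodization, tilt_deg = tilts[1])
  structure(list(
    slices = list(ori = sl_ori, tilt = sl_tlt),
    isino = list(ori = poly_counts_from_paths(paths_ori, sp, i0, geom),
                 tilt = poly_counts_from_paths(paths_tlt, sp, i0, geom)),
    reference = ref, roi = roi %||% roi_between_metals(sl_ori),
    sp = sp, geom = geom, grid = grid, i0 = i0, apodization = apodization),
    class = "study_inputs")
}

#' One noise realization of the replication study
#'
#' Applies Poisson and Gaussian noise to the noise-free count data of both
#' scans, reconstructs, runs the LI-MAR and NMAR baselines on the ordinary
#' scan's sinogram, T-MAR on the image pair (and optionally AT-MAR,
#' augmented by the NMAR image), and evaluates everything against the
#' artifact-free reference.
#'
#' @param inputs a [study_inputs()] object.
#' @param seed master seed for this realization.
#' @param gaussian_var log-domain Gaussian noise variance.
#' @param mar a [tmar_params()].
#' @param atmar also run the augmented second pass.
#' @param metal_threshold metal segmentation threshold, cm^-1.
#' @return list with the per-method `images`, the [compare_methods()]
#'   `report`, and the `tmar`/`atmar` results.
#' @export
study_realization <- function(inputs, seed = 1, gaussian_var = 0.001,
                              mar = tmar_params(), atmar = FALSE,
                              metal_threshold = 1.2) {
  grid <- inputs$grid; geom <- inputs$geom; apo <- inputs$apodization
  recon_one <- function(isino, seed, tilt_deg) {
    sino <- log_transform(add_poisson(isino, derive_seed(seed, 0)))
    sino <- add_gaussian(sino, gaussian_var, derive_seed(seed, 1))
    list(sino = sino, img = fbp(sino, grid, apo, tilt_deg = tilt_deg))
  }
  ori <- recon_one(inputs$isino$ori, derive_seed(seed, 10),
                   inputs$slices$ori$tilt_deg)
  tlt <- recon_one(inputs$isino$tilt, derive_seed(seed, 20),
                   inputs$slices$tilt$tilt_deg)
  metal <- segment_metal(ori$img, metal_threshold)
  trace <- metal_trace(metal, geom, grid$pixel_cm, dilate_channels = 2)
  # inpainting baselines run on the virtual sinogram of the corrupted
  # ordinary reconstruction (raw data are unavailable on clinical systems);
  # streaks already baked into out-of-trace bins therefore persist
  vsino <- virtual_sinogram(ori$img, geom)
  img_li <- limar(vsino, trace, grid, metal = metal,
                  uncorrected = ori$img, apodization = apo)
  prior <- build_prior(img_li, metal)
  img_nm <- nmar(vsino, trace, prior, grid, metal = metal,
                 uncorrected = ori$img, apodization = apo)
  mar$metal_threshold <- mar$metal_threshold %||% metal_threshold
  tm <- tmar_pipeline(ori$img, tlt$img, mar)
  methods <- list(original = ori$img, tilted = tlt$img,
                  limar = img_li, nmar = img_nm, tmar = tm$fused)
  at <- NULL
  if (isTRUE(atmar)) {
    at <- atmar_pipeline(ori$img, tlt$img, mar, augment = img_nm)
    methods$atmar <- at$fused
  }
  report <- compare_methods(methods, inputs$reference, inputs$roi)
  list(images = methods, report = report, tmar = tm, atmar = at,
       metal = metal, trace = trace,
       sinograms = list(ori = ori$sino, tilt = tlt$sino))
}

#' Run the full replication study on a phantom
#'
#' Convenience wrapper: [study_inputs()] followed by one
#' [study_realization()].
#'
#' @inheritParams study_inputs
#' @inheritParams study_realization
#' @param gaussian_var log-domain Gaussian noise variance (default 0.001).
#' @param seed master seed.
#' @return the [study_realization()] result, with `reference`, `roi` and
#'   `slices` attached.
#' @export
run_study <- function(phantom, tilts = c(0, 10), axis = "ap",
                      sp = make_spectrum(120, 6), geom = fan_geometry(),
                      grid = recon_grid(), i0 = 1e7, gaussian_var = 0.001,
                      seed = 1, mar = tmar_params(), atmar = FALSE,
                      metal_threshold = 1.2, apodization = "hann") {
  inputs <- study_inputs(phantom, tilts, axis, sp, geom, grid, i0,
                         apodization)
  res <- study_realization(inputs, seed, gaussian_var, mar, atmar,
                           metal_threshold)
  res$reference <- inputs$reference
  res$roi <- inputs$roi
  res$slices <- inputs$slices
  res
}
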