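# Parametric voxel phantoms. These stand in for licensed anthropomorphic
# phantoms: ellipse-based bodies with bone structures and
# cylindrical metal rods whose z-spans control which rods an oblique slice
# still contains. All generation is deterministic (no RNG).

#' Labeled voxel phantom
#'
#' @param labels 3-D integer array of material IDs (1-based indices into
#'   `materials`); array dims are (row = anterior->posterior, column =
#'   right->left, slice = inferior->superior).
#' @param spacing voxel size per axis, cm, length 3 (x, y, z).
#' @param materials character vector of material names; `labels` index it.
#' @return an object of class `voxel_phantom`.
#' @export
voxel_phantom <- function(labels, spacing, materials) {
  if (length(dim(labels)) != 3) stop("labels must be a 3-D array")
  if (any(spacing <= 0)) stop("spacing must be > 0 on each axis")
  rng <- range(labels)
  if (rng[1] < 1 || rng[2] > length(materials))
    stop("all labels must reference a defined material")
  structure(list(labels = labels, spacing = spacing, materials = materials,
                 origin = c(0, 0, 0)),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("voxel_phantom: %d x %d x %d voxels (%.3g x %.3g x %.3g cm), materials: %s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              paste(x$materials, collapse = ", ")))
  invisible(x)
}

ellipse_mask <- function(n, px, cx, cy, a, b) {
  co <- pixel_coords(n, n, px)
  outer(co$y, co$x, function(y, x) ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1)
}

check_rod_in_body <- function(rod, body) {
  ok <- ((abs(rod$center[1]) + rod$radius) / body[1])^2 +
    ((abs(rod$center[2]) + rod$radius) / body[2])^2 <= 1
  if (!ok) stop("metal rod extends outside the body ellipse")
}

check_rods_disjoint <- function(rods) {
  if (length(rods) < 2) return(invisible(TRUE))
  for (i in seq_along(rods)) for (j in seq_along(rods)) {
    if (i >= j) next
    d <- sqrt(sum((rods[[i]]$center - rods[[j]]$center)^2))
    if (d < rods[[i]]$radius + rods[[j]]$radius)
      stop("metal rods overlap each other")
  }
  invisible(TRUE)
}

build_phantom <- function(cfg, base_builder, materials) {
  n <- cfg$n_xy; px <- cfg$spacing; dz <- cfg$z_spacing
  nz <- 2L * as.integer(round(cfg$z_half / dz)) + 1L
  zc <- (seq_len(nz) - (nz + 1) / 2) * dz
  base <- base_builder(n, px)
  for (rod in cfg$rods) check_rod_in_body(rod, cfg$body)
  check_rods_disjoint(cfg$rods)
  metal_id <- length(materials)
  labels <- array(rep(base, nz), dim = c(n, n, nz))
  for (rod in cfg$rods) {
    m <- disk_mask(n, px, rod$center[1], rod$center[2], rod$radius)
    ks <- which(zc >= rod$z[1] & zc <= rod$z[2])
    for (k in ks) {
      sl <- labels[, , k]
      sl[m] <- metal_id
      labels[, , k] <- sl
    }
  }
  voxel_phantom(labels, c(px, px, dz), materials)
}

#' Pelvis phantom configuration
#'
#' Geometry of the bilateral-hip-implant phantom: a soft-tissue body ellipse
#' with simplified sacrum/iliac/pubic bone structures, a water-filled
#' bladder, two bowel-gas pockets, pelvic fat lobules, and two lateral
#' cobalt-chromium implant rods of radius 0.85 cm (steel and titanium are
#' available through `metal`). The rods share the axial plane z = 0
#' (so ordinary-scan rays traverse both) but occupy staggered z-spans: a
#' 10-degree oblique cut about the anterior-posterior axis meets the left
#' rod inside its span and the right rod outside it, so the tilted slice
#' contains a single rod cross-section and no ray crosses two rods.
#'
#' @param n_xy grid side, voxels. @param spacing in-plane voxel size, cm.
#' @param z_spacing,z_half z sampling and half-extent, cm.
#' @param rod_radius metal rod radius, cm (0.85 by default).
#' @param rod_x lateral rod-centre offset, cm.
#' @param rod_z_left,rod_z_right rod z-spans, cm.
#' @param metal rod material name.
#' @return a config list for [make_pelvis_phantom()].
#' @export
pelvis_config <- function(n_xy = 512, spacing = 0.1, z_spacing = spacing,
                          z_half = 4.2, rod_radius = 0.85, rod_x = 7.5,
                          rod_z_left = c(-2.5, 4.0),
                          rod_z_right = c(-4.0, 1.0),
                          metal = "cocr") {
  list(n_xy = as.integer(n_xy), spacing = spacing, z_spacing = z_spacing,
       z_half = z_half,
       body = c(16, 10),
       bones = list(list(center = c(0, -6.2), semi = c(3.0, 1.8)),
                    list(center = c(-5.6, -4.2), semi = c(2.3, 1.3)),
                    list(center = c(5.6, -4.2), semi = c(2.3, 1.3)),
                    list(center = c(0, 6.2), semi = c(2.6, 0.9))),
       bladder = list(center = c(0, 2.6), semi = c(3.2, 2.2)),
       gas = list(list(center = c(0, -3.4), semi = c(1.5, 1.0)),
                  list(center = c(4.2, 3.2), semi = c(1.2, 0.8))),
       fat = list(list(center = c(-4.2, -0.2), semi = c(1.4, 0.6)),
                  list(center = c(-1.4, 0.1), semi = c(1.2, 0.5)),
                  list(center = c(1.8, -0.4), semi = c(1.3, 0.55)),
                  list(center = c(4.4, 0.2), semi = c(1.2, 0.5)),
                  list(center = c(0, -1.6), semi = c(1.6, 0.6))),
       rods = list(list(center = c(-rod_x, 0), radius = rod_radius,
                        z = rod_z_left),
                   list(center = c(rod_x, 0), radius = rod_radius,
                        z = rod_z_right)),
       metal = metal)
}

#' Generate the pelvis phantom
#'
#' @param cfg a [pelvis_config()] list.
#' @return a [voxel_phantom()] with materials air, soft_tissue, bone, water
#'   and the configured metal.
#' @export
make_pelvis_phantom <- function(cfg = pelvis_config()) {
  mats <- c("air", "soft_tissue", "bone", "water", "adipose")
  if (length(cfg$rods) > 0) mats <- c(mats, cfg$metal)
  build_phantom(cfg, function(n, px) {
    base <- matrix(1L, n, n)
    base[ellipse_mask(n, px, 0, 0, cfg$body[1], cfg$body[2])] <- 2L
    for (b in cfg$bones)
      base[ellipse_mask(n, px, b$center[1], b$center[2], b$semi[1], b$semi[2])] <- 3L
    base[ellipse_mask(n, px, cfg$bladder$center[1], cfg$bladder$center[2],
                      cfg$bladder$semi[1], cfg$bladder$semi[2])] <- 4L
    for (f in cfg$fat)
      base[ellipse_mask(n, px, f$center[1], f$center[2], f$semi[1],
                        f$semi[2])] <- 5L
    for (g in cfg$gas)
      base[ellipse_mask(n, px, g$center[1], g$center[2], g$semi[1],
                        g$semi[2])] <- 1L
    base
  }, mats)
}

#' Head phantom configuration
#'
#' Head-sized tissue ellipse with a gypsum skull shell and jaw block and two
#' 0.6 cm metal rods (Cerrobend by default) in the gingiva region. Rod
#' z-spans are staggered so a 15-degree oblique cut about the
#' anterior-posterior axis separates their traces; pass long symmetric
#' spans (e.g. `c(-3, 3)` for both) to emulate an insufficient tilt in which
#' both rods stay in the tilted slice.
#'
#' @inheritParams pelvis_config
#' @param rod_y anterior rod-centre offset, cm.
#' @param n_rods number of rods (0, 1 or 2).
#' @return a config list for [make_head_phantom()].
#' @export
head_config <- function(n_xy = 512, spacing = 0.1, z_spacing = spacing,
                        z_half = 3.2, rod_radius = 0.6, rod_x = 2.0,
                        rod_y = 6.0,
                        rod_z_left = c(-1.5, 3.0),
                        rod_z_right = c(-3.0, 0.3),
                        n_rods = 2, metal = "cerrobend") {
  rods <- list(list(center = c(-rod_x, rod_y), radius = rod_radius,
                    z = rod_z_left),
               list(center = c(rod_x, rod_y), radius = rod_radius,
                    z = rod_z_right))[seq_len(n_rods)]
  list(n_xy = as.integer(n_xy), spacing = spacing, z_spacing = z_spacing,
       z_half = z_half,
       body = c(8, 10),
       skull_outer = c(7.6, 9.6), skull_inner = c(6.8, 8.8),
       jaw = list(center = c(0, 5.2), semi = c(4.4, 2.6)),
       mouth = list(center = c(0, 5.0), semi = c(2.8, 1.4)),
       rods = rods, metal = metal)
}

#' Generate the head phantom
#'
#' @param cfg a [head_config()] list.
#' @return a [voxel_phantom()] with materials air, soft_tissue, gypsum and
#'   (when rods are present) the configured metal.
#' @export
make_head_phantom <- function(cfg = head_config()) {
  mats <- c("air", "soft_tissue", "gypsum")
  if (length(cfg$rods) > 0) mats <- c(mats, cfg$metal)
  build_phantom(cfg, function(n, px) {
    base <- matrix(1L, n, n)
    base[ellipse_mask(n, px, 0, 0, cfg$body[1], cfg$body[2])] <- 2L
    shell <- ellipse_mask(n, px, 0, 0, cfg$skull_outer[1], cfg$skull_outer[2]) &
      !ellipse_mask(n, px, 0, 0, cfg$skull_inner[1], cfg$skull_inner[2])
    base[shell] <- 3L
    base[ellipse_mask(n, px, cfg$jaw$center[1], cfg$jaw$center[2],
                      cfg$jaw$semi[1], cfg$jaw$semi[2])] <- 3L
    base[ellipse_mask(n, px, cfg$mouth$center[1], cfg$mouth$center[2],
                      cfg$mouth$semi[1], cfg$mouth$semi[2])] <- 2L
    base
  }, mats)
}

#' Cut an (oblique) slice from a voxel phantom
#'
#' Samples the label grid on a plane tilted by `tilt_deg` about an in-plane
#' axis through `z = z0`, by nearest-neighbour lookup (labels are
#' categorical, so interpolation would invent materials). In-plane sample
#' spacing equals the phantom's xy voxel size; points outside the grid are
#' air. With `axis = "ap"` the plane height varies along the left-right
#' direction (this is the axis that discriminates bilaterally separated
#' rods); with `axis = "lateral"` it varies along the anterior-posterior
#' direction.
#'
#' @param ph a [voxel_phantom()].
#' @param tilt_deg tilt angle, degrees, in `[-30, 30]`.
#' @param z0 height of the plane on the rotation axis, cm.
#' @param axis rotation axis: `"ap"` (anterior-posterior) or `"lateral"`.
#' @param registered sample a sheared plane (`z` varies but in-plane
#'   coordinates stay the world x/y) instead of the metrically rotated one.
#'   The sheared slice of a z-extruded structure is pixel-identical to the
#'   axial slice, which realises the co-registered-input assumption of the
#'   fusion method exactly; the default `FALSE` keeps true slice geometry
#'   (cross-sections foreshorten by 1/cos(tilt)).
#' @return an object of class `material_slice`.
#' @export
oblique_slice <- function(ph, tilt_deg, z0 = 0, axis = c("ap", "lateral"),
                          registered = FALSE) {
  axis <- match.arg(axis)
  if (abs(tilt_deg) > 30) stop("tilt_deg must lie in [-30, 30]")
  d <- dim(ph$labels)
  n1 <- d[1]; n2 <- d[2]; nz <- d[3]
  px <- ph$spacing[1]; dz <- ph$spacing[3]
  th <- tilt_deg * pi / 180
  scale <- if (registered) 1 else cos(th)
  u <- (seq_len(n2) - (n2 + 1) / 2) * px            # column coordinate
  v <- ((n1 + 1) / 2 - seq_len(n1)) * ph$spacing[2] # row coordinate
  if (axis == "ap") {
    x <- matrix(u * scale, n1, n2, byrow = TRUE)
    y <- matrix(v, n1, n2)
    z <- matrix(z0 + u * sin(th), n1, n2, byrow = TRUE)
  } else {
    x <- matrix(u, n1, n2, byrow = TRUE)
    y <- matrix(v * scale, n1, n2)
    z <- matrix(z0 + v * sin(th), n1, n2)
  }
  ix <- as.integer(round(x / px + (n2 + 1) / 2))
  iy <- as.integer(round((n1 + 1) / 2 - y / ph$spacing[2]))
  iz <- as.integer(round(z / dz + (nz + 1) / 2))
  inside <- ix >= 1L & ix <= n2 & iy >= 1L & iy <= n1 & iz >= 1L & iz <= nz
  if (!any(inside)) stop("cutting plane misses the voxel grid")
  labels <- matrix(1L, n1, n2)
  idx <- cbind(iy[inside], ix[inside], iz[inside])
  labels[inside] <- ph$labels[idx]
  structure(list(labels = labels, materials = ph$materials,
                 spacing = px, tilt_deg = tilt_deg, axis = axis, z0 = z0),
            class = "material_slice")
}

#' @export
print.material_slice <- function(x, ...) {
  cat(sprintf("material_slice: %d x %d px (%.3g cm), tilt %g deg about %s axis, z0 %g cm\n",
              nrow(x$labels), ncol(x$labels), x$spacing, x$tilt_deg, x$axis, x$z0))
  invisible(x)
}

#' Binary mask of one material in a slice
#' @param slice a [oblique_slice()] result.
#' @param material material name.
#' @return logical matrix.
#' @export
slice_mask <- function(slice, material) {
  id <- match(material, slice$materials)
  if (is.na(id)) return(matrix(FALSE, nrow(slice$labels), ncol(slice$labels)))
  slice$labels == id
}

#' Monochromatic attenuation image of a slice
#'
#' @param slice a `material_slice`.
#' @param energy_kev photon energy, keV.
#' @param replace optional named character vector mapping material names to
#'   substitute materials (e.g. `c(titanium = "soft_tissue")` for an
#'   artifact-free reference).
#' @return numeric matrix of linear attenuation, cm^-1.
#' @export
slice_mu <- function(slice, energy_kev, replace = NULL) {
  mats <- slice$materials
  eff <- mats
  if (!is.null(replace)) eff[match(names(replace), mats)] <- replace
  mu <- vapply(eff, attenuation, numeric(1), energy_kev = energy_kev)
  matrix(mu[slice$labels], nrow(slice$labels), ncol(slice$labels))
}

#' Spectrum-effective attenuation image of a slice
#'
#' @inheritParams slice_mu
#' @param sp a [make_spectrum()] object.
#' @return numeric matrix of effective linear attenuation, cm^-1.
#' @export
slice_mu_effective <- function(slice, sp, replace = NULL) {
  mats <- slice$materials
  eff <- mats
  if (!is.null(replace)) eff[match(names(replace), mats)] <- replace
  mu <- vapply(eff, effective_mu, numeric(1), sp = sp)
  matrix(mu[slice$labels], nrow(slice$labels), ncol(slice$labels))
}
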