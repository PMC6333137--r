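# Desk-scale replication experiments. These fix the study conditions the
# package's quantitative claims are made under: the geometry, spectrum and
# noise model follow the simulation protocol (120 kVp six-bin beam, SID
# 400/605 mm, SDD 1100/1062 mm, 720 views over 360 degrees, ~1e7 incident
# photons, Gaussian log-domain variance 0.001); phantoms are rendered on a
# 256^2 grid so a multi-realization study stays within minutes on one CPU.

#' Pelvis replication: bilateral hip implants, 0/10-degree scans
#'
#' Runs the full method comparison (original, tilted, LI-MAR, NMAR, T-MAR)
#' over several Poisson/Gaussian noise realizations of the pelvis phantom
#' and reports per-seed soft-tissue-ROI MAPEs plus their medians.
#'
#' @param seed master seed; per-realization seeds derive from it.
#' @param n_realizations number of noise realizations (default 10).
#' @param n_xy phantom/reconstruction grid side (default 256).
#' @param spacing pixel size, cm (default 0.2, covering the 32 cm body).
#' @param atmar also run AT-MAR in each realization.
#' @return list with `mape` (realizations x methods matrix), `median`
#'   (named vector) and the [study_inputs()] used.
#' @export
pelvis_replication <- function(seed = 1, n_realizations = 10, n_xy = 256,
                               spacing = 0.2, atmar = FALSE) {
  ph <- make_pelvis_phantom(pelvis_config(n_xy = n_xy, spacing = spacing))
  inp <- study_inputs(ph, tilts = c(0, 10),
                      geom = fan_geometry(400, 1100, 720, 365, 170),
                      grid = recon_grid(n_xy, spacing))
  collect_replication(inp, seed, n_realizations, atmar)
}

#' Head replication: Cerrobend dental inserts, insufficient 15-degree tilt
#'
#' The head phantom is configured with long rod spans so both metal rods
#' remain in the 15-degree oblique slice: the tilted scan cannot supply
#' complementary information where both scans are corrupted, the regime the
#' augmented second pass exists for. Evaluation uses the whole soft-tissue
#' mask (the corridor between the inserts contains almost no soft tissue).
#'
#' @inheritParams pelvis_replication
#' @param spacing pixel size, cm (default 0.1 for the head).
#' @export
head_replication <- function(seed = 1, n_realizations = 5, n_xy = 256,
                             spacing = 0.1, atmar = TRUE) {
  cfg <- head_config(n_xy = n_xy, spacing = spacing,
                     rod_z_left = c(-3, 3), rod_z_right = c(-3, 3))
  ph <- make_head_phantom(cfg)
  sl0 <- oblique_slice(ph, 0, registered = TRUE)
  inp <- study_inputs(ph, tilts = c(0, 15),
                      geom = fan_geometry(605, 1062, 720, 365, 110),
                      grid = recon_grid(n_xy, spacing),
                      roi = default_roi(sl0))
  collect_replication(inp, seed, n_realizations, atmar)
}

collect_replication <- function(inp, seed, n_realizations, atmar) {
  rows <- lapply(seq_len(n_realizations), function(k) {
    r <- study_realization(inp, seed = derive_seed(seed, 100 + k),
                           atmar = atmar)
    stats::setNames(r$report$mape_pct, r$report$method)
  })
  methods <- names(rows[[1]])
  m <- do.call(rbind, lapply(rows, function(r) r[methods]))
  rownames(m) <- paste0("realization", seq_len(n_realizations))
  list(mape = m, median = apply(m, 2, median), inputs = inp)
}
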