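# Readers and writers. Images and sinograms travel as plain TSV matrices
# with a JSON sidecar carrying grid metadata; derived images can be
# exported as DICOM CT slices. The DICOM code handles the explicit-VR
# little-endian subset used by single-frame CT series.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a reconstructed image
#'
#' Tab-separated values plus a `.json` sidecar (pixel size, units, tilt).
#'
#' @param img a [recon_image()].
#' @param path output file path (e.g. `ori.tsv`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  utils::write.table(img$values, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(pixel_cm = img$pixel_cm, units = img$units,
               tilt_deg = img$tilt_deg,
               shape = dim(img$values))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a reconstructed image written by [write_image()]
#' @param path file path.
#' @return a [recon_image()].
#' @export
read_image <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  v <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(v) <- NULL
  recon_image(v, meta$pixel_cm, meta$units,
              if (is.null(meta$tilt_deg)) NA_real_ else meta$tilt_deg)
}

#' Write a sinogram (values + geometry sidecar)
#' @param sino a [sinogram()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sinogram <- function(sino, path) {
  utils::write.table(sino$values, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  g <- sino$geometry
  jsonlite::write_json(unclass(g), sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a sinogram written by [write_sinogram()]
#' @param path file path.
#' @return a [sinogram()].
#' @export
read_sinogram <- function(path) {
  g <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  v <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(v) <- NULL
  geom <- structure(g, class = "fan_geometry")
  sinogram(v, geom)
}

# ---- DICOM (explicit VR little endian, single-frame CT) ----

dcm_uid_root <- "1.2.826.0.1.3680043.9999"

dcm_pad <- function(s, nul = FALSE) {
  pad <- if (nul) rawToChar(as.raw(0L)) else " "
  if (nchar(s) %% 2 == 1) paste0(s, pad) else s
}

dcm_element <- function(group, element, vr, value) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(as.integer(c(group, element)), con, size = 2, endian = "little")
  writeChar(vr, con, eos = NULL)
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
    writeBin(as.integer(0), con, size = 2, endian = "little")
    writeBin(as.integer(length(value)), con, size = 4, endian = "little")
    writeBin(value, con)
  } else {
    if (vr == "US") {
      payload <- writeBin(as.integer(value), raw(), size = 2,
                          endian = "little")
    } else if (vr == "UL") {
      payload <- writeBin(as.integer(value), raw(), size = 4,
                          endian = "little")
    } else {
      s <- dcm_pad(as.character(value), nul = vr == "UI")
      payload <- charToRaw(s)
    }
    writeBin(as.integer(length(payload)), con, size = 2, endian = "little")
    writeBin(payload, con)
  }
  rawConnectionValue(con)
}

#' Write a CT slice as a DICOM file
#'
#' Explicit-VR little-endian single-frame CT with mandatory rescale
#' slope/intercept; pixel values are stored as unsigned 16-bit
#' `(HU - intercept) / slope`.
#'
#' @param img a [recon_image()] in HU.
#' @param path output file.
#' @param series_uid series instance UID shared by the slices of one stack.
#' @param instance instance number (1-based slice index).
#' @param z_mm slice position along the patient axis, mm.
#' @param gantry_tilt_deg gantry/detector tilt tag value.
#' @param intercept,slope rescale intercept and slope.
#' @return `path`, invisibly.
#' @export
write_dicom_slice <- function(img, path, series_uid, instance = 1, z_mm = 0,
                              gantry_tilt_deg = 0, intercept = -1024,
                              slope = 1) {
  if (!identical(img$units, "HU")) stop("DICOM export expects an HU image")
  stored <- round((t(img$values) - intercept) / slope)  # column-major -> row-major
  if (any(stored < 0 | stored > 65535)) stop("pixel values outside uint16")
  pix <- writeBin(as.integer(stored), raw(), size = 2, endian = "little")
  ts <- dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  meta <- c(dcm_element(0x0002, 0x0000, "UL", length(ts)), ts)
  sop_uid <- sprintf("%s.%s.%d", dcm_uid_root, series_uid, instance)
  ds <- c(
    dcm_element(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    dcm_element(0x0008, 0x0018, "UI", sop_uid),
    dcm_element(0x0008, 0x0060, "CS", "CT"),
    dcm_element(0x0018, 0x1120, "DS", format(gantry_tilt_deg)),
    dcm_element(0x0020, 0x000D, "UI", paste0(dcm_uid_root, ".1")),
    dcm_element(0x0020, 0x000E, "UI", series_uid),
    dcm_element(0x0020, 0x0013, "IS", format(instance)),
    dcm_element(0x0020, 0x0032, "DS",
                sprintf("0\\0\\%s", format(z_mm))),
    dcm_element(0x0028, 0x0002, "US", 1),
    dcm_element(0x0028, 0x0010, "US", nrow(img$values)),
    dcm_element(0x0028, 0x0011, "US", ncol(img$values)),
    dcm_element(0x0028, 0x0030, "DS",
                sprintf("%s\\%s", format(img$pixel_cm * 10),
                        format(img$pixel_cm * 10))),
    dcm_element(0x0028, 0x0100, "US", 16),
    dcm_element(0x0028, 0x0101, "US", 16),
    dcm_element(0x0028, 0x0102, "US", 15),
    dcm_element(0x0028, 0x0103, "US", 0),
    dcm_element(0x0028, 0x1052, "DS", format(intercept)),
    dcm_element(0x0028, 0x1053, "DS", format(slope)),
    dcm_element(0x7FE0, 0x0010, "OW", pix))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  writeBin(c(meta, ds), con)
  invisible(path)
}

read_uint <- function(r, i, n) {
  sum(as.integer(r[i:(i + n - 1)]) * 256^(0:(n - 1)))
}

read_dicom_file <- function(path) {
  r <- readBin(path, "raw", file.size(path))
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM")
    stop(sprintf("%s is not a DICOM part-10 file", path))
  i <- 133
  out <- list()
  long_vrs <- c("OB", "OW", "SQ", "UN", "UT")
  while (i + 8 <= length(r) + 1) {
    group <- read_uint(r, i, 2); element <- read_uint(r, i + 2, 2)
    vr <- rawToChar(r[(i + 4):(i + 5)])
    if (vr %in% long_vrs) {
      len <- read_uint(r, i + 8, 4); i <- i + 12
    } else {
      len <- read_uint(r, i + 6, 2); i <- i + 8
    }
    val <- if (len > 0) r[i:(i + len - 1)] else raw(0)
    i <- i + len
    key <- sprintf("%04X%04X", group, element)
    out[[key]] <- list(vr = vr, value = val)
  }
  out
}

dcm_str <- function(el) {
  v <- el$value
  v <- v[v != as.raw(0L)]
  sub(" +$", "", rawToChar(v))
}
dcm_num <- function(el) as.numeric(strsplit(dcm_str(el), "\\\\")[[1]])
dcm_us <- function(el) read_uint(el$value, 1, 2)

#' Read a directory of single-frame CT DICOM files
#'
#' Slices are sorted by the z component of ImagePositionPatient; rescale
#' slope and intercept are applied to produce HU values; the gantry-tilt
#' tag, when present, is surfaced in the result.
#'
#' @param path directory containing one DICOM series.
#' @return list with `stack` (list of [recon_image()]s in HU, sorted by
#'   position), `z_mm` (positions), `series_uid` and `gantry_tilt_deg`.
#' @export
read_dicom_series <- function(path) {
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("no files in DICOM directory")
  parsed <- lapply(files, read_dicom_file)
  uids <- vapply(parsed, function(p) dcm_str(p[["0020000E"]]), character(1))
  if (length(unique(uids)) > 1)
    stop("directory mixes multiple DICOM series")
  z <- vapply(parsed, function(p) dcm_num(p[["00200032"]])[3], numeric(1))
  ord <- order(z)
  stack <- lapply(parsed[ord], function(p) {
    if (is.null(p[["00281052"]]) || is.null(p[["00281053"]]))
      stop("missing rescale intercept/slope tags")
    rows <- dcm_us(p[["00280010"]]); cols <- dcm_us(p[["00280011"]])
    stored <- matrix(NA_real_, rows, cols)
    raw_pix <- p[["7FE00010"]]$value
    vals <- read_uint_vec(raw_pix)
    stored <- matrix(vals, rows, cols, byrow = TRUE)
    hu <- stored * dcm_num(p[["00281053"]]) + dcm_num(p[["00281052"]])
    px_mm <- dcm_num(p[["00280030"]])[1]
    tilt <- if (!is.null(p[["00181120"]])) dcm_num(p[["00181120"]]) else NA_real_
    recon_image(hu, px_mm / 10, units = "HU", tilt_deg = tilt)
  })
  tilt <- stack[[1]]$tilt_deg
  list(stack = stack, z_mm = sort(z), series_uid = uids[1],
       gantry_tilt_deg = tilt)
}

read_uint_vec <- function(r) {
  n <- length(r) / 2
  lo <- as.integer(r[seq(1, by = 2, length.out = n)])
  hi <- as.integer(r[seq(2, by = 2, length.out = n)])
  lo + 256 * hi
}

#' Write a windowed 8-bit PNG preview of an image
#'
#' Applies a display window (width/level, same units as the image) and
#' writes an 8-bit greyscale PNG. Typical windows: WW/WL 0.023/0.025 cm^-1
#' for simulated attenuation images, 850/2000 HU for head images.
#'
#' @param img a [recon_image()].
#' @param path output PNG path.
#' @param ww,wl window width and level in the image's units.
#' @return `path`, invisibly.
#' @export
write_preview <- function(img, path, ww, wl) {
  v <- (img$values - (wl - ww / 2)) / ww
  png::writePNG(pmin(pmax(v, 0), 1), path)
  invisible(path)
}
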