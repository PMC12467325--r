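#' Pixel classes used by label maps and ground truth
#'
#' Order matters: it is the deterministic tie-break order used by the
#' classifiers (`DKK3_POSITIVE` wins ties over `NUCLEI`, which wins over
#' `BACKGROUND`).
#'
#' @export
LABEL_CLASSES <- c("DKK3_POSITIVE", "NUCLEI", "BACKGROUND", "UNCLASSIFIED")

#' Staining intensity tiers
#'
#' @export
TIERS <- c("NEGATIVE", "WEAK", "MODERATE", "STRONG")

#' Validate a wavelength axis
#'
#' A wavelength axis is a strictly increasing numeric vector of wavelengths
#' in nanometres, confined to the visible/near-infrared range covered by
#' microscope-mounted hyperspectral cameras.
#'
#' @param values Numeric vector of wavelengths in nm.
#' @return The validated numeric vector, invisibly usable as an axis.
#' @export
wavelength_axis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("wavelength axis must have at least 2 values", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("wavelength axis must be finite", call. = FALSE)
  }
  if (any(diff(values) <= 0)) {
    stop("wavelength axis must be strictly increasing", call. = FALSE)
  }
  if (any(values < 400 | values > 1100)) {
    stop("wavelengths must lie within [400, 1100] nm", call. = FALSE)
  }
  values
}

#' Construct a hyperspectral cube
#'
#' A spectral cube holds one spectrum per pixel: a 3-axis array of
#' `rows x cols x bands`, plus the wavelength axis (nm) and the kind of
#' signal stored. Reflectance is unitless and clipped to \[0, 1.5\] (the
#' ceiling tolerates specular pixels); absorbance is optical density,
#' `-log10` of reflectance, and non-negative.
#'
#' @param data 3-axis numeric array (rows x cols x bands).
#' @param wavelengths Wavelength axis in nm; length must equal the band count.
#' @param signal_kind One of `"RAW"`, `"REFLECTANCE"`, `"ABSORBANCE"`.
#' @param meta Free-form named list of provenance.
#' @return An object of class `spectral_cube`.
#' @export
spectral_cube <- function(data, wavelengths,
                          signal_kind = c("RAW", "REFLECTANCE", "ABSORBANCE"),
                          meta = list()) {
  signal_kind <- match.arg(signal_kind)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("cube data must be a 3-axis array (rows x cols x bands)", call. = FALSE)
  }
  wavelengths <- wavelength_axis(wavelengths)
  if (dim(data)[3] != length(wavelengths)) {
    stop(sprintf("band count (%d) does not match wavelength axis length (%d)",
                 dim(data)[3], length(wavelengths)), call. = FALSE)
  }
  tol <- 1e-9
  if (signal_kind == "REFLECTANCE" &&
      (min(data) < -tol || max(data) > 1.5 + tol)) {
    stop("REFLECTANCE values must lie within [0, 1.5]", call. = FALSE)
  }
  if (signal_kind == "ABSORBANCE" && min(data) < -tol) {
    stop("ABSORBANCE values must be non-negative", call. = FALSE)
  }
  structure(
    list(data = data, wavelengths = wavelengths,
         signal_kind = signal_kind, meta = meta),
    class = "spectral_cube"
  )
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_cube> %d x %d pixels, %d bands (%.0f-%.0f nm), %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              x$signal_kind))
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$data)

n_bands <- function(cube) length(cube$wavelengths)
spatial_shape <- function(cube) dim(cube$data)[1:2]

# Flatten to pixels x bands (row-major pixel order is irrelevant as long as
# it is consistent; R's column-major order is used throughout).
cube_matrix <- function(cube) {
  d <- dim(cube$data)
  matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
}

matrix_to_cube_data <- function(m, shape) {
  array(m, dim = c(shape[1], shape[2], ncol(m)))
}

#' Calibrate raw counts to reflectance
#'
#' Converts raw sensor counts to reflectance using dark and white (bright)
#' reference frames recorded under the same optics and illumination:
#' `R = (raw - dark) / (white - dark)`, clipped to \[0, 1.5\].
#'
#' @param raw 3-axis array of raw counts, or a `spectral_cube` with
#'   `signal_kind = "RAW"`.
#' @param dark,white Reference frames, same shape as `raw` (averaged
#'   replicate frames are supplied pre-averaged).
#' @param wavelengths Wavelength axis for the result; taken from `raw` when
#'   it is a cube.
#' @return A `spectral_cube` with `signal_kind = "REFLECTANCE"`.
#' @export
calibrate_reflectance <- function(raw, dark, white, wavelengths = NULL) {
  meta <- list()
  if (inherits(raw, "spectral_cube")) {
    wavelengths <- raw$wavelengths
    meta <- raw$meta
    raw <- raw$data
  }
  if (is.null(wavelengths)) {
    stop("wavelengths must be supplied when raw is a bare array", call. = FALSE)
  }
  if (!identical(dim(raw), dim(dark)) || !identical(dim(raw), dim(white))) {
    stop("raw, dark and white frames must share one shape", call. = FALSE)
  }
  denom <- white - dark
  bad <- apply(denom == 0, 3, any)
  if (any(bad)) {
    stop(sprintf(
      "calibration error: white - dark is zero at band(s) %s (%.0f nm ...)",
      paste(which(bad)[seq_len(min(3, sum(bad)))], collapse = ", "),
      wavelengths[which(bad)[1]]), call. = FALSE)
  }
  r <- (raw - dark) / denom
  r <- pmin(pmax(r, 0), 1.5)
  meta$calibrated <- TRUE
  spectral_cube(r, wavelengths, "REFLECTANCE", meta)
}

#' Convert reflectance to absorbance (optical density)
#'
#' `A = -log10(max(R, floor))`. The floor guards fully opaque pixels; at the
#' default `1e-4` a zero reflectance maps to OD 4.
#'
#' @param cube A `spectral_cube` with `signal_kind = "REFLECTANCE"`.
#' @param floor Small positive reflectance floor (default `1e-4`).
#' @return A `spectral_cube` with `signal_kind = "ABSORBANCE"`.
#' @export
reflectance_to_absorbance <- function(cube, floor = 1e-4) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (cube$signal_kind != "REFLECTANCE") {
    stop(sprintf("cube is %s, not REFLECTANCE", cube$signal_kind), call. = FALSE)
  }
  if (!is.numeric(floor) || floor <= 0) {
    stop("floor must be a positive reflectance", call. = FALSE)
  }
  a <- -log10(pmax(cube$data, floor))
  a[a < 0] <- 0  # reflectance in (1, 1.5] (specular) carries no stain signal
  spectral_cube(a, cube$wavelengths, "ABSORBANCE", cube$meta)
}

#' Crop a cube to a spectral window
#'
#' Keeps bands with `lo <= lambda <= hi`, both ends inclusive. A window of
#' 520-725 nm is the default analysis window for DAB/hematoxylin
#' discrimination.
#'
#' @param cube A `spectral_cube`.
#' @param lo,hi Window bounds in nm, `lo < hi`.
#' @return The windowed `spectral_cube`.
#' @export
crop_spectral_window <- function(cube, lo, hi) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (!(lo < hi)) stop("window requires lo < hi", call. = FALSE)
  keep <- cube$wavelengths >= lo & cube$wavelengths <= hi
  if (!any(keep)) {
    stop(sprintf("window error: [%g, %g] nm contains no bands of the axis (%g-%g nm)",
                 lo, hi, min(cube$wavelengths), max(cube$wavelengths)),
         call. = FALSE)
  }
  spectral_cube(cube$data[, , keep, drop = FALSE], cube$wavelengths[keep],
                cube$signal_kind, cube$meta)
}

#' Mean spectrum over a pixel mask
#'
#' Per-band arithmetic mean over the pixels where `mask` is TRUE.
#'
#' @param cube A `spectral_cube`.
#' @param mask Logical matrix matching the cube's spatial shape.
#' @return Numeric vector, one mean per band.
#' @export
mean_spectrum <- function(cube, mask) {
  stopifnot(inherits(cube, "spectral_cube"))
  mask <- as.logical(mask)
  dim(mask) <- dim(cube$data)[1:2]
  if (!any(mask)) stop("mask error: mask selects no pixels", call. = FALSE)
  m <- cube_matrix(cube)
  colMeans(m[as.vector(mask), , drop = FALSE])
}
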