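#' Write a hyperspectral cube to disk
#'
#' Two on-disk dialects are supported:
#' \describe{
#'   \item{ENVI}{a binary cube at `path` plus a text header at `<path>.hdr`.
#'     Cubes are written band-sequential (BSQ) as little-endian doubles, so
#'     ENVI round-trips are bit-exact. BIL and BSQ are accepted on read.
#'     Wavelengths (nm) go in the header's `wavelength` list and the signal
#'     kind in a `signal kind` entry.}
#'   \item{TIFF}{a multi-page 32-bit float TIFF (one page per band) at
#'     `path`, with a plain-text wavelength sidecar at
#'     `<path>.wavelengths.txt`, one nm value per line, plus the signal kind
#'     at `<path>.signal.txt`. Float storage keeps about 7 significant
#'     digits.}
#' }
#'
#' @param cube A `spectral_cube`.
#' @param path Output path (data file; companions are derived from it).
#' @param format `"ENVI"` or `"TIFF"`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, format = c("ENVI", "TIFF")) {
  stopifnot(inherits(cube, "spectral_cube"))
  format <- match.arg(format)
  d <- dim(cube$data)
  if (format == "ENVI") {
    hdr <- c(
      "ENVI",
      sprintf("samples = %d", d[2]),
      sprintf("lines = %d", d[1]),
      sprintf("bands = %d", d[3]),
      "header offset = 0",
      "file type = ENVI Standard",
      "data type = 5",
      "interleave = bsq",
      "byte order = 0",
      "wavelength units = Nanometers",
      sprintf("signal kind = %s", cube$signal_kind),
      sprintf("wavelength = { %s }",
              paste(format(cube$wavelengths, trim = TRUE, digits = 15),
                    collapse = ", "))
    )
    writeLines(hdr, paste0(path, ".hdr"))
    con <- file(path, "wb")
    on.exit(close(con))
    # BSQ: band-major, within a band row-major (line by line)
    for (b in seq_len(d[3])) {
      writeBin(as.vector(t(cube$data[, , b])), con,
               size = 8, endian = "little")
    }
  } else {
    pages <- lapply(seq_len(d[3]), function(b) cube$data[, , b])
    # float TIFF pages; values may exceed 1 (reflectance ceiling 1.5, OD > 1)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    writeLines(format(cube$wavelengths, trim = TRUE, digits = 15),
               paste0(path, ".wavelengths.txt"))
    writeLines(cube$signal_kind, paste0(path, ".signal.txt"))
  }
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  get_scalar <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?mi)^\\s*", key, "\\s*=\\s*(\\S[^\n]*)"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) NULL else trimws(m[2])
  }
  get_list <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?si)", key, "\\s*=\\s*\\{([^}]*)\\}"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) return(NULL)
    as.numeric(strsplit(m[2], "[,\n]")[[1]])
  }
  list(
    samples = as.integer(get_scalar("samples")),
    lines = as.integer(get_scalar("lines")),
    bands = as.integer(get_scalar("bands")),
    data_type = as.integer(get_scalar("data type")),
    interleave = tolower(get_scalar("interleave")),
    byte_order = as.integer(get_scalar("byte order")),
    signal_kind = get_scalar("signal kind"),
    wavelength = get_list("wavelength")
  )
}

#' Read a hyperspectral cube from disk
#'
#' Counterpart of [write_cube()]. For ENVI, the header must declare the band
#' count and a wavelength list that agree; for TIFF, the wavelength sidecar
#' `<path>.wavelengths.txt` must exist and match the page count.
#'
#' @param path Path to the data file written by [write_cube()].
#' @param format `"ENVI"` or `"TIFF"`.
#' @return A `spectral_cube`.
#' @export
read_cube <- function(path, format = c("ENVI", "TIFF")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (format == "ENVI") {
    hdr_path <- paste0(path, ".hdr")
    if (!file.exists(hdr_path)) {
      stop(sprintf("format error: missing ENVI header %s", hdr_path),
           call. = FALSE)
    }
    h <- parse_envi_header(hdr_path)
    if (is.null(h$wavelength)) {
      stop("format error: ENVI header lacks a wavelength list", call. = FALSE)
    }
    if (length(h$wavelength) != h$bands) {
      stop(sprintf(
        "format error: header declares %d bands but %d wavelengths",
        h$bands, length(h$wavelength)), call. = FALSE)
    }
    if (!h$interleave %in% c("bsq", "bil")) {
      stop(sprintf("format error: unsupported interleave '%s'", h$interleave),
           call. = FALSE)
    }
    size <- switch(as.character(h$data_type), "4" = 4L, "5" = 8L,
                   stop(sprintf("format error: unsupported ENVI data type %d",
                                h$data_type), call. = FALSE))
    endian <- if (identical(h$byte_order, 1L)) "big" else "little"
    n <- h$samples * h$lines * h$bands
    con <- file(path, "rb")
    on.exit(close(con))
    vals <- readBin(con, "double", n = n, size = size, endian = endian)
    if (length(vals) != n) {
      stop("format error: cube file shorter than header declares", call. = FALSE)
    }
    data <- array(0, dim = c(h$lines, h$samples, h$bands))
    if (h$interleave == "bsq") {
      for (b in seq_len(h$bands)) {
        off <- (b - 1L) * h$samples * h$lines
        data[, , b] <- matrix(vals[off + seq_len(h$samples * h$lines)],
                              nrow = h$lines, byrow = TRUE)
      }
    } else { # bil: per line, band-major rows of samples
      a <- array(vals, dim = c(h$samples, h$bands, h$lines))
      data <- aperm(a, c(3, 1, 2))
    }
    kind <- if (is.null(h$signal_kind)) "RAW" else h$signal_kind
    spectral_cube(data, h$wavelength, kind, meta = list(source = path))
  } else {
    sidecar <- paste0(path, ".wavelengths.txt")
    if (!file.exists(sidecar)) {
      stop(sprintf("format error: missing wavelength sidecar %s", sidecar),
           call. = FALSE)
    }
    wl <- as.numeric(readLines(sidecar, warn = FALSE))
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) != length(wl)) {
      stop(sprintf("format error: %d TIFF pages but %d sidecar wavelengths",
                   length(pages), length(wl)), call. = FALSE)
    }
    kind_file <- paste0(path, ".signal.txt")
    kind <- if (file.exists(kind_file)) readLines(kind_file, warn = FALSE)[1]
            else "RAW"
    if (!kind %in% c("RAW", "REFLECTANCE", "ABSORBANCE")) kind <- "RAW"
    data <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
    for (b in seq_along(pages)) data[, , b] <- pages[[b]]
    spectral_cube(data, wl, kind, meta = list(source = path))
  }
}

#' Write a boolean mask as an 8-bit PNG
#'
#' Nonzero pixels encode TRUE.
#'
#' @param mask Logical matrix.
#' @param path Output PNG path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a boolean mask from an 8-bit PNG
#'
#' @param path PNG path; any nonzero pixel is TRUE.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0
}

# class <-> 8-bit PNG value map for label images (value / 255 in the file)
LABEL_PNG_CODES <- c(UNCLASSIFIED = 0L, DKK3_POSITIVE = 1L, NUCLEI = 2L,
                     BACKGROUND = 3L)

#' Write a label image as an 8-bit PNG
#'
#' Class-to-value map: UNCLASSIFIED = 0, DKK3_POSITIVE = 1, NUCLEI = 2,
#' BACKGROUND = 3 (stored as value/255). A CSV legend with the same map is
#' written alongside as `<path>.legend.csv`.
#'
#' @param classes Character matrix of class names (see [LABEL_CLASSES]).
#' @param path Output PNG path.
#' @export
write_label_image <- function(classes, path) {
  codes <- LABEL_PNG_CODES[classes]
  dim(codes) <- dim(classes)
  png::writePNG(codes / 255, path)
  utils::write.csv(
    data.frame(class = names(LABEL_PNG_CODES),
               value = unname(LABEL_PNG_CODES)),
    paste0(path, ".legend.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a label image written by [write_label_image()]
#'
#' @param path PNG path.
#' @return Character matrix of class names.
#' @export
read_label_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  codes <- as.integer(round(img * 255))
  cls <- names(LABEL_PNG_CODES)[match(codes, LABEL_PNG_CODES)]
  dim(cls) <- dim(img)
  cls
}
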