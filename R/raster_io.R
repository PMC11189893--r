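# Raster readers/writers. PNG and TIFF are accepted on input; outputs are
# TIFF (16-bit integer labels, 32-bit IEEE float maps). Intensities are kept
# on their native integer scale (0..255 or 0..65535); float TIFFs are read
# as-is.

raster_exts <- c("png", "tif", "tiff")

read_any_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8
    attr(img, "info") <- NULL
    list(pixels = img * (2^bits - 1), bits = bits)
  } else if (ext %in% c("tif", "tiff")) {
    # as.is=TRUE returns raw integers but rejects float TIFFs, which are
    # already on their physical scale
    is_float <- FALSE
    img <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
                    error = function(e) {
                      is_float <<- TRUE
                      tiff::readTIFF(path, info = TRUE)
                    })
    bits <- attr(img, "bits.per.sample") %||% 8
    attributes(img) <- list(dim = dim(img))
    if (is_float) list(pixels = img, bits = 32L)
    else list(pixels = img, bits = bits)
  } else {
    stop("unsupported raster format '", ext, "' (expected PNG or TIFF): ",
         path)
  }
}

#' Read an intensity image
#'
#' Reads a grayscale or RGB raster (PNG or TIFF, 8- or 16-bit). An alpha
#' channel, if present, is dropped. Intensities are returned on their native
#' integer scale.
#'
#' @param path Path to a PNG or TIFF file.
#' @return A list of class `bb_image` with fields `name`, `pixels` (an H x W
#'   matrix or H x W x 3 array) and `bits`.
#' @export
read_raster <- function(path) {
  r <- read_any_raster(path)
  px <- r$pixels
  if (length(dim(px)) == 3) {
    if (dim(px)[3] == 2) px <- px[, , 1] # gray + alpha
    else if (dim(px)[3] == 4) px <- px[, , 1:3] # rgb + alpha
    else if (dim(px)[3] == 1) px <- px[, , 1]
  }
  if (any(!is.finite(px)) || any(px < 0))
    stop("image intensities must be finite and non-negative: ", path)
  structure(list(name = tools::file_path_sans_ext(basename(path)),
                 pixels = px, bits = r$bits),
            class = "bb_image")
}

#' Read an integer label raster
#'
#' Reads a single-channel integer label map (0 = background, each positive
#' integer one region). RGB input is rejected because channel triples do not
#' define unique region IDs.
#'
#' @param path Path to a single-channel PNG or TIFF file.
#' @return An integer matrix.
#' @export
read_label_raster <- function(path) {
  r <- read_any_raster(path)
  px <- r$pixels
  if (length(dim(px)) == 3) {
    if (dim(px)[3] == 2) px <- px[, , 1]
    else stop("label rasters must be single-channel; got ", dim(px)[3],
              " channels: ", path)
  }
  if (any(px != round(px)) || any(px < 0))
    stop("label raster contains non-integer or negative values: ", path)
  matrix(as.integer(round(px)), nrow(px), ncol(px))
}

#' Write an integer label raster
#'
#' Writes a label map as an uncompressed 16-bit single-channel TIFF. The
#' write/read round trip is exact for IDs up to 65535.
#'
#' @param map Integer matrix (values in 0..65535).
#' @param path Output path (`.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_label_raster <- function(map, path) {
  if (any(map < 0) || any(map > 65535) || any(map != round(map)))
    stop("label maps must hold integers in 0..65535")
  if (!tolower(tools::file_ext(path)) %in% c("tif", "tiff"))
    stop("label rasters are written as TIFF; use a .tif path")
  tiff::writeTIFF(map / 65535, path, bits.per.sample = 16,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' Write a 32-bit float raster
#'
#' Writes a real-valued map (probability or distance) as an uncompressed
#' single-strip 32-bit IEEE-float TIFF, losslessly at float32 precision.
#' Values are stored as-is; no scaling is applied.
#'
#' @param map Numeric matrix.
#' @param path Output path (`.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_float_raster <- function(map, path) {
  if (!is.matrix(map) || !is.numeric(map)) stop("map must be a numeric matrix")
  if (!tolower(tools::file_ext(path)) %in% c("tif", "tiff"))
    stop("float rasters are written as TIFF; use a .tif path")
  h <- nrow(map); w <- ncol(map)
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  data_off <- 8L
  nbytes <- h * w * 4L
  ifd_off <- data_off + nbytes
  # header
  writeBin(charToRaw("II"), con)
  wr2(42L)
  wr4(ifd_off)
  # pixel data, scanline (row-major) order
  writeBin(as.vector(t(map)), con, size = 4, endian = "little")
  # IFD: tag, type (3 = SHORT, 4 = LONG), count, value
  entry <- function(tag, type, count, value) {
    wr2(tag); wr2(type); wr4(count)
    if (type == 3L) { wr2(value); wr2(0L) } else wr4(value)
  }
  tags <- list(
    c(256L, 4L, 1L, w),        # ImageWidth
    c(257L, 4L, 1L, h),        # ImageLength
    c(258L, 3L, 1L, 32L),      # BitsPerSample
    c(259L, 3L, 1L, 1L),       # Compression: none
    c(262L, 3L, 1L, 1L),       # Photometric: BlackIsZero
    c(273L, 4L, 1L, data_off), # StripOffsets
    c(277L, 3L, 1L, 1L),       # SamplesPerPixel
    c(278L, 4L, 1L, h),        # RowsPerStrip
    c(279L, 4L, 1L, nbytes),   # StripByteCounts
    c(339L, 3L, 1L, 3L)        # SampleFormat: IEEE float
  )
  wr2(length(tags))
  for (tg in tags) entry(tg[1], tg[2], tg[3], tg[4])
  wr4(0L) # no next IFD
  invisible(path)
}

#' Read a 32-bit float raster
#'
#' @param path Path to a float TIFF written by [write_float_raster()] or any
#'   IEEE-float TIFF.
#' @return A numeric matrix.
#' @export
read_float_raster <- function(path) {
  img <- tiff::readTIFF(path)
  attributes(img) <- list(dim = dim(img))
  img
}

# locate a raster named `name` (any supported extension) inside `dir`
find_raster <- function(dir, name) {
  for (ext in raster_exts) {
    p <- file.path(dir, paste0(name, ".", ext))
    if (file.exists(p)) return(p)
  }
  NULL
}

list_rasters <- function(dir) {
  if (!dir.exists(dir)) return(character(0))
  fs <- list.files(dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
  sort(fs)
}
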