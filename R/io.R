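# Movie I/O: multi-frame 32-bit float TIFF for interchange, and a
# serialized R container that round-trips all metadata bit-exactly.

#' Write a movie as multi-frame 32-bit float TIFF
#'
#' One directory entry per frame, 32-bit floating point samples. The TIFF
#' writer stores samples in `[0, 1]`, so values are min-max normalised by
#' default (the affine transform is returned as an attribute); TIFF also
#' carries no frame-rate metadata, so reading it back requires the rate to
#' be supplied. The native container ([writeMovieRDS()]) is the lossless
#' path.
#'
#' @param movie a [VoltageMovie]
#' @param path output file
#' @param normalize min-max scale samples into `[0, 1]` (default); set
#'   `FALSE` only for data already in range
#' @return `path`, invisibly, with attributes `offset` and `scale` such
#'   that `original = stored * scale + offset`
#' @export
writeMovieTIFF <- function(movie, path, normalize = TRUE) {
  stopifnot(is(movie, "VoltageMovie"))
  dat <- movieData(movie)
  offset <- 0; scale <- 1
  if (normalize) {
    rng <- range(dat)
    offset <- rng[1]
    scale <- if (diff(rng) > 0) diff(rng) else 1
    dat <- (dat - offset) / scale
  }
  frames <- lapply(seq_len(nFrames(movie)), function(t) dat[t, , ])
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  invisible(structure(path, offset = offset, scale = scale))
}

#' Write a movie to the native serialized container
#'
#' Stores the data array together with frame rate, pixel pitch, valid
#' mask, and an optional generating spec; [readMovie()] restores it
#' bit-exactly.
#'
#' @param movie a [VoltageMovie]
#' @param path output file (conventionally `.rds`)
#' @param spec optional [movieSpec()] to embed for provenance
#' @return `path`, invisibly
#' @export
writeMovieRDS <- function(movie, path, spec = NULL) {
  stopifnot(is(movie, "VoltageMovie"))
  saveRDS(list(container = "cortexwave-movie", version = 1L,
               data = movieData(movie), frameRate = frameRate(movie),
               pixelPitch = pixelPitch(movie), validMask = validMask(movie),
               spec = spec),
          path)
  invisible(path)
}

#' Read a movie from TIFF or the native container
#'
#' @param path a multi-frame TIFF (`.tif`/`.tiff`) or a native container
#'   (`.rds`)
#' @param frameRate acquisition rate in Hz; required for TIFF input
#'   (errors if absent), ignored for the container
#' @param pixelPitch micrometres/pixel (TIFF input only)
#' @return a [VoltageMovie]
#' @export
readMovie <- function(path, frameRate = NULL, pixelPitch = NA_real_) {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (is.null(frameRate))
      stop("TIFF input carries no frame rate: supply 'frameRate'")
    frames <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(frames)) frames <- list(frames)
    d <- dim(frames[[1]])
    if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
      stop("non-uniform frame shapes in '", path, "'")
    dat <- array(0, dim = c(length(frames), d[1], d[2]))
    for (t in seq_along(frames)) dat[t, , ] <- frames[[t]]
    VoltageMovie(dat, frameRate = frameRate, pixelPitch = pixelPitch)
  } else if (ext == "rds") {
    x <- readRDS(path)
    if (!identical(x$container, "cortexwave-movie"))
      stop("'", path, "' is not a movie container")
    VoltageMovie(x$data, frameRate = x$frameRate, pixelPitch = x$pixelPitch,
                 validMask = x$validMask)
  } else stop("unsupported movie format: '.", ext, "'")
}

#' Read a region label map from a text grid or TIFF
#'
#' @param path whitespace-delimited integer grid (`.txt`) or TIFF label
#'   image
#' @return integer label matrix
#' @export
readRegionMap <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path, as.is = TRUE)
    storage.mode(m) <- "integer"
    m
  } else {
    as.matrix(read.table(path))
  }
}

#' Read a hierarchy-index table
#'
#' @param path delimited text with columns `region` and `hierarchyIndex`
#' @return data.frame
#' @export
readHierarchyTable <- function(path) {
  h <- read.csv(path)
  if (!all(c("region", "hierarchyIndex") %in% names(h)))
    stop("hierarchy table needs columns 'region' and 'hierarchyIndex'")
  h
}
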