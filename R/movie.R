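#' Movie stack container
#'
#' A `movie_stack` holds a greyscale high-speed video as a 3-D integer array
#' (frame, row, col) together with its frame rate. It is the raw unit of the
#' ciliary-beat-frequency analysis: each pixel's intensity trace over frames
#' is a time series whose dominant oscillation is the beat frequency.
#'
#' @param frames 3-D numeric array, dimension (frame, row, col). Intensities
#'   must lie within the declared bit depth.
#' @param fps frame rate in Hz (> 0).
#' @param bit_depth bits per sample, 8 or 16; intensities must be in
#'   `[0, 2^bit_depth - 1]`.
#' @return An object of class `movie_stack` with elements `frames`, `fps`,
#'   `frame_count`, `height`, `width`, `bit_depth`.
#' @export
movie_stack <- function(frames, fps, bit_depth = 8L) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frames must be a 3-D array (frame, row, col)")
  d <- dim(frames)
  if (d[1] < 2L) stop("a movie needs at least 2 frames")
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("fps must be a positive number")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  rng <- range(frames)
  if (any(!is.finite(rng))) stop("frames contain non-finite intensities")
  if (rng[1] < 0 || rng[2] > 2^bit_depth - 1)
    stop("intensities outside the declared bit depth")
  structure(
    list(frames = frames, fps = fps, frame_count = d[1],
         height = d[2], width = d[3], bit_depth = as.integer(bit_depth)),
    class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  cat(sprintf("movie_stack: %d frames of %dx%d px, %g fps, %d-bit\n",
              x$frame_count, x$height, x$width, x$fps, x$bit_depth))
  invisible(x)
}

#' Load a cilia movie from disk
#'
#' Reads a multi-frame greyscale TIFF, or a raw binary intensity dump with a
#' JSON sidecar declaring `{"shape": [frames, height, width], "dtype":
#' "uint8"|"uint16", "fps": <Hz>}`. The sidecar is `<path>.json` or the file
#' itself when `path` ends in `.json`.
#'
#' @param path movie file path (`.tif`/`.tiff`, `.bin`/`.raw`, or the sidecar
#'   `.json`).
#' @param fps frame rate in Hz; overrides any sidecar value. Required for
#'   TIFF input.
#' @return A [movie_stack()].
#' @export
load_movie <- function(path, fps = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (is.null(fps)) stop("fps must be given for TIFF input")
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (any(vapply(pages, function(p) length(dim(p)) > 2L, logical(1))))
      stop("not greyscale: multi-channel TIFF")
    dims <- vapply(pages, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("frames of unequal shape")
    bd <- if (max(vapply(pages, max, numeric(1))) > 255) 16L else 8L
    frames <- aperm(simplify2array(pages), c(3, 1, 2))
    return(movie_stack(frames, fps = fps, bit_depth = bd))
  }
  sidecar <- if (ext == "json") path else paste0(path, ".json")
  if (!file.exists(sidecar)) stop("no JSON sidecar found for raw input: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  datafile <- if (ext == "json") {
    if (!is.null(meta$data)) file.path(dirname(path), meta$data)
    else sub("\\.json$", "", path)
  } else path
  if (!file.exists(datafile)) stop("raw data file not found: ", datafile)
  shp <- as.integer(meta$shape)
  if (length(shp) != 3L) stop("sidecar shape must be [frames, height, width]")
  dtype <- if (is.null(meta$dtype)) "uint8" else meta$dtype
  sz <- switch(dtype, uint8 = 1L, uint16 = 2L,
               stop("unsupported dtype: ", dtype))
  vals <- readBin(datafile, what = "integer", n = prod(shp), size = sz,
                  signed = FALSE, endian = "little")
  if (length(vals) != prod(shp)) stop("raw file shorter than declared shape")
  # row-major (C order) frame, row, col layout
  frames <- aperm(array(vals, dim = rev(shp)), 3:1)
  fps_use <- if (!is.null(fps)) fps else meta$fps
  if (is.null(fps_use)) stop("fps not given and absent from sidecar")
  movie_stack(frames, fps = fps_use,
              bit_depth = if (sz == 1L) 8L else 16L)
}

#' Write a movie stack to disk
#'
#' Writes either a multi-page greyscale TIFF or a raw little-endian binary
#' dump plus JSON sidecar, the two container formats [load_movie()] reads.
#'
#' @param stack a [movie_stack()].
#' @param path output path; format chosen from the extension (`.tif`/`.tiff`
#'   vs anything else, which gets `<path>` + `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_movie <- function(stack, path) {
  stopifnot(inherits(stack, "movie_stack"))
  ext <- tolower(tools::file_ext(path))
  maxv <- 2^stack$bit_depth - 1
  if (ext %in% c("tif", "tiff")) {
    pages <- lapply(seq_len(stack$frame_count),
                    function(i) stack$frames[i, , ] / maxv)
    tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth)
  } else {
    vals <- as.integer(round(aperm(stack$frames, 3:1)))
    writeBin(vals, path, size = stack$bit_depth / 8L, endian = "little")
    jsonlite::write_json(
      list(shape = c(stack$frame_count, stack$height, stack$width),
           dtype = if (stack$bit_depth == 8L) "uint8" else "uint16",
           fps = stack$fps),
      paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}
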