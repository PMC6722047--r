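#' Subsample pixels from a movie stack
#'
#' Retains the pixels on a regular grid (`offset + k * step` on each axis)
#' and extracts each retained pixel's full intensity time series. With step 8
#' on both axes the sampling ratio is 1/64, the working resolution of the
#' beat-frequency analysis.
#'
#' @param stack a [movie_stack()].
#' @param step_row,step_col sampling step per axis, integers in 1..8.
#' @param offset integer vector `(row, col)` of 0-based grid offsets, each
#'   `< step` on its axis.
#' @return A `pixel_series_set`: list with `rows`, `cols` (1-based pixel
#'   coordinates per retained series), `series` (frame_count x n_pixels
#'   matrix, one time series per column), `fps`, `sampling_step`,
#'   `sampling_ratio`.
#' @export
subsample_pixels <- function(stack, step_row = 8L, step_col = 8L,
                             offset = c(0L, 0L)) {
  stopifnot(inherits(stack, "movie_stack"))
  step_row <- as.integer(step_row); step_col <- as.integer(step_col)
  if (step_row < 1L || step_row > 8L || step_col < 1L || step_col > 8L)
    stop("sampling steps must be integers in 1..8")
  if (offset[1] < 0L || offset[1] >= step_row ||
      offset[2] < 0L || offset[2] >= step_col)
    stop("offset must be nonnegative and smaller than the step")
  rows <- seq.int(1L + offset[1], stack$height, by = step_row)
  cols <- seq.int(1L + offset[2], stack$width, by = step_col)
  grid <- expand.grid(row = rows, col = cols)
  series <- matrix(stack$frames[, rows, cols, drop = FALSE],
                   nrow = stack$frame_count)
  structure(
    list(rows = grid$row, cols = grid$col, series = series, fps = stack$fps,
         sampling_step = c(step_row, step_col),
         sampling_ratio = 1 / (step_row * step_col)),
    class = "pixel_series_set")
}

# One-sided periodogram PSD of mean-centered series (columns of `y`).
# power[k] = |DFT_k|^2 / N^2, doubled at interior bins, so that
# sum(power) over the reported one-sided grid equals the population
# variance of the centered series (Parseval). DC is exactly 0 after
# centering. Returns list(freq, power) restricted to [0, fmax].
periodogram_psd <- function(y, fps, fmax = 50) {
  y <- if (is.matrix(y)) y else cbind(y)
  n <- nrow(y)
  yc <- sweep(y, 2L, colMeans(y))
  ft <- stats::mvfft(yc)
  nk <- floor(n / 2) + 1L
  pw <- Mod(ft[seq_len(nk), , drop = FALSE])^2 / n^2
  dbl <- rep(2, nk)
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[nk] <- 1
  pw <- pw * dbl
  freq <- (seq_len(nk) - 1L) * fps / n
  keep <- freq <= min(fmax, fps / 2) + 1e-12
  list(freq = freq[keep], power = pw[keep, , drop = FALSE])
}

spectral_density <- function(freq, power, smoothed = FALSE) {
  if (any(diff(freq) <= 0)) stop("frequency grid must be strictly increasing")
  if (any(power < 0)) stop("spectral power must be nonnegative")
  structure(list(freq = freq, power = power, smoothed = smoothed),
            class = "spectral_density")
}

#' Per-pixel spectrum of an intensity time series
#'
#' The pixel-level step of the beat-frequency analysis: the series is
#' mean-centered (removing the DC intensity offset), its periodogram power
#' spectral density is computed by FFT on the grid `k * fps / N` restricted
#' to 0 to `min(50, fps/2)` Hz, and the raw spectrum is smoothed with a
#' penalized B-spline and clipped at zero.
#'
#' @param series numeric intensity-over-time vector (length >= 8).
#' @param fps sampling rate in Hz.
#' @param smooth_params list of P-spline settings passed to
#'   [pspline_smooth()]: `lambda` (default 1), `knot_spacing`,
#'   `penalty_order`. Set `lambda = 0` for an (essentially) unsmoothed fit.
#' @param smooth if `FALSE`, return the raw periodogram (used by tests and
#'   by oracles; the analysis pipeline keeps it `TRUE`).
#' @return a `spectral_density`: list with `freq` (Hz), `power`
#'   (nonnegative), `smoothed` flag. When the input is a matrix (one series
#'   per column) `power` is a matrix with matching columns.
#' @export
pixel_spectrum <- function(series, fps, smooth_params = list(), smooth = TRUE) {
  y <- if (is.matrix(series)) series else cbind(series)
  if (nrow(y) < 8L) stop("series must have at least 8 frames")
  if (!all(is.finite(y))) stop("series contains non-finite values")
  if (fps <= 0) stop("fps must be positive")
  pg <- periodogram_psd(y, fps)
  pw <- pg$power
  if (smooth) {
    sp <- utils::modifyList(list(lambda = 1, knot_spacing = 1L,
                                 penalty_order = 2L), smooth_params)
    pw <- pspline_smooth(pw, pg$freq, lambda = sp$lambda,
                         knot_spacing = sp$knot_spacing,
                         penalty_order = sp$penalty_order)
  }
  if (!is.matrix(series)) pw <- drop(pw)
  spectral_density(pg$freq, pw, smoothed = smooth)
}

#' Movie-level median spectrum
#'
#' Aggregates per-pixel spectra into one spectrum per movie: the median
#' spectral density over pixels at each frequency, smoothed again with a
#' penalized B-spline and clipped at zero. The median makes the movie
#' spectrum robust to saturated or non-beating pixels.
#'
#' @param pixel_spectra a list of `spectral_density` objects sharing one
#'   frequency grid, or a single `spectral_density` whose `power` is a
#'   matrix (one pixel per column).
#' @inheritParams pixel_spectrum
#' @return a smoothed `spectral_density` with vector `power`.
#' @export
movie_spectrum <- function(pixel_spectra, smooth_params = list(),
                           smooth = TRUE) {
  if (inherits(pixel_spectra, "spectral_density")) {
    freq <- pixel_spectra$freq
    pmat <- if (is.matrix(pixel_spectra$power)) pixel_spectra$power
            else cbind(pixel_spectra$power)
  } else {
    if (!is.list(pixel_spectra) || length(pixel_spectra) == 0L)
      stop("pixel_spectra must be a nonempty list of spectra")
    freq <- pixel_spectra[[1L]]$freq
    for (s in pixel_spectra)
      if (length(s$freq) != length(freq) || any(s$freq != freq))
        stop("all pixel spectra must share one frequency grid")
    pmat <- vapply(pixel_spectra, `[[`, numeric(length(freq)), "power")
  }
  med <- apply(pmat, 1L, stats::median)
  if (smooth) {
    sp <- utils::modifyList(list(lambda = 1, knot_spacing = 1L,
                                 penalty_order = 2L), smooth_params)
    med <- pspline_smooth(med, freq, lambda = sp$lambda,
                          knot_spacing = sp$knot_spacing,
                          penalty_order = sp$penalty_order)
  }
  spectral_density(freq, med, smoothed = smooth)
}

#' Dominant beat frequency of a movie spectrum
#'
#' Finds the dominant frequency as the grid point of maximal spectral power
#' within the physiological search band (default 2.5 to 25 Hz; the floor
#' excludes slow mucus movement, the ceiling high-frequency noise). The peak
#' band is the maximal interval around the dominant frequency over which
#' power decreases strictly moving away from the peak (a plateau or a zero
#' power value terminates it), and the weighted frequency is the
#' power-weighted mean frequency over the peak band.
#'
#' @param spectrum a `spectral_density` with vector `power` (typically the
#'   output of [movie_spectrum()]).
#' @param band numeric `(low, high)` search band in Hz, default `c(2.5, 25)`.
#' @return a `cbf_result`: list with `dominant_frequency`, `peak_band`
#'   (`c(low, high)` Hz), `weighted_frequency`, `peak_power`, `band_limits`,
#'   `no_peak` flag. When no power is present in the band, `no_peak` is
#'   `TRUE` and the frequencies are `NA`.
#' @export
dominant_peak <- function(spectrum, band = c(2.5, 25)) {
  stopifnot(inherits(spectrum, "spectral_density"))
  freq <- spectrum$freq
  pw <- spectrum$power
  if (is.matrix(pw)) stop("dominant_peak needs a single (movie) spectrum")
  if (length(band) != 2L || band[1] >= band[2]) stop("invalid band")
  inband <- which(freq >= band[1] & freq <= band[2])
  if (length(inband) == 0L) stop("band contains no grid points")
  res <- list(dominant_frequency = NA_real_, peak_band = c(NA_real_, NA_real_),
              weighted_frequency = NA_real_, peak_power = NA_real_,
              band_limits = band, no_peak = TRUE)
  if (all(pw[inband] <= 0)) return(structure(res, class = "cbf_result"))
  imax <- inband[which.max(pw[inband])]  # which.max: lowest index wins ties
  # extend while strictly decreasing away from the peak; stop at a
  # non-decrease (plateau within relative tol 1e-12) or at zero power
  dec <- function(a, b) b < a * (1 - 1e-12) && b > 0
  lo <- imax
  while (lo > 1L && dec(pw[lo], pw[lo - 1L])) lo <- lo - 1L
  hi <- imax
  while (hi < length(freq) && dec(pw[hi], pw[hi + 1L])) hi <- hi + 1L
  idx <- lo:hi
  res$dominant_frequency <- freq[imax]
  res$peak_band <- c(freq[lo], freq[hi])
  res$weighted_frequency <- sum(freq[idx] * pw[idx]) / sum(pw[idx])
  res$peak_power <- pw[imax]
  res$no_peak <- FALSE
  structure(res, class = "cbf_result")
}

#' @export
print.cbf_result <- function(x, ...) {
  if (x$no_peak) {
    cat("cbf_result: no peak in band",
        sprintf("[%g, %g] Hz\n", x$band_limits[1], x$band_limits[2]))
  } else {
    cat(sprintf(
      "cbf_result: dominant %.3f Hz (power %.4g), peak band [%.3f, %.3f] Hz, weighted %.3f Hz\n",
      x$dominant_frequency, x$peak_power, x$peak_band[1], x$peak_band[2],
      x$weighted_frequency))
  }
  invisible(x)
}

#' Full ciliary-beat-frequency analysis of one movie
#'
#' Runs the whole pipeline: subsample pixels on a regular grid, compute and
#' P-spline-smooth each pixel's periodogram, take the per-frequency median
#' across pixels, smooth the median, and locate the dominant peak in the
#' physiological band.
#'
#' @param stack a [movie_stack()] (or a path accepted by [load_movie()],
#'   with `fps` forwarded).
#' @param step_row,step_col,offset pixel subsampling grid, see
#'   [subsample_pixels()].
#' @param band search band in Hz, default `c(2.5, 25)`.
#' @param smooth_params P-spline settings shared by the pixel-level and
#'   movie-level smoothers (override per level via `pixel_smooth` /
#'   `movie_smooth`).
#' @param pixel_smooth,movie_smooth optional per-level overrides of
#'   `smooth_params`.
#' @param fps frame rate, only used when `stack` is a path.
#' @return a `cbf_result` (see [dominant_peak()]) with the movie spectrum
#'   attached as attribute `spectrum` and the raw (unsmoothed) median as
#'   attribute `spectrum_raw`.
#' @export
cbf <- function(stack, step_row = 8L, step_col = 8L, offset = c(0L, 0L),
                band = c(2.5, 25), smooth_params = list(),
                pixel_smooth = smooth_params, movie_smooth = smooth_params,
                fps = NULL) {
  if (is.character(stack)) stack <- load_movie(stack, fps = fps)
  pix <- subsample_pixels(stack, step_row, step_col, offset)
  spec <- pixel_spectrum(pix$series, stack$fps, smooth_params = pixel_smooth)
  raw_med <- movie_spectrum(spec, smooth = FALSE)
  mspec <- movie_spectrum(spec, smooth_params = movie_smooth)
  out <- dominant_peak(mspec, band = band)
  attr(out, "spectrum") <- mspec
  attr(out, "spectrum_raw") <- raw_med
  out
}

#' Write a CBF result as JSON (and optionally the spectrum as TSV)
#'
#' @param result a `cbf_result` from [cbf()] or [dominant_peak()].
#' @param path output JSON path.
#' @param spectrum_tsv optional path for a TSV of the movie spectrum
#'   (`freq_hz`, `power_raw`, `power_smooth`); requires a result produced by
#'   [cbf()].
#' @return `path`, invisibly.
#' @export
write_cbf_result <- function(result, path, spectrum_tsv = NULL) {
  stopifnot(inherits(result, "cbf_result"))
  jsonlite::write_json(
    list(dominant_frequency_hz = result$dominant_frequency,
         weighted_frequency_hz = result$weighted_frequency,
         peak_band_hz = result$peak_band,
         peak_power = result$peak_power,
         no_peak_flag = result$no_peak),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(spectrum_tsv)) {
    sm <- attr(result, "spectrum"); rw <- attr(result, "spectrum_raw")
    if (is.null(sm) || is.null(rw))
      stop("spectrum TSV needs a result produced by cbf()")
    utils::write.table(
      data.frame(freq_hz = sm$freq, power_raw = rw$power,
                 power_smooth = sm$power),
      spectrum_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
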