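test_that("pixel subsampling retains the expected grid", {
  m <- movie_stack(array(seq_len(4 * 16 * 16) %% 256, dim = c(4, 16, 16)),
                   fps = 100)
  ps <- subsample_pixels(m, 8, 8)
  expect_equal(ncol(ps$series), 4)  # 2 x 2 retained
  expect_equal(ps$sampling_ratio, 1 / 64)
  ps1 <- subsample_pixels(m, 1, 1)
  expect_equal(ncol(ps1$series), 256)
  expect_equal(ps1$sampling_ratio, 1)

  m5 <- movie_stack(array(0, dim = c(2, 5, 5)), fps = 10)
  ps5 <- subsample_pixels(m5, 2, 2)
  # brute-force enumeration of retained 0-based indices {0,2,4} per axis
  expect_equal(ncol(ps5$series), 9)
  expect_equal(sort(unique(ps5$rows)), c(1, 3, 5))

  # series are the actual pixel traces
  idx <- which(ps$rows == 9 & ps$cols == 9)
  expect_equal(ps$series[, idx], m$frames[, 9, 9])

  expect_error(subsample_pixels(m, 9, 1), "1..8")
  expect_error(subsample_pixels(m, 2, 2, offset = c(2, 0)), "offset")
})

test_that("raw periodogram matches the direct DFT definition on a pure cosine", {
  n <- 512; fps <- 100
  t <- seq_len(n) - 1
  y <- 128 + 30 * cos(2 * pi * 41 * t / n)  # bin 41 = 8.0078 Hz
  sp <- pixel_spectrum(y, fps, smooth = FALSE)
  expect_equal(sp$power, brute_periodogram(y)[seq_along(sp$freq)],
               tolerance = 1e-10)
  off_dc <- sp$power[-1]
  expect_equal(sp$freq[-1][which.max(off_dc)], 41 * fps / n)
})

test_that("centering kills a constant series and Parseval holds on noise", {
  sp <- pixel_spectrum(rep(128, 512), 100, smooth = FALSE)
  expect_true(all(sp$power == 0))

  set.seed(7)
  y <- rnorm(512, 100, 4)
  sp <- pixel_spectrum(y, 100, smooth = FALSE)
  expect_equal(sum(sp$power), mean((y - mean(y))^2), tolerance = 1e-9)

  expect_error(pixel_spectrum(rnorm(4), 100), "at least 8")
  expect_error(pixel_spectrum(c(rnorm(511), NA), 100), "non-finite")
})

test_that("frequency grid spans 0 to min(50, fps/2)", {
  sp <- pixel_spectrum(rnorm(512), 100, smooth = FALSE)
  expect_equal(max(sp$freq), 50)
  expect_equal(sp$freq[2] - sp$freq[1], 100 / 512)
  sp2 <- pixel_spectrum(rnorm(64), 20, smooth = FALSE)
  expect_lte(max(sp2$freq), 10)
})

test_that("movie spectrum is the per-frequency median, robust to outliers", {
  freq <- seq(0, 50, by = 0.5)
  mk <- function(v) structure(list(freq = freq,
                                   power = rep(v, length(freq)),
                                   smoothed = FALSE),
                              class = "spectral_density")
  med <- movie_spectrum(list(mk(1), mk(5), mk(100)), smooth = FALSE)
  expect_true(all(med$power == 5))
  # median of identical spectra is each input
  med2 <- movie_spectrum(list(mk(3), mk(3), mk(3)), smooth = FALSE)
  expect_true(all(med2$power == 3))
  # permutation invariance over pixels
  med3 <- movie_spectrum(list(mk(100), mk(1), mk(5)), smooth = FALSE)
  expect_equal(med3$power, med$power)
  expect_error(movie_spectrum(list()), "nonempty")
  bad <- mk(1); bad$freq <- freq + 0.1
  expect_error(movie_spectrum(list(mk(1), bad)), "grid")
})

test_that("singleton movie spectrum equals the smoothed input spectrum", {
  set.seed(3)
  y <- rnorm(512, 128, 5)
  raw <- pixel_spectrum(y, 100, smooth = FALSE)
  expect_equal(movie_spectrum(list(raw))$power,
               pspline_smooth(raw$power, raw$freq))
})

test_that("desynchronized beating pixels aggregate to one movie peak", {
  # many random-phase cosines at a common frequency: the median spectrum's
  # off-DC argmax must sit at the shared beat bin (oracle: unsmoothed median)
  n <- 512; fps <- 100; npix <- 300
  set.seed(11)
  t <- seq_len(n) - 1
  ser <- vapply(runif(npix, 0, 2 * pi),
                function(ph) 128 + 20 * cos(2 * pi * 8 * t / fps + ph) +
                  rnorm(n, 0, 5),
                numeric(n))
  spec <- pixel_spectrum(ser, fps, smooth = FALSE)
  med <- movie_spectrum(spec, smooth = FALSE)
  expect_equal(med$freq[which.max(med$power)],
               med$freq[which.min(abs(med$freq - 8))])
})

test_that("dominant peak matches the exhaustive-scan worked example", {
  freq <- as.numeric(0:50)
  pw <- numeric(51)
  pw[c(1, 6, 7, 8, 9, 10, 30) + 1] <- c(10, 3, 2, 5, 4, 1, 7)
  sp <- structure(list(freq = freq, power = pw, smoothed = TRUE),
                  class = "spectral_density")
  r <- dominant_peak(sp)
  expect_false(r$no_peak)
  expect_equal(r$dominant_frequency, 8)   # 1 Hz and 30 Hz outside band
  expect_equal(r$peak_band, c(7, 10))
  expect_equal(r$weighted_frequency, 100 / 12)
  expect_equal(r$peak_power, 5)
  expect_true(r$weighted_frequency >= r$peak_band[1] &&
                r$weighted_frequency <= r$peak_band[2])
})

test_that("degenerate peaks and empty bands are handled", {
  freq <- as.numeric(0:50)
  pw <- numeric(51); pw[11] <- 4
  sp <- structure(list(freq = freq, power = pw, smoothed = TRUE),
                  class = "spectral_density")
  r <- dominant_peak(sp)
  expect_equal(r$dominant_frequency, 10)
  expect_equal(r$peak_band, c(10, 10))
  expect_equal(r$weighted_frequency, 10)

  none <- dominant_peak(structure(
    list(freq = freq, power = numeric(51), smoothed = TRUE),
    class = "spectral_density"))
  expect_true(none$no_peak)
  expect_true(is.na(none$dominant_frequency))
  expect_error(dominant_peak(sp, band = c(25, 2.5)), "band")
})

test_that("power outside the band never changes the dominant frequency", {
  freq <- as.numeric(0:50)
  base <- numeric(51); base[9] <- 5; base[10] <- 2
  sp <- function(pw) structure(list(freq = freq, power = pw, smoothed = TRUE),
                               class = "spectral_density")
  r0 <- dominant_peak(sp(base))
  for (contam in list(c(2, 50), c(2, 500), c(31, 1000), c(49, 77))) {
    pw <- base; pw[contam[1]] <- contam[2]
    expect_equal(dominant_peak(sp(pw))$dominant_frequency,
                 r0$dominant_frequency)
  }
})

test_that("smoothing moves a strong isolated argmax by at most one bin", {
  freq <- seq(0, 50, by = 100 / 512)
  set.seed(5)
  for (i in 1:10) {
    pw <- runif(length(freq), 0, 1)
    peak_at <- sample(which(freq > 3 & freq < 24), 1)
    pw[peak_at] <- 5 * max(pw[-peak_at]) * 2
    sm <- pspline_smooth(pw, freq)
    expect_lte(abs(which.max(sm) - peak_at), 1)
  }
})

test_that("full cbf pipeline recovers a planted beat and writes output", {
  mv <- gen_beat_movie(8.0078125, fps = 100, n_frames = 512, height = 32,
                       width = 32, amplitude = 30, noise_sd = 10, seed = 5)
  r <- cbf(mv, step_row = 2, step_col = 2)
  expect_false(r$no_peak)
  expect_lte(abs(r$dominant_frequency - 8.0078125), 100 / 512 + 1e-9)
  expect_true(r$dominant_frequency >= r$peak_band[1] &&
                r$dominant_frequency <= r$peak_band[2])

  jf <- tempfile(fileext = ".json"); tf <- tempfile(fileext = ".tsv")
  write_cbf_result(r, jf, spectrum_tsv = tf)
  out <- jsonlite::read_json(jf)
  expect_equal(out$dominant_frequency_hz, r$dominant_frequency)
  expect_false(out$no_peak_flag)
  spec <- read.delim(tf)
  expect_named(spec, c("freq_hz", "power_raw", "power_smooth"))
  expect_equal(nrow(spec), 257)
})
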