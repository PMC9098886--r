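#' Time-frequency surface configuration
#'
#' Parameters of the smoothed spectral surface on which reconstructions are
#' compared. The surface is the (log-)magnitude short-time Fourier
#' transform, kernel-smoothed over the time-frequency grid so that it
#' estimates a smooth regression function of grid position.
#'
#' @param fft_length Frame/FFT length in samples (default 256).
#' @param hop Hop between frames in samples (default 128).
#' @param window Taper; `"hann"` or `"rect"`.
#' @param log_magnitude Take the log of the magnitude (default `TRUE`;
#'   stabilises variance across frequency).
#' @param smoothing_bandwidth Length-2 numeric: Gaussian kernel bandwidth in
#'   grid cells along (time, frequency); default `c(2, 2)`.
#' @param log_floor Magnitude floor applied before the log (default 1e-10).
#' @return A `surface_config` list.
#' @export
surface_config <- function(fft_length = 256, hop = 128, window = c("hann", "rect"),
                           log_magnitude = TRUE, smoothing_bandwidth = c(2, 2),
                           log_floor = 1e-10) {
  window <- match.arg(window)
  if (fft_length < 8) abort("`fft_length` must be >= 8.", class = "sdcl_validation_error")
  if (hop <= 0 || hop > fft_length) {
    abort("`hop` must satisfy 0 < hop <= fft_length.", class = "sdcl_validation_error")
  }
  if (length(smoothing_bandwidth) != 2 || any(smoothing_bandwidth <= 0)) {
    abort("`smoothing_bandwidth` must be two positive numbers.", class = "sdcl_validation_error")
  }
  structure(list(fft_length = as.integer(fft_length), hop = as.integer(hop),
                 window = window, log_magnitude = log_magnitude,
                 smoothing_bandwidth = as.double(smoothing_bandwidth),
                 log_floor = log_floor),
            class = "surface_config")
}

taper <- function(window, n) {
  switch(window,
         hann = 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)),
         rect = rep(1, n))
}

# Row-stochastic Nadaraya-Watson smoother matrix over grid indices 1..n.
nw_smoother <- function(n, bandwidth) {
  d <- outer(seq_len(n), seq_len(n), `-`)
  w <- exp(-0.5 * (d / bandwidth)^2)
  w / rowSums(w)
}

new_spectral_surface <- function(values, raw_values, times, freqs, config,
                                 cell_area) {
  structure(list(values = values, raw_values = raw_values, times = times,
                 freqs = freqs, config = config, cell_area = cell_area),
            class = "spectral_surface")
}

#' Compute a smoothed time-frequency surface
#'
#' Windows the signal into overlapping frames, takes the DFT magnitude
#' (optionally log-compressed) on the time x frequency grid, and smooths
#' the result with a separable Gaussian Nadaraya-Watson kernel. The smoothed
#' surface is the regression-function estimate that the stopping-rule test
#' compares across reconstructions.
#'
#' @param signal Numeric vector or [audio_signal()].
#' @param rate Sampling rate in Hz (taken from the signal if it is an
#'   [audio_signal()]).
#' @param config A [surface_config()].
#' @return A `spectral_surface`: `raw_values` and smoothed `values` are
#'   frames x frequency-bin matrices; `times` and `freqs` label the grid.
#' @export
compute_surface <- function(signal, rate = NULL, config = surface_config()) {
  if (inherits(signal, "audio_signal")) {
    rate <- signal$rate
    x <- signal$samples
  } else {
    x <- as.double(signal)
    if (is.null(rate)) abort("`rate` required for plain numeric input.",
                             class = "sdcl_validation_error")
  }
  nfft <- config$fft_length
  hop <- config$hop
  n <- length(x)
  if (n < nfft) {
    abort(sprintf("Signal (%d samples) shorter than one %d-sample frame.", n, nfft),
          class = "sdcl_validation_error")
  }
  n_frames <- 1L + (n - nfft) %/% hop
  win <- taper(config$window, nfft)
  n_bins <- nfft %/% 2L + 1L

  raw <- matrix(0, n_frames, n_bins)
  for (f in seq_len(n_frames)) {
    seg <- x[((f - 1L) * hop + 1L):((f - 1L) * hop + nfft)] * win
    mag <- Mod(fft(seg))[seq_len(n_bins)]
    raw[f, ] <- if (config$log_magnitude) log(pmax(mag, config$log_floor)) else mag
  }

  values <- smooth_surface(raw, config$smoothing_bandwidth)
  new_spectral_surface(
    values = values, raw_values = raw,
    times = (seq_len(n_frames) - 1L) * hop / rate + nfft / (2 * rate),
    freqs = (seq_len(n_bins) - 1L) * rate / nfft,
    config = config,
    cell_area = (hop / rate) * (rate / nfft)
  )
}

smooth_surface <- function(raw, bandwidth, st = NULL, sf = NULL) {
  st <- st %||% nw_smoother(nrow(raw), bandwidth[1])
  sf <- sf %||% nw_smoother(ncol(raw), bandwidth[2])
  st %*% raw %*% t(sf)
}

#' @export
print.spectral_surface <- function(x, ...) {
  cat(sprintf("<spectral_surface> %d frames x %d bins (%.3g s x %.4g Hz per cell)\n",
              nrow(x$values), ncol(x$values),
              if (length(x$times) > 1) diff(x$times[1:2]) else NA,
              if (length(x$freqs) > 1) diff(x$freqs[1:2]) else NA))
  invisible(x)
}

#' Surface as a tidy grid
#'
#' @param x A `spectral_surface`.
#' @param ... Unused.
#' @return Tibble with columns `time_s`, `freq_hz`, `value` (smoothed) and
#'   `raw`.
#' @export
tidy.spectral_surface <- function(x, ...) {
  grid <- expand.grid(time_s = x$times, freq_hz = x$freqs)
  tibble(
    time_s = grid$time_s, freq_hz = grid$freq_hz,
    value = as.vector(x$values), raw = as.vector(x$raw_values)
  )
}

#' @export
autoplot.spectral_surface <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$freq_hz,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log |X|") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}
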