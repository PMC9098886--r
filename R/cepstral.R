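#' Hz to mel conversion
#'
#' The standard mel scale: `mel(f) = 2595 * log10(1 + f/700)`.
#'
#' @param f Frequency (or vector of frequencies) in Hz, >= 0.
#' @return Mel value(s).
#' @examples
#' mel_scale(c(0, 700, 1000))
#' @export
mel_scale <- function(f) {
  if (any(f < 0)) abort("Frequencies must be non-negative.", class = "sdcl_validation_error")
  2595 * log10(1 + f / 700)
}

mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Framing and filterbank configuration for MFCC extraction
#'
#' @param frame_length Frame/FFT length in samples (default 2048).
#' @param hop Hop between frames in samples (default 512).
#' @param window Taper; `"hann"` (default) or `"rect"`.
#' @param n_mels Number of triangular mel filters (default 128).
#' @param n_coeffs Cepstral coefficients kept per frame, counting the
#'   energy (0th DCT) coefficient (default 13).
#' @param fmin,fmax Filterbank edge frequencies in Hz; `fmax = NULL` means
#'   the Nyquist frequency at use time.
#' @param log_floor Floor applied to filterbank energies before the log.
#' @return A `frame_config` list.
#' @export
frame_config <- function(frame_length = 2048, hop = 512, window = c("hann", "rect"),
                         n_mels = 128, n_coeffs = 13, fmin = 0, fmax = NULL,
                         log_floor = 1e-10) {
  window <- match.arg(window)
  if (hop <= 0 || hop > frame_length) {
    abort("`hop` must satisfy 0 < hop <= frame_length.", class = "sdcl_validation_error")
  }
  if (n_coeffs < 1 || n_coeffs > n_mels) {
    abort("`n_coeffs` must be in [1, n_mels].", class = "sdcl_validation_error")
  }
  if (!is.null(fmax) && fmin >= fmax) {
    abort("`fmin` must be below `fmax`.", class = "sdcl_validation_error")
  }
  structure(list(frame_length = as.integer(frame_length), hop = as.integer(hop),
                 window = window, n_mels = as.integer(n_mels),
                 n_coeffs = as.integer(n_coeffs), fmin = fmin, fmax = fmax,
                 log_floor = log_floor),
            class = "frame_config")
}

# Triangular mel filterbank: n_mels x n_bins weights, peaks 1, centres
# equally spaced on the mel scale between fmin and fmax.
mel_filterbank <- function(n_mels, n_bins, nfft, rate, fmin, fmax) {
  mel_pts <- seq(mel_scale(fmin), mel_scale(fmax), length.out = n_mels + 2)
  hz_pts <- mel_to_hz(mel_pts)
  bin_freqs <- (seq_len(n_bins) - 1) * rate / nfft
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- hz_pts[m]; ce <- hz_pts[m + 1]; hi <- hz_pts[m + 2]
    up <- (bin_freqs - lo) / max(ce - lo, .Machine$double.eps)
    down <- (hi - bin_freqs) / max(hi - ce, .Machine$double.eps)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal DCT-II matrix, n_out x n_in.
dct_matrix <- function(n_out, n_in) {
  k <- seq_len(n_out) - 1
  n <- seq_len(n_in) - 1
  m <- sqrt(2 / n_in) * cos(outer(k, n + 0.5) * pi / n_in)
  m[1, ] <- m[1, ] / sqrt(2)
  m
}

new_cepstral_sequence <- function(coeffs, frame_times) {
  structure(list(coeffs = coeffs, frame_times = frame_times),
            class = "cepstral_sequence")
}

#' @export
print.cepstral_sequence <- function(x, ...) {
  cat(sprintf("<cepstral_sequence> %d frames x %d coefficients\n",
              nrow(x$coeffs), ncol(x$coeffs)))
  invisible(x)
}

#' @export
dim.cepstral_sequence <- function(x) dim(x$coeffs)

#' Mel-frequency cepstral coefficients
#'
#' Per frame: taper, power spectrum, triangular mel filterbank (centres
#' equally spaced on the mel scale), log, orthonormal DCT-II, first
#' `n_coeffs` coefficients (the energy coefficient included).
#'
#' @param signal An [audio_signal()] with at least `frame_length` samples.
#' @param config A [frame_config()].
#' @return A `cepstral_sequence`: `coeffs` is a frames x `n_coeffs` matrix,
#'   `frame_times` gives the frame-centre times in seconds.
#' @export
mfcc <- function(signal, config = frame_config()) {
  stopifnot(inherits(signal, "audio_signal"))
  x <- signal$samples
  rate <- signal$rate
  nfft <- config$frame_length
  hop <- config$hop
  if (length(x) < nfft) {
    abort(sprintf("Signal (%d samples) shorter than one %d-sample frame.",
                  length(x), nfft), class = "sdcl_validation_error")
  }
  fmax <- config$fmax %||% (rate / 2)
  if (fmax > rate / 2 + 1e-9) {
    abort(sprintf("`fmax` (%g Hz) exceeds the Nyquist frequency (%g Hz).",
                  fmax, rate / 2), class = "sdcl_validation_error")
  }
  n_frames <- 1L + (length(x) - nfft) %/% hop
  n_bins <- nfft %/% 2L + 1L
  win <- taper(config$window, nfft)
  fb <- mel_filterbank(config$n_mels, n_bins, nfft, rate, config$fmin, fmax)
  dct <- dct_matrix(config$n_coeffs, config$n_mels)

  coeffs <- matrix(0, n_frames, config$n_coeffs)
  for (f in seq_len(n_frames)) {
    seg <- x[((f - 1L) * hop + 1L):((f - 1L) * hop + nfft)] * win
    pw <- Mod(fft(seg))[seq_len(n_bins)]^2
    loge <- log(pmax(as.vector(fb %*% pw), config$log_floor))
    coeffs[f, ] <- as.vector(dct %*% loge)
  }
  new_cepstral_sequence(coeffs, (seq_len(n_frames) - 1L) * hop / rate + nfft / (2 * rate))
}

as_coeff_matrix <- function(C) {
  if (inherits(C, "cepstral_sequence")) C$coeffs else as.matrix(C)
}

clamp_idx <- function(i, T_) pmin(pmax(i, 1L), T_)

#' Delta-cepstral coefficients
#'
#' `delta[t] = C[t + d] - C[t - d]`, with out-of-range frame indices
#' replaced by the nearest valid frame (edge replication), so the output
#' has as many frames as the input.
#'
#' @param C A `cepstral_sequence` or frames x coefficients matrix.
#' @param d Lag in frames (>= 1, < number of frames).
#' @return Frames x coefficients matrix of deltas.
#' @export
delta_cepstra <- function(C, d = 1) {
  M <- as_coeff_matrix(C)
  T_ <- nrow(M)
  if (d < 1 || d != round(d)) abort("`d` must be a positive integer.",
                                    class = "sdcl_validation_error")
  if (d >= T_) abort(sprintf("`d` (%d) must be below the frame count (%d).", d, T_),
                     class = "sdcl_validation_error")
  t_idx <- seq_len(T_)
  M[clamp_idx(t_idx + d, T_), , drop = FALSE] - M[clamp_idx(t_idx - d, T_), , drop = FALSE]
}

#' Shifted delta cepstra configuration
#'
#' @param d Delta lag in frames (default 2).
#' @param P Time shift between concatenated blocks, in frames (default 2).
#' @param K_blocks Number of concatenated delta blocks (default 2).
#' @return An `sdc_config` list.
#' @export
sdc_config <- function(d = 2, P = 2, K_blocks = 2) {
  if (d < 1 || P < 1 || K_blocks < 1) {
    abort("`d`, `P` and `K_blocks` must all be >= 1.", class = "sdcl_validation_error")
  }
  structure(list(d = as.integer(d), P = as.integer(P),
                 K_blocks = as.integer(K_blocks)),
            class = "sdc_config")
}

#' Shifted delta cepstra (plain differences)
#'
#' Block `j` (j = 0..K_blocks-1) at frame `t` is
#' `C[t + jP + d] - C[t + jP - d]`; the blocks are concatenated so each
#' output row holds `K_blocks` delta vectors of `N` coefficients each.
#' Out-of-range frames are edge-replicated.
#'
#' @param C A `cepstral_sequence` or frames x coefficients matrix.
#' @param cfg An [sdc_config()].
#' @return Frames x (N * K_blocks) matrix.
#' @export
sdc_plain <- function(C, cfg = sdc_config()) {
  M <- as_coeff_matrix(C)
  T_ <- nrow(M)
  if (cfg$d >= T_) abort(sprintf("`d` (%d) must be below the frame count (%d).",
                                 cfg$d, T_), class = "sdcl_validation_error")
  t_idx <- seq_len(T_)
  blocks <- lapply(seq_len(cfg$K_blocks) - 1L, function(j) {
    M[clamp_idx(t_idx + j * cfg$P + cfg$d, T_), , drop = FALSE] -
      M[clamp_idx(t_idx + j * cfg$P - cfg$d, T_), , drop = FALSE]
  })
  do.call(cbind, blocks)
}

#' Shifted delta cepstra (regression-adjusted form)
#'
#' The scale-adjusted SDC: block `j` at frame `t` is the local regression
#' slope `sum_{u=-d..d} u * C[t + jP + u] / sum_{u=-d..d} u^2`, i.e. the
#' least-squares slope of the cepstra over the `2d+1` frames centred at the
#' shifted position. This is the variant used to build the SDC-L feature.
#'
#' @inheritParams sdc_plain
#' @return Frames x (N * K_blocks) matrix.
#' @export
sdc_adjusted <- function(C, cfg = sdc_config()) {
  M <- as_coeff_matrix(C)
  T_ <- nrow(M)
  if (cfg$d >= T_) abort(sprintf("`d` (%d) must be below the frame count (%d).",
                                 cfg$d, T_), class = "sdcl_validation_error")
  t_idx <- seq_len(T_)
  u <- seq(-cfg$d, cfg$d)
  denom <- sum(u^2)
  blocks <- lapply(seq_len(cfg$K_blocks) - 1L, function(j) {
    acc <- matrix(0, T_, ncol(M))
    for (ui in u) {
      if (ui == 0) next
      acc <- acc + ui * M[clamp_idx(t_idx + j * cfg$P + ui, T_), , drop = FALSE]
    }
    acc / denom
  })
  do.call(cbind, blocks)
}

#' SDC-L: shifted delta cepstra in the reduced EMD subspace
#'
#' The composed feature: decompose the signal by [emd()], reconstruct the
#' low subspace from the first `K` IMFs, extract MFCCs of the
#' reconstruction, and apply the regression-adjusted SDC. Exactly equal to
#' the explicit composition
#' `sdc_adjusted(mfcc(reconstruct(emd(signal), K)), sdc_config)`.
#'
#' @param signal An [audio_signal()].
#' @param K Number of leading IMFs retained (>= 1), e.g. as chosen by
#'   [select_k()].
#' @param emd_config An [emd_config()].
#' @param frame_config A [frame_config()].
#' @param sdc_config An [sdc_config()].
#' @return Frames x (n_coeffs * K_blocks) matrix.
#' @export
sdc_l <- function(signal, K, emd_config = sdcl::emd_config(),
                  frame_config = sdcl::frame_config(),
                  sdc_config = sdcl::sdc_config()) {
  stopifnot(inherits(signal, "audio_signal"))
  if (K < 1) abort("`K` must be >= 1.", class = "sdcl_validation_error")
  decomp <- emd(signal, emd_config)
  if (length(decomp$imfs) == 0) {
    abort("No IMF found; cannot form a subspace.", class = "sdcl_validation_error")
  }
  K_use <- min(K, length(decomp$imfs))
  low <- audio_signal(emd_reconstruct(decomp, K_use), signal$rate,
                      paste0(signal$source_id, ":low", K_use))
  sdc_adjusted(mfcc(low, frame_config), sdc_config)
}

#' Pool a per-frame feature matrix into a fixed-length vector
#'
#' Classifiers need fixed-length inputs from variable-length respiration
#' cycles; this collapses the time axis.
#'
#' @param m Frames x features matrix (at least one frame).
#' @param scheme `"mean"` (column means), `"mean_sd"` (means followed by
#'   per-column standard deviations, length 2M), or `"flatten_truncate"`
#'   (first `n_frames` rows flattened row-major, edge-padded when shorter).
#' @param n_frames Frames kept by `"flatten_truncate"` (default 10).
#' @return Numeric vector.
#' @export
pool_features <- function(m, scheme = c("mean", "mean_sd", "flatten_truncate"),
                          n_frames = 10) {
  scheme <- match.arg(scheme)
  m <- as.matrix(m)
  if (nrow(m) < 1 || ncol(m) < 1) {
    abort("Feature matrix must be non-empty.", class = "sdcl_validation_error")
  }
  switch(scheme,
    mean = colMeans(m),
    mean_sd = {
      sds <- if (nrow(m) > 1) apply(m, 2, sd) else rep(0, ncol(m))
      c(colMeans(m), sds)
    },
    flatten_truncate = {
      rows <- clamp_idx(seq_len(n_frames), nrow(m))
      as.vector(t(m[rows, , drop = FALSE]))
    }
  )
}
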