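#' Denoiser configuration
#'
#' Parameters of the iterative stationary/nonstationary wavelet filter. The
#' scheme separates the broadband vesicular background (stationary part)
#' from transient content — crackles, clicks, friction artefacts
#' (nonstationary part) — by hard-thresholding detail coefficients of a
#' Daubechies decomposition.
#'
#' @param wavelet_name Daubechies family member, `"db8"` (default) or `"db4"`.
#' @param levels Decomposition depth; `NULL` (default) picks
#'   `min(6, floor(log2(N)) - 2)` per signal.
#' @param threshold_factor Coefficients whose magnitude exceeds
#'   `threshold_factor * MAD / 0.6745` within their level are declared
#'   nonstationary (default 3).
#' @param max_iterations Maximum outer iterations (default 10).
#' @param convergence_tol Stop when the relative change in nonstationary
#'   energy falls below this (default 0.01).
#' @return A `denoise_config` list.
#' @export
denoise_config <- function(wavelet_name = "db8", levels = NULL,
                           threshold_factor = 3, max_iterations = 10,
                           convergence_tol = 0.01) {
  if (!is.null(levels) && (levels < 1 || levels != round(levels))) {
    abort("`levels` must be a positive integer (or NULL).", class = "sdcl_validation_error")
  }
  if (threshold_factor <= 0) {
    abort("`threshold_factor` must be > 0.", class = "sdcl_validation_error")
  }
  if (max_iterations < 1) {
    abort("`max_iterations` must be >= 1.", class = "sdcl_validation_error")
  }
  if (convergence_tol <= 0) {
    abort("`convergence_tol` must be > 0.", class = "sdcl_validation_error")
  }
  structure(list(wavelet_name = wavelet_name, levels = levels,
                 threshold_factor = threshold_factor,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol),
            class = "denoise_config")
}

resolve_levels <- function(config, n) {
  lv <- config$levels %||% max(1L, min(6L, floor(log2(n)) - 2L))
  if (n < 2^lv) {
    abort(sprintf("Signal of length %d too short for %d levels; at most %d feasible.",
                  n, lv, max(0L, floor(log2(n)))),
          class = "sdcl_validation_error")
  }
  as.integer(lv)
}

#' Stationary/nonstationary wavelet separation
#'
#' Iteratively splits a signal into a stationary part (vesicular background)
#' and a nonstationary part (transients). Each pass decomposes the current
#' stationary estimate with the configured Daubechies wavelet; detail
#' coefficients whose magnitude exceeds `threshold_factor` times the
#' level-wise robust scale (median absolute coefficient / 0.6745) are moved
#' to the nonstationary part; the two parts are reconstructed and the pass
#' repeats until the nonstationary energy stabilises. The decomposition is
#' additive: `stationary + nonstationary == input` to machine precision.
#'
#' @param signal An [audio_signal()].
#' @param config A [denoise_config()].
#' @return A list with elements `stationary` and `nonstationary`, both
#'   [audio_signal()]s, plus `iterations` (passes used).
#' @export
sns_filter <- function(signal, config = denoise_config()) {
  stopifnot(inherits(signal, "audio_signal"))
  x <- signal$samples
  n <- length(x)
  levels <- resolve_levels(config, n)

  stationary <- x
  ns_energy_prev <- 0
  iters <- 0L
  for (it in seq_len(config$max_iterations)) {
    iters <- it
    w <- dwt_periodized(stationary, config$wavelet_name, levels)
    moved <- FALSE
    for (j in seq_along(w$details)) {
      d <- w$details[[j]]
      sigma <- median(abs(d)) / 0.6745
      thr <- config$threshold_factor * sigma
      hit <- abs(d) > thr
      if (any(hit)) {
        moved <- TRUE
        d[hit] <- 0
        w$details[[j]] <- d
      }
    }
    if (!moved && it == 1L) break
    stationary <- idwt_periodized(w)
    ns_energy <- sum((x - stationary)^2)
    if (ns_energy == 0) break
    rel <- abs(ns_energy - ns_energy_prev) / ns_energy
    ns_energy_prev <- ns_energy
    if (rel < config$convergence_tol) break
  }
  nonstationary <- x - stationary

  list(
    stationary = audio_signal(stationary, signal$rate,
                              paste0(signal$source_id, ":stationary")),
    nonstationary = audio_signal(nonstationary, signal$rate,
                                 paste0(signal$source_id, ":nonstationary")),
    iterations = iters
  )
}

#' Denoised signal for feature extraction
#'
#' Convenience wrapper returning the component fed to the decomposition
#' stage: the stationary part of [sns_filter()] by default, or the untouched
#' input when `passthrough = TRUE` (for ablation runs).
#'
#' @inheritParams sns_filter
#' @param passthrough If `TRUE`, skip filtering and return the input.
#' @return An [audio_signal()].
#' @export
denoised <- function(signal, config = denoise_config(), passthrough = FALSE) {
  stopifnot(inherits(signal, "audio_signal"))
  if (passthrough) return(signal)
  sns_filter(signal, config)$stationary
}
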