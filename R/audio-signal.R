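#' Construct an audio signal
#'
#' A lightweight container for a sampled mono waveform: the basic unit every
#' stage of the pipeline (denoising, decomposition, cepstral extraction)
#' operates on. Amplitudes are dimensionless floats, conventionally in
#' `[-1, 1]` when read from or destined for PCM WAV files.
#'
#' @param samples Numeric vector of amplitudes; must be finite and non-empty.
#' @param rate Sampling rate in Hz (> 0).
#' @param source_id Opaque identifier carried along for bookkeeping
#'   (typically the originating file name).
#'
#' @return An object of class `audio_signal`: a list with elements
#'   `samples`, `rate` and `source_id`.
#' @examples
#' s <- audio_signal(sin(2 * pi * 10 * seq(0, 1, by = 1 / 1000)), rate = 1000)
#' duration(s)
#' @export
audio_signal <- function(samples, rate, source_id = "unnamed") {
  samples <- as.double(samples)
  if (length(samples) < 1L) {
    abort("`samples` must contain at least one value.", class = "sdcl_validation_error")
  }
  if (!all(is.finite(samples))) {
    abort("`samples` must be finite.", class = "sdcl_validation_error")
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    abort("`rate` must be a single positive number (Hz).", class = "sdcl_validation_error")
  }
  structure(
    list(samples = samples, rate = as.double(rate), source_id = as.character(source_id)),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf(
    "<audio_signal> %s: %d samples @ %g Hz (%.3f s), range [%.4g, %.4g]\n",
    x$source_id, length(x$samples), x$rate,
    length(x$samples) / x$rate, min(x$samples), max(x$samples)
  ))
  invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)

#' Duration of an audio signal in seconds
#' @param signal An [audio_signal()].
#' @return Duration in seconds.
#' @export
duration <- function(signal) {
  stopifnot(inherits(signal, "audio_signal"))
  length(signal$samples) / signal$rate
}

as_audio_signal <- function(x, rate = NULL, source_id = "unnamed") {
  if (inherits(x, "audio_signal")) return(x)
  audio_signal(x, rate = rate, source_id = source_id)
}
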