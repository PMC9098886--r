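#' EMD configuration
#'
#' Controls the sifting procedure of the empirical mode decomposition.
#'
#' @param max_imfs Cap on the number of extracted IMFs; `NULL` (default)
#'   uses the dyadic bound `ceiling(log2(N))` of the input length.
#' @param sift_sd_threshold Cauchy-type stopping threshold for the inner
#'   sift: sifting stops once `sum((h_prev - h)^2) / sum(h_prev^2)` falls
#'   below it (default 0.2, the conventional choice).
#' @param max_sifts Maximum sift iterations per IMF (default 50).
#' @param interpolation Envelope interpolation scheme; `"spline"` (natural
#'   cubic spline through the extrema, the standard choice).
#' @param boundary Envelope boundary scheme; `"mirror"` reflects the two
#'   nearest extrema about each end before spline fitting.
#' @return An `emd_config` list.
#' @export
emd_config <- function(max_imfs = NULL, sift_sd_threshold = 0.2, max_sifts = 50,
                       interpolation = "spline", boundary = "mirror") {
  if (!is.null(max_imfs) && max_imfs < 1) {
    abort("`max_imfs` must be >= 1.", class = "sdcl_validation_error")
  }
  if (sift_sd_threshold <= 0) {
    abort("`sift_sd_threshold` must be > 0.", class = "sdcl_validation_error")
  }
  if (max_sifts < 1) {
    abort("`max_sifts` must be >= 1.", class = "sdcl_validation_error")
  }
  interpolation <- match.arg(interpolation, "spline")
  boundary <- match.arg(boundary, "mirror")
  structure(list(max_imfs = max_imfs, sift_sd_threshold = sift_sd_threshold,
                 max_sifts = as.integer(max_sifts),
                 interpolation = interpolation, boundary = boundary),
            class = "emd_config")
}

# Indices of local maxima and minima; plateaus contribute their midpoint.
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(maxima = integer(), minima = integer()))
  dx <- diff(x)
  s <- sign(dx)
  # carry the preceding slope sign across zero runs so plateaus count once
  nz <- which(s != 0)
  if (length(nz) < 2L) return(list(maxima = integer(), minima = integer()))
  if (length(nz) == length(s)) {
    filled <- s
  } else {
    idx <- seq_along(s)
    pos <- cummax(ifelse(s != 0, idx, 0L))
    filled <- s
    valid <- pos > 0L
    filled[valid] <- s[pos[valid]]
  }
  turns <- which(diff(filled) != 0) + 1L
  maxima <- turns[filled[turns - 1L] > 0]
  minima <- turns[filled[turns - 1L] < 0]
  list(maxima = maxima, minima = minima)
}

# Count of sign changes, zeros skipped.
count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}

# Envelope through extrema with mirrored boundary extrema; natural spline.
envelope_through <- function(idx, vals, n) {
  if (length(idx) < 2L) return(rep(mean(vals), n))
  # mirror the two nearest extrema about each end
  li <- head(idx, 2L); lv <- head(vals, 2L)
  ri <- tail(idx, 2L); rv <- tail(vals, 2L)
  ext_i <- c(2L - rev(li), idx, 2L * n - rev(ri))
  ext_v <- c(rev(lv), vals, rev(rv))
  keep <- !duplicated(ext_i)
  sp <- spline(ext_i[keep], ext_v[keep], xout = seq_len(n), method = "natural")
  sp$y
}

mean_envelope <- function(x) {
  ex <- find_extrema(x)
  if (length(ex$maxima) < 2L || length(ex$minima) < 2L) return(NULL)
  n <- length(x)
  upper <- envelope_through(ex$maxima, x[ex$maxima], n)
  lower <- envelope_through(ex$minima, x[ex$minima], n)
  (upper + lower) / 2
}

#' Extract one intrinsic mode function by sifting
#'
#' Repeatedly subtracts the mean of the upper and lower spline envelopes
#' until the Cauchy criterion falls below `sift_sd_threshold` and the IMF
#' extrema/zero-crossing condition holds, or `max_sifts` is reached. A
#' signal with fewer than two maxima or two minima is a residue by
#' definition and is returned unchanged with `found = FALSE`.
#'
#' @param signal Numeric vector (or [audio_signal()]).
#' @param config An [emd_config()].
#' @return A list: `imf` (numeric vector), `found` (logical), `sifts`
#'   (iterations used).
#' @export
sift_one <- function(signal, config = emd_config()) {
  x <- if (inherits(signal, "audio_signal")) signal$samples else as.double(signal)
  if (!all(is.finite(x))) {
    abort("Signal must be finite.", class = "sdcl_validation_error")
  }
  ex <- find_extrema(x)
  if (length(ex$maxima) < 2L || length(ex$minima) < 2L) {
    return(list(imf = x, found = FALSE, sifts = 0L))
  }
  h <- x
  sifts <- 0L
  sd_crit <- Inf
  repeat {
    m <- mean_envelope(h)
    if (is.null(m)) {
      # sifting degenerated the candidate; treat the input as a residue
      return(list(imf = x, found = FALSE, sifts = sifts))
    }
    # accept once the Cauchy criterion is met AND the candidate satisfies
    # the two defining IMF properties (extrema/zero-crossing balance and a
    # near-zero local envelope mean)
    if (sifts >= 1L && sd_crit < config$sift_sd_threshold &&
        imf_condition(h) && max(abs(m)) < 0.1 * max(abs(h))) {
      break
    }
    if (sifts >= config$max_sifts) break
    h_new <- h - m
    sifts <- sifts + 1L
    sd_crit <- sum((h - h_new)^2) / sum(h^2)
    h <- h_new
  }
  list(imf = h, found = TRUE, sifts = sifts)
}

imf_condition <- function(x, tolerance = 1L) {
  ex <- find_extrema(x)
  n_ext <- length(ex$maxima) + length(ex$minima)
  abs(n_ext - count_zero_crossings(x)) <= tolerance
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions and a residue:
#' `x(t) = sum_k y_k(t) + r_K(t)`. IMFs are extracted by [sift_one()] from
#' the running remainder until no further IMF is found or `max_imfs` is
#' reached; the decomposition is exactly additive by construction.
#'
#' @param signal An [audio_signal()] or numeric vector (length >= 8).
#' @param config An [emd_config()].
#' @return An `emd_decomposition`: list with `imfs` (list of numeric
#'   vectors, highest frequency first), `residue`, `sift_counts`,
#'   `input_length` and `rate`.
#' @examples
#' t <- seq(0, 4, length.out = 2048)
#' x <- audio_signal(sin(2 * pi * 50 * t) + sin(2 * pi * 5 * t), rate = 512)
#' d <- emd(x)
#' length(d$imfs)
#' @export
emd <- function(signal, config = emd_config()) {
  x <- if (inherits(signal, "audio_signal")) signal$samples else as.double(signal)
  rate <- if (inherits(signal, "audio_signal")) signal$rate else NA_real_
  n <- length(x)
  if (n < 8L) {
    abort("Signal must have at least 8 samples.", class = "sdcl_validation_error")
  }
  max_imfs <- config$max_imfs %||% ceiling(log2(n))

  imfs <- list()
  sift_counts <- integer()
  remainder <- x
  while (length(imfs) < max_imfs) {
    st <- sift_one(remainder, config)
    if (!st$found) break
    imfs[[length(imfs) + 1L]] <- st$imf
    sift_counts <- c(sift_counts, st$sifts)
    remainder <- remainder - st$imf
  }
  structure(list(imfs = imfs, residue = remainder, sift_counts = sift_counts,
                 input_length = n, rate = rate),
            class = "emd_decomposition")
}

#' @export
print.emd_decomposition <- function(x, ...) {
  cat(sprintf("<emd_decomposition> %d IMFs + residue (N = %d)\n",
              length(x$imfs), x$input_length))
  invisible(x)
}

#' Per-IMF summary of a decomposition
#'
#' @param x An `emd_decomposition`.
#' @param ... Unused.
#' @return Tibble with one row per IMF: index, energy fraction,
#'   zero-crossing rate (per sample) and sift count.
#' @export
tidy.emd_decomposition <- function(x, ...) {
  total <- sum(vapply(x$imfs, function(v) sum(v^2), 1)) + sum(x$residue^2)
  tibble(
    imf = seq_along(x$imfs),
    energy_fraction = vapply(x$imfs, function(v) sum(v^2), 1) / max(total, .Machine$double.xmin),
    zero_crossing_rate = vapply(x$imfs, function(v) count_zero_crossings(v) / length(v), 1),
    sifts = x$sift_counts
  )
}

#' @export
autoplot.emd_decomposition <- function(object, ...) {
  n <- object$input_length
  t <- if (is.finite(object$rate)) (seq_len(n) - 1) / object$rate else seq_len(n)
  comps <- c(object$imfs, list(object$residue))
  labs <- c(sprintf("IMF %d", seq_along(object$imfs)), "residue")
  df <- tibble(
    t = rep(t, length(comps)),
    value = unlist(comps),
    component = factor(rep(labs, each = n), levels = labs)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component), scales = "free_y") +
    ggplot2::labs(x = if (is.finite(object$rate)) "time (s)" else "sample",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Reconstruct the low subspace from the first K IMFs
#'
#' Returns `y(t) = sum_{i=1}^{K} y_i(t)`; the residue is excluded.
#'
#' @param decomp An `emd_decomposition` from [emd()].
#' @param K Number of leading IMFs to sum (1 <= K <= number of IMFs).
#' @return Numeric vector of the same length as the input signal.
#' @export
emd_reconstruct <- function(decomp, K) {
  stopifnot(inherits(decomp, "emd_decomposition"))
  n_imfs <- length(decomp$imfs)
  if (length(K) != 1 || K < 1 || K > n_imfs || K != round(K)) {
    abort(sprintf("`K` must be an integer in [1, %d].", n_imfs),
          class = "sdcl_validation_error")
  }
  Reduce(`+`, decomp$imfs[seq_len(K)])
}

#' Test whether a sequence satisfies the IMF defining conditions
#'
#' TRUE iff the number of extrema and the number of zero crossings differ
#' by at most `tolerance` and the mean of the upper and lower envelopes is
#' small (max magnitude below 10% of the candidate's peak). Constant or
#' monotone sequences fail (no oscillation left — a residue).
#'
#' @param candidate Numeric vector (length >= 3).
#' @param tolerance Allowed |extrema - zero crossings| difference (default 1).
#' @return Logical flag.
#' @export
is_imf <- function(candidate, tolerance = 1) {
  x <- if (inherits(candidate, "audio_signal")) candidate$samples else as.double(candidate)
  if (length(x) < 3L) {
    abort("Candidate must have at least 3 samples.", class = "sdcl_validation_error")
  }
  m <- mean_envelope(x)
  if (is.null(m)) return(FALSE)
  if (!imf_condition(x, tolerance)) return(FALSE)
  max(abs(m)) < 0.1 * max(abs(x))
}
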