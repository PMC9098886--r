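# Periodized orthogonal discrete wavelet transform (Daubechies family).
#
# The scaling filters below are the standard published Daubechies
# coefficients (db4 = 4 vanishing moments / 8 taps, db8 = 8 / 16). With
# periodization the analysis operator is orthonormal, so synthesis is its
# transpose and reconstruction is exact to machine precision — which is what
# makes the stationary + nonstationary = input identity of the denoiser hold
# exactly.

daubechies_filters <- function(wavelet_name) {
  scaling <- switch(
    wavelet_name,
    db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
            -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
            0.0328830116668852, -0.010597401785069032),
    db8 = c(0.05441584224310401, 0.31287159091429995, 0.6756307362972898,
            0.5853546836542067, -0.015829105256349306, -0.2840155429615469,
            0.0004724845739132828, 0.12874742662047847, -0.017369301001807547,
            -0.044088253930794755, 0.013981027917398282, 0.008746094047405777,
            -0.004870352993451574, -0.00039174037337694705,
            0.0006754494064505693, -0.00011747678412476953),
    abort(sprintf("Unknown wavelet '%s' (supported: db4, db8).", wavelet_name),
          class = "sdcl_validation_error")
  )
  L <- length(scaling)
  wavelet <- rev(scaling) * (-1)^(seq_len(L) - 1)
  list(lo = scaling, hi = wavelet, length = L)
}

# One analysis level: x (even length) -> list(a, d), each length N/2.
# a[k] = sum_l lo[l] x[(2(k-1) + l - 1) mod N + 1]; rows are orthonormal.
dwt_step <- function(x, filt) {
  n <- length(x)
  half <- n %/% 2L
  idx0 <- 2L * (seq_len(half) - 1L)
  a <- numeric(half)
  d <- numeric(half)
  for (l in seq_len(filt$length)) {
    xi <- x[(idx0 + l - 1L) %% n + 1L]
    a <- a + filt$lo[l] * xi
    d <- d + filt$hi[l] * xi
  }
  list(a = a, d = d)
}

# Inverse of dwt_step (transpose of the orthonormal analysis operator).
idwt_step <- function(a, d, filt) {
  half <- length(a)
  n <- 2L * half
  x <- numeric(n)
  idx0 <- 2L * (seq_len(half) - 1L)
  for (l in seq_len(filt$length)) {
    pos <- (idx0 + l - 1L) %% n + 1L
    contrib <- filt$lo[l] * a + filt$hi[l] * d
    # positions can repeat when the filter wraps; accumulate safely
    x <- x + tabulate_add(pos, contrib, n)
  }
  x
}

tabulate_add <- function(pos, val, n) {
  out <- numeric(n)
  # pos entries are distinct within one tap shift unless n < filter length;
  # handle the general case with a grouped sum
  if (anyDuplicated(pos)) {
    s <- rowsum(val, group = pos)
    out[as.integer(rownames(s))] <- s[, 1]
  } else {
    out[pos] <- val
  }
  out
}

# Full periodized DWT to `levels`; odd lengths are padded by repeating the
# final sample, and the pad is trimmed again on reconstruction.
dwt_periodized <- function(x, wavelet_name = "db8", levels = 1L) {
  filt <- daubechies_filters(wavelet_name)
  details <- vector("list", levels)
  pads <- integer(levels)
  cur <- x
  for (j in seq_len(levels)) {
    if (length(cur) %% 2L == 1L) {
      cur <- c(cur, cur[length(cur)])
      pads[j] <- 1L
    }
    if (length(cur) < filt$length) {
      abort(sprintf("Signal too short for %d-level %s transform.", levels, wavelet_name),
            class = "sdcl_validation_error")
    }
    st <- dwt_step(cur, filt)
    details[[j]] <- st$d
    cur <- st$a
  }
  structure(list(approx = cur, details = details, pads = pads,
                 wavelet = wavelet_name, n = length(x)),
            class = "sdcl_dwt")
}

idwt_periodized <- function(w) {
  filt <- daubechies_filters(w$wavelet)
  cur <- w$approx
  for (j in rev(seq_along(w$details))) {
    cur <- idwt_step(cur, w$details[[j]], filt)
    if (w$pads[j] == 1L) cur <- cur[-length(cur)]
  }
  cur[seq_len(w$n)]
}
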