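# Shared fixtures, built in code and cached for the duration of the run.

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Two tones three octaves apart in light noise: IMFs 1-2 carry the tones.
two_band_signal <- function(seed, noise_sd = 0.05, n = 4096, rate = 1000) {
  t <- (seq_len(n) - 1) / rate
  x <- sdcl:::with_seed(seed,
    sin(2 * pi * 350 * t) + sin(2 * pi * 40 * t) + noise_sd * rnorm(n))
  audio_signal(x, rate, sprintf("two_band_%d", seed))
}

# Null-process surface: white Gaussian noise, rectangular non-overlapping
# frames so grid cells are independent (the regime the wild bootstrap
# assumes).
null_surface_config <- function() {
  surface_config(fft_length = 128, hop = 128, window = "rect")
}

null_surface <- function(seed, n = 2048, rate = 1000, shift = 0) {
  x <- sdcl:::with_seed(seed, rnorm(n)) + shift * 0
  compute_surface(x, rate, null_surface_config())
}

# A surface whose raw field is shifted by `delta` (units of the raw scale).
shifted_surface <- function(seed, delta, n = 2048, rate = 1000) {
  x <- sdcl:::with_seed(seed, rnorm(n))
  s <- compute_surface(x, rate, null_surface_config())
  raw <- s$raw_values + delta
  vals <- sdcl:::smooth_surface(raw, s$config$smoothing_bandwidth)
  sdcl:::new_spectral_surface(vals, raw, s$times, s$freqs, s$config, s$cell_area)
}

# Small on-disk dataset shared by integration tests.
tiny_dataset <- function() {
  cache_fixture("tiny_dataset", function() {
    dir <- file.path(tempdir(), "sdcl_tiny_ds")
    cfg <- synth_config(duration_s = 5, cycle_length_s = 2.5)
    list(manifest = gen_dataset(2, cfg, dir, seed = 42), dir = dir)
  })
}

# Per-cycle pooled features for the separability harness (3 x 20 recordings,
# fixed seed, fixed K = 2); expensive, so computed once.
separability_features <- function() {
  cache_fixture("separability_features", function() {
    dir <- file.path(tempdir(), "sdcl_sep_ds")
    man <- gen_dataset(20, synth_config(), dir, seed = 7)
    feats <- list(); labs <- character(); i <- 0L
    for (r in seq_len(nrow(man))) {
      sig <- read_wav(man$wav[r])
      ann <- parse_annotations(man$annotation[r])
      for (cyc in segment_cycles(sig, ann)) {
        i <- i + 1L
        feats[[i]] <- pool_features(sdc_l(cyc, 2), "mean_sd")
        labs <- c(labs, man$label[r])
      }
    }
    list(x = do.call(rbind, feats), labels = labs)
  })
}

# 100 decompositions of seeded random signals (lengths 512/1024/4096),
# shared by the completeness and IMF-predicate checks.
random_decompositions <- function() {
  cache_fixture("random_decompositions", function() {
    set.seed(101)
    lengths <- rep(c(512, 1024, 4096), length.out = 100)
    lapply(1:100, function(i) {
      x <- rnorm(lengths[i])
      list(x = x, decomp = emd(audio_signal(x, 1000)))
    })
  })
}

expect_close <- function(object, expected, tol = 1e-8) {
  expect_true(max(abs(object - expected)) < tol)
}
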