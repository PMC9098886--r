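test_that("the mel scale matches its closed form and is monotone", {
  expect_equal(mel_scale(0), 0)
  expect_equal(mel_scale(700), 2595 * log10(2), tolerance = 1e-9)
  f <- seq(0, 4000, by = 50)
  expect_true(all(diff(mel_scale(f)) > 0))
  expect_error(mel_scale(-1), class = "sdcl_validation_error")
})

test_that("MFCC framing, energy behaviour and degenerate input are correct", {
  set.seed(21)
  sig <- audio_signal(rnorm(8192), 4000)
  fc <- frame_config(frame_length = 1024, hop = 256, n_mels = 40, n_coeffs = 13)
  C <- mfcc(sig, fc)
  expect_equal(nrow(C$coeffs), 1 + (8192 - 1024) %/% 256)
  expect_equal(ncol(C$coeffs), 13)

  # doubling amplitude shifts only the energy coefficient
  C2 <- mfcc(audio_signal(2 * sig$samples, 4000), fc)
  expect_lt(max(abs(C2$coeffs[, -1] - C$coeffs[, -1])), 1e-6)
  expect_gt(min(C2$coeffs[, 1] - C$coeffs[, 1]), 0.1)

  # zero signal: DCT of the constant log floor, coefficients 2..N vanish
  Cz <- mfcc(audio_signal(rep(0, 2048), 4000), fc)
  expect_lt(max(abs(Cz$coeffs[, -1])), 1e-10)

  expect_error(mfcc(audio_signal(rnorm(256), 4000), fc),
               class = "sdcl_validation_error")
  expect_error(mfcc(sig, frame_config(frame_length = 1024, fmax = 3000)),
               class = "sdcl_validation_error")
})

test_that("delta cepstra follow the lagged-difference definition with edge padding", {
  M <- matrix(rep(seq_len(10), 3), 10, 3)       # C[t] = t in every coefficient
  d1 <- delta_cepstra(M, 1)
  expect_true(all(d1[2:9, ] == 2))
  expect_equal(d1[1, ], M[2, ] - M[1, ])        # edge-padded first frame
  expect_equal(d1[10, ], M[10, ] - M[9, ])
  expect_true(all(delta_cepstra(matrix(5, 6, 2), 2) == 0))
  expect_error(delta_cepstra(M, 10), class = "sdcl_validation_error")
  expect_error(delta_cepstra(M, 0), class = "sdcl_validation_error")
})

test_that("plain SDC reduces to delta cepstra and matches a brute-force oracle", {
  set.seed(8)
  M <- matrix(rnorm(30), 10, 3)
  expect_identical(sdc_plain(M, sdc_config(d = 1, P = 3, K_blocks = 1)),
                   delta_cepstra(M, 1))
  expect_true(all(sdc_plain(matrix(2, 8, 2), sdc_config()) == 0))

  cfg <- sdc_config(d = 1, P = 2, K_blocks = 2)
  out <- sdc_plain(M, cfg)
  clamp <- function(i) min(max(i, 1), 10)
  brute <- matrix(0, 10, 6)
  for (t in 1:10) for (j in 0:1) for (n in 1:3) {
    brute[t, j * 3 + n] <- M[clamp(t + j * 2 + 1), n] - M[clamp(t + j * 2 - 1), n]
  }
  expect_equal(out, brute, tolerance = 1e-12)
  expect_equal(dim(out), c(10, 6))
})

test_that("adjusted SDC is the local regression slope and matches its oracle", {
  ramp <- matrix(rep(seq_len(12), 2), 12, 2)
  for (d in 1:3) {
    out <- sdc_adjusted(ramp, sdc_config(d = d, P = 1, K_blocks = 1))
    interior <- (d + 1):(12 - d)
    expect_true(all(abs(out[interior, ] - 1) < 1e-12))
  }
  expect_true(all(sdc_adjusted(matrix(3, 9, 2), sdc_config()) == 0))

  set.seed(9)
  M <- matrix(rnorm(30), 10, 3)
  cfg <- sdc_config(d = 2, P = 2, K_blocks = 2)
  out <- sdc_adjusted(M, cfg)
  clamp <- function(i) min(max(i, 1), 10)
  brute <- matrix(0, 10, 6)
  denom <- sum((-2:2)^2)
  for (t in 1:10) for (j in 0:1) for (n in 1:3) {
    acc <- 0
    for (u in -2:2) acc <- acc + u * M[clamp(t + j * 2 + u), n]
    brute[t, j * 3 + n] <- acc / denom
  }
  expect_equal(out, brute, tolerance = 1e-12)
})

test_that("output dimensions are frames x (coefficients * blocks)", {
  M <- matrix(rnorm(40), 8, 5)
  for (kb in 1:3) {
    cfg <- sdc_config(d = 1, P = 2, K_blocks = kb)
    expect_equal(dim(sdc_plain(M, cfg)), c(8, 5 * kb))
    expect_equal(dim(sdc_adjusted(M, cfg)), c(8, 5 * kb))
  }
})

test_that("sdc_l equals the explicit four-stage composition bitwise", {
  set.seed(33)
  t <- (0:8191) / 4000
  for (i in 1:3) {
    x <- audio_signal(sin(2 * pi * sample(100:800, 1) * t) + 0.3 * rnorm(8192), 4000)
    fc <- frame_config(frame_length = 1024, hop = 512, n_mels = 40)
    sc <- sdc_config()
    direct <- sdc_l(x, 2, frame_config = fc, sdc_config = sc)
    d <- emd(x)
    low <- audio_signal(emd_reconstruct(d, min(2, length(d$imfs))), 4000)
    expect_identical(direct, sdc_adjusted(mfcc(low, fc), sc))
  }
})

test_that("SDC-L separates wheeze from vesicular cycles", {
  cfgs <- list(v = synth_config(duration_s = 5, seed = 1),
               w = synth_config(duration_s = 5, class_label = "wheeze", seed = 2))
  pooled <- function(gen, cfg, n) {
    out <- list()
    for (i in seq_len(n)) {
      cfg$seed <- cfg$seed + 97L * i
      rec <- gen(cfg)
      cycs <- segment_cycles(rec$signal, rec$annotations)
      out[[i]] <- pool_features(sdc_l(cycs[[1]], 2), "mean")
    }
    do.call(rbind, out)
  }
  A <- pooled(gen_vesicular, cfgs$v, 8)
  B <- pooled(gen_wheeze, cfgs$w, 8)
  dmat <- as.matrix(dist(rbind(A, B)))
  within <- mean(c(dmat[1:8, 1:8][upper.tri(diag(8))],
                   dmat[9:16, 9:16][upper.tri(diag(8))]))
  between <- mean(dmat[1:8, 9:16])
  expect_gt(between, within)
})

test_that("pooling schemes collapse the time axis as documented", {
  m <- matrix(rnorm(28), 7, 4)
  expect_equal(pool_features(m, "mean"), colSums(m) / 7, tolerance = 1e-12)
  expect_equal(pool_features(m[1, , drop = FALSE], "mean"), m[1, ])
  const <- matrix(rep(c(1, 2, 3), each = 5), 5, 3)
  expect_equal(pool_features(const, "mean_sd"), c(1, 2, 3, 0, 0, 0))
  expect_equal(length(pool_features(m, "mean_sd")), 8)
  flat <- pool_features(m, "flatten_truncate", n_frames = 3)
  expect_equal(flat, as.vector(t(m[1:3, ])))
  expect_error(pool_features(matrix(nrow = 0, ncol = 3)),
               class = "sdcl_validation_error")
})
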