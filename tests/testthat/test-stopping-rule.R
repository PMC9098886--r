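make_flat_surface <- function(value, nt = 4, nf = 5, cell_area = 1 / 20) {
  m <- matrix(value, nt, nf)
  sdcl:::new_spectral_surface(m, m, seq_len(nt), seq_len(nf),
                              surface_config(128, 64), cell_area)
}

make_random_surface <- function(seed, nt = 4, nf = 5, cell_area = 1 / 20) {
  raw <- sdcl:::with_seed(seed, matrix(rnorm(nt * nf), nt, nf))
  vals <- sdcl:::smooth_surface(raw, c(2, 2))
  sdcl:::new_spectral_surface(vals, raw, seq_len(nt), seq_len(nf),
                              surface_config(128, 64), cell_area)
}

test_that("the L2 statistic matches closed forms and a brute-force oracle", {
  s <- make_random_surface(1)
  expect_equal(l2_statistic(list(s, s)), 0)

  a <- make_flat_surface(1); b <- make_flat_surface(3)  # unit-area grid
  expect_equal(l2_statistic(list(a, b)), 4)

  surfs <- lapply(1:3, make_random_surface)
  brute <- 0
  for (i in 1:2) for (k in (i + 1):3) {
    for (r in 1:4) for (cc in 1:5) {
      brute <- brute + (surfs[[i]]$values[r, cc] - surfs[[k]]$values[r, cc])^2 * (1 / 20)
    }
  }
  expect_equal(l2_statistic(surfs), brute, tolerance = 1e-12)

  expect_error(l2_statistic(list(s)), class = "sdcl_validation_error")
  expect_error(l2_statistic(list(s, make_random_surface(2, nt = 6))),
               class = "sdcl_validation_error")
  expect_error(l2_statistic(list(a, b), weight = matrix(-1, 4, 5)),
               class = "sdcl_validation_error")
})

test_that("the statistic is non-negative and zero only for identical surfaces", {
  for (seed in 1:10) {
    a <- make_random_surface(seed); b <- make_random_surface(seed + 100)
    expect_gte(l2_statistic(list(a, b)), 0)
  }
  a <- make_random_surface(3)
  expect_identical(l2_statistic(list(a, a)), 0)
})

test_that("the wild bootstrap is deterministic given the seed", {
  a <- null_surface(10); b <- null_surface(11)
  r1 <- wild_bootstrap_test(a, b, B = 99, seed = 5)
  r2 <- wild_bootstrap_test(a, b, B = 99, seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$statistic, r2$statistic)
  expect_equal(r1$reject, r1$p_value <= r1$alpha)
})

test_that("the p-value is invariant to common positive rescaling under uniform weight", {
  a <- null_surface(20); b <- null_surface(21)
  scale_surface <- function(s, c) {
    sdcl:::new_spectral_surface(s$values * c, s$raw_values * c, s$times,
                                s$freqs, s$config, s$cell_area)
  }
  r1 <- wild_bootstrap_test(a, b, B = 99, seed = 9)
  r2 <- wild_bootstrap_test(scale_surface(a, 7), scale_surface(b, 7), B = 99, seed = 9)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r2$statistic, 49 * r1$statistic, tolerance = 1e-9)
})

test_that("a clear mean shift is detected, mismatched grids are rejected", {
  a <- null_surface(30)
  b <- shifted_surface(31, delta = 5)
  expect_true(wild_bootstrap_test(a, b, B = 199, seed = 1)$reject)
  small <- make_flat_surface(1)
  expect_error(wild_bootstrap_test(a, small, B = 99, seed = 1),
               class = "sdcl_validation_error")
  expect_error(wild_bootstrap_test(a, a, B = 5, seed = 1),
               class = "sdcl_validation_error")
})

test_that("identical reconstructions give p = 1 and stop the scan cleanly", {
  t <- (0:4095) / 1000
  sel <- select_k(audio_signal(sin(2 * pi * 200 * t), 1000), B = 99, seed = 3)
  expect_equal(sel$K, 1L)
  expect_equal(sel$trail[[1]]$p_value, 1)
})

test_that("the scan stops at the first non-rejection", {
  # scripted p-value trail (significant, then not): the scan must stop at
  # K = 2 without testing further
  calls <- 0L
  scripted <- c(0.0199, 0.1393, 0.0001)
  testthat::local_mocked_bindings(
    wild_bootstrap_test = function(surf_a, surf_b, B = 1000, alpha = 0.05,
                                   seed = 1, weight = NULL,
                                   multiplier = "rademacher") {
      calls <<- calls + 1L
      sdcl:::new_surface_test_result(1, scripted[calls], B, alpha)
    },
    .package = "sdcl"
  )
  sig <- two_band_signal(1)
  sel <- select_k(sig, B = 99, seed = 1)
  expect_equal(sel$K, 2L)
  expect_equal(calls, 2L)
  expect_equal(tidy(sel)$p_value, c(0.0199, 0.1393))
  expect_equal(tidy(sel)$reject, c(TRUE, FALSE))
})

test_that("select_k is deterministic and errors without IMFs", {
  sig <- two_band_signal(4)
  s1 <- select_k(sig, B = 49, seed = 8)
  s2 <- select_k(sig, B = 49, seed = 8)
  expect_identical(s1$K, s2$K)
  expect_identical(tidy(s1), tidy(s2))
  expect_error(select_k(audio_signal(rep(1, 64), 1000), B = 49, seed = 1),
               class = "sdcl_validation_error")
})

test_that("the two-band fixture selects K = 2", {
  sel <- select_k(two_band_signal(5), B = 199, seed = 5)
  expect_equal(sel$K, 2L)
  expect_true(all(tidy(sel)$reject[1]))
})
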