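test_that("WAV write/read round-trips within quantisation", {
  t <- seq(0, 1, by = 1 / 4000)
  sig <- audio_signal(0.8 * sin(2 * pi * 100 * t), 4000, "sine")
  for (depth in c("pcm16", "pcm24", "float32")) {
    path <- withr::local_tempfile(fileext = ".wav")
    write_wav(sig, path, depth)
    back <- read_wav(path)
    expect_equal(back$rate, 4000)
    expect_equal(length(back), length(sig))
    tol <- switch(depth, pcm16 = 2 / 32768, pcm24 = 2 / 8388608, float32 = 1e-7)
    expect_lt(max(abs(back$samples - sig$samples)), tol)
  }
})

test_that("WAV writer clips out-of-range samples with a warning", {
  path <- withr::local_tempfile(fileext = ".wav")
  sig <- audio_signal(c(0, 0.5, 1.5, -2), 1000)
  expect_warning(write_wav(sig, path), "clipped")
  back <- read_wav(path)
  expect_equal(back$samples[3], 1, tolerance = 1e-3)
  expect_equal(back$samples[4], -1, tolerance = 1e-3)
})

test_that("all-zero signal round-trips to zeros", {
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(audio_signal(rep(0, 100), 8000), path)
  expect_true(all(read_wav(path)$samples == 0))
})

test_that("stereo files reduce to channel 1 with a warning", {
  # hand-craft a 2-channel pcm16 file: L = ramp, R = zeros
  path <- withr::local_tempfile(fileext = ".wav")
  n <- 50L
  left <- as.integer(seq(-10000, 10000, length.out = n))
  inter <- as.integer(rbind(left, 0L))
  con <- file(path, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 4 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  for (v in list(c(1L, 2L), c(2L, 2L), c(8000L, 4L), c(32000L, 4L), c(4L, 2L),
                 c(16L, 2L))) {
    writeBin(v[1], con, size = v[2], endian = "little")
  }
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(4 * n), con, size = 4, endian = "little")
  writeBin(inter, con, size = 2, endian = "little")
  close(con)

  expect_warning(sig <- read_wav(path), "channel")
  expect_equal(length(sig), n)
  expect_equal(sig$samples, left / 32768, tolerance = 1e-9)
})

test_that("missing and degenerate files raise typed errors", {
  expect_error(read_wav(file.path(tempdir(), "nope.wav")), class = "sdcl_io_error")
  empty <- withr::local_tempfile(fileext = ".wav")
  file.create(empty)
  expect_error(read_wav(empty), class = "sdcl_format_error")
})

test_that("annotation parsing handles ICBHI lines, blanks and errors", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0.364\t2.436\t0\t0", "", "2.436  4.5 1 1"), path)
  ann <- parse_annotations(path)
  expect_equal(nrow(ann), 2)
  expect_equal(ann$start_s, c(0.364, 2.436))
  expect_equal(ann$crackle, c(0L, 1L))
  expect_equal(ann$wheeze, c(0L, 1L))

  writeLines(character(), path)
  expect_equal(nrow(parse_annotations(path)), 0)

  writeLines("0.1 0.5 0", path)
  expect_error(parse_annotations(path), "4 columns", class = "sdcl_format_error")
  writeLines("1.0 0.5 0 0", path)
  expect_error(parse_annotations(path), class = "sdcl_validation_error")
})

test_that("annotation write/parse is the identity", {
  ann <- tibble::tibble(start_s = c(0, 1 / 3, 2.436), end_s = c(1 / 3, 2.436, 7.1),
                        crackle = c(0L, 1L, 0L), wheeze = c(1L, 0L, 0L))
  path <- withr::local_tempfile(fileext = ".txt")
  write_annotations(ann, path)
  expect_equal(parse_annotations(path), ann)
})

test_that("diagnosis loading filters rare classes case-insensitively", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,diagnosis",
               sprintf("C%02d,COPD", 1:6), "C07,copd",
               "A01,Asthma", "A02,asthma"), path)
  d <- load_diagnoses(path, min_subjects = 5)
  expect_equal(nrow(d), 7)                       # 7 COPD (case-folded), asthma dropped
  expect_true(all(tolower(d$diagnosis) == "copd"))

  d_all <- load_diagnoses(path, min_subjects = 1)
  expect_equal(nrow(d_all), 9)                   # nothing dropped

  # brute-force check on a 10-patient table with class sizes {6, 4}
  path2 <- withr::local_tempfile(fileext = ".tsv")
  labels <- c(rep("URTI", 6), rep("Pneumonia", 4))
  writeLines(sprintf("P%02d\t%s", 1:10, labels), path2)
  d2 <- load_diagnoses(path2, min_subjects = 5)
  expected <- sum(table(labels)[table(labels) >= 5])
  expect_equal(nrow(d2), expected)
  expect_true(all(d2$diagnosis == "URTI"))

  writeLines(c("P1,COPD", "P1,URTI"), path)
  expect_error(load_diagnoses(path), "conflicting", class = "sdcl_validation_error")
})

test_that("cycle segmentation follows the half-open rounding convention", {
  sig <- audio_signal(seq_len(10000) / 10000, 1000)
  ann <- tibble::tibble(start_s = 1, end_s = 2, crackle = 0L, wheeze = 0L)
  seg <- segment_cycles(sig, ann)
  expect_equal(length(seg[[1]]), 1000)
  expect_equal(seg[[1]]$samples[1], sig$samples[1001])

  # abutting cycles share no sample
  ann2 <- tibble::tibble(start_s = c(0, 1), end_s = c(1, 2),
                         crackle = 0L, wheeze = 0L)
  segs <- segment_cycles(sig, ann2)
  expect_equal(c(segs[[1]]$samples, segs[[2]]$samples), sig$samples[1:2000])

  expect_equal(segment_cycles(sig, ann2[0, ]), list())

  ann3 <- tibble::tibble(start_s = 9, end_s = 11, crackle = 0L, wheeze = 0L)
  expect_error(segment_cycles(sig, ann3), "Cycle 1", class = "sdcl_validation_error")
})

test_that("segment lengths equal the rounded index differences for random cycles", {
  sig <- audio_signal(rnorm(44100), 4410)
  set.seed(1)
  starts <- sort(runif(5, 0, 8))
  ends <- starts + runif(5, 0.3, 1.5)
  ann <- tibble::tibble(start_s = starts, end_s = ends, crackle = 0L, wheeze = 0L)
  segs <- segment_cycles(sig, ann)
  expect_equal(vapply(segs, length, 1L),
               as.integer(round(ends * 4410) - round(starts * 4410)))
})
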