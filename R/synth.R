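#' Synthetic lung-sound configuration
#'
#' Defines one synthetic recording. The vesicular (normal breathing) model
#' is band-limited Gaussian noise in roughly 100-1000 Hz with an extra
#' roll-off below 200 Hz, amplitude-modulated by a raised-cosine
#' inspiration/expiration envelope with a louder inspiration. Adventitious
#' classes superimpose onto this base: a wheeze adds a vibrato tone during
#' expiration; crackles add brief (about 5 ms) damped oscillatory bursts
#' during inspiration.
#'
#' @param rate Sampling rate in Hz (>= 2000; default 4000, a common rate
#'   for digital stethoscope recordings).
#' @param duration_s Recording length in seconds (default 10).
#' @param cycle_length_s Respiration-cycle length in seconds (default 2.5,
#'   a typical adult resting cycle).
#' @param class_label One of `"vesicular"`, `"wheeze"`, `"crackle"`.
#' @param snr_db Adventitious-to-vesicular power ratio in dB (default 5).
#' @param wheeze_freq Wheeze tone frequency in Hz (default 400, within the
#'   100-1000 Hz band typical of wheezes).
#' @param crackle_rate Expected crackle events per cycle (default 8).
#' @param seed Integer seed; generators are pure functions of config + seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(rate = 4000, duration_s = 10, cycle_length_s = 2.5,
                         class_label = c("vesicular", "wheeze", "crackle"),
                         snr_db = 5, wheeze_freq = 400, crackle_rate = 8,
                         seed = 1) {
  class_label <- match.arg(class_label)
  if (rate < 2000) abort("`rate` must be >= 2000 Hz.", class = "sdcl_validation_error")
  if (cycle_length_s <= 0 || duration_s < cycle_length_s) {
    abort("Need duration_s >= cycle_length_s > 0.", class = "sdcl_validation_error")
  }
  if (!is.finite(snr_db)) abort("`snr_db` must be finite.", class = "sdcl_validation_error")
  if (crackle_rate < 0) abort("`crackle_rate` must be >= 0.", class = "sdcl_validation_error")
  structure(list(rate = rate, duration_s = duration_s,
                 cycle_length_s = cycle_length_s, class_label = class_label,
                 snr_db = snr_db, wheeze_freq = wheeze_freq,
                 crackle_rate = crackle_rate, seed = as.integer(seed)),
            class = "synth_config")
}

# Cycle table tiling [0, duration): floor(duration / cycle) cycles, the last
# one stretched to the recording end when duration is not an exact multiple.
cycle_table <- function(config, crackle = 0L, wheeze = 0L) {
  n_cycles <- floor(config$duration_s / config$cycle_length_s)
  starts <- (seq_len(n_cycles) - 1) * config$cycle_length_s
  ends <- starts + config$cycle_length_s
  ends[n_cycles] <- config$duration_s
  tibble(start_s = starts, end_s = ends,
         crackle = rep(as.integer(crackle), n_cycles),
         wheeze = rep(as.integer(wheeze), n_cycles))
}

# Per-sample respiration envelope plus phase masks. Inspiration occupies the
# first 40% of each cycle at full gain, expiration the rest at 60% gain;
# each phase is shaped by a raised cosine; a small floor keeps the
# background audible between phases.
respiration_envelope <- function(config, n) {
  t <- (seq_len(n) - 1) / config$rate
  tau <- (t %% config$cycle_length_s) / config$cycle_length_s
  insp_frac <- 0.4
  insp <- tau < insp_frac
  phase <- ifelse(insp, tau / insp_frac, (tau - insp_frac) / (1 - insp_frac))
  rc <- 0.5 * (1 - cos(2 * pi * phase))
  env <- 0.15 + 0.85 * rc * ifelse(insp, 1, 0.6)
  list(env = env, insp = insp, insp_weight = rc * insp,
       exp_weight = rc * (!insp))
}

vesicular_base <- function(config) {
  n <- round(config$rate * config$duration_s)
  noise <- with_seed(config$seed, rnorm(n))
  nyq <- config$rate / 2
  bp <- signal::butter(4, c(100, 1000) / nyq, type = "pass")
  x <- signal::filtfilt(bp, noise)
  hp <- signal::butter(1, 200 / nyq, type = "high")  # gentle roll-off < 200 Hz
  x <- signal::filtfilt(hp, x)
  resp <- respiration_envelope(config, n)
  x <- x * resp$env
  x <- 0.5 * x / stats::sd(x)
  list(x = x, resp = resp, n = n)
}

finish_signal <- function(x, config, label) {
  peak <- max(abs(x))
  if (peak > 0.99) x <- 0.99 * x / peak
  audio_signal(x, config$rate,
               sprintf("synth_%s_seed%d", label, config$seed))
}

#' Generate a synthetic vesicular (normal) lung sound
#'
#' @param config A [synth_config()].
#' @return A list: `signal` ([audio_signal()]) and `annotations` (tibble in
#'   ICBHI 4-column form, crackle = wheeze = 0).
#' @export
gen_vesicular <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  base <- vesicular_base(config)
  list(signal = finish_signal(base$x, config, "vesicular"),
       annotations = cycle_table(config, 0L, 0L))
}

#' Generate a synthetic wheeze recording
#'
#' Vesicular base plus a continuous tone at `wheeze_freq` with slight
#' vibrato, active during expiration phases, scaled to `snr_db` relative to
#' the vesicular power.
#'
#' @param config A [synth_config()] (100 <= `wheeze_freq` <= 1000).
#' @return As [gen_vesicular()], with `wheeze = 1` annotations.
#' @export
gen_wheeze <- function(config = synth_config(class_label = "wheeze")) {
  stopifnot(inherits(config, "synth_config"))
  if (config$wheeze_freq < 100 || config$wheeze_freq > 1000) {
    abort("`wheeze_freq` must lie in [100, 1000] Hz.", class = "sdcl_validation_error")
  }
  base <- vesicular_base(config)
  t <- (seq_len(base$n) - 1) / config$rate
  inst_freq <- config$wheeze_freq * (1 + 0.01 * sin(2 * pi * 4 * t))  # 4 Hz vibrato
  phase <- 2 * pi * cumsum(inst_freq) / config$rate
  tone <- sin(phase) * base$resp$exp_weight
  ves_pow <- mean(base$x^2)
  tone_pow <- mean(tone^2)
  gain <- sqrt(ves_pow * 10^(config$snr_db / 10) / max(tone_pow, .Machine$double.xmin))
  list(signal = finish_signal(base$x + gain * tone, config, "wheeze"),
       annotations = cycle_table(config, 0L, 1L))
}

#' Generate a synthetic crackle recording
#'
#' Vesicular base plus Poisson-placed damped sinusoid bursts (about 5 ms,
#' centre about 700 Hz) during inspiration phases.
#'
#' @param config A [synth_config()].
#' @return As [gen_vesicular()], with `crackle = 1` annotations; the
#'   returned list also carries `n_events`, the realised burst count.
#' @export
gen_crackle <- function(config = synth_config(class_label = "crackle")) {
  stopifnot(inherits(config, "synth_config"))
  base <- vesicular_base(config)
  x <- base$x
  n_cycles <- floor(config$duration_s / config$cycle_length_s)
  insp_frac <- 0.4

  burst_len <- round(0.005 * config$rate)                 # ~5 ms
  tb <- (seq_len(burst_len) - 1) / config$rate
  burst <- exp(-tb / 0.0012) * sin(2 * pi * 700 * tb)
  amp <- 3 * sqrt(mean(base$x^2))

  # events drawn from a separate stream so crackle_rate = 0 leaves the base
  # byte-identical to the vesicular recording with the same seed
  n_events <- 0L
  with_seed(config$seed + 1000003L, {
    for (c_i in seq_len(n_cycles)) {
      k <- rpois(1, config$crackle_rate)
      if (k == 0) next
      cycle_start <- (c_i - 1) * config$cycle_length_s
      times <- cycle_start + runif(k, 0.02, insp_frac * config$cycle_length_s - 0.01)
      for (tt in times) {
        i0 <- round(tt * config$rate) + 1
        idx <- i0:min(i0 + burst_len - 1, base$n)
        x[idx] <- x[idx] + amp * burst[seq_along(idx)]
        n_events <- n_events + 1L
      }
    }
  })
  out <- list(signal = finish_signal(x, config, "crackle"),
              annotations = cycle_table(config, 1L, 0L),
              n_events = n_events)
  out
}

synth_generator <- function(class_label) {
  switch(class_label,
         vesicular = gen_vesicular, wheeze = gen_wheeze, crackle = gen_crackle)
}

#' Generate a synthetic labelled dataset on disk
#'
#' Writes `n_per_class` recordings for each of the three synthetic classes
#' (vesicular, wheeze, crackle) as WAV files with ICBHI-format annotation
#' text files, plus one diagnosis CSV mapping each synthetic patient to its
#' class label. Each recording belongs to its own synthetic patient. Fully
#' reproducible from `seed`.
#'
#' @param n_per_class Recordings per class (>= 1).
#' @param base_config A [synth_config()] supplying everything but class
#'   label and per-recording seed.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; per-recording seeds are derived from it.
#' @return A manifest tibble: `wav`, `annotation`, `patient_id`, `label`,
#'   `seed`; the diagnosis table is written to `diagnoses.csv` in `out_dir`.
#' @export
gen_dataset <- function(n_per_class, base_config = synth_config(), out_dir,
                        seed = 1) {
  if (n_per_class < 1) abort("`n_per_class` must be >= 1.", class = "sdcl_validation_error")
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) {
    abort(sprintf("Cannot write to directory: %s", out_dir), class = "sdcl_io_error")
  }
  classes <- c("vesicular", "wheeze", "crackle")
  rows <- list()
  idx <- 0L
  for (cl in classes) {
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      rec_seed <- as.integer(seed + 101L * idx)
      cfg <- base_config
      cfg$class_label <- cl
      cfg$seed <- rec_seed
      rec <- synth_generator(cl)(cfg)
      patient <- sprintf("P%03d", idx)
      stem <- file.path(out_dir, sprintf("%s_%s", patient, cl))
      write_wav(rec$signal, paste0(stem, ".wav"), "pcm16")
      write_annotations(rec$annotations, paste0(stem, ".txt"))
      rows[[idx]] <- tibble(wav = paste0(stem, ".wav"),
                            annotation = paste0(stem, ".txt"),
                            patient_id = patient, label = cl, seed = rec_seed)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  writeLines(c("patient_id,diagnosis",
               sprintf("%s,%s", manifest$patient_id, manifest$label)),
             file.path(out_dir, "diagnoses.csv"))
  manifest
}
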