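#' Default pipeline configuration
#'
#' Nested configuration for the end-to-end run: one section per stage plus
#' a global seed. Every section mirrors its stage's config constructor and
#' is validated through it before any computation starts.
#'
#' @return A named list of sections: `denoise`, `emd`, `surface`,
#'   `stopping_rule`, `cepstral`, `sdc`, `evaluate`, `synth`, `seed`,
#'   `log_level`.
#' @export
default_config <- function() {
  list(
    denoise = list(wavelet_name = "db8", levels = NULL, threshold_factor = 3,
                   max_iterations = 10, convergence_tol = 0.01,
                   passthrough = FALSE),
    emd = list(max_imfs = NULL, sift_sd_threshold = 0.2, max_sifts = 50),
    surface = list(fft_length = 256, hop = 128, window = "hann",
                   log_magnitude = TRUE, smoothing_bandwidth = c(2, 2)),
    stopping_rule = list(B = 1000, alpha = 0.05, multiplier = "rademacher"),
    cepstral = list(frame_length = 2048, hop = 512, window = "hann",
                    n_mels = 128, n_coeffs = 13, fmin = 0, fmax = NULL),
    sdc = list(d = 2, P = 2, K_blocks = 2),
    evaluate = list(test_fraction = 0.2, stratified = TRUE,
                    classifiers = c("svm", "knn", "rf"),
                    pool = "mean"),
    synth = list(rate = 4000, duration_s = 10, cycle_length_s = 2.5,
                 snr_db = 5, wheeze_freq = 400, crackle_rate = 8),
    seed = 1,
    log_level = "info"
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      abort(sprintf("Unknown configuration key: %s", full),
            class = "sdcl_validation_error")
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        abort(sprintf("Configuration section %s must be a mapping.", full),
              class = "sdcl_validation_error")
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      # [key] <- list(...) keeps explicit NULLs instead of deleting the entry
      defaults[key] <- list(user[[key]])
    }
  }
  defaults
}

validate_config <- function(config) {
  dn <- config$denoise
  denoise_config(dn$wavelet_name, dn$levels, dn$threshold_factor,
                 dn$max_iterations, dn$convergence_tol)
  em <- config$emd
  emd_config(em$max_imfs, em$sift_sd_threshold, em$max_sifts)
  su <- config$surface
  surface_config(su$fft_length, su$hop, su$window, su$log_magnitude,
                 su$smoothing_bandwidth)
  ce <- config$cepstral
  frame_config(ce$frame_length, ce$hop, ce$window, ce$n_mels, ce$n_coeffs,
               ce$fmin, ce$fmax)
  sd_ <- config$sdc
  sdc_config(sd_$d, sd_$P, sd_$K_blocks)
  sr <- config$stopping_rule
  if (sr$B < 19) abort("stopping_rule.B must be >= 19.", class = "sdcl_validation_error")
  if (sr$alpha <= 0 || sr$alpha >= 1) {
    abort("stopping_rule.alpha must be in (0, 1).", class = "sdcl_validation_error")
  }
  ev <- config$evaluate
  if (ev$test_fraction <= 0 || ev$test_fraction >= 1) {
    abort("evaluate.test_fraction must be in (0, 1).", class = "sdcl_validation_error")
  }
  unknown <- setdiff(ev$classifiers, names(classifier_registry()))
  if (length(unknown)) {
    abort(sprintf("Unknown classifier '%s' (available: %s).", unknown[1],
                  paste(names(classifier_registry()), collapse = ", ")),
          class = "sdcl_validation_error")
  }
  invisible(config)
}

classifier_registry <- function() {
  list(svm = classifier_svm(), svm_radial = classifier_svm("radial"),
       knn = classifier_knn(), rf = classifier_rf(), lda = classifier_lda(),
       mlp = classifier_mlp())
}

#' Load and validate a pipeline configuration file
#'
#' Reads a YAML document, fills absent keys with [default_config()] values,
#' rejects unknown keys, and validates every section through its stage's
#' constructor.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return The validated nested configuration list.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  config <- merge_config(default_config(), user)
  validate_config(config)
  config
}

pipeline_configs <- function(config) {
  dn <- config$denoise; em <- config$emd; su <- config$surface
  ce <- config$cepstral; sd_ <- config$sdc
  list(
    denoise = denoise_config(dn$wavelet_name, dn$levels, dn$threshold_factor,
                             dn$max_iterations, dn$convergence_tol),
    emd = emd_config(em$max_imfs, em$sift_sd_threshold, em$max_sifts),
    surface = surface_config(su$fft_length, su$hop, su$window,
                             su$log_magnitude, su$smoothing_bandwidth),
    cepstral = frame_config(ce$frame_length, ce$hop, ce$window, ce$n_mels,
                            ce$n_coeffs, ce$fmin, ce$fmax),
    sdc = sdc_config(sd_$d, sd_$P, sd_$K_blocks)
  )
}

#' Run the full feature-extraction and evaluation pipeline
#'
#' For every recording in the manifest: denoise, segment into annotated
#' respiration cycles, and per cycle either run the stopping rule to choose
#' K or use the fixed `k`; extract three pooled feature vectors per cycle
#' (MFCC, SDC in the original space, SDC-L in the reduced subspace); then
#' evaluate every configured classifier on each feature set. Deterministic
#' given the configuration seed.
#'
#' @param config A configuration list from [load_config()] /
#'   [default_config()].
#' @param manifest Tibble with columns `wav`, `annotation`, `label` (as
#'   produced by [gen_dataset()]).
#' @param k Fixed number of retained IMFs; `NULL` runs [select_k()] per
#'   cycle (slow — the bootstrap dominates).
#' @return An `sdcl_report`: list with `metrics` (tibble: feature,
#'   classifier, accuracy, precision, recall, f1), `k_trail` (tibble:
#'   recording, cycle, k, statistic, p_value, selected_k), `features`
#'   (per-cycle feature tibbles), and `config`.
#' @export
run_pipeline <- function(config = default_config(), manifest, k = 2) {
  validate_config(config)
  if (nrow(manifest) == 0) abort("Manifest is empty.", class = "sdcl_validation_error")
  cfgs <- pipeline_configs(config)
  sr <- config$stopping_rule
  pool_scheme <- config$evaluate$pool

  feats_mfcc <- list(); feats_sdc <- list(); feats_sdcl <- list()
  labels <- character(); trail_rows <- list()
  item <- 0L

  for (r in seq_len(nrow(manifest))) {
    rec_id <- basename(manifest$wav[r])
    stage <- "read"
    tryCatch({
      sig <- read_wav(manifest$wav[r])
      ann <- parse_annotations(manifest$annotation[r])
      stage <- "denoise"
      clean <- denoised(sig, cfgs$denoise, passthrough = isTRUE(config$denoise$passthrough))
      stage <- "segment"
      cycles <- segment_cycles(clean, ann)
      for (ci in seq_along(cycles)) {
        stage <- sprintf("cycle %d", ci)
        cyc <- cycles[[ci]]
        item <- item + 1L
        decomp <- emd(cyc, cfgs$emd)
        if (length(decomp$imfs) == 0) next
        if (is.null(k)) {
          sel <- select_k(cyc, cfgs$emd, cfgs$surface, B = sr$B,
                          alpha = sr$alpha,
                          seed = config$seed + 13L * item,
                          multiplier = sr$multiplier)
          k_used <- sel$K
          tr <- tidy(sel)
          if (nrow(tr)) {
            tr$recording <- rec_id; tr$cycle <- ci; tr$selected_k <- sel$K
            trail_rows[[length(trail_rows) + 1L]] <- tr
          }
        } else {
          k_used <- min(k, length(decomp$imfs))
        }
        C_full <- mfcc(cyc, cfgs$cepstral)
        low <- audio_signal(emd_reconstruct(decomp, k_used), cyc$rate)
        C_low <- mfcc(low, cfgs$cepstral)
        feats_mfcc[[item]] <- pool_features(C_full$coeffs, pool_scheme)
        feats_sdc[[item]] <- pool_features(sdc_adjusted(C_full, cfgs$sdc), pool_scheme)
        feats_sdcl[[item]] <- pool_features(sdc_adjusted(C_low, cfgs$sdc), pool_scheme)
        labels <- c(labels, manifest$label[r])
      }
    }, sdcl_validation_error = function(e) {
      abort(sprintf("Pipeline failed at stage '%s' of recording %s: %s",
                    stage, rec_id, conditionMessage(e)),
            class = "sdcl_pipeline_error")
    })
  }

  keep <- !vapply(feats_mfcc, is.null, TRUE)
  sets <- list(
    mfcc = do.call(rbind, feats_mfcc[keep]),
    sdc = do.call(rbind, feats_sdc[keep]),
    `sdc-l` = do.call(rbind, feats_sdcl[keep])
  )

  registry <- classifier_registry()
  rows <- list()
  for (fname in names(sets)) {
    for (cname in config$evaluate$classifiers) {
      rep <- evaluate_features(sets[[fname]], labels, registry[[cname]],
                               test_fraction = config$evaluate$test_fraction,
                               stratified = config$evaluate$stratified,
                               seed = config$seed)
      g <- glance(rep)
      rows[[length(rows) + 1L]] <- tibble(
        feature = fname, classifier = cname,
        accuracy = g$accuracy, precision = g$precision,
        recall = g$recall, f1 = g$f1
      )
    }
  }

  structure(list(
    metrics = dplyr::bind_rows(rows),
    k_trail = if (length(trail_rows)) dplyr::bind_rows(trail_rows) else
      tibble(k = integer(), statistic = double(), p_value = double(),
             reject = logical(), recording = character(), cycle = integer(),
             selected_k = integer()),
    features = sets, labels = labels, config = config
  ), class = "sdcl_report")
}

#' @export
print.sdcl_report <- function(x, ...) {
  cat(sprintf("<sdcl_report> %d cycles, %d feature sets x %d classifiers\n",
              length(x$labels), length(x$features),
              length(unique(x$metrics$classifier))))
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.sdcl_report <- function(x, ...) x$metrics

#' @export
autoplot.sdcl_report <- function(object, ...) {
  ggplot2::ggplot(object$metrics,
                  ggplot2::aes(x = .data$classifier, y = .data$accuracy,
                               fill = .data$feature)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "accuracy", x = NULL, fill = "feature") +
    ggplot2::theme_minimal()
}

#' Serialise a pipeline report to JSON
#'
#' Writes the metrics table and K-selection trail as a JSON document;
#' byte-stable for identical reports.
#'
#' @param report An `sdcl_report` from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  payload <- list(
    seed = report$config$seed,
    metrics = report$metrics,
    k_trail = report$k_trail
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
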