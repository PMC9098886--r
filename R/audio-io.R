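#' Read a WAV file
#'
#' Reads a RIFF/WAV file (integer PCM at 8, 16, 24 or 32 bits, or IEEE float
#' at 32 or 64 bits). Integer PCM samples are rescaled to `[-1, 1]`.
#' Multichannel files are reduced to channel 1 with a warning; respiratory
#' sound corpora such as ICBHI are mono so this only affects foreign inputs.
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_signal()]; `source_id` is the file's base name.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("WAV file not found: %s", path), class = "sdcl_io_error")
  }
  size <- file.info(path)$size
  if (is.na(size) || size < 44) {
    abort(sprintf("Not a parseable WAV file (too short): %s", path),
          class = "sdcl_format_error")
  }
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  riff <- readChar(con, 4, useBytes = TRUE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    abort(sprintf("Not a RIFF/WAVE file: %s", path), class = "sdcl_format_error")
  }

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    chunk_size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", chunk_size)
      u16 <- function(off) sum(as.integer(body[off + 1:2]) * c(1, 256))
      u32 <- function(off) sum(as.integer(body[off + 1:4]) * c(1, 256, 65536, 16777216))
      fmt <- list(
        audio_format = u16(0), n_channels = u16(2), rate = u32(4),
        bits = u16(14)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", chunk_size)
    } else {
      # skip unknown chunk (word-aligned)
      invisible(readBin(con, "raw", chunk_size + chunk_size %% 2))
      next
    }
    if (chunk_size %% 2 == 1) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    abort(sprintf("WAV file missing fmt/data chunk: %s", path), class = "sdcl_format_error")
  }
  if (length(data_raw) == 0) {
    abort(sprintf("WAV file has an empty data chunk: %s", path), class = "sdcl_format_error")
  }

  bits <- fmt$bits
  n_ch <- fmt$n_channels
  x <- switch(
    as.character(fmt$audio_format),
    "1" = {  # integer PCM
      if (bits == 8) {
        (as.integer(data_raw) - 128) / 128
      } else if (bits == 16) {
        readBin(data_raw, "integer", length(data_raw) / 2, size = 2,
                signed = TRUE, endian = "little") / 32768
      } else if (bits == 24) {
        n <- length(data_raw) %/% 3
        b <- matrix(as.integer(data_raw[seq_len(3 * n)]), nrow = 3)
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      } else if (bits == 32) {
        readBin(data_raw, "integer", length(data_raw) / 4, size = 4,
                endian = "little") / 2147483648
      } else {
        abort(sprintf("Unsupported PCM bit depth %d in %s", bits, path),
              class = "sdcl_format_error")
      }
    },
    "3" = {  # IEEE float
      readBin(data_raw, "double", length(data_raw) / (bits / 8),
              size = bits / 8, endian = "little")
    },
    abort(sprintf("Unsupported WAV audio format code %d in %s", fmt$audio_format, path),
          class = "sdcl_format_error")
  )
  if (n_ch > 1) {
    warn(sprintf("%s has %d channels; using channel 1 only.", basename(path), n_ch))
    x <- x[seq(1, length(x), by = n_ch)]
  }
  audio_signal(x, rate = fmt$rate, source_id = basename(path))
}

#' Write a WAV file
#'
#' Writes an [audio_signal()] to a RIFF/WAV file. Samples outside `[-1, 1]`
#' are clipped with a warning before quantisation.
#'
#' @param signal An [audio_signal()].
#' @param path Output path.
#' @param bit_depth One of `"pcm16"`, `"pcm24"`, `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, bit_depth = c("pcm16", "pcm24", "float32")) {
  stopifnot(inherits(signal, "audio_signal"))
  bit_depth <- match.arg(bit_depth)
  x <- signal$samples
  if (any(x > 1 | x < -1)) {
    warn("Samples outside [-1, 1] clipped before writing.")
    x <- pmin(pmax(x, -1), 1)
  }
  rate <- as.integer(round(signal$rate))

  con <- tryCatch(file(path, "wb"),
                  error = function(e) abort(sprintf("Cannot open %s for writing: %s",
                                                    path, conditionMessage(e)),
                                            class = "sdcl_io_error"))
  on.exit(close(con), add = TRUE)

  spec <- switch(bit_depth,
    pcm16   = list(fmt = 1L, bits = 16L),
    pcm24   = list(fmt = 1L, bits = 24L),
    float32 = list(fmt = 3L, bits = 32L)
  )
  bytes_per <- spec$bits %/% 8L
  data_size <- length(x) * bytes_per

  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(spec$fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(as.integer(rate * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(spec$bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")

  if (bit_depth == "pcm16") {
    q <- as.integer(pmin(pmax(round(x * 32767), -32768), 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else if (bit_depth == "pcm24") {
    q <- pmin(pmax(round(x * 8388607), -8388608), 8388607)
    q <- ifelse(q < 0, q + 16777216, q)
    b <- rbind(q %% 256, (q %/% 256) %% 256, (q %/% 65536) %% 256)
    writeBin(as.raw(as.integer(b)), con)
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Parse an ICBHI-style respiration-cycle annotation file
#'
#' Each non-empty line holds four whitespace-separated fields: cycle start
#' (s), cycle end (s), crackle flag (0/1), wheeze flag (0/1).
#'
#' @param path Path to the annotation text file.
#' @return A tibble with columns `start_s`, `end_s`, `crackle`, `wheeze`,
#'   one row per respiration cycle in file order.
#' @export
parse_annotations <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Annotation file not found: %s", path), class = "sdcl_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) {
    return(tibble(start_s = double(), end_s = double(),
                  crackle = integer(), wheeze = integer()))
  }
  rows <- lapply(keep, function(i) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) != 4) {
      abort(sprintf("Line %d of %s: expected 4 columns, found %d.",
                    i, basename(path), length(toks)),
            class = "sdcl_format_error")
    }
    vals <- suppressWarnings(as.numeric(toks))
    if (any(is.na(vals))) {
      abort(sprintf("Line %d of %s: non-numeric field.", i, basename(path)),
            class = "sdcl_format_error")
    }
    vals
  })
  m <- do.call(rbind, rows)
  ann <- tibble(
    start_s = m[, 1], end_s = m[, 2],
    crackle = as.integer(m[, 3]), wheeze = as.integer(m[, 4])
  )
  validate_annotations(ann, origin = basename(path))
  ann
}

validate_annotations <- function(ann, origin = "annotations") {
  bad <- which(!(ann$start_s >= 0 & ann$start_s < ann$end_s))
  if (length(bad)) {
    abort(sprintf("%s: cycle %d has start >= end (or negative start).",
                  origin, bad[1]), class = "sdcl_validation_error")
  }
  if (!all(ann$crackle %in% c(0L, 1L)) || !all(ann$wheeze %in% c(0L, 1L))) {
    abort(sprintf("%s: crackle/wheeze flags must be 0 or 1.", origin),
          class = "sdcl_validation_error")
  }
  invisible(ann)
}

#' Write an ICBHI-style annotation file
#'
#' Inverse of [parse_annotations()]: writes one tab-separated line per cycle.
#' Times are written with enough digits that a parse round-trip reproduces
#' the doubles exactly.
#'
#' @param annotations Tibble as returned by [parse_annotations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  validate_annotations(annotations)
  fmt_num <- function(x) formatC(x, digits = 17, format = "g")
  lines <- sprintf("%s\t%s\t%d\t%d",
                   fmt_num(annotations$start_s), fmt_num(annotations$end_s),
                   annotations$crackle, annotations$wheeze)
  writeLines(lines, path)
  invisible(path)
}

#' Load a patient-diagnosis table, dropping rare diagnosis classes
#'
#' Reads a two-column table (patient id, diagnosis label) and drops every
#' diagnosis class represented by fewer than `min_subjects` distinct
#' patients, mirroring the usual corpus curation step in which rare classes
#' are excluded before multiclass classification. Matching of diagnosis
#' labels is case-insensitive with surrounding whitespace stripped.
#'
#' @param path Path to a 2-column CSV/TSV; the delimiter (comma, tab or
#'   whitespace) is auto-detected from the first line. A first line whose
#'   second field reads "diagnosis" is treated as a header.
#' @param min_subjects Minimum number of distinct patients a diagnosis class
#'   needs to be retained (default 5).
#' @return A tibble with columns `patient_id` and `diagnosis`, one row per
#'   retained patient.
#' @export
load_diagnoses <- function(path, min_subjects = 5) {
  if (!file.exists(path)) {
    abort(sprintf("Diagnosis table not found: %s", path), class = "sdcl_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(patient_id = character(), diagnosis = character()))
  }
  first <- lines[[1]]
  delim <- if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else "\\s+"
  split1 <- function(l) trimws(strsplit(l, delim)[[1]])
  toks <- lapply(lines, split1)
  bad <- which(vapply(toks, length, 1L) < 2)
  if (length(bad)) {
    abort(sprintf("Line %d of %s: expected 2 delimited columns.", bad[1], basename(path)),
          class = "sdcl_format_error")
  }
  if (grepl("diagnosis", tolower(toks[[1]][2]))) toks <- toks[-1]
  ids <- vapply(toks, `[`, "", 1L)
  diag <- vapply(toks, `[`, "", 2L)
  key <- tolower(diag)

  # conflicting duplicate ids are an error; identical duplicates collapse
  by_id <- split(key, ids)
  conflict <- names(by_id)[vapply(by_id, function(k) length(unique(k)) > 1, TRUE)]
  if (length(conflict)) {
    abort(sprintf("Patient %s appears with conflicting diagnoses.", conflict[1]),
          class = "sdcl_validation_error")
  }
  dup <- duplicated(ids)
  ids <- ids[!dup]; diag <- diag[!dup]; key <- key[!dup]

  # canonical casing: first occurrence per class
  canon <- tapply(diag, key, function(v) v[1])
  class_sizes <- table(key)
  keep_classes <- names(class_sizes)[class_sizes >= min_subjects]
  sel <- key %in% keep_classes
  tibble(patient_id = ids[sel], diagnosis = unname(canon[key[sel]]))
}

#' Cut a recording into annotated respiration-cycle segments
#'
#' Segment `i` holds the samples in the half-open index interval
#' `[round(start_s * rate), round(end_s * rate))` (0-based indices,
#' round-half-to-even), so abutting cycles share no sample.
#'
#' @param signal An [audio_signal()].
#' @param annotations Tibble as returned by [parse_annotations()].
#' @return A list of [audio_signal()] segments in annotation order.
#' @export
segment_cycles <- function(signal, annotations) {
  stopifnot(inherits(signal, "audio_signal"))
  validate_annotations(annotations)
  n <- length(signal$samples)
  rate <- signal$rate
  out <- vector("list", nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    i0 <- round(annotations$start_s[i] * rate)
    i1 <- round(annotations$end_s[i] * rate)
    if (i1 > n + 1) {
      abort(sprintf("Cycle %d ends at %.3f s, beyond the %.3f s signal.",
                    i, annotations$end_s[i], n / rate),
            class = "sdcl_validation_error")
    }
    i1 <- min(i1, n)
    if (i1 <= i0) {
      abort(sprintf("Cycle %d is empty after rounding to sample indices.", i),
            class = "sdcl_validation_error")
    }
    out[[i]] <- audio_signal(signal$samples[(i0 + 1):i1], rate = rate,
                             source_id = sprintf("%s#cycle%d", signal$source_id, i))
  }
  out
}
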