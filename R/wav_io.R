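#' Write a mono WAV file
#'
#' Minimal RIFF/WAVE writer for mono audio, either 16-bit PCM or 32-bit IEEE
#' float. Covers the stimulus-export needs of the package without an audio
#' dependency.
#'
#' @param samples Numeric vector in `[-1, 1]`.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param path Output file path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate_hz, path, bits = 16) {
  stopifnot(bits %in% c(16, 32), is.numeric(samples))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  bytes_per_sample <- bits / 8
  data_size <- n * bytes_per_sample
  fmt_tag <- if (bits == 16) 1L else 3L # PCM vs IEEE float

  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_tag, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little") # mono
  writeBin(as.integer(sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * bytes_per_sample), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per_sample), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16) {
    writeBin(as.integer(round(pmax(-1, pmin(1, samples)) * 32767)), con,
             size = 2, endian = "little")
  } else {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file written by [write_wav()]
#'
#' @param path File path.
#' @return List with `samples` (numeric, in `[-1, 1]` for PCM) and
#'   `sample_rate_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  }
  fmt_tag <- NA_integer_
  n_channels <- NA_integer_
  sample_rate <- NA_integer_
  bits <- NA_integer_
  repeat {
    chunk_id <- readChar(con, 4)
    if (length(chunk_id) == 0L || nchar(chunk_id) < 4L) stop("no data chunk found", call. = FALSE)
    chunk_size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(chunk_id, "fmt ")) {
      fmt_tag <- readBin(con, integer(), size = 2, endian = "little")
      n_channels <- readBin(con, integer(), size = 2, endian = "little")
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      extra <- chunk_size - 16L
      if (extra > 0L) invisible(readBin(con, raw(), n = extra))
    } else if (identical(chunk_id, "data")) {
      if (n_channels != 1L) stop("only mono WAV supported", call. = FALSE)
      if (fmt_tag == 1L && bits == 16L) {
        raw_vals <- readBin(con, integer(), n = chunk_size / 2, size = 2,
                            signed = TRUE, endian = "little")
        samples <- raw_vals / 32767
      } else if (fmt_tag == 3L && bits == 32L) {
        samples <- readBin(con, numeric(), n = chunk_size / 4, size = 4,
                           endian = "little")
      } else {
        stop("unsupported WAV encoding", call. = FALSE)
      }
      return(list(samples = samples, sample_rate_hz = sample_rate))
    } else {
      invisible(readBin(con, raw(), n = chunk_size))
    }
  }
}

#' Export a call library as WAV files plus a JSON manifest
#'
#' Writes one mono WAV per call and a manifest mapping each call id to its
#' category, relative WAV path and duration.
#'
#' @param library A [synth_call_library()] object.
#' @param dir Output directory (created if missing).
#' @param bits Bit depth for [write_wav()].
#' @return Path of the manifest file, invisibly.
#' @export
export_call_library <- function(library, dir, bits = 16) {
  stopifnot(inherits(library, "call_library"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (id in names(library$calls)) {
    w <- library$calls[[id]]
    wav_name <- paste0(id, ".wav")
    write_wav(w$samples, w$sample_rate_hz, file.path(dir, wav_name), bits = bits)
    manifest[[id]] <- list(
      category = w$category,
      wav = wav_name,
      duration_ms = w$duration_ms,
      sample_rate_hz = w$sample_rate_hz
    )
  }
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest_path)
}

#' Import a call library exported with [export_call_library()]
#'
#' @param dir Directory containing `manifest.json` and the WAV files.
#' @return A `call_library` object.
#' @export
import_call_library <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  calls <- list()
  categories <- list()
  for (id in names(manifest)) {
    m <- manifest[[id]]
    wav <- read_wav(file.path(dir, m$wav))
    w <- call_waveform(id, m$category, wav$samples, wav$sample_rate_hz)
    calls[[id]] <- w
    categories[[m$category]] <- c(categories[[m$category]], id)
  }
  structure(list(calls = calls, categories = categories, seed = NA),
            class = "call_library")
}
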