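# File formats: BIDS-dialect events TSV, flat-binary float32 recordings
# with a JSON sidecar, a minimal EDF writer/reader, and tab-separated
# spectra / cluster tables.  Every writer emits provenance comment lines
# ("# key: value") which readers skip.

provenance_lines <- function(seed = NULL, extra = NULL) {
  lines <- c(sprintf("# generator: chunktag %s", .chunktag_version()))
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed: %d", as.integer(seed)))
  if (!is.null(extra)) lines <- c(lines, sprintf("# %s: %s", names(extra), extra))
  lines
}

write_tsv_with_header <- function(df, path, seed = NULL, extra = NULL) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_lines(seed, extra), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    body <- do.call(paste, c(lapply(df, function(col) {
      if (is.numeric(col) && !is.integer(col)) format(col, digits = 15, trim = TRUE, scientific = FALSE)
      else as.character(col)
    }), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

#' Write / read an event table as tab-separated text
#'
#' BIDS-events dialect: columns `onset`, `duration`, `trial_type` first
#' (with `trial_type` carrying the dependency role), then the remaining
#' event fields; UTF-8, '.' decimal, leading `# key: value` provenance
#' lines.
#'
#' @param events an [event_table()].
#' @param path output file path.
#' @param seed optional integer recorded in the provenance header.
#' @return `path`, invisibly (writer); an [event_table()] (reader).
#' @export
write_events <- function(events, path, seed = NULL) {
  df <- data.frame(
    onset = events$onset_s,
    duration = events$duration_s,
    trial_type = events$role,
    syllable = events$syllable,
    chunk_index = events$chunk_index,
    position = events$position,
    condition = events$condition,
    phase = events$phase,
    trial_index = events$trial_index,
    stringsAsFactors = FALSE
  )
  write_tsv_with_header(df, path, seed = seed)
}

#' @rdname write_events
#' @param timing a [timing_spec()] used to validate the re-read table.
#' @export
read_events <- function(path, timing = timing_spec()) {
  # na.strings disabled: "NA" is a real syllable label in the inventory
  df <- utils::read.delim(path, comment.char = "#", fileEncoding = "UTF-8",
                          na.strings = character(0))
  needed <- c("onset", "duration", "trial_type", "syllable", "chunk_index",
              "position", "condition", "phase", "trial_index")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("malformed events file, missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  event_table(data.frame(
    onset_s = df$onset, duration_s = df$duration,
    syllable = as.character(df$syllable),
    chunk_index = as.integer(df$chunk_index),
    position = as.integer(df$position),
    condition = as.character(df$condition),
    phase = as.character(df$phase),
    role = as.character(df$trial_type),
    trial_index = as.integer(df$trial_index),
    stringsAsFactors = FALSE
  ), timing = timing)
}

#' Write / read a recording as flat binary + JSON sidecar
#'
#' Samples are little-endian 32-bit floats, channel-interleaved (channel
#' index varies fastest), in `<path>`; the sidecar `<path>.json` records
#' sampling rate, shape, channel labels and byte order.  Round trips are
#' exact to float32 precision (~1e-7 relative).
#'
#' @param rec an `eeg_recording`.
#' @param path output path for the binary payload (sidecar gets `.json`
#'   appended).
#' @param seed optional integer recorded in the sidecar.
#' @return `path`, invisibly (writer); an `eeg_recording` (reader).
#' @export
write_recording_bin <- function(rec, path, seed = NULL) {
  sidecar <- list(
    generator = paste("chunktag", .chunktag_version()),
    srate = rec$srate,
    n_channels = nrow(rec$data),
    n_samples = ncol(rec$data),
    labels = rec$labels,
    dtype = "float32",
    byte_order = "little",
    order = "channel-interleaved"
  )
  if (!is.null(seed)) sidecar$seed <- as.integer(seed)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_recording_bin
#' @param expected_srate if given, a mismatch with the sidecar is an error.
#' @export
read_recording_bin <- function(path, expected_srate = NULL) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path))
    stop("missing sidecar: ", sidecar_path, call. = FALSE)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (k in c("srate", "n_channels", "n_samples"))
    if (is.null(meta[[k]])) stop("malformed sidecar: missing ", k, call. = FALSE)
  if (!is.null(expected_srate) && meta$srate != expected_srate)
    stop("sampling rate mismatch: sidecar ", meta$srate, " vs expected ",
         expected_srate, call. = FALSE)
  n <- meta$n_channels * meta$n_samples
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n + 1L, size = 4L, endian = "little")
  if (length(x) != n)
    stop("payload size does not match sidecar shape", call. = FALSE)
  data <- matrix(x, meta$n_channels, meta$n_samples)
  recording(data, meta$srate, labels = meta$labels)
}

# ---- minimal EDF (continuous, one data record, 16-bit) ------------------

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write / read a recording in EDF format
#'
#' A minimal European Data Format writer/reader: continuous recording, one
#' data record holding all samples, 16-bit little-endian integers with
#' per-channel physical scaling.  Round trips are exact to the 16-bit
#' quantization step `(max - min) / 65535` per channel.
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @return `path`, invisibly (writer); an `eeg_recording` (reader).
#' @export
write_edf <- function(rec, path) {
  data <- rec$data
  ns <- nrow(data); nsamp <- ncol(data)
  pmin_ <- apply(data, 1L, min); pmax_ <- apply(data, 1L, max)
  flat <- pmax_ - pmin_ == 0
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8L),
    edf_pad("X X X X", 80L),                        # patient id
    edf_pad("Startdate X chunktag", 80L),           # recording id
    edf_pad("01.01.00", 8L), edf_pad("00.00.00", 8L),
    edf_pad(256L + ns * 256L, 8L),
    edf_pad("", 44L),
    edf_pad(1L, 8L),                                # one data record
    edf_pad(format(nsamp / rec$srate, digits = 8), 8L),
    edf_pad(ns, 4L)
  )
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(rec$labels, edf_pad, "", width = 16L),
    rep(edf_pad("", 80L), ns),                      # transducer
    rep(edf_pad("uV", 8L), ns),
    vapply(format(pmin_, digits = 7), edf_pad, "", width = 8L),
    vapply(format(pmax_, digits = 7), edf_pad, "", width = 8L),
    rep(edf_pad(dmin, 8L), ns),
    rep(edf_pad(dmax, 8L), ns),
    rep(edf_pad("", 80L), ns),                      # prefiltering
    rep(edf_pad(nsamp, 8L), ns),
    rep(edf_pad("", 32L), ns)                       # reserved
  )
  for (f in fields) writeChar(paste0(f, collapse = ""), con, eos = NULL)
  for (ch in seq_len(ns)) {
    scaled <- (data[ch, ] - pmin_[ch]) / (pmax_[ch] - pmin_[ch])
    dig <- as.integer(round(dmin + scaled * (dmax - dmin)))
    writeBin(dig, con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' @rdname write_edf
#' @param expected_srate if given, a mismatch with the header is an error.
#' @export
read_edf <- function(path, expected_srate = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8L); rd(80L); rd(80L); rd(8L); rd(8L)
  n_header <- as.integer(rd(8L)); rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header", call. = FALSE)
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16L), ""))
  vapply(seq_len(ns), function(i) rd(80L), "")
  vapply(seq_len(ns), function(i) rd(8L), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  vapply(seq_len(ns), function(i) rd(80L), "")
  nsamp <- as.integer(vapply(seq_len(ns), function(i) rd(8L), ""))
  vapply(seq_len(ns), function(i) rd(32L), "")
  if (length(unique(nsamp)) != 1L)
    stop("per-channel sample counts differ; unsupported", call. = FALSE)
  srate <- nsamp[1L] / rec_dur
  if (!is.null(expected_srate) && abs(srate - expected_srate) > 1e-6)
    stop("sampling rate mismatch: EDF ", srate, " vs expected ",
         expected_srate, call. = FALSE)
  data <- matrix(0, ns, nsamp[1L] * n_rec)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nsamp[ch], size = 2L,
                     endian = "little", signed = TRUE)
      phys <- pmin_[ch] + (dig - dmin[ch]) / (dmax[ch] - dmin[ch]) *
        (pmax_[ch] - pmin_[ch])
      data[ch, (r - 1L) * nsamp[1L] + seq_len(nsamp[1L])] <- phys
    }
  }
  recording(data, srate, labels = labels)
}

#' Write / read a spectra table (tab-separated)
#'
#' One row per frequency bin with EP, normalized EP and ITPC columns
#' (channel-averaged, plus any extra columns supplied).  Numeric round
#' trips are exact to better than 1e-6.
#'
#' @param df data.frame with at least a `frequency` column.
#' @param path output file path.
#' @param seed optional integer recorded in the provenance header.
#' @return `path`, invisibly (writer); a data.frame (reader).
#' @export
write_spectra <- function(df, path, seed = NULL) {
  stopifnot("frequency" %in% names(df))
  write_tsv_with_header(df, path, seed = seed)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  utils::read.delim(path, comment.char = "#")
}

#' Write a cluster test result as tab-separated text
#'
#' Emits the cluster table (id, sign, size, mass, p) and, with
#' `members = TRUE`, a second file `<path>.members.tsv` listing the
#' (channel, sample) members of each cluster.
#'
#' @param x a `cluster_test`.
#' @param path output file path.
#' @param members also write the member list (default TRUE).
#' @param seed optional integer recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(x, path, members = TRUE, seed = NULL) {
  write_tsv_with_header(x$clusters, path, seed = seed,
                        extra = c(n_perm = as.character(x$n_perm)))
  if (members && length(x$members)) {
    mem <- do.call(rbind, lapply(seq_along(x$members), function(id) {
      data.frame(id = id, x$members[[id]])
    }))
    write_tsv_with_header(mem, paste0(path, ".members.tsv"), seed = seed)
  }
  invisible(path)
}
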