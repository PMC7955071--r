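# Minimal European Data Format (EDF) support: fixed-layout ASCII header,
# 16-bit little-endian samples scaled between digital and physical ranges.
# An "EDF Annotations" signal (EDF+) is skipped on read; scored events are
# supplied through the sidecar mechanism of read_recording() instead.

edf_field <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

#' Read an EDF recording
#'
#' Parses the standard EDF header and signal records and returns all
#' ordinary signal channels at their stated physical scale. All channels
#' must share one sampling rate (true of the two-derivation sleep montage
#' this package targets); an EDF+ annotations channel is ignored.
#'
#' @param path path to an `.edf` file.
#' @return an [eeg_recording].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- edf_field(con, 8)
  if (version != "0") stop("corrupt EDF header (version field '", version, "')")
  readBin(con, "raw", 80 + 80 + 8 + 8)          # patient, recording, date, time
  header_bytes <- as.integer(edf_field(con, 8))
  readBin(con, "raw", 44)                        # reserved
  n_records <- as.integer(edf_field(con, 8))
  record_dur <- as.numeric(edf_field(con, 8))
  ns <- as.integer(edf_field(con, 4))
  if (is.na(ns) || ns < 1 || is.na(n_records)) stop("corrupt EDF header")
  labels   <- vapply(seq_len(ns), function(i) edf_field(con, 16), "")
  readBin(con, "raw", ns * (80 + 8))             # transducer, dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(edf_field(con, 8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(edf_field(con, 8)), 0)
  dig_min  <- vapply(seq_len(ns), function(i) as.numeric(edf_field(con, 8)), 0)
  dig_max  <- vapply(seq_len(ns), function(i) as.numeric(edf_field(con, 8)), 0)
  readBin(con, "raw", ns * 80)                   # prefiltering
  nsamp    <- vapply(seq_len(ns), function(i) as.integer(edf_field(con, 8)), 0L)
  readBin(con, "raw", ns * 32)                   # reserved
  seek(con, header_bytes)

  keep <- which(labels != "EDF Annotations")
  if (length(keep) == 0) stop("EDF file has no signal channels")
  if (length(unique(nsamp[keep])) != 1)
    stop("channels with differing sampling rates are not supported")
  fs <- nsamp[keep[1]] / record_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  sig <- lapply(keep, function(i) numeric(n_records * nsamp[i]))
  names(sig) <- labels[keep]
  for (rec in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = nsamp[i], size = 2,
                     signed = TRUE, endian = "little")
      if (i %in% keep) {
        j <- match(i, keep)
        sig[[j]][((rec - 1) * nsamp[i] + 1):(rec * nsamp[i])] <-
          phys_min[i] + gain[i] * (raw - dig_min[i])
      }
    }
  }
  eeg_recording(sig, fs)
}

pad_field <- function(x, n) {
  x <- as.character(x)
  if (nchar(x) > n) stop("EDF header field too long: ", x)
  formatC(x, width = -n)
}

#' Write an EDF recording
#'
#' Writes an [eeg_recording] as a plain EDF file with one data record per
#' second. Samples are quantized to the 16-bit digital range spanning the
#' observed physical range of each channel, so a round-trip preserves
#' signals to quantization precision (about 1/65000 of the channel range).
#'
#' @param rec an [eeg_recording]; total length must be a whole number of
#'   seconds.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- length(rec$channels)
  n_total <- length(rec$samples[[1]])
  nsamp <- as.integer(round(rec$fs))
  if (n_total %% nsamp != 0)
    stop("recording length must be a whole number of seconds")
  n_records <- n_total %/% nsamp
  phys_min <- vapply(rec$samples, function(s) floor(min(s)) - 1, 0)
  phys_max <- vapply(rec$samples, function(s) ceiling(max(s)) + 1, 0)
  dig_min <- rep(-32768, ns); dig_max <- rep(32767, ns)
  header_bytes <- 256 + ns * 256

  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x, n) writeBin(charToRaw(pad_field(x, n)), con)
  put("0", 8); put("X X X X", 80); put("Startdate X X X X", 80)
  put("01.01.00", 8); put("00.00.00", 8)
  put(header_bytes, 8); put("", 44); put(n_records, 8); put(1, 8); put(ns, 4)
  for (lab in rec$channels) put(lab, 16)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put("uV", 8)
  for (i in seq_len(ns)) put(phys_min[i], 8)
  for (i in seq_len(ns)) put(phys_max[i], 8)
  for (i in seq_len(ns)) put(dig_min[i], 8)
  for (i in seq_len(ns)) put(dig_max[i], 8)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put(nsamp, 8)
  for (i in seq_len(ns)) put("", 32)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      seg <- rec$samples[[i]][((r - 1) * nsamp + 1):(r * nsamp)]
      dig <- as.integer(round(dig_min[i] + (seg - phys_min[i]) / gain[i]))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
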