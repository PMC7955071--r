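#' Construct an EEG recording
#'
#' Container for a continuous multi-channel recording: per-channel sample
#' vectors (microvolts), a sampling rate, and optional event annotations.
#'
#' @param samples named list of equal-length numeric vectors, one per channel.
#' @param fs sampling rate in Hz (the central-EEG sleep montage used here is
#'   conventionally digitized at 100 Hz).
#' @param annotations data frame with columns `start_s`, `duration_s`,
#'   `label` marking scored events, or `NULL`.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, annotations = NULL) {
  if (!is.list(samples) || length(samples) == 0 || is.null(names(samples)))
    stop("samples must be a non-empty named list of numeric vectors")
  lens <- vapply(samples, length, integer(1))
  if (length(unique(lens)) != 1)
    stop("all channels must have equal length")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a single positive number")
  if (is.null(annotations)) {
    annotations <- data.frame(start_s = numeric(0), duration_s = numeric(0),
                              label = character(0))
  } else {
    need <- c("start_s", "duration_s", "label")
    if (!all(need %in% names(annotations)))
      stop("annotations must have columns start_s, duration_s, label")
  }
  structure(list(channels = names(samples), fs = fs,
                 samples = lapply(samples, as.numeric),
                 annotations = annotations),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  n <- length(x$samples[[1]])
  cat(sprintf("<eeg_recording> %d channel(s) [%s], %.1f s at %g Hz, %d annotation(s)\n",
              length(x$channels), paste(x$channels, collapse = ", "),
              n / x$fs, x$fs, nrow(x$annotations)))
  invisible(x)
}

# canonical form for channel-name matching: uppercase, alphanumeric only,
# leading "EEG" stripped -- so "EEG C3-A2", "c3a2" and "C3-A2" all agree
canon_channel <- function(x) {
  x <- toupper(gsub("[^A-Za-z0-9]", "", x))
  sub("^EEG", "", x)
}

match_channels <- function(available, wanted) {
  idx <- match(canon_channel(wanted), canon_channel(available))
  if (anyNA(idx)) {
    stop("channel(s) not found: ", paste(wanted[is.na(idx)], collapse = ", "),
         "; available: ", paste(available, collapse = ", "))
  }
  idx
}

#' Read an EEG recording from EDF or CSV
#'
#' Reads a recording and keeps only the requested derivations. Channel name
#' matching is case-insensitive and tolerant of punctuation and an "EEG "
#' prefix ("C3A2", "C3-A2" and "EEG C3-A2" all match).
#'
#' The CSV dialect is one column per channel with a header row; the sampling
#' rate is taken from `fs` (CSV files carry no rate). EDF files carry their
#' own rate. Event annotations, when available as a file `<path>.events.csv`
#' with columns `start_s,duration_s,label`, are attached automatically.
#'
#' @param path file path.
#' @param format `"edf"` or `"csv"`; default guesses from the extension.
#' @param channels derivations to keep (default `c("C3-A2", "C4-A1")`).
#' @param fs sampling rate in Hz, required for CSV input (default 100).
#' @return an [eeg_recording].
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv"),
                           channels = c("C3-A2", "C4-A1"), fs = 100) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "edf") {
    rec <- read_edf(path)
  } else {
    tab <- utils::read.csv(path, check.names = FALSE)
    if (nrow(tab) == 0) stop("empty recording: ", path)
    rec <- eeg_recording(as.list(tab), fs = fs)
  }
  idx <- match_channels(rec$channels, channels)
  out <- eeg_recording(stats::setNames(rec$samples[idx], channels), rec$fs,
                       rec$annotations)
  ev_path <- paste0(path, ".events.csv")
  if (file.exists(ev_path)) {
    out$annotations <- utils::read.csv(ev_path, stringsAsFactors = FALSE)
  }
  out
}

#' Construct an epoch set
#'
#' A labeled set of fixed-length multi-channel signal segments, the
#' classification unit of the pipeline.
#'
#' @param epochs numeric array of shape (n_epochs, n_channels, samples).
#' @param labels per-epoch event labels in \{OSA, CSA, NB\}.
#' @param fs sampling rate in Hz.
#' @param channel_names channel names, length = dim 2 of `epochs`.
#' @param epoch_len_s epoch duration in seconds; must satisfy
#'   `round(epoch_len_s * fs) == dim(epochs)[3]`.
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, labels, fs, channel_names, epoch_len_s) {
  if (length(dim(epochs)) != 3) stop("epochs must be a 3-d array")
  labels <- event_labels(labels)
  if (length(labels) != dim(epochs)[1])
    stop("labels length must equal the number of epochs")
  if (length(channel_names) != dim(epochs)[2])
    stop("channel_names length must equal the number of channels")
  if (round(epoch_len_s * fs) != dim(epochs)[3])
    stop("epoch_len_s * fs must equal the number of samples per epoch")
  structure(list(epochs = epochs, labels = labels, fs = fs,
                 channel_names = channel_names, epoch_len_s = epoch_len_s),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channel(s) x %d samples (%g s at %g Hz)\n",
              dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3],
              x$epoch_len_s, x$fs))
  print(table(x$labels))
  invisible(x)
}

#' Segment a recording into labeled epochs
#'
#' Cuts the recording into consecutive non-overlapping epochs of
#' `epoch_len_s` seconds (a trailing partial epoch is dropped). An epoch is
#' labeled with the annotated event covering at least half of it; epochs
#' without such an event are labeled NB (normal breathing). When several
#' events reach 50% coverage the one with the largest overlap wins.
#'
#' @param rec an [eeg_recording].
#' @param epoch_len_s epoch duration in seconds (default 30, the standard
#'   sleep-scoring epoch).
#' @return an [epoch_set].
#' @export
segment_epochs <- function(rec, epoch_len_s = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_total <- length(rec$samples[[1]])
  if (n_total == 0) stop("empty recording")
  len <- round(epoch_len_s * rec$fs)
  n_ep <- floor(n_total / len)
  if (n_ep < 1) stop("recording shorter than one epoch")
  n_ch <- length(rec$channels)
  arr <- array(0, dim = c(n_ep, n_ch, len))
  for (ch in seq_len(n_ch)) {
    sig <- rec$samples[[ch]]
    for (e in seq_len(n_ep)) {
      arr[e, ch, ] <- sig[((e - 1) * len + 1):(e * len)]
    }
  }
  labels <- rep("NB", n_ep)
  ann <- rec$annotations
  if (nrow(ann) > 0) {
    for (e in seq_len(n_ep)) {
      e0 <- (e - 1) * epoch_len_s
      e1 <- e0 + epoch_len_s
      ov <- pmin(e1, ann$start_s + ann$duration_s) - pmax(e0, ann$start_s)
      ok <- which(ov >= epoch_len_s / 2)
      if (length(ok) > 0) labels[e] <- ann$label[ok[which.max(ov[ok])]]
    }
  }
  epoch_set(arr, labels, rec$fs, rec$channels, epoch_len_s)
}

#' Write / read an epoch set as CSV plus JSON sidecar
#'
#' The portable on-disk epoch format: `epochs.csv` holds one row per
#' (epoch, channel) with sample columns, and `epochs.json` carries the
#' sampling rate, epoch length, channel names and labels. Values are written
#' in full precision so a round-trip reproduces samples exactly.
#'
#' @param es an [epoch_set].
#' @param dir output directory (created if needed).
#' @return `write_epochs` returns `dir` invisibly; `read_epochs` returns the
#'   re-read [epoch_set].
#' @export
write_epochs <- function(es, dir) {
  stopifnot(inherits(es, "epoch_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(es$epochs)
  flat <- matrix(0, nrow = d[1] * d[2], ncol = d[3])
  meta <- data.frame(epoch = integer(d[1] * d[2]), channel = character(d[1] * d[2]))
  k <- 1
  for (e in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      flat[k, ] <- es$epochs[e, ch, ]
      meta$epoch[k] <- e
      meta$channel[k] <- es$channel_names[ch]
      k <- k + 1
    }
  }
  tab <- cbind(meta, as.data.frame(flat))
  names(tab) <- c("epoch", "channel", sprintf("s%d", seq_len(d[3])))
  con <- file(file.path(dir, "epochs.csv"), open = "w", encoding = "UTF-8")
  utils::write.csv(format(tab, digits = 17, scientific = FALSE, trim = TRUE),
                   con, row.names = FALSE, quote = FALSE)
  close(con)
  jsonlite::write_json(
    list(fs = es$fs, epoch_len_s = es$epoch_len_s,
         channel_names = es$channel_names,
         labels = as.character(es$labels)),
    file.path(dir, "epochs.json"), auto_unbox = TRUE, digits = I(17))
  invisible(dir)
}

#' @rdname write_epochs
#' @param dir directory previously written by `write_epochs`.
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "epochs.json"), simplifyVector = TRUE)
  tab <- utils::read.csv(file.path(dir, "epochs.csv"), check.names = FALSE)
  n_ep <- max(tab$epoch)
  n_ch <- length(meta$channel_names)
  len <- ncol(tab) - 2
  arr <- array(0, dim = c(n_ep, n_ch, len))
  for (k in seq_len(nrow(tab))) {
    ch <- match(tab$channel[k], meta$channel_names)
    arr[tab$epoch[k], ch, ] <- as.numeric(tab[k, -(1:2)])
  }
  epoch_set(arr, meta$labels, meta$fs, meta$channel_names, meta$epoch_len_s)
}
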