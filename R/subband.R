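#' Canonical EEG sub-band table
#'
#' The five frequency bands used throughout the pipeline: delta 0.5-4 Hz,
#' theta 4-8 Hz, alpha 8-12 Hz, sigma 12-16 Hz, beta 16-40 Hz.
#'
#' @return data frame with columns `name`, `low_hz`, `high_hz`.
#' @export
eeg_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "sigma", "beta"),
             low_hz = c(0.5, 4, 8, 12, 16),
             high_hz = c(4, 8, 12, 16, 40),
             stringsAsFactors = FALSE)
}

validate_bands <- function(bands, fs) {
  need <- c("name", "low_hz", "high_hz")
  if (!all(need %in% names(bands))) stop("band table needs name, low_hz, high_hz")
  if (any(bands$low_hz <= 0) || any(bands$low_hz >= bands$high_hz))
    stop("band edges must satisfy 0 < low_hz < high_hz")
  if (any(bands$high_hz >= fs / 2))
    stop("band edge at or above the Nyquist frequency (fs/2 = ", fs / 2, " Hz)")
  bands
}

#' Design a Butterworth band-pass filter in second-order sections
#'
#' Order-`order` IIR Butterworth band-pass design: the analog low-pass
#' prototype poles are frequency-transformed to the (pre-warped) band and
#' discretized by the bilinear transform, then grouped into conjugate-pair
#' biquads. The cascaded second-order-sections form stays numerically
#' well-conditioned even for narrow low-frequency bands, where the expanded
#' transfer-function polynomial is ill-conditioned. Gain is normalized to
#' exactly 1 at the geometric band center.
#'
#' @param low_hz,high_hz band edges in Hz; must lie strictly inside
#'   (0, fs/2).
#' @param fs sampling rate in Hz.
#' @param order filter order per band (default 4); the band-pass transfer
#'   function has degree `2 * order`.
#' @return object of class `sos_filter`: list of biquads (`b`, `a`) plus
#'   the scalar `gain`.
#' @export
design_bandpass <- function(low_hz, high_hz, fs, order = 4) {
  if (order < 1) stop("order must be >= 1")
  validate_bands(data.frame(name = "x", low_hz = low_hz, high_hz = high_hz), fs)
  # pre-warped analog band edges
  w1 <- 2 * fs * tan(pi * low_hz / fs)
  w2 <- 2 * fs * tan(pi * high_hz / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # unit-circle LP poles
  # low-pass -> band-pass: p maps to the roots of s^2 - p*bw*s + w0^2
  p_bp <- unlist(lapply(p_lp, function(p) {
    disc <- sqrt((p * bw / 2)^2 - w0^2)
    c(p * bw / 2 + disc, p * bw / 2 - disc)
  }))
  pd <- (1 + p_bp / (2 * fs)) / (1 - p_bp / (2 * fs))  # bilinear transform
  # digital zeros: `order` at z = 1 (from s = 0) and `order` at z = -1
  pu <- pd[Im(pd) >= 0]
  pu <- pu[order(-Mod(pu))]
  sos <- lapply(pu, function(p)
    list(b = c(1, 0, -1),                      # (z - 1)(z + 1)
         a = c(1, -2 * Re(p), Mod(p)^2)))
  filt <- structure(list(sos = sos, gain = 1,
                         low_hz = low_hz, high_hz = high_hz, fs = fs,
                         order = order),
                    class = "sos_filter")
  centre <- sqrt(low_hz * high_hz)
  filt$gain <- 1 / sqrt(sos_response(filt, fs, centre))
  filt
}

# squared magnitude (one-pass power) response of an sos_filter
sos_response <- function(filt, fs, freqs_hz) {
  z <- exp(1i * 2 * pi * freqs_hz / fs)
  h <- rep(filt$gain + 0i, length(z))
  for (s in filt$sos)
    h <- h * (s$b[1] + s$b[2] / z + s$b[3] / z^2) /
             (s$a[1] + s$a[2] / z + s$a[3] / z^2)
  Mod(h)^2
}

# one biquad pass: moving-average part then the AR recursion (both in C)
biquad_filter <- function(b, a, x) {
  v <- stats::filter(c(0, 0, x), b, method = "convolution", sides = 1)[-(1:2)]
  as.numeric(stats::filter(v, -a[2:3], method = "recursive"))
}

# Zero-phase (forward-backward) application of the section cascade.
# The signal is extended at both ends by odd reflection before filtering;
# the extension length is set from the slowest pole's decay so start-up
# transients die out inside the padding even for the narrow delta band,
# whose poles sit very close to the unit circle.
sos_filtfilt <- function(filt, x) {
  n <- length(x)
  maxmod <- sqrt(max(vapply(filt$sos, function(s) s$a[3], 0)))
  pad <- min(n - 1, ceiling(21 / max(1 - maxmod, 1e-3)))
  y <- c(2 * x[1] - x[seq(pad + 1, 2)], x, 2 * x[n] - x[seq(n - 1, n - pad)])
  for (s in filt$sos) y <- biquad_filter(s$b, s$a, y)
  y <- rev(y)
  for (s in filt$sos) y <- biquad_filter(s$b, s$a, y)
  y <- rev(y)
  y[(pad + 1):(pad + n)] * filt$gain^2
}

#' Decompose a signal into EEG sub-bands
#'
#' Applies the Butterworth band-pass bank with zero-phase (forward-backward)
#' filtering, so band-limited outputs are time-aligned with the input and
#' entropy/variance features are not affected by filter phase delay.
#'
#' @param x numeric signal vector (one epoch, one channel).
#' @param fs sampling rate in Hz.
#' @param bands band table as from [eeg_bands()].
#' @param order Butterworth order per band (default 4).
#' @return numeric matrix `length(x)` x `nrow(bands)`, columns named by band.
#' @export
decompose_subbands <- function(x, fs, bands = eeg_bands(), order = 4) {
  bands <- validate_bands(bands, fs)
  if (length(x) <= 3 * order)
    stop("epoch too short for filtering: need length > 3 * order")
  out <- matrix(0, nrow = length(x), ncol = nrow(bands))
  colnames(out) <- bands$name
  for (b in seq_len(nrow(bands))) {
    filt <- design_bandpass(bands$low_hz[b], bands$high_hz[b], fs, order)
    out[, b] <- sos_filtfilt(filt, x)
  }
  out
}

#' Decompose every epoch and channel of an epoch set
#'
#' @param es an [epoch_set].
#' @inheritParams decompose_subbands
#' @return list with one element per epoch; each element is a list per
#'   channel holding the samples-by-bands matrix from
#'   [decompose_subbands()].
#' @export
decompose_epochs <- function(es, bands = eeg_bands(), order = 4) {
  stopifnot(inherits(es, "epoch_set"))
  d <- dim(es$epochs)
  lapply(seq_len(d[1]), function(e) {
    chans <- lapply(seq_len(d[2]), function(ch)
      decompose_subbands(es$epochs[e, ch, ], es$fs, bands, order))
    names(chans) <- es$channel_names
    chans
  })
}

#' Filter-bank magnitude response
#'
#' Evaluates the two-pass (zero-phase) power gain of one band filter at the
#' given frequencies; used to verify passband flatness and stopband
#' attenuation. The one-pass magnitude in dB is `10 * log10` of the
#' returned value.
#'
#' @inheritParams design_bandpass
#' @param freqs_hz frequencies at which to evaluate, in Hz.
#' @return numeric vector of two-pass power gains at `freqs_hz`.
#' @export
bandpass_response <- function(low_hz, high_hz, fs, freqs_hz, order = 4) {
  filt <- design_bandpass(low_hz, high_hz, fs, order)
  sos_response(filt, fs, freqs_hz)
}
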