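# Synthetic two-channel EEG epoch generator. Each epoch is a sum of
# band-limited oscillations (white noise filtered into each sub-band and
# rescaled, so spectra are narrowband but not tonal) plus broadband white
# noise controlling signal complexity. Class profiles encode the intended
# physiology-like contrasts: apnea-like classes are slow-wave dominated and
# more regular (low sample entropy, high low-frequency variance), normal
# breathing is noise-dominated and complex; the two apnea classes differ in
# their delta/theta balance and in inter-hemispheric (C3 vs C4) gain.

#' Default class profiles for the synthetic generator
#'
#' @return list with `band_amplitude` (class x band matrix of oscillation
#'   standard deviations, arbitrary microvolt-like units), `noise_sd`
#'   (per-class broadband noise standard deviation), and `asymmetry`
#'   (class x channel gain factors).
#' @export
synth_profiles <- function() {
  bands <- eeg_bands()$name
  amp <- rbind(OSA = c(18, 5, 2.5, 1.5, 1.5),
               CSA = c(8, 12, 2.5, 1.5, 1.5),
               NB  = c(4, 3, 5, 3, 3))
  colnames(amp) <- bands
  list(band_amplitude = amp,
       noise_sd = c(OSA = 1.5, CSA = 2, NB = 6),
       asymmetry = rbind(OSA = c(1, 1), CSA = c(1, 1.4), NB = c(1, 1)))
}

#' Synthetic-data configuration
#'
#' @param n_per_class epochs per class (ignored when `class_sizes` given).
#' @param class_sizes optional named or ordered vector of per-class epoch
#'   counts (OSA, CSA, NB), e.g. `c(1229, 812, 1418)` for the class balance
#'   of a typical clinical event set.
#' @param fs sampling rate in Hz (default 100).
#' @param epoch_len_s epoch duration in seconds (default 30).
#' @param profiles class profiles as from [synth_profiles()].
#' @param channel_names names of the two generated channels.
#' @param seed RNG seed; generation is fully reproducible from it.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_per_class = 100, class_sizes = NULL, fs = 100,
                         epoch_len_s = 30, profiles = synth_profiles(),
                         channel_names = c("C3-A2", "C4-A1"), seed = 1) {
  if (is.null(class_sizes))
    class_sizes <- stats::setNames(rep(n_per_class, 3), EVENT_LEVELS)
  if (is.null(names(class_sizes))) names(class_sizes) <- EVENT_LEVELS
  if (!setequal(names(class_sizes), EVENT_LEVELS))
    stop("class_sizes must cover OSA, CSA, NB")
  amp <- profiles$band_amplitude
  if (!setequal(rownames(amp), EVENT_LEVELS) || ncol(amp) != 5 ||
      any(amp < 0) || any(profiles$noise_sd < 0))
    stop("invalid profile: need nonnegative amplitudes for 3 classes x 5 bands")
  structure(list(class_sizes = class_sizes[EVENT_LEVELS], fs = fs,
                 epoch_len_s = epoch_len_s, profiles = profiles,
                 channel_names = channel_names, seed = seed),
            class = "synth_config")
}

# one band-limited oscillation: unit-sd filtered white noise
narrowband_noise <- function(n, low_hz, high_hz, fs, order = 4) {
  x <- sos_filtfilt(design_bandpass(low_hz, high_hz, fs, order),
                    stats::rnorm(n))
  s <- stats::sd(x)
  if (s == 0) return(x)
  x / s
}

#' Generate a synthetic labeled epoch set
#'
#' See [synth_config()] and [synth_profiles()] for the generating model.
#' Epochs are grouped by class in OSA, CSA, NB order.
#'
#' @param config a [synth_config()].
#' @return an [epoch_set].
#' @export
generate_epochs <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  bands <- eeg_bands()
  n_samp <- round(config$epoch_len_s * config$fs)
  n_total <- sum(config$class_sizes)
  n_ch <- length(config$channel_names)
  arr <- array(0, dim = c(n_total, n_ch, n_samp))
  labels <- rep(names(config$class_sizes), config$class_sizes)
  pf <- config$profiles
  withr::with_seed(config$seed, {
    for (e in seq_len(n_total)) {
      cl <- labels[e]
      for (ch in seq_len(n_ch)) {
        x <- numeric(n_samp)
        for (b in seq_len(nrow(bands))) {
          a <- pf$band_amplitude[cl, b]
          if (a > 0)
            x <- x + a * narrowband_noise(n_samp, bands$low_hz[b],
                                          bands$high_hz[b], config$fs)
        }
        x <- x + pf$noise_sd[cl] * stats::rnorm(n_samp)
        arr[e, ch, ] <- pf$asymmetry[cl, ch] * x
      }
    }
  })
  epoch_set(arr, labels, config$fs, config$channel_names, config$epoch_len_s)
}

# class-mean patterns cycled over informative columns; scaled by effect size
signal_patterns <- list(c(-1, 0, 1), c(1, -1, 0), c(0, 1, -1),
                        c(-1, 1, 0), c(1, 0, -1), c(0, -1, 1))

#' Generate a synthetic tabular feature matrix
#'
#' Direct generator for testing the selection and classification stages in
#' isolation: standard-normal features where the informative columns receive
#' class-dependent mean shifts of `effect_size` standard deviations (a
#' different three-class contrast pattern per column, cycled), and all
#' other columns are exchangeable noise.
#'
#' @param n total rows, split evenly over OSA/CSA/NB (ignored when
#'   `class_sizes` given).
#' @param informative_columns indices of signal-carrying columns.
#' @param effect_size mean shift in standard deviations (default 3).
#' @param seed RNG seed.
#' @param class_sizes optional per-class row counts (OSA, CSA, NB order).
#' @param n_features total number of columns (default 20).
#' @return a [feature_matrix] (generic column registry).
#' @export
generate_feature_table <- function(n = 300, informative_columns = 1:5,
                                   effect_size = 3, seed = 1,
                                   class_sizes = NULL, n_features = 20) {
  if (is.null(class_sizes)) {
    base <- n %/% 3
    class_sizes <- c(base, base, n - 2 * base)
  }
  stopifnot(all(informative_columns >= 1),
            all(informative_columns <= n_features))
  labels <- rep(EVENT_LEVELS, class_sizes)
  n_total <- length(labels)
  X <- withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n_total * n_features), n_total, n_features)
    for (k in seq_along(informative_columns)) {
      col <- informative_columns[k]
      pat <- signal_patterns[[(k - 1) %% length(signal_patterns) + 1]]
      shift <- effect_size * pat[match(labels, EVENT_LEVELS)]
      X[, col] <- X[, col] + shift
    }
    X
  })
  colnames(X) <- sprintf("f%02d", seq_len(n_features))
  cols <- data.frame(index = seq_len(n_features),
                     feature = colnames(X),
                     channel = NA_character_, band = NA_character_,
                     stringsAsFactors = FALSE)
  feature_matrix(X, cols, labels)
}
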