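#' Sample entropy
#'
#' SampEn(m, r, N) = -ln(B^(m+1) / B^m), where B^m and B^(m+1) are the
#' fractions of template pairs of length m and m+1 whose Chebyshev distance
#' is at most r. Templates of both lengths are drawn from the same start
#' indices 1..N-m and self-matches are excluded (the Richman-Moorman
#' convention), which makes SampEn(constant series) exactly 0 and keeps the
#' statistic amplitude-invariant when r is tied to the signal's own scale.
#'
#' The similarity radius defaults to `r_factor * sd(x)`, recomputed from
#' each input series, so scaling a signal by any positive constant leaves
#' its sample entropy unchanged.
#'
#' When no template pair matches at length m+1 the raw statistic is
#' infinite; to keep downstream feature matrices finite the conditional
#' probability is then floored at its smallest resolvable value,
#' 2 / ((N-m-1)(N-m)), giving the finite upper bound
#' -ln(2/((N-m-1)(N-m))) with a warning.
#'
#' @param x numeric series of length N >= m + 2.
#' @param m embedding dimension (template length), default 2.
#' @param r_factor similarity radius as a multiple of `sd(x)`, default 0.2.
#' @param r absolute similarity radius; overrides `r_factor` when given.
#' @return nonnegative scalar.
#' @export
sample_entropy <- function(x, m = 2, r_factor = 0.2, r = NULL) {
  x <- as.numeric(x)
  if (m < 1) stop("m must be >= 1")
  if (length(x) < m + 2) stop("series too short: need length >= m + 2")
  if (is.null(r)) r <- r_factor * stats::sd(x)
  cnt <- sampen_counts(x, as.integer(m), r)
  if (cnt$B == 0 || cnt$A == 0) {
    nt <- cnt$n_templates
    warning("no template matches at length m+1; returning the finite upper bound")
    return(-log(2 / ((nt - 1) * nt)))
  }
  -log(cnt$A / cnt$B)
}

#' Population variance
#'
#' Mean squared deviation from the mean, normalized by N (population form,
#' not the N-1 sample form): `sum((x - mean(x))^2) / length(x)`.
#'
#' @param x numeric vector, length >= 1.
#' @return nonnegative scalar in squared input units.
#' @export
variance_pop <- function(x) {
  if (length(x) < 1) stop("empty series")
  mean((x - mean(x))^2)
}

#' The feature-column registry
#'
#' Enumerates the feature layout: variance first, then sample entropy; for
#' each feature, channels in order; for each channel, the five sub-bands in
#' delta/theta/alpha/sigma/beta order. The default two-channel configuration
#' yields the canonical 20 columns.
#'
#' @param channels channel short names, default `c("C3", "C4")`.
#' @param bands band table as from [eeg_bands()].
#' @return data frame with columns `index`, `feature`, `channel`, `band`.
#' @export
feature_columns <- function(channels = c("C3", "C4"), bands = eeg_bands()) {
  grid <- expand.grid(band = bands$name, channel = channels,
                      feature = c("variance", "sample_entropy"),
                      stringsAsFactors = FALSE)
  data.frame(index = seq_len(nrow(grid)),
             feature = grid$feature, channel = grid$channel, band = grid$band,
             stringsAsFactors = FALSE)
}

#' Extract the sub-band feature matrix
#'
#' For every epoch: decompose each channel into the five sub-bands, then
#' compute the population variance and the sample entropy of each
#' band-limited signal. Columns follow [feature_columns()] (20 columns for
#' the default two-channel, five-band configuration); rows preserve epoch
#' order and carry the epoch labels.
#'
#' @param es an [epoch_set].
#' @param bands band table, default [eeg_bands()].
#' @param m,r_factor sample-entropy parameters (defaults m = 2,
#'   r = 0.2 * sd of each band-limited signal).
#' @param order Butterworth filter order (default 4).
#' @return object of class `feature_matrix`: list with `values`
#'   (n_epochs x n_features matrix), `columns` (registry), `labels`.
#' @export
extract_features <- function(es, bands = eeg_bands(), m = 2, r_factor = 0.2,
                             order = 4) {
  stopifnot(inherits(es, "epoch_set"))
  d <- dim(es$epochs)
  if (d[1] == 0) stop("empty epoch set")
  short <- sub("-.*$", "", es$channel_names)  # "C3-A2" -> "C3"
  cols <- feature_columns(short, bands)
  vals <- matrix(0, nrow = d[1], ncol = nrow(cols))
  colnames(vals) <- paste(cols$feature, cols$channel, cols$band, sep = "_")
  for (e in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      sub <- decompose_subbands(es$epochs[e, ch, ], es$fs, bands, order)
      for (b in seq_len(nrow(bands))) {
        sig <- sub[, b]
        iv <- which(cols$feature == "variance" & cols$channel == short[ch] &
                      cols$band == bands$name[b])
        ie <- which(cols$feature == "sample_entropy" & cols$channel == short[ch] &
                      cols$band == bands$name[b])
        vals[e, iv] <- variance_pop(sig)
        vals[e, ie] <- sample_entropy(sig, m = m, r_factor = r_factor)
      }
    }
  }
  feature_matrix(vals, cols, es$labels)
}

#' Construct a feature matrix object
#'
#' @param values numeric matrix, epochs x features.
#' @param columns column registry as from [feature_columns()].
#' @param labels per-row event labels.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, columns, labels) {
  values <- as.matrix(values)
  labels <- event_labels(labels)
  if (nrow(values) != length(labels)) stop("labels length must match rows")
  if (ncol(values) != nrow(columns)) stop("column registry must match columns")
  structure(list(values = values, columns = columns, labels = labels),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d epochs x %d features\n",
              nrow(x$values), ncol(x$values)))
  print(table(x$labels))
  invisible(x)
}

#' Write / read a feature matrix as CSV plus JSON sidecar
#'
#' @param fm a [feature_matrix].
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @param params optional list of extraction parameters echoed into the
#'   sidecar.
#' @export
write_features <- function(fm, path, params = list()) {
  stopifnot(inherits(fm, "feature_matrix"))
  tab <- data.frame(label = as.character(fm$labels), fm$values,
                    check.names = FALSE)
  con <- file(path, open = "w", encoding = "UTF-8")
  utils::write.csv(format(tab, digits = 17, scientific = FALSE, trim = TRUE),
                   con, row.names = FALSE, quote = FALSE)
  close(con)
  jsonlite::write_json(list(columns = fm$columns, params = params),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  feature_matrix(as.matrix(tab[, -1, drop = FALSE]), meta$columns, tab$label)
}
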