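# Independent oracles used across the suite. These deliberately share no
# code with the package implementations they check.

# Naive sample entropy: for every template start i, Chebyshev distances to
# all other templates are formed directly from the embedded vectors. Counts
# every ordered pair (so both A and B are doubled relative to unordered
# counting; the ratio, and hence the entropy, is unchanged).
sampen_bruteforce <- function(x, m, r) {
  N <- length(x)
  nt <- N - m
  B <- 0
  A <- 0
  for (i in seq_len(nt)) {
    d <- abs(x[i] - x[seq_len(nt)])
    for (k in seq_len(m - 1)) d <- pmax(d, abs(x[i + k] - x[seq_len(nt) + k]))
    d[i] <- Inf  # exclude the self-match
    hit <- d <= r
    B <- B + sum(hit)
    d1 <- pmax(d, abs(x[i + m] - x[seq_len(nt) + m]))
    A <- A + sum(d1 <= r)
  }
  # same degenerate convention as the package: floor the conditional
  # probability at its smallest resolvable value when no m+1 pair matches
  if (A == 0 || B == 0) return(-log(2 / ((nt - 1) * nt)))
  -log(A / B)
}

# Cohen's kappa by direct marginal arithmetic
kappa_bruteforce <- function(cm) {
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  a <- rowSums(cm)
  b <- colSums(cm)
  pe <- sum(a * b) / (n * n)
  (po - pe) / (1 - pe)
}

# small labeled recording for io tests: two named sinusoid channels
make_test_recording <- function(seconds = 90, fs = 100, ann = NULL) {
  t <- seq_len(seconds * fs) / fs
  eeg_recording(list("C3-A2" = 10 * sin(2 * pi * 2 * t),
                     "C4-A1" = 5 * sin(2 * pi * 9 * t)),
                fs = fs, annotations = ann)
}
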