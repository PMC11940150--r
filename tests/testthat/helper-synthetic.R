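# Shared fixtures, all generated in code.

# A six-channel recording built from a single series replicated.
rec_from_series <- function(x, fs = 100, markers = NULL) {
  ch <- matrix(rep(x, 6), ncol = 6,
               dimnames = list(NULL, c("acc_v", "acc_ml", "acc_ap",
                                       "gyr_v", "gyr_ml", "gyr_ap")))
  if (is.null(markers))
    markers <- data.frame(task = "tug", trial = 1L, start = 0L,
                          end = length(x))
  sensor_recording(ch, fs, markers)
}

# A small random feature table with optional informative columns whose
# class means differ by `shift`.
mk_feature_table <- function(n = 40, p = 50, seed = 1, n_signal = 0,
                             shift = 2, minority_every = 5,
                             task = "tug") {
  set.seed(seed)
  labels <- rep("pd", n)
  labels[seq(minority_every, n, by = minority_every)] <- "nonpd"
  V <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  if (n_signal > 0)
    V[labels == "nonpd", seq_len(n_signal)] <-
      V[labels == "nonpd", seq_len(n_signal)] + shift
  tasks <- rep(task, p)
  structure(list(
    values = V,
    meta = data.frame(name = colnames(V), task = tasks,
                      derivation = "t1", segpos = "walk_out",
                      subtask = "walk", channel = "acc_v",
                      domain = "time"),
    participants = sprintf("P%03d", seq_len(n)),
    labels = labels), class = "feature_table")
}

# Amplitude of a pure tone in a series, by complex demodulation over a
# core window (edges excluded).
tone_amplitude <- function(y, f, fs, trim = 2 * fs) {
  n <- length(y)
  core <- (trim + 1):(n - trim)
  t <- (core - 1) / fs
  2 * abs(sum(y[core] * exp(-2i * pi * f * t))) / length(core)
}
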