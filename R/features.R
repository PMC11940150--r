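#' The fixed feature registry
#'
#' The catalogue is versioned and fixed: 42 time-domain features per
#' channel, 22 frequency-domain features per channel, the top 10 power
#' amplitudes of the discrete Fourier transform and of the Lomb-Scargle
#' periodogram per channel, and 3 cross-channel features per unordered
#' channel pair (15 pairs). Every definition is a pure function of one
#' channel segment (or one pair).
#'
#' @return Named list of character vectors: `time` (42), `frequency`
#'   (22), `dft` (10), `lsp` (10), `pairwise` (3), plus `version`.
#' @export
feature_registry <- function() {
  list(
    version = "1.0",
    time = c("mean", "median", "sd", "variance", "mad", "iqr", "min",
             "max", "range", "rms", "mean_abs", "max_abs", "energy",
             "skewness", "kurtosis", "cv", "p5", "p25", "p75", "p95",
             "trimmed_mean10", "zero_cross_rate", "mean_cross_rate",
             "peak_rate", "slope_sign_rate", "diff_mean_abs", "diff_sd",
             "diff_rms", "diff_max_abs", "diff2_mean_abs", "diff2_rms",
             "acf_lag1", "acf_lag2", "acf_lag5", "acf_lag10",
             "acf_lag20", "sample_entropy", "crest_factor",
             "impulse_factor", "shape_factor", "margin_factor",
             "hist_entropy"),
    frequency = c("centroid", "spread", "skewness", "kurtosis",
                  "entropy", "flatness", "dominant_freq",
                  "dominant_power_rel", "median_freq", "edge_freq95",
                  "rolloff85", "total_power", "bp_0.5_3", "bp_3_8",
                  "bp_8_15", "bp_15_20", "rbp_0.5_3", "rbp_3_8",
                  "rbp_8_15", "rbp_15_20", "harmonic_ratio",
                  "spectral_crest"),
    dft = paste0("dft_amp", 1:10),
    lsp = paste0("lsp_amp", 1:10),
    pairwise = c("corr", "max_xcorr", "mag_ratio"))
}

# Frequency grid for the Lomb-Scargle periodogram (Hz).
LSP_GRID <- seq(0.1, 20, by = 0.1)

#' Time-domain features of one channel segment
#'
#' Computes the registry's 42 time-domain statistics: location and
#' spread (mean, median, sd, variance, mad, iqr, percentiles, trimmed
#' mean), extremes and magnitude (min/max/range, rms, mean and max
#' absolute value, signal energy), shape (skewness, kurtosis,
#' coefficient of variation, crest/impulse/shape/margin factors),
#' event rates per sample (zero and mean crossings, local peaks, slope
#' sign changes), first- and second-difference statistics,
#' autocorrelation at lags 1, 2, 5, 10 and 20, sample entropy
#' (m = 2, r = 0.2 sd, evaluated on up to the first 600 samples), and
#' the Shannon entropy of the 16-bin amplitude histogram. Statistics
#' undefined for a given segment (for example autocorrelation of a
#' constant) are returned as `NA` and handled by table preprocessing.
#'
#' @param x numeric series (length >= 2).
#' @return Named numeric vector of length 42.
#' @export
time_domain_features <- function(x) {
  n <- length(x)
  if (n < 2)
    stop_pdm("time-domain features need at least 2 samples",
             "pdm_feature_error")
  setNames(cpp_time_features(as.numeric(x)), feature_registry()$time)
}

# One-sided power spectrum (DC removed, rectangular window).
onesided_psd <- function(x, fs) {
  n <- length(x)
  X <- fft(x - mean(x))
  nf <- n %/% 2
  p <- (Mod(X[2:(nf + 1)])^2) / n
  list(freq = (1:nf) * fs / n, power = p)
}

#' Frequency-domain features of one channel segment
#'
#' Computes the registry's 22 spectral statistics from the one-sided
#' power spectrum of the mean-removed segment (rectangular window):
#' spectral moments (centroid, spread, skewness, kurtosis), normalised
#' spectral entropy, flatness and crest, dominant frequency and its
#' relative power, median / 95% edge / 85% roll-off frequencies, total
#' power, and absolute plus relative band powers over 0.5-3, 3-8, 8-15
#' and 15-20 Hz, and the ratio of power at twice the dominant frequency
#' to power at the dominant frequency (harmonic ratio).
#'
#' @param x numeric series (length >= 8).
#' @param sample_rate Hz.
#' @return Named numeric vector of length 22.
#' @export
frequency_domain_features <- function(x, sample_rate) {
  if (length(x) < 8)
    stop_pdm("frequency-domain features need at least 8 samples",
             "pdm_feature_error")
  sp <- onesided_psd(x, sample_rate)
  f <- sp$freq; p <- sp$power
  tot <- sum(p)
  if (tot <= 0) {
    out <- rep(NA_real_, 22)
    names(out) <- feature_registry()$frequency
    out[["total_power"]] <- 0
    return(out)
  }
  q <- p / tot
  cen <- sum(f * q)
  spr <- sqrt(sum((f - cen)^2 * q))
  sk <- if (spr > 0) sum((f - cen)^3 * q) / spr^3 else NA_real_
  ku <- if (spr > 0) sum((f - cen)^4 * q) / spr^4 else NA_real_
  ent <- if (length(q) > 1) -sum(q[q > 0] * log(q[q > 0])) / log(length(q))
         else 0
  flat <- exp(mean(log(p + 1e-300))) / mean(p)
  imax <- which.max(p)
  cum <- cumsum(q)
  medf <- f[which(cum >= 0.5)[1]]
  edge95 <- f[which(cum >= 0.95)[1]]
  roll85 <- f[which(cum >= 0.85)[1]]
  band <- function(lo, hi) sum(p[f >= lo & f < hi])
  b1 <- band(0.5, 3); b2 <- band(3, 8); b3 <- band(8, 15)
  b4 <- band(15, 20)
  i2 <- which.min(abs(f - 2 * f[imax]))
  out <- c(centroid = cen, spread = spr, skewness = sk, kurtosis = ku,
           entropy = ent, flatness = flat, dominant_freq = f[imax],
           dominant_power_rel = max(p) / tot, median_freq = medf,
           edge_freq95 = edge95, rolloff85 = roll85, total_power = tot,
           "bp_0.5_3" = b1, bp_3_8 = b2, bp_8_15 = b3, bp_15_20 = b4,
           "rbp_0.5_3" = b1 / tot, rbp_3_8 = b2 / tot,
           rbp_8_15 = b3 / tot, rbp_15_20 = b4 / tot,
           harmonic_ratio = p[i2] / p[imax],
           spectral_crest = max(p) / mean(p))
  out
}

#' Top spectral power amplitudes
#'
#' The k largest power values of the one-sided discrete Fourier power
#' spectrum, or of the Lomb-Scargle periodogram evaluated on the fixed
#' frequency grid 0.1-20 Hz (0.1 Hz step), sorted descending.
#'
#' @param x numeric series (length >= 2k).
#' @param sample_rate Hz.
#' @param method `"dft"` or `"lsp"`.
#' @param k number of amplitudes (default 10).
#' @return Named numeric vector of length `k`, non-increasing.
#' @export
top_power_amplitudes <- function(x, sample_rate, method = c("dft", "lsp"),
                                 k = 10L) {
  method <- match.arg(method)
  n <- length(x)
  if (n < 2 * k)
    stop_pdm(sprintf("top_power_amplitudes needs at least %d samples", 2 * k),
             "pdm_feature_error")
  p <- if (method == "dft") {
    onesided_psd(x, sample_rate)$power
  } else {
    t <- (seq_len(n) - 1) / sample_rate
    cpp_lsp(x, t, LSP_GRID)
  }
  amps <- sort(p, decreasing = TRUE)[seq_len(k)]
  names(amps) <- paste0(method, "_amp", seq_len(k))
  amps
}

#' Cross-channel features of one channel pair
#'
#' The registry's three pairwise statistics: Pearson correlation,
#' maximum absolute normalised cross-correlation over lags up to 1 s
#' (100 samples), and the ratio of mean absolute amplitudes.
#'
#' @param a,b equal-length numeric series.
#' @return Named numeric vector of length 3.
#' @export
pairwise_features <- function(a, b) {
  if (length(a) != length(b))
    stop_pdm("pairwise features need equal-length series",
             "pdm_feature_error")
  if (length(a) < 2)
    stop_pdm("pairwise features need at least 2 samples",
             "pdm_feature_error")
  cc <- if (sd(a) > 0 && sd(b) > 0) cor(a, b) else NA_real_
  mb <- mean(abs(b))
  c(corr = cc,
    max_xcorr = cpp_max_xcorr(a, b, min(100L, length(a) - 2L)),
    mag_ratio = if (mb > 0) mean(abs(a)) / mb else NA_real_)
}

# All per-channel features (42 + 22 + 10 + 10 = 84) of one segment of
# one channel, in registry order.
channel_segment_features <- function(x, fs) {
  c(time_domain_features(x),
    frequency_domain_features(x, fs),
    top_power_amplitudes(x, fs, "dft"),
    top_power_amplitudes(x, fs, "lsp"))
}

# All features of one window (6 channels x 84 + 15 pairs x 3 = 549).
window_features <- function(ch, fs) {
  per <- unlist(lapply(CHANNELS, function(cn)
    channel_segment_features(ch[, cn], fs)), use.names = FALSE)
  pairs <- utils::combn(CHANNELS, 2)
  pw <- unlist(lapply(seq_len(ncol(pairs)), function(i)
    pairwise_features(ch[, pairs[1, i]], ch[, pairs[2, i]])),
    use.names = FALSE)
  c(per, pw)
}

# Feature names of one window, matching window_features() order.
window_feature_names <- function() {
  reg <- feature_registry()
  per_channel <- c(paste0("time_", reg$time),
                   paste0("freq_", reg$frequency), reg$dft, reg$lsp)
  per <- unlist(lapply(CHANNELS, function(cn)
    paste(cn, per_channel, sep = ".")), use.names = FALSE)
  pairs <- utils::combn(CHANNELS, 2)
  pw <- unlist(lapply(seq_len(ncol(pairs)), function(i)
    paste(paste0(pairs[1, i], "_", pairs[2, i]),
          paste0("pair_", reg$pairwise), sep = ".")), use.names = FALSE)
  c(per, pw)
}

# Metadata (channel, domain) of one window's features.
window_feature_meta <- function() {
  reg <- feature_registry()
  per_domain <- c(rep("time", length(reg$time)),
                  rep("frequency", length(reg$frequency)),
                  rep("dft", length(reg$dft)),
                  rep("lsp", length(reg$lsp)))
  pairs <- utils::combn(CHANNELS, 2)
  data.frame(
    channel = c(rep(CHANNELS, each = length(per_domain)),
                rep(paste0(pairs[1, ], "_", pairs[2, ]),
                    each = length(reg$pairwise))),
    domain = c(rep(per_domain, length(CHANNELS)),
               rep("pairwise", length(reg$pairwise) * ncol(pairs))))
}
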