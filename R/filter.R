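#' Low-pass filter specification
#'
#' The defaults follow common practice for human-movement inertial data:
#' a 4th-order low-pass Butterworth at 20 Hz, applied forward and
#' backward so the effective magnitude response is the squared one-pass
#' response and the phase shift is zero.
#'
#' @param order filter order (>= 1).
#' @param cutoff cutoff frequency in Hz.
#' @param zero_lag apply forward-backward (zero-phase)?
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(order = 4L, cutoff = 20, zero_lag = TRUE) {
  stopifnot(order >= 1, cutoff > 0)
  structure(list(order = as.integer(order), cutoff = cutoff,
                 kind = "low", zero_lag = isTRUE(zero_lag)),
            class = "filter_spec")
}

# Steady-state initial filter conditions (so a step input produces no
# startup transient), solved from the direct-form II transposed update.
butter_zi <- function(b, a) {
  nf <- length(b)
  if (nf < 2) return(numeric(0))
  A <- diag(nf - 1) - cbind(-a[2:nf], rbind(diag(1, nf - 2), 0))
  as.numeric(solve(A, b[2:nf] - b[1] * a[2:nf]))
}

# One forward-backward pass over a single series with odd-reflection
# padding of length 3 x order to suppress edge transients.
zerophase_pass <- function(x, b, a, order) {
  n <- length(x)
  p <- min(3L * order, n - 1L)
  front <- 2 * x[1] - x[(p + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - p)]
  xp <- c(front, x, back)
  zi <- butter_zi(b, a)
  y <- cpp_iir(b, a, xp, zi * xp[1])
  y <- rev(cpp_iir(b, a, rev(y), zi * y[length(y)]))
  y[(p + 1):(p + n)]
}

#' Apply the low-pass Butterworth filter to every channel
#'
#' Each channel is filtered independently. With `zero_lag = TRUE` the
#' filter runs forward and backward (squared magnitude response,
#' zero phase); otherwise a single forward pass is used.
#'
#' @param rec a `sensor_recording`.
#' @param spec a [filter_spec()].
#' @return The filtered `sensor_recording` (markers unchanged).
#' @export
lowpass_filter <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "sensor_recording"), inherits(spec, "filter_spec"))
  if (spec$cutoff >= rec$sample_rate / 2)
    stop_pdm("filter cutoff must be below the Nyquist frequency",
             "pdm_filter_error")
  bf <- signal::butter(spec$order, spec$cutoff / (rec$sample_rate / 2),
                       type = "low")
  b <- as.numeric(bf$b); a <- as.numeric(bf$a)
  out <- rec
  for (ch in colnames(rec$channels)) {
    x <- rec$channels[, ch]
    out$channels[, ch] <- if (spec$zero_lag) {
      zerophase_pass(x, b, a, spec$order)
    } else {
      zi <- butter_zi(b, a)
      cpp_iir(b, a, x, zi * x[1])
    }
  }
  out
}
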