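#' Canonical double-gamma hemodynamic response function
#'
#' Samples the conventional "canonical" HRF (difference of two gamma
#' densities) used to convolve end-tidal CO2 traces before regression
#' against the BOLD signal.
#'
#' @param dt_s Sampling interval in seconds (must be positive).
#' @param duration_s Kernel length in seconds (default 32).
#' @param peak_delay_s Delay of the positive lobe in seconds (default 6).
#' @param undershoot_delay_s Delay of the undershoot in seconds (default 16).
#' @param dispersion_s Dispersion (gamma scale) of the positive lobe.
#' @param undershoot_dispersion_s Dispersion of the undershoot.
#' @param undershoot_ratio Relative amplitude of the undershoot (default 1/6).
#' @param normalize Either `"area"` (default; unit integral, so a sustained
#'   end-tidal change in mmHg passes through convolution with unit gain and
#'   regressor units remain mmHg) or `"peak"` (unit maximum).
#'
#' @return Numeric vector of kernel samples with attributes `dt_s` and
#'   `parameters`.
#' @examples
#' h <- canonical_hrf(0.3)
#' which.max(h) # peak near 5 s
#' @export
canonical_hrf <- function(dt_s, duration_s = 32,
                          peak_delay_s = 6, undershoot_delay_s = 16,
                          dispersion_s = 1, undershoot_dispersion_s = 1,
                          undershoot_ratio = 1 / 6,
                          normalize = c("area", "peak")) {
  if (!is.numeric(dt_s) || length(dt_s) != 1L || dt_s <= 0)
    stop("'dt_s' must be a single positive number")
  normalize <- match.arg(normalize)
  t <- seq(0, duration_s, by = dt_s)
  h <- stats::dgamma(t, shape = peak_delay_s / dispersion_s,
                     scale = dispersion_s) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_delay_s /
                                       undershoot_dispersion_s,
                                     scale = undershoot_dispersion_s)
  h <- switch(normalize,
              area = h / (sum(h) * dt_s),
              peak = h / max(h))
  structure(h, dt_s = dt_s,
            parameters = list(duration_s = duration_s,
                              peak_delay_s = peak_delay_s,
                              undershoot_delay_s = undershoot_delay_s,
                              dispersion_s = dispersion_s,
                              undershoot_dispersion_s = undershoot_dispersion_s,
                              undershoot_ratio = undershoot_ratio,
                              normalize = normalize))
}

# causal discrete convolution approximating the integral:
# out[i] = sum_j x[j] h[i-j+1] * dt, aligned to the time grid of x
.conv_causal <- function(x, h, dt_s) {
  n <- length(x)
  out <- stats::convolve(x, rev(h), type = "open")[seq_len(n)]
  out * dt_s
}
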