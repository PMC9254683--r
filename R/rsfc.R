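#' Remove a least-squares quadratic trend
#'
#' @param x Numeric series (at least 4 time points).
#' @return Residual series (mean approximately zero) with the original
#'   series mean stored in attribute `original_mean` (used to normalize
#'   RSFA).
#' @export
detrend_quadratic <- function(x) {
  n <- length(x)
  if (n < 4) stop("need at least 4 time points for quadratic detrending")
  t <- seq_len(n)
  X <- cbind(1, t, t^2)
  res <- stats::lm.fit(X, x)$residuals
  structure(as.numeric(res), original_mean = mean(x))
}

#' Ideal frequency-domain bandpass filter
#'
#' Zeroes every discrete-Fourier coefficient whose frequency falls outside
#' `[low_hz, high_hz]` (the DC term is always removed) and returns the
#' inverse transform. Exact by construction for sinusoids on the DFT grid.
#'
#' @param x Numeric series.
#' @param low_hz,high_hz Pass-band edges in Hz; `high_hz` must be below
#'   the Nyquist frequency `1/(2 tr_s)`.
#' @param tr_s Sampling interval (repetition time) in seconds.
#' @return Filtered numeric series.
#' @export
bandpass_filter <- function(x, low_hz, high_hz, tr_s) {
  n <- length(x)
  nyq <- 1 / (2 * tr_s)
  if (!(low_hz >= 0 && high_hz > low_hz)) stop("invalid band")
  if (high_hz > nyq + 1e-12)
    stop("'high_hz' exceeds the Nyquist frequency ", signif(nyq, 4), " Hz")
  k <- 0:(n - 1)
  f <- pmin(k, n - k) / (n * tr_s) # two-sided frequency magnitude
  keep <- f >= low_hz & f <= high_hz & k != 0
  if (!any(keep)) stop("empty pass band for a series of length ", n)
  z <- stats::fft(x)
  z[!keep] <- 0
  Re(stats::fft(z, inverse = TRUE)) / n
}

# one-sided amplitude spectrum (bins 1..floor(n/2)) of a series
.amp_spectrum <- function(z, n, tr_s) {
  kmax <- n %/% 2
  a <- Mod(z[2:(kmax + 1)]) * 2 / n
  list(freq = (1:kmax) / (n * tr_s), amp = a)
}

#' Resting-state fluctuation amplitude maps (ALFF, fALFF, mRSFA)
#'
#' Each in-mask voxel series is quadratically detrended, then: ALFF is the
#' mean one-sided amplitude-spectrum value inside the pass band; fALFF is
#' the in-band amplitude sum divided by the full non-DC amplitude sum (up
#' to Nyquist); RSFA is the standard deviation of the ideally bandpassed
#' series and mRSFA normalizes it by the voxel's original mean. When
#' `fwhm_mm > 0` the volumes are Gaussian-smoothed before metric
#' computation and the unsmoothed variant is always returned as well,
#' because parcel correlations of ALFF/mRSFA are sensitive to smoothing.
#'
#' @param bold 4D BOLD array (analyzed volumes; drop any discard prefix
#'   with `n_discard`).
#' @param mask 3D logical mask.
#' @param tr_s Repetition time (s).
#' @param band_hz Pass band, default `c(0.01, 0.1)` Hz.
#' @param fwhm_mm Smoothing kernel FWHM in mm (default 4; 0 disables).
#' @param voxel_mm Voxel size in mm.
#' @param n_discard Initial volumes to drop (default 0).
#' @param min_volumes Minimum series length for stable spectra (default 64).
#' @return Object of class `rsfc_maps`: lists `smoothed` and `unsmoothed`
#'   (each with 3D `alff`, `falff`, `mrsfa`), `band_hz`, `fwhm_mm`.
#'   `smoothed` is `NULL` when `fwhm_mm = 0`. Zero-mean voxels get
#'   `NaN` mRSFA and are counted in `n_zero_mean`.
#' @export
rsfc_metrics <- function(bold, mask, tr_s, band_hz = c(0.01, 0.1),
                         fwhm_mm = 4, voxel_mm = 2, n_discard = 0,
                         min_volumes = 64) {
  stopifnot(length(dim(bold)) == 4)
  sp <- dim(bold)[1:3]
  mask <- array(as.logical(mask), sp)
  n_total <- dim(bold)[4]
  nv <- n_total - n_discard
  if (nv < min_volumes)
    stop("segment too short: ", nv, " volumes < ", min_volumes)
  if (band_hz[2] > 1 / (2 * tr_s))
    stop("band upper edge exceeds Nyquist")

  compute <- function(vol4) {
    flat <- matrix(vol4, prod(sp), n_total)
    Y <- t(flat[mask, (n_discard + 1L):n_total, drop = FALSE]) # nv x nvox
    mu <- colMeans(Y)
    t <- seq_len(nv)
    X <- cbind(1, t, t^2)
    Yd <- as.matrix(stats::lm.fit(X, Y)$residuals)
    Z <- stats::mvfft(Yd)
    kmax <- nv %/% 2
    amp <- Mod(Z[2:(kmax + 1), , drop = FALSE]) * 2 / nv
    freq <- (1:kmax) / (nv * tr_s)
    inband <- freq >= band_hz[1] & freq <= band_hz[2]
    if (!any(inband)) stop("empty pass band")
    alff <- colMeans(amp[inband, , drop = FALSE])
    falff <- colSums(amp[inband, , drop = FALSE]) / colSums(amp)
    bp <- as.matrix(apply(Yd, 2, bandpass_filter, low_hz = band_hz[1],
                          high_hz = band_hz[2], tr_s = tr_s))
    rsfa <- apply(bp, 2, stats::sd)
    zero_mean <- abs(mu) < .Machine$double.eps * 100
    mrsfa <- ifelse(zero_mean, NaN, rsfa / mu)
    to_map <- function(v) { a <- array(NA_real_, sp); a[mask] <- v; a }
    list(alff = to_map(alff), falff = to_map(falff),
         mrsfa = to_map(mrsfa), n_zero_mean = sum(zero_mean))
  }

  unsmoothed <- compute(bold)
  smoothed <- NULL
  if (fwhm_mm > 0) {
    sm <- array(0, dim(bold))
    for (v in seq_len(n_total)) {
      sv <- smooth_volume(bold[, , , v], fwhm_mm, voxel_mm, mask)
      sv[!mask] <- 0
      sm[, , , v] <- sv
    }
    smoothed <- compute(sm)
  }
  structure(list(smoothed = smoothed, unsmoothed = unsmoothed,
                 band_hz = band_hz, fwhm_mm = fwhm_mm,
                 n_zero_mean = unsmoothed$n_zero_mean),
            class = "rsfc_maps")
}
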