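#' Detect end-tidal CO2 peaks in a capnography trace
#'
#' Identifies one expiratory peak per breath. A lightly smoothed copy of
#' the trace is used to locate breaths (local maxima separated by at least
#' `min_breath_period_s` and with prominence at least
#' `min_prominence_mmhg`); the reported end-tidal value and time are then
#' taken from the raw trace maximum in a small window around each located
#' breath, so a noiseless trace is recovered exactly.
#'
#' @param trace A [co2_trace()].
#' @param min_breath_period_s Minimum separation between breaths (s).
#' @param min_prominence_mmhg Minimum peak prominence (mmHg).
#' @return An object of class `petco2_series`: list with `peak_times_s`,
#'   `petco2_mmhg` and the detection parameters.
#' @export
detect_end_tidal <- function(trace, min_breath_period_s = 2,
                             min_prominence_mmhg = 5) {
  stopifnot(inherits(trace, "co2_trace"))
  if (min_breath_period_s <= 0 || min_prominence_mmhg <= 0)
    stop("detection parameters must be positive")
  x <- trace$co2_mmhg
  fs <- trace$sample_rate_hz
  n <- length(x)
  # smoothing for segmentation only (~0.3 s running mean)
  w <- max(1L, as.integer(round(0.3 * fs)))
  if (w %% 2L == 0L) w <- w + 1L
  xs <- if (w > 1L) stats::filter(x, rep(1 / w, w), sides = 2) else x
  xs <- as.numeric(xs)
  pad <- which(is.na(xs)); xs[pad] <- x[pad]

  cand <- which(diff(sign(diff(xs))) < 0) + 1L
  if (!length(cand)) stop("no breaths detected: trace has no local maxima")
  # enforce minimum separation, keeping higher peaks first
  cand <- cand[order(xs[cand], decreasing = TRUE)]
  keep <- logical(0); kept_pos <- numeric(0)
  min_gap <- min_breath_period_s * fs * 0.5
  for (p in cand) {
    if (!length(kept_pos) || all(abs(kept_pos - p) >= min_gap)) {
      kept_pos <- c(kept_pos, p)
    }
  }
  kept_pos <- sort(kept_pos)
  # prominence: drop to the higher of the two surrounding minima
  prom <- vapply(seq_along(kept_pos), function(i) {
    p <- kept_pos[i]
    lo <- if (i == 1L) 1L else kept_pos[i - 1L]
    hi <- if (i == length(kept_pos)) n else kept_pos[i + 1L]
    xs[p] - max(min(xs[lo:p]), min(xs[p:hi]))
  }, numeric(1))
  kept_pos <- kept_pos[prom >= min_prominence_mmhg]
  if (!length(kept_pos))
    stop("no breaths detected: no peak exceeds the prominence threshold")
  # refine on the raw trace
  half <- max(1L, as.integer(round(0.25 * min_breath_period_s * fs)))
  pk_t <- numeric(length(kept_pos)); pk_v <- numeric(length(kept_pos))
  for (i in seq_along(kept_pos)) {
    lo <- max(1L, kept_pos[i] - half); hi <- min(n, kept_pos[i] + half)
    j <- lo + which.max(x[lo:hi]) - 1L
    pk_t[i] <- trace$time_s[j]; pk_v[i] <- x[j]
  }
  ok <- c(TRUE, diff(pk_t) > 0)
  structure(list(peak_times_s = pk_t[ok], petco2_mmhg = pk_v[ok],
                 min_breath_period_s = min_breath_period_s,
                 min_prominence_mmhg = min_prominence_mmhg),
            class = "petco2_series")
}

#' End-tidal series from planted ground truth
#'
#' Wraps a data frame of planted peak times/values (as produced by
#' [simulate_co2_trace()]) in the same container that [detect_end_tidal()]
#' returns, for forward modeling and oracle tests.
#' @param petco2_true Data frame with `time_s` and `petco2_mmhg`.
#' @return A `petco2_series`.
#' @export
petco2_series <- function(petco2_true) {
  stopifnot(is.data.frame(petco2_true),
            all(c("time_s", "petco2_mmhg") %in% names(petco2_true)),
            all(diff(petco2_true$time_s) > 0))
  structure(list(peak_times_s = petco2_true$time_s,
                 petco2_mmhg = petco2_true$petco2_mmhg),
            class = "petco2_series")
}

#' Build the lagged family of HRF-convolved end-tidal regressors
#'
#' Pipeline order: linear interpolation of the end-tidal peaks onto a fine
#' grid at `lag_step_s` resolution (edge values held) -> baseline
#' subtraction -> convolution with the canonical HRF -> shift by each lag
#' -> sampling at the acquisition times of the analyzed volumes. Positive
#' lag means the regressor is delayed relative to the BOLD series (the
#' BOLD response lags the CO2 stimulus).
#'
#' The baseline is the mean of the end-tidal values falling inside the
#' protocol's free-breathing `rest` events, unless `baseline_mmhg` is
#' supplied.
#'
#' @param petco2 A `petco2_series`.
#' @param protocol The segment's [make_protocol()] object.
#' @param lag_limit_s Maximal shift (default 15 s).
#' @param lag_step_s Shift increment (default 0.3 s; must divide
#'   `lag_limit_s`).
#' @param alignment_offset_s Constant offset between trigger clock and CO2
#'   clock (default 0).
#' @param baseline_mmhg Optional fixed baseline overriding the rest-event
#'   mean.
#' @param hrf Optional HRF kernel sampled at `lag_step_s`
#'   (default [canonical_hrf()]).
#' @return An object of class `regressor_set`: `lags_s`, `regressors`
#'   (matrix, one row per lag), `hrf_kernel`, `tr_s`, `baseline_mmhg`,
#'   `sample_times_s` and `boundary_rows` (rows whose unshifted samples
#'   fall outside the recorded peak span and therefore rely on edge-held
#'   values).
#' @export
build_regressors <- function(petco2, protocol, lag_limit_s = 15,
                             lag_step_s = 0.3, alignment_offset_s = 0,
                             baseline_mmhg = NULL, hrf = NULL) {
  stopifnot(inherits(petco2, "petco2_series"),
            inherits(protocol, "task_protocol"))
  if (lag_step_s <= 0 || lag_limit_s < 0) stop("invalid lag grid")
  k <- lag_limit_s / lag_step_s
  if (abs(k - round(k)) > 1e-8)
    stop("'lag_step_s' must divide 'lag_limit_s'")
  k <- as.integer(round(k))
  lags <- lag_step_s * (-k:k)
  nv <- n_analyzed(protocol)
  if (nv <= 0) stop("empty analyzed window")
  tv <- volume_times(protocol) + alignment_offset_s

  if (is.null(hrf)) hrf <- canonical_hrf(lag_step_s)
  hrf_len_s <- (length(hrf) - 1L) * lag_step_s
  dt <- lag_step_s
  t0 <- floor((min(tv) - lag_limit_s - hrf_len_s - dt) / dt) * dt
  t1 <- ceiling((max(tv) + lag_limit_s + dt) / dt) * dt
  tf <- seq(t0, t1, by = dt)

  tide <- stats::approx(petco2$peak_times_s, petco2$petco2_mmhg,
                        xout = tf, rule = 2)$y
  if (is.null(baseline_mmhg)) {
    rest_ev <- protocol$events[protocol$events$kind == "rest", , drop = FALSE]
    inside <- rep(FALSE, length(petco2$peak_times_s))
    for (r in seq_len(nrow(rest_ev)))
      inside <- inside | (petco2$peak_times_s >= rest_ev$onset_s[r] &
                            petco2$peak_times_s <= rest_ev$onset_s[r] + rest_ev$duration_s[r])
    if (!any(inside)) inside <- rep(TRUE, length(inside))
    baseline_mmhg <- mean(petco2$petco2_mmhg[inside])
  }
  delta <- tide - baseline_mmhg
  conv <- .conv_causal(delta, as.numeric(hrf), dt)

  reg <- matrix(NA_real_, nrow = length(lags), ncol = nv)
  for (i in seq_along(lags))
    reg[i, ] <- stats::approx(tf, conv, xout = tv - lags[i], rule = 2)$y
  first_pk <- min(petco2$peak_times_s); last_pk <- max(petco2$peak_times_s)
  boundary_rows <- (min(tv) - lags) < first_pk | (max(tv) - lags) > last_pk
  if (any(!is.finite(reg))) stop("non-finite regressor values")

  structure(list(lags_s = lags, regressors = reg, hrf_kernel = hrf,
                 tr_s = protocol$tr_s, baseline_mmhg = baseline_mmhg,
                 sample_times_s = tv, boundary_rows = boundary_rows,
                 lag_limit_s = lag_limit_s, lag_step_s = lag_step_s),
            class = "regressor_set")
}

#' Extract one lag's regressor row
#' @param rs A `regressor_set`.
#' @param lag_s Lag in seconds; must lie on the grid.
#' @return Numeric vector (one regressor row).
#' @export
regressor_row <- function(rs, lag_s) {
  stopifnot(inherits(rs, "regressor_set"))
  i <- which(abs(rs$lags_s - lag_s) < rs$lag_step_s / 100)
  if (length(i) != 1L) stop("lag ", lag_s, " s is not on the lag grid")
  rs$regressors[i, ]
}

#' @export
print.regressor_set <- function(x, ...) {
  cat(sprintf("Lagged end-tidal regressor set: %d lags in [%+.1f, %+.1f] s (step %.2g s), %d volumes\n",
              length(x$lags_s), min(x$lags_s), max(x$lags_s), x$lag_step_s,
              ncol(x$regressors)))
  cat(sprintf("  baseline %.2f mmHg; %d boundary-affected rows\n",
              x$baseline_mmhg, sum(x$boundary_rows)))
  invisible(x)
}
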