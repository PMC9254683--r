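#' Construct a raw CO2 trace object
#'
#' @param time_s Sample times in seconds (uniform).
#' @param co2_mmhg CO2 partial pressure per sample (mmHg, non-negative).
#' @param sample_rate_hz Sampling rate in Hz.
#' @param trigger_times_s Scanner volume-trigger times in seconds.
#' @return An object of class `co2_trace`.
#' @export
co2_trace <- function(time_s, co2_mmhg, sample_rate_hz, trigger_times_s) {
  if (length(time_s) != length(co2_mmhg))
    stop("'time_s' and 'co2_mmhg' must have equal length")
  dt <- diff(time_s)
  if (length(dt) && max(abs(dt - 1 / sample_rate_hz)) > 1e-6)
    stop("trace must be uniformly sampled at 'sample_rate_hz'")
  if (any(co2_mmhg < 0)) stop("'co2_mmhg' must be non-negative")
  structure(list(time_s = time_s, co2_mmhg = co2_mmhg,
                 sample_rate_hz = sample_rate_hz,
                 trigger_times_s = trigger_times_s),
            class = "co2_trace")
}

#' Simulate a capnography trace for one data segment
#'
#' Generates a raised-cosine breath train between a near-room-air
#' inspiratory level and end-tidal peaks that track a planted end-tidal
#' curve: breath holds suppress breaths and elevate the first post-hold
#' peak by `bh_rise_mmhg` (washing out exponentially), cued deep breathing
#' progressively depresses peaks by up to `cdb_dip_mmhg`, and free
#' breathing carries a slow autoregressive end-tidal fluctuation of
#' standard deviation `rest_fluct_sd` (the small "natural" fluctuation that
#' makes rest-only CVR modeling hard). Every breath peak falls on exactly
#' one sample of the output grid, so at zero sensor noise the end-tidal
#' detector recovers the planted values exactly.
#'
#' @param protocol A [make_protocol()] object.
#' @param baseline_mmhg End-tidal baseline (default 38 mmHg).
#' @param bh_rise_mmhg End-tidal rise after each breath hold (default 9).
#' @param cdb_dip_mmhg Maximal end-tidal dip from deep breathing (default 6).
#' @param breath_period_s Free-breathing period (default 4 s).
#' @param rest_fluct_sd SD of the slow end-tidal fluctuation (mmHg).
#' @param rest_fluct_tau_s Correlation time of that fluctuation (s).
#' @param washout_tau_s Recovery time constant after task perturbations (s).
#' @param insp_mmhg Inspiratory (trough) level (default 2 mmHg).
#' @param sample_rate_hz Output sampling rate (default 1000 Hz).
#' @param noise_sd Gaussian sensor noise SD in mmHg (default 0.1).
#' @param seed Integer seed; required whenever any random component
#'   (`noise_sd` or `rest_fluct_sd`) is positive.
#'
#' @return A list of class `co2_sim` with elements `trace` (a
#'   [co2_trace()]), `petco2_true` (data frame of planted end-tidal peak
#'   times and values), `baseline_mmhg` and `seed`.
#' @export
simulate_co2_trace <- function(protocol, baseline_mmhg = 38,
                               bh_rise_mmhg = 9, cdb_dip_mmhg = 6,
                               breath_period_s = 4,
                               rest_fluct_sd = 1.2, rest_fluct_tau_s = 25,
                               washout_tau_s = 15, insp_mmhg = 2,
                               sample_rate_hz = 1000, noise_sd = 0.1,
                               seed = NULL) {
  stopifnot(inherits(protocol, "task_protocol"))
  if (baseline_mmhg <= 0) stop("'baseline_mmhg' must be positive")
  if (baseline_mmhg < 25 || baseline_mmhg > 55)
    warning("baseline outside the usual physiological range (25-55 mmHg)")
  if ((noise_sd > 0 || rest_fluct_sd > 0) && is.null(seed))
    stop("'seed' is required when 'noise_sd' or 'rest_fluct_sd' is positive")
  if (!is.null(seed)) set.seed(seed)
  fs <- sample_rate_hz
  snap <- function(t) round(t * fs) / fs

  ## ---- breath schedule -------------------------------------------------
  ev <- protocol$events
  peaks <- numeric(0)       # peak times
  kind <- character(0)      # breath kind: free / paced / deep
  post_hold_lead_s <- 1.5   # exhale shortly after the hold ends
  i <- 1L
  while (i <= nrow(ev)) {
    k <- ev$kind[i]
    if (k %in% c("rest", "recover")) {
      onset <- ev$onset_s[i]; dur <- ev$duration_s[i]
      after_hold <- i > 1L && ev$kind[i - 1L] == "hold"
      first <- if (after_hold) onset + post_hold_lead_s else onset + breath_period_s * 0.75
      tt <- seq(first, onset + dur - 0.3, by = breath_period_s)
      peaks <- c(peaks, tt); kind <- c(kind, rep("free", length(tt)))
      i <- i + 1L
    } else if (k %in% c("paced_out", "deep_out")) {
      t_pk <- ev$onset_s[i] + ev$duration_s[i] - 0.15 # end-expiration
      peaks <- c(peaks, t_pk)
      kind <- c(kind, if (k == "paced_out") "paced" else "deep")
      i <- i + 1L
    } else {
      i <- i + 1L # paced_in / deep_in / hold: no peak
    }
  }
  ord <- order(peaks)
  peaks <- snap(peaks[ord]); kind <- kind[ord]
  # deep-breathing blocks: label runs of consecutive deep breaths
  block_id <- integer(length(peaks)); deep_j <- integer(length(peaks))
  in_run <- FALSE; blk <- 0L; j <- 0L
  for (b in seq_along(peaks)) {
    if (kind[b] == "deep") {
      if (!in_run) { blk <- blk + 1L; j <- 0L; in_run <- TRUE }
      j <- j + 1L; block_id[b] <- blk; deep_j[b] <- j
    } else in_run <- FALSE
  }

  ## ---- end-tidal values ------------------------------------------------
  n_b <- length(peaks)
  if (n_b < 2L) stop("protocol too short: fewer than two breaths")
  fluct <- numeric(n_b)
  if (rest_fluct_sd > 0) {
    fluct[1] <- stats::rnorm(1, 0, rest_fluct_sd)
    for (b in 2:n_b) {
      phi <- exp(-(peaks[b] - peaks[b - 1]) / rest_fluct_tau_s)
      fluct[b] <- phi * fluct[b - 1] +
        stats::rnorm(1, 0, rest_fluct_sd * sqrt(1 - phi^2))
    }
  }
  offset <- numeric(n_b)
  holds <- ev[ev$kind == "hold", , drop = FALSE]
  if (nrow(holds)) {
    # the most recent hold governs each breath (full rise at the first
    # post-hold exhale, exponential washout afterwards)
    for (hh in seq_len(nrow(holds))) {
      h_end <- holds$onset_s[hh] + holds$duration_s[hh]
      idx <- which(peaks >= h_end)
      if (length(idx)) {
        t0 <- peaks[idx[1]]
        offset[idx] <- bh_rise_mmhg * exp(-(peaks[idx] - t0) / washout_tau_s)
      }
    }
  }
  if (any(block_id > 0L)) {
    for (bb in seq_len(max(block_id))) {
      inb <- which(block_id == bb)
      m <- length(inb)
      offset[inb] <- offset[inb] - cdb_dip_mmhg * deep_j[inb] / m
      t1 <- peaks[inb[m]]
      after <- which(peaks > t1 & block_id == 0L)
      if (length(after))
        offset[after] <- offset[after] - cdb_dip_mmhg * exp(-(peaks[after] - t1) / washout_tau_s)
    }
  }
  et <- baseline_mmhg + fluct + offset
  et <- pmax(et, insp_mmhg + 1)

  ## ---- waveform --------------------------------------------------------
  n_s <- as.integer(round(protocol$duration_s * fs)) + 1L
  tt <- (seq_len(n_s) - 1L) / fs
  w <- rep(insp_mmhg, n_s)
  idx_pk <- as.integer(round(peaks * fs)) + 1L
  hold_iv <- cbind(holds$onset_s, holds$onset_s + holds$duration_s)
  ramp_s <- 1.2
  for (b in seq_len(n_b - 1L)) {
    i0 <- idx_pk[b]; i1 <- idx_pk[b + 1L]
    if (i1 <= i0 + 1L) next
    gap <- peaks[b + 1L] - peaks[b]
    spans_hold <- nrow(holds) > 0 &&
      any(hold_iv[, 1] >= peaks[b] - 1e-9 & hold_iv[, 2] <= peaks[b + 1L] + 1e-9)
    seg <- i0:i1
    ts <- tt[seg]
    if (spans_hold || gap > 3 * breath_period_s) {
      # exhale down, sit at the inspiratory level, rise into the next breath
      v <- rep(insp_mmhg, length(seg))
      down <- ts <= peaks[b] + ramp_s
      v[down] <- insp_mmhg + (et[b] - insp_mmhg) *
        (1 + cos(pi * (ts[down] - peaks[b]) / ramp_s)) / 2
      up <- ts >= peaks[b + 1L] - ramp_s
      v[up] <- insp_mmhg + (et[b + 1L] - insp_mmhg) *
        (1 + cos(pi * (peaks[b + 1L] - ts[up]) / ramp_s)) / 2
      w[seg] <- pmax(w[seg], v)
    } else {
      # two half-cosine pieces with zero slope at each peak, so the
      # waveform maximum sits exactly on the planted peak sample
      u <- (ts - peaks[b]) / gap
      v <- ifelse(u <= 0.5,
                  insp_mmhg + (et[b] - insp_mmhg) * (1 + cos(2 * pi * u)) / 2,
                  insp_mmhg + (et[b + 1L] - insp_mmhg) *
                    (1 + cos(2 * pi * (1 - u))) / 2)
      w[seg] <- v
    }
  }
  # edges before the first / after the last peak
  i0 <- idx_pk[1]
  if (i0 > 1L) {
    ts <- tt[1:i0]
    up <- ts >= peaks[1] - ramp_s
    v <- rep(insp_mmhg, i0)
    v[up] <- insp_mmhg + (et[1] - insp_mmhg) *
      (1 + cos(pi * (peaks[1] - ts[up]) / ramp_s)) / 2
    w[1:i0] <- v
  }
  iN <- idx_pk[n_b]
  if (iN < n_s) {
    ts <- tt[iN:n_s]
    down <- ts <= peaks[n_b] + ramp_s
    v <- rep(insp_mmhg, length(ts))
    v[down] <- insp_mmhg + (et[n_b] - insp_mmhg) *
      (1 + cos(pi * (ts[down] - peaks[n_b]) / ramp_s)) / 2
    w[iN:n_s] <- v
  }
  if (noise_sd > 0) w <- w + stats::rnorm(n_s, 0, noise_sd)
  w <- pmax(w, 0)

  trig <- seq(0, by = protocol$tr_s, length.out = protocol$n_volumes_total)
  structure(list(trace = co2_trace(tt, w, fs, trig),
                 petco2_true = data.frame(time_s = peaks, petco2_mmhg = et),
                 baseline_mmhg = baseline_mmhg,
                 seed = seed),
            class = "co2_sim")
}
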