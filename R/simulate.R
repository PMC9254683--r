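#' Study-level configuration for the synthetic world and analysis defaults
#'
#' Collects every tunable parameter of the synthetic study and the analysis
#' pipeline. Unknown keys passed to this constructor (e.g. from a parsed
#' JSON/YAML list via `do.call`) are rejected by normal argument matching.
#'
#' @param tr_s Repetition time (s). @param rest_duration_s Segment length (s).
#' @param n_discard Discarded initial volumes.
#' @param lag_limit_s,lag_step_s Lag grid (+/- limit, step).
#' @param grid_shape,n_regions,voxel_mm,gm_threshold Atlas geometry.
#' @param tsnr Temporal signal-to-noise ratio of the BOLD series
#'   (mean / noise SD; `Inf` for noiseless).
#' @param mean_signal Mean BOLD signal level (arbitrary units).
#' @param cvr_range Range of planted parcel CVR amplitudes (%BOLD/mmHg).
#' @param cvr_within_sd Within-parcel CVR SD.
#' @param lag_range_s Range of planted hemodynamic lags (s).
#' @param lag_within_sd Within-parcel lag SD before snapping to the grid.
#' @param coupling_rho Planted parcelwise Spearman coupling between CVR and
#'   baseline CBF.
#' @param cbf_gm_mean,cbf_gm_sd,cbf_within_sd,cbf_wm_mean Planted CBF
#'   distribution (ml/100 g/min).
#' @param baseline_mmhg,bh_rise_mmhg,cdb_dip_mmhg,breath_period_s,rest_fluct_sd,co2_noise_sd,sample_rate_hz
#'   Capnography parameters (see [simulate_co2_trace()]).
#' @param drift_sd,motion_amplitude,motion_coupling_sd BOLD nuisance levels.
#' @param intrinsic_pct_range Range of the voxelwise intrinsic low-frequency
#'   fluctuation amplitude, as percent of the voxel mean (SD of a
#'   band-limited process; skipped in zero-noise simulations).
#' @param intrinsic_band_hz Band of the intrinsic fluctuations (Hz).
#' @param n_shared_components,shared_pct Number of spatially structured
#'   intrinsic components (smooth spatial loadings times band-limited time
#'   courses, emulating resting-state networks) and the SD each
#'   contributes, as percent of the voxel mean. Because these components
#'   are shared across voxels they do not average out within parcels; they
#'   are what degrades rest-only CVR estimates at the parcel level.
#' @param asl [asl_params()] used for the pCASL forward model.
#' @param asl_noise_sd,m0_value pCASL noise SD and M0 level.
#' @param band_hz,fwhm_mm Resting-state metric band and smoothing kernel.
#' @param n_perm Permutations for group inference.
#' @param segments The five data segments to simulate.
#' @return A list of class `study_config`.
#' @export
study_config <- function(tr_s = 1.2, rest_duration_s = 480, n_discard = 10,
                         lag_limit_s = 15, lag_step_s = 0.3,
                         grid_shape = c(24, 24, 12), n_regions = 48,
                         voxel_mm = 2, gm_threshold = 0.5,
                         tsnr = 50, mean_signal = 1000,
                         cvr_range = c(0.1, 0.4), cvr_within_sd = 0.02,
                         lag_range_s = c(-10, 10), lag_within_sd = 0.5,
                         coupling_rho = 0.6,
                         cbf_gm_mean = 55, cbf_gm_sd = 12,
                         cbf_within_sd = 5, cbf_wm_mean = 22,
                         baseline_mmhg = 38, bh_rise_mmhg = 9,
                         cdb_dip_mmhg = 6, breath_period_s = 4,
                         rest_fluct_sd = 1.2, co2_noise_sd = 0.1,
                         sample_rate_hz = 1000,
                         drift_sd = 10, motion_amplitude = 0.05,
                         motion_coupling_sd = 1,
                         intrinsic_pct_range = c(0.3, 1.5),
                         intrinsic_band_hz = c(0.008, 0.12),
                         n_shared_components = 6, shared_pct = 0.5,
                         asl = asl_params(), asl_noise_sd = 2,
                         m0_value = 1200,
                         band_hz = c(0.01, 0.1), fwhm_mm = 4,
                         n_perm = 2000,
                         segments = c("BH+REST", "CDB+REST", "REST",
                                      "REST_BH", "REST_CDB")) {
  stopifnot(tr_s > 0, rest_duration_s > 0, tsnr > 0, mean_signal > 0,
            lag_step_s > 0, lag_limit_s >= 0,
            diff(cvr_range) >= 0, diff(lag_range_s) >= 0,
            max(abs(lag_range_s)) <= lag_limit_s,
            abs(coupling_rho) <= 1, length(band_hz) == 2)
  cfg <- as.list(environment())
  structure(cfg, class = "study_config")
}

#' Plant voxelwise ground truth on a synthetic atlas
#'
#' Parcel-level CVR amplitudes are drawn uniformly over `cvr_range`,
#' hemodynamic lags uniformly over `lag_range_s` (snapped to the lag grid so
#' on-grid recovery is well defined), and baseline CBF values are coupled to
#' the CVR parcel means at Spearman correlation `coupling_rho` via
#' [couple_fields()]. Voxel-level jitter is added within parcels; non-GM
#' brain tissue receives low CVR and white-matter-like CBF.
#'
#' @param atlas_obj A [make_atlas()] result.
#' @param seed Integer seed.
#' @param config A [study_config()].
#' @return Object of class `ground_truth`: `cvr_amp_map`, `lag_map`,
#'   `cbf_map`, `mean_map` (3D arrays), `coupling_rho`, `seed`, `atlas`.
#' @export
simulate_truth <- function(atlas_obj, seed, config = study_config()) {
  stopifnot(inherits(atlas_obj, "synthetic_atlas"),
            inherits(config, "study_config"))
  set.seed(seed)
  P <- atlas_obj$n_parcels
  lab <- atlas_obj$atlas
  gm <- atlas_obj$gm_mask; brain <- atlas_obj$brain_mask
  gs <- atlas_obj$grid_shape

  cvr_parcel <- stats::runif(P, config$cvr_range[1], config$cvr_range[2])
  lag_parcel <- stats::runif(P, config$lag_range_s[1], config$lag_range_s[2])
  cbf_seed <- sample.int(.Machine$integer.max, 1)
  zc <- couple_fields(cvr_parcel, config$coupling_rho, cbf_seed)
  cbf_parcel <- config$cbf_gm_mean + config$cbf_gm_sd * zc

  cvr <- array(0, gs); lagm <- array(0, gs); cbf <- array(0, gs)
  sel <- lab > 0L
  n_gm <- sum(sel)
  cvr[sel] <- pmax(cvr_parcel[lab[sel]] +
                     stats::rnorm(n_gm, 0, config$cvr_within_sd), 0.02)
  lag_raw <- lag_parcel[lab[sel]] + stats::rnorm(n_gm, 0, config$lag_within_sd)
  lag_raw <- pmin(pmax(lag_raw, config$lag_range_s[1]), config$lag_range_s[2])
  lagm[sel] <- round(lag_raw / config$lag_step_s) * config$lag_step_s
  cbf[sel] <- pmax(cbf_parcel[lab[sel]] +
                     stats::rnorm(n_gm, 0, config$cbf_within_sd), 1)
  deep <- brain & !sel
  cvr[deep] <- pmax(0.08 + stats::rnorm(sum(deep), 0, 0.01), 0.01)
  cbf[deep] <- pmax(config$cbf_wm_mean + stats::rnorm(sum(deep), 0, 3), 1)
  meanm <- array(0, gs)
  meanm[brain] <- config$mean_signal *
    pmax(1 + stats::rnorm(sum(brain), 0, 0.05), 0.3)

  structure(list(cvr_amp_map = cvr, lag_map = lagm, cbf_map = cbf,
                 mean_map = meanm, coupling_rho = config$coupling_rho,
                 seed = seed, atlas = atlas_obj),
            class = "ground_truth")
}

#' Forward-model a BOLD segment from planted truth
#'
#' Each brain voxel's series is
#' `mean * (1 + cvr/100 * x_lag)` plus a polynomial drift, a motion-coupled
#' nuisance and white Gaussian noise, where `x_lag` is the HRF-convolved,
#' baseline-subtracted end-tidal regressor shifted by the voxel's planted
#' lag — built with [build_regressors()], i.e. exactly the regressor family
#' the analysis uses, so at zero noise the estimators invert the model to
#' numerical precision. Drift and motion terms are mean-free over the
#' analyzed window, so the fitted intercept estimates the voxel mean.
#'
#' @param truth A [simulate_truth()] object.
#' @param petco2 A `co2_sim`, `petco2_series`, or data frame of planted
#'   end-tidal peaks.
#' @param protocol The segment's [make_protocol()].
#' @param config A [study_config()]; supplies lag grid, nuisance levels
#'   and noise (`tsnr`).
#' @param seed Integer seed (required unless all noise terms are zero).
#' @param noise_sd BOLD noise SD; default `mean_signal / tsnr` from config.
#' @return List of class `bold_sim`: `bold` (4D array over all volumes,
#'   discard prefix included), `motion` (matrix, all volumes x 6),
#'   `regressors` (the forward `regressor_set`), `protocol`, `seed`.
#' @export
simulate_bold <- function(truth, petco2, protocol, config = study_config(),
                          seed = NULL, noise_sd = NULL) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(protocol, "task_protocol"))
  if (inherits(petco2, "co2_sim")) petco2 <- petco2$petco2_true
  if (is.data.frame(petco2)) petco2 <- petco2_series(petco2)
  if (is.null(noise_sd)) noise_sd <- config$mean_signal / config$tsnr
  random <- noise_sd > 0 || config$drift_sd > 0 || config$motion_amplitude > 0
  if (random && is.null(seed)) stop("'seed' required for stochastic simulation")
  if (!is.null(seed)) set.seed(seed)

  rs <- build_regressors(petco2, protocol, config$lag_limit_s,
                         config$lag_step_s)
  atlas_obj <- truth$atlas
  brain <- which(atlas_obj$brain_mask)
  nvox <- length(brain)
  nv <- n_analyzed(protocol)
  n_total <- protocol$n_volumes_total

  lag_v <- truth$lag_map[brain]
  row_i <- match(round(lag_v / config$lag_step_s),
                 round(rs$lags_s / config$lag_step_s))
  if (any(is.na(row_i)))
    stop("planted lag outside the representable lag grid")
  X <- t(rs$regressors)[, row_i, drop = FALSE]           # nv x nvox
  mu <- truth$mean_map[brain]
  amp <- mu * truth$cvr_amp_map[brain] / 100
  Y <- matrix(mu, nv, nvox, byrow = TRUE) + X * matrix(amp, nv, nvox, byrow = TRUE)

  tv <- volume_times(protocol)
  drift_order <- max(1L, floor((nv * protocol$tr_s) / 150))
  if (config$drift_sd > 0) {
    Bd <- stats::poly(tv, degree = drift_order) * sqrt(nv) # ~unit-SD columns
    Gd <- matrix(stats::rnorm(drift_order * nvox, 0, config$drift_sd),
                 drift_order, nvox)
    Y <- Y + Bd %*% Gd
  }
  motion <- matrix(0, n_total, 6)
  if (config$motion_amplitude > 0) {
    motion <- apply(matrix(stats::rnorm(n_total * 6, 0,
                                        config$motion_amplitude),
                           n_total, 6), 2, cumsum)
    Mc <- scale(motion[(protocol$n_discard + 1L):n_total, , drop = FALSE],
                center = TRUE, scale = FALSE)
    Gm <- matrix(stats::rnorm(6 * nvox, 0, config$motion_coupling_sd), 6, nvox)
    Y <- Y + Mc %*% Gm
  }
  if (noise_sd > 0 && max(config$intrinsic_pct_range) > 0) {
    # intrinsic low-frequency fluctuations (neural/physiological), with
    # voxel-varying amplitude as a percentage of the voxel mean; these are
    # what masks the small end-tidal fluctuations in rest-only modeling.
    # Zero-noise simulations stay fully deterministic for closure tests.
    pct <- stats::runif(nvox, config$intrinsic_pct_range[1],
                        config$intrinsic_pct_range[2])
    z <- matrix(stats::rnorm(nv * nvox), nv, nvox)
    Z <- stats::mvfft(z)
    kk <- 0:(nv - 1)
    ff <- pmin(kk, nv - kk) / (nv * protocol$tr_s)
    Z[!(ff >= config$intrinsic_band_hz[1] &
          ff <= config$intrinsic_band_hz[2] & kk != 0), ] <- 0
    Fl <- Re(stats::mvfft(Z, inverse = TRUE)) / nv
    sds <- apply(Fl, 2, stats::sd)
    Fl <- sweep(Fl, 2, pmax(sds, 1e-12), "/")
    Y <- Y + Fl * matrix(mu * pct / 100, nv, nvox, byrow = TRUE)
    K <- config$n_shared_components
    if (K > 0 && config$shared_pct > 0) {
      # spatially smooth loading maps x band-limited time courses: shared
      # fluctuations that survive parcel averaging, like resting networks
      L <- matrix(0, K, nvox)
      for (cmp in seq_len(K)) {
        fld <- array(stats::rnorm(prod(atlas_obj$grid_shape)),
                     atlas_obj$grid_shape)
        sm <- smooth_volume(fld, fwhm_mm = 4 * atlas_obj$voxel_mm,
                            voxel_mm = atlas_obj$voxel_mm,
                            mask = atlas_obj$brain_mask)
        lv <- sm[brain]
        L[cmp, ] <- lv / stats::sd(lv)
      }
      zt <- matrix(stats::rnorm(nv * K), nv, K)
      Zt <- stats::mvfft(zt)
      Zt[!(ff >= config$intrinsic_band_hz[1] &
             ff <= config$intrinsic_band_hz[2] & kk != 0), ] <- 0
      Tc <- Re(stats::mvfft(Zt, inverse = TRUE)) / nv
      Tc <- sweep(Tc, 2, pmax(apply(Tc, 2, stats::sd), 1e-12), "/")
      Y <- Y + (Tc %*% L) * matrix(mu * config$shared_pct / 100, nv, nvox,
                                   byrow = TRUE)
    }
  }
  if (noise_sd > 0) Y <- Y + matrix(stats::rnorm(nv * nvox, 0, noise_sd), nv, nvox)

  bold <- array(0, c(atlas_obj$grid_shape, n_total))
  flat <- matrix(bold, prod(atlas_obj$grid_shape), n_total)
  if (protocol$n_discard > 0) {
    pre <- matrix(mu, nvox, protocol$n_discard)
    if (noise_sd > 0)
      pre <- pre + matrix(stats::rnorm(nvox * protocol$n_discard, 0, noise_sd),
                          nvox, protocol$n_discard)
    flat[brain, seq_len(protocol$n_discard)] <- pre
  }
  flat[brain, (protocol$n_discard + 1L):n_total] <- t(Y)
  bold <- array(flat, c(atlas_obj$grid_shape, n_total))
  colnames(motion) <- paste0("mot", 1:6)

  structure(list(bold = bold, motion = motion, regressors = rs,
                 protocol = protocol, seed = seed),
            class = "bold_sim")
}

#' Forward-model a pCASL tag/control/M0 series
#'
#' Eleven tag and eleven control volumes (interleaved, tag first by
#' default) plus a trailing M0 calibration volume. Each control-minus-tag
#' difference equals the single-compartment consensus kinetic model
#' evaluated at the planted CBF map, plus optional Gaussian noise.
#'
#' @param truth A [simulate_truth()] object.
#' @param params [asl_params()].
#' @param n_pairs Number of tag/control pairs (default 11).
#' @param noise_sd Gaussian noise SD added to every tag/control/M0 volume.
#' @param m0_value Mean M0 level inside the brain; must be positive.
#' @param order `"tc"` (tag first) or `"ct"`.
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @return 4D array with `2*n_pairs + 1` volumes and attributes `order` and
#'   `m0_index`.
#' @export
simulate_pcasl <- function(truth, params = asl_params(), n_pairs = 11,
                           noise_sd = 2, m0_value = 1200,
                           order = c("tc", "ct"), seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  order <- match.arg(order)
  if (m0_value <= 0) stop("'m0_value' must be positive")
  if (noise_sd > 0 && is.null(seed)) stop("'seed' required when noise_sd > 0")
  if (!is.null(seed)) set.seed(seed)
  atlas_obj <- truth$atlas
  gs <- atlas_obj$grid_shape
  brain <- atlas_obj$brain_mask
  m0 <- array(0, gs)
  m0[brain] <- m0_value
  dm <- .cbf_forward(truth$cbf_map, m0, params)
  nvol <- 2L * n_pairs + 1L
  series <- array(0, c(gs, nvol))
  for (p in seq_len(n_pairs)) {
    ctrl <- m0
    tag <- m0 - dm
    i_tag <- if (order == "tc") 2L * p - 1L else 2L * p
    i_ctl <- if (order == "tc") 2L * p else 2L * p - 1L
    series[, , , i_tag] <- tag
    series[, , , i_ctl] <- ctrl
  }
  series[, , , nvol] <- m0
  if (noise_sd > 0)
    series <- series + array(stats::rnorm(length(series), 0, noise_sd),
                             dim(series))
  attr(series, "order") <- order
  attr(series, "m0_index") <- nvol
  series
}

#' Simulate one complete synthetic subject
#'
#' Generates the shared atlas, subject-specific ground truth, the five data
#' segments (capnography + BOLD + motion) and a pCASL series, all from a
#' single integer seed. Identical seed and configuration give bit-identical
#' output.
#'
#' @param seed Integer seed.
#' @param config A [study_config()].
#' @param atlas_obj Optional pre-built atlas (it is deterministic given the
#'   config, so sharing one across subjects is safe and faster).
#' @param segments Segments to simulate (default: all five in the config).
#' @param with_pcasl Simulate the pCASL series (default TRUE).
#' @return Object of class `synthetic_subject`: `segments` (named list with
#'   `protocol`, `co2`, `bold`), `pcasl`, `atlas`, `truth`, `seed`.
#' @export
simulate_subject <- function(seed, config = study_config(),
                             atlas_obj = NULL,
                             segments = config$segments,
                             with_pcasl = TRUE) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(atlas_obj))
    atlas_obj <- make_atlas(config$grid_shape, config$n_regions,
                            config$voxel_mm, config$gm_threshold)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(segments) * 2L + 2L)
  truth <- simulate_truth(atlas_obj, sub_seeds[1], config)
  segs <- vector("list", length(segments))
  names(segs) <- segments
  for (s in seq_along(segments)) {
    protocol <- make_protocol(segments[s], tr_s = config$tr_s,
                              rest_duration_s = config$rest_duration_s,
                              n_discard = config$n_discard)
    co2 <- simulate_co2_trace(protocol,
                              baseline_mmhg = config$baseline_mmhg,
                              bh_rise_mmhg = config$bh_rise_mmhg,
                              cdb_dip_mmhg = config$cdb_dip_mmhg,
                              breath_period_s = config$breath_period_s,
                              rest_fluct_sd = config$rest_fluct_sd,
                              sample_rate_hz = config$sample_rate_hz,
                              noise_sd = config$co2_noise_sd,
                              seed = sub_seeds[2 * s])
    bold <- simulate_bold(truth, co2, protocol, config,
                          seed = sub_seeds[2 * s + 1])
    segs[[s]] <- list(protocol = protocol, co2 = co2, bold = bold)
  }
  pcasl <- NULL
  if (with_pcasl)
    pcasl <- simulate_pcasl(truth, config$asl, noise_sd = config$asl_noise_sd,
                            m0_value = config$m0_value,
                            seed = sub_seeds[length(sub_seeds)])
  structure(list(segments = segs, pcasl = pcasl, atlas = atlas_obj,
                 truth = truth, seed = seed),
            class = "synthetic_subject")
}
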