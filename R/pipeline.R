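#' Recovery of planted truth by a CVR fit
#'
#' @param fit A [cvr_fit()] result.
#' @param truth The matching [simulate_truth()] object.
#' @param mask Evaluation mask (default: the GM mask of the truth's atlas).
#' @return One-row data frame: `median_abs_lag_err_s`, `frac_lag_exact`,
#'   `median_rel_amp_err`, `max_rel_amp_err`, `n_voxels`.
#' @export
recovery_metrics <- function(fit, truth, mask = NULL) {
  stopifnot(inherits(fit, "cvr_fit"), inherits(truth, "ground_truth"))
  if (is.null(mask)) mask <- truth$atlas$gm_mask
  m <- mask & fit$mask & is.finite(fit$cvr_amp)
  lag_err <- abs(fit$lag_s[m] - truth$lag_map[m])
  amp_err <- abs(fit$cvr_amp[m] - truth$cvr_amp_map[m]) / truth$cvr_amp_map[m]
  data.frame(median_abs_lag_err_s = stats::median(lag_err),
             frac_lag_exact = mean(lag_err < 1e-9),
             median_rel_amp_err = stats::median(amp_err),
             max_rel_amp_err = max(amp_err),
             n_voxels = sum(m))
}

#' Analyze one simulated segment with both CVR schemes
#'
#' Runs the analysis path the way it would run on real data: end-tidal
#' detection on the raw trace, regressor construction, then voxelwise
#' fits without and with lag optimization.
#'
#' @param seg One element of `simulate_subject()$segments`.
#' @param atlas_obj The subject's atlas.
#' @param config The [study_config()].
#' @param schemes Which schemes to fit (subset of `c("none", "lag")`).
#' @return List of `cvr_fit`s named by scheme, plus `regressors`.
#' @export
analyze_segment <- function(seg, atlas_obj, config, schemes = c("none", "lag")) {
  pet <- detect_end_tidal(seg$co2$trace)
  rs <- build_regressors(pet, seg$protocol, config$lag_limit_s,
                         config$lag_step_s)
  fits <- list()
  for (sc in schemes)
    fits[[sc]] <- cvr_fit(seg$bold$bold, rs, atlas_obj$brain_mask,
                          motion = seg$bold$motion, optimize = sc)
  fits$regressors <- rs
  fits
}

#' Run a complete synthetic study
#'
#' Simulates `n_subjects` subjects, analyzes every requested segment with
#' the requested CVR schemes, reduces CVR and baseline-CBF maps to parcel
#' means and GM medians, computes the within-subject spatial correlations
#' (Spearman, outlier parcels removed, Fisher Z) and the between-subject
#' GM-median Pearson correlations (influential subjects removed, FDR
#' across tests), and tests scheme and segment effects on the Fisher-Z
#' values with a permutation repeated-measures ANOVA. Ground-truth
#' recovery metrics are reported for every fit.
#'
#' @param n_subjects Number of subjects.
#' @param config A [study_config()].
#' @param seed Integer master seed.
#' @param cbf_source `"planted"` (use the ground-truth CBF map) or
#'   `"asl"` (quantify CBF from the simulated pCASL series).
#' @param schemes CVR schemes to run (default both).
#' @param segments Segments to run (default: all in config).
#' @param do_rsfc Also compute resting-state metrics on rest-only segments
#'   and correlate them with CBF (default FALSE).
#' @param verbose Print progress (default FALSE).
#' @return Object of class `study_report`: `correlations` (long data
#'   frame), `between_subjects`, `anova`, `recovery`, `rsfc`, `config`,
#'   `seed`.
#' @export
run_study <- function(n_subjects, config = study_config(), seed,
                      cbf_source = c("planted", "asl"),
                      schemes = c("none", "lag"),
                      segments = config$segments,
                      do_rsfc = FALSE, verbose = FALSE) {
  cbf_source <- match.arg(cbf_source)
  if (missing(seed)) stop("'seed' is required")
  atlas_obj <- make_atlas(config$grid_shape, config$n_regions,
                          config$voxel_mm, config$gm_threshold)
  set.seed(seed)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  anova_seed <- sample.int(.Machine$integer.max - 1L, 1)

  corr <- list(); recov <- list(); med <- list(); rsfc_rows <- list()
  for (i in seq_len(n_subjects)) {
    if (verbose) message("subject ", i, "/", n_subjects)
    subj <- simulate_subject(subj_seeds[i], config, atlas_obj = atlas_obj,
                             segments = segments,
                             with_pcasl = cbf_source == "asl")
    if (cbf_source == "planted") {
      cbf_vol <- subj$truth$cbf_map
    } else {
      dm <- tag_control_diff(subj$pcasl)
      cbf_vol <- quantify_cbf(dm$delta_m, dm$m0, config$asl,
                              atlas_obj$brain_mask, dm$n_pairs)$cbf
    }
    cbf_tab <- parcel_means(cbf_vol, atlas_obj, map_kind = "cbf")
    cbf_med <- as.numeric(gm_median(cbf_vol, atlas_obj$gm_mask))

    for (sg in segments) {
      fits <- analyze_segment(subj$segments[[sg]], atlas_obj, config, schemes)
      for (sc in schemes) {
        fit <- fits[[sc]]
        cvr_tab <- parcel_means(fit$cvr_amp, atlas_obj, map_kind = "cvr_amp")
        cr <- correlate_spatial(cvr_tab, cbf_tab)
        corr[[length(corr) + 1L]] <- data.frame(
          subject = i, segment = sg, scheme = sc,
          rho = cr$r, fisher_z = cr$fisher_z,
          n_used = cr$n_used, n_removed = length(cr$removed_indices),
          significant = cr$significant)
        recov[[length(recov) + 1L]] <- cbind(
          data.frame(subject = i, segment = sg, scheme = sc),
          recovery_metrics(fit, subj$truth))
        med[[length(med) + 1L]] <- data.frame(
          subject = i, segment = sg, scheme = sc,
          gm_cvr = as.numeric(gm_median(fit$cvr_amp, atlas_obj$gm_mask)),
          gm_cbf = cbf_med)
      }
      if (do_rsfc && !(sg %in% c("BH+REST", "CDB+REST"))) {
        seg <- subj$segments[[sg]]
        rm_ <- rsfc_metrics(seg$bold$bold, atlas_obj$brain_mask,
                            tr_s = config$tr_s, band_hz = config$band_hz,
                            fwhm_mm = config$fwhm_mm,
                            voxel_mm = config$voxel_mm,
                            n_discard = seg$protocol$n_discard)
        for (metric in c("alff", "falff", "mrsfa")) {
          for (variant in c("smoothed", "unsmoothed")) {
            maps <- rm_[[variant]]
            if (is.null(maps)) next
            mtab <- parcel_means(maps[[metric]], atlas_obj, map_kind = metric)
            mc <- correlate_spatial(mtab, cbf_tab)
            rsfc_rows[[length(rsfc_rows) + 1L]] <- data.frame(
              subject = i, segment = sg, metric = metric,
              variant = variant, rho = mc$r, fisher_z = mc$fisher_z,
              n_used = mc$n_used, significant = mc$significant)
          }
        }
      }
    }
  }
  correlations <- do.call(rbind, corr)
  recovery <- do.call(rbind, recov)
  medians <- do.call(rbind, med)
  rsfc <- if (length(rsfc_rows)) do.call(rbind, rsfc_rows) else NULL

  between <- NULL
  if (n_subjects >= 4) {
    rows <- list()
    for (sg in segments) for (sc in schemes) {
      sel <- medians$segment == sg & medians$scheme == sc
      bt <- correlate_between_subjects(medians$gm_cbf[sel],
                                       medians$gm_cvr[sel])
      rows[[length(rows) + 1L]] <- data.frame(
        segment = sg, scheme = sc, r = bt$r, p = bt$p,
        n_used = bt$n_used, n_removed = length(bt$removed_indices),
        r_unscreened = bt$unscreened$r, p_unscreened = bt$unscreened$p)
    }
    between <- do.call(rbind, rows)
    between$p_fdr <- stats::p.adjust(between$p, method = "BH")
    between$p_unscreened_fdr <- stats::p.adjust(between$p_unscreened,
                                                method = "BH")
  }

  anova <- NULL
  if (length(schemes) == 2 && length(segments) >= 2 && n_subjects >= 3) {
    long <- data.frame(subject = correlations$subject,
                       scheme = correlations$scheme,
                       segment = correlations$segment,
                       value = correlations$fisher_z)
    anova <- perm_rm_anova(long, n_perm = config$n_perm,
                           seed = anova_seed %% .Machine$integer.max)
  }

  structure(list(correlations = correlations, between_subjects = between,
                 anova = anova, recovery = recovery, medians = medians,
                 rsfc = rsfc, config = config, seed = seed,
                 n_subjects = n_subjects, schemes = schemes,
                 segments = segments),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Synthetic study report: %d subjects, %d segment(s), %s\n",
              x$n_subjects, length(x$segments),
              paste(x$schemes, collapse = "/")))
  agg <- stats::aggregate(fisher_z ~ segment + scheme, x$correlations, mean)
  cat("mean Fisher Z of parcelwise CVR-CBF correlation:\n")
  print(agg, row.names = FALSE)
  if (!is.null(x$anova)) print(x$anova)
  invisible(x)
}
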