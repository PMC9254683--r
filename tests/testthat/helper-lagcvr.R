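# Small study conditions for unit tests: coarse grid, shorter segments,
# lower CO2 sampling rate. Acceptance tests use the full-size defaults.
quick_cfg <- function(...) {
  args <- list(...)
  base <- list(grid_shape = c(12, 12, 6), n_regions = 8,
               rest_duration_s = 300, sample_rate_hz = 250)
  do.call(study_config, utils::modifyList(base, args))
}

quick_atlas <- function(cfg = quick_cfg()) {
  make_atlas(cfg$grid_shape, cfg$n_regions, cfg$voxel_mm, cfg$gm_threshold)
}

# one simulated segment ready for fitting
quick_segment <- function(segment = "BH+REST", seed = 1, cfg = quick_cfg(),
                          atlas_obj = quick_atlas(cfg)) {
  truth <- simulate_truth(atlas_obj, seed, cfg)
  protocol <- make_protocol(segment, tr_s = cfg$tr_s,
                            rest_duration_s = cfg$rest_duration_s,
                            n_discard = cfg$n_discard)
  co2 <- simulate_co2_trace(protocol, baseline_mmhg = cfg$baseline_mmhg,
                            bh_rise_mmhg = cfg$bh_rise_mmhg,
                            cdb_dip_mmhg = cfg$cdb_dip_mmhg,
                            rest_fluct_sd = cfg$rest_fluct_sd,
                            sample_rate_hz = cfg$sample_rate_hz,
                            noise_sd = cfg$co2_noise_sd, seed = seed + 1)
  bold <- simulate_bold(truth, co2, protocol, cfg, seed = seed + 2)
  list(truth = truth, protocol = protocol, co2 = co2, bold = bold,
       atlas = atlas_obj, cfg = cfg)
}

# long-format repeated-measures data frame helper
rm_long <- function(Y, schemes = c("none", "lag"),
                    segments = paste0("seg", seq_len(ncol(Y) / 2))) {
  a <- length(schemes); b <- length(segments); S <- nrow(Y)
  data.frame(subject = rep(seq_len(S), a * b),
             scheme = rep(schemes, each = S * b),
             segment = rep(rep(segments, each = S), a),
             value = as.vector(Y))
}
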