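test_that("design drift block is orthonormal and blocks are labeled", {
  set.seed(1)
  d <- build_design(100, 1.2, drift_order = 3,
                    motion = matrix(rnorm(600), 100, 6),
                    regressor = rnorm(100))
  G <- crossprod(d$X[, d$blocks$drift])
  expect_equal(G, diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(colSums(d$X[, d$blocks$drift])), rep(0, 3),
               tolerance = 1e-12)
  expect_named(d$blocks, c("intercept", "drift", "motion", "petco2"),
               ignore.order = TRUE)
  expect_true(is.finite(d$condition_number))
})

test_that("zero motion columns are dropped and duplicates raise rank errors", {
  set.seed(2)
  x <- rnorm(50)
  expect_message(d <- build_design(50, 1.2, 0, motion = matrix(0, 50, 6),
                                   regressor = x),
                 "constant motion")
  expect_equal(ncol(d$X), 2L) # intercept + regressor
  m <- cbind(x, matrix(rnorm(250), 50, 5)) # motion col duplicates regressor
  expect_error(build_design(50, 1.2, 0, motion = m, regressor = x),
               "rank deficient")
  expect_error(build_design(50, 1.2, 0, regressor = rep(1, 50)),
               "rank deficient") # constant regressor collinear with intercept
})

test_that("fit_voxel matches a pseudoinverse oracle to 1e-10", {
  set.seed(3)
  X <- cbind(1, matrix(rnorm(40 * 3), 40, 3))
  colnames(X) <- c("intercept", "a", "b", "c")
  y <- rnorm(40)
  f <- fit_voxel(y, X)
  sv <- svd(X)
  beta_pinv <- sv$v %*% diag(1 / sv$d) %*% crossprod(sv$u, y)
  expect_equal(unname(f$betas), as.numeric(beta_pinv), tolerance = 1e-10)
  # y in the column space -> R^2 = 1
  y2 <- X %*% c(2, -1, 3, 0.5)
  expect_equal(fit_voxel(as.numeric(y2), X)$r_squared, 1, tolerance = 1e-12)
  # y orthogonal to all non-intercept columns -> R^2 = 0
  Q <- qr.Q(qr(X))
  y3 <- rnorm(40)
  y3 <- y3 - Q %*% crossprod(Q, y3) + 5
  expect_equal(fit_voxel(as.numeric(y3), X)$r_squared, 0, tolerance = 1e-10)
  expect_warning(f0 <- fit_voxel(rep(0, 40), X), "all-zero")
  expect_equal(f0$r_squared, 0)
})

test_that("no-lag-optimization CVR recovers a planted noiseless map exactly", {
  cfg <- quick_cfg(tsnr = Inf, co2_noise_sd = 0, lag_range_s = c(0, 0),
                   lag_within_sd = 0)
  qs <- quick_segment("BH+REST", seed = 10, cfg = cfg)
  rs <- build_regressors(detect_end_tidal(qs$co2$trace), qs$protocol)
  fit <- cvr_no_opt(qs$bold$bold, rs, qs$atlas$brain_mask,
                    motion = qs$bold$motion)
  m <- qs$atlas$brain_mask
  expect_lt(max(abs(fit$cvr_amp[m] - qs$truth$cvr_amp_map[m]) /
                  qs$truth$cvr_amp_map[m]), 1e-6)
  expect_true(all(fit$lag_s[m] == 0))
  expect_true(all(fit$r_squared[m] >= 0 & fit$r_squared[m] <= 1))
})

test_that("lag optimization recovers a planted 6 s lag exactly at zero noise", {
  cfg <- quick_cfg(tsnr = Inf, co2_noise_sd = 0, lag_range_s = c(6, 6),
                   lag_within_sd = 0)
  qs <- quick_segment("BH+REST", seed = 11, cfg = cfg)
  rs <- build_regressors(detect_end_tidal(qs$co2$trace), qs$protocol)
  fit <- cvr_lag_opt(qs$bold$bold, rs, qs$atlas$brain_mask,
                     motion = qs$bold$motion)
  gm <- qs$atlas$gm_mask
  expect_true(all(fit$lag_s[gm] == 6))
  expect_lt(max(abs(fit$cvr_amp[gm] - qs$truth$cvr_amp_map[gm]) /
                  qs$truth$cvr_amp_map[gm]), 1e-6)
  expect_false(any(fit$boundary_flag[gm]))
})

test_that("with a planted zero lag, lag optimization equals the unshifted fit", {
  cfg <- quick_cfg(tsnr = Inf, co2_noise_sd = 0, lag_range_s = c(0, 0),
                   lag_within_sd = 0)
  qs <- quick_segment("BH+REST", seed = 12, cfg = cfg)
  rs <- build_regressors(detect_end_tidal(qs$co2$trace), qs$protocol)
  m <- qs$atlas$brain_mask
  f0 <- cvr_no_opt(qs$bold$bold, rs, m, motion = qs$bold$motion)
  f1 <- cvr_lag_opt(qs$bold$bold, rs, m, motion = qs$bold$motion)
  expect_true(all(f1$lag_s[m] == 0))
  expect_equal(f1$cvr_amp[m], f0$cvr_amp[m], tolerance = 1e-12)
})

test_that("lag-optimized R^2 dominates the unshifted R^2 at every voxel", {
  cfg <- quick_cfg()
  qs <- quick_segment("CDB+REST", seed = 13, cfg = cfg)
  rs <- build_regressors(detect_end_tidal(qs$co2$trace), qs$protocol)
  m <- qs$atlas$brain_mask
  f0 <- cvr_no_opt(qs$bold$bold, rs, m, motion = qs$bold$motion)
  f1 <- cvr_lag_opt(qs$bold$bold, rs, m, motion = qs$bold$motion)
  expect_gte(min(f1$r_squared[m] - f0$r_squared[m]), 0)
})

test_that("CVR amplitude is invariant to a global BOLD scale factor", {
  cfg <- quick_cfg()
  qs <- quick_segment("BH+REST", seed = 14, cfg = cfg)
  rs <- build_regressors(detect_end_tidal(qs$co2$trace), qs$protocol)
  m <- qs$atlas$brain_mask
  f1 <- cvr_lag_opt(qs$bold$bold, rs, m, motion = qs$bold$motion)
  f2 <- cvr_lag_opt(qs$bold$bold * 3.7, rs, m, motion = qs$bold$motion)
  expect_equal(f2$cvr_amp[m], f1$cvr_amp[m], tolerance = 1e-9)
  expect_equal(f2$lag_s[m], f1$lag_s[m])
})

test_that("rest-only segments recover amplitude worse than breath-hold at matched noise", {
  cfg <- quick_cfg() # tSNR 50 for both segments
  atl <- quick_atlas(cfg)
  err <- sapply(c("BH+REST", "REST"), function(sg) {
    med <- sapply(1:3, function(s) {
      qs <- quick_segment(sg, seed = 20 + s, cfg = cfg, atlas_obj = atl)
      rs <- build_regressors(detect_end_tidal(qs$co2$trace), qs$protocol)
      fit <- cvr_lag_opt(qs$bold$bold, rs, atl$brain_mask,
                         motion = qs$bold$motion)
      recovery_metrics(fit, qs$truth)$median_rel_amp_err
    })
    median(med)
  })
  expect_gt(err["REST"], err["BH+REST"])
})

test_that("near-zero-mean voxels are flagged with NaN amplitude", {
  cfg <- quick_cfg(tsnr = Inf, co2_noise_sd = 0)
  qs <- quick_segment("BH+REST", seed = 15, cfg = cfg)
  rs <- build_regressors(detect_end_tidal(qs$co2$trace), qs$protocol)
  bold <- qs$bold$bold
  m <- qs$atlas$brain_mask
  vox <- which(m)[1]
  idx <- arrayInd(vox, dim(m))
  bold[idx[1], idx[2], idx[3], ] <- 0
  fit <- cvr_no_opt(bold, rs, m, motion = qs$bold$motion)
  expect_true(is.nan(fit$cvr_amp[idx[1], idx[2], idx[3]]))
  expect_true(fit$mean_flag[idx[1], idx[2], idx[3]])
})
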