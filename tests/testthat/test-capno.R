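test_that("end-tidal detection recovers the planted envelope exactly at zero noise", {
  p <- make_protocol("BH+REST", rest_duration_s = 300)
  sim <- simulate_co2_trace(p, rest_fluct_sd = 1.2, noise_sd = 0,
                            sample_rate_hz = 250, seed = 4)
  pet <- detect_end_tidal(sim$trace)
  expect_equal(length(pet$peak_times_s), nrow(sim$petco2_true))
  expect_equal(pet$peak_times_s, sim$petco2_true$time_s, tolerance = 1e-12)
  expect_equal(pet$petco2_mmhg, sim$petco2_true$petco2_mmhg,
               tolerance = 1e-12)
  expect_true(all(diff(pet$peak_times_s) > 0))
})

test_that("detection stays close to truth under sensor noise", {
  p <- make_protocol("REST", rest_duration_s = 120)
  sim <- simulate_co2_trace(p, noise_sd = 0.1, sample_rate_hz = 250, seed = 5)
  pet <- detect_end_tidal(sim$trace)
  expect_equal(length(pet$peak_times_s), nrow(sim$petco2_true))
  expect_lt(max(abs(pet$petco2_mmhg - sim$petco2_true$petco2_mmhg)), 0.5)
})

test_that("a flat trace raises a no-breaths error", {
  tr <- co2_trace(seq(0, 10, by = 0.01), rep(40, 1001), 100, numeric(0))
  expect_error(detect_end_tidal(tr), "no breaths")
})

test_that("breath holds leave a gap in peaks and an elevated first post-hold peak", {
  p <- make_protocol("BH+REST", rest_duration_s = 300)
  sim <- simulate_co2_trace(p, rest_fluct_sd = 0, noise_sd = 0,
                            sample_rate_hz = 250, seed = 2)
  pet <- detect_end_tidal(sim$trace)
  holds <- p$events[p$events$kind == "hold", ]
  for (h in seq_len(nrow(holds))) {
    h0 <- holds$onset_s[h]; h1 <- h0 + holds$duration_s[h]
    expect_false(any(pet$peak_times_s > h0 & pet$peak_times_s < h1))
    post <- pet$petco2_mmhg[which(pet$peak_times_s >= h1)[1]]
    expect_equal(post, sim$baseline_mmhg + 9, tolerance = 1e-9)
  }
})

test_that("canonical HRF has the expected shape", {
  h <- canonical_hrf(0.1)
  expect_gt(sum(h) * 0.1, 0)
  expect_equal(sum(h) * 0.1, 1, tolerance = 1e-12) # unit area default
  peak_t <- (which.max(h) - 1) * 0.1
  expect_true(peak_t >= 4.5 && peak_t <= 6.5)
  expect_lt(min(h), 0)                 # undershoot present
  expect_lt(abs(min(h)), max(h) / 3)   # single dominant positive lobe
  hp <- canonical_hrf(0.1, normalize = "peak")
  expect_equal(max(hp), 1)
})

test_that("HRF sampling is consistent across refinements", {
  h1 <- canonical_hrf(0.1); h3 <- canonical_hrf(0.3)
  common <- seq(0, 32, by = 0.3)
  idx1 <- match(round(common, 6), round(seq(0, 32, by = 0.1), 6))
  expect_equal(h1[idx1] / max(h1), as.numeric(h3) / max(h3),
               tolerance = 2e-3)
})

test_that("zero delta gives identically zero regressors and the grid includes lag 0", {
  p <- make_protocol("REST", rest_duration_s = 120)
  peaks <- data.frame(time_s = seq(2, 118, by = 4), petco2_mmhg = 40)
  rs <- build_regressors(petco2_series(peaks), p)
  expect_equal(nrow(rs$regressors), 2 * (15 / 0.3) + 1)
  expect_equal(sum(abs(rs$lags_s) < 1e-12), 1L)
  expect_equal(rs$lags_s, -rev(rs$lags_s))
  expect_true(all(rs$regressors == 0))
  expect_equal(rs$baseline_mmhg, 40)
})

test_that("adjacent lag rows are one-sample shifts when TR equals the lag step", {
  p <- make_protocol("REST", rest_duration_s = 60, tr_s = 0.3, n_discard = 0)
  set.seed(1)
  peaks <- data.frame(time_s = seq(1, 59, by = 4),
                      petco2_mmhg = 40 + rnorm(15))
  rs <- build_regressors(petco2_series(peaks), p, lag_limit_s = 3)
  k0 <- which(rs$lags_s == 0)
  n <- ncol(rs$regressors)
  # a positive lag delays the regressor by one sample, a negative one
  # advances it; composing the two returns the unshifted row (interior)
  expect_equal(rs$regressors[k0 + 1, 2:n], rs$regressors[k0, 1:(n - 1)],
               tolerance = 1e-9)
  expect_equal(rs$regressors[k0 - 1, 1:(n - 1)], rs$regressors[k0, 2:n],
               tolerance = 1e-9)
})

test_that("lag-0 row matches a brute-force dense convolution oracle", {
  p <- make_protocol("REST", rest_duration_s = 120)
  set.seed(3)
  peaks <- data.frame(time_s = sort(runif(30, 1, 119)),
                      petco2_mmhg = 40 + cumsum(rnorm(30, 0, 0.5)))
  rs <- build_regressors(petco2_series(peaks), p)
  # oracle: O(n^2) direct convolution on the same fine grid
  dt <- 0.3
  h <- canonical_hrf(dt)
  tf <- seq(floor((12 - 15 - 32 - dt) / dt) * dt,
            ceiling((p$duration_s - p$tr_s + 15 + dt) / dt) * dt, by = dt)
  tide <- approx(peaks$time_s, peaks$petco2_mmhg, xout = tf, rule = 2)$y
  delta <- tide - rs$baseline_mmhg
  conv <- vapply(seq_along(delta), function(i) {
    j <- seq_len(min(i, length(h)))
    sum(delta[i - j + 1] * h[j]) * dt
  }, numeric(1))
  oracle <- approx(tf, conv, xout = volume_times(p))$y
  expect_equal(as.numeric(rs$regressors[which(rs$lags_s == 0), ]), oracle,
               tolerance = 1e-9)
})

test_that("regressor construction is linear in the end-tidal excursion", {
  p <- make_protocol("REST", rest_duration_s = 120)
  set.seed(4)
  v <- rnorm(30)
  mk <- function(a) petco2_series(data.frame(time_s = seq(2, 118, length.out = 30),
                                             petco2_mmhg = a * v))
  r1 <- build_regressors(mk(1), p, baseline_mmhg = 0)
  r3 <- build_regressors(mk(3), p, baseline_mmhg = 0)
  expect_equal(3 * r1$regressors, r3$regressors, tolerance = 1e-9)
})

test_that("lag step must divide the lag limit", {
  p <- make_protocol("REST", rest_duration_s = 120)
  peaks <- petco2_series(data.frame(time_s = seq(2, 118, by = 4),
                                    petco2_mmhg = 40))
  expect_error(build_regressors(peaks, p, lag_limit_s = 1, lag_step_s = 0.3),
               "divide")
})
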