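test_that("gray-matter median matches a sort oracle and ignores NaN", {
  m <- array(0, c(4, 4, 2))
  m[] <- seq_along(m)
  mask <- array(FALSE, c(4, 4, 2)); mask[1:3, , ] <- TRUE
  v <- sort(m[mask])
  n <- length(v)
  mid <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  expect_equal(as.numeric(gm_median(m, mask)), mid)
  expect_equal(as.numeric(gm_median(array(7, c(4, 4, 2)), mask)), 7)
  # NaN voxels inside the mask are excluded, not propagated
  m2 <- m; m2[4, 1, 1] <- NaN
  mask2 <- mask; mask2[4, 1, 1] <- TRUE
  expect_equal(as.numeric(gm_median(m2, mask2)), as.numeric(gm_median(m, mask)))
  expect_equal(attr(gm_median(m2, mask2), "n_excluded"), 1L)
  expect_error(gm_median(m, array(FALSE, c(4, 4, 2))), "empty")
})

test_that("parcel means recover piecewise constants and 96 parcels from 48 regions", {
  atl <- make_atlas(c(24, 24, 12), 48)
  expect_equal(atl$n_parcels, 96L)
  vals <- seq_len(96) * 1.5
  vol <- parcel_paint(atl, vals)
  tab <- parcel_means(vol, atl)
  expect_equal(nrow(tab), 96L)
  expect_equal(tab$parcel_mean, vals, tolerance = 1e-12)
  expect_true(all(tab$n_voxels >= 1))
  # voxel order invariance: means depend only on label membership
  expect_error(parcel_means(vol[1:10, , ], atl), "grid")
})

test_that("Cook's distance matches a leave-one-out refit oracle to 1e-10", {
  set.seed(11)
  x <- rnorm(12); y <- 1 + 2 * x + rnorm(12, 0, 0.5)
  D <- cooks_distance(x, y)
  loo_oracle <- function(x, y) {
    n <- length(x)
    fit <- lm(y ~ x)
    s2 <- sum(resid(fit)^2) / (n - 2)
    yhat <- fitted(fit)
    vapply(seq_len(n), function(i) {
      fi <- lm(y[-i] ~ x[-i])
      yhat_i <- coef(fi)[1] + coef(fi)[2] * x
      sum((yhat - yhat_i)^2) / (2 * s2)
    }, numeric(1))
  }
  expect_equal(D, loo_oracle(x, y), tolerance = 1e-10)
  # duplicating every point roughly halves D (exact finite-n relation:
  # leverages halve, and the residual variance df changes n-2 -> 2n-2)
  n <- length(x)
  D2 <- cooks_distance(rep(x, 2), rep(y, 2))
  h <- 1 / n + (x - mean(x))^2 / sum((x - mean(x))^2)
  expected_ratio <- 0.5 * (n - 1) / (n - 2) * (1 - h)^2 / (1 - h / 2)^2
  expect_equal(D2[1:12] / D, expected_ratio, tolerance = 1e-10)
  expect_gt(cor(D2[1:12], D, method = "spearman"), 0.9)
  expect_error(cooks_distance(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("a point on the common line has near-zero Cook's distance", {
  x <- c(1:8, 4.5)
  y <- 2 * x + 1
  y[9] <- 2 * 4.5 + 1
  y[1:8] <- y[1:8] + rnorm(8, 0, 0.3)
  D <- cooks_distance(x, y)
  expect_lt(D[9], max(D[1:8]))
})

test_that("between-subject correlation: exact line, outlier flagging", {
  x <- seq(1, 9)
  r <- correlate_between_subjects(x, 2 * x + 1, remove_influential = FALSE)
  expect_equal(r$r, 1, tolerance = 1e-12)
  # one gross high-leverage outlier in an otherwise perfect relation
  y <- 2 * x + 1; y[9] <- 60
  rr <- correlate_between_subjects(x, y)
  expect_true(9 %in% rr$removed_indices)
  expect_equal(rr$removal_rule, "cooks_4_over_n")
  expect_gt(rr$r, cor(x, y)) # screening restores the relation
  expect_equal(rr$unscreened$n, 9)
})

test_that("between-subject test holds its type-I error at n = 9", {
  set.seed(12)
  nrep <- 10000
  hits <- 0L
  for (i in seq_len(nrep)) {
    p <- correlate_between_subjects(rnorm(9), rnorm(9),
                                    remove_influential = FALSE)$unscreened$p
    hits <- hits + (p < 0.05)
  }
  rate <- hits / nrep
  expect_gt(rate, 0.04)
  expect_lt(rate, 0.06)
})

test_that("spatial rank correlation is 1 under monotone transforms", {
  set.seed(13)
  x <- rnorm(96)
  r <- correlate_spatial(x, exp(x), remove_outlier_parcels = FALSE)
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_true(r$significant)
  # invariance of rho under monotone transform of either input
  y <- rnorm(96)
  r1 <- correlate_spatial(x, y, remove_outlier_parcels = FALSE)
  r2 <- correlate_spatial(exp(x), y, remove_outlier_parcels = FALSE)
  expect_equal(r1$r, r2$r, tolerance = 1e-12)
  expect_error(correlate_spatial(x[1:5], y[1:5]), "at least 10")
})

test_that("outlier parcels are screened on ranks and reduce n_used", {
  set.seed(14)
  x <- rnorm(96); y <- 0.6 * x + 0.8 * rnorm(96)
  r <- correlate_spatial(x, y)
  expect_equal(r$n_used, 96 - length(r$removed_indices))
  rx <- rank(x); ry <- rank(y)
  expect_equal(sort(r$removed_indices),
               sort(which(cooks_distance(rx, ry) > 4 / 96)))
})

test_that("critical values follow the Fisher-Z normal approximation", {
  cv <- adjusted_critical_value(96)
  expect_equal(round(cv$z_crit, 2), 1.96)
  expect_equal(cv$r_threshold, tanh(qnorm(0.975) / sqrt(93)), tolerance = 1e-12)
  # numeric inversion oracle: the threshold solves atanh(r)*sqrt(n-3) = z
  root <- uniroot(function(r) atanh(r) * sqrt(93) - qnorm(0.975),
                  c(1e-6, 0.999), tol = 1e-12)$root
  expect_equal(cv$r_threshold, root, tolerance = 1e-9)
  # removing parcels strictly raises the required |rho|
  th <- vapply(c(96, 90, 80, 20), function(n)
    adjusted_critical_value(n)$r_threshold, numeric(1))
  expect_true(all(diff(th) > 0))
})

test_that("Fisher Z round-trips and standardizes correctly", {
  r <- seq(-0.999, 0.999, length.out = 21)
  expect_equal(tanh(fisher_z(r)), r, tolerance = 1e-12)
  expect_equal(fisher_z(0.5, n = 96), atanh(0.5) * sqrt(93))
})

test_that("influence screening is idempotent at one pass", {
  set.seed(15)
  x <- rnorm(40); y <- x + rnorm(40, 0, 0.4); y[7] <- 8
  r1 <- correlate_spatial(x, y)
  keep <- setdiff(seq_along(x), r1$removed_indices)
  # the documented contract is a single screening pass on the full data
  r2 <- correlate_spatial(x[keep], y[keep], remove_outlier_parcels = FALSE)
  expect_equal(r2$r, r1$r, tolerance = 1e-12)
})
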